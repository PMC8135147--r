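#' Cohen's d treatment effect size between arms
#'
#' Standardized mean difference with the classic pooled standard deviation
#' (degrees-of-freedom denominator `n1 + n2 - 2`):
#' `d = (mean(placebo) - mean(treatment)) / sd_pooled`. Lower week-6 scores
#' are better, so a positive d means the treatment arm did better.
#'
#' @param treatment_outcomes,placebo_outcomes Numeric outcome vectors, at
#'   least two values each.
#' @return Cohen's d, a single number.
#' @export
#' @examples
#' cohens_d(c(6, 8), c(10, 12))  # 2.828...
cohens_d <- function(treatment_outcomes, placebo_outcomes) {
  t <- treatment_outcomes[!is.na(treatment_outcomes)]
  p <- placebo_outcomes[!is.na(placebo_outcomes)]
  if (length(t) < 2 || length(p) < 2) {
    stop("need at least 2 outcomes per arm", call. = FALSE)
  }
  sp2 <- ((length(t) - 1) * stats::var(t) + (length(p) - 1) * stats::var(p)) /
    (length(t) + length(p) - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  (mean(p) - mean(t)) / sqrt(sp2)
}

#' Binary classification metrics against the PAI labels
#'
#' Accuracy, F1 (positive class `treatment_indicated`), AUC from the
#' predicted indicated-probabilities, and the confusion matrix (true label
#' in rows, predicted in columns). AUC is computed with `pROC` with a fixed
#' direction (higher probability means indicated), never auto-flipped; it is
#' `NA` when the truth has a single class.
#'
#' @param truth True (PAI) labels.
#' @param predicted Predicted (rule-list) labels.
#' @param prob_indicated Predicted probability of `treatment_indicated`.
#' @return A list with `accuracy`, `f1`, `auc`, and `confusion`.
#' @export
classification_metrics <- function(truth, predicted, prob_indicated) {
  cls <- brl_classes()
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(prob_indicated))
  truth <- factor(truth, levels = cls)
  predicted <- factor(predicted, levels = cls)
  confusion <- table(truth = truth, predicted = predicted)
  accuracy <- mean(truth == predicted)
  tp <- confusion[1, 1]
  fp <- confusion[2, 1]
  fn <- confusion[1, 2]
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  auc <- if (length(unique(truth)) < 2) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(
      response = truth, predictor = prob_indicated,
      levels = c("rest_indicated", "treatment_indicated"),
      direction = "<", quiet = TRUE)))
  }
  list(accuracy = accuracy, f1 = f1, auc = auc, confusion = confusion)
}

make_stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the rule-list classifier
#'
#' Folds are stratified by the PAI label. For each fold a rule list is
#' learned on the training 80% (predicates and antecedents are mined on the
#' training rows only) and applied to the held-out 20%; no test row
#' influences its fold's training. Per-fold train and test accuracy / AUC /
#' F1 are reported together with pooled metrics over the union of test
#' predictions and the pooled test confusion matrix.
#'
#' @param dataset A LOCF-complete `trial_dataset`.
#' @param labels Data frame `patient_id, label` (from [pai_labels()]).
#' @param hyper A [brl_hyper()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and per-fold samplers.
#' @param n_boot Bootstrap resamples for per-fold rule CIs; 0 skips them.
#' @return An object of class `cv_report`: `fold_lists`, `fold_metrics`
#'   (data frame), `pooled` (metrics list incl. confusion matrix),
#'   `test_labels` (per-patient test-fold predictions), `k`, `seed`.
#' @export
kfold_cv <- function(dataset, labels, hyper = brl_hyper(), k = 5,
                     seed = 1L, n_boot = 0) {
  stopifnot(inherits(dataset, "trial_dataset"), k >= 2)
  merged <- merge_labels(dataset, labels)
  features <- merged$features
  y <- merged$label
  fold <- make_stratified_folds(y, k, seed)
  for (f in seq_len(k)) {
    if (length(unique(y[fold != f])) < 2 || !any(fold == f)) {
      stop("fold ", f, " leaves a single class in training; ",
           "try a different seed", call. = FALSE)
    }
  }
  fold_lists <- vector("list", k)
  rows <- list()
  test_pred <- data.frame(patient_id = merged$patient_id, fold = fold,
                          truth = y, label = NA_character_,
                          prob_indicated = NA_real_,
                          stringsAsFactors = FALSE)
  for (f in seq_len(k)) {
    train <- fold != f
    rl <- brl_fit(features[train, , drop = FALSE], y[train], hyper,
                  seed = seed + 7919L * f, n_boot = n_boot)
    fold_lists[[f]] <- rl
    ptr <- predict(rl, features[train, , drop = FALSE])
    pte <- predict(rl, features[!train, , drop = FALSE])
    mtr <- classification_metrics(y[train], ptr$label, ptr$prob_indicated)
    mte <- classification_metrics(y[!train], pte$label, pte$prob_indicated)
    rows[[f]] <- data.frame(
      fold = f,
      train_accuracy = mtr$accuracy, train_auc = mtr$auc, train_f1 = mtr$f1,
      test_accuracy = mte$accuracy, test_auc = mte$auc, test_f1 = mte$f1)
    test_pred$label[!train] <- pte$label
    test_pred$prob_indicated[!train] <- pte$prob_indicated
  }
  pooled <- classification_metrics(test_pred$truth, test_pred$label,
                                   test_pred$prob_indicated)
  structure(list(fold_lists = fold_lists,
                 fold_metrics = do.call(rbind, rows),
                 pooled = pooled,
                 test_labels = test_pred,
                 k = k, seed = seed),
            class = "cv_report")
}

merge_labels <- function(dataset, labels) {
  stopifnot(is.data.frame(labels),
            all(c("patient_id", "label") %in% names(labels)))
  keep <- dataset$patient_id %in% labels$patient_id
  dataset <- dataset[keep, , drop = FALSE]
  lab <- labels$label[match(dataset$patient_id, labels$patient_id)]
  if (anyNA(lab)) stop("labels missing for some patients", call. = FALSE)
  list(features = brl_features(dataset), label = lab,
       patient_id = dataset$patient_id,
       arm = dataset$arm, week_6 = dataset$week_6)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$k, "-fold stratified cross-validation\n", sep = "")
  print(round(colMeans(x$fold_metrics[, -1]), 3))
  cat("pooled test: accuracy ", round(x$pooled$accuracy, 3),
      ", AUC ", round(x$pooled$auc, 3),
      ", F1 ", round(x$pooled$f1, 3), "\n", sep = "")
  invisible(x)
}

#' Repeated-subgrouping treatment-effect improvement test
#'
#' Quantifies whether rule-list patient selection improves the treatment
#' effect. The PAI labels are computed once and held fixed; the full
#' rule-list procedure (stratified fold split + MCMC) is then repeated
#' `n_repeats` times with distinct seeds. In each repeat every patient gets
#' the out-of-fold test label from that repeat's cross-validation, and
#' Cohen's d between actual arms is computed from actual week-6 totals
#' within the repeat's treatment-indicated subgroup. The distribution of
#' repeat d's is compared with the full-sample d by a two-sided one-sample
#' t-test.
#'
#' @param dataset A LOCF-complete `trial_dataset`.
#' @param labels PAI labels (`patient_id`, `label`).
#' @param hyper A [brl_hyper()].
#' @param k CV folds per repeat.
#' @param n_repeats Number of repeats (at least 2; the t-test is undefined
#'   for one).
#' @param seed Integer base seed; repeat r uses `seed + r`.
#' @return An object of class `effect_report`: `d_full`, `d_subgroup` (from
#'   the first repeat), `d_distribution`, `t_statistic`, `p_value`,
#'   `n_repeats_used`, `n_excluded`.
#' @export
effect_improvement_test <- function(dataset, labels, hyper = brl_hyper(),
                                    k = 5, n_repeats = 100, seed = 1L) {
  if (n_repeats < 2) {
    stop("n_repeats must be at least 2 for the one-sample t-test",
         call. = FALSE)
  }
  merged <- merge_labels(dataset, labels)
  trt <- merged$arm == "treatment"
  d_full <- cohens_d(merged$week_6[trt], merged$week_6[!trt])
  ds <- numeric(0)
  n_excluded <- 0L
  for (r in seq_len(n_repeats)) {
    cv <- kfold_cv(dataset, labels, hyper, k = k, seed = seed + r)
    sub <- cv$test_labels$label == "treatment_indicated"
    n_t <- sum(sub & trt)
    n_p <- sum(sub & !trt)
    if (n_t < 2 || n_p < 2) {
      message("repeat ", r, ": treatment-indicated subgroup has ", n_t,
              "/", n_p, " patients per arm; excluded")
      n_excluded <- n_excluded + 1L
      next
    }
    ds <- c(ds, cohens_d(merged$week_6[sub & trt], merged$week_6[sub & !trt]))
  }
  if (length(ds) < 2) {
    stop("fewer than 2 usable repeats; increase n_repeats", call. = FALSE)
  }
  tt <- stats::t.test(ds, mu = d_full, alternative = "two.sided")
  structure(list(d_full = d_full,
                 d_subgroup = ds[1],
                 d_distribution = ds,
                 d_mean = mean(ds), d_sd = stats::sd(ds),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value,
                 n_repeats_used = length(ds),
                 n_excluded = n_excluded),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  cat("<effect_report>\n",
      "  full-sample Cohen's d = ", round(x$d_full, 3), "\n",
      "  subgroup d over ", x$n_repeats_used, " repeats: mean ",
      round(x$d_mean, 3), " (sd ", round(x$d_sd, 3), ")\n",
      "  two-sided one-sample t-test vs full-sample d: t = ",
      round(x$t_statistic, 2), ", p = ", format.pval(x$p_value, digits = 3),
      "\n", sep = "")
  if (x$n_excluded) cat("  (", x$n_excluded, " repeat(s) excluded)\n", sep = "")
  invisible(x)
}

#' Labeling-consistency histogram across fold rule lists
#'
#' Classifies every patient with each of the k fold rule lists and counts
#' how many times each patient was labeled treatment-indicated (0..k). The
#' counts are tabulated split by the patient's PAI label, so a consistent
#' classifier shows mass at 0 (PAI rest) and k (PAI indicated).
#'
#' @param fold_rule_lists The `fold_lists` from one [kfold_cv()] run.
#' @param dataset The `trial_dataset`.
#' @param labels PAI labels (`patient_id`, `label`).
#' @return An object of class `consistency_histogram`: a matrix with one row
#'   per PAI label and one column per count 0..k, plus `per_patient` counts.
#' @export
consistency_histogram <- function(fold_rule_lists, dataset, labels) {
  stopifnot(is.list(fold_rule_lists), length(fold_rule_lists) >= 1)
  merged <- merge_labels(dataset, labels)
  k <- length(fold_rule_lists)
  ind <- matrix(FALSE, nrow(merged$features), k)
  for (j in seq_len(k)) {
    ind[, j] <- predict(fold_rule_lists[[j]],
                        merged$features)$label == "treatment_indicated"
  }
  count <- rowSums(ind)
  tab <- table(factor(merged$label, levels = brl_classes()),
               factor(count, levels = 0:k))
  counts <- matrix(as.integer(tab), nrow = 2,
                   dimnames = list(brl_classes(), as.character(0:k)))
  structure(list(counts = counts,
                 per_patient = data.frame(patient_id = merged$patient_id,
                                          pai_label = merged$label,
                                          times_indicated = count,
                                          stringsAsFactors = FALSE),
                 k = k),
            class = "consistency_histogram")
}

#' @export
print.consistency_histogram <- function(x, ...) {
  cat("<consistency_histogram> times labeled treatment-indicated across ",
      x$k, " rule lists\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Final rule-list model trained on the full labeled dataset
#'
#' Trains a single rule list on all rows (the exportable model) with
#' bootstrap CIs, and reports accuracy / AUC / F1 computed on the training
#' data itself, flagged as in-sample.
#'
#' @param dataset A LOCF-complete `trial_dataset`.
#' @param labels PAI labels (`patient_id`, `label`).
#' @param hyper A [brl_hyper()].
#' @param seed Optional seed overriding `hyper$seed`.
#' @param n_boot Bootstrap resamples for rule CIs.
#' @return A list of class `brl_final`: `rule_list` and `metrics` (with
#'   `in_sample = TRUE`).
#' @export
final_model <- function(dataset, labels, hyper = brl_hyper(), seed = NULL,
                        n_boot = 1000) {
  merged <- merge_labels(dataset, labels)
  rl <- brl_fit(merged$features, merged$label, hyper, seed = seed,
                n_boot = n_boot)
  pred <- predict(rl, merged$features)
  metrics <- classification_metrics(merged$label, pred$label,
                                    pred$prob_indicated)
  metrics$in_sample <- TRUE
  structure(list(rule_list = rl, metrics = metrics), class = "brl_final")
}

#' @export
print.brl_final <- function(x, ...) {
  print(x$rule_list)
  cat("in-sample: accuracy ", round(x$metrics$accuracy, 3),
      ", AUC ", round(x$metrics$auc, 3),
      ", F1 ", round(x$metrics$f1, 3), "\n", sep = "")
  invisible(x)
}

#' Does a rule list mention a given predicate?
#'
#' Utility for rule-recovery checks: tests whether any (non-default) rule of
#' the list contains a predicate on `feature` with operator `op` and cutoff
#' `cutoff`.
#'
#' @param rule_list A `brl_rule_list`.
#' @param feature Feature name.
#' @param op Operator string.
#' @param cutoff Cutoff value.
#' @return `TRUE` or `FALSE`.
#' @export
rule_list_mentions <- function(rule_list, feature, op = ">=", cutoff = 3) {
  for (rule in rule_list$rules) {
    p <- rule$predicates
    if (any(p$feature == feature & p$op == op & p$cutoff == cutoff)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Does a rule list cut an ordinal feature at a given cutpoint?
#'
#' For ordinal items the predicates `feature >= c` and `feature <= c - 1`
#' split the patients at the identical boundary -- one phrases the rule for
#' the treatment-indicated class, the other for its complement. A planted
#' rule "item >= 3" therefore counts as recovered when the final list uses
#' either form of the cutpoint between `c - 1` and `c`.
#'
#' @param rule_list A `brl_rule_list`.
#' @param feature Feature name.
#' @param cutoff Ordinal cutoff `c` of the planted `>= c` rule.
#' @return `TRUE` or `FALSE`.
#' @export
rule_recovers_cutpoint <- function(rule_list, feature, cutoff = 3) {
  rule_list_mentions(rule_list, feature, ">=", cutoff) ||
    rule_list_mentions(rule_list, feature, "<=", cutoff - 1)
}
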