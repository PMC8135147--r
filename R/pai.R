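#' Specification of the PAI outcome-regression model
#'
#' The Personalized Advantage Index (PAI) model is a penalized linear
#' regression of the week-6 total symptom score on baseline features, the
#' randomized arm, and arm-by-feature interactions. Hyperparameters are
#' chosen by inner k-fold cross-validated mean squared prediction error over
#' the full grid; the final model is refit on all rows.
#'
#' `alpha_grid` is the overall penalty strength and `l1_ratio_grid` the
#' lasso/ridge mixing weight, in the scikit-learn parameterization; these
#' map one-to-one onto glmnet's `lambda` and `alpha` (the two objectives are
#' identical), and the defaults are the grids used in the source analysis:
#' alpha in \{0.001, 0.01, 0.1, 1, 10\}, l1_ratio in \{0.1, 0.5, 0.9\}.
#'
#' @param include_interactions Include arm-by-feature interaction columns
#'   (the PAI counterfactual contrast is identically the arm coefficient
#'   without them).
#' @param include_baseline_total Keep the baseline total score as a
#'   predictor despite its collinearity with the item scores.
#' @param alpha_grid Penalty strengths searched.
#' @param l1_ratio_grid Mixing weights searched (1 = pure lasso).
#' @param inner_cv_folds Folds for the hyperparameter grid search.
#' @param convergence_thresh Coordinate-descent convergence threshold passed
#'   to the solver; tighten (e.g. `1e-20`) when near-exact coefficients are
#'   needed at vanishing penalties.
#' @param seed Seed for the inner CV fold assignment.
#' @return An object of class `pai_spec`.
#' @export
pai_spec <- function(include_interactions = TRUE,
                     include_baseline_total = TRUE,
                     alpha_grid = c(0.001, 0.01, 0.1, 1, 10),
                     l1_ratio_grid = c(0.1, 0.5, 0.9),
                     inner_cv_folds = 5,
                     convergence_thresh = 1e-10,
                     seed = 1L) {
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid > 0),
            length(l1_ratio_grid) >= 1,
            all(l1_ratio_grid >= 0 & l1_ratio_grid <= 1),
            inner_cv_folds >= 2)
  structure(list(
    include_interactions = isTRUE(include_interactions),
    include_baseline_total = isTRUE(include_baseline_total),
    alpha_grid = alpha_grid,
    l1_ratio_grid = l1_ratio_grid,
    inner_cv_folds = as.integer(inner_cv_folds),
    convergence_thresh = convergence_thresh,
    seed = as.integer(seed)
  ), class = "pai_spec")
}

#' Baseline feature names used by both modeling stages
#'
#' Age, sex, the 30 ordinal items, the baseline total score (optional), two
#' sleep visual-analogue scores, the social-performance score, and the
#' quality-of-life total.
#'
#' @param n_items Number of ordinal items.
#' @param include_baseline_total Include the baseline total score.
#' @return Character vector of feature (column) names.
#' @export
baseline_feature_names <- function(n_items = 30L, include_baseline_total = TRUE) {
  c("age", "sex", item_cols(n_items),
    if (include_baseline_total) "total_baseline",
    "vas_drowsiness", "vas_sleep_quality", "psp", "sqls")
}

#' Build the PAI design matrix and outcome vector
#'
#' Assembles `[features, arm, arm x features]` with arm coded treatment = 1,
#' placebo = 0, so the arm coefficient is directly the predicted
#' drug-minus-placebo contrast at zero covariates. Rows with any missing
#' baseline feature are dropped (the exclusions are reported by patient id
#' and recorded in the result); the outcome is the week-6 total and must be
#' complete, i.e. the dataset must already be LOCF-imputed.
#'
#' @param dataset A `trial_dataset` with no missing `week_6` values.
#' @param spec A [pai_spec()].
#' @return A list of class `pai_design` with elements `x` (matrix), `y`
#'   (outcome vector), `patient_id`, `arm01`, `manifest` (column-name
#'   manifest), and `excluded` (patient ids dropped for missing baselines).
#' @export
build_design_matrix <- function(dataset, spec = pai_spec()) {
  stopifnot(inherits(dataset, "trial_dataset"))
  n_items <- attr(dataset, "n_items") %||% 30L
  feats <- baseline_feature_names(n_items, spec$include_baseline_total)
  if (!all(dataset$arm %in% c("treatment", "placebo"))) {
    stop_validation("unknown arm value(s): ",
                    paste(setdiff(unique(dataset$arm),
                                  c("treatment", "placebo")), collapse = ", "))
  }
  fmat <- as.matrix(dataset[, feats, drop = FALSE])
  keep <- stats::complete.cases(fmat)
  excluded <- dataset$patient_id[!keep]
  if (length(excluded)) {
    message("dropping ", length(excluded),
            " patient(s) with missing baseline features: ",
            paste(excluded, collapse = ", "))
  }
  dataset <- dataset[keep, , drop = FALSE]
  fmat <- fmat[keep, , drop = FALSE]
  y <- dataset$week_6
  if (anyNA(y)) {
    stop_validation("missing week-6 outcome for patient(s) ",
                    paste(dataset$patient_id[is.na(y)], collapse = ", "),
                    "; run locf_impute() first")
  }
  arm01 <- as.numeric(dataset$arm == "treatment")
  x <- cbind(fmat, arm = arm01)
  manifest <- list(features = feats, arm = "arm", interactions = character(0))
  if (spec$include_interactions) {
    inter <- fmat * arm01
    colnames(inter) <- paste0("arm_x_", feats)
    x <- cbind(x, inter)
    manifest$interactions <- colnames(inter)
  }
  structure(list(x = x, y = y, patient_id = dataset$patient_id,
                 arm01 = arm01, manifest = manifest, excluded = excluded),
            class = "pai_design")
}

grid_table <- function(spec) {
  expand.grid(alpha = spec$alpha_grid, l1_ratio = spec$l1_ratio_grid,
              KEEP.OUT.ATTRS = FALSE)
}

glmnet_at <- function(x, y, l1_ratio, lambda_seq, thresh = 1e-10) {
  glmnet::glmnet(x, y, family = "gaussian", alpha = l1_ratio,
                 lambda = lambda_seq, standardize = TRUE,
                 thresh = thresh, maxit = 1e6)
}

#' Fit the PAI elastic-net outcome regression
#'
#' Grid-searches `(alpha, l1_ratio)` by `inner_cv_folds`-fold cross-validated
#' mean squared prediction error, then refits on all rows at the selected
#' pair (the model that produces the indication labels is trained on the
#' full sample by design). Coefficients are reported on the original feature
#' scale; features are standardized internally before penalization. Ties in
#' CV error are broken toward the first pair in grid order.
#'
#' @param design A `pai_design` from [build_design_matrix()].
#' @param spec The [pai_spec()] used to build the design.
#' @return An object of class `pai_fit` with the selected hyperparameters,
#'   intercept and coefficient vector, in-sample `r_squared` and
#'   `adjusted_r_squared` (adjusting for all design columns), and the CV
#'   error table.
#' @export
fit_outcome_model <- function(design, spec = pai_spec()) {
  stopifnot(inherits(design, "pai_design"))
  x <- design$x
  y <- design$y
  if (length(unique(y)) < 2) {
    stop("degenerate design: outcome has fewer than 2 distinct values",
         call. = FALSE)
  }
  n <- nrow(x)
  k <- min(spec$inner_cv_folds, n)
  folds <- withr::with_seed(spec$seed, sample(rep_len(seq_len(k), n)))
  lambda_seq <- sort(unique(spec$alpha_grid), decreasing = TRUE)
  grid <- grid_table(spec)

  cv_sse <- matrix(0, length(lambda_seq), length(spec$l1_ratio_grid),
                   dimnames = list(format(lambda_seq), format(spec$l1_ratio_grid)))
  for (f in seq_len(k)) {
    test <- folds == f
    for (j in seq_along(spec$l1_ratio_grid)) {
      fit <- glmnet_at(x[!test, , drop = FALSE], y[!test],
                       spec$l1_ratio_grid[j], lambda_seq,
                       spec$convergence_thresh)
      pred <- stats::predict(fit, newx = x[test, , drop = FALSE],
                             s = lambda_seq)
      cv_sse[, j] <- cv_sse[, j] + colSums((pred - y[test])^2)
    }
  }
  cv_mse <- cv_sse / n
  grid$cv_mse <- vapply(seq_len(nrow(grid)), function(i) {
    cv_mse[match(grid$alpha[i], lambda_seq),
           match(grid$l1_ratio[i], spec$l1_ratio_grid)]
  }, numeric(1))
  best <- which.min(grid$cv_mse)
  sel_alpha <- grid$alpha[best]
  sel_l1 <- grid$l1_ratio[best]

  full <- glmnet_at(x, y, sel_l1, lambda_seq, spec$convergence_thresh)
  beta <- as.numeric(stats::coef(full, s = sel_alpha))
  names(beta) <- c("(Intercept)", colnames(x))
  pred <- beta[1] + drop(x %*% beta[-1])
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  p <- ncol(x)
  adj_r2 <- if (n - p - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_

  structure(list(
    selected_alpha = sel_alpha,
    selected_l1_ratio = sel_l1,
    coefficients = beta,
    r_squared = r2,
    adjusted_r_squared = adj_r2,
    cv_table = grid,
    manifest = design$manifest,
    n = n,
    spec = spec
  ), class = "pai_fit")
}

#' @export
print.pai_fit <- function(x, ...) {
  nz <- sum(x$coefficients[-1] != 0)
  cat("<pai_fit> elastic net, n = ", x$n, "\n",
      "  selected alpha = ", format(x$selected_alpha),
      ", l1_ratio = ", format(x$selected_l1_ratio), "\n",
      "  R^2 = ", round(x$r_squared, 3),
      " (adjusted ", round(x$adjusted_r_squared, 3), "), ",
      nz, " nonzero coefficients\n", sep = "")
  invisible(x)
}

linear_predictor <- function(fit, x) {
  fit$coefficients[1] + drop(x %*% fit$coefficients[-1])
}

#' Predict actual and counterfactual outcomes and PAI scores
#'
#' Evaluates the fitted regression twice for every patient: once with the
#' arm (and every arm-interaction column) set to treatment and once set to
#' placebo. The PAI score is the treatment prediction minus the placebo
#' prediction -- a function of covariates only, so it does not depend on the
#' arm a patient was actually randomized to; negative scores mean a better
#' (lower) predicted score on drug. `predicted_actual` is the prediction
#' under the patient's randomized arm and `predicted_counterfactual` under
#' the other arm.
#'
#' @param fit A `pai_fit`.
#' @param design The `pai_design` the fit was trained on (or one built with
#'   the same spec on new data); the column manifests must match.
#' @return A data frame with columns `patient_id, arm, predicted_actual,
#'   predicted_counterfactual, pai_score`.
#' @export
predict_counterfactual <- function(fit, design) {
  stopifnot(inherits(fit, "pai_fit"), inherits(design, "pai_design"))
  if (!identical(fit$manifest, design$manifest)) {
    stop("design column manifest does not match the fitted model", call. = FALSE)
  }
  m <- design$manifest
  x_trt <- design$x
  x_trt[, m$arm] <- 1
  x_pbo <- design$x
  x_pbo[, m$arm] <- 0
  if (length(m$interactions)) {
    x_trt[, m$interactions] <- design$x[, m$features, drop = FALSE]
    x_pbo[, m$interactions] <- 0
  }
  pred_trt <- linear_predictor(fit, x_trt)
  pred_pbo <- linear_predictor(fit, x_pbo)
  on_trt <- design$arm01 == 1
  data.frame(
    patient_id = design$patient_id,
    arm = ifelse(on_trt, "treatment", "placebo"),
    predicted_actual = ifelse(on_trt, pred_trt, pred_pbo),
    predicted_counterfactual = ifelse(on_trt, pred_pbo, pred_trt),
    pai_score = pred_trt - pred_pbo,
    stringsAsFactors = FALSE
  )
}

#' Threshold PAI scores into indication labels
#'
#' Scans candidate thresholds 0, -step, -2 step, ... down to the smallest
#' score. At each threshold the treatment-indicated fraction is the fraction
#' of scores at or below it; the threshold whose fraction is closest to
#' `target_fraction` wins, with ties broken toward the largest (least
#' negative) threshold. If every score is positive no threshold can indicate
#' anyone: threshold 0 is returned with an empty indicated class and a
#' warning.
#'
#' @param scores Numeric PAI scores (finite).
#' @param step Scan step (default 0.5).
#' @param target_fraction Desired treatment-indicated fraction (default 0.5,
#'   giving balanced classes for the downstream classifier).
#' @return An object of class `pai_threshold`: `threshold`, `labels`
#'   (`treatment_indicated` / `rest_indicated`), `fraction`, and the scanned
#'   `candidates` table.
#' @export
select_threshold <- function(scores, step = 0.5, target_fraction = 0.5) {
  stopifnot(is.numeric(scores), all(is.finite(scores)), step > 0,
            target_fraction > 0, target_fraction < 1)
  label_at <- function(t) {
    ifelse(scores <= t, "treatment_indicated", "rest_indicated")
  }
  if (all(scores > 0)) {
    warning("all PAI scores are positive; no patient is treatment-indicated ",
            "at any scanned threshold", call. = FALSE)
    return(structure(list(threshold = 0, labels = label_at(0), fraction = 0,
                          candidates = data.frame(threshold = 0, fraction = 0)),
                     class = "pai_threshold"))
  }
  lowest <- -step * ceiling(-min(scores) / step)
  cand <- seq(0, lowest, by = -step)
  frac <- vapply(cand, function(t) mean(scores <= t), numeric(1))
  best <- which.min(abs(frac - target_fraction))  # first = largest threshold
  structure(list(threshold = cand[best], labels = label_at(cand[best]),
                 fraction = frac[best],
                 candidates = data.frame(threshold = cand, fraction = frac)),
            class = "pai_threshold")
}

#' @export
print.pai_threshold <- function(x, ...) {
  cat("<pai_threshold> ", format(x$threshold),
      " -> ", sum(x$labels == "treatment_indicated"), " treatment-indicated / ",
      sum(x$labels == "rest_indicated"), " rest-indicated (fraction ",
      round(x$fraction, 3), ")\n", sep = "")
  invisible(x)
}

#' Run the full PAI stage: fit, counterfactual scores, labels
#'
#' Convenience wrapper chaining [build_design_matrix()],
#' [fit_outcome_model()], [predict_counterfactual()] and
#' [select_threshold()].
#'
#' @param dataset A LOCF-complete `trial_dataset`.
#' @param spec A [pai_spec()].
#' @param step,target_fraction Passed to [select_threshold()].
#' @return An object of class `pai_result`: `fit`, `scores` (per-patient
#'   data frame with `label` appended), `threshold` (`pai_threshold`), and
#'   `excluded`.
#' @export
compute_pai <- function(dataset, spec = pai_spec(), step = 0.5,
                        target_fraction = 0.5) {
  design <- build_design_matrix(dataset, spec)
  fit <- fit_outcome_model(design, spec)
  scores <- predict_counterfactual(fit, design)
  thr <- select_threshold(scores$pai_score, step, target_fraction)
  scores$label <- thr$labels
  structure(list(fit = fit, scores = scores, threshold = thr,
                 excluded = design$excluded),
            class = "pai_result")
}

#' @export
print.pai_result <- function(x, ...) {
  print(x$fit)
  print(x$threshold)
  if (length(x$excluded)) {
    cat("  excluded for missing baselines: ", length(x$excluded),
        " patient(s)\n", sep = "")
  }
  invisible(x)
}

#' Extract the per-patient indication labels from a PAI result
#'
#' @param result A `pai_result`.
#' @return Data frame with columns `patient_id` and `label`.
#' @export
pai_labels <- function(result) {
  stopifnot(inherits(result, "pai_result"))
  result$scores[, c("patient_id", "label")]
}
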