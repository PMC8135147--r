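#' Configuration for the synthetic two-arm trial generator
#'
#' Builds the parameter set for [simulate_trial()]. Defaults emulate a 6-week
#' two-arm antipsychotic trial: two arms of 113 and 120 patients, 30
#' clinician-rated ordinal symptom items scored 1--7 (7 most severe) summed
#' to a total score, and a week-6 total-score endpoint whose drug-vs-placebo
#' benefit is concentrated in a latent subgroup defined by an OR-rule over
#' item cutoffs.
#'
#' Items are generated from a per-patient latent severity factor plus item
#' noise and discretized with fixed thresholds, which gives positive
#' inter-item correlation and a controllable planted-rule prevalence
#' (defaults give marginal `P(item >= 3) = 0.30` per item and a subgroup
#' prevalence near 47%).
#'
#' @param n_treatment,n_placebo Patients per arm (each at least 2).
#' @param n_items Number of ordinal symptom items (default 30).
#' @param planted_rule List of predicates `list(item =, cutoff =)` combined
#'   by OR; a patient is in the responsive subgroup when any listed item is
#'   at or above its cutoff. Default: items 22 and 27 at cutoff 3.
#' @param effect_in_subgroup,effect_outside_subgroup Mean extra week-6
#'   total-score reduction (points) on drug relative to placebo, inside and
#'   outside the planted subgroup.
#' @param placebo_change Mean week-6 total-score reduction (points) in the
#'   placebo arm (applies to both arms as the non-specific response).
#' @param noise_sd Standard deviation (points) of week-6 outcome noise;
#'   intermediate weeks use `noise_sd / 2`.
#' @param dropout_rate Fraction in `[0, 1)` of patients who drop out before
#'   week 6; dropouts have a uniform last-observed week in 1..5 and missing
#'   values afterwards.
#' @param dropout_informative If `TRUE`, dropout probability increases with a
#'   poorer (higher) underlying week-6 score instead of being independent of
#'   outcome.
#' @param item_correlation Shared-factor loading (squared correlation between
#'   the latent severity factor and each item's latent scale), in `[0, 1)`.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return An object of class `trial_config`.
#' @export
#' @examples
#' cfg <- trial_config(n_treatment = 20, n_placebo = 20, seed = 1)
#' trial <- simulate_trial(cfg)
trial_config <- function(n_treatment = 113,
                         n_placebo = 120,
                         n_items = 30,
                         planted_rule = list(list(item = 22, cutoff = 3),
                                             list(item = 27, cutoff = 3)),
                         effect_in_subgroup = 12,
                         effect_outside_subgroup = 3,
                         placebo_change = 6,
                         noise_sd = 10,
                         dropout_rate = 0.3,
                         dropout_informative = FALSE,
                         item_correlation = 0.3,
                         seed = 1L) {
  stopifnot(n_treatment >= 2, n_placebo >= 2, n_items >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            item_correlation >= 0, item_correlation < 1,
            noise_sd >= 0, length(planted_rule) >= 1)
  for (p in planted_rule) {
    if (!all(c("item", "cutoff") %in% names(p))) {
      stop("each planted_rule predicate needs 'item' and 'cutoff'", call. = FALSE)
    }
    if (p$item < 1 || p$item > n_items) {
      stop("planted_rule item index out of range 1..n_items", call. = FALSE)
    }
    if (p$cutoff < 2 || p$cutoff > 7) {
      stop("planted_rule cutoff must be in 2..7", call. = FALSE)
    }
  }
  structure(list(
    n_treatment = as.integer(n_treatment),
    n_placebo = as.integer(n_placebo),
    n_items = as.integer(n_items),
    planted_rule = planted_rule,
    effect_in_subgroup = effect_in_subgroup,
    effect_outside_subgroup = effect_outside_subgroup,
    placebo_change = placebo_change,
    noise_sd = noise_sd,
    dropout_rate = dropout_rate,
    dropout_informative = isTRUE(dropout_informative),
    item_correlation = item_correlation,
    seed = as.integer(seed)
  ), class = "trial_config")
}

# Fixed latent-normal thresholds: score = 1 + #(latent > break).
# Chosen so marginal P(score >= k) = .75, .30, .15, .06, .02, .005 for k=2..7.
item_breaks <- function() {
  stats::qnorm(c(0.25, 0.70, 0.85, 0.94, 0.98, 0.995))
}

item_cols <- function(n_items = 30L) sprintf("item_%02d", seq_len(n_items))
week_cols <- function() sprintf("week_%d", 0:6)

#' Evaluate a planted OR-rule on an item-score matrix
#' @noRd
planted_membership <- function(items, planted_rule) {
  hit <- rep(FALSE, nrow(items))
  for (p in planted_rule) hit <- hit | (items[, p$item] >= p$cutoff)
  hit
}

#' Simulate a randomized two-arm trial with a planted responsive subgroup
#'
#' Generates a complete per-patient dataset: demographics, 30 baseline
#' ordinal items (1--7) with positive inter-item correlation, auxiliary
#' scale scores, a randomized arm, weekly total-score trajectories from
#' week 0 (baseline) to week 6, dropout with missing weekly values, and the
#' latent ground-truth subgroup label implied by the planted rule.
#'
#' The week-6 mean change is `-placebo_change` for placebo patients and
#' `-placebo_change - effect` for treated patients, where `effect` is
#' `effect_in_subgroup` inside the planted subgroup and
#' `effect_outside_subgroup` elsewhere. Weekly values interpolate linearly
#' between baseline and the week-6 target with independent noise. Auxiliary
#' scales (VAS drowsiness / sleep quality, PSP, SQLS) and demographics are
#' generated independent of outcome.
#'
#' @param config A [trial_config()].
#' @param seed Optional integer overriding `config$seed`.
#' @return A `trial_dataset`: a data frame with one row per patient and
#'   columns `patient_id, age, sex, item_01..item_30, total_baseline,
#'   vas_drowsiness, vas_sleep_quality, psp, sqls, arm, week_0..week_6,
#'   latent_label`.
#' @export
simulate_trial <- function(config = trial_config(), seed = NULL) {
  stopifnot(inherits(config, "trial_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  withr::with_seed(seed, simulate_trial_impl(config))
}

simulate_trial_impl <- function(config) {
  n <- config$n_treatment + config$n_placebo
  k <- config$n_items
  rho <- config$item_correlation

  severity <- stats::rnorm(n)
  latent <- sqrt(rho) * severity +
    sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
  br <- item_breaks()
  items <- matrix(1L, n, k)
  for (b in br) items <- items + (latent > b)
  storage.mode(items) <- "integer"
  colnames(items) <- item_cols(k)

  subgroup <- planted_membership(items, config$planted_rule)
  if (!any(subgroup) || all(subgroup)) {
    stop("planted rule selects ", sum(subgroup), " of ", n, " patients; ",
         "adjust planted_rule cutoffs or sample sizes so the subgroup ",
         "fraction lies strictly between 0 and 1", call. = FALSE)
  }

  arm <- sample(rep(c("treatment", "placebo"),
                    c(config$n_treatment, config$n_placebo)))
  baseline_total <- as.integer(rowSums(items))

  effect <- ifelse(subgroup, config$effect_in_subgroup,
                   config$effect_outside_subgroup)
  delta <- -config$placebo_change - (arm == "treatment") * effect

  weekly <- matrix(NA_real_, n, 7, dimnames = list(NULL, week_cols()))
  weekly[, 1] <- baseline_total
  for (w in 1:5) {
    weekly[, w + 1] <- baseline_total + (w / 6) * delta +
      stats::rnorm(n, 0, config$noise_sd / 2)
  }
  weekly[, 7] <- baseline_total + delta + stats::rnorm(n, 0, config$noise_sd)

  if (config$dropout_rate > 0) {
    if (config$dropout_informative) {
      # poorer underlying response -> higher dropout probability
      z <- as.numeric(scale(weekly[, 7] - baseline_total))
      w8 <- stats::plogis(z)
      p_drop <- pmin(config$dropout_rate * w8 / mean(w8), 0.95)
    } else {
      p_drop <- rep(config$dropout_rate, n)
    }
    drops <- stats::runif(n) < p_drop
    last_week <- sample(1:5, n, replace = TRUE)
    for (i in which(drops)) {
      weekly[i, (last_week[i] + 2):7] <- NA_real_
    }
  }

  out <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = pmin(pmax(round(stats::rnorm(n, 37, 10)), 18), 65),
    sex = stats::rbinom(n, 1, 0.7),
    items,
    total_baseline = baseline_total,
    vas_drowsiness = round(stats::runif(n, 0, 100)),
    vas_sleep_quality = round(stats::runif(n, 0, 100)),
    psp = round(pmin(pmax(stats::rnorm(n, 50, 12), 10), 90)),
    sqls = round(pmin(pmax(stats::rnorm(n, 55, 15), 5), 95)),
    arm = arm,
    weekly,
    latent_label = ifelse(subgroup, "indicated", "rest"),
    stringsAsFactors = FALSE
  )
  as_trial_dataset(out)
}

#' Coerce and validate a per-patient trial data frame
#'
#' Checks the documented schema: required columns, ordinal item scores in
#' 1--7, exactly the two arm values, `total_baseline` equal to the item sum,
#' and a non-missing week-0 value for every patient. Row-level violations
#' are reported together with the offending `patient_id`.
#'
#' @param x A data frame with the `trial_dataset` columns.
#' @return `x` with class `trial_dataset` prepended.
#' @export
as_trial_dataset <- function(x) {
  stopifnot(is.data.frame(x))
  n_items <- sum(grepl("^item_\\d+$", names(x)))
  required <- c("patient_id", "age", "sex", item_cols(n_items),
                "total_baseline", "vas_drowsiness", "vas_sleep_quality",
                "psp", "sqls", "arm", week_cols())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop_validation("missing required column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  items <- as.matrix(x[, item_cols(n_items), drop = FALSE])
  bad <- which(!is.na(items) & (items < 1 | items > 7 | items != round(items)),
               arr.ind = TRUE)
  if (nrow(bad)) {
    problems <- c(problems, sprintf(
      "patient %s: %s = %s outside the 1-7 ordinal range",
      x$patient_id[bad[, 1]], colnames(items)[bad[, 2]], items[bad]))
  }
  if (anyNA(items)) {
    problems <- c(problems, sprintf("patient %s: missing item score",
                                    x$patient_id[apply(is.na(items), 1, any)]))
  }
  bad_arm <- !x$arm %in% c("treatment", "placebo")
  if (any(bad_arm)) {
    problems <- c(problems, sprintf("patient %s: unknown arm '%s'",
                                    x$patient_id[bad_arm], x$arm[bad_arm]))
  }
  bad_w0 <- is.na(x$week_0)
  if (any(bad_w0)) {
    problems <- c(problems, sprintf("patient %s: missing week_0 value",
                                    x$patient_id[bad_w0]))
  }
  tot <- rowSums(items)
  bad_tot <- !is.na(x$total_baseline) & !is.na(tot) & x$total_baseline != tot
  if (any(bad_tot)) {
    problems <- c(problems, sprintf(
      "patient %s: total_baseline (%s) != sum of items (%s)",
      x$patient_id[bad_tot], x$total_baseline[bad_tot], tot[bad_tot]))
  }
  if (length(problems)) {
    stop_validation("invalid trial dataset:\n  ",
                    paste(utils::head(problems, 20), collapse = "\n  "))
  }
  class(x) <- unique(c("trial_dataset", class(x)))
  attr(x, "n_items") <- n_items
  x
}

#' @export
print.trial_dataset <- function(x, ...) {
  n_items <- attr(x, "n_items") %||% sum(grepl("^item_\\d+$", names(x)))
  cat("<trial_dataset> ", nrow(x), " patients (",
      sum(x$arm == "treatment"), " treatment / ",
      sum(x$arm == "placebo"), " placebo), ",
      n_items, " ordinal items\n", sep = "")
  miss <- sum(is.na(x$week_6))
  cat("  week-6 outcome missing for ", miss, " patient(s)",
      if (miss) " (run locf_impute())", "\n", sep = "")
  if ("latent_label" %in% names(x)) {
    cat("  latent subgroup: ", sum(x$latent_label == "indicated"),
        " indicated / ", sum(x$latent_label == "rest"), " rest\n", sep = "")
  }
  invisible(x)
}

#' Last-observation-carried-forward imputation of the week-6 outcome
#'
#' Replaces a missing week-6 total score with the patient's last observed
#' weekly total (week 0 is always observed, so every patient ends up with a
#' week-6 value). Patients with a complete trajectory are unchanged; the
#' input is not modified.
#'
#' @param dataset A `trial_dataset`.
#' @return A new `trial_dataset` with no missing `week_6` values.
#' @export
locf_impute <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"))
  wk <- as.matrix(dataset[, week_cols(), drop = FALSE])
  if (anyNA(wk[, 1])) {
    stop_validation("week_0 must be observed for every patient")
  }
  observed <- !is.na(wk)
  last_col <- max.col(observed * col(observed), ties.method = "last")
  out <- dataset
  out$week_6 <- wk[cbind(seq_len(nrow(wk)), last_col)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("paibrl_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
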