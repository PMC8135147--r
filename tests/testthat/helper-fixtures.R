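# Fixtures are generated in code; nothing is stored on disk.

# A small, fast generator configuration used across tests.
small_config <- function(...) {
  args <- utils::modifyList(list(n_treatment = 40, n_placebo = 40,
                                 dropout_rate = 0.2, seed = 7L),
                            list(...))
  do.call(trial_config, args)
}

# Hand-built minimal trial dataset with fully controlled weekly
# trajectories. `weeks` is an n x 7 matrix (week 0..6); items are constant
# except where overridden, so total_baseline stays consistent.
manual_trial <- function(weeks, arm = NULL, items = NULL) {
  n <- nrow(weeks)
  if (is.null(arm)) arm <- rep(c("treatment", "placebo"), length.out = n)
  if (is.null(items)) items <- matrix(2L, n, 30)
  colnames(items) <- sprintf("item_%02d", 1:30)
  colnames(weeks) <- sprintf("week_%d", 0:6)
  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = rep(40L, n), sex = rep(0L, n),
    items,
    total_baseline = as.integer(rowSums(items)),
    vas_drowsiness = rep(50, n), vas_sleep_quality = rep(50, n),
    psp = rep(60, n), sqls = rep(55, n),
    arm = arm, weeks, stringsAsFactors = FALSE)
  as_trial_dataset(df)
}

# Tiny labeled feature set with a pool small enough to enumerate: three
# binary features, single-predicate antecedents only.
enum_fixture <- function(n = 24, seed = 11) {
  withr::with_seed(seed, {
    f <- data.frame(a = rep(c(0, 1), length.out = n),
                    b = rep(c(0, 0, 1), length.out = n),
                    c = sample(c(0, 1), n, replace = TRUE))
    # labels associated with feature a, plus noise
    y <- ifelse(f$a == 1 & stats::runif(n) < 0.9, "treatment_indicated",
                ifelse(stats::runif(n) < 0.2, "treatment_indicated",
                       "rest_indicated"))
    list(features = f, labels = y)
  })
}

enum_hyper <- function(...) {
  brl_hyper(max_rule_length = 1, min_support = 0, max_support = 1,
            max_list_length = 2, ...)
}

# Total-variation distance between sampled list frequencies and an
# enumerated posterior table (keys are comma-joined antecedent indices).
tv_distance <- function(samples, enum) {
  keys <- vapply(samples$lists, paste, character(1), collapse = ",")
  freq <- table(keys) / length(keys)
  idx <- match(names(freq), enum$key)   # name-indexing fails for the "" key
  stopifnot(!anyNA(idx))
  p_hat <- rep(0, nrow(enum))
  p_hat[idx] <- as.numeric(freq)
  sum(abs(p_hat - enum$probability)) / 2
}
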