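#' Extract the baseline feature frame used by the rule-list classifier
#'
#' The rule-list stage uses the same baseline features as the PAI regression
#' except the randomized arm and its interactions.
#'
#' @param dataset A `trial_dataset`.
#' @param include_baseline_total Include the baseline total score.
#' @return A data frame of baseline features, one row per patient, with
#'   `patient_id` as row names.
#' @export
brl_features <- function(dataset, include_baseline_total = TRUE) {
  stopifnot(inherits(dataset, "trial_dataset"))
  n_items <- attr(dataset, "n_items") %||% 30L
  feats <- baseline_feature_names(n_items, include_baseline_total)
  out <- dataset[, feats, drop = FALSE]
  rownames(out) <- dataset$patient_id
  class(out) <- "data.frame"
  out
}

#' Build candidate Boolean predicates from baseline features
#'
#' Per-feature discretization follows the feature's type:
#' * ordinal 1--7 items: `>= c` for every integer cutoff above the observed
#'   minimum and `<= c` for every integer cutoff below the observed maximum,
#'   so rules of the form "item >= 3" are expressible exactly;
#' * binary features (exactly two observed values): one `==` predicate per
#'   value;
#' * continuous features: `<=`/`>=` pairs at the empirical quartiles.
#'
#' Constant features yield no predicates (reported via a message).
#'
#' @param features A data frame of numeric baseline features (see
#'   [brl_features()]).
#' @return A data frame of class `brl_predicates` with columns `feature`,
#'   `op` (`">="`, `"<="`, `"=="`), and `cutoff`.
#' @export
build_predicates <- function(features) {
  stopifnot(is.data.frame(features), nrow(features) >= 1)
  rows <- list()
  for (f in names(features)) {
    v <- features[[f]]
    if (!is.numeric(v)) stop("feature '", f, "' is not numeric", call. = FALSE)
    u <- sort(unique(v[!is.na(v)]))
    if (length(u) < 2) {
      message("feature '", f, "' is constant; no predicates emitted")
      next
    }
    if (length(u) == 2) {
      rows[[f]] <- data.frame(feature = f, op = "==", cutoff = u)
    } else if (all(u == round(u)) && min(u) >= 1 && max(u) <= 7) {
      ge <- seq(min(u) + 1, max(u))
      le <- seq(min(u), max(u) - 1)
      rows[[f]] <- data.frame(
        feature = f,
        op = c(rep(">=", length(ge)), rep("<=", length(le))),
        cutoff = c(ge, le))
    } else {
      q <- unique(stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE,
                                  names = FALSE))
      q <- q[q > min(u) & q < max(u)]
      if (!length(q)) next
      rows[[f]] <- data.frame(feature = f,
                              op = rep(c("<=", ">="), each = length(q)),
                              cutoff = c(q, q))
    }
  }
  if (!length(rows)) stop("no predicates could be built", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("brl_predicates", "data.frame")
  out
}

#' Evaluate predicates against a feature frame
#'
#' @param predicates A `brl_predicates` data frame.
#' @param features Feature data frame covering every named feature; missing
#'   values are not allowed.
#' @return Logical matrix, rows = patients, columns = predicates.
#' @export
evaluate_predicates <- function(predicates, features) {
  missing_feats <- setdiff(unique(predicates$feature), names(features))
  if (length(missing_feats)) {
    stop("feature(s) not present in data: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  }
  out <- matrix(FALSE, nrow(features), nrow(predicates))
  for (i in seq_len(nrow(predicates))) {
    v <- features[[predicates$feature[i]]]
    if (anyNA(v)) {
      stop("missing value in feature '", predicates$feature[i],
           "'; no implicit imputation is performed", call. = FALSE)
    }
    out[, i] <- switch(predicates$op[i],
                       ">=" = v >= predicates$cutoff[i],
                       "<=" = v <= predicates$cutoff[i],
                       "==" = v == predicates$cutoff[i],
                       stop("unknown operator ", predicates$op[i]))
  }
  out
}

format_predicate <- function(predicates, i) {
  sprintf("%s %s %s", predicates$feature[i], predicates$op[i],
          format(predicates$cutoff[i], trim = TRUE))
}

format_antecedent <- function(predicates, idx) {
  paste(vapply(idx, function(i) format_predicate(predicates, i), character(1)),
        collapse = " and ")
}

#' Mine the antecedent pool by level-wise conjunction enumeration
#'
#' Enumerates all conjunctions of 1..`max_rule_length` predicates with
#' training support in `[min_support, max_support]`, Apriori-style (a
#' conjunction is only extended if it is itself frequent; predicates above
#' `max_support` are satisfied by nearly every row, carry no class
#' information, and are excluded). Conjunctions repeating a feature
#' with the same operator are skipped as logically redundant -- the collapsed
#' shorter antecedent is already in the pool -- while interval conjunctions
#' (`>=` and `<=` on one feature) are kept. If the pool would exceed
#' `max_antecedents`, the level being built is truncated to the
#' highest-support antecedents (stable order), keeping per-fold mining
#' tractable at desk scale.
#'
#' @param predicates A `brl_predicates` data frame.
#' @param features Training feature frame.
#' @param hyper A [brl_hyper()] supplying `max_rule_length`, `min_support`
#'   and `max_antecedents`.
#' @return An object of class `brl_pool`: `antecedents` (list of predicate
#'   index vectors), `cardinality`, `support`, `capture` (n x pool logical
#'   matrix), and the `predicates` table.
#' @export
mine_antecedents <- function(predicates, features, hyper = brl_hyper()) {
  P <- evaluate_predicates(predicates, features)
  n <- nrow(P)
  supp1 <- colMeans(P)
  freq1 <- which(supp1 >= hyper$min_support & supp1 <= hyper$max_support)
  if (!length(freq1)) {
    stop("no predicate has support within [", hyper$min_support, ", ",
         hyper$max_support, "]; lower min_support", call. = FALSE)
  }
  feat_op <- paste(predicates$feature, predicates$op)
  if (length(freq1) > hyper$max_antecedents) {
    keep <- sort(order(-supp1[freq1])[seq_len(hyper$max_antecedents)])
    freq1 <- freq1[keep]
  }

  ants <- lapply(freq1, function(i) i)
  supp <- supp1[freq1]
  caps <- P[, freq1, drop = FALSE]
  level_idx <- ants      # antecedents of the current level (index vectors)
  level_cap <- caps

  budget_left <- function() hyper$max_antecedents - length(ants)
  lvl <- 1L
  while (lvl < hyper$max_rule_length && length(level_idx) &&
         budget_left() > 0) {
    # support counts of every (level antecedent) x (frequent predicate)
    counts <- crossprod(level_cap * 1, P[, freq1, drop = FALSE] * 1)
    new_idx <- list()
    new_supp <- numeric(0)
    keep_pairs <- which(counts >= hyper$min_support * n - 1e-9, arr.ind = TRUE)
    if (nrow(keep_pairs)) {
      ord <- order(keep_pairs[, 1], keep_pairs[, 2])
      keep_pairs <- keep_pairs[ord, , drop = FALSE]
      for (r in seq_len(nrow(keep_pairs))) {
        a <- level_idx[[keep_pairs[r, 1]]]
        j <- freq1[keep_pairs[r, 2]]
        if (j <= max(a)) next                 # canonical order: extend upward
        if (feat_op[j] %in% feat_op[a]) next  # same feature+op is redundant
        new_idx[[length(new_idx) + 1L]] <- c(a, j)
        new_supp[length(new_supp) + 1L] <- counts[keep_pairs[r, 1],
                                                  keep_pairs[r, 2]] / n
      }
    }
    if (!length(new_idx)) break
    if (length(new_idx) > budget_left()) {
      keep <- order(-new_supp)[seq_len(budget_left())]
      keep <- sort(keep)  # stable enumeration order among the kept
      new_idx <- new_idx[keep]
      new_supp <- new_supp[keep]
    }
    new_cap <- vapply(new_idx, function(a) {
      rowSums(P[, a, drop = FALSE]) == length(a)
    }, logical(n))
    if (is.null(dim(new_cap))) new_cap <- matrix(new_cap, nrow = n)
    ants <- c(ants, new_idx)
    supp <- c(supp, new_supp)
    caps <- cbind(caps, new_cap)
    level_idx <- new_idx
    level_cap <- new_cap
    lvl <- lvl + 1L
  }
  structure(list(antecedents = ants,
                 cardinality = vapply(ants, length, integer(1)),
                 support = unname(supp),
                 capture = caps,
                 predicates = predicates,
                 n = n,
                 min_support = hyper$min_support),
            class = "brl_pool")
}

#' @export
print.brl_pool <- function(x, ...) {
  cat("<brl_pool> ", length(x$antecedents), " antecedents over ",
      nrow(x$predicates), " predicates (n = ", x$n, ", min_support = ",
      x$min_support, ")\n", sep = "")
  cat("  cardinality: ",
      paste(sprintf("%d:%d", sort(unique(x$cardinality)),
                    tabulate(x$cardinality)[sort(unique(x$cardinality))]),
            collapse = "  "), "\n", sep = "")
  invisible(x)
}
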