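#' Bayesian Rule List hyperparameters
#'
#' Structural prior and sampler settings for the rule-list classifier. The
#' defaults follow the source analysis where stated -- maximum rule length 3,
#' expected individual rule length `eta = 2`, expected rule-list length
#' `lambda = 2` (excluding the final default rule) -- and standard choices
#' elsewhere: uniform Dirichlet pseudo-counts (1, 1), antecedent support
#' threshold 0.1, and a Metropolis-Hastings budget of 3 chains.
#'
#' @param max_rule_length Maximum number of Boolean predicates conjoined in
#'   one rule.
#' @param eta Expected rule cardinality (truncated-Poisson prior).
#' @param lambda Expected rule-list length (truncated-Poisson prior).
#' @param dirichlet_alpha Length-2 positive pseudo-counts for the
#'   (treatment_indicated, rest_indicated) class probabilities.
#' @param min_support Minimum training-set support for a mined antecedent.
#' @param max_support Maximum support: antecedents satisfied by almost every
#'   row carry no class information and only crowd the pool.
#' @param max_antecedents Deterministic cap on the mined pool size.
#' @param mcmc_iterations Iterations per chain.
#' @param n_chains Number of independent chains (run sequentially from one
#'   seeded stream).
#' @param burn_in Fraction of each chain discarded.
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param max_list_length Hard cap on list length (default unbounded; the
#'   prior already penalizes long lists). Used by the enumeration oracle.
#' @param seed Integer seed.
#' @return An object of class `brl_hyper`.
#' @export
brl_hyper <- function(max_rule_length = 3,
                      eta = 2,
                      lambda = 2,
                      dirichlet_alpha = c(1, 1),
                      min_support = 0.1,
                      max_support = 0.9,
                      max_antecedents = 2000,
                      mcmc_iterations = 10000,
                      n_chains = 3,
                      burn_in = 0.5,
                      thin = 10,
                      max_list_length = Inf,
                      seed = 1L) {
  stopifnot(max_rule_length >= 1, eta > 0, lambda > 0,
            length(dirichlet_alpha) == 2, all(dirichlet_alpha > 0),
            min_support >= 0, min_support < 1,
            max_support > min_support, max_support <= 1,
            max_antecedents >= 1,
            mcmc_iterations >= 2, n_chains >= 1,
            burn_in >= 0, burn_in < 1, thin >= 1, max_list_length >= 0)
  structure(list(max_rule_length = as.integer(max_rule_length),
                 eta = eta, lambda = lambda,
                 dirichlet_alpha = dirichlet_alpha,
                 min_support = min_support,
                 max_support = max_support,
                 max_antecedents = as.integer(max_antecedents),
                 mcmc_iterations = as.integer(mcmc_iterations),
                 n_chains = as.integer(n_chains),
                 burn_in = burn_in, thin = as.integer(thin),
                 max_list_length = max_list_length,
                 seed = as.integer(seed)),
            class = "brl_hyper")
}

brl_classes <- function() c("treatment_indicated", "rest_indicated")

# y -> logical "is treatment_indicated"
as_indicated <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% brl_classes())) {
    stop("labels must be 'treatment_indicated' or 'rest_indicated'",
         call. = FALSE)
  }
  labels == "treatment_indicated"
}

# log of a Poisson pmf truncated to the integer support set `values`
log_trunc_pois <- function(x, rate, values) {
  if (!x %in% values) return(-Inf)
  lp <- stats::dpois(values, rate, log = TRUE)
  stats::dpois(x, rate, log = TRUE) - log_sum_exp(lp)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Dirichlet-multinomial log marginal likelihood for one rule's captured rows
dirmult_ll <- function(n_ind, n_rest, alpha) {
  lgamma(alpha[1] + n_ind) + lgamma(alpha[2] + n_rest) -
    lgamma(sum(alpha) + n_ind + n_rest) +
    lgamma(sum(alpha)) - lgamma(alpha[1]) - lgamma(alpha[2])
}

# First-match captured (n_ind, n_rest) per rule; last row = default rule.
capture_counts <- function(idx, capture, y_ind) {
  m <- length(idx)
  out <- matrix(0, m + 1, 2)
  rem <- rep(TRUE, length(y_ind))
  for (j in seq_len(m)) {
    cap <- capture[, idx[j]] & rem
    out[j, 1] <- sum(cap & y_ind)
    out[j, 2] <- sum(cap) - out[j, 1]
    rem <- rem & !cap
  }
  out[m + 1, 1] <- sum(rem & y_ind)
  out[m + 1, 2] <- sum(rem) - out[m + 1, 1]
  out
}

#' Log posterior of an ordered rule list
#'
#' Computes `log prior + log marginal likelihood` for a rule list given as a
#' vector of antecedent indices into the mined pool. The prior is a
#' truncated Poisson(`lambda`) on list length; each rule then draws its
#' cardinality from a truncated Poisson(`eta`) over the cardinalities still
#' available in the pool and the antecedent uniformly among remaining pool
#' members of that cardinality. The likelihood is the product over rules
#' (including the default rule capturing unmatched rows) of the
#' Dirichlet-multinomial marginal of the captured labels with pseudo-counts
#' `dirichlet_alpha`.
#'
#' @param idx Integer vector of pool antecedent indices (may be empty: the
#'   list is then the default rule alone).
#' @param pool A `brl_pool` from [mine_antecedents()].
#' @param labels Class labels (or a logical "is treatment-indicated"
#'   vector), one per pool training row.
#' @param hyper A [brl_hyper()].
#' @return The log posterior (unnormalized), a single number.
#' @export
brl_log_posterior <- function(idx, pool, labels, hyper = brl_hyper()) {
  idx <- as.integer(idx)
  M <- length(pool$antecedents)
  if (anyDuplicated(idx) || any(idx < 1 | idx > M)) {
    stop("rule list must be distinct antecedent indices from the mined pool",
         call. = FALSE)
  }
  y_ind <- as_indicated(labels)
  stopifnot(length(y_ind) == pool$n)
  card <- pool$cardinality
  l_max <- min(M, hyper$max_list_length)
  lp <- log_trunc_pois(length(idx), hyper$lambda, 0:l_max)
  tab <- tabulate(card, nbins = max(card))
  for (j in idx) {
    avail <- which(tab > 0)
    lp <- lp + log_trunc_pois(card[j], hyper$eta, avail) - log(tab[card[j]])
    tab[card[j]] <- tab[card[j]] - 1L
  }
  counts <- capture_counts(idx, pool$capture, y_ind)
  ll <- sum(dirmult_ll(counts[, 1], counts[, 2], hyper$dirichlet_alpha))
  lp + ll
}

# Draw a rule list from the prior (used for chain initialization).
draw_prior_list <- function(pool, hyper) {
  card <- pool$cardinality
  M <- length(card)
  l_max <- min(M, hyper$max_list_length)
  lens <- 0:l_max
  pl <- stats::dpois(lens, hyper$lambda)
  m <- if (length(lens) == 1) lens else sample(lens, 1, prob = pl)
  idx <- integer(0)
  remaining <- seq_len(M)
  for (j in seq_len(m)) {
    avail_card <- sort(unique(card[remaining]))
    pc <- stats::dpois(avail_card, hyper$eta)
    cj <- if (length(avail_card) == 1) avail_card else
      sample(avail_card, 1, prob = pc)
    cand <- remaining[card[remaining] == cj]
    pick <- if (length(cand) == 1) cand else sample(cand, 1)
    idx <- c(idx, pick)
    remaining <- setdiff(remaining, pick)
  }
  idx
}

#' Sample rule lists by Metropolis-Hastings
#'
#' Random-walk MCMC over ordered rule lists with three proposal moves:
#' insert an unused pool antecedent at a random position, remove a random
#' rule, or swap two rules. A move type is chosen uniformly among those
#' feasible in the current state and the acceptance ratio includes the
#' proposal-asymmetry correction. Chains start from independent draws from
#' the prior and run sequentially from one seeded stream, so results are
#' fully reproducible.
#'
#' @param pool A `brl_pool`.
#' @param labels Training labels (one per pool row).
#' @param hyper A [brl_hyper()] (iterations, chains, burn-in, thinning,
#'   seed).
#' @param seed Optional seed overriding `hyper$seed`.
#' @return An object of class `brl_samples`: `lists` (list of index
#'   vectors, thinned, post burn-in, all chains), `log_posterior`, `chain`,
#'   `accept_rate`, plus the `pool` and `hyper` used.
#' @export
brl_mcmc <- function(pool, labels, hyper = brl_hyper(), seed = NULL) {
  stopifnot(inherits(pool, "brl_pool"))
  y_ind <- as_indicated(labels)
  stopifnot(length(y_ind) == pool$n)
  seed <- if (is.null(seed)) hyper$seed else as.integer(seed)
  n_burn <- floor(hyper$mcmc_iterations * hyper$burn_in)
  if (hyper$mcmc_iterations <= n_burn) {
    stop("mcmc_iterations must exceed the burn-in", call. = FALSE)
  }
  withr::with_seed(seed, brl_mcmc_impl(pool, y_ind, hyper, n_burn))
}

brl_mcmc_impl <- function(pool, y_ind, hyper, n_burn) {
  M <- length(pool$antecedents)
  l_max <- min(M, hyper$max_list_length)
  lp_of <- function(idx) brl_log_posterior(idx, pool, y_ind, hyper)

  lists <- list()
  lps <- numeric(0)
  chains <- integer(0)
  accepted <- 0L
  total <- 0L
  for (ch in seq_len(hyper$n_chains)) {
    cur <- draw_prior_list(pool, hyper)
    cur_lp <- lp_of(cur)
    for (it in seq_len(hyper$mcmc_iterations)) {
      m <- length(cur)
      moves <- c(if (m < l_max && m < M) "insert",
                 if (m >= 1) "remove",
                 if (m >= 2) "swap")
      move <- if (length(moves) == 1) moves else sample(moves, 1)
      log_q_fwd <- -log(length(moves))
      if (move == "insert") {
        unused <- setdiff(seq_len(M), cur)
        j <- if (length(unused) == 1) unused else sample(unused, 1)
        pos <- sample.int(m + 1, 1)
        prop <- append(cur, j, after = pos - 1)
        log_q_fwd <- log_q_fwd - log(M - m) - log(m + 1)
        # reverse: remove that rule from the proposed (m+1)-list
        mp <- m + 1
        rev_moves <- 1 + (mp < l_max && mp < M) + (mp >= 2)
        log_q_rev <- -log(rev_moves) - log(mp)
      } else if (move == "remove") {
        r <- sample.int(m, 1)
        prop <- cur[-r]
        log_q_fwd <- log_q_fwd - log(m)
        # reverse: insert the removed antecedent back at position r
        mp <- m - 1
        rev_moves <- 1 + (mp >= 1) + (mp >= 2)  # insert always feasible here
        log_q_rev <- -log(rev_moves) - log(M - mp) - log(mp + 1)
      } else {
        pr <- sample.int(m, 2)
        prop <- cur
        prop[pr] <- prop[rev(pr)]
        log_q_fwd <- log_q_fwd - lchoose(m, 2)
        rev_moves <- length(moves)  # same length, same feasibility
        log_q_rev <- -log(rev_moves) - lchoose(m, 2)
      }
      prop_lp <- lp_of(prop)
      total <- total + 1L
      if (log(stats::runif(1)) < prop_lp - cur_lp + log_q_rev - log_q_fwd) {
        cur <- prop
        cur_lp <- prop_lp
        accepted <- accepted + 1L
      }
      if (it > n_burn && (it - n_burn) %% hyper$thin == 0) {
        lists[[length(lists) + 1L]] <- cur
        lps[length(lps) + 1L] <- cur_lp
        chains[length(chains) + 1L] <- ch
      }
    }
  }
  structure(list(lists = lists, log_posterior = lps, chain = chains,
                 accept_rate = accepted / total, pool = pool, hyper = hyper),
            class = "brl_samples")
}

#' @export
print.brl_samples <- function(x, ...) {
  cat("<brl_samples> ", length(x$lists), " thinned samples from ",
      x$hyper$n_chains, " chain(s) x ", x$hyper$mcmc_iterations,
      " iterations (accept rate ", round(x$accept_rate, 2), ")\n", sep = "")
  invisible(x)
}

#' Exhaustively enumerate the rule-list posterior
#'
#' Enumeration oracle for desk-scale pools: computes the normalized
#' posterior over every ordered list of distinct pool antecedents up to
#' `max_list_length`. Feasible only for small pools (the space grows
#' factorially).
#'
#' @param pool A `brl_pool` (a handful of antecedents).
#' @param labels Training labels.
#' @param hyper A [brl_hyper()]; set `max_list_length` to bound the space.
#' @return Data frame with columns `key` (antecedent indices joined by
#'   `","`), `length`, `log_posterior`, and normalized `probability`.
#' @export
brl_enumerate_posterior <- function(pool, labels, hyper = brl_hyper()) {
  M <- length(pool$antecedents)
  l_max <- min(M, hyper$max_list_length)
  if (choose(M, l_max) * factorial(l_max) > 2e5) {
    stop("pool too large to enumerate", call. = FALSE)
  }
  acc <- list()
  recurse <- function(prefix) {
    acc[[length(acc) + 1L]] <<- prefix
    if (length(prefix) < l_max) {
      for (j in setdiff(seq_len(M), prefix)) recurse(c(prefix, j))
    }
  }
  recurse(integer(0))
  lp <- vapply(acc, brl_log_posterior, numeric(1),
               pool = pool, labels = labels, hyper = hyper)
  prob <- exp(lp - log_sum_exp(lp))
  data.frame(key = vapply(acc, paste, character(1), collapse = ","),
             length = vapply(acc, length, integer(1)),
             log_posterior = lp, probability = prob,
             stringsAsFactors = FALSE)
}

#' Point-estimate rule list from posterior samples
#'
#' Returns the sampled list with the highest log posterior (ties broken
#' toward the first encountered in sampling order). Consequent class
#' probabilities are the Dirichlet posterior means `(n_c + alpha_c) /
#' (n + sum(alpha))` of the labels captured by each rule on the training
#' data.
#'
#' @param samples A `brl_samples`.
#' @param labels The training labels the sampler was run on.
#' @return A `brl_rule_list`: ordered `rules` (each with a predicate table,
#'   captured counts and class probabilities), a `default_rule`, the class
#'   names, and the training `log_posterior`.
#' @export
brl_point_estimate <- function(samples, labels) {
  stopifnot(inherits(samples, "brl_samples"), length(samples$lists) >= 1)
  best <- which.max(samples$log_posterior)
  idx <- samples$lists[[best]]
  new_rule_list(idx, samples$pool, labels, samples$hyper,
                samples$log_posterior[best])
}

new_rule_list <- function(idx, pool, labels, hyper, log_post = NULL) {
  y_ind <- as_indicated(labels)
  counts <- capture_counts(idx, pool$capture, y_ind)
  alpha <- hyper$dirichlet_alpha
  probs <- (t(counts) + alpha) / rep(rowSums(counts) + sum(alpha),
                                     each = 2)
  rules <- lapply(seq_along(idx), function(j) {
    list(predicates = pool$predicates[pool$antecedents[[idx[j]]], ,
                                      drop = FALSE],
         n_captured = sum(counts[j, ]),
         probs = stats::setNames(probs[, j], brl_classes()),
         ci = NULL)
  })
  default_rule <- list(predicates = NULL,
                       n_captured = sum(counts[length(idx) + 1, ]),
                       probs = stats::setNames(probs[, length(idx) + 1],
                                               brl_classes()),
                       ci = NULL)
  if (is.null(log_post)) {
    log_post <- brl_log_posterior(idx, pool, y_ind, hyper)
  }
  structure(list(rules = rules, default_rule = default_rule,
                 classes = brl_classes(), hyper = hyper,
                 log_posterior = log_post),
            class = "brl_rule_list")
}

rule_label <- function(rule) {
  # argmax with ties toward treatment_indicated (first class)
  names(rule$probs)[which.max(rule$probs)]
}

format_rule_consequent <- function(rule) {
  lab <- rule_label(rule)
  p <- rule$probs[[lab]]
  ci <- rule$ci
  if (!is.null(ci)) {
    ci_lab <- ci[[lab]]
    sprintf("%s (%.2f, CI %.2f-%.2f)", lab, p, ci_lab[1], ci_lab[2])
  } else {
    sprintf("%s (%.2f)", lab, p)
  }
}

#' Human-readable if-then-else rendering of a rule list
#'
#' @param x A `brl_rule_list`.
#' @param ... Unused.
#' @return Character vector, one line per rule.
#' @export
format.brl_rule_list <- function(x, ...) {
  lines <- character(0)
  for (j in seq_along(x$rules)) {
    rule <- x$rules[[j]]
    cond <- format_antecedent(rule$predicates, seq_len(nrow(rule$predicates)))
    lines <- c(lines, sprintf("%s %s then %s",
                              if (j == 1) "If" else "else if",
                              cond, format_rule_consequent(rule)))
  }
  c(lines, sprintf("%s %s", if (length(x$rules)) "else" else "Always",
                   format_rule_consequent(x$default_rule)))
}

#' @export
print.brl_rule_list <- function(x, ...) {
  cat(format(x), sep = "\n")
  cat(sprintf("[log posterior %.2f on training data]\n", x$log_posterior))
  invisible(x)
}

#' Classify patients with a rule list
#'
#' First-match semantics: the first rule whose antecedent the patient
#' satisfies fires; the default rule fires when none match. Missing feature
#' values raise an error -- there is no implicit imputation at prediction
#' time.
#'
#' @param object A `brl_rule_list`.
#' @param newdata Feature data frame (e.g. [brl_features()]) covering every
#'   feature named in the list.
#' @param ... Unused.
#' @return Data frame with columns `rule` (1-based firing rule index, 0 for
#'   the default rule), `label`, `probability` (of the emitted label), and
#'   `prob_indicated`.
#' @export
predict.brl_rule_list <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata))
  n <- nrow(newdata)
  fired <- rep(0L, n)
  open <- rep(TRUE, n)
  for (j in seq_along(object$rules)) {
    preds <- object$rules[[j]]$predicates
    hit <- rowSums(evaluate_predicates(preds, newdata)) == nrow(preds)
    take <- open & hit
    fired[take] <- j
    open <- open & !take
  }
  rules_all <- c(object$rules, list(object$default_rule))
  ridx <- ifelse(fired == 0L, length(rules_all), fired)
  labs <- vapply(rules_all, rule_label, character(1))
  p_emit <- vapply(rules_all, function(r) r$probs[[rule_label(r)]], numeric(1))
  p_ind <- vapply(rules_all, function(r) r$probs[["treatment_indicated"]],
                  numeric(1))
  data.frame(rule = fired, label = labs[ridx], probability = p_emit[ridx],
             prob_indicated = p_ind[ridx], stringsAsFactors = FALSE)
}

#' Bootstrap confidence intervals for rule probabilities
#'
#' Holding the rule list fixed, resamples the training rows with replacement
#' `n_boot` times, recomputes each rule's Dirichlet-posterior-mean class
#' probability from the rows it captures in the resample, and reports the
#' 2.5th--97.5th percentile interval. A rule capturing no rows in a resample
#' contributes the Dirichlet prior mean for that resample.
#'
#' @param rule_list A `brl_rule_list`.
#' @param features Training feature frame.
#' @param labels Training labels.
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer seed.
#' @return The rule list with a `ci` element (per-class intervals) attached
#'   to every rule and the default rule.
#' @export
brl_bootstrap_cis <- function(rule_list, features, labels, n_boot = 1000,
                              seed = 1L) {
  stopifnot(inherits(rule_list, "brl_rule_list"), n_boot >= 100)
  y_ind <- as_indicated(labels)
  stopifnot(nrow(features) == length(y_ind))
  fired <- predict(rule_list, features)$rule
  n_rules <- length(rule_list$rules) + 1L  # + default
  fired[fired == 0L] <- n_rules
  alpha <- rule_list$hyper$dirichlet_alpha
  prior_mean <- alpha[1] / sum(alpha)
  n <- length(y_ind)
  boot <- withr::with_seed(seed, {
    out <- matrix(NA_real_, n_boot, n_rules)
    for (b in seq_len(n_boot)) {
      take <- sample.int(n, n, replace = TRUE)
      f <- fired[take]
      yi <- y_ind[take]
      n_cap <- tabulate(f, nbins = n_rules)
      n_ind <- tabulate(f[yi], nbins = n_rules)
      p <- (n_ind + alpha[1]) / (n_cap + sum(alpha))
      p[n_cap == 0] <- prior_mean
      out[b, ] <- p
    }
    out
  })
  attach_ci <- function(rule, j) {
    qs <- stats::quantile(boot[, j], c(0.025, 0.975), names = FALSE)
    rule$ci <- list(treatment_indicated = qs,
                    rest_indicated = rev(1 - qs))
    rule
  }
  rule_list$rules <- lapply(seq_along(rule_list$rules), function(j) {
    attach_ci(rule_list$rules[[j]], j)
  })
  rule_list$default_rule <- attach_ci(rule_list$default_rule, n_rules)
  rule_list
}

#' Serialize a rule list to JSON
#'
#' Machine-readable counterpart of the if-then-else text: rules with their
#' predicates, class probabilities and intervals, the default rule, the log
#' posterior, and the hyperparameters.
#'
#' @param rule_list A `brl_rule_list`.
#' @param path Optional output path; if omitted the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
brl_to_json <- function(rule_list, path = NULL) {
  rule_json <- function(rule) {
    out <- list(probs = as.list(rule$probs), n_captured = rule$n_captured)
    if (!is.null(rule$predicates)) {
      out$predicates <- lapply(seq_len(nrow(rule$predicates)), function(i) {
        list(feature = rule$predicates$feature[i],
             op = rule$predicates$op[i],
             cutoff = rule$predicates$cutoff[i])
      })
    }
    if (!is.null(rule$ci)) out$ci <- lapply(rule$ci, as.numeric)
    out
  }
  obj <- list(rules = lapply(rule_list$rules, rule_json),
              default_rule = rule_json(rule_list$default_rule),
              log_posterior = rule_list$log_posterior,
              hyperparams = rule_list$hyper[c("max_rule_length", "eta",
                                              "lambda", "dirichlet_alpha",
                                              "min_support")],
              seed = rule_list$hyper$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Fit a rule list end to end on labeled training data
#'
#' Convenience wrapper: build predicates, mine antecedents, run MCMC, take
#' the point estimate, and optionally attach bootstrap intervals.
#'
#' @param features Feature data frame.
#' @param labels Class labels.
#' @param hyper A [brl_hyper()].
#' @param seed Optional seed overriding `hyper$seed`.
#' @param n_boot Bootstrap resamples for the rule CIs; 0 skips them.
#' @return A `brl_rule_list`.
#' @export
brl_fit <- function(features, labels, hyper = brl_hyper(), seed = NULL,
                    n_boot = 0) {
  preds <- build_predicates(features)
  pool <- mine_antecedents(preds, features, hyper)
  samples <- brl_mcmc(pool, labels, hyper, seed = seed)
  rl <- brl_point_estimate(samples, labels)
  if (n_boot > 0) {
    rl <- brl_bootstrap_cis(rl, features, labels, n_boot = n_boot,
                            seed = (seed %||% hyper$seed) + 1L)
  }
  rl
}
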