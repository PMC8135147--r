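# pool with single-predicate antecedents over binary features; small enough
# to enumerate every ordered rule list.
make_enum_pool <- function(fx = enum_fixture(), hyper = enum_hyper()) {
  p <- build_predicates(fx$features)
  mine_antecedents(p, fx$features, hyper)
}

fake_samples <- function(lists, lps, pool, hyper) {
  structure(list(lists = lists, log_posterior = lps,
                 chain = rep(1L, length(lists)), accept_rate = 1,
                 pool = pool, hyper = hyper),
            class = "brl_samples")
}

test_that("empty-list marginal likelihood matches the Beta closed form", {
  f <- data.frame(a = rep(c(0, 1), 5), b = rep(c(0, 0, 1, 1, 1), 2))
  labels <- rep(c("treatment_indicated", "rest_indicated"), each = 5)
  hyper <- enum_hyper()
  pool <- mine_antecedents(build_predicates(f), f, hyper)
  lp <- brl_log_posterior(integer(0), pool, labels, hyper)
  # prior of the empty list: truncated Poisson(lambda = 2) mass at 0
  l_max <- min(length(pool$antecedents), hyper$max_list_length)
  log_prior <- stats::dpois(0, 2, log = TRUE) -
    log(sum(stats::dpois(0:l_max, 2)))
  expect_equal(lp - log_prior, lbeta(6, 6) - lbeta(1, 1), tolerance = 1e-10)
})

test_that("the enumerated posterior is a proper distribution", {
  fx <- enum_fixture()
  hyper <- enum_hyper()
  pool <- make_enum_pool(fx, hyper)
  enum <- brl_enumerate_posterior(pool, fx$labels, hyper)
  expect_equal(sum(enum$probability), 1, tolerance = 1e-12)
  expect_true(all(is.finite(enum$log_posterior)))
  # lists: empty + 6 singletons + 6*5 ordered pairs
  expect_equal(nrow(enum), 1 + 6 + 30)
})

test_that("duplicating the dataset changes the likelihood but not the prior", {
  f <- data.frame(a = rep(c(0, 1), 6), b = rep(c(0, 1, 1), 4))
  y <- rep(c("treatment_indicated", "rest_indicated", "rest_indicated"), 4)
  hyper <- enum_hyper()
  pool1 <- mine_antecedents(build_predicates(f), f, hyper)
  f2 <- rbind(f, f)
  y2 <- c(y, y)
  pool2 <- mine_antecedents(build_predicates(f2), f2, hyper)
  expect_identical(pool1$antecedents, pool2$antecedents)  # same pool
  for (idx in list(integer(0), 1L, c(2L, 1L))) {
    ll1 <- sum(paibrl:::dirmult_ll(
      n1 <- paibrl:::capture_counts(idx, pool1$capture,
                                    y == "treatment_indicated")[, 1],
      rowSums(paibrl:::capture_counts(idx, pool1$capture,
                                      y == "treatment_indicated")) - n1,
      c(1, 1)))
    prior1 <- brl_log_posterior(idx, pool1, y, hyper) - ll1
    ll2 <- sum(paibrl:::dirmult_ll(
      n2 <- paibrl:::capture_counts(idx, pool2$capture,
                                    y2 == "treatment_indicated")[, 1],
      rowSums(paibrl:::capture_counts(idx, pool2$capture,
                                      y2 == "treatment_indicated")) - n2,
      c(1, 1)))
    prior2 <- brl_log_posterior(idx, pool2, y2, hyper) - ll2
    expect_equal(prior1, prior2, tolerance = 1e-12)
  }
})

test_that("antecedents outside the pool are rejected", {
  fx <- enum_fixture()
  pool <- make_enum_pool(fx)
  expect_error(brl_log_posterior(99L, pool, fx$labels, enum_hyper()), "pool")
  expect_error(brl_log_posterior(c(1L, 1L), pool, fx$labels, enum_hyper()),
               "distinct")
})

test_that("MCMC is reproducible under a seed and differs across seeds", {
  fx <- enum_fixture()
  hyper <- enum_hyper(mcmc_iterations = 400, n_chains = 2, thin = 5)
  pool <- make_enum_pool(fx, hyper)
  s1 <- brl_mcmc(pool, fx$labels, hyper, seed = 4)
  s2 <- brl_mcmc(pool, fx$labels, hyper, seed = 4)
  s3 <- brl_mcmc(pool, fx$labels, hyper, seed = 5)
  expect_identical(s1$lists, s2$lists)
  expect_identical(s1$log_posterior, s2$log_posterior)
  expect_false(identical(s1$lists, s3$lists))
})

test_that("MCMC frequencies match the enumerated posterior (small pool)", {
  fx <- enum_fixture()
  hyper <- enum_hyper(mcmc_iterations = 40000, n_chains = 1, thin = 5)
  pool <- make_enum_pool(fx, hyper)
  enum <- brl_enumerate_posterior(pool, fx$labels, hyper)
  samples <- brl_mcmc(pool, fx$labels, hyper, seed = 2)
  expect_lt(tv_distance(samples, enum), 0.07)
})

test_that("with labels independent of features the MAP list is empty", {
  f <- data.frame(a = rep(c(0, 1), 10), b = rep(c(0, 0, 1, 1), 5))
  y <- rep(c("treatment_indicated", "rest_indicated"), each = 10)
  hyper <- enum_hyper()
  pool <- mine_antecedents(build_predicates(f), f, hyper)
  enum <- brl_enumerate_posterior(pool, y, hyper)
  expect_equal(enum$key[which.max(enum$probability)], "")
})

test_that("point estimate returns the best sampled list with posterior-mean probs", {
  f <- data.frame(a = c(rep(1, 10), rep(0, 4)), b = rep(c(0, 1), 7))
  y <- c(rep("treatment_indicated", 8), rep("rest_indicated", 6))
  hyper <- enum_hyper()
  pool <- mine_antecedents(build_predicates(f), f, hyper)
  # antecedent "a == 1" captures rows 1..10: 8 indicated, 2 rest
  a1 <- which(vapply(pool$antecedents, function(ix) {
    pool$predicates$feature[ix] == "a" && pool$predicates$cutoff[ix] == 1
  }, logical(1)))
  samples <- fake_samples(list(a1, integer(0)), c(-1, -5), pool, hyper)
  rl <- brl_point_estimate(samples, y)
  expect_equal(length(rl$rules), 1)
  expect_equal(unname(rl$rules[[1]]$probs["treatment_indicated"]), 9 / 12)
  expect_equal(rl$rules[[1]]$n_captured, 10)
  # single distinct sampled list -> that list
  s1 <- fake_samples(list(integer(0)), -2, pool, hyper)
  expect_equal(length(brl_point_estimate(s1, y)$rules), 0)
  # tie in log posterior -> first encountered wins
  tie <- fake_samples(list(a1, integer(0)), c(-3, -3), pool, hyper)
  expect_equal(length(brl_point_estimate(tie, y)$rules), 1)
})

test_that("prediction follows first-match semantics with a default rule", {
  f <- data.frame(item_x = c(rep(5, 6), rep(2, 3), rep(1, 3)))
  y <- c(rep("treatment_indicated", 6), rep("rest_indicated", 6))
  hyper <- brl_hyper(max_rule_length = 1, min_support = 0, max_support = 1)
  pool <- mine_antecedents(build_predicates(f), f, hyper)
  ge3 <- which(vapply(pool$antecedents, function(ix) {
    pool$predicates$op[ix] == ">=" && pool$predicates$cutoff[ix] == 3
  }, logical(1)))
  ge2 <- which(vapply(pool$antecedents, function(ix) {
    pool$predicates$op[ix] == ">=" && pool$predicates$cutoff[ix] == 2
  }, logical(1)))
  rl <- brl_point_estimate(fake_samples(list(c(ge3, ge2)), 0, pool, hyper), y)

  newdata <- data.frame(item_x = c(5, 2, 1))
  pred <- predict(rl, newdata)
  # item 5 satisfies both rules; rule 1 fires (precedence)
  expect_equal(pred$rule, c(1, 2, 0))
  expect_equal(pred$label[1], "treatment_indicated")
  expect_equal(pred$probability[1], unname(rl$rules[[1]]$probs[1]))
  # default rule for item 1
  expect_equal(pred$label[3], "rest_indicated")
  # missing feature value errors, no silent imputation
  expect_error(predict(rl, data.frame(item_x = NA_real_)), "missing")
  expect_error(predict(rl, data.frame(other = 1)), "not present")
})

test_that("rule coverage partitions the data for any sampled list", {
  fx <- enum_fixture()
  hyper <- enum_hyper(mcmc_iterations = 500, n_chains = 1)
  pool <- make_enum_pool(fx, hyper)
  samples <- brl_mcmc(pool, fx$labels, hyper, seed = 9)
  for (idx in samples$lists[seq(1, length(samples$lists), by = 10)]) {
    counts <- paibrl:::capture_counts(idx, pool$capture,
                                      fx$labels == "treatment_indicated")
    expect_equal(sum(counts), nrow(fx$features))
  }
})

test_that("with no data the sampler draws from the structural prior", {
  preds <- data.frame(feature = paste0("f", 1:12),
                      op = ">=", cutoff = 1)
  class(preds) <- c("brl_predicates", "data.frame")
  pool <- structure(list(
    antecedents = as.list(1:12),
    cardinality = rep(c(1L, 2L, 3L), each = 4),
    support = rep(0.5, 12),
    capture = matrix(FALSE, 0, 12),
    predicates = preds, n = 0L, min_support = 0),
    class = "brl_pool")
  hyper <- brl_hyper(mcmc_iterations = 20000, n_chains = 1, thin = 5)
  samples <- brl_mcmc(pool, logical(0), hyper, seed = 3)
  lens <- vapply(samples$lists, length, integer(1))
  l_max <- 12
  expected_len <- sum((0:l_max) * stats::dpois(0:l_max, 2)) /
    sum(stats::dpois(0:l_max, 2))
  expect_equal(mean(lens), expected_len, tolerance = 0.15)
  cards <- unlist(lapply(samples$lists, function(ix) pool$cardinality[ix]))
  expected_card <- sum(c(1, 2, 3) * stats::dpois(1:3, 2)) /
    sum(stats::dpois(1:3, 2))
  expect_equal(mean(cards), expected_card, tolerance = 0.2)
})

test_that("bootstrap CIs are reproducible, collapse on one row, and are tight for pure rules", {
  # default-only list on 100 identically labeled rows: every resample gives
  # the same posterior mean 101/102, so the interval is a point below 1
  f <- data.frame(a = rep(c(0, 1), 50))
  y <- rep("treatment_indicated", 100)
  hyper <- enum_hyper()
  pool <- mine_antecedents(build_predicates(f), f, hyper)
  rl <- brl_point_estimate(fake_samples(list(integer(0)), 0, pool, hyper), y)
  rl <- brl_bootstrap_cis(rl, f, y, n_boot = 200, seed = 1)
  ci <- rl$default_rule$ci$treatment_indicated
  expect_equal(ci[1], 101 / 102)
  expect_equal(ci[2], 101 / 102)
  expect_gt(ci[1], 0.5)
  expect_lt(ci[2], 1)

  # seeded reproducibility on a mixed-label dataset
  fx <- enum_fixture()
  pool2 <- make_enum_pool(fx)
  rl2 <- brl_point_estimate(fake_samples(list(1L), 0, pool2, enum_hyper()),
                            fx$labels)
  b1 <- brl_bootstrap_cis(rl2, fx$features, fx$labels, n_boot = 150, seed = 7)
  b2 <- brl_bootstrap_cis(rl2, fx$features, fx$labels, n_boot = 150, seed = 7)
  expect_identical(b1$rules[[1]]$ci, b2$rules[[1]]$ci)
  expect_true(b1$rules[[1]]$ci$treatment_indicated[1] <=
                b1$rules[[1]]$probs[["treatment_indicated"]])

  # one-row dataset: both percentiles equal
  f1 <- data.frame(a = c(1, 0))[1, , drop = FALSE]
  y1 <- "treatment_indicated"
  rl3 <- brl_point_estimate(fake_samples(list(integer(0)), 0, pool, hyper), y)
  rl3 <- brl_bootstrap_cis(rl3, f1, y1, n_boot = 100, seed = 2)
  ci3 <- rl3$default_rule$ci$treatment_indicated
  expect_equal(ci3[1], ci3[2])
})

test_that("rule lists render as if-then-else text and serialize to JSON", {
  fx <- enum_fixture()
  hyper <- enum_hyper()
  pool <- make_enum_pool(fx, hyper)
  rl <- brl_point_estimate(fake_samples(list(c(1L, 2L)), 0, pool, hyper),
                           fx$labels)
  txt <- format(rl)
  expect_length(txt, 3)
  expect_match(txt[1], "^If ")
  expect_match(txt[2], "^else if ")
  expect_match(txt[3], "^else ")
  js <- jsonlite::fromJSON(brl_to_json(rl), simplifyVector = FALSE)
  expect_length(js$rules, 2)
  expect_equal(js$hyperparams$lambda, 2)
  expect_equal(js$rules[[1]]$probs$treatment_indicated +
                 js$rules[[1]]$probs$rest_indicated, 1, tolerance = 1e-12)
})
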