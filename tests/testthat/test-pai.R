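# Build a trial whose week-6 outcome is an exact linear function of the
# design columns, with known arm and interaction coefficients. The fitted
# model can then be checked against the generating truth and the PAI score
# against the analytic drug-placebo contrast.
linear_trial <- function(arm_coef = -5, interactions = c(item_22 = -1.5,
                                                         item_27 = -0.8),
                         seed = 21L, n_each = 150) {
  tr <- simulate_trial(trial_config(n_treatment = n_each, n_placebo = n_each,
                                    dropout_rate = 0, seed = seed))
  arm01 <- as.numeric(tr$arm == "treatment")
  y <- 20 + 0.8 * tr$total_baseline + arm_coef * arm01
  for (f in names(interactions)) {
    y <- y + interactions[[f]] * arm01 * tr[[f]]
  }
  tr$week_6 <- y
  list(trial = tr, arm_coef = arm_coef, interactions = interactions)
}

# Near-unpenalized spec: with a noise-free linear outcome and n >> p the
# elastic net at a vanishing penalty reproduces the OLS (= generating) fit.
# The baseline total is excluded because it is the exact item sum: keeping
# it makes the design singular and the generating coefficients unidentified.
exact_spec <- function() {
  pai_spec(include_baseline_total = FALSE, alpha_grid = 1e-8,
           l1_ratio_grid = 0.5, inner_cv_folds = 3,
           convergence_thresh = 1e-20, seed = 1L)
}

test_that("design matrix has features, arm, and interaction columns with a manifest", {
  tr <- locf_impute(simulate_trial(small_config()))
  des <- build_design_matrix(tr, pai_spec())
  expect_equal(ncol(des$x), 37 + 1 + 37)
  expect_equal(des$manifest$features, baseline_feature_names())
  expect_equal(des$manifest$interactions,
               paste0("arm_x_", baseline_feature_names()))
  expect_equal(length(des$y), nrow(tr))
  # excluding the baseline total drops one feature and one interaction
  des2 <- build_design_matrix(tr, pai_spec(include_baseline_total = FALSE))
  expect_equal(ncol(des2$x), 36 + 1 + 36)
})

test_that("patients with missing baseline features are excluded and reported", {
  tr <- locf_impute(simulate_trial(small_config()))
  tr$age[4] <- NA
  expect_message(des <- build_design_matrix(tr, pai_spec()), "P0004")
  expect_equal(des$excluded, "P0004")
  expect_equal(nrow(des$x), nrow(tr) - 1)
  expect_false("P0004" %in% des$patient_id)
})

test_that("interactions are identically zero in a placebo-only dataset", {
  tr <- locf_impute(simulate_trial(small_config()))
  tr$arm <- rep("placebo", nrow(tr))
  des <- build_design_matrix(tr, pai_spec())
  expect_true(all(des$x[, des$manifest$interactions] == 0))
  expect_true(all(des$x[, "arm"] == 0))
})

test_that("missing week-6 outcomes are rejected with a pointer to LOCF", {
  tr <- simulate_trial(small_config())  # has dropout, week_6 NA
  expect_error(build_design_matrix(tr, pai_spec()), "locf_impute")
})

test_that("noise-free generating coefficients are recovered at vanishing penalty", {
  lt <- linear_trial()
  des <- build_design_matrix(lt$trial, exact_spec())
  fit <- fit_outcome_model(des, exact_spec())
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  beta <- fit$coefficients
  expect_equal(unname(beta["arm"]), lt$arm_coef, tolerance = 1e-3)
  expect_equal(unname(beta["arm_x_item_22"]), -1.5, tolerance = 1e-3)
  # 0.8 * total score = 0.8 on every individual item
  expect_equal(unname(beta["item_05"]), 0.8, tolerance = 1e-3)
})

test_that("degenerate outcomes and forced grids behave as documented", {
  tr <- locf_impute(simulate_trial(small_config()))
  des <- build_design_matrix(tr, pai_spec())
  des$y <- rep(100, length(des$y))
  expect_error(fit_outcome_model(des, pai_spec()), "distinct")

  spec1 <- pai_spec(alpha_grid = 0.1, l1_ratio_grid = 0.9)
  des <- build_design_matrix(tr, spec1)
  fit <- fit_outcome_model(des, spec1)
  expect_equal(fit$selected_alpha, 0.1)
  expect_equal(fit$selected_l1_ratio, 0.9)
})

test_that("selected hyperparameters are grid members and R^2 is in range", {
  tr <- locf_impute(simulate_trial(small_config()))
  des <- build_design_matrix(tr, pai_spec())
  fit <- fit_outcome_model(des, pai_spec())
  expect_true(fit$selected_alpha %in% pai_spec()$alpha_grid)
  expect_true(fit$selected_l1_ratio %in% pai_spec()$l1_ratio_grid)
  expect_lte(fit$r_squared, 1)
  expect_lte(fit$adjusted_r_squared, fit$r_squared)
})

test_that("PAI scores equal the analytic drug-placebo contrast on noise-free data", {
  lt <- linear_trial()
  des <- build_design_matrix(lt$trial, exact_spec())
  fit <- fit_outcome_model(des, exact_spec())
  res <- predict_counterfactual(fit, des)
  analytic <- lt$arm_coef + lt$interactions[["item_22"]] * lt$trial$item_22 +
    lt$interactions[["item_27"]] * lt$trial$item_27
  expect_equal(res$pai_score, analytic, tolerance = 1e-6)
})

test_that("zero arm effect gives zero PAI scores; constant arm effect a constant", {
  tr <- locf_impute(simulate_trial(small_config()))
  des <- build_design_matrix(tr, pai_spec())
  fit <- fit_outcome_model(des, pai_spec())
  # null out every arm-related coefficient
  fit0 <- fit
  fit0$coefficients[c("arm", fit$manifest$interactions)] <- 0
  expect_equal(predict_counterfactual(fit0, des)$pai_score,
               rep(0, nrow(des$x)))
  fit5 <- fit0
  fit5$coefficients["arm"] <- -5
  res <- predict_counterfactual(fit5, des)
  expect_equal(res$pai_score, rep(-5, nrow(des$x)))
  # bookkeeping: actual prediction matches the randomized arm's prediction
  trt <- des$arm01 == 1
  expect_equal(res$predicted_actual[trt] - res$predicted_counterfactual[trt],
               rep(-5, sum(trt)))
})

test_that("PAI scores do not depend on the arm patients were randomized to", {
  tr <- locf_impute(simulate_trial(small_config()))
  spec <- pai_spec()
  des <- build_design_matrix(tr, spec)
  fit <- fit_outcome_model(des, spec)
  flipped <- tr
  flipped$arm <- ifelse(tr$arm == "treatment", "placebo", "treatment")
  des_f <- build_design_matrix(flipped, spec)
  expect_equal(predict_counterfactual(fit, des)$pai_score,
               predict_counterfactual(fit, des_f)$pai_score)
})

test_that("manifest mismatch between fit and design is rejected", {
  tr <- locf_impute(simulate_trial(small_config()))
  des <- build_design_matrix(tr, pai_spec())
  fit <- fit_outcome_model(des, pai_spec())
  des2 <- build_design_matrix(tr, pai_spec(include_baseline_total = FALSE))
  expect_error(predict_counterfactual(fit, des2), "manifest")
})

test_that("threshold sweep matches hand enumeration and documented tie-breaks", {
  thr <- select_threshold(c(-10, -10, -10, 1, 1, 1))
  expect_equal(thr$threshold, 0)
  expect_equal(sum(thr$labels == "treatment_indicated"), 3)
  expect_equal(thr$fraction, 0.5)

  # all scores equal: every scanned threshold captures everyone; the tie is
  # broken toward the largest (least negative) threshold
  thr2 <- select_threshold(rep(-2, 5))
  expect_equal(thr2$threshold, 0)
  expect_true(all(thr2$labels == "treatment_indicated"))

  # all positive scores: warning, empty indicated class at threshold 0
  expect_warning(thr3 <- select_threshold(c(0.5, 1, 2)), "positive")
  expect_equal(thr3$threshold, 0)
  expect_true(all(thr3$labels == "rest_indicated"))
})

test_that("thresholding partitions the sample and is monotone in the cut", {
  tr <- locf_impute(simulate_trial(small_config()))
  pai <- compute_pai(tr)
  lab <- pai_labels(pai)
  expect_equal(nrow(lab), nrow(tr) - length(pai$excluded))
  expect_equal(sum(lab$label == "treatment_indicated") +
                 sum(lab$label == "rest_indicated"), nrow(lab))
  # lowering the threshold never grows the indicated class
  scores <- pai$scores$pai_score
  cand <- pai$threshold$candidates
  sizes <- vapply(cand$threshold, function(t) sum(scores <= t), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # labels agree with the score-threshold rule
  expect_identical(pai$scores$label,
                   ifelse(scores <= pai$threshold$threshold,
                          "treatment_indicated", "rest_indicated"))
})
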