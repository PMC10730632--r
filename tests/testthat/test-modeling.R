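test_that("log transform: natural log for ratios, signed log for delta TTE", {
  df <- data.frame(r_wir_ws = c(1, 2.3), delta_tte_ws = c(0, -5),
                   r_volume = c(1, 4))
  tr <- log_transform_features(df)
  expect_equal(tr$r_wir_ws, c(0, log(2.3)))
  expect_equal(tr$r_wir_ws[2], 0.8329, tolerance = 1e-4)
  expect_equal(tr$delta_tte_ws, c(0, -log(6)))
  expect_equal(tr$r_volume, c(0, log(4)))
  bad <- data.frame(r_wir_ws = c(1, -0.1))
  expect_error(log_transform_features(bad), "non-positive")
  # a single relative-features object transforms field-wise
  rf <- structure(list(r_wir = 2.3, r_mre = 1, r_auc = 4, delta_tte = -5,
                       r_volume = 2), class = "relative_features")
  v <- log_transform_features(rf)
  expect_equal(unname(v), c(log(2.3), 0, log(4), -log(6), log(2)))
  # signed log is odd and invertible
  x <- c(-20, -1, 0, 3.5, 40)
  expect_equal(signed_exp(signed_log(x)), x)
  expect_equal(signed_log(-x), -signed_log(x))
})

test_that("fold-wise normalizer z-scores on training parameters only", {
  withr::with_seed(11, {
    x <- matrix(rnorm(60, mean = 5, sd = 2), 30, 2)
  })
  norm <- fit_normalizer(x)
  z <- apply_normalizer(norm, x)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  # a constant shift of validation data propagates through unchanged sd
  zv <- apply_normalizer(norm, x + 1)
  expect_equal(zv - z, matrix(1 / norm$sd[col(z)], nrow(z), ncol(z)))
  expect_error(fit_normalizer(cbind(rep(1, 10))), "zero variance")
})

test_that("normalization parameters never leak from the validation fold", {
  # training fold centered at 0, validation fold deliberately centered at 2:
  # with honest fold-wise normalization the validation z-scores keep a
  # nonzero mean; a leaky normalizer (fitted on all rows) would center them
  withr::with_seed(12, {
    train <- matrix(rnorm(40), 20, 2)
    valid <- matrix(rnorm(20, mean = 2), 10, 2)
  })
  norm <- fit_normalizer(train)
  z_valid <- apply_normalizer(norm, valid)
  expect_gt(min(abs(colMeans(z_valid))), 0.5)
  leaky <- fit_normalizer(rbind(train, valid))
  z_leak <- apply_normalizer(leaky, rbind(train, valid))
  expect_lt(max(abs(colMeans(z_leak))), 1e-10)  # what leakage would look like
})

test_that("IRLS logistic fit matches glm at zero ridge", {
  withr::with_seed(13, {
    x <- matrix(rnorm(200), 100, 2)
    y <- rbinom(100, 1, plogis(0.5 + x %*% c(1, -0.7)))
  })
  fit <- fit_logistic(x, y, ridge_lambda = 0)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$slopes), unname(coef(ref)[-1]), tolerance = 1e-6)
  # duplicating every row leaves the unpenalized fit unchanged
  fit2 <- fit_logistic(rbind(x, x), c(y, y), ridge_lambda = 0)
  expect_equal(fit2$slopes, fit$slopes, tolerance = 1e-6)
  expect_error(fit_logistic(x, rep(1, 100)), "both outcome classes")
})

test_that("logistic fit under independence and separation behaves as theory says", {
  withr::with_seed(14, {
    x <- matrix(rnorm(4000), 2000, 2)
    y <- rbinom(2000, 1, 0.3)
  })
  fit <- fit_logistic(x, y, ridge_lambda = 0)
  expect_equal(unname(fit$slopes), c(0, 0), tolerance = 0.12)
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 0.12)
  # perfectly separated single feature: training AUC 1, monotone probs
  xs <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  ys <- c(0, 0, 0, 1, 1, 1)
  fs <- fit_logistic(xs, ys, ridge_lambda = 1e-4)
  probs <- predict_logistic(fs, xs)
  expect_equal(osteodce:::auc_score(probs, ys), 1)
  expect_true(all(diff(probs) > 0))
})

test_that("rank AUC matches pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    for (i in 1:20) {
      y <- rbinom(40, 1, 0.5)
      if (length(unique(y)) < 2) next
      p <- rnorm(40)
      expect_equal(osteodce:::auc_score(p, y),
                   as.numeric(pROC::auc(pROC::roc(
                     y, p, quiet = TRUE, direction = "<",
                     levels = c(0, 1)))))
    }
  })
})

test_that("corrected resampled t-test CI widens the naive interval", {
  expect_equal(corrected_resampled_ci(rep(0.8, 10), 44, 11), c(0.8, 0.8))
  withr::with_seed(16, scores <- runif(250, 0.7, 1))
  ci <- corrected_resampled_ci(scores, 44, 11)
  naive <- mean(scores) + c(-1, 1) * qt(0.975, 249) * sd(scores) / sqrt(250)
  expect_gt(diff(ci), diff(naive))
  # direct formula evaluation at J=250, test/train = 1/4, var = 0.01
  scores2 <- scores * sqrt(0.01) / sd(scores)
  half <- diff(corrected_resampled_ci(scores2, 200, 50)) / 2
  expect_equal(half, qt(0.975, 249) * sqrt(0.01 * (1 / 250 + 0.25)),
               tolerance = 1e-12)
  expect_error(corrected_resampled_ci(0.8, 44, 11), "2 fold scores")
})

test_that("cross-validation is deterministic and sane on a null cohort", {
  coh <- generate_cohort(cohort_config(seed = 31))
  spec <- model_spec("whole_slab", "r_wir")
  a <- cross_validate(coh, spec, repeats = 5, seed = 7)
  b <- cross_validate(coh, spec, repeats = 5, seed = 7)
  expect_identical(a$scores, b$scores)
  expect_equal(nrow(a$scores), 25)
  expect_true(all(a$scores$auc >= 0 & a$scores$auc <= 1))
  # permuted labels destroy the signal; a single permutation of n=55 labels
  # retains chance association (AUC sd ~ 0.1), so average a few permutations
  null_aucs <- vapply(1:5, function(s) {
    null <- coh
    null$response <- withr::with_seed(s + 40, sample(null$response))
    cross_validate(null, spec, repeats = 10,
                   seed = s + 50)$means[["auc"]]
  }, numeric(1))
  expect_lt(abs(mean(null_aucs) - 0.5), 0.1)
  expect_lt(max(null_aucs), 0.8)  # far below the true-signal regime
})

test_that("model selection maximizes mean AUC with stable tie-breaks", {
  fake <- function(auc, method, features) {
    structure(list(spec = model_spec(method, features),
                   means = c(auc = auc)), class = "cv_result")
  }
  res <- list(fake(0.86, "whole_slab", c("r_mre", "r_auc")),
              fake(0.93, "whole_slab", "r_wir"),
              fake(0.89, "focal_area", "r_auc"))
  expect_equal(select_model(res)$features, "r_wir")
  # tie between single- and two-feature specs: fewer features wins
  tie <- list(fake(0.9, "whole_slab", c("r_wir", "r_mre")),
              fake(0.9, "whole_slab", "r_auc"))
  expect_equal(select_model(tie)$features, "r_auc")
  # permutation invariance of candidate order
  expect_equal(select_model(rev(res))$features,
               select_model(res)$features)
  expect_error(select_model(list()), "no candidate")
  # grid layout: 9 single (incl. rVolume), 12 perfusion pairs, 8 rVolume pairs
  grid <- candidate_model_grid()
  expect_equal(length(grid), 29)
  n_feats <- vapply(grid, function(s) length(s$features), integer(1))
  expect_equal(sum(n_feats == 1), 9)
  has_vol <- vapply(grid, function(s) "r_volume" %in% s$features, logical(1))
  expect_equal(sum(n_feats == 2 & !has_vol), 12)
  expect_equal(sum(n_feats == 2 & has_vol), 8)
})

test_that("Youden threshold equals the exhaustive scan", {
  probs <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  th <- youden_threshold(probs, y)
  expect_equal(as.numeric(th), 0.5)
  expect_equal(attr(th, "J"), 1)
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(6:40, 1)
      p <- runif(n)
      yy <- rbinom(n, 1, 0.5)
      if (length(unique(yy)) < 2) next
      mine <- youden_threshold(p, yy)
      oracle <- brute_force_youden(p, yy)
      expect_equal(attr(mine, "J"), oracle$J, tolerance = 1e-12)
      expect_true(attr(mine, "J") >= 0)
    }
  })
  expect_error(youden_threshold(probs, c(1, 1, 1, 1)), "both outcome")
})

test_that("natural-scale threshold inverts the link, normalization and log", {
  m <- structure(list(
    spec = model_spec("whole_slab", "r_wir"),
    columns = "r_wir_ws",
    normalizer = list(mean = 0, sd = 1),
    intercept = 0, slopes = -1, prob_threshold = 0.5
  ), class = "fitted_response_model")
  nt <- natural_scale_threshold(m)
  expect_equal(nt$threshold, 1.0)
  expect_equal(nt$direction, "poor_below")
  # monotone in the probability threshold (negative slope: lower p, higher x)
  thr_at <- function(p) {
    m$prob_threshold <- p
    natural_scale_threshold(m)$threshold
  }
  expect_true(thr_at(0.3) > thr_at(0.5) && thr_at(0.5) > thr_at(0.7))
  # round trip: predicting at the threshold returns the probability threshold
  coh <- generate_cohort(cohort_config(seed = 33))
  fm <- finalize_model(coh, model_spec("whole_slab", "r_wir"))
  x <- log(fm$natural_threshold$threshold)
  z <- (x - fm$normalizer$mean[1]) / fm$normalizer$sd[1]
  p <- plogis(fm$intercept + fm$slopes[1] * z)
  expect_equal(unname(p), fm$prob_threshold, tolerance = 1e-10)
  # two-feature model cannot be inverted to a scalar cutoff
  fm2 <- finalize_model(coh, model_spec("whole_slab", c("r_wir", "r_mre")))
  expect_error(natural_scale_threshold(fm2), "single-feature")
})

test_that("ratio-to-percent-decrease conversion", {
  expect_equal(round(ratio_to_percent_decrease(2.3)), 57)
  expect_equal(ratio_to_percent_decrease(2.3), 56.5217, tolerance = 1e-4)
  expect_equal(ratio_to_percent_decrease(1), 0)
  expect_equal(ratio_to_percent_decrease(2), 50)
  expect_error(ratio_to_percent_decrease(0), "> 0")
})

test_that("external validation applies the frozen model without refitting", {
  coh <- generate_cohort(cohort_config(seed = 35))
  fm <- finalize_model(coh, model_spec("whole_slab", "r_wir"))
  # test cohort = training cohort: metrics equal resubstitution metrics
  ev <- external_validate(fm, coh, use_combat = FALSE)
  pred_res <- as.integer(fm$training_probs >= fm$prob_threshold)
  y <- as.integer(coh$response == "poor")
  expect_equal(ev$predicted, pred_res)
  expect_equal(ev$accuracy, mean(pred_res == y))
  # label permutation on the test side pushes AUC to chance
  null <- generate_cohort(cohort_config(n_patients = 400, center_id = "test",
                                        seed = 36))
  null$response <- withr::with_seed(37, sample(null$response))
  ev0 <- external_validate(fm, null, use_combat = FALSE)
  expect_lt(abs(ev0$auc - 0.5), 0.1)
  expect_error(external_validate(fm, null, use_combat = TRUE), "train_records")
})
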