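test_that("onset detection fires at the first >20% rise over its own baseline", {
  tic <- new_tic(0:9, c(rep(100, 5), rep(130, 5)))
  det <- detect_t0(tic)
  expect_true(det$enhancing)
  expect_equal(det$t0, 5)

  flat <- new_tic(0:9, rep(100, 10))
  expect_false(detect_t0(flat)$enhancing)

  weak <- new_tic(0:9, c(rep(100, 5), rep(115, 5)))  # 15% rise only
  expect_false(detect_t0(weak)$enhancing)

  expect_error(detect_t0(new_tic(0:1, c(1, 2))), "3 samples")
  # spike at the very first candidate cannot fire before 2 baseline samples
  spike <- new_tic(0:5, c(100, 500, 100, 100, 100, 100))
  expect_false(detect_t0(spike)$enhancing)
})

test_that("onset detection agrees with the brute-force scan oracle", {
  withr::with_seed(101, {
    for (i in 1:300) {
      tic <- random_tic()
      if (length(tic$si) < 3) next
      expect_identical(detect_t0(tic), brute_force_t0(tic))
    }
  })
})

test_that("TTE is the tumor-artery onset difference", {
  artery <- new_tic(0:29, c(rep(100, 9), rep(200, 21)))   # T0 = 9
  tumor <- new_tic(0:29, c(rep(100, 15), rep(200, 15)))   # T0 = 15
  expect_equal(compute_tte(tumor, artery), 6)
  expect_equal(compute_tte(tumor, tumor), 0)
  expect_warning(tte <- compute_tte(artery, tumor), "negative")
  expect_equal(tte, -6)
  flat <- new_tic(0:29, rep(100, 30))
  expect_warning(res <- compute_tte(flat, artery), "non-enhancing")
  expect_true(is.na(res))
})

test_that("wash-in rate matches closed forms", {
  # linear rise 10 units/s from onset 10 s to peak 200, baseline 100
  tic <- rise_tic()
  expect_equal(compute_wir(tic), 0.10)
  # slope invariant under uniform 2 s resampling of the same line
  tic2 <- rise_tic(dt = 2)
  expect_equal(compute_wir(tic2), 0.10)
  # instant jump then plateau: single-pair maximum jump/(dt * baseline)
  jump <- step_tic(base = 100, jump_to = 200, n = 20, jump_at = 11,
                   baseline_window = 1:10)
  expect_equal(compute_wir(jump), 100 / (1 * 100))
  expect_true(is.na(compute_wir(new_tic(0:9, rep(100, 10),
                                        baseline_window = 1:3))))
})

test_that("maximum relative enhancement follows the chosen convention", {
  tic <- rise_tic()  # baseline 100, peak 200
  expect_equal(compute_mre(tic), 1.0)
  expect_equal(compute_mre(tic, convention = "ratio"), 2.0)
  flat <- new_tic(0:9, rep(100, 10), baseline_window = 1:5)
  expect_equal(compute_mre(flat), 0)
})

test_that("curve AUC integrates relative enhancement on the irregular grid", {
  # jump to double baseline held for 100 s: rectangle of height 1
  t <- c(0:9, seq(10, 110, by = 1))
  si <- c(rep(100, 10), rep(200, 101))
  rect <- new_tic(t, si, baseline_window = 1:10)
  expect_equal(compute_auc(rect), 100)
  # jump then linear decay back to baseline: triangle of area 50
  si_tri <- c(rep(100, 10), seq(200, 100, length.out = 101))
  tri <- new_tic(t, si_tri, baseline_window = 1:10)
  expect_equal(compute_auc(tri), 50)
  # flat curve: no enhancement, zero area
  expect_equal(compute_auc(new_tic(0:9, rep(100, 10), baseline_window = 1:5)), 0)
  # trapezoid honors non-uniform spacing: same rectangle, coarsened tail
  t_irr <- c(0:9, 10, 20, 50, 110)
  rect_irr <- new_tic(t_irr, c(rep(100, 10), rep(200, 4)),
                      baseline_window = 1:10)
  expect_equal(compute_auc(rect_irr), 100)
})

test_that("features are scale-invariant and time-shift equivariant", {
  tic <- rise_tic(base = 80, onset = 12, slope = 8, peak = 240, t_end = 60)
  for (c_mult in c(0.5, 3, 17)) {
    scaled <- new_tic(tic$times, tic$si * c_mult, tic$baseline_window)
    expect_equal(detect_t0(scaled)$t0, detect_t0(tic)$t0)
    expect_equal(compute_wir(scaled), compute_wir(tic))
    expect_equal(compute_mre(scaled), compute_mre(tic))
    expect_equal(compute_auc(scaled), compute_auc(tic))
  }
  shift <- 7.5
  moved <- new_tic(tic$times + shift, tic$si, tic$baseline_window)
  expect_equal(detect_t0(moved)$t0, detect_t0(tic)$t0 + shift)
  expect_equal(compute_wir(moved), compute_wir(tic))
  expect_equal(compute_auc(moved), compute_auc(tic))
})

test_that("relative features divide pre by post with eps-censoring", {
  g <- make_sampling_grid(120, 1, 3, 6)
  pre <- perfusion_features(generate_tic(enhancement_params(100, 15, 10, 200), g),
                            generate_tic(enhancement_params(200, 9, 120, 600), g))
  ident <- relative_features(pre, pre, 1000, 1000)
  expect_equal(ident$r_wir, 1)
  expect_equal(ident$r_mre, 1)
  expect_equal(ident$r_auc, 1)
  expect_equal(ident$delta_tte, 0)
  expect_equal(relative_features(pre, pre, 1000, 500)$r_volume, 2)

  # the published decision boundary: 0.10 / 0.043 is just above ratio 2.3
  pre2 <- pre; pre2$wir <- 0.10
  post2 <- pre; post2$wir <- 0.043
  expect_equal(relative_features(pre2, post2, 1, 1)$r_wir, 0.10 / 0.043,
               tolerance = 1e-12)

  # non-enhancing post scan: censored ratios are finite and large,
  # TTE censored at end of acquisition
  post_flat <- perfusion_features(
    generate_tic(enhancement_params(100, 15, 0, 100), g),
    generate_tic(enhancement_params(200, 9, 120, 600), g))
  expect_false(post_flat$enhancing)
  rf <- relative_features(pre, post_flat, 1000, 900)
  expect_true(is.finite(rf$r_wir) && rf$r_wir > 1e3)
  expect_equal(rf$delta_tte, (post_flat$t_end - post_flat$artery_t0) - pre$tte)
  expect_error(relative_features(pre, pre, -1, 1), "volumes")
})

test_that("focal averaging is field-wise with censoring for one dead ROI", {
  g <- make_sampling_grid(120, 1, 3, 6)
  art <- generate_tic(enhancement_params(200, 9, 120, 600), g)
  f1 <- perfusion_features(generate_tic(enhancement_params(100, 13, 10, 200), g), art)
  f2 <- perfusion_features(generate_tic(enhancement_params(100, 17, 20, 300), g), art)
  avg <- focal_average(f1, f2)
  expect_equal(avg$wir, mean(c(f1$wir, f2$wir)))
  expect_equal(avg$tte, mean(c(f1$tte, f2$tte)))
  same <- focal_average(f1, f1)
  expect_equal(same$mre, f1$mre)
  dead <- perfusion_features(generate_tic(enhancement_params(100, 13, 0, 100), g), art)
  mixed <- focal_average(f1, dead, eps = 1e-6)
  expect_true(mixed$enhancing)
  expect_equal(mixed$wir, mean(c(f1$wir, 1e-6)))
  expect_equal(mixed$tte, mean(c(f1$tte, dead$t_end - dead$artery_t0)))
})

test_that("the chord WIR estimator equals max-pair on noiseless curves", {
  expect_equal(compute_wir(rise_tic(), "rise_chord"),
               compute_wir(rise_tic(), "max_pair"))
  jump <- step_tic(base = 100, jump_to = 200, n = 20, jump_at = 11,
                   baseline_window = 1:10)
  expect_equal(compute_wir(jump, "rise_chord"), compute_wir(jump, "max_pair"))
  # rise ending exactly on a sample with a flat plateau: chord is exact
  g <- make_sampling_grid(120, 1, 3, 6)
  for (slope in c(4, 9, 12)) {
    tic <- generate_tic(enhancement_params(100, 14, slope, 280, 0), g)
    expect_equal(compute_wir(tic, "rise_chord"), slope / 100,
                 tolerance = 1e-10)
  }
})

test_that("curve-level extraction recovers the generator's drawn rWIR", {
  # at 2% curve noise the chord estimator keeps the recovery error small;
  # the max-pair estimator would carry the order-statistic bias of a
  # maximum over ~20 noisy single-pair slopes
  coh <- generate_cohort(cohort_config(n_patients = 30, seed = 21),
                         emit_curves = TRUE)
  rec <- vapply(seq_len(nrow(coh)), function(i) {
    pre <- perfusion_features(coh$curves_pre[[i]]$tumor,
                              coh$curves_pre[[i]]$artery,
                              wir_method = "rise_chord")
    post <- perfusion_features(coh$curves_post[[i]]$tumor,
                               coh$curves_post[[i]]$artery,
                               wir_method = "rise_chord")
    relative_features(pre, post, 1, 1)$r_wir
  }, numeric(1))
  rel_err <- abs(rec - coh$r_wir_ws) / coh$r_wir_ws
  expect_lt(median(rel_err), 0.10)
})
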