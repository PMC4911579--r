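test_that("saturation current follows the square-law with correct units and sign", {
  # study geometry, hand-evaluated after unit conversion:
  # (W/2L) = 10, C_i = 9e-5 F/m^2, mu = 1e-6 m^2/Vs, overdrive^2 = 8100 V^2
  i <- saturation_current(-100, v_t = -10, mu = 1e-6,
                          W = 4e-3, L = 200e-6, C_i = 9e-5)
  expect_equal(abs(i), 7.29e-6, tolerance = 1e-12)
  expect_lt(i, 0)  # p-type accumulation carries negative current

  expect_identical(saturation_current(-10, -10, 1e-6, 4e-3, 200e-6, 9e-5), 0)
  # off side of threshold is zero for p-type
  expect_identical(saturation_current(0, -10, 1e-6, 4e-3, 200e-6, 9e-5), 0)
  # linear in mobility
  expect_equal(saturation_current(-100, -10, 2e-6, 4e-3, 200e-6, 9e-5),
               2 * saturation_current(-100, -10, 1e-6, 4e-3, 200e-6, 9e-5))
  expect_error(saturation_current(-100, -10, 1e-6, W = -1, L = 200e-6,
                                  C_i = 9e-5), "positive")
  expect_error(saturation_current(-100, -10, mu = 0, W = 4e-3, L = 200e-6,
                                  C_i = 9e-5), "positive")
})

test_that("noiseless extraction inverts the generator over a parameter grid", {
  for (vt in c(-30, -10, 5)) {
    for (mu in c(5e-7, 1e-6, 2e-6)) {
      tc <- gen_transfer_curve(v_t = vt, mu = mu)
      f <- otft_fit(tc)
      expect_lt(abs(f$threshold_voltage - vt) / abs(vt), 1e-9)
      expect_lt(abs(f$mobility - mu) / mu, 1e-9)
      expect_gt(f$fit_r2, 1 - 1e-12)
      expect_gte(f$n_points, 4)
      expect_true(f$fit_window[1] >= min(tc$v_g) &&
                  f$fit_window[2] <= max(tc$v_g))
    }
  }
})

test_that("extraction stays accurate under multiplicative noise", {
  errs <- vapply(1:50, function(k) {
    f <- otft_fit(gen_transfer_curve(-10, 1e-6, noise_rel = 0.02, seed = k))
    abs(f$threshold_voltage + 10)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("fit window dodges the contact-resistance roll-off", {
  errs <- vapply(1:20, function(k) {
    tc <- gen_transfer_curve(-10, 1e-6, noise_rel = 0.02,
                             rolloff_onset = -70, seed = 400 + k)
    f <- otft_fit(tc)
    # window must not reach past the roll-off onset
    expect_gte(f$fit_window[1], -70)
    abs(f$threshold_voltage + 10)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("degenerate sweeps raise the extraction-failure error", {
  flat <- transfer_curve(seq(20, -100, -10), rep(-1e-9, 13),
                         W = 4e-3, L = 200e-6, C_i = 9e-5)
  expect_error(otft_fit(flat), "extraction failure")
  # n-type sign convention violated (positive branch currents on p device)
  vg <- seq(20, -100, -10)
  i_wrong <- abs(saturation_current(vg, -10, 1e-6, 4e-3, 200e-6, 9e-5))
  bad <- transfer_curve(vg, i_wrong, W = 4e-3, L = 200e-6, C_i = 9e-5)
  expect_error(otft_fit(bad), "extraction failure|data-convention")
})

test_that("otft_fit methods are coherent with the fitted parameters", {
  tc <- gen_transfer_curve(-10, 1e-6, noise_rel = 0.01, seed = 11)
  f <- otft_fit(tc)
  expect_named(coef(f), c("V_T", "mu"))
  # prediction at the fitted parameters reproduces the noiseless law
  expect_equal(predict(f, -100),
               saturation_current(-100, f$threshold_voltage, f$mobility,
                                  tc$W, tc$L, tc$C_i))
  expect_length(residuals(f), f$n_points)
  sims <- simulate(f, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "transfer_curve")
  expect_output(print(summary(f)), "V_T")
})

test_that("normalized response has the study sign convention and invariances", {
  expect_equal(normalized_response(-1e-6, -1e-6), 0)
  # 30% magnitude drop on a negative-current device is -0.30
  expect_equal(normalized_response(-0.7e-6, -1e-6), -0.30)
  expect_error(normalized_response(-1e-6, 0, "d1"), "d1")
  # invariant under common rescaling of both currents
  expect_equal(normalized_response(-0.7e-6, -1e-6),
               normalized_response(-0.7e-3, -1e-3))
})

test_that("first-order decoupling solves each unknown and closes", {
  expect_equal(decompose_response(delta_mu_rel = -0.20,
                                  delta_vt_term = 0)$delta_I_rel, -0.20)
  expect_equal(decompose_response(delta_mu_rel = 0,
                                  delta_vt_term = 0.16)$delta_I_rel, -0.32)
  expect_equal(decompose_response(delta_mu_rel = 0,
                                  delta_vt_term = 0)$delta_I_rel, 0)
  # unknown mobility term
  r <- decompose_response(delta_I_rel = -0.32, delta_vt_term = 0.16)
  expect_equal(r$delta_mu_rel, 0)
  # unknown threshold term
  r <- decompose_response(delta_I_rel = -0.32, delta_mu_rel = 0)
  expect_equal(r$delta_vt_term, 0.16)
  # all three supplied: residual is the closure gap
  r <- decompose_response(delta_I_rel = -0.25, delta_mu_rel = -0.20,
                          delta_vt_term = 0.01)
  expect_equal(r$residual, -0.25 - (-0.20 - 0.02))
  expect_error(decompose_response(delta_I_rel = -0.2), "at least two")
})

test_that("first-order closure residual is quadratic in the perturbation", {
  # noiseless paired curves, |perturbation| <= 0.05 on either channel; the
  # exact residual is t^2 - 2*t*dmu + dmu*t^2, bounded by (3 + |dmu|) eps^2
  resid_at <- function(dmu, dvt_term) {
    dvt <- dvt_term * (-100 - (-10))     # V_G - V_T0 = -90 V
    p <- gen_paired_curves(-10, 1e-6, delta_vt = dvt, delta_mu_rel = dmu)
    pair_response(p$baseline, p$signal)$residual
  }
  for (dmu in c(-0.05, 0, 0.05)) {
    for (dvt_term in c(-0.05, 0, 0.05)) {
      r1 <- resid_at(dmu, dvt_term)
      expect_lte(abs(r1), 3.05 * 0.05^2)
      # second-order scaling: halved perturbations shrink it ~4x (a third
      # of the original leaves room for the cubic cross term)
      if (abs(r1) > 1e-6)
        expect_lte(abs(resid_at(dmu / 2, dvt_term / 2)), abs(r1) / 3)
    }
  }
})

test_that("negative threshold shifts on p-type devices depress the current", {
  # (V_G - V_T0) < 0 and dV_T < 0: positive threshold term, negative dI/I0
  p <- gen_paired_curves(-10, 1e-6, delta_vt = -4.5)
  r <- pair_response(p$baseline, p$signal)
  expect_gt(r$delta_vt_term, 0)
  expect_lt(r$delta_I_rel, 0)
})

test_that("replicate aggregation reports mean, SD and RSD", {
  a <- aggregate_responses(rep(-0.23, 9))
  expect_equal(a$sd, 0)
  expect_equal(a$rsd, 0)
  expect_equal(a$n_devices, 9)
  b <- aggregate_responses(c(-0.2, -0.3, -0.4))
  expect_equal(b$rsd, sd(c(-0.2, -0.3, -0.4)) / 0.3)
})

test_that("Welch comparison matches stats::t.test and the printed verdict", {
  set.seed(42)
  x <- rnorm(9, -0.23, 0.05); y <- rnorm(9, -0.30, 0.17)
  ours <- compare_groups(x, y)
  ref <- t.test(x, y)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # the two published streptavidin responses are not significantly different
  v <- compare_groups(c(-0.23, 0.01, 9), c(-0.30, 0.17, 9))
  expect_false(v$significant)
  expect_gt(v$p_value, 0.05)
  # self-comparison
  self <- compare_groups(x, x)
  expect_equal(self$p_value, 1)
  expect_error(compare_groups(c(-0.2, 0.1, 1), c(-0.3, 0.1, 9)),
               "insufficient replicates")
})
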