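# Recoil model fits, frame-averaging correction, weighted bootstrap.

test_that("noiseless exponential data are fitted exactly and fits are equivariant", {
  t <- seq(0, 10, 0.5)
  d <- data.frame(time_s = t, speed_um_s = 10 * exp(-t / 2))
  f <- fit_recoil(d)
  expect_equal(f$v0, 10, tolerance = 1e-6)
  expect_equal(f$tau, 2, tolerance = 1e-6)

  # scaling speeds scales v0 and leaves tau unchanged
  d2 <- d; d2$speed_um_s <- 3.5 * d2$speed_um_s
  f2 <- fit_recoil(d2)
  expect_equal(f2$v0, 3.5 * f$v0, tolerance = 1e-6)
  expect_equal(f2$tau, f$tau, tolerance = 1e-6)

  # constant-velocity data push tau to the upper bound, with a warning
  dc <- data.frame(time_s = t, speed_um_s = rep(5, length(t)))
  expect_warning(fc <- fit_recoil(dc), "bound")
  expect_true(fc$flagged)
})

test_that("fit recovers parameters under measurement noise", {
  set.seed(11)
  t <- seq(0, 10, length.out = 200)
  n_ok_v <- 0; n_ok_tau <- 0; n_rep <- 120
  for (i in seq_len(n_rep)) {
    v <- pmax(10 * exp(-t / 2) + rnorm(length(t), 0, 1), 0)
    f <- suppressWarnings(fit_recoil(data.frame(time_s = t, speed_um_s = v)))
    if (f$v0 > 9 && f$v0 < 11) n_ok_v <- n_ok_v + 1
    if (f$tau > 1.7 && f$tau < 2.3) n_ok_tau <- n_ok_tau + 1
  }
  expect_gte(n_ok_v / n_rep, 0.95)
  expect_gte(n_ok_tau / n_rep, 0.95)
})

test_that("frame-averaging correction behaves analytically", {
  # no correction in the slow-decay limit
  expect_equal(correct_initial_velocity(list(v0 = 10, tau = 1e9)), 10,
               tolerance = 1e-6)
  expect_equal(correct_initial_velocity(list(v0 = 10, tau = 1)), 16.6)
  expect_equal(correct_initial_velocity(list(v0 = 10, tau = 0.66)), 20)
})

test_that("calibration coefficient is monotone in the frame interval and tau is unbiased", {
  cb1 <- calibrate_bias(0.25, n_sims = 150, seed = 5, duration = 6)
  cb2 <- calibrate_bias(0.5, n_sims = 150, seed = 5, duration = 8)
  cb3 <- calibrate_bias(1.0, n_sims = 150, seed = 5)
  expect_true(cb1$coef < cb2$coef && cb2$coef < cb3$coef)
  expect_lt(cb1$coef, 0.2)
  # fitted decay rates track the truth closely
  expect_lt(cb3$tau_rel_error, 0.05)
})

test_that("weighted bootstrap gives a null p-value near 0.5 for identical conditions", {
  # the two conditions share the very same tracked points, so only the
  # resampling differs
  conds <- data.frame(condition = "L", v0 = 10, tau = 2,
                      n_cuts = 5, markers_per_cut = 8)
  dl <- simulate_recoil_data(conds, seed = 3)
  dr <- dl
  dr$condition <- "R"
  dr$cut_id <- paste0(dr$cut_id, "R")
  d <- recoil_dataset(rbind(as.data.frame(dl)[1:4], as.data.frame(dr)[1:4]))
  boot <- weighted_bootstrap(d, n_boot = 200, seed = 4, contrast = c("L", "R"))
  expect_gt(boot$p_value, 0.25)
  expect_lt(boot$p_value, 0.75)
  expect_true(all(boot$summary$v0_lo < boot$summary$v0))
  expect_true(all(boot$summary$v0 < boot$summary$v0_hi))
})

test_that("clearly separated conditions give a significant one-sided p-value", {
  conds <- data.frame(condition = c("posterior", "anterior"),
                      v0 = c(10, 18), tau = c(2, 1.5),
                      n_cuts = 6, markers_per_cut = 10)
  d <- simulate_recoil_data(conds, seed = 7)
  boot <- weighted_bootstrap(d, n_boot = 300, seed = 8,
                             contrast = c("anterior", "posterior"))
  # "anterior <= posterior" should almost never happen
  expect_lt(boot$p_value, 0.01)
  s <- boot$summary
  expect_gt(s$v0[s$condition == "anterior"], s$v0[s$condition == "posterior"])
})

test_that("per-cut weights equalize contributions within a condition", {
  d <- recoil_dataset(data.frame(
    time_s = rep(0:4, 3), speed_um_s = rep(5, 15),
    cut_id = rep(c("a", "a", "b"), each = 5)[1:15],
    condition = "x"))
  wa <- sum(d$weight[d$cut_id == "a"])
  wb <- sum(d$weight[d$cut_id == "b"])
  expect_equal(wa, wb, tolerance = 1e-12)
  expect_equal(sum(d$weight), 1, tolerance = 1e-12)
})
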