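test_that("trapezoidal AUC and AUMC reproduce simple geometry", {
  p <- conc_time_profile("s", 0:3, c(0, 10, 10, 0), dose = 1)
  expect_equal(auc_trapezoid(p)$auc, 20)  # trapezoid: 5 + 10 + 5
  r <- auc_trapezoid(conc_time_profile("s", c(0, 2), c(5, 5), dose = 1))
  expect_equal(r$auc, 10)
  expect_equal(r$aumc, 10)
  expect_error(auc_trapezoid(p, t_end = 0.5), "t_end")
})

test_that("trapezoid converges to the closed-form exponential integral", {
  times <- seq(0, 100, by = 0.01)
  p <- conc_time_profile("s", times, 100 * exp(-0.1 * times), dose = 1)
  a <- auc_trapezoid(p)
  expect_equal(a$auc, 1000, tolerance = 0.005)
  # log-down trapezoid is exact for a mono-exponential even on a coarse grid
  coarse <- seq(0, 50, by = 2)
  p2 <- conc_time_profile("s", coarse, 100 * exp(-0.1 * coarse), dose = 1)
  expect_equal(auc_trapezoid(p2, method = "linear_up_log_down")$auc,
               1000 * (1 - exp(-5)), tolerance = 1e-9)
})

test_that("AUC is additive over subintervals on any grid", {
  set.seed(11)
  for (i in 1:5) {
    times <- sort(c(0, runif(10, 0, 24), 24))
    conc <- abs(rnorm(12, 50, 20))
    p <- conc_time_profile("s", times, conc, dose = 1)
    a <- times[6]
    full <- auc_trapezoid(p, t_end = 24)$auc
    left <- auc_trapezoid(p, t_end = a)$auc
    p_right <- conc_time_profile("s", times[times >= a] - a, conc[times >= a], dose = 1)
    right <- auc_trapezoid(p_right)$auc
    expect_equal(left + right, full, tolerance = 1e-10)
  }
})

test_that("lambda-z is exact on a noiseless mono-exponential tail", {
  times <- c(0, 0.5, 1, 2, 4, 6, 8, 12)
  conc <- one_compartment_conc(times, 2, 0.2, 1, route = "iv")
  p <- conc_time_profile("s", times, conc, dose = 2, route = "iv")
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.2, tolerance = 1e-10)
  expect_equal(fit$r2adj, 1, tolerance = 1e-9)
  expect_equal(fit$t_half_z, log(2) / 0.2, tolerance = 1e-10)
})

test_that("too few terminal points yields no lambda-z but AUC survives", {
  p <- conc_time_profile("s", c(0, 1, 2, 3), c(0, 100, 80, 60),
                         dose = 1, route = "oral")
  # only 2 quantifiable points after Cmax (Cmax excluded for oral)
  res <- single_dose_nca(p)
  expect_true(res$flags$no_lambda_z)
  expect_true(is.na(res$auc_0inf))
  expect_gt(res$auc_0t, 0)
})

test_that("IV-bolus NCA recovers one-compartment closed forms", {
  res <- single_dose_nca(dense_iv_profile(dose = 2, v = 1, ke = 0.5))
  expect_equal(res$cl_f, 0.5, tolerance = 1e-3)   # L/h/kg
  expect_equal(res$vz_f, 1, tolerance = 1e-3)     # L/kg
  expect_equal(res$mrt_0inf, 2, tolerance = 1e-3) # h
  expect_equal(res$t_half_z, log(2) / 0.5, tolerance = 1e-6)
  expect_false(res$flags$high_extrapolation)
})

test_that("degenerate profiles are rejected or flagged", {
  p0 <- conc_time_profile("s", 0:3, rep(0, 4), dose = 1)
  expect_error(single_dose_nca(p0), "no quantifiable data")
  # truncating a slow profile early forces heavy extrapolation
  times <- c(0, 0.5, 1, 2, 3)
  conc <- one_compartment_conc(times, 2, 0.05, 1, route = "iv")
  p <- conc_time_profile("s", times, conc, dose = 2, route = "iv")
  res <- single_dose_nca(p)
  expect_gt(res$extrap_pct, 20)
  expect_true(res$flags$high_extrapolation)
})

test_that("bioavailability handles identical arms and group means", {
  po <- list(nca_stub(2, auc_0t = 417.73))
  iv <- list(nca_stub(2, auc_0t = 1007.57))
  f <- bioavailability(po, iv, pairing = "ratio_of_means")
  expect_equal(f$f_pct, 100 * 417.73 / 1007.57, tolerance = 1e-12)
  same <- list(nca_stub(2, auc_0t = 500, subject_id = "a"))
  expect_equal(bioavailability(same, same)$f_pct, 100)
  expect_error(bioavailability(po, list()), "missing iv arm")
})

test_that("crossover bioavailability recovers a programmed F", {
  f_true <- 0.4
  iv <- simulate_pk("iv_1cmt", n_subjects = 5, dose = 2, ke = 0.3, v = 5,
                    noise_cv = 0.05, seed = 101)
  po <- simulate_pk("oral_1cmt", n_subjects = 5, dose = 2, ka = 2, ke = 0.3,
                    v = 5, f = f_true, noise_cv = 0.05, seed = 102)
  est <- bioavailability(lapply(po, single_dose_nca),
                         lapply(iv, single_dose_nca),
                         pairing = "by_subject", metric = "auc_0inf")
  expect_equal(est$f_pct, 100 * f_true, tolerance = 0.05)
})

test_that("steady-state metrics follow their definitions", {
  p <- conc_time_profile("s", c(0, 6, 12), rep(300, 3), dose = 5, tau = 12)
  res <- steady_state_metrics(p)
  expect_equal(res$c_av, 300)
  expect_equal(res$df, 0)
  expect_equal(res$auc_ss, 3600)
  expect_error(steady_state_metrics(conc_time_profile("s", c(0, 6, 12),
                                                      rep(300, 3), dose = 5)),
               "tau missing")
  # trough flatness: no trend over steady troughs
  res2 <- steady_state_metrics(p, troughs = c(84.17, 64.21, 86.13, 95.71))
  expect_true(res2$at_steady_state)
})

test_that("dose-proportionality ratios normalize to the lowest dose", {
  groups <- lapply(c(1, 2, 4), function(d) list(nca_stub(d, auc_0t = 100 * d)))
  dp <- dose_proportionality(groups, metric = "auc_0t")
  expect_equal(dp$metric_ratio, c(1, 2, 4))
  expect_equal(dp$dose_ratio, c(1, 2, 4))
  expect_error(dose_proportionality(groups[1]), ">= 2 dose groups")
  expect_error(dose_proportionality(list(groups[[1]], list())), "empty dose group")
})

test_that("dose-dependent clearance shows supra-proportional exposure", {
  # emulate saturable elimination: ke falls as dose rises
  doses <- c(8, 20, 50)
  kes <- c(0.25, 0.18, 0.12)
  groups <- Map(function(d, k) {
    lapply(simulate_pk("oral_1cmt", n_subjects = 3, dose = d, ka = 2, ke = k,
                       v = 8, noise_cv = 0, seed = 7), single_dose_nca)
  }, doses, kes)
  dp <- dose_proportionality(groups, metric = "auc_0t")
  expect_true(all(dp$metric_ratio[-1] > dp$dose_ratio[-1]))
})
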