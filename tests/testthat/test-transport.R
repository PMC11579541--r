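test_that("cumulative receiver amount corrects for sampled aliquots", {
  e <- transport_experiment("AtoB", c0 = 1, times = c(30, 60),
                            receiver_conc = c(1, 1),
                            receiver_volume = 1200, sample_volume = 50)
  expect_equal(cumulative_receiver_amount(e)$q, c(1.20, 1.25))
  # no-replacement limit: zero sample volume leaves Q = C * V_receiver
  e0 <- transport_experiment("AtoB", c0 = 1, times = c(15, 30, 60),
                             receiver_conc = rep(0.5, 3),
                             receiver_volume = 1200, sample_volume = 0)
  expect_equal(cumulative_receiver_amount(e0)$q, rep(0.6, 3))
  expect_equal(cumulative_receiver_amount(e, correct_sampling = FALSE)$q,
               c(1.2, 1.2))
})

test_that("Papp analysis inverts the transport generator at zero noise", {
  sim <- simulate_transport(papp_ab = 1e-5, efflux_factor = 1.9, c0 = 1)
  ab <- apparent_permeability(sim$ab)
  ba <- apparent_permeability(sim$ba)
  expect_equal(ab$papp, 1e-5, tolerance = 1e-8)
  expect_equal(ab$slope_r2, 1, tolerance = 1e-9)
  er <- efflux_ratio(ab, ba)
  expect_equal(er$er, 1.9, tolerance = 1e-8)
  expect_true(er$flags$pgp_substrate)
  # uncorrected analysis of replacement-sampled data understates the flux
  naive <- apparent_permeability(sim$ab, correct_sampling = FALSE)
  expect_lt(naive$papp, ab$papp)
})

test_that("Papp edge cases flag rather than fail", {
  e <- transport_experiment("AtoB", c0 = 1, times = c(15, 30, 60),
                            receiver_conc = rep(0, 3))
  expect_warning(res <- apparent_permeability(e), "floored")
  expect_equal(res$papp, 0)
  expect_true(res$flags$nonpositive_slope)
  expect_error(apparent_permeability(
    transport_experiment("AtoB", 1, c(15, 30), c(0.1, 0.2))), ">= 3")
  # BBB flag follows the 3e-6 cm/s threshold on the A-to-B direction
  fast <- apparent_permeability(simulate_transport(papp_ab = 6.6e-6)$ab)
  expect_true(fast$flags$bbb_permeable)
  slow <- apparent_permeability(simulate_transport(papp_ab = 1e-6)$ab)
  expect_false(slow$flags$bbb_permeable)
  # sink-condition warning when receiver approaches donor concentration
  sat <- transport_experiment("AtoB", c0 = 1, times = c(15, 30, 60),
                              receiver_conc = c(0.05, 0.09, 0.15))
  expect_true(apparent_permeability(sat)$flags$sink_violation)
})

test_that("efflux ratio is symmetric, scale-invariant and censorable", {
  sim <- simulate_transport(papp_ab = 1e-5, efflux_factor = 1)
  er <- efflux_ratio(apparent_permeability(sim$ab),
                     apparent_permeability(sim$ba))
  expect_equal(er$er, 1, tolerance = 1e-8)
  expect_false(er$flags$pgp_substrate)
  # common rescaling of both donor concentrations leaves ER unchanged
  s1 <- simulate_transport(papp_ab = 1e-5, efflux_factor = 1.9, c0 = 0.2)
  s2 <- simulate_transport(papp_ab = 1e-5, efflux_factor = 1.9, c0 = 5)
  er1 <- efflux_ratio(apparent_permeability(s1$ab), apparent_permeability(s1$ba))
  er2 <- efflux_ratio(apparent_permeability(s2$ab), apparent_permeability(s2$ba))
  expect_equal(er1$er, er2$er, tolerance = 1e-8)
  # zero A-to-B permeability censors the ratio
  zero_ab <- transport_experiment("AtoB", 1, c(15, 30, 60), rep(0, 3))
  suppressWarnings(pz <- apparent_permeability(zero_ab))
  erc <- efflux_ratio(pz, apparent_permeability(s1$ba))
  expect_true(erc$flags$er_censored)
  expect_true(is.na(erc$er))
})

test_that("inhibitor comparison quantifies efflux collapse", {
  base <- simulate_transport(papp_ab = 1e-5, efflux_factor = 1.9)
  inh <- simulate_transport(papp_ab = 1e-5, efflux_factor = 1.9,
                            inhibitor = "verapamil")
  res <- inhibitor_effect(list(base$ab, base$ba), list(inh$ab, inh$ba))
  ab_row <- res$comparison[res$comparison$direction == "AtoB", ]
  expect_gt(ab_row$fold_change, 1)
  expect_equal(res$er_summary$er_base, 1.9, tolerance = 1e-8)
  expect_equal(res$er_summary$er_inhibited, 1, tolerance = 1e-8)
  # identical data gives fold-change 1 everywhere
  same <- inhibitor_effect(list(base$ab, base$ba), list(base$ab, base$ba))
  expect_equal(same$comparison$fold_change, c(1, 1), tolerance = 1e-12)
  expect_error(inhibitor_effect(list(base$ab), list()), "empty")
  expect_error(inhibitor_effect(list(base$ab), list(base$ba)), "unmatched")
})

test_that("TC50 fitting recovers a programmed midpoint and censors flat curves", {
  conc <- c(0.5, 2, 8, 20, 50, 80, 120, 200, 500)
  tc50_true <- 80
  rgr_true <- 100 / (1 + exp((log(conc) - log(tc50_true)) / 0.5))
  set.seed(42)
  rgr <- rgr_true * (1 + rnorm(length(conc), 0, 0.02))
  fit <- fit_tc50(conc, rgr)
  expect_false(fit$censored)
  expect_equal(fit$tc50, tc50_true, tolerance = 0.10)
  # all-viable curve is censored above the tested range
  flat <- fit_tc50(conc, rep(100, length(conc)) + rnorm(9, 0, 0.5))
  expect_true(flat$censored)
  expect_equal(flat$censor_bound, 500)
  expect_error(fit_tc50(c(1, 10, 100), c(100, 60, 20)), ">= 5")
})
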