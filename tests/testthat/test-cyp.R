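test_that("transformation ratio follows its definition", {
  expect_equal(transformation_ratio(1, 1)$transformed_pct, 0)
  expect_equal(transformation_ratio(0.7373, 1, "2C19")$transformed_pct, 26.27,
               tolerance = 1e-9)
  expect_equal(transformation_ratio(0.7551, 1, "3A4")$transformed_pct, 24.49,
               tolerance = 1e-9)
  expect_error(transformation_ratio(0.5, 0), "control")
  # NADPH-free negative control validates the run
  expect_true(transformation_ratio(0.7, 1, negative_control_pct = 1)$valid_run)
  expect_false(transformation_ratio(0.7, 1, negative_control_pct = 20)$valid_run)
})

test_that("IC50 fitting recovers programmed values across a potency grid", {
  conc <- c(0.1, 0.5, 2, 10, 50, 100)
  grid <- expand.grid(ic50 = c(1, 10, 50), hill = c(0.8, 1, 1.5))
  ok <- mapply(function(ic50, hill) {
    s <- simulate_inhibition("3A4", ic50 = ic50, hill = hill, conc = conc,
                             noise_cv = 0.03, seed = round(1000 * ic50 + 10 * hill))
    fit <- fit_ic50(s)
    !fit$censored && abs(fit$ic50 - ic50) / ic50 < 0.15
  }, grid$ic50, grid$hill)
  expect_gte(mean(ok), 0.9)
})

test_that("activity staying above 50% is always censored, never numeric", {
  conc <- c(0.1, 1, 10, 50, 100)
  for (ic50_true in c(150, 400, 1000)) {
    s <- simulate_inhibition("2D6", ic50 = ic50_true, conc = conc, noise_cv = 0)
    fit <- fit_ic50(s)
    expect_true(fit$censored)
    expect_equal(fit$censor_bound, 100)
    expect_match(fit$label, "> 100")
  }
  # weak-inhibition pattern: ~34% maximal inhibition still censored
  s <- inhibition_series("2D6", conc,
                         cbind(c(99, 97, 90, 78, 65.86)))
  fit <- fit_ic50(s)
  expect_true(fit$censored)
  expect_equal(fit$max_inhibition_pct, 100 - 65.86)
})

test_that("a symmetric curve crossing 50% at a tested point returns it", {
  conc <- c(1, 5, 25, 125, 625)
  s <- simulate_inhibition("1A2", ic50 = 25, hill = 1, conc = conc, noise_cv = 0)
  fit <- fit_ic50(s)
  expect_equal(fit$ic50, 25, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
})

test_that("inhibition classes use censoring and the 10/50 umol/L bands", {
  mk <- function(ic50, censored, max_inh) {
    structure(list(ic50 = ic50, censored = censored, censor_bound = 100,
                   max_inhibition_pct = max_inh),
              class = "ic50_result")
  }
  expect_equal(classify_inhibition(mk(NA, TRUE, 34.14)), "weak")
  expect_equal(classify_inhibition(mk(NA, TRUE, 5)), "negligible")
  expect_equal(classify_inhibition(mk(1, FALSE, 95)), "potent")
  expect_equal(classify_inhibition(mk(30, FALSE, 80)), "moderate")
  expect_equal(classify_inhibition(mk(80, FALSE, 55)), "weak")
})
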