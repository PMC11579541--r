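test_that("fit_depletion inverts a noise-free mono-exponential exactly", {
  ke_true <- 0.0541
  s <- simulate_depletion("rat", ke = ke_true,
                          times = c(0, 2, 5, 10, 15), n_replicates = 3)
  fit <- fit_depletion(s)
  expect_equal(fit$ke_mean, ke_true, tolerance = 1e-10)
  expect_equal(fit$t_half_mean, 0.693 / ke_true, tolerance = 1e-10)
  expect_equal(unname(fit$r2), rep(1, 3), tolerance = 1e-9)
  # half-life lands on the rat-liver-microsome magnitude
  expect_equal(fit$t_half_mean, 12.81, tolerance = 1e-3)
})

test_that("a flat depletion series is flagged stable with infinite half-life", {
  s <- depletion_series("human", c(0, 15, 30, 60), rep(100, 4))
  fit <- fit_depletion(s)
  expect_true(fit$stable)
  expect_equal(fit$t_half_mean, Inf)
  res <- microsomal_stability(s)
  expect_equal(res$cl_int_mean, 0)
  expect_equal(res$cl_h_mean, 0)
})

test_that("the linear window auto-detects a depletion plateau", {
  s <- simulate_depletion("rat", ke = 0.0541,
                          times = c(0, 2, 5, 10, 15, 30, 60),
                          n_replicates = 1, plateau_after = 15)
  fit <- fit_depletion(s)
  expect_equal(fit$window, c(0, 15))
  # explicit window overrides detection
  s2 <- depletion_series("rat", s$times, s$remaining, linear_window = c(0, 10))
  expect_equal(fit_depletion(s2)$window, c(0, 10))
})

test_that("intrinsic clearance scales half-life with the species constants", {
  # doubling the half-life halves the clearance
  expect_equal(intrinsic_clearance(100, 0.2, "rat"),
               2 * intrinsic_clearance(200, 0.2, "rat"))
  # published human and monkey half-lives land on the published CL_int
  expect_equal(intrinsic_clearance(249.30, 0.2, "human"), 16.08,
               tolerance = 0.01)
  expect_equal(intrinsic_clearance(7.57, 0.2, "monkey"), 618.10,
               tolerance = 0.01)
  expect_error(intrinsic_clearance(100, 0.2, "mouse"), "unknown species")
  expect_error(intrinsic_clearance(-1, 0.2, "rat"), "t_half")
})

test_that("well-stirred clearance is flow-bounded and monotone", {
  expect_equal(hepatic_clearance(0, "rat"), 0)
  qh <- species_scaling("human")$qh
  expect_equal(hepatic_clearance(1e12, "human"), qh, tolerance = 1e-6)
  grid <- 10^seq(-2, 4, length.out = 40)
  clh <- hepatic_clearance(grid, "dog")
  expect_true(all(clh < species_scaling("dog")$qh))
  expect_true(all(diff(clh) > 0))
  expect_equal(hepatic_clearance(16.08, "human"), 9.05, tolerance = 0.01)
})

test_that("species are ranked by turnover with ties flagged", {
  mk <- function(ke) list(ke_mean = ke)
  # ke from the published half-lives: monkey > rat > dog > human
  res <- list(human = mk(0.693 / 249.30), dog = mk(0.693 / 138.42),
              monkey = mk(0.693 / 7.57), rat = mk(0.693 / 12.81))
  rank <- species_rank(res)
  expect_equal(rank$species, c("monkey", "rat", "dog", "human"))
  expect_false(any(rank$tied))
  expect_equal(nrow(species_rank(list(rat = mk(0.1)))), 1L)
  tied <- species_rank(list(a = mk(0.2), b = mk(0.2)))
  expect_true(all(tied$tied))
})

test_that("unknown species never defaults silently", {
  expect_error(species_scaling("mouse"), "unknown species")
  expect_error(species_scaling(NA_character_), "unknown species")
})
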