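small_dataset <- function(sigma = 0, seed = 1) {
  cached(paste0("gld_", sigma, "_", seed),
         generate_growth_law_data(nutrient_grid = c(0.2, 0.5, 1.0),
                                  inhibitor_grid = c(1, 0.6),
                                  sigma = sigma, seed = seed))
}

test_that("noiseless growth-law data equals the model predictions", {
  ds <- small_dataset(sigma = 0)
  expect_equal(ds$lam_obs, ds$lam_true)
  expect_equal(ds$phi_R_obs, ds$phi_R_true)
  expect_true(all(ds$converged))
  expect_true(all(ds$phi_R_obs >= 0 & ds$phi_R_obs <= 1))
  # growth rises with nutrient quality at zero inhibitor
  unin <- ds[ds$inhibitor == 1, ]
  expect_true(all(diff(unin$lam_obs[order(unin$n_s)]) > 0))
})

test_that("the generator is deterministic given its seed", {
  d1 <- generate_growth_law_data(nutrient_grid = c(0.3, 1),
                                 inhibitor_grid = 1, sigma = 0.05, seed = 7)
  d2 <- generate_growth_law_data(nutrient_grid = c(0.3, 1),
                                 inhibitor_grid = 1, sigma = 0.05, seed = 7)
  expect_identical(d1$lam_obs, d2$lam_obs)
  d3 <- generate_growth_law_data(nutrient_grid = c(0.3, 1),
                                 inhibitor_grid = 1, sigma = 0.05, seed = 8)
  expect_false(identical(d1$lam_obs, d3$lam_obs))
  expect_identical(attr(d1, "seed"), 7)
})

test_that("fitting from the truth is a no-op with zero loss", {
  ds <- small_dataset(sigma = 0)
  fit <- fit_growth_law_params(ds, "gamma_max")
  expect_lt(fit$loss, 1e-10)
  expect_equal(unname(fit$estimates["gamma_max"]), 1260, tolerance = 1e-4)
})

test_that("a perturbed elongation rate is recovered from noiseless data", {
  ds <- small_dataset(sigma = 0)
  fit <- fit_growth_law_params(ds, "gamma_max",
                               start = c(gamma_max = 2500))
  expect_equal(unname(fit$estimates["gamma_max"]), 1260, tolerance = 0.01)
})

test_that("fit input validation is strict", {
  ds <- small_dataset(sigma = 0)
  expect_error(fit_growth_law_params(ds, character(0)), "non-empty")
  expect_error(fit_growth_law_params(ds, "not_a_param"), "unknown")
  expect_error(fit_growth_law_params(ds, "gamma_max",
                                     start = c(gamma_max = 1e9),
                                     bounds = list(gamma_max = c(100, 2000))),
               "bounds")
  expect_error(generate_growth_law_data(nutrient_grid = numeric(0)),
               "non-empty")
})

test_that("recovery error grows with observation noise", {
  err_at <- function(sigma, seed) {
    ds <- generate_growth_law_data(nutrient_grid = c(0.3, 1.0),
                                   inhibitor_grid = 1,
                                   sigma = sigma, seed = seed)
    fit <- fit_growth_law_params(ds, "gamma_max",
                                 start = c(gamma_max = 1600))
    abs(fit$estimates[["gamma_max"]] - 1260) / 1260
  }
  noiseless <- mean(vapply(1:3, function(s) err_at(0, s), numeric(1)))
  noisy <- mean(vapply(1:3, function(s) err_at(0.1, s), numeric(1)))
  expect_lt(noiseless, 0.01)
  expect_gt(noisy, noiseless)
})
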