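test_that("the all-zero state is an exact equilibrium", {
  m <- base_model()
  y <- initial_state(m)
  y[] <- 0
  expect_identical(cell_ode_rhs(0, y, m), y * 0)
})

test_that("non-finite states are rejected with the species index", {
  m <- base_model()
  y <- initial_state(m)
  y["e"] <- NaN
  expect_error(cell_ode_rhs(0, y, m), "index 2")
})

test_that("default steady state converges and is self-consistent", {
  ss <- base_steady()
  expect_true(ss$converged)
  expect_gt(ss$lam, 0)
  expect_true(all(ss$state >= 0))
  f <- cell_ode_rhs(0, ss$state, base_model())
  expect_lt(max(abs(f) / pmax(1, abs(ss$state))), 1e-6)
})

test_that("re-solving from a converged steady state is idempotent", {
  ss <- base_steady()
  ss2 <- solve_steady_state(base_model(), init = ss$state)
  expect_identical(ss2$newton_steps, 0L)
  expect_equal(ss2$state, ss$state, tolerance = 1e-10)
})

test_that("steady state agrees between long-time integration and Newton", {
  # oracle: pure trajectory integration, no Newton polish
  m <- base_model()
  sim <- simulate_model(m, times = c(0, 1e5))
  y_int <- as.numeric(sim[2, species_names(m)])
  ss <- base_steady()
  expect_equal(y_int / pmax(ss$state, 1e-12), rep(1, length(y_int)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sim$lam[2], ss$lam, tolerance = 1e-6)
})

test_that("the interior steady state is reached from distinct initials", {
  ss1 <- base_steady()
  init2 <- initial_state(base_model(),
                         overrides = c(s_i = 10, e = 5000, R = 500,
                                       p_H = 1e5))
  ss2 <- solve_steady_state(base_model(), init = init2,
                            newton_first = FALSE)
  expect_true(ss2$converged)
  expect_equal(as.numeric(ss2$state), as.numeric(ss1$state),
               tolerance = 1e-6)
})

test_that("removing the substrate collapses energy and growth", {
  ss <- solve_steady_state(cell_model(host_params(s_ext = 0)))
  expect_lt(ss$state[["e"]], 1e-3)
  expect_lt(ss$lam, 1e-6)
})

test_that("trajectories respect non-negativity and saturation bounds", {
  m <- base_model()
  p <- host_params()
  sim <- simulate_model(m, times = seq(0, 2000, by = 50))
  sp <- as.matrix(sim[, species_names(m)])
  expect_true(min(sp) >= -1e-9)
  gam <- p$gamma_max * sim$e / (p$K_gamma + sim$e)
  for (X in c("T", "E", "H", "R")) {
    # translation flux bounded by c * gamma_max / n
    flux <- sim[[paste0("c_", X)]] * gam / p[[paste0("n_", X)]]
    expect_true(all(flux <= sim[[paste0("c_", X)]] * p$gamma_max /
                      p[[paste0("n_", X)]] + 1e-9))
  }
})

test_that("growth laws: nutrient quality and translation inhibition", {
  # nutrient sweep: lambda and phi_R co-increase
  lam <- phi <- numeric(0)
  warm <- NULL
  for (ns in c(0.1, 0.3, 1.0)) {
    ss <- solve_steady_state(cell_model(host_params(n_s = ns)), init = warm,
                             newton_first = !is.null(warm))
    warm <- ss$state
    lam <- c(lam, ss$lam); phi <- c(phi, ss$phi_R)
  }
  expect_true(all(diff(lam) > 0))
  expect_true(all(diff(phi) > 0))
  # chloramphenicol mimic: reducing gamma_max raises phi_R, lowers lambda
  ss_inh <- solve_steady_state(cell_model(host_params(gamma_max = 630)))
  ss0 <- base_steady()
  expect_lt(ss_inh$lam, ss0$lam)
  expect_gt(ss_inh$phi_R, ss0$phi_R)
})

test_that("complexes only decay when binding is switched off", {
  p <- host_params(b_T = 0, b_E = 0, b_H = 0, b_R = 0)
  m <- cell_model(p)
  y <- initial_state(m, overrides = c(c_T = 5, c_E = 5, c_H = 5, c_R = 5))
  f <- cell_ode_rhs(0, y, m)
  names(f) <- species_names(m)
  expect_true(all(f[c("c_T", "c_E", "c_H", "c_R")] <= 0))
})

test_that("host parameter validation rejects bad values", {
  expect_error(host_params(gamma_max = -1), "strictly positive")
  expect_error(host_params(delta_m = -0.1), "non-negative")
  expect_error(host_params(h_H = 0.5), "h_H")
  expect_error(host_params(nonsense = 1), "unknown")
})
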