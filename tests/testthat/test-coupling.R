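test_that("isocost OLS fit matches a normal-equations oracle", {
  # brute-force normal equations, independent of stats::lm
  ols_oracle <- function(x, y) {
    X <- cbind(1, x)
    unname(solve(t(X) %*% X, t(X) %*% y))
  }
  set.seed(42)
  for (rep in 1:5) {
    x <- runif(3 + rep, 0, 100)
    x <- sort(x)
    y <- 50 - 0.3 * x + rnorm(length(x), 0, 2)
    fit <- fit_isocost_line(x, y)
    beta <- ols_oracle(x, y)
    expect_equal(fit$intercept, beta[1, 1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2, 1], tolerance = 1e-10)
  }
  # exact on collinear input
  fit <- fit_isocost_line(c(0, 1, 2), c(5, 4, 3))
  expect_equal(fit$slope, -1)
  expect_equal(fit$intercept, 5)
  expect_equal(fit$r_squared, 1)
  # two-point arithmetic
  fit2 <- fit_isocost_line(c(0, 1), c(1, 0))
  expect_equal(fit2$slope, -1)
  expect_equal(fit2$intercept, 1)
  # constant constitutive value gives slope exactly 0
  fit3 <- fit_isocost_line(c(1, 2, 3), c(7, 7, 7))
  expect_equal(fit3$slope, 0)
})

test_that("a silent circuit gene leaves the model unchanged", {
  m0 <- opool_model()
  m1 <- add_circuit_gene(m0, circuit_gene("dead", omega = 0, pool = "host"))
  ss0 <- opool_steady()
  ss1 <- solve_steady_state(m1)
  shared <- species_names(m0)
  expect_equal(as.numeric(ss1$state[shared]), as.numeric(ss0$state),
               tolerance = 1e-8)
  expect_lt(ss1$state[["p_dead"]], 1e-8)
})

test_that("a strongly binding host gene depletes free host ribosomes", {
  m <- add_circuit_gene(base_model(),
                        circuit_gene("hog", omega = 100, pool = "host",
                                     b = 50))
  ss <- solve_steady_state(m)
  expect_lt(ss$state[["R"]], base_steady()$state[["R"]])
})

test_that("genes on distinct pools share no binding reaction", {
  m <- cell_model()
  m <- add_o_pool(m, o_pool_spec("a", omega_rho = 100))
  m <- add_o_pool(m, o_pool_spec("b", omega_rho = 100))
  m <- add_circuit_gene(m, circuit_gene("g1", omega = 10, pool = "a"))
  m <- add_circuit_gene(m, circuit_gene("g2", omega = 10, pool = "b"))
  bm <- ribopool:::build_cell_model(m)
  r1 <- bm$tt$i_rib[match("g1", bm$tt$label)]
  r2 <- bm$tt$i_rib[match("g2", bm$tt$label)]
  expect_false(r1 == r2)
  # reaction-network audit: each translation row has exactly one ribosome
  # partner, and host rows never touch pool ribosomes
  host_rows <- match(c("T", "E", "H", "R"), bm$tt$label)
  expect_true(all(bm$tt$i_rib[host_rows] == match("R", bm$species)))
})

test_that("isocost sweep warm and cold starts agree", {
  m <- two_reporter_model()
  grid <- c(1, 100, 1000)
  sw_warm <- isocost_sweep(m, "rfp", "gfp", grid)
  # cold: each point solved independently from the default initial state
  cold <- vapply(grid, function(w) {
    mm <- add_circuit_gene(
      add_o_pool(cell_model(), o_pool_spec("o1", omega_rho = 500)),
      circuit_gene("gfp", omega = 100, pool = "host"))
    mm <- add_circuit_gene(mm, circuit_gene("rfp", omega = w,
                                            pool = "host"))
    ss <- solve_steady_state(mm)
    c(ss$state[["p_gfp"]], ss$state[["p_rfp"]])
  }, numeric(2))
  expect_equal(sw_warm$constitutive_ss, cold[1, ], tolerance = 1e-6)
  expect_equal(sw_warm$induced_ss, cold[2, ], tolerance = 1e-6)
})

test_that("isocost sweep validates its inputs and normalises to [0, 1]", {
  m <- two_reporter_model()
  expect_error(isocost_sweep(m, "rfp", "gfp", numeric(0)), "non-empty")
  expect_error(isocost_sweep(m, "rfp", "gfp", c(10, 1)), "increasing")
  expect_error(isocost_sweep(m, "nope", "gfp", c(1, 10)), "not registered")
  sw <- isocost_sweep(m, "rfp", "gfp", c(1, 30, 1000))
  expect_true(all(sw$induced_norm >= 0 & sw$induced_norm <= 1))
  expect_true(all(sw$constitutive_norm >= 0 & sw$constitutive_norm <= 1))
  expect_equal(max(sw$induced_norm), 1)
  expect_lt(sw$slope_norm, 0)  # induction costs constitutive expression
})

test_that("an uninduced two-pool study shows zero constitutive drop", {
  tp <- two_pool_decoupling(omega_rho_grid1 = 100, omega_rho_grid2 = 100,
                            omega_grid = 0)
  expect_equal(tp$best$gfp_drop_pct, 0)
})

test_that("the configuration table matches a standalone sweep", {
  grid <- c(1, 30, 1000)
  cc <- configuration_comparison(configs = "hh", omega_grid = grid)
  m <- two_reporter_model(rfp_pool = "host", gfp_pool = "host")
  sw <- isocost_sweep(m, "rfp", "gfp", grid)
  expect_equal(cc$table$slope, sw$slope, tolerance = 1e-8)
  expect_equal(cc$sweeps$hh$constitutive_ss, sw$constitutive_ss,
               tolerance = 1e-8)
})
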