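test_that("a silent pool reduces exactly to the base model", {
  mo <- opool_model(omega_rho = 0)
  mb <- base_model()
  # algebraic identity of the shared dynamics on random states
  for (seed in 1:5) {
    yb <- random_state(mb, seed)
    yo <- initial_state(mo)
    yo[names(yb)] <- yb
    yo[c("rho_o1", "P_o1")] <- 0
    fb <- cell_ode_rhs(0, yb, mb)
    fo <- cell_ode_rhs(0, yo, mo)
    names(fo) <- species_names(mo)
    expect_equal(as.numeric(fo[names(yb)]), as.numeric(fb),
                 tolerance = 1e-14)
    expect_identical(as.numeric(fo[c("rho_o1", "P_o1")]), c(0, 0))
  }
  # the base steady state, padded with zeros, is a steady state of the
  # extended model: solving from it returns it unchanged
  ssb <- base_steady()
  padded <- initial_state(mo)
  padded[names(ssb$state)] <- ssb$state
  padded[c("rho_o1", "P_o1")] <- 0
  sso <- solve_steady_state(mo, init = padded)
  expect_true(sso$converged)
  expect_equal(as.numeric(sso$state[species_names(mb)]),
               as.numeric(ssb$state), tolerance = 1e-10)
  # an independent cold solve lands on the same state within solver tol
  sso2 <- solve_steady_state(mo)
  expect_equal(as.numeric(sso2$state[species_names(mb)]),
               as.numeric(ssb$state), tolerance = 1e-6)
})

test_that("without assembly the o-ribosome pool can only shrink", {
  mo <- opool_model(b_rho = 0)
  y <- initial_state(mo, overrides = c(P_o1 = 100))
  sim <- simulate_model(mo, times = seq(0, 500, by = 50))
  expect_true(all(diff(sim$P_o1) <= 1e-9))
})

test_that("o-rRNA expression sequesters empty ribosomes from the host", {
  sso <- opool_steady()
  ssb <- base_steady()
  expect_gt(sso$state[["P_o1"]], 0)
  expect_lt(sso$state[["R"]], ssb$state[["R"]])
})

test_that("pool assembly flux balances pool consumption at steady state", {
  sso <- opool_steady()
  st <- sso$state
  p <- host_params()
  spec <- o_pool_spec("o1", omega_rho = 500)
  asm <- spec$b_rho * st[["p_R"]] * st[["rho_o1"]] -
    spec$u_rho * st[["P_o1"]]
  lam <- sso$lam
  # no circuit genes: net assembly goes to degradation + dilution of P
  expect_equal(asm, (p$delta_R + lam) * st[["P_o1"]], tolerance = 1e-6)
})

test_that("two identical pools reach a symmetric steady state", {
  m <- cell_model()
  m <- add_o_pool(m, o_pool_spec("a", omega_rho = 300))
  m <- add_o_pool(m, o_pool_spec("b", omega_rho = 300))
  m <- add_circuit_gene(m, circuit_gene("g1", omega = 50, pool = "a"))
  m <- add_circuit_gene(m, circuit_gene("g2", omega = 50, pool = "b"))
  ss <- solve_steady_state(m)
  expect_true(ss$converged)
  expect_equal(ss$state[["rho_a"]], ss$state[["rho_b"]], tolerance = 1e-8)
  expect_equal(ss$state[["P_a"]], ss$state[["P_b"]], tolerance = 1e-8)
  expect_equal(ss$state[["p_g1"]], ss$state[["p_g2"]], tolerance = 1e-8)
})

test_that("pool size response is monotone and burden is bounded", {
  m <- opool_model(omega_rho = 0)
  tab <- pool_size_response(m, c(0, 100, 500))
  expect_equal(tab$P[1], 0, tolerance = 1e-8)
  expect_true(all(diff(tab$P) > 0))
  expect_true(all(tab$converged))
  # growth burden of a gene-free pool is modest (regression bound)
  expect_gt(tab$lam[3], 0.8 * tab$lam[1])
  expect_error(pool_size_response(m, numeric(0)), "non-empty")
})

test_that("duplicate pool ids and bad specs are rejected", {
  m <- opool_model()
  expect_error(add_o_pool(m, o_pool_spec("o1", omega_rho = 1)),
               "already registered")
  expect_error(o_pool_spec("host", omega_rho = 1), "reserved")
  expect_error(o_pool_spec("x", omega_rho = -1), "omega_rho")
})

test_that("one-way interference is off by default and structural when on", {
  m0 <- add_circuit_gene(opool_model(),
                         circuit_gene("hgene", omega = 50, pool = "host"))
  expect_false(any(grepl("^cx_", species_names(m0))))
  m1 <- add_circuit_gene(
    add_o_pool(cell_model(), o_pool_spec("o1", omega_rho = 500,
                                         b_cross = 0.1)),
    circuit_gene("hgene", omega = 50, pool = "host"))
  expect_true("cx_hgene_o1" %in% species_names(m1))
  # o-ribosome cross-translation adds to host-RBS gene output
  ss0 <- solve_steady_state(m0)
  ss1 <- solve_steady_state(m1)
  expect_true(ss1$converged)
  expect_gt(ss1$state[["p_hgene"]], ss0$state[["p_hgene"]])
})
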