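test_that("a silent repressor reduces the closed loop to the open loop", {
  ctrl <- controller_params(omega_F = 0, target_pool = "o1")
  mcl <- controller_model(ctrl = ctrl, omega_rho_max = 500)
  mol <- open_loop_model(omega_rho = 500)
  # algebraic identity of the shared dynamics on random states
  for (seed in 1:5) {
    yo <- random_state(mol, seed)
    yc <- initial_state(mcl)
    yc[names(yo)] <- yo
    yc[c("m_F", "c_F", "p_F")] <- 0
    fo <- cell_ode_rhs(0, yo, mol)
    fc <- cell_ode_rhs(0, yc, mcl)
    names(fc) <- species_names(mcl)
    expect_equal(as.numeric(fc[names(yo)]), as.numeric(fo),
                 tolerance = 1e-14)
    expect_identical(as.numeric(fc[c("m_F", "c_F", "p_F")]), c(0, 0, 0))
  }
  ss_cl <- solve_steady_state(mcl)
  ss_ol <- solve_steady_state(mol)
  expect_equal(as.numeric(ss_cl$state[species_names(mol)]),
               as.numeric(ss_ol$state), tolerance = 1e-10)
})

test_that("repressor level senses circuit translational demand", {
  # at fixed controller, steady-state p_F falls as circuit demand rises
  ctrl <- controller_params(target_pool = "o1")
  pf <- numeric(0)
  warm <- NULL
  for (w in c(1, 30, 1000)) {
    m <- controller_model(ctrl = ctrl, omega_rfp = w)
    ss <- solve_steady_state(m, init = warm, newton_first = !is.null(warm))
    warm <- ss$state
    pf <- c(pf, ss$state[["p_F"]])
  }
  expect_true(all(diff(pf) < 0))
})

test_that("induction de-represses o-rRNA production in the step response", {
  tr <- cached("step_resp", closed_loop_step_response(
    controller_model(), gene = "rfp", omega_before = 1,
    omega_after = 100, t_step = 400, horizon = 3000, dt = 20))
  pre <- tr[tr$phase == "pre", ]
  post <- tr[tr$phase == "post", ]
  # repression factor relaxes (less repression) after induction
  expect_gt(post$rep_factor[nrow(post)], pre$rep_factor[nrow(pre)])
  # repressor protein falls
  expect_lt(post$p_F[nrow(post)], pre$p_F[nrow(pre)])
  expect_error(closed_loop_step_response(controller_model(), t_step = 10,
                                         horizon = 5), "t_step")
})

test_that("a zero-size step leaves the trajectories flat", {
  tr <- closed_loop_step_response(controller_model(), gene = "rfp",
                                  omega_before = 1, omega_after = 1,
                                  t_step = 200, horizon = 600, dt = 50)
  expect_equal(tr$p_gfp[nrow(tr)], tr$p_gfp[1], tolerance = 1e-5)
  expect_equal(tr$rep_factor[nrow(tr)], tr$rep_factor[1], tolerance = 1e-5)
})

test_that("open-loop matching reproduces the closed-loop expression", {
  mcl <- cached("mcl_default", controller_model())
  mol <- open_loop_model()
  mt <- cached("ol_match", tune_open_loop_match(mcl, mol))
  expect_lt(mt$rel_error, 1e-3)
  # matched open loop run at the found omega_rho reproduces the target
  ss <- solve_steady_state(set_pool_omega(mol, "o1", mt$omega_rho))
  expect_equal(ss$state[["p_gfp"]], mt$target, tolerance = 1e-3)
})

test_that("an unrepressed closed loop matches its own pool rate", {
  # silent repressor gene and repression factor ~ 1: the closed loop is
  # dynamically identical to an open loop, so matching must recover its
  # own omega_rho_max (with the repressor expressed, the extra pool load
  # would legitimately shift the matched rate)
  ctrl <- controller_params(omega_F = 0, k_D = 1e12, target_pool = "o1")
  mcl <- controller_model(ctrl = ctrl, omega_rho_max = 400)
  mol <- open_loop_model(omega_rho = 100)
  mt <- tune_open_loop_match(mcl, mol)
  expect_equal(mt$omega_rho, 400, tolerance = 0.01)
})

test_that("design search honours its contract on a tiny grid", {
  des <- cached("tiny_design", design_controller(
    bounds = list(b_F = c(5, 50), k_D = c(50, 500)),
    n_grid = 2, w = 0, omega_grid = c(1, 100, 1000)))
  fr <- des$frontier
  ok <- !is.na(fr$J)
  expect_true(any(ok))
  # with w = 0 the optimum minimises |slope| over the evaluated grid
  expect_equal(des$best$J, min(abs(fr$slope_norm[ok])))
  expect_true(all(abs(des$best$slope_norm) <= abs(fr$slope_norm[ok]) + 1e-12))
  expect_error(design_controller(bounds = list(b_F = c(-1, 5))), "positive")
})

test_that("robustness Monte Carlo is seeded and conserves draws", {
  mc1 <- robustness_mc(n = 3, frac = 0.4, seed = 11,
                       omega_grid = c(1, 100, 1000))
  mc2 <- robustness_mc(n = 3, frac = 0.4, seed = 11,
                       omega_grid = c(1, 100, 1000))
  expect_identical(mc1$draws, mc2$draws)
  expect_equal(nrow(mc1$draws), 3)
  expect_equal(sum(mc1$draws$converged) + mc1$n_excluded, 3)
  # frac = 0 reproduces the unperturbed optimum in every draw
  mc0 <- robustness_mc(n = 2, frac = 0, seed = 5,
                       omega_grid = c(1, 100, 1000))
  expect_equal(mc0$draws$slope_norm[1], mc0$draws$slope_norm[2],
               tolerance = 1e-10)
  expect_equal(mc0$draws$slope_norm[1], mc0$baseline$slope_norm,
               tolerance = 1e-8)
  expect_error(robustness_mc(n = 2, frac = 0.5), "seed")
})
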