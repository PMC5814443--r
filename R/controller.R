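# Dynamic resource allocation controller: closed-loop circuit builders,
# step response, open-loop matching, design search, sensitivity sweeps and
# the robustness Monte Carlo.

#' Build the closed-loop controller circuit
#'
#' Constructs the standard two-reporter circuit on a single repressible
#' orthogonal pool -- constitutive `gfp`, inducible `rfp`, both translated
#' by the pool -- together with the controller repressor, which is
#' constitutively transcribed, translated by the same pool, and represses
#' the pool's o-rRNA transcription.
#'
#' @param params [host_params()].
#' @param ctrl [controller_params()] (with `target_pool = "o1"`).
#' @param omega_rho_max Maximal (unrepressed) o-rRNA transcription rate of
#'   the pool.
#' @param omega_gfp Constitutive reporter transcription rate.
#' @param omega_rfp Initial transcription rate of the induced reporter.
#' @return A `cell_model`.
#' @export
controller_model <- function(params = host_params(),
                             ctrl = controller_params(),
                             omega_rho_max = 1000,
                             omega_gfp = 100, omega_rfp = 1) {
  m <- cell_model(params)
  m <- add_o_pool(m, o_pool_spec("o1", omega_rho = omega_rho_max,
                                 repressible = TRUE))
  m <- add_circuit_gene(m, circuit_gene("gfp", omega = omega_gfp,
                                        pool = "o1"))
  m <- add_circuit_gene(m, circuit_gene("rfp", omega = omega_rfp,
                                        pool = "o1"))
  add_controller(m, ctrl)
}

#' Build the matching open-loop circuit
#'
#' Same two-reporter circuit on one orthogonal pool, with a fixed o-rRNA
#' transcription rate and no controller.
#'
#' @inheritParams controller_model
#' @param omega_rho Fixed o-rRNA transcription rate.
#' @return A `cell_model`.
#' @export
open_loop_model <- function(params = host_params(), omega_rho = 500,
                            omega_gfp = 100, omega_rfp = 1) {
  m <- cell_model(params)
  m <- add_o_pool(m, o_pool_spec("o1", omega_rho = omega_rho))
  m <- add_circuit_gene(m, circuit_gene("gfp", omega = omega_gfp,
                                        pool = "o1"))
  m <- add_circuit_gene(m, circuit_gene("rfp", omega = omega_rfp,
                                        pool = "o1"))
  m
}

#' Closed-loop response to a step in circuit demand
#'
#' Equilibrates the circuit at the pre-step induction level, then applies a
#' step in the induced gene's transcription rate and integrates the
#' transient. Returns the full trajectories plus the instantaneous
#' repression factor so the controller's sensing action (falling repressor
#' translation, rising o-rRNA production) can be inspected.
#'
#' @param model A `cell_model` (typically from [controller_model()]; a
#'   model without controller gives the open-loop response).
#' @param gene Name of the stepped gene.
#' @param omega_before,omega_after Transcription rate before/after the step.
#' @param t_step Step time (min).
#' @param horizon Total simulated time (min), > `t_step`.
#' @param dt Output resolution (min).
#' @return Data frame of trajectories (`time`, species, `lam`, `rep_factor`,
#'   `phase` pre/post).
#' @export
closed_loop_step_response <- function(model, gene = "rfp",
                                      omega_before = 1, omega_after = 100,
                                      t_step = 500, horizon = 2000,
                                      dt = 10) {
  if (t_step <= 0 || t_step >= horizon)
    stop("t_step must lie strictly inside (0, horizon)", call. = FALSE)
  bm <- as_built(model)
  bm0 <- set_gene_omega(bm, gene, omega_before)
  ss0 <- solve_steady_state(bm0)
  pre <- simulate_model(bm0, times = seq(0, t_step, by = dt),
                        init = ss0$state)
  bm1 <- set_gene_omega(bm, gene, omega_after)
  post <- simulate_model(bm1, times = seq(t_step, horizon, by = dt),
                         init = as.numeric(pre[nrow(pre), bm$species]))
  pre$phase <- "pre"
  post$phase <- "post"
  out <- rbind(pre[-nrow(pre), ], post)
  if (!is.null(bm$ctrl)) {
    out$rep_factor <- repression_factor(out$p_F, bm$ctrl$k_D, bm$ctrl$h)
  } else {
    out$rep_factor <- 1
  }
  out
}

#' Match open-loop o-rRNA production to a closed-loop circuit
#'
#' Finds the fixed o-rRNA transcription rate at which the open-loop circuit
#' produces the same pre-induction constitutive protein level as the
#' closed-loop circuit, by scalar root finding in `log10(omega_rho)`.
#'
#' @param model_cl Closed-loop `cell_model` (with controller).
#' @param model_ol Open-loop `cell_model` sharing the circuit definition.
#' @param gene Constitutive gene to match (default `"gfp"`).
#' @param rel_tol Relative matching tolerance on the protein level.
#' @param interval Log10 search interval for `omega_rho`. Defaults to
#'   `[1e-2, omega_rho_max of the closed loop's pool]`: repression only
#'   ever reduces the effective o-rRNA rate, and far larger fixed pools
#'   push the host into collapse where expression is no longer monotone
#'   in `omega_rho`.
#' @return List with `omega_rho`, `target` (closed-loop protein level),
#'   `achieved`, `rel_error`.
#' @export
tune_open_loop_match <- function(model_cl, model_ol, gene = "gfp",
                                 rel_tol = 1e-3, interval = NULL) {
  bm_cl <- as_built(model_cl)
  target <- solve_steady_state(bm_cl)$state[[paste0("p_", gene)]]
  bm_ol <- as_built(model_ol)
  pid <- bm_ol$pool_ids[1]
  if (is.null(interval))
    interval <- c(-2, log10(max(bm_cl$pool_omega)))
  warm <- new.env(parent = emptyenv())
  warm$state <- NULL
  eval_gfp <- function(lw) {
    bmi <- set_pool_omega(bm_ol, pid, 10^lw)
    ss <- solve_steady_state(bmi, init = warm$state,
                             newton_first = !is.null(warm$state))
    warm$state <- ss$state
    ss$state[[paste0("p_", gene)]]
  }
  f <- function(lw) eval_gfp(lw) - target
  flo <- f(interval[1]); fhi <- f(interval[2])
  # accept an endpoint that already matches (e.g. a feedback-free closed
  # loop whose own omega_rho_max is the upper bound of the search)
  for (ei in 1:2) {
    fe <- c(flo, fhi)[ei]
    if (abs(fe) / target <= rel_tol) {
      w <- 10^interval[ei]
      return(list(omega_rho = w, target = target,
                  achieved = target + fe, rel_error = abs(fe) / target))
    }
  }
  if (flo * fhi > 0)
    stop("no omega_rho in 10^[", interval[1], ", ", interval[2],
         "] matches the closed-loop expression", call. = FALSE)
  rt <- stats::uniroot(f, interval, tol = 1e-6)
  achieved <- eval_gfp(rt$root)
  rel <- abs(achieved - target) / target
  if (rel > rel_tol)
    warning("open-loop match achieved only ", signif(rel, 3),
            " relative error", call. = FALSE)
  list(omega_rho = 10^rt$root, target = target, achieved = achieved,
       rel_error = rel)
}

# slope and pre-induction expression of a two-reporter circuit model
circuit_coupling <- function(model, omega_grid, warm_states = NULL,
                             tol = 1e-8) {
  sw <- isocost_sweep(model, "rfp", "gfp", omega_grid,
                      warm_states = warm_states, tol = tol)
  list(slope_norm = sw$slope_norm, slope = sw$slope,
       expression = sw$constitutive_ss[1], sweep = sw)
}

#' Grid search for controller parameters
#'
#' Evaluates candidate controllers on a log-spaced grid over the design
#' box (`omega_rho_max`, `omega_F`, `b_F`, `k_D`, `h`) and scores each by
#' `J = |slope_norm| + w * shortfall`, where `slope_norm` is the
#' normalised isocost slope of the closed-loop circuit and `shortfall` is
#' the relative loss of pre-induction constitutive expression versus a
#' fixed reference: the uncontrolled pool at `omega_rho_ref`. (A reference
#' that moves with the candidate's own `omega_rho_max` is degenerate --
#' an uncontrolled pool at very high o-rRNA production burdens the host so
#' much that its own expression collapses, zeroing the shortfall exactly
#' for the candidates that need it most.) The full evaluated frontier is
#' returned so the decoupling-vs-expression trade-off can be inspected and
#' alternative objectives scored.
#'
#' @param params [host_params()].
#' @param bounds Named list of length-2 numeric ranges for any of
#'   `omega_rho_max`, `omega_F`, `b_F`, `k_D`, `h`.
#' @param n_grid Points per dimension (log-spaced; recycled).
#' @param w Weight of the expression shortfall in the objective.
#' @param omega_rho_ref o-rRNA rate of the uncontrolled reference pool
#'   used for the shortfall.
#' @param omega_grid Induction grid for the isocost sweeps.
#' @param omega_gfp Constitutive transcription rate.
#' @param tol Residual tolerance.
#' @return List with `best` (a [controller_params()] plus `omega_rho_max`
#'   and its scores) and `frontier` (one row per evaluated candidate).
#' @export
design_controller <- function(params = host_params(),
                              bounds = list(omega_rho_max = c(250, 4000),
                                            omega_F = c(10, 1000),
                                            b_F = c(2, 200),
                                            k_D = c(10, 1000),
                                            h = c(1, 4)),
                              n_grid = 3, w = 1, omega_rho_ref = 500,
                              omega_grid = logspace(0, 3, 8),
                              omega_gfp = 100, tol = 1e-8) {
  dims <- c("omega_rho_max", "omega_F", "b_F", "k_D", "h")
  if (!all(names(bounds) %in% dims))
    stop("bounds may only name ", paste(dims, collapse = ", "),
         call. = FALSE)
  if (any(vapply(bounds, function(b) any(!is.finite(b)) || any(b <= 0),
                 logical(1))))
    stop("bounds must be finite and positive", call. = FALSE)
  n_grid <- rep_len(n_grid, length(bounds))
  axes <- mapply(function(b, n) {
    if (n == 1) sqrt(b[1] * b[2]) else logspace(log10(b[1]), log10(b[2]), n)
  }, bounds, n_grid, SIMPLIFY = FALSE)
  cand <- expand.grid(axes)
  fixed <- list(omega_rho_max = 1000, omega_F = 100, b_F = 10, k_D = 100,
                h = 2)
  for (d in dims) if (is.null(cand[[d]])) cand[[d]] <- fixed[[d]]
  cand$slope_norm <- cand$expression <- cand$shortfall <- cand$J <- NA_real_
  mref <- open_loop_model(params, omega_rho = omega_rho_ref,
                          omega_gfp = omega_gfp, omega_rfp = omega_grid[1])
  ref <- solve_steady_state(mref, tol = tol)$state[["p_gfp"]]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    ct <- controller_params(omega_F = cand$omega_F[i], b_F = cand$b_F[i],
                            k_D = cand$k_D[i], h = cand$h[i],
                            target_pool = "o1")
    mcl <- controller_model(params, ct, omega_rho_max = cand$omega_rho_max[i],
                            omega_gfp = omega_gfp,
                            omega_rfp = omega_grid[1])
    cc <- tryCatch(circuit_coupling(mcl, omega_grid, tol = tol),
                   error = function(e) NULL)
    if (is.null(cc) || !all(cc$sweep$converged)) next
    shortfall <- max(0, (ref - cc$expression) / ref)
    J <- abs(cc$slope_norm) + w * shortfall
    cand$slope_norm[i] <- cc$slope_norm
    cand$expression[i] <- cc$expression
    cand$shortfall[i] <- shortfall
    cand$J[i] <- J
    if (is.null(best) || J < best$J) {
      best <- list(ctrl = ct, omega_rho_max = cand$omega_rho_max[i],
                   J = J, slope_norm = cc$slope_norm,
                   expression = cc$expression, shortfall = shortfall)
    }
  }
  if (is.null(best)) stop("no candidate controller converged", call. = FALSE)
  list(best = best, frontier = cand)
}

#' One-parameter controller sensitivity sweep
#'
#' Varies a single design parameter of the closed-loop circuit and reports
#' the coupling (isocost slope) and expression (pre-induction constitutive
#' protein) per value, exposing the decoupling-vs-expression trade-off.
#'
#' @param params [host_params()].
#' @param ctrl Baseline [controller_params()].
#' @param omega_rho_max Baseline maximal o-rRNA transcription rate.
#' @param param One of `"omega_rho_max"`, `"omega_F"`, `"b_F"`, `"k_D"`,
#'   `"h"`.
#' @param values Positive values to scan.
#' @param omega_grid Induction grid.
#' @param omega_gfp Constitutive transcription rate.
#' @param tol Residual tolerance.
#' @return Data frame with `value`, `slope`, `slope_norm`, `expression`,
#'   `n_converged`.
#' @export
sensitivity_sweep <- function(params = host_params(),
                              ctrl = controller_params(),
                              omega_rho_max = 1000,
                              param, values,
                              omega_grid = logspace(0, 3, 8),
                              omega_gfp = 100, tol = 1e-8) {
  allowed <- c("omega_rho_max", "omega_F", "b_F", "k_D", "h")
  if (!param %in% allowed)
    stop("param must be one of ", paste(allowed, collapse = ", "),
         call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)
  out <- data.frame(value = values, slope = NA_real_, slope_norm = NA_real_,
                    expression = NA_real_, n_converged = NA_integer_)
  for (i in seq_along(values)) {
    ct <- unclass(ctrl)
    wrm <- omega_rho_max
    if (param == "omega_rho_max") wrm <- values[i] else ct[[param]] <- values[i]
    ct <- do.call(controller_params, ct)
    mcl <- controller_model(params, ct, omega_rho_max = wrm,
                            omega_gfp = omega_gfp, omega_rfp = omega_grid[1])
    cc <- tryCatch(circuit_coupling(mcl, omega_grid, tol = tol),
                   error = function(e) NULL)
    if (is.null(cc)) next
    out$slope[i] <- cc$slope
    out$slope_norm[i] <- cc$slope_norm
    out$expression[i] <- cc$expression
    out$n_converged[i] <- sum(cc$sweep$converged)
  }
  out
}

#' Robustness Monte Carlo of the controller design
#'
#' Perturbs every parameter controlling o-rRNA production and the
#' controller protein -- `omega_rho_max`, `o_rho`, `b_rho`, `u_rho`,
#' `delta_rho`, `omega_F`, `o_F`, `b_F`, `u_F`, `n_F`, `k_D`, `h` -- by an
#' independent multiplicative factor drawn uniformly from
#' `[1 - frac, 1 + frac]`, recomputes the closed-loop isocost slope per
#' draw, and reports the fraction of draws whose coupling magnitude beats
#' the matched open-loop circuit (same pre-induction expression, fixed
#' o-rRNA production, no controller). Deterministic given `seed`; the Hill
#' coefficient is floored at 1 after perturbation.
#'
#' @param params [host_params()].
#' @param ctrl The controller design to perturb.
#' @param omega_rho_max Maximal o-rRNA transcription rate of the design.
#' @param n Number of draws.
#' @param frac Perturbation half-width in `[0, 1)`.
#' @param seed Integer RNG seed (required; the analysis is stochastic).
#' @param omega_grid Induction grid.
#' @param omega_gfp Constitutive transcription rate.
#' @param tol Residual tolerance.
#' @return List with `draws` (one row per draw: factors, `slope_norm`,
#'   `expression`, `converged`, `outperforms`), `fraction_outperforming`
#'   (over converged draws), `n_excluded`, `open_loop` (matched `omega_rho`
#'   and slope), `baseline` (unperturbed closed-loop slope), `seed`.
#' @export
robustness_mc <- function(params = host_params(),
                          ctrl = controller_params(),
                          omega_rho_max = 1000,
                          n = 1000, frac = 0.5, seed,
                          omega_grid = logspace(0, 3, 8),
                          omega_gfp = 100, tol = 1e-8) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (frac < 0 || frac >= 1) stop("frac must lie in [0, 1)", call. = FALSE)

  mcl <- controller_model(params, ctrl, omega_rho_max = omega_rho_max,
                          omega_gfp = omega_gfp, omega_rfp = omega_grid[1])
  base <- circuit_coupling(mcl, omega_grid, tol = tol)
  mol <- open_loop_model(params, omega_rho = 500, omega_gfp = omega_gfp,
                         omega_rfp = omega_grid[1])
  match_ol <- tune_open_loop_match(mcl, mol)
  mol <- set_pool_omega(mol, "o1", match_ol$omega_rho)
  ol <- circuit_coupling(mol, omega_grid, tol = tol)

  pnames <- c("omega_rho_max", "o_rho", "b_rho", "u_rho", "delta_rho",
              "omega_F", "o_F", "b_F", "u_F", "n_F", "k_D", "h")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fac <- matrix(stats::runif(n * length(pnames), 1 - frac, 1 + frac),
                nrow = n, dimnames = list(NULL, pnames))

  draws <- as.data.frame(fac)
  draws$slope_norm <- draws$expression <- NA_real_
  draws$converged <- FALSE
  pool0 <- o_pool_spec("o1", omega_rho = 1, repressible = TRUE)
  for (i in seq_len(n)) {
    f <- fac[i, ]
    pool <- o_pool_spec("o1",
                        omega_rho = omega_rho_max * f[["omega_rho_max"]],
                        o_rho = pool0$o_rho * f[["o_rho"]],
                        b_rho = pool0$b_rho * f[["b_rho"]],
                        u_rho = pool0$u_rho * f[["u_rho"]],
                        delta_rho = pool0$delta_rho * f[["delta_rho"]],
                        repressible = TRUE)
    ct <- controller_params(omega_F = ctrl$omega_F * f[["omega_F"]],
                            o_F = ctrl$o_F * f[["o_F"]],
                            n_F = ctrl$n_F * f[["n_F"]],
                            b_F = ctrl$b_F * f[["b_F"]],
                            u_F = ctrl$u_F * f[["u_F"]],
                            k_D = ctrl$k_D * f[["k_D"]],
                            h = max(1, ctrl$h * f[["h"]]),
                            target_pool = "o1")
    m <- cell_model(params)
    m <- add_o_pool(m, pool)
    m <- add_circuit_gene(m, circuit_gene("gfp", omega = omega_gfp,
                                          pool = "o1"))
    m <- add_circuit_gene(m, circuit_gene("rfp", omega = omega_grid[1],
                                          pool = "o1"))
    m <- add_controller(m, ct)
    cc <- tryCatch(
      suppressWarnings(circuit_coupling(m, omega_grid,
                                        warm_states = base$sweep$states,
                                        tol = tol)),
      error = function(e) NULL)
    if (!is.null(cc) && all(cc$sweep$converged)) {
      draws$slope_norm[i] <- cc$slope_norm
      draws$expression[i] <- cc$expression
      draws$converged[i] <- TRUE
    }
  }
  draws$outperforms <- draws$converged &
    abs(draws$slope_norm) < abs(ol$slope_norm)
  n_conv <- sum(draws$converged)
  list(draws = draws,
       fraction_outperforming = if (n_conv)
         sum(draws$outperforms) / n_conv else NA_real_,
       n_excluded = n - n_conv,
       open_loop = list(omega_rho = match_ol$omega_rho,
                        slope_norm = ol$slope_norm, slope = ol$slope),
       baseline = list(slope_norm = base$slope_norm, slope = base$slope,
                       expression = base$expression),
       seed = seed)
}
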