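# ODE right-hand side and steady-state machinery.
#
# The state layout and reaction bookkeeping live in the built model
# (see build_cell_model); the RHS below is written against precomputed
# integer index vectors so that it stays cheap inside stiff integration
# and finite-difference Jacobians.

#' Evaluate the model's ODE right-hand side
#'
#' Time-autonomous mass-action dynamics of the full model: substrate import
#' and catabolism, energy-limited transcription, reversible ribosome-mRNA
#' binding, translation (which consumes energy in proportion to protein
#' length), ribosome biosynthesis from protein and rRNA components,
#' orthogonal-pool assembly and translation, optional controller repression
#' and pathway kinetics, with every species degraded (`delta` terms) and
#' diluted at the growth rate `lambda`.
#'
#' @param t Time (min); unused (autonomous system) but kept for solvers.
#' @param state Numeric state vector in model layout order.
#' @param model A `cell_model` or built model.
#' @return Numeric vector of time derivatives, one per species.
#' @export
cell_ode_rhs <- function(t, state, model) {
  bm <- as_built(model)
  check_state(state, bm)
  bad <- which(!is.finite(state))
  if (length(bad))
    stop("non-finite state at species index ", bad[1], " ('",
         bm$species[bad[1]], "')", call. = FALSE)
  stats::setNames(rhs_raw(state, bm), bm$species)
}

rhs_raw <- function(y, bm) {
  p <- bm$p
  tt <- bm$tt
  e <- y[2L]
  gam <- p$gamma_max * e / (p$K_gamma + e)
  m <- y[tt$i_m]
  cc <- y[tt$i_c]
  ctot <- sum(cc)
  lam <- gam * ctot / p$M
  v <- gam * cc / tt$n
  rib <- y[tt$i_rib]
  bind <- tt$b * rib * m
  unb <- tt$u * cc

  tx <- tt$omega * e / (tt$o + e)
  tx[bm$iH_row] <- tx[bm$iH_row] / (1 + (y[bm$i_pH] / p$K_H)^p$h_H)

  dy <- numeric(bm$n)

  # mRNA and protein species
  flux_m <- v + unb - bind
  prim <- tt$primary
  if (bm$shared_m) {
    for (rr in seq_along(flux_m)) {
      dy[tt$i_m[rr]] <- dy[tt$i_m[rr]] + flux_m[rr]
      dy[tt$i_p[rr]] <- dy[tt$i_p[rr]] + v[rr]
    }
    dy[tt$i_m[prim]] <- dy[tt$i_m[prim]] + tx[prim] -
      (tt$delta_m[prim] + lam) * m[prim]
    dy[tt$i_p[prim]] <- dy[tt$i_p[prim]] - lam * y[tt$i_p[prim]]
  } else {
    dy[tt$i_m] <- tx - (tt$delta_m + lam) * m + flux_m
    dy[tt$i_p] <- v - lam * y[tt$i_p]
  }

  # translation complexes
  dy[tt$i_c] <- bind - unb - v - lam * cc

  # ribosome assembly: p_R + r <-> R and p_R + rho_k <-> P_k
  ipR <- bm$idx$p_R; ir <- bm$idx$r; iR <- bm$idx$R
  pR <- y[ipR]; r_ <- y[ir]; R_ <- y[iR]
  asm_host <- p$b_r * pR * r_ - p$u_r * R_
  dy[ipR] <- dy[ipR] - p$delta_pR * pR - asm_host
  dy[ir] <- p$omega_r * e / (p$o_r + e) - asm_host - (p$delta_r + lam) * r_
  fl <- bm$rib_rows[[1L]]
  dy[iR] <- asm_host + sum(v[fl] + unb[fl] - bind[fl]) -
    (p$delta_R + lam) * R_

  if (bm$n_pool) {
    rep_fac <- rep(1, bm$n_pool)
    if (!is.null(bm$ctrl)) {
      k <- bm$ctrl$target_k
      if (bm$pool_repressible[k]) {
        rep_fac[k] <- 1 / (1 + (y[bm$ctrl$i_pF] / bm$ctrl$k_D)^bm$ctrl$h)
      }
    }
    for (k in seq_len(bm$n_pool)) {
      rho <- y[bm$irho[k]]; P <- y[bm$iP[k]]
      asm <- bm$pool_b[k] * pR * rho - bm$pool_u[k] * P
      dy[ipR] <- dy[ipR] - asm
      dy[bm$irho[k]] <- bm$pool_omega[k] * rep_fac[k] * e /
        (bm$pool_o[k] + e) - asm - (bm$pool_delta[k] + lam) * rho
      fk <- bm$rib_rows[[k + 1L]]
      dy[bm$iP[k]] <- asm +
        (if (length(fk)) sum(v[fk] + unb[fk] - bind[fk]) else 0) -
        (p$delta_R + lam) * P
    }
  }

  # metabolism and energy
  si <- y[1L]
  v_imp <- y[bm$idx$p_T] * p$v_T * p$s_ext / (p$K_T + p$s_ext)
  v_cat <- y[bm$idx$p_E] * p$v_E * si / (p$K_E + si)
  dy[1L] <- v_imp - v_cat - lam * si
  dy[2L] <- p$n_s * v_cat - gam * ctot - lam * e

  # metabolic pathway (irreversible Michaelis-Menten chain)
  if (!is.null(bm$pw)) {
    pw <- bm$pw
    S <- c(pw$S, y[pw$i_I])
    vstep <- pw$kcat * y[pw$i_p] * S / (pw$Km + S)
    dy[pw$i_I] <- vstep[1:4] - vstep[2:5] - lam * y[pw$i_I]
    dy[pw$i_V] <- vstep[5] - lam * y[pw$i_V]
  }

  dy
}

# deSolve-facing wrapper
rhs_desolve <- function(t, y, bm) list(rhs_raw(y, bm))

scaled_residual <- function(f, y) {
  max(abs(f) / pmax(1, abs(y)))
}

# ---- Newton refinement -------------------------------------------------

fd_jacobian <- function(bm, y, f0 = rhs_raw(y, bm)) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1.5e-8 * max(abs(y[j]), 1)
    yp <- y
    yp[j] <- y[j] + h
    J[, j] <- (rhs_raw(yp, bm) - f0) / h
  }
  J
}

newton_refine <- function(bm, y, tol = 1e-10, max_iter = 30L) {
  f <- rhs_raw(y, bm)
  res <- scaled_residual(f, y)
  steps <- 0L
  while (is.finite(res) && res > tol && steps < max_iter) {
    J <- fd_jacobian(bm, y, f)
    dy <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dy)) {
      mu <- 1e-8 * max(abs(J))
      dy <- tryCatch(solve(J + diag(mu, length(y)), -f),
                     error = function(e) NULL)
      if (is.null(dy)) break
    }
    alpha <- 1
    improved <- FALSE
    for (ls in 1:12) {
      yn <- y + alpha * dy
      fn <- tryCatch(rhs_raw(yn, bm), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn))) {
        rn <- scaled_residual(fn, yn)
        if (rn < res) {
          y <- yn; f <- fn; res <- rn; improved <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!improved) break
    steps <- steps + 1L
  }
  list(y = y, residual = res, steps = steps, converged = res <= tol)
}

# ---- simulation and steady states --------------------------------------

#' Simulate model trajectories
#'
#' Integrates the stiff ODE system with `deSolve::lsoda`.
#'
#' @param model A `cell_model` or built model.
#' @param times Numeric vector of output times (min).
#' @param init Initial state; defaults to [initial_state()].
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A data frame with a `time` column, one column per species
#'   (negative solver undershoot clipped to zero) and a derived `lam`
#'   column (growth rate per min).
#' @examples
#' \donttest{
#' sim <- simulate_model(cell_model(), times = seq(0, 1000, by = 100))
#' tail(sim$lam, 1)
#' }
#' @export
simulate_model <- function(model, times, init = NULL,
                           rtol = 1e-9, atol = 1e-12) {
  bm <- as_built(model)
  if (is.null(init)) init <- initial_state(bm$model)
  check_state(init, bm)
  if (any(init < 0)) stop("initial state must be non-negative", call. = FALSE)
  out <- deSolve::lsoda(y = stats::setNames(as.numeric(init), bm$species),
                        times = times, func = rhs_desolve, parms = bm,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  sp <- df[, -1, drop = FALSE]
  sp[sp < 0 & sp > -1e-9] <- 0
  df[, -1] <- sp
  df$lam <- apply(as.matrix(sp), 1, function(yy) growth_rate(yy, bm))
  df
}

#' Solve for a steady state
#'
#' Integrates with a stiff solver (with an early-exit root condition on the
#' scaled residual) and then refines the endpoint by damped Newton
#' iteration on the right-hand side. When an initial state close to the
#' solution is supplied (e.g. warm-starting a parameter sweep), Newton is
#' attempted first and integration is skipped if it converges. Re-solving
#' from a converged steady state returns it unchanged with zero accepted
#' Newton steps.
#'
#' @param model A `cell_model` or built model.
#' @param init Initial state (named or plain numeric in layout order). By
#'   default, a model carrying pools or circuit genes is initialised from
#'   the steady state of its circuit-free host core (extension species at
#'   zero) -- the in-silico analogue of transforming a construct into a
#'   healthily growing cell; the bare host model starts from
#'   [initial_state()].
#' @param t_max Integration horizon (min).
#' @param tol Convergence tolerance on the scaled residual
#'   `max(|dy/dt| / max(1, |y|))`.
#' @param newton_first Try Newton from `init` before integrating. Defaults
#'   to `TRUE` when `init` is supplied.
#' @param rtol,atol Integration tolerances.
#' @return An object of class `steady_state`: list with `state` (named,
#'   clipped to non-negative), `lam`, `phi_R`, `residual_norm`, `converged`,
#'   `newton_steps`.
#' @examples
#' \donttest{
#' ss <- solve_steady_state(cell_model())
#' ss$lam
#' }
#' @export
solve_steady_state <- function(model, init = NULL, t_max = 1e5, tol = 1e-8,
                               newton_first = !is.null(init),
                               rtol = 1e-9, atol = 1e-12) {
  if (t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  bm <- as_built(model)
  y0 <- if (is.null(init)) healthy_initial_state(bm, t_max, rtol, atol)
        else as.numeric(init)
  check_state(y0, bm)
  if (any(y0 < -1e-9)) stop("initial state must be non-negative",
                            call. = FALSE)
  y0 <- pmax(y0, 0)

  if (newton_first) {
    nt <- newton_refine(bm, y0, tol = min(tol, 1e-10))
    if (nt$converged && min(nt$y) > -1e-6) {
      return(finish_steady(bm, nt, tol))
    }
  }

  rootfun <- function(t, y, parms) scaled_residual(rhs_raw(y, parms), y) - tol * 1e-2
  out <- tryCatch(
    deSolve::lsodar(y = y0, times = c(0, t_max), func = rhs_desolve,
                    parms = bm, rootfunc = rootfun,
                    rtol = rtol, atol = atol, maxsteps = 200000),
    error = function(e) NULL)
  if (is.null(out)) {
    # fall back to plain lsoda at looser tolerance, keep last valid state
    out <- tryCatch(
      deSolve::lsoda(y = y0, times = c(0, t_max), func = rhs_desolve,
                     parms = bm, rtol = 1e-6, atol = 1e-9,
                     maxsteps = 200000),
      error = function(e) stop("steady-state integration failed",
                               call. = FALSE))
  }
  yT <- as.numeric(out[nrow(out), -1])
  nt <- newton_refine(bm, pmax(yT, 0), tol = min(tol, 1e-10))
  finish_steady(bm, nt, tol)
}

# Default cold-start: steady state of the circuit-free host core (memoised
# per host parameter set), padded with zeros for all extension species.
# Seeding from a healthy growing cell keeps strongly sequestering circuits
# out of spurious slow transients near the collapsed (non-growing) regime.
.host_core_cache <- new.env(parent = emptyenv())

healthy_initial_state <- function(bm, t_max, rtol, atol) {
  core <- cell_model(bm$p)
  if (bm$n == length(species_names(core))) return(initial_state(core))
  key <- paste(unlist(bm$p), collapse = "|")
  if (is.null(.host_core_cache[[key]])) {
    ss <- solve_steady_state(core, t_max = t_max, rtol = rtol, atol = atol)
    .host_core_cache[[key]] <- ss$state
  }
  y <- stats::setNames(numeric(bm$n), bm$species)
  y[names(.host_core_cache[[key]])] <- .host_core_cache[[key]]
  y
}

finish_steady <- function(bm, nt, tol) {
  y <- nt$y
  y[y < 0 & y > -1e-9] <- 0
  neg_ok <- min(y) >= 0
  st <- stats::setNames(pmax(y, 0), bm$species)
  res <- scaled_residual(rhs_raw(nt$y, bm), nt$y)
  structure(list(state = st,
                 lam = growth_rate(st, bm),
                 phi_R = ribosome_mass_fraction(st, bm),
                 residual_norm = res,
                 converged = res <= tol && neg_ok,
                 newton_steps = nt$steps),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> converged:", x$converged,
      " residual:", format(x$residual_norm, digits = 3),
      " lambda:", format(x$lam, digits = 4), "/min",
      " phi_R:", format(x$phi_R, digits = 3), "\n")
  invisible(x)
}
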