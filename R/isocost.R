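# Isocost-line coupling analysis: induction sweeps, OLS slope fitting,
# the four pool-allocation configurations and the two-pool decoupling
# optimisation.

#' Fit an isocost line by ordinary least squares
#'
#' Straight-line fit of the constitutive reporter against the induced
#' reporter through all points. The slope of this line quantifies
#' resource-mediated gene-gene coupling: how much constitutive expression
#' is lost per unit of induced expression gained under a fixed cellular
#' resource budget.
#'
#' @param induced,constitutive Numeric vectors of equal length (steady-state
#'   protein amounts).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @examples
#' fit_isocost_line(c(0, 1), c(1, 0))  # slope -1, intercept 1
#' @export
fit_isocost_line <- function(induced, constitutive) {
  if (length(induced) != length(constitutive))
    stop("induced and constitutive must have equal length", call. = FALSE)
  keep <- is.finite(induced) & is.finite(constitutive)
  if (sum(keep) < 2)
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_))
  fit <- stats::lm(constitutive[keep] ~ induced[keep])
  co <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((constitutive[keep] - mean(constitutive[keep]))^2)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_)
}

#' Induction sweep with isocost-line fit
#'
#' Sweeps the induced gene's transcription rate over `omega_grid`, solving
#' a steady state per grid point (warm-started from the previous point),
#' and fits the isocost line of constitutive versus induced reporter by
#' ordinary least squares through all converged points. Reporter values are
#' also normalised by the maximum reached across the sweep, giving a
#' dimensionless slope comparable across pool allocations; raw values and
#' the raw-slope fit are always retained alongside.
#'
#' @param model A `cell_model` containing both genes.
#' @param induced,constitutive Names of the induced and constitutive genes.
#' @param omega_grid Strictly increasing transcription-rate grid
#'   (mRNAs per min) for the induced gene.
#' @param warm_states Optional list of states to warm-start each grid point
#'   (as returned in the `states` element of a previous result).
#' @param tol Steady-state residual tolerance.
#' @return An object of class `isocost_result`: a list with the sweep table
#'   (`omega_induced`, `induced_ss`, `constitutive_ss`, `induced_norm`,
#'   `constitutive_norm`, `lam`, `converged`), the raw and normalised OLS
#'   fits (`slope`, `intercept`, `r_squared`, `slope_norm`,
#'   `intercept_norm`), the per-point steady states (`states`) and the gene
#'   names.
#' @export
isocost_sweep <- function(model, induced, constitutive, omega_grid,
                          warm_states = NULL, tol = 1e-8) {
  if (length(omega_grid) < 1L)
    stop("omega_grid must be non-empty", call. = FALSE)
  if (is.unsorted(omega_grid, strictly = TRUE))
    stop("omega_grid must be strictly increasing", call. = FALSE)
  bm <- as_built(model)
  for (g in c(induced, constitutive)) {
    if (!(g %in% bm$tt$label))
      stop("gene '", g, "' is not registered", call. = FALSE)
  }
  n <- length(omega_grid)
  ind <- con <- lam <- numeric(n)
  conv <- logical(n)
  states <- vector("list", n)
  prev <- NULL
  for (i in seq_len(n)) {
    bmi <- set_gene_omega(bm, induced, omega_grid[i])
    init <- if (!is.null(warm_states) && !is.null(warm_states[[i]]))
      warm_states[[i]] else prev
    ss <- solve_steady_state(bmi, init = init, tol = tol,
                             newton_first = !is.null(init))
    states[[i]] <- ss$state
    prev <- ss$state
    ind[i] <- ss$state[[paste0("p_", induced)]]
    con[i] <- ss$state[[paste0("p_", constitutive)]]
    lam[i] <- ss$lam
    conv[i] <- ss$converged
    if (!ss$converged)
      warning("steady state did not converge at omega = ", omega_grid[i],
              "; point excluded from fit", call. = FALSE)
  }
  ind_f <- ifelse(conv, ind, NA_real_)
  con_f <- ifelse(conv, con, NA_real_)
  fit_raw <- fit_isocost_line(ind_f, con_f)
  imax <- max(ind_f, na.rm = TRUE)
  cmax <- max(con_f, na.rm = TRUE)
  ind_n <- if (imax > 0) ind / imax else ind
  con_n <- if (cmax > 0) con / cmax else con
  fit_n <- fit_isocost_line(ifelse(conv, ind_n, NA_real_),
                            ifelse(conv, con_n, NA_real_))
  structure(list(
    induced = induced, constitutive = constitutive,
    omega_induced = omega_grid,
    induced_ss = ind, constitutive_ss = con,
    induced_norm = ind_n, constitutive_norm = con_n,
    lam = lam, converged = conv,
    slope = fit_raw$slope, intercept = fit_raw$intercept,
    r_squared = fit_raw$r_squared,
    slope_norm = fit_n$slope, intercept_norm = fit_n$intercept,
    r_squared_norm = fit_n$r_squared,
    states = states
  ), class = "isocost_result")
}

#' @export
print.isocost_result <- function(x, ...) {
  cat("<isocost_result> ", x$constitutive, " vs ", x$induced,
      " over ", length(x$omega_induced), " points\n", sep = "")
  cat("  slope (raw):", format(x$slope, digits = 4),
      "  slope (normalised):", format(x$slope_norm, digits = 4), "\n")
  invisible(x)
}

#' Convert an isocost result to a data frame
#'
#' @param x An `isocost_result`.
#' @param ... Unused.
#' @return One row per grid point.
#' @export
as.data.frame.isocost_result <- function(x, ...) {
  data.frame(omega_induced = x$omega_induced,
             induced_ss = x$induced_ss,
             constitutive_ss = x$constitutive_ss,
             induced_norm = x$induced_norm,
             constitutive_norm = x$constitutive_norm,
             lam = x$lam, converged = x$converged)
}

#' Steady-state response to orthogonal pool size
#'
#' Sweeps the single registered pool's maximal o-rRNA transcription rate
#' and reports the steady-state o-ribosome level, free host ribosomes and
#' growth rate, for assessing the (non-linear) physiological burden of
#' o-ribosome production.
#'
#' @param model A `cell_model` with exactly one registered pool.
#' @param omega_rho_values Numeric vector of o-rRNA transcription rates.
#' @param tol Residual tolerance.
#' @return Data frame with columns `omega_rho`, `P`, `R`, `lam`,
#'   `converged`.
#' @export
pool_size_response <- function(model, omega_rho_values, tol = 1e-8) {
  stopifnot(inherits(model, "cell_model"))
  if (length(omega_rho_values) < 1L)
    stop("omega_rho_values must be non-empty", call. = FALSE)
  if (length(model$pools) != 1L)
    stop("pool_size_response requires exactly one registered pool",
         call. = FALSE)
  pid <- names(model$pools)[1]
  bm <- as_built(model)
  out <- data.frame(omega_rho = omega_rho_values, P = NA_real_,
                    R = NA_real_, lam = NA_real_, converged = NA)
  prev <- NULL
  for (i in seq_along(omega_rho_values)) {
    bmi <- set_pool_omega(bm, pid, omega_rho_values[i])
    ss <- solve_steady_state(bmi, init = prev, tol = tol,
                             newton_first = !is.null(prev))
    prev <- ss$state
    out$P[i] <- ss$state[[paste0("P_", pid)]]
    out$R[i] <- ss$state[["R"]]
    out$lam[i] <- ss$lam
    out$converged[i] <- ss$converged
  }
  out
}

#' Compare gene coupling across the four ribosome-pool allocations
#'
#' Builds, for each requested configuration, a two-reporter circuit
#' (constitutive `gfp` at `omega_gfp`; induced `rfp` swept over
#' `omega_grid`) on a host model carrying one orthogonal pool at
#' `omega_rho`, and reports the fitted isocost slope per configuration.
#' Configuration labels give the pool of the induced then the constitutive
#' gene: `"hh"`, `"oo"`, `"ho"` (induced on host, constitutive orthogonal;
#' the insulated arrangement) and `"oh"` (induced orthogonal, constitutive
#' host; the arrangement that depletes shared ribosome components).
#'
#' Cross-configuration comparisons use the normalised slope
#' (`slope_norm`), which is dimensionless and so comparable across
#' allocations with very different absolute expression scales; the raw
#' slope in protein-molecule units is always reported alongside. Note
#' that on a fully subscribed shared pool the normalised slope is pinned
#' near the transcription-share bound regardless of kinetics (see the
#' methods vignette).
#'
#' @param params [host_params()] for the base model.
#' @param configs Subset of `c("hh", "oo", "ho", "oh")`.
#' @param omega_grid Induction grid for `rfp`.
#' @param omega_rho o-rRNA transcription rate of the shared pool.
#' @param omega_gfp Constitutive transcription rate.
#' @param tol Residual tolerance.
#' @return List with `table` (one row per configuration: slopes raw and
#'   normalised, r-squared, convergence count) and `sweeps` (the underlying
#'   `isocost_result` objects, named by configuration).
#' @export
configuration_comparison <- function(params = host_params(),
                                     configs = c("hh", "oo", "ho", "oh"),
                                     omega_grid = logspace(0, 3, 10),
                                     omega_rho = 500,
                                     omega_gfp = 100, tol = 1e-8) {
  allowed <- c("hh", "oo", "ho", "oh")
  if (!all(configs %in% allowed))
    stop("configs must be a subset of ", paste(allowed, collapse = ", "),
         call. = FALSE)
  sweeps <- list()
  for (cf in configs) {
    rfp_pool <- if (substr(cf, 1, 1) == "o") "o1" else "host"
    gfp_pool <- if (substr(cf, 2, 2) == "o") "o1" else "host"
    m <- cell_model(params)
    m <- add_o_pool(m, o_pool_spec("o1", omega_rho = omega_rho))
    m <- add_circuit_gene(m, circuit_gene("gfp", omega = omega_gfp,
                                          pool = gfp_pool))
    m <- add_circuit_gene(m, circuit_gene("rfp", omega = omega_grid[1],
                                          pool = rfp_pool))
    sweeps[[cf]] <- isocost_sweep(m, "rfp", "gfp", omega_grid, tol = tol)
  }
  tab <- data.frame(
    config = configs,
    induced_pool = ifelse(substr(configs, 1, 1) == "o", "o1", "host"),
    constitutive_pool = ifelse(substr(configs, 2, 2) == "o", "o1", "host"),
    slope = vapply(sweeps, function(s) s$slope, numeric(1)),
    slope_norm = vapply(sweeps, function(s) s$slope_norm, numeric(1)),
    r_squared_norm = vapply(sweeps, function(s) s$r_squared_norm,
                            numeric(1)),
    n_converged = vapply(sweeps, function(s) sum(s$converged), integer(1)),
    row.names = NULL
  )
  list(table = tab, sweeps = sweeps)
}

#' Two-orthogonal-pool decoupling optimisation
#'
#' Dedicates one orthogonal ribosome pool to each circuit gene
#' (constitutive `gfp` on pool 1, induced `rfp` on pool 2), then
#' grid-searches both pools' o-rRNA production rates for the combination
#' that minimises the relative drop of the constitutive reporter across the
#' full induction sweep, `100 * (GFP at minimum induction - GFP at maximum
#' induction) / GFP at minimum induction`.
#'
#' @param params [host_params()] for the base model.
#' @param omega_rho_grid1,omega_rho_grid2 Candidate o-rRNA production rates
#'   for the constitutive-gene and induced-gene pools.
#' @param omega_grid Induction grid for `rfp`.
#' @param omega_gfp Constitutive transcription rate.
#' @param tol Residual tolerance.
#' @return List with `best` (`omega_rho1`, `omega_rho2`, `gfp_drop_pct`),
#'   `grid` (all evaluated combinations and their drops), and `sweep` (the
#'   `isocost_result` at the optimum).
#' @export
two_pool_decoupling <- function(params = host_params(),
                                omega_rho_grid1 = logspace(1, 3, 8),
                                omega_rho_grid2 = logspace(1, 3, 8),
                                omega_grid = logspace(0, 3, 8),
                                omega_gfp = 100, tol = 1e-8) {
  if (!length(omega_rho_grid1) || !length(omega_rho_grid2))
    stop("pool production grids must be non-empty", call. = FALSE)
  base <- cell_model(params)
  base <- add_o_pool(base, o_pool_spec("o1", omega_rho = omega_rho_grid1[1]))
  base <- add_o_pool(base, o_pool_spec("o2", omega_rho = omega_rho_grid2[1]))
  base <- add_circuit_gene(base, circuit_gene("gfp", omega = omega_gfp,
                                              pool = "o1"))
  base <- add_circuit_gene(base, circuit_gene("rfp",
                                              omega = omega_grid[1],
                                              pool = "o2"))
  bm <- as_built(base)
  grid <- expand.grid(omega_rho1 = omega_rho_grid1,
                      omega_rho2 = omega_rho_grid2)
  grid$gfp_drop_pct <- NA_real_
  best <- NULL
  warm <- NULL
  for (j in seq_len(nrow(grid))) {
    bmj <- set_pool_omega(bm, "o1", grid$omega_rho1[j])
    bmj <- set_pool_omega(bmj, "o2", grid$omega_rho2[j])
    sw <- isocost_sweep(bmj, "rfp", "gfp", omega_grid,
                        warm_states = warm, tol = tol)
    warm <- sw$states
    if (!all(sw$converged)) next
    g <- sw$constitutive_ss
    drop <- 100 * (g[1] - g[length(g)]) / g[1]
    grid$gfp_drop_pct[j] <- drop
    if (is.null(best) || drop < best$gfp_drop_pct) {
      best <- list(omega_rho1 = grid$omega_rho1[j],
                   omega_rho2 = grid$omega_rho2[j],
                   gfp_drop_pct = drop, sweep = sw)
    }
  }
  if (is.null(best))
    stop("no grid point converged across the full sweep", call. = FALSE)
  list(best = best[c("omega_rho1", "omega_rho2", "gfp_drop_pct")],
       grid = grid, sweep = best$sweep)
}

#' Log-spaced grid
#'
#' @param from,to Decadic exponents of the first and last point.
#' @param n Number of points.
#' @return `10^seq(from, to, length.out = n)`.
#' @export
logspace <- function(from, to, n) 10^seq(from, to, length.out = n)
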