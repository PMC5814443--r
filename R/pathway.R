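# Violacein pathway analyses: induction dose-response of the downstream
# operon and the resource-allocation comparison between host-pool and
# o-pool expression of the first enzyme.

#' Pathway induction dose-response
#'
#' Sweeps the shared transcription rate of the downstream `vioBCDE` operon,
#' solving a steady state per grid point (warm-started), and reports the
#' enzyme levels, the final metabolite `V` and the metabolite scaled by the
#' largest amount achieved across the induction (so the maximum of
#' `V_scaled` is exactly 1).
#'
#' @param model A `cell_model` with a registered pathway (see
#'   [add_pathway()]).
#' @param omega_BCDE_grid Strictly increasing operon transcription-rate
#'   grid.
#' @param tol Residual tolerance.
#' @return Data frame with columns `omega_BCDE`, `p_vioA`..`p_vioE`, `V`,
#'   `V_scaled`, `lam`, `converged`.
#' @export
induction_dose_response <- function(model, omega_BCDE_grid, tol = 1e-8) {
  stopifnot(inherits(model, "cell_model"))
  if (is.null(model$pathway))
    stop("model has no registered pathway", call. = FALSE)
  if (is.unsorted(omega_BCDE_grid, strictly = TRUE))
    stop("omega_BCDE_grid must be strictly increasing", call. = FALSE)
  bm <- as_built(model)
  n <- length(omega_BCDE_grid)
  enz <- paste0("p_", c("vioA", "vioB", "vioC", "vioD", "vioE"))
  out <- data.frame(omega_BCDE = omega_BCDE_grid)
  for (e in enz) out[[e]] <- NA_real_
  out$V <- NA_real_
  out$lam <- NA_real_
  out$converged <- NA
  prev <- NULL
  for (i in seq_len(n)) {
    bmi <- bm
    for (g in c("vioB", "vioC", "vioD", "vioE"))
      bmi <- set_gene_omega(bmi, g, omega_BCDE_grid[i])
    ss <- solve_steady_state(bmi, init = prev, tol = tol,
                             newton_first = !is.null(prev))
    prev <- ss$state
    for (e in enz) out[[e]][i] <- ss$state[[e]]
    out$V[i] <- ss$state[["V"]]
    out$lam[i] <- ss$lam
    out$converged[i] <- ss$converged
  }
  vmax <- max(out$V[out$converged], na.rm = TRUE)
  out$V_scaled <- if (vmax > 0) out$V / vmax else out$V
  out
}

#' Compare host-pool and o-pool allocation of the first pathway enzyme
#'
#' Runs [induction_dose_response()] twice on the same host background and
#' pathway: once with `vioA` translated by the host pool and once with
#' `vioA` allocated to an orthogonal pool, and summarises the relative drop
#' of the constitutive enzyme A across the induction and the final
#' metabolite level at maximal induction.
#'
#' @param params [host_params()] for the base model.
#' @param spec A [pathway_spec()].
#' @param omega_BCDE_grid Induction grid for the downstream operon.
#' @param omega_rho o-rRNA transcription rate of the pool used in the
#'   o-pool arrangement (present, at the same rate, in both arrangements so
#'   the host backgrounds match).
#' @param tol Residual tolerance.
#' @return List with `host` and `opool` dose-response tables and a
#'   `summary` data frame (per arrangement: relative drop in enzyme A
#'   across the grid, metabolite at maximal induction).
#' @export
pathway_allocation_comparison <- function(params = host_params(),
                                          spec = pathway_spec(),
                                          omega_BCDE_grid = logspace(0, 3, 8),
                                          omega_rho = 500, tol = 1e-8) {
  run <- function(pool) {
    m <- cell_model(params)
    m <- add_o_pool(m, o_pool_spec("o1", omega_rho = omega_rho))
    m <- add_pathway(m, spec, vioA_pool = pool)
    induction_dose_response(m, omega_BCDE_grid, tol = tol)
  }
  host <- run("host")
  opool <- run("o1")
  drop_rel <- function(d) {
    a <- d$p_vioA
    (a[1] - a[length(a)]) / a[1]
  }
  summary <- data.frame(
    arrangement = c("host", "opool"),
    vioA_drop_rel = c(drop_rel(host), drop_rel(opool)),
    V_at_max_induction = c(host$V[nrow(host)], opool$V[nrow(opool)])
  )
  list(host = host, opool = opool, summary = summary)
}
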