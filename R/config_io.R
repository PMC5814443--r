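# Scenario configuration (YAML), strict validation, dispatch and result
# serialisation. All tabular outputs are plain CSV with species/parameter
# symbols as headers; summaries are JSON; every run writes a manifest with
# file checksums so runs are reproducible and auditable.

ANALYSES <- c("simulate", "isocost", "compare-configs", "two-pool", "vio",
              "controller-design", "sensitivity", "robustness", "calibrate")

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file describing the host parameters, orthogonal
#' pools, circuit genes, optional pathway and controller blocks, and
#' exactly one analysis block. Validation is strict: unknown keys are
#' rejected by name (silent default substitution for misspelled keys would
#' corrupt parameter studies), referenced pool/gene names must resolve and
#' stochastic analyses must carry a seed.
#'
#' @param path Path to a YAML file.
#' @return A validated `scenario_config` list with defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

validate_config <- function(raw) {
  known_top <- c("host", "pools", "genes", "pathway", "controller",
                 "analysis", "output_dir")
  check_keys(raw, known_top, "top level")
  if (is.null(raw$analysis) || is.null(raw$analysis$type))
    stop("config must contain an analysis block with a 'type'",
         call. = FALSE)
  if (!raw$analysis$type %in% ANALYSES)
    stop("unknown analysis type '", raw$analysis$type, "'; expected one of ",
         paste(ANALYSES, collapse = ", "), call. = FALSE)

  host <- do.call(host_params, as.list(raw$host %||% list()))

  pools <- list()
  for (pb in raw$pools %||% list()) {
    check_keys(pb, names(formals(o_pool_spec)), "pool block")
    sp <- do.call(o_pool_spec, pb)
    pools[[sp$pool_id]] <- sp
  }
  genes <- list()
  for (gb in raw$genes %||% list()) {
    check_keys(gb, names(formals(circuit_gene)), "gene block")
    g <- do.call(circuit_gene, gb)
    if (!identical(g$pool, "host") && !(g$pool %in% names(pools)))
      stop("gene '", g$name, "' references unknown pool '", g$pool, "'",
           call. = FALSE)
    genes[[g$name]] <- g
  }
  pathway <- NULL
  vioA_pool <- "host"
  if (!is.null(raw$pathway)) {
    pb <- raw$pathway
    check_keys(pb, c(names(formals(pathway_spec)), "vioA_pool"),
               "pathway block")
    vioA_pool <- pb$vioA_pool %||% "host"
    pb$vioA_pool <- NULL
    pathway <- do.call(pathway_spec, pb)
    if (!identical(vioA_pool, "host") && !(vioA_pool %in% names(pools)))
      stop("pathway references unknown pool '", vioA_pool, "'",
           call. = FALSE)
  }
  controller <- NULL
  if (!is.null(raw$controller)) {
    check_keys(raw$controller, names(formals(controller_params)),
               "controller block")
    controller <- do.call(controller_params, raw$controller)
    if (!(controller$target_pool %in% names(pools)))
      stop("controller references unknown pool '", controller$target_pool,
           "'", call. = FALSE)
  }
  analysis <- validate_analysis(raw$analysis)
  structure(list(host = host, pools = pools, genes = genes,
                 pathway = pathway, vioA_pool = vioA_pool,
                 controller = controller, analysis = analysis,
                 output_dir = raw$output_dir %||% "ribopool-results"),
            class = "scenario_config")
}

analysis_keys <- list(
  "simulate" = c("t_max", "dt", "rtol", "atol"),
  "isocost" = c("induced", "constitutive", "omega_grid", "tol"),
  "compare-configs" = c("configs", "omega_grid", "omega_rho", "omega_gfp",
                        "tol"),
  "two-pool" = c("omega_rho_grid1", "omega_rho_grid2", "omega_grid",
                 "omega_gfp", "tol"),
  "vio" = c("omega_BCDE_grid", "omega_rho", "tol"),
  "controller-design" = c("bounds", "n_grid", "w", "omega_grid",
                          "omega_gfp", "tol"),
  "sensitivity" = c("param", "values", "omega_rho_max", "omega_grid",
                    "omega_gfp", "tol"),
  "robustness" = c("n_draws", "frac", "seed", "omega_rho_max",
                   "omega_grid", "omega_gfp", "tol"),
  "calibrate" = c("nutrient_grid", "inhibitor_grid", "sigma", "seed",
                  "free_params", "tol")
)

validate_analysis <- function(a) {
  type <- a$type
  check_keys(a[setdiff(names(a), "type")], analysis_keys[[type]],
             paste0("analysis block (type ", type, ")"))
  if (type %in% c("robustness", "calibrate") && is.null(a$seed))
    stop("analysis '", type, "' is stochastic and requires a seed",
         call. = FALSE)
  for (k in grep("grid|values", names(a), value = TRUE)) {
    a[[k]] <- parse_grid(a[[k]], k)
  }
  a
}

# note: grid blocks use 'points', not 'n', because YAML 1.1 reads a bare
# 'n' key as the boolean FALSE
parse_grid <- function(g, key) {
  if (is.numeric(g)) return(as.numeric(g))
  if (is.list(g) && all(c("from", "to", "points") %in% names(g))) {
    check_keys(g, c("from", "to", "points", "log"),
               paste0("grid '", key, "'"))
    if (isTRUE(g$log)) return(logspace(g$from, g$to, g$points))
    return(seq(g$from, g$to, length.out = g$points))
  }
  stop("grid '", key, "' must be a numeric vector or ",
       "{from, to, points, log}", call. = FALSE)
}

check_keys <- function(block, allowed, where) {
  if (is.null(block)) return(invisible())
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         "; expected only ", paste(allowed, collapse = ", "),
         call. = FALSE)
  invisible()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise a scenario configuration back to YAML
#'
#' Writing then re-loading a configuration yields an identical validated
#' configuration (round trip).
#'
#' @param config A `scenario_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  raw <- list(
    host = as.list(unclass(config$host)),
    pools = unname(lapply(config$pools, unclass)),
    genes = unname(lapply(config$genes, unclass)),
    analysis = config$analysis,
    output_dir = config$output_dir
  )
  if (!is.null(config$pathway)) {
    pw <- unclass(config$pathway)
    pw$n_enzymes <- as.numeric(pw$n_enzymes)
    pw$vioA_pool <- config$vioA_pool
    raw$pathway <- pw
  }
  if (!is.null(config$controller)) raw$controller <- unclass(config$controller)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  yaml::write_yaml(raw, path)
  invisible(path)
}

build_from_config <- function(config) {
  m <- cell_model(config$host)
  for (sp in config$pools) m <- add_o_pool(m, sp)
  for (g in config$genes) m <- add_circuit_gene(m, g)
  if (!is.null(config$pathway))
    m <- add_pathway(m, config$pathway, vioA_pool = config$vioA_pool)
  if (!is.null(config$controller)) m <- add_controller(m, config$controller)
  m
}

#' Write a state snapshot as CSV
#'
#' One row per species, columns `species` (model symbol) and `amount`.
#'
#' @param state Named state vector.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(state, path) {
  utils::write.csv(data.frame(species = names(state),
                              amount = as.numeric(state)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Run a scenario end to end
#'
#' Builds the model described by the configuration, dispatches to the named
#' analysis, writes CSV/JSON outputs into the output directory and finishes
#' with a run manifest (config hash, seed, tolerances, wall clock, package
#' version, and an md5 checksum per output file). Numeric outputs are fully
#' determined by the configuration and its seed.
#'
#' @param config A `scenario_config` (from [load_config()]) or a path to a
#'   YAML config file.
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, the manifest list. The manifest's `converged` element
#'   reports whether all steady-state solves in the analysis converged.
#' @export
run_scenario <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "scenario_config"))
  out_dir <- output_dir %||% config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  a <- config$analysis
  files <- character(0)
  summary <- list(analysis = a$type)
  converged <- TRUE
  emit_csv <- function(df, name) {
    f <- file.path(out_dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }

  tol <- a$tol %||% 1e-8
  if (a$type == "simulate") {
    t_max <- a$t_max %||% 1e4
    if (t_max <= 0) {
      m <- build_from_config(config)
      y0 <- initial_state(m)
      emit_csv(data.frame(time = 0, t(y0)), "trajectory.csv")
    } else {
      times <- seq(0, t_max, by = a$dt %||% (t_max / 200))
      sim <- simulate_model(build_from_config(config), times,
                            rtol = a$rtol %||% 1e-9,
                            atol = a$atol %||% 1e-12)
      emit_csv(sim, "trajectory.csv")
    }
  } else if (a$type == "isocost") {
    m <- build_from_config(config)
    sw <- isocost_sweep(m, a$induced, a$constitutive, a$omega_grid,
                        tol = tol)
    converged <- all(sw$converged)
    emit_csv(as.data.frame(sw), "isocost.csv")
    summary$fit <- sw[c("slope", "intercept", "r_squared", "slope_norm",
                        "intercept_norm", "r_squared_norm")]
  } else if (a$type == "compare-configs") {
    cc <- configuration_comparison(config$host,
                                   configs = unlist(a$configs) %||%
                                     c("hh", "oo", "ho", "oh"),
                                   omega_grid = a$omega_grid %||%
                                     logspace(0, 3, 10),
                                   omega_rho = a$omega_rho %||% 500,
                                   omega_gfp = a$omega_gfp %||% 100,
                                   tol = tol)
    converged <- all(vapply(cc$sweeps, function(s) all(s$converged),
                            logical(1)))
    emit_csv(cc$table, "configuration_slopes.csv")
    for (cf in names(cc$sweeps))
      emit_csv(as.data.frame(cc$sweeps[[cf]]),
               paste0("isocost_", cf, ".csv"))
  } else if (a$type == "two-pool") {
    tp <- two_pool_decoupling(config$host,
                              omega_rho_grid1 = a$omega_rho_grid1 %||%
                                logspace(1, 3, 8),
                              omega_rho_grid2 = a$omega_rho_grid2 %||%
                                logspace(1, 3, 8),
                              omega_grid = a$omega_grid %||%
                                logspace(0, 3, 8),
                              omega_gfp = a$omega_gfp %||% 100, tol = tol)
    emit_csv(tp$grid, "two_pool_grid.csv")
    emit_csv(as.data.frame(tp$sweep), "two_pool_best_sweep.csv")
    summary$best <- tp$best
  } else if (a$type == "vio") {
    pc <- pathway_allocation_comparison(
      config$host, config$pathway %||% pathway_spec(),
      omega_BCDE_grid = a$omega_BCDE_grid %||% logspace(0, 3, 8),
      omega_rho = a$omega_rho %||% 500, tol = tol)
    converged <- all(pc$host$converged) && all(pc$opool$converged)
    emit_csv(pc$host, "vio_host_pool.csv")
    emit_csv(pc$opool, "vio_o_pool.csv")
    emit_csv(pc$summary, "vio_summary.csv")
  } else if (a$type == "controller-design") {
    des <- design_controller(config$host,
                             bounds = lapply(a$bounds %||%
                                               formals(design_controller)$bounds,
                                             as.numeric),
                             n_grid = a$n_grid %||% 3, w = a$w %||% 1,
                             omega_grid = a$omega_grid %||% logspace(0, 3, 8),
                             omega_gfp = a$omega_gfp %||% 100, tol = tol)
    emit_csv(des$frontier, "design_frontier.csv")
    summary$best <- c(unclass(des$best$ctrl),
                      list(omega_rho_max = des$best$omega_rho_max,
                           J = des$best$J,
                           slope_norm = des$best$slope_norm))
  } else if (a$type == "sensitivity") {
    ct <- config$controller %||% controller_params()
    sv <- sensitivity_sweep(config$host, ct,
                            omega_rho_max = a$omega_rho_max %||% 1000,
                            param = a$param, values = a$values,
                            omega_grid = a$omega_grid %||% logspace(0, 3, 8),
                            omega_gfp = a$omega_gfp %||% 100, tol = tol)
    emit_csv(sv, "sensitivity.csv")
  } else if (a$type == "robustness") {
    ct <- config$controller %||% controller_params()
    mc <- robustness_mc(config$host, ct,
                        omega_rho_max = a$omega_rho_max %||% 1000,
                        n = a$n_draws %||% 1000, frac = a$frac %||% 0.5,
                        seed = a$seed,
                        omega_grid = a$omega_grid %||% logspace(0, 3, 8),
                        omega_gfp = a$omega_gfp %||% 100, tol = tol)
    emit_csv(mc$draws, "robustness_draws.csv")
    summary$robustness <- mc[c("fraction_outperforming", "n_excluded",
                               "open_loop", "baseline", "seed")]
  } else if (a$type == "calibrate") {
    ds <- generate_growth_law_data(config$host,
                                   nutrient_grid = a$nutrient_grid %||%
                                     c(0.1, 0.2, 0.3, 0.5, 0.7, 1.0),
                                   inhibitor_grid = a$inhibitor_grid %||%
                                     c(1, 0.7, 0.5),
                                   sigma = a$sigma %||% 0, seed = a$seed,
                                   tol = tol)
    converged <- all(ds$converged)
    emit_csv(as.data.frame(ds), "growth_law_data.csv")
    free <- unlist(a$free_params) %||% c("gamma_max", "omega_R")
    fit <- fit_growth_law_params(ds, free, params = config$host, tol = tol)
    summary$fit <- list(estimates = as.list(fit$estimates),
                        loss = fit$loss, niter = fit$niter,
                        message = fit$message)
  }

  # summary JSON + manifest
  sum_file <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sum_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  files <- c(files, sum_file)
  cfg_file <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_file)
  files <- c(files, cfg_file)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ribopool")),
    analysis = a$type,
    seed = a$seed %||% NA,
    tol = tol,
    config_hash = unname(tools::md5sum(cfg_file)),
    wall_clock_sec = as.numeric(Sys.time() - t_start, units = "secs"),
    converged = converged,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
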