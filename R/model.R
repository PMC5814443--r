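#' Create a host cell model
#'
#' Builds the base host-aware model object. Orthogonal ribosome pools,
#' circuit genes, a metabolic pathway and a feedback controller are added
#' with [add_o_pool()], [add_circuit_gene()], [add_pathway()] and
#' [add_controller()]; each returns a new model value, so models compose
#' functionally. The full species layout (index map) is derived
#' deterministically from the registration order and is the single source of
#' truth for all solvers and analyses.
#'
#' @param params A [host_params()] object.
#' @return An object of class `cell_model`.
#' @examples
#' m <- cell_model()
#' species_names(m)
#' @export
cell_model <- function(params = host_params()) {
  if (!inherits(params, "host_params")) {
    params <- do.call(host_params, as.list(params))
  }
  structure(list(params = params, pools = list(), genes = list(),
                 controller = NULL, pathway = NULL),
            class = "cell_model")
}

#' Register an orthogonal ribosome pool
#'
#' Adds the species `rho_<id>` (free o-rRNA) and `P_<id>` (o-ribosomes) and
#' their reactions: energy-dependent o-rRNA transcription, reversible
#' association of the o-rRNA with the empty-ribosome protein `p_R`, and
#' translation of the circuit genes allocated to the pool. Host ribosomes
#' never translate o-RBS mRNAs; optional one-way interference of o-ribosomes
#' with host-RBS circuit mRNAs is controlled by the pool's `b_cross`.
#'
#' @param model A `cell_model`.
#' @param spec An [o_pool_spec()].
#' @return The extended `cell_model`.
#' @export
add_o_pool <- function(model, spec) {
  stopifnot(inherits(model, "cell_model"))
  if (!inherits(spec, "o_pool_spec")) stop("spec must be an o_pool_spec",
                                           call. = FALSE)
  if (spec$pool_id %in% names(model$pools))
    stop("pool '", spec$pool_id, "' is already registered", call. = FALSE)
  model$pools[[spec$pool_id]] <- spec
  model
}

#' Register a circuit gene
#'
#' Adds the species `m_<name>`, `c_<name>`, `p_<name>` and mass-action
#' binding/translation reactions against the allocated ribosome pool only.
#' The protein contributes to growth-rate (dilution) and proteome-mass
#' accounting like any host protein.
#'
#' @param model A `cell_model`.
#' @param gene A [circuit_gene()].
#' @return The extended `cell_model`.
#' @export
add_circuit_gene <- function(model, gene) {
  stopifnot(inherits(model, "cell_model"))
  if (!inherits(gene, "circuit_gene")) stop("gene must be a circuit_gene",
                                            call. = FALSE)
  if (gene$name %in% names(model$genes))
    stop("gene '", gene$name, "' is already registered", call. = FALSE)
  if (!identical(gene$pool, "host") && !(gene$pool %in% names(model$pools)))
    stop("gene '", gene$name, "' allocated to unknown pool '", gene$pool,
         "'", call. = FALSE)
  model$genes[[gene$name]] <- gene
  model
}

#' Register the feedback resource allocation controller
#'
#' Adds the repressor gene (species `m_F`, `c_F`, `p_F`) translated by the
#' target orthogonal pool, and gates that pool's o-rRNA transcription with
#' the Hill factor `1 / (1 + (p_F / k_D)^h)`. The repression acts on the
#' o-rRNA transcription term only.
#'
#' @param model A `cell_model` with the target pool registered as
#'   repressible.
#' @param ctrl A [controller_params()].
#' @return The extended `cell_model`.
#' @export
add_controller <- function(model, ctrl) {
  stopifnot(inherits(model, "cell_model"))
  if (!inherits(ctrl, "controller_params"))
    stop("ctrl must be controller_params", call. = FALSE)
  if (!is.null(model$controller))
    stop("a controller is already registered", call. = FALSE)
  if (!(ctrl$target_pool %in% names(model$pools)))
    stop("target pool '", ctrl$target_pool, "' is not registered",
         call. = FALSE)
  if (!isTRUE(model$pools[[ctrl$target_pool]]$repressible))
    stop("target pool '", ctrl$target_pool, "' is not repressible",
         call. = FALSE)
  if ("F" %in% names(model$genes))
    stop("gene name 'F' is reserved for the controller repressor",
         call. = FALSE)
  model$controller <- ctrl
  model
}

#' Register the violacein pathway
#'
#' Adds the five enzyme genes (`vioA` on the chosen pool; `vioB`..`vioE` as
#' a polycistronic host-translated operon sharing one transcription rate and
#' RBS strength) together with the metabolic intermediates `I1`..`I4` and
#' the final product `V`. Each catalytic step is irreversible
#' Michaelis-Menten kinetics; the external substrate is held constant;
#' intermediates and product dilute at the growth rate.
#'
#' @param model A `cell_model`.
#' @param spec A [pathway_spec()].
#' @param vioA_pool `"host"` or a registered `pool_id` for `vioA`
#'   translation. Enzymes B--E always use the host pool.
#' @return The extended `cell_model`.
#' @export
add_pathway <- function(model, spec = pathway_spec(), vioA_pool = "host") {
  stopifnot(inherits(model, "cell_model"))
  if (!inherits(spec, "pathway_spec")) stop("spec must be a pathway_spec",
                                            call. = FALSE)
  if (!is.null(model$pathway)) stop("a pathway is already registered",
                                    call. = FALSE)
  if (!identical(vioA_pool, "host") && !(vioA_pool %in% names(model$pools)))
    stop("unknown vioA pool '", vioA_pool, "'", call. = FALSE)
  enz <- c("vioA", "vioB", "vioC", "vioD", "vioE")
  if (any(enz %in% names(model$genes)))
    stop("pathway gene names are already in use", call. = FALSE)
  model <- add_circuit_gene(model, circuit_gene(
    "vioA", omega = spec$omega_A, n = spec$n_enzymes[["A"]],
    pool = vioA_pool, b = spec$b, u = spec$u, delta_m = spec$delta_m))
  for (i in 2:5) {
    model <- add_circuit_gene(model, circuit_gene(
      enz[i], omega = spec$omega_BCDE,
      n = spec$n_enzymes[[c("A", "B", "C", "D", "E")[i]]],
      pool = "host", b = spec$b, u = spec$u, delta_m = spec$delta_m))
  }
  model$pathway <- spec
  model
}

#' Species names of a model
#'
#' @param model A `cell_model`.
#' @return Character vector naming every state variable in layout order.
#' @export
species_names <- function(model) {
  build_cell_model(model)$species
}

#' @export
print.cell_model <- function(x, ...) {
  cat("<cell_model>\n")
  cat("  pools:", if (length(x$pools)) paste(names(x$pools), collapse = ", ")
      else "(host only)", "\n")
  cat("  circuit genes:",
      if (length(x$genes)) paste(names(x$genes), collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$controller))
    cat("  controller on pool:", x$controller$target_pool, "\n")
  if (!is.null(x$pathway)) cat("  violacein pathway registered\n")
  cat("  species:", length(species_names(x)), "\n")
  invisible(x)
}

# ---- internal: build the flat numerical representation -----------------

# The built model carries a fixed species index map plus a "translation
# table": one row per (mRNA species x ribosome pool) binding interaction,
# covering the four host genes, every circuit gene, the controller repressor
# and any cross-binding (o-ribosome on host-RBS mRNA) interactions.
build_cell_model <- function(model) {
  if (inherits(model, "built_cell_model")) return(model)
  stopifnot(inherits(model, "cell_model"))
  p <- model$params

  species <- c("s_i", "e",
               "m_T", "m_E", "m_H", "m_R",
               "c_T", "c_E", "c_H", "c_R",
               "p_T", "p_E", "p_H", "p_R",
               "r", "R")
  idx <- as.list(seq_along(species))
  names(idx) <- species

  pool_ids <- names(model$pools)
  n_pool <- length(pool_ids)
  irho <- iP <- integer(n_pool)
  for (k in seq_len(n_pool)) {
    species <- c(species, paste0("rho_", pool_ids[k]), paste0("P_", pool_ids[k]))
    irho[k] <- length(species) - 1L
    iP[k] <- length(species)
  }

  # translation-table columns
  tt_im <- tt_ic <- tt_ip <- tt_irib <- integer(0)
  tt_b <- tt_u <- tt_n <- tt_omega <- tt_o <- tt_dm <- numeric(0)
  tt_primary <- logical(0)
  tt_label <- character(0)

  add_row <- function(im, ic, ip, irib, b, u, n, omega, o, dm, primary, lab) {
    tt_im <<- c(tt_im, im); tt_ic <<- c(tt_ic, ic); tt_ip <<- c(tt_ip, ip)
    tt_irib <<- c(tt_irib, irib)
    tt_b <<- c(tt_b, b); tt_u <<- c(tt_u, u); tt_n <<- c(tt_n, n)
    tt_omega <<- c(tt_omega, omega); tt_o <<- c(tt_o, o)
    tt_dm <<- c(tt_dm, dm); tt_primary <<- c(tt_primary, primary)
    tt_label <<- c(tt_label, lab)
  }

  iR <- idx$R
  for (X in c("T", "E", "H", "R")) {
    add_row(idx[[paste0("m_", X)]], idx[[paste0("c_", X)]],
            idx[[paste0("p_", X)]], iR,
            p[[paste0("b_", X)]], p[[paste0("u_", X)]],
            p[[paste0("n_", X)]], p[[paste0("omega_", X)]],
            p[[paste0("o_", X)]], p$delta_m, TRUE, X)
  }
  iH_row <- 3L  # housekeeping autoinhibition row

  genes <- model$genes
  ctrl <- model$controller
  if (!is.null(ctrl)) {
    genes[["F"]] <- circuit_gene("F", omega = ctrl$omega_F, o = ctrl$o_F,
                                 n = ctrl$n_F, pool = ctrl$target_pool,
                                 b = ctrl$b_F, u = ctrl$u_F)
  }

  gene_pool_k <- integer(length(genes))  # 0 = host, else pool index
  names(gene_pool_k) <- names(genes)
  for (g in names(genes)) {
    gn <- genes[[g]]
    species <- c(species, paste0("m_", g), paste0("c_", g), paste0("p_", g))
    im <- length(species) - 2L; ic <- length(species) - 1L
    ip <- length(species)
    k <- if (identical(gn$pool, "host")) 0L else match(gn$pool, pool_ids)
    gene_pool_k[g] <- k
    irib <- if (k == 0L) iR else iP[k]
    add_row(im, ic, ip, irib, gn$b, gn$u, gn$n, gn$omega, gn$o, gn$delta_m,
            TRUE, g)
  }

  # optional cross-binding: o-ribosomes translating host-RBS circuit mRNAs
  for (k in seq_len(n_pool)) {
    bc <- model$pools[[k]]$b_cross
    if (bc > 0) {
      for (g in names(genes)) {
        if (gene_pool_k[g] == 0L) {
          gn <- genes[[g]]
          im <- idx_of(species, paste0("m_", g))
          ip <- idx_of(species, paste0("p_", g))
          species <- c(species, paste0("cx_", g, "_", pool_ids[k]))
          add_row(im, length(species), ip, iP[k], bc, gn$u, gn$n,
                  0, gn$o, gn$delta_m, FALSE, paste0(g, "x", pool_ids[k]))
        }
      }
    }
  }

  pw <- NULL
  if (!is.null(model$pathway)) {
    sp <- model$pathway
    i_pE <- vapply(c("vioA", "vioB", "vioC", "vioD", "vioE"),
                   function(g) idx_of(species, paste0("p_", g)), integer(1))
    species <- c(species, "I1", "I2", "I3", "I4", "V")
    nsp <- length(species)
    pw <- list(i_I = (nsp - 4L):(nsp - 1L), i_V = nsp, i_p = i_pE,
               kcat = sp$kcat, Km = sp$Km, S = sp$substrate_level)
  }

  nsp <- length(species)
  rib_idx <- c(iR, iP)                       # ribosome species per group
  rib_rows <- lapply(rib_idx, function(ix) which(tt_irib == ix))

  ctrl_built <- NULL
  if (!is.null(ctrl)) {
    ctrl_built <- list(k_D = ctrl$k_D, h = ctrl$h,
                       target_k = match(ctrl$target_pool, pool_ids),
                       i_pF = idx_of(species, "p_F"))
  }

  pools <- model$pools
  pool_vec <- function(f) if (n_pool) vapply(pools, function(s) s[[f]],
                                             numeric(1)) else numeric(0)

  bm <- list(
    species = species, n = nsp, p = p,
    idx = list(s_i = 1L, e = 2L, p_T = idx$p_T, p_E = idx$p_E,
               p_H = idx$p_H, p_R = idx$p_R, r = idx$r, R = iR),
    tt = list(i_m = tt_im, i_c = tt_ic, i_p = tt_ip, i_rib = tt_irib,
              b = tt_b, u = tt_u, n = tt_n, omega = tt_omega, o = tt_o,
              delta_m = tt_dm, primary = tt_primary, label = tt_label),
    iH_row = iH_row, i_pH = idx$p_H,
    n_pool = n_pool, pool_ids = pool_ids,
    irho = irho, iP = iP,
    pool_omega = unname(pool_vec("omega_rho")),
    pool_o = unname(pool_vec("o_rho")),
    pool_b = unname(pool_vec("b_rho")),
    pool_u = unname(pool_vec("u_rho")),
    pool_delta = unname(pool_vec("delta_rho")),
    pool_repressible = if (n_pool)
      vapply(pools, function(s) isTRUE(s$repressible), logical(1))
      else logical(0),
    rib_rows = rib_rows,
    ctrl = ctrl_built, pw = pw,
    shared_m = anyDuplicated(tt_im) > 0L,
    model = model
  )
  class(bm) <- "built_cell_model"
  bm
}

idx_of <- function(species, name) {
  i <- match(name, species)
  if (is.na(i)) stop("species '", name, "' not found", call. = FALSE)
  i
}

as_built <- function(model) {
  if (inherits(model, "built_cell_model")) model else build_cell_model(model)
}

#' Default initial state of a model
#'
#' All species start at zero except a small seed of free host ribosomes
#' (needed because ribosome biosynthesis is autocatalytic: with no ribosomes
#' nothing is translated and the all-zero state is a fixed point) and small
#' amounts of internal substrate and energy.
#'
#' @param model A `cell_model`.
#' @param overrides Named numeric vector of initial values to override.
#' @return Named numeric state vector in layout order.
#' @export
initial_state <- function(model, overrides = NULL) {
  bm <- as_built(model)
  y <- stats::setNames(numeric(bm$n), bm$species)
  y["s_i"] <- 1e3
  y["e"] <- 1e3
  y["R"] <- 10
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% bm$species))
      stop("initial-state overrides must be named after model species",
           call. = FALSE)
    y[names(overrides)] <- overrides
  }
  y
}

#' Set a circuit gene's transcription rate
#'
#' Changes a registered gene's maximal transcription rate (the induction
#' input) without altering the species layout, so sweeps can reuse solver
#' warm starts.
#'
#' @param model A `cell_model` (or built model).
#' @param name Registered gene name.
#' @param omega New transcription rate (mRNAs per min).
#' @return The modified model.
#' @export
set_gene_omega <- function(model, name, omega) {
  if (inherits(model, "built_cell_model")) {
    row <- match(name, model$tt$label)
    if (is.na(row)) stop("unknown gene '", name, "'", call. = FALSE)
    model$tt$omega[row] <- omega
    model$model$genes[[name]]$omega <- omega
    return(model)
  }
  stopifnot(inherits(model, "cell_model"))
  if (!(name %in% names(model$genes)))
    stop("unknown gene '", name, "'", call. = FALSE)
  model$genes[[name]]$omega <- omega
  model
}

#' Set an orthogonal pool's maximal o-rRNA transcription rate
#'
#' @param model A `cell_model` (or built model).
#' @param pool_id Registered pool id.
#' @param omega_rho New maximal o-rRNA transcription rate (per min).
#' @return The modified model.
#' @export
set_pool_omega <- function(model, pool_id, omega_rho) {
  if (inherits(model, "built_cell_model")) {
    k <- match(pool_id, model$pool_ids)
    if (is.na(k)) stop("unknown pool '", pool_id, "'", call. = FALSE)
    model$pool_omega[k] <- omega_rho
    model$model$pools[[pool_id]]$omega_rho <- omega_rho
    return(model)
  }
  stopifnot(inherits(model, "cell_model"))
  if (!(pool_id %in% names(model$pools)))
    stop("unknown pool '", pool_id, "'", call. = FALSE)
  model$pools[[pool_id]]$omega_rho <- omega_rho
  model
}
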