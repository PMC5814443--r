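#' Specification of an orthogonal ribosome pool
#'
#' An orthogonal (quasi-orthogonal) ribosome pool is created by expressing a
#' synthetic 16S rRNA (`rho`) whose anti-Shine-Dalgarno sequence pairs only
#' with matching orthogonal ribosome binding sites. The o-rRNA competes with
#' the host rRNA for the shared "empty ribosome" protein `p_R`; the resulting
#' o-ribosomes `P` translate only the circuit genes allocated to the pool.
#'
#' @param pool_id Pool label; must be unique within a model and not `"host"`.
#' @param omega_rho Maximal o-rRNA transcription rate (rRNAs per min).
#' @param o_rho Transcriptional energy threshold. Defaults to the host
#'   non-ribosomal threshold: the o-rRNA follows the same dynamics as the
#'   host rRNA, but as a plasmid-carried gene it responds to energy like
#'   an ordinary host gene rather than like the tightly growth-controlled
#'   rRNA operons. This makes the pool's supply insensitive to host load,
#'   which is what lets it insulate the genes allocated to it.
#' @param b_rho,u_rho Association (per molecule per min) and dissociation
#'   (per min) rates with the empty-ribosome protein.
#' @param delta_rho Free o-rRNA degradation rate (per min).
#' @param repressible If `TRUE`, a registered feedback controller may gate
#'   `omega_rho` with its Hill repression factor.
#' @param b_cross Optional cross-binding rate of o-ribosomes onto host-RBS
#'   circuit mRNAs (one-way interference); default 0 (off).
#' @return An object of class `o_pool_spec`.
#' @examples
#' o_pool_spec("o1", omega_rho = 500)
#' @export
o_pool_spec <- function(pool_id, omega_rho, o_rho = 4.379733,
                        b_rho = 1, u_rho = 1, delta_rho = 0.1,
                        repressible = FALSE, b_cross = 0) {
  if (!is.character(pool_id) || length(pool_id) != 1L || !nzchar(pool_id))
    stop("pool_id must be a non-empty string", call. = FALSE)
  if (identical(pool_id, "host"))
    stop("pool_id 'host' is reserved", call. = FALSE)
  for (nm in c("omega_rho", "b_rho", "u_rho", "delta_rho", "b_cross")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a non-negative finite scalar", call. = FALSE)
  }
  if (!is.numeric(o_rho) || length(o_rho) != 1L || o_rho <= 0)
    stop("'o_rho' must be strictly positive", call. = FALSE)
  structure(list(pool_id = pool_id, omega_rho = omega_rho, o_rho = o_rho,
                 b_rho = b_rho, u_rho = u_rho, delta_rho = delta_rho,
                 repressible = isTRUE(repressible), b_cross = b_cross),
            class = "o_pool_spec")
}

#' Specification of a heterologous circuit gene
#'
#' A circuit gene adds an mRNA, a translation complex and a protein species
#' to the model. Its mRNA is transcribed at rate
#' `omega * e / (o + e)` and translated by the ribosome pool named in `pool`
#' (the host pool or a registered orthogonal pool, selected in vivo by the
#' choice of ribosome binding site).
#'
#' @param name Gene name (species suffix); must be fresh in the model.
#' @param omega Maximal transcription rate (mRNAs per min); this is the
#'   induction input swept in coupling analyses.
#' @param o Transcriptional energy threshold.
#' @param n Protein length (amino acids).
#' @param pool `"host"` or the `pool_id` of a registered orthogonal pool.
#' @param b,u RBS association/dissociation rates with the allocated pool.
#' @param delta_m mRNA degradation rate (per min).
#' @return An object of class `circuit_gene`.
#' @examples
#' circuit_gene("gfp", omega = 100, pool = "host")
#' @export
circuit_gene <- function(name, omega, o = 4.379733, n = 300, pool = "host",
                         b = 1, u = 1, delta_m = 0.1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene name must be a non-empty string", call. = FALSE)
  if (!is.character(pool) || length(pool) != 1L)
    stop("pool must be a string", call. = FALSE)
  for (nm in c("omega", "b", "u", "delta_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a non-negative finite scalar", call. = FALSE)
  }
  if (!is.numeric(o) || o <= 0) stop("'o' must be > 0", call. = FALSE)
  if (!is.numeric(n) || n <= 0) stop("'n' must be > 0", call. = FALSE)
  structure(list(name = name, omega = omega, o = o, n = n, pool = pool,
                 b = b, u = u, delta_m = delta_m),
            class = "circuit_gene")
}

#' Parameters of the dynamic resource allocation controller
#'
#' The controller is a constitutively transcribed repressor gene translated
#' by the orthogonal pool it regulates. Because its mRNA level is constant,
#' its translation rate senses the competition for o-ribosomes: rising
#' circuit demand lowers repressor production, de-represses o-rRNA
#' transcription and co-opts more empty ribosomes into the orthogonal pool.
#'
#' Default values follow the design principles that emerge from the
#' sensitivity analysis (see [sensitivity_sweep()] and the methods
#' vignette): the repressor must sequester o-ribosomes strongly (`b_F`
#' well above the host RBS rate), bind its operator tightly (`k_D` small
#' relative to typical repressor levels, as for LacI) and act
#' cooperatively (`h = 2`, reflecting repressor dimerisation).
#'
#' @param omega_F Repressor transcription rate (mRNAs per min).
#' @param o_F Transcriptional energy threshold.
#' @param n_F Repressor length (amino acids).
#' @param b_F,u_F RBS association/dissociation rates with the target pool.
#' @param k_D Repression dissociation constant (molecules).
#' @param h Hill coefficient of repression (>= 1).
#' @param target_pool `pool_id` of the repressible orthogonal pool whose
#'   o-rRNA transcription is gated by `1 / (1 + (p_F / k_D)^h)`.
#' @return An object of class `controller_params`.
#' @examples
#' controller_params(target_pool = "o1")
#' @export
controller_params <- function(omega_F = 100, o_F = 4.379733, n_F = 300,
                              b_F = 20, u_F = 1, k_D = 100, h = 2,
                              target_pool = "o1") {
  if (!is.numeric(k_D) || length(k_D) != 1L || k_D <= 0)
    stop("'k_D' must be strictly positive", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || h < 1)
    stop("Hill coefficient 'h' must be >= 1", call. = FALSE)
  for (nm in c("omega_F", "b_F", "u_F")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a non-negative finite scalar", call. = FALSE)
  }
  if (!is.numeric(o_F) || o_F <= 0) stop("'o_F' must be > 0", call. = FALSE)
  if (!is.numeric(n_F) || n_F <= 0) stop("'n_F' must be > 0", call. = FALSE)
  if (!is.character(target_pool) || length(target_pool) != 1L)
    stop("'target_pool' must be a pool id string", call. = FALSE)
  structure(list(omega_F = omega_F, o_F = o_F, n_F = n_F, b_F = b_F,
                 u_F = u_F, k_D = k_D, h = h, target_pool = target_pool),
            class = "controller_params")
}

#' Specification of the five-enzyme violacein pathway
#'
#' The violacein pathway converts l-tryptophan into violacein through five
#' enzymes (A--E). Enzyme A (`vioA`) is expressed from its own constitutive
#' cassette; enzymes B--E form one polycistronic operon sharing a single
#' transcription rate and RBS strength, their steady-state levels differing
#' only through protein length. Each catalytic step is an irreversible
#' Michaelis-Menten reaction; the external substrate is held constant.
#'
#' @param substrate_level Constant l-tryptophan supply (molecules).
#' @param omega_A `vioA` transcription rate (mRNAs per min).
#' @param omega_BCDE Shared operon transcription rate (the induction input).
#' @param n_enzymes Protein lengths (aa) of enzymes A..E. `vioB` defaults to
#'   three times the length of the other enzymes, reflecting its
#'   disproportionate ribosome sequestration.
#' @param kcat Per-step turnover numbers (per min), length 5 (recycled).
#' @param Km Per-step Michaelis constants (molecules), length 5 (recycled).
#' @param b,u RBS association/dissociation rates shared by all pathway genes.
#' @param delta_m Pathway mRNA degradation rate (per min).
#' @return An object of class `pathway_spec`.
#' @examples
#' pathway_spec()
#' @export
pathway_spec <- function(substrate_level = 1e5, omega_A = 25,
                         omega_BCDE = 100,
                         n_enzymes = c(A = 300, B = 900, C = 300,
                                       D = 300, E = 300),
                         kcat = 10, Km = 1e3, b = 1, u = 1, delta_m = 0.1) {
  if (length(n_enzymes) != 5L || any(n_enzymes <= 0))
    stop("'n_enzymes' must give 5 positive lengths (A..E)", call. = FALSE)
  kcat <- rep_len(kcat, 5L); Km <- rep_len(Km, 5L)
  if (any(kcat < 0) || any(Km <= 0))
    stop("'kcat' must be >= 0 and 'Km' > 0", call. = FALSE)
  for (nm in c("substrate_level", "omega_A", "omega_BCDE", "b", "u",
               "delta_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a non-negative finite scalar", call. = FALSE)
  }
  names(n_enzymes) <- c("A", "B", "C", "D", "E")
  structure(list(substrate_level = substrate_level, omega_A = omega_A,
                 omega_BCDE = omega_BCDE, n_enzymes = n_enzymes,
                 kcat = kcat, Km = Km, b = b, u = u, delta_m = delta_m),
            class = "pathway_spec")
}
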