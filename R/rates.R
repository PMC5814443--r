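#' Energy-dependent transcription rate
#'
#' Transcripts are born at a rate saturating in the cell's internal energy,
#' `omega * e / (o + e)`, optionally scaled by an autoinhibition factor in
#' \[0, 1\] (used for the housekeeping class and for controller-gated
#' o-rRNA transcription).
#'
#' @param omega Maximal transcription rate (transcripts per min), >= 0.
#' @param e Internal energy (energy units), >= 0.
#' @param o Energy threshold (half-saturation), > 0.
#' @param autoinhibition Multiplicative factor in \[0, 1\].
#' @return Transcription rate in \[0, omega\]; monotone non-decreasing in `e`.
#' @examples
#' transcription_rate(100, e = 0, o = 4.38)      # 0
#' transcription_rate(100, e = 4.38, o = 4.38)   # 50
#' @export
transcription_rate <- function(omega, e, o, autoinhibition = 1) {
  if (any(omega < 0)) stop("omega must be >= 0", call. = FALSE)
  if (any(e < 0)) stop("energy 'e' must be >= 0", call. = FALSE)
  if (any(o <= 0)) stop("threshold 'o' must be > 0", call. = FALSE)
  if (any(autoinhibition < 0 | autoinhibition > 1))
    stop("autoinhibition must lie in [0, 1]", call. = FALSE)
  omega * e / (o + e) * autoinhibition
}

#' Translation rate of a pool of elongating complexes
#'
#' Proteins are completed at rate `c * gamma(e) / n`, where
#' `gamma(e) = gamma_max * e / (K_gamma + e)` is the energy-dependent
#' elongation rate (amino acids per min per ribosome) and `n` the protein
#' length. Linear in the complex count and bounded by `c * gamma_max / n`.
#'
#' @param c Number of translation complexes, >= 0.
#' @param e Internal energy, >= 0.
#' @param n Protein length (amino acids), > 0.
#' @param gamma_max Maximal elongation rate (aa per min per ribosome).
#' @param K_gamma Energy half-saturation of elongation.
#' @return Protein completions per minute.
#' @examples
#' translation_rate(10, e = 7, n = 300, gamma_max = 1260, K_gamma = 7) # 21
#' @export
translation_rate <- function(c, e, n, gamma_max = 1260, K_gamma = 7) {
  if (any(c < 0)) stop("complex count must be >= 0", call. = FALSE)
  if (any(e < 0)) stop("energy 'e' must be >= 0", call. = FALSE)
  if (any(n <= 0)) stop("protein length 'n' must be > 0", call. = FALSE)
  c * gamma_max * e / (K_gamma + e) / n
}

#' Hill repression factor of the resource allocation controller
#'
#' @param p_F Repressor protein amount (molecules), >= 0.
#' @param k_D Dissociation constant (molecules), > 0.
#' @param h Hill coefficient, >= 1.
#' @return `1 / (1 + (p_F / k_D)^h)`, in (0, 1\]; monotone decreasing in
#'   `p_F`; 1 at `p_F = 0` and 1/2 at `p_F = k_D`.
#' @examples
#' repression_factor(0, 100, 2)    # 1
#' repression_factor(100, 100, 2)  # 0.5
#' @export
repression_factor <- function(p_F, k_D, h) {
  if (any(p_F < 0)) stop("p_F must be >= 0", call. = FALSE)
  if (any(k_D <= 0)) stop("k_D must be > 0", call. = FALSE)
  if (any(h < 1)) stop("Hill coefficient h must be >= 1", call. = FALSE)
  1 / (1 + (p_F / k_D)^h)
}

#' Instantaneous growth (dilution) rate
#'
#' The growth rate is total translational flux divided by proteome mass:
#' `lambda = gamma(e) / M * sum(c)` where the sum runs over every
#' translating complex of every ribosome pool, including circuit genes and
#' the controller repressor; all translation produces proteome mass.
#'
#' @param state Named state vector (layout of the model).
#' @param model A `cell_model` (or built model).
#' @return Growth rate (per min), >= 0.
#' @export
growth_rate <- function(state, model) {
  bm <- as_built(model)
  check_state(state, bm)
  e <- state[[bm$idx$e]]
  gam <- bm$p$gamma_max * e / (bm$p$K_gamma + e)
  gam * sum(state[bm$tt$i_c]) / bm$p$M
}

#' Ribosomal proteome mass fraction
#'
#' Fraction of the proteome mass held in ribosomal protein: free ribosomes,
#' the empty-ribosome protein, every mRNA-bound translation complex (each
#' contains one ribosome) and the o-ribosomes of every orthogonal pool,
#' each weighted by the ribosomal protein length `n_R`. rRNA mass is
#' excluded: `M` is a proteome size.
#'
#' @inheritParams growth_rate
#' @return Mass fraction in \[0, 1\].
#' @export
ribosome_mass_fraction <- function(state, model) {
  bm <- as_built(model)
  check_state(state, bm)
  tot <- state[[bm$idx$R]] + state[[bm$idx$p_R]] + sum(state[bm$tt$i_c])
  if (bm$n_pool) tot <- tot + sum(state[bm$iP])
  min(1, bm$p$n_R * tot / bm$p$M)
}

check_state <- function(state, bm) {
  if (length(state) != bm$n)
    stop("state has length ", length(state), " but the model has ", bm$n,
         " species", call. = FALSE)
  invisible(state)
}
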