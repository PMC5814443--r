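#' Kinetic parameters of the host cell model
#'
#' Constructs the full parameter set of the coarse-grained host model:
#' a simple metabolism (substrate import and catabolism into an internal
#' "energy" currency), transcription of four host gene classes
#' (transporter `T`, catabolic enzyme `E`, housekeeping `H`, ribosomal `R`),
#' translation by free ribosomes, and ribosome biosynthesis from a lumped
#' ribosomal protein (the "empty ribosome" `p_R`) plus an rRNA component `r`.
#'
#' Units: time in minutes, amounts in molecules per cell, protein lengths in
#' amino acids, energy in arbitrary "energy units". No volume scaling is
#' applied. Defaults are the published fitted parameter set of the
#' Weisse et al. (2015) growth model, extended with explicit rRNA species
#' kinetics (`omega_r`, `o_r`, `b_r`, `u_r`, `delta_r`). The rRNA
#' transcription capacity `omega_r` defaults to 1e4 per min -- roughly
#' tenfold the ribosomal-protein mRNA rate -- reflecting that rRNA
#' operons dominate bacterial transcription; an rRNA-starved host (low
#' `omega_r`) is pathologically fragile to any diversion of the
#' empty-ribosome protein into an orthogonal pool.
#'
#' @param ... named overrides of any default parameter, e.g.
#'   `host_params(s_ext = 1e3, gamma_max = 630)`.
#'
#' @return An object of class `host_params`: a named list with elements
#' \describe{
#'   \item{s_ext}{external substrate concentration (molecules), held constant}
#'   \item{v_T, K_T}{substrate import Vmax (per min per transporter) and
#'     Michaelis constant (molecules)}
#'   \item{v_E, K_E}{catabolism Vmax and Michaelis constant}
#'   \item{n_s}{energy units yielded per catabolised substrate molecule}
#'   \item{omega_T, omega_E, omega_H, omega_R, omega_r}{maximal transcription
#'     rates (transcripts per min) of the transporter, enzyme, housekeeping
#'     and ribosomal-protein mRNAs and of the rRNA}
#'   \item{o_T, o_E, o_H, o_R, o_r}{transcriptional energy thresholds}
#'   \item{K_H, h_H}{housekeeping negative autoregulation threshold
#'     (molecules) and Hill coefficient}
#'   \item{b_T..b_R, u_T..u_R}{ribosome-mRNA association (per molecule per
#'     min) and dissociation (per min) rates}
#'   \item{n_T, n_E, n_H, n_R}{protein lengths (amino acids)}
#'   \item{gamma_max, K_gamma}{maximal translation elongation rate (aa per min
#'     per ribosome) and its energy half-saturation threshold}
#'   \item{M}{total proteome mass (amino acids)}
#'   \item{b_r, u_r}{empty-ribosome/rRNA association and dissociation rates}
#'   \item{delta_m, delta_r, delta_R, delta_pR}{degradation rates (per min) of
#'     mRNA, free rRNA, assembled ribosomes and the empty-ribosome protein}
#' }
#' @examples
#' p <- host_params()
#' p$gamma_max
#' host_params(s_ext = 100)$s_ext
#' @export
host_params <- function(...) {
  p <- list(
    s_ext = 1e4,
    v_T = 726, K_T = 1e3,
    v_E = 5800, K_E = 1e3,
    n_s = 0.5,
    omega_T = 4.139172, omega_E = 4.139172,
    omega_H = 948.9349, omega_R = 929.9678, omega_r = 1e4,
    o_T = 4.379733, o_E = 4.379733, o_H = 4.379733,
    o_R = 426.8693, o_r = 426.8693,
    K_H = 1.522190e5, h_H = 4,
    b_T = 1, b_E = 1, b_H = 1, b_R = 1,
    u_T = 1, u_E = 1, u_H = 1, u_R = 1,
    n_T = 300, n_E = 300, n_H = 300, n_R = 7549,
    gamma_max = 1260, K_gamma = 7,
    M = 1e8,
    b_r = 1, u_r = 1,
    delta_m = 0.1, delta_r = 0.1, delta_R = 0, delta_pR = 0
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("host_params() overrides must be named", call. = FALSE)
    unknown <- setdiff(names(ov), names(p))
    if (length(unknown))
      stop("unknown host parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    p[names(ov)] <- ov
  }
  validate_host_params(p)
  structure(p, class = "host_params")
}

validate_host_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]]))
      stop("host parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  pos <- c("v_T", "K_T", "v_E", "K_E", "n_s", "o_T", "o_E", "o_H", "o_R",
           "o_r", "K_H", "n_T", "n_E", "n_H", "n_R", "gamma_max", "K_gamma",
           "M")
  for (nm in pos) if (p[[nm]] <= 0)
    stop("host parameter '", nm, "' must be strictly positive", call. = FALSE)
  nonneg <- c("s_ext", "omega_T", "omega_E", "omega_H", "omega_R", "omega_r",
              "b_T", "b_E", "b_H", "b_R", "u_T", "u_E", "u_H", "u_R",
              "b_r", "u_r", "delta_m", "delta_r", "delta_R", "delta_pR")
  for (nm in nonneg) if (p[[nm]] < 0)
    stop("host parameter '", nm, "' must be non-negative", call. = FALSE)
  if (p$h_H < 1) stop("Hill coefficient 'h_H' must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.host_params <- function(x, ...) {
  cat("<host_params> (minutes / molecules per cell / amino acids)\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}
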