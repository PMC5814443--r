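# Growth-law calibration: synthetic dataset generation in the structure of
# classic growth-rate vs ribosomal-mass-fraction experiments (nutrient
# quality and translation-inhibitor modulation), and least-squares
# parameter fitting validated by recovery of the generating values.

#' Generate a synthetic growth-law dataset
#'
#' Simulates the host model across a grid of nutrient qualities (values of
#' `n_s`, the energy yield per catabolised substrate) and translation
#' inhibitor levels (multiplicative factors on `gamma_max`, mimicking a
#' chloramphenicol dose), records the steady-state growth rate and
#' ribosomal mass fraction, and applies multiplicative Gaussian noise.
#'
#' @param params Generating [host_params()].
#' @param nutrient_grid Values of `n_s` (nutrient quality).
#' @param inhibitor_grid Multiplicative factors in (0, 1\] on `gamma_max`.
#' @param sigma Relative noise standard deviation (0 for noiseless data).
#' @param seed Integer RNG seed; recorded in the dataset.
#' @param tol Residual tolerance for the steady-state solves.
#' @return A data frame of class `growth_law_data` with columns
#'   `condition`, `n_s`, `inhibitor`, `lam_obs`, `phi_R_obs`, `lam_true`,
#'   `phi_R_true`, `sigma`, `converged`, and attribute `seed`.
#' @export
generate_growth_law_data <- function(params = host_params(),
                                     nutrient_grid = c(0.1, 0.2, 0.3,
                                                       0.5, 0.7, 1.0),
                                     inhibitor_grid = c(1, 0.7, 0.5),
                                     sigma = 0, seed = 1, tol = 1e-8) {
  if (!length(nutrient_grid) || !length(inhibitor_grid))
    stop("grids must be non-empty", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  grid <- expand.grid(n_s = nutrient_grid, inhibitor = inhibitor_grid)
  n <- nrow(grid)
  lam <- phi <- numeric(n)
  conv <- logical(n)
  warm <- NULL
  for (i in seq_len(n)) {
    p <- params
    p$n_s <- grid$n_s[i]
    p$gamma_max <- params$gamma_max * grid$inhibitor[i]
    m <- cell_model(do.call(host_params, unclass(p)))
    ss <- solve_steady_state(m, init = warm, tol = tol,
                             newton_first = !is.null(warm))
    warm <- ss$state
    lam[i] <- ss$lam
    phi[i] <- ss$phi_R
    conv[i] <- ss$converged
    if (!ss$converged)
      warning("condition ", i, " did not converge; row flagged",
              call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  noise_l <- stats::rnorm(n, 0, sigma)
  noise_p <- stats::rnorm(n, 0, sigma)
  out <- data.frame(
    condition = sprintf("ns%.3g_inh%.3g", grid$n_s, grid$inhibitor),
    n_s = grid$n_s, inhibitor = grid$inhibitor,
    lam_obs = lam * (1 + noise_l),
    phi_R_obs = pmin(1, pmax(0, phi * (1 + noise_p))),
    lam_true = lam, phi_R_true = phi,
    sigma = sigma, converged = conv
  )
  attr(out, "seed") <- seed
  class(out) <- c("growth_law_data", "data.frame")
  out
}

#' Fit host parameters to growth-law data
#'
#' Weighted least squares over the joint growth-rate and ribosomal-mass-
#' fraction residuals, by Levenberg-Marquardt (via `minpack.lm::nls.lm`)
#' in log-parameter space (all fitted parameters are positive). Residuals
#' are scaled by the observation means so the two observables contribute
#' comparably. Deterministic given the starting point.
#'
#' @param dataset A [generate_growth_law_data()] data frame (or any data
#'   frame with columns `n_s`, `inhibitor`, `lam_obs`, `phi_R_obs`).
#' @param free_params Character vector of host parameters to fit
#'   (e.g. `c("gamma_max", "omega_R")`).
#' @param start Named numeric starting values; defaults to the
#'   [host_params()] defaults of the free parameters.
#' @param bounds Named list of length-2 ranges bracketing each free
#'   parameter; defaults to (default/10, default*10).
#' @param params Fixed values for the remaining parameters.
#' @param tol Residual tolerance for the steady-state solves.
#' @return List with `estimates` (named vector), `loss` (sum of squared
#'   scaled residuals), `residuals` (per condition and observable),
#'   `niter`, `message`.
#' @export
fit_growth_law_params <- function(dataset, free_params, start = NULL,
                                  bounds = NULL, params = host_params(),
                                  tol = 1e-8) {
  if (!length(free_params)) stop("free_params must be non-empty",
                                 call. = FALSE)
  if (!all(free_params %in% names(params)))
    stop("unknown parameter(s): ",
         paste(setdiff(free_params, names(params)), collapse = ", "),
         call. = FALSE)
  need <- c("n_s", "inhibitor", "lam_obs", "phi_R_obs")
  if (!all(need %in% names(dataset)))
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  defaults <- unlist(params[free_params])
  if (is.null(start)) start <- defaults
  start <- start[free_params]
  if (is.null(bounds))
    bounds <- stats::setNames(lapply(defaults, function(v) c(v / 10, v * 10)),
                              free_params)
  lo <- vapply(bounds[free_params], `[`, numeric(1), 1)
  hi <- vapply(bounds[free_params], `[`, numeric(1), 2)
  if (any(start < lo | start > hi))
    stop("start values must lie inside the bounds", call. = FALSE)

  sc_l <- mean(dataset$lam_obs)
  sc_p <- mean(dataset$phi_R_obs)
  warm <- new.env(parent = emptyenv())

  predict_rows <- function(theta) {
    p <- unclass(params)
    p[free_params] <- as.list(theta)
    lamv <- phiv <- numeric(nrow(dataset))
    for (i in seq_len(nrow(dataset))) {
      pi <- p
      pi$n_s <- dataset$n_s[i]
      pi$gamma_max <- p$gamma_max * dataset$inhibitor[i]
      m <- cell_model(do.call(host_params, pi))
      key <- paste0("c", i)
      init <- warm[[key]]
      ss <- solve_steady_state(m, init = init, tol = tol,
                               newton_first = !is.null(init))
      warm[[key]] <- ss$state
      lamv[i] <- ss$lam
      phiv[i] <- ss$phi_R
    }
    list(lam = lamv, phi = phiv)
  }

  resid_fn <- function(ltheta) {
    theta <- exp(ltheta)
    theta <- pmin(pmax(theta, lo), hi)
    pr <- predict_rows(theta)
    c((pr$lam - dataset$lam_obs) / sc_l,
      (pr$phi - dataset$phi_R_obs) / sc_p)
  }

  fit <- minpack.lm::nls.lm(par = log(start), fn = resid_fn,
                            lower = log(lo), upper = log(hi),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-10))
  est <- stats::setNames(exp(fit$par), free_params)
  res <- resid_fn(log(est))
  list(estimates = est,
       loss = sum(res^2),
       residuals = data.frame(condition = rep(dataset$condition, 2),
                              observable = rep(c("lam", "phi_R"),
                                               each = nrow(dataset)),
                              residual = res),
       niter = fit$niter,
       message = fit$message)
}
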