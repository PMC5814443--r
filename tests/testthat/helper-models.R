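# Shared fixtures: models are built in code and expensive steady states are
# memoised for the duration of the test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

base_model <- function() cell_model()

base_steady <- function() cached("base_ss", solve_steady_state(base_model()))

opool_model <- function(omega_rho = 500, ...) {
  add_o_pool(cell_model(), o_pool_spec("o1", omega_rho = omega_rho, ...))
}

opool_steady <- function() cached("opool_ss", solve_steady_state(opool_model()))

two_reporter_model <- function(rfp_pool = "host", gfp_pool = "host",
                               omega_rho = 500, omega_rfp = 1,
                               omega_gfp = 100) {
  m <- cell_model()
  m <- add_o_pool(m, o_pool_spec("o1", omega_rho = omega_rho))
  m <- add_circuit_gene(m, circuit_gene("gfp", omega = omega_gfp,
                                        pool = gfp_pool))
  m <- add_circuit_gene(m, circuit_gene("rfp", omega = omega_rfp,
                                        pool = rfp_pool))
  m
}

# a random strictly-positive state for property checks (deterministic)
random_state <- function(model, seed) {
  sp <- species_names(model)
  withr_seed <- .Random.seed_save()
  on.exit(.Random.seed_restore(withr_seed))
  set.seed(seed)
  stats::setNames(stats::runif(length(sp), 0.1, 1000), sp)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(s) {
  if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
}

# project an extended-model state onto another model's species (missing
# species must be zero-filled by the caller)
project_state <- function(state, to_model) {
  sp <- species_names(to_model)
  stats::setNames(state[sp], sp)
}
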