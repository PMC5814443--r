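minimal_yaml <- function(dir, extra = "") {
  path <- file.path(dir, "scenario.yaml")
  writeLines(c(
    "host:",
    "  s_ext: 10000.0",
    "analysis:",
    "  type: simulate",
    "  t_max: 10",
    "  dt: 5",
    extra
  ), path)
  path
}

test_that("a minimal config is valid and defaults are filled", {
  d <- withr::local_tempdir()
  cfg <- load_config(minimal_yaml(d))
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$analysis$type, "simulate")
  expect_equal(cfg$host$s_ext, 1e4)
  expect_equal(cfg$host$gamma_max, 1260)  # default filled
})

test_that("unknown keys are rejected by name", {
  d <- withr::local_tempdir()
  p <- file.path(d, "bad.yaml")
  writeLines(c("hosst:", "  s_ext: 1", "analysis:", "  type: simulate"), p)
  expect_error(load_config(p), "hosst")
  writeLines(c("analysis:", "  type: simulate", "  t_maxx: 5"), p)
  expect_error(load_config(p), "t_maxx")
  writeLines(c("analysis:", "  type: warp"), p)
  expect_error(load_config(p), "unknown analysis type")
  writeLines(c("analysis:", "  type: robustness", "  n_draws: 2"), p)
  expect_error(load_config(p), "seed")
})

test_that("configs round-trip through serialisation", {
  d <- withr::local_tempdir()
  p <- file.path(d, "full.yaml")
  writeLines(c(
    "pools:",
    "  - pool_id: o1",
    "    omega_rho: 500.0",
    "    repressible: true",
    "genes:",
    "  - name: gfp",
    "    omega: 100.0",
    "    pool: o1",
    "controller:",
    "  target_pool: o1",
    "analysis:",
    "  type: isocost",
    "  induced: gfp",
    "  constitutive: gfp",
    "  omega_grid: [1.0, 10.0]"
  ), p)
  cfg <- load_config(p)
  p2 <- file.path(d, "rt.yaml")
  write_config(cfg, p2)
  cfg2 <- load_config(p2)
  cfg2$output_dir <- cfg$output_dir
  expect_equal(cfg2[names(cfg2) != "analysis"],
               cfg[names(cfg) != "analysis"])
  expect_equal(cfg2$analysis[order(names(cfg2$analysis))],
               cfg$analysis[order(names(cfg$analysis))])
})

test_that("grids parse from explicit lists and from/to/n blocks", {
  d <- withr::local_tempdir()
  p <- file.path(d, "g.yaml")
  writeLines(c("analysis:",
               "  type: isocost",
               "  induced: a", "  constitutive: b",
               "  omega_grid: {from: 0, to: 2, points: 3, log: true}"), p)
  cfg <- load_config(p)
  expect_equal(cfg$analysis$omega_grid, c(1, 10, 100))
})

test_that("run_scenario writes outputs, summary and a complete manifest", {
  d <- withr::local_tempdir()
  cfg <- load_config(minimal_yaml(d))
  out <- file.path(d, "res")
  man <- run_scenario(cfg, output_dir = out)
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(all(names(man$files) %in% list.files(out)))
  # every listed file's checksum matches what is on disk
  for (f in names(man$files)) {
    expect_equal(unname(tools::md5sum(file.path(out, f))), man$files[[f]])
  }
  # rerun with the identical config gives byte-identical numeric output
  out2 <- file.path(d, "res2")
  run_scenario(cfg, output_dir = out2)
  expect_identical(readLines(file.path(out, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))
})

test_that("a zero-horizon simulation echoes the initial state", {
  d <- withr::local_tempdir()
  p <- file.path(d, "z.yaml")
  writeLines(c("analysis:", "  type: simulate", "  t_max: 0"), p)
  out <- file.path(d, "res")
  run_scenario(load_config(p), output_dir = out)
  tr <- utils::read.csv(file.path(out, "trajectory.csv"))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$time, 0)
  expect_equal(tr$R, 10)  # default seed ribosomes
})

test_that("state snapshots serialise species by symbol", {
  d <- withr::local_tempdir()
  ss <- base_steady()
  f <- file.path(d, "state.csv")
  write_state_csv(ss$state, f)
  df <- utils::read.csv(f)
  expect_equal(df$species[1:2], c("s_i", "e"))
  expect_equal(df$amount, unname(as.numeric(ss$state)))
})

test_that("a calibrate scenario runs end to end with a recorded seed", {
  d <- withr::local_tempdir()
  p <- file.path(d, "cal.yaml")
  writeLines(c("analysis:",
               "  type: calibrate",
               "  nutrient_grid: [0.3, 1.0]",
               "  inhibitor_grid: [1.0]",
               "  sigma: 0.0",
               "  seed: 3",
               "  free_params: [gamma_max]"), p)
  out <- file.path(d, "res")
  man <- run_scenario(load_config(p), output_dir = out)
  expect_true(man$converged)
  expect_equal(man$seed, 3)
  sm <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(sm$fit$estimates$gamma_max, 1260, tolerance = 1e-3)
  ds <- utils::read.csv(file.path(out, "growth_law_data.csv"))
  expect_equal(nrow(ds), 2)
})
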