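small_config <- function(R = 0.1) {
  experiment_config(model = "wsg", params = small_wsg_params(),
                    n_ensemble = 10, horizon = 30, observed = "sheep",
                    R = R, interval = 10)
}

test_that("virtual patients are reproducible and carry consistent records", {
  cfg <- small_config()
  a <- make_virtual_patient(cfg, seed = 21)
  b <- make_virtual_patient(cfg, seed = 21)
  expect_identical(a, b)

  expect_equal(nrow(a$macro_raw), cfg$horizon + 1)
  expect_equal(length(a$true_params), 2)
  # parameter columns are constant over time at the true values
  expect_true(all(a$macro_raw[, "wolf_reproduce_pct"] == a$true_params[1]))

  # near-zero measurement noise reproduces the true observed component
  cfg0 <- small_config(R = 1e-12)
  p0 <- make_virtual_patient(cfg0, seed = 22)
  truth <- p0$macro_transformed[p0$measurements$times + 1, "sheep"]
  expect_equal(unname(p0$measurements$Y[, "sheep"]), unname(truth),
               tolerance = 1e-4)
})

test_that("the assimilation loop runs, records beliefs, and is reproducible", {
  cfg <- small_config()
  pat <- make_virtual_patient(cfg, seed = 31)
  r1 <- run_abmkf(cfg, pat, seed = 32)
  r2 <- run_abmkf(cfg, pat, seed = 32)
  expect_equal(r1$surprisal, r2$surprisal)
  expect_equal(r1$pred_mean, r2$pred_mean)

  expect_equal(length(r1$surprisal), cfg$horizon + 1)
  expect_true(all(is.finite(r1$surprisal)))
  expect_equal(names(r1$post_beliefs), as.character(cfg$measure$times))

  # forecast baseline: no updates, no posterior records
  base <- run_abmkf(cfg, pat, seed = 32, assimilate = FALSE)
  expect_equal(length(base$post_beliefs), 0)
  expect_equal(length(base$surprisal_post), 0)
})

test_that("a fully observed near-exact measurement pins the posterior mean", {
  cfg <- experiment_config(model = "wsg", params = small_wsg_params(),
                           n_ensemble = 30, horizon = 10,
                           observed = c("wolves", "sheep", "grass"),
                           R = 1e-8, interval = 5)
  pat <- make_virtual_patient(cfg, seed = 41)
  res <- run_abmkf(cfg, pat, seed = 42)
  for (ti in seq_along(cfg$measure$times)) {
    t <- cfg$measure$times[ti]
    y <- pat$measurements$Y[ti, ]
    post <- res$post_beliefs[[as.character(t)]]$mean[1:3]
    expect_equal(unname(post), unname(y), tolerance = 0.01)
  }
})

test_that("microstate snapshots survive a JSON round trip", {
  p <- small_wsg_params()
  set.seed(51)
  m <- init_wsg(p)
  for (t in 1:5) m <- step_wsg(m, p)
  path <- tempfile(fileext = ".json")
  save_microstate_json(m, path)
  expect_equal(load_microstate_json(path), m, tolerance = 1e-12)

  vp <- viral_params(n = 8)
  vm <- init_viral(vp, 2)
  for (t in 1:5) vm <- step_viral(vm, vp)
  path2 <- tempfile(fileext = ".json")
  save_microstate_json(vm, path2)
  back <- load_microstate_json(path2)
  expect_equal(back$epithelium, vm$epithelium)
  expect_equal(back$virus, vm$virus, tolerance = 1e-12)
  expect_equal(summarize_viral(back)$values, summarize_viral(vm)$values,
               tolerance = 1e-12)
})

test_that("the command-line interface runs its subcommands", {
  cfg_path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    version = "abmkf-config/1", model = "wsg",
    params = list(world_width = 15, world_height = 15, init_wolves = 15,
                  init_sheep = 30),
    n_ensemble = 8, horizon = 20, observed = "sheep", R = 0.1, interval = 10,
    n_patients = 2, measurements = "sheep", r_levels = c(1, 0.1)),
    cfg_path, auto_unbox = TRUE)

  # simulate is deterministic: same seed, byte-identical CSV
  out1 <- tempfile(fileext = ".csv"); out2 <- tempfile(fileext = ".csv")
  expect_equal(abmkf_cli(c("simulate", "--config", cfg_path, "--seed", "3",
                           "--out", out1)), 0L)
  abmkf_cli(c("simulate", "--config", cfg_path, "--seed", "3", "--out", out2))
  expect_identical(readLines(out1), readLines(out2))
  sim <- utils::read.csv(out1)
  expect_equal(sort(unique(sim$patient)), 1:2)

  # tune produces one group per (measurement, R) setting
  out3 <- tempfile(fileext = ".csv")
  expect_equal(abmkf_cli(c("tune", "--config", cfg_path, "--seed", "3",
                           "--out", out3)), 0L)
  tu <- utils::read.csv(out3)
  expect_equal(nrow(unique(tu[c("measurement", "R")])), 2)

  # assimilate writes a belief/surprisal table
  out4 <- tempfile(fileext = ".csv")
  expect_equal(abmkf_cli(c("assimilate", "--config", cfg_path, "--seed", "3",
                           "--out", out4)), 0L)
  asm <- utils::read.csv(out4)
  expect_true(all(c("time", "surprisal", "mean_sheep", "sd_sheep") %in% names(asm)))

  # cluster on the simulate output
  out5 <- tempfile(fileext = ".csv")
  expect_equal(abmkf_cli(c("cluster", "--config", cfg_path, "--seed", "3",
                           "--out", out5, "--traj", out1)), 0L)
  cl <- utils::read.csv(out5)
  expect_equal(nrow(cl), 2)

  # failure modes: missing file and malformed config exit nonzero
  expect_equal(suppressMessages(
    abmkf_cli(c("assimilate", "--config", "/nonexistent.json",
                "--out", out4))), 1L)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(model = "unknown"), bad, auto_unbox = TRUE)
  expect_equal(suppressMessages(
    abmkf_cli(c("assimilate", "--config", bad, "--out", out4))), 1L)
  expect_equal(suppressMessages(abmkf_cli(character(0))), 1L)
})
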