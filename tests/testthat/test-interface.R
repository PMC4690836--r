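test_that("run configurations validate keys and fall back to defaults", {
  cfg <- read_run_config(list(parent_diameter_mm = 3.5))
  expect_equal(cfg$parent_diameter_mm, 3.5)
  expect_equal(cfg$target_porosity, 0.70)
  expect_error(read_run_config(list(bogus_key = 1)), "unknown config keys")
  expect_error(read_run_config(list(stl_path = "nope.stl")), "does not exist")
})

test_that("the demo pipeline produces a coherent, deterministic report", {
  demo <- system.file("extdata/demo_config.yaml", package = "stentflow")
  cfg <- read_run_config(demo)
  cfg$out_dir <- tempfile("run1_")
  cfg$deploy_max_iters <- 400
  rep1 <- run_pipeline(cfg, verbose = FALSE)
  expect_true(file.exists(file.path(cfg$out_dir, "report.json")))
  st <- rep1$stages
  expect_lt(abs(st$device$measured_porosity - 0.70), 0.01)
  expect_equal(st$crimp$crimped_diameter, 1.0)
  expect_lt(st$crimp$strand_length_error, 0.01)
  expect_true(st$deploy$converged)
  expect_gt(st$flow$inflow_reduction_pct, 0)
  expect_identical(length(st$flow$pressure_sweep),
                   length(cfg$jailed_bias_sweep_pa))
  # deterministic rerun: identical numbers
  cfg2 <- cfg
  cfg2$out_dir <- tempfile("run2_")
  rep2 <- run_pipeline(cfg2, verbose = FALSE)
  expect_identical(rep1$stages$flow$inflow_reduction_pct,
                   rep2$stages$flow$inflow_reduction_pct)
  expect_identical(rep1$stages$deploy$apposition_mean_mm,
                   rep2$stages$deploy$apposition_mean_mm)
})

test_that("stage failures yield a partial report with diagnostics", {
  cfg <- read_run_config(list(out_dir = tempfile("bad_"),
                              catheter_diameter_mm = 0.01))
  rep <- run_pipeline(cfg, verbose = FALSE, last_stage = "deploy")
  expect_true(!is.null(rep$stages$crimp$error))
  expect_true(!is.null(rep$stages$geometry$source))
})

test_that("the CLI dispatches subcommands and flags errors", {
  expect_identical(cli(character(0)), 0L)
  expect_identical(cli("--version"), 0L)
  expect_identical(suppressMessages(cli("frobnicate")), 2L)
  dir <- tempfile("cli_"); dir.create(dir)
  old <- setwd(dir); on.exit(setwd(old))
  code <- suppressMessages(cli(c("make-device", "--out", "dev",
                                 "--strands", "48", "--wire-um", "30",
                                 "--porosity", "0.7")))
  expect_identical(code, 0L)
  expect_true(file.exists("dev.stl"))
  expect_true(file.exists("dev.obj"))
  meta <- jsonlite::read_json("dev.json")
  expect_lt(abs(meta$measured_porosity - 0.70), 0.01)
  expect_gte(meta$pore_diameter_um, 120)
  expect_lte(meta$pore_diameter_um, 260)
})
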