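write_config <- function(dir, model_file, expr_file, out_dir, extra = list()) {
  cfg <- c(list(
    model = model_file,
    expression = expr_file,
    measured_growth = 4,
    pc_range = c(0, 40),
    output_dir = out_dir,
    sampler = list(n_points = 200, thinning = 5, seed = 11)
  ), extra)
  path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, path)
  path
}

setup_run <- function() {
  dir <- tempfile(); dir.create(dir)
  m <- generate_toy_model(seed = 1)
  prof <- expression_profile(c(gT = 100, g1 = 50), condition = "chain")
  paths <- write_fixtures(m, prof, dir, basename = "chain")
  list(dir = dir, model = paths[["json"]], expr = paths[["expression"]])
}

test_that("config reading validates paths and numeric settings", {
  s <- setup_run()
  cfg_path <- write_config(s$dir, s$model, s$expr, file.path(s$dir, "out"))
  cfg <- read_run_config(cfg_path)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$sampler$thinning, 5)
  expect_equal(cfg$growth_tolerance, 1e-3)  # default filled in

  bad <- write_config(s$dir, file.path(s$dir, "missing.json"), s$expr,
                      s$dir)
  expect_error(read_run_config(bad), "does not exist")
  expect_error(read_run_config(tempfile()), "not found")
})

test_that("run_fit_pc executes the pipeline and writes its reports", {
  s <- setup_run()
  out <- file.path(s$dir, "fit_out")
  cfg <- write_config(s$dir, s$model, s$expr, out)
  fit <- run_fit_pc(cfg)
  expect_equal(fit$status, "fit")
  expect_equal(fit$delta_fit, 8, tolerance = 1e-2)
  expect_true(file.exists(file.path(out, "pc_scan.tsv")))
  scan <- read.delim(file.path(out, "pc_scan.tsv"))
  expect_equal(names(scan), c("delta", "growth", "status"))
  report <- jsonlite::read_json(file.path(out, "pc_fit.json"))
  expect_equal(report$status, "fit")
  expect_equal(report$delta_fit, fit$delta_fit, tolerance = 1e-9)
  prov <- jsonlite::read_json(file.path(out, "provenance_fit.json"))
  expect_equal(prov$stage, "fit-pc")
  expect_true(!is.null(prov$package_version))
})

test_that("a measured growth above the plateau is reported, not an error", {
  s <- setup_run()
  out <- file.path(s$dir, "plateau_out")
  cfg <- write_config(s$dir, s$model, s$expr, out)
  # rewrite with unreachable growth
  y <- yaml::read_yaml(cfg); y$measured_growth <- 12
  yaml::write_yaml(y, cfg)
  fit <- run_fit_pc(cfg)
  expect_equal(fit$status, "at-plateau-unreachable")
})

test_that("run_sample writes samples and a byte-stable summary", {
  s <- setup_run()
  out1 <- file.path(s$dir, "s1"); out2 <- file.path(s$dir, "s2")
  cfg1 <- write_config(s$dir, s$model, s$expr, out1)
  samples <- run_sample(cfg1, delta = 8)
  expect_s3_class(samples, "flux_sample_set")
  expect_true(file.exists(file.path(out1, "samples.tsv.gz")))
  summ <- read.delim(file.path(out1, "flux_summary.tsv"))
  # biomass is pinned at (a fraction of) the optimum 4
  expect_equal(summ$mean[summ$reaction == "BIOMASS"], 4, tolerance = 0.01)
  # identical config + seed => byte-identical summary
  cfg2 <- write_config(s$dir, s$model, s$expr, out2)
  run_sample(cfg2, delta = 8)
  expect_identical(readLines(file.path(out1, "flux_summary.tsv")),
                   readLines(file.path(out2, "flux_summary.tsv")))
})

test_that("sampling an over-constrained model fails loudly", {
  dir <- tempfile(); dir.create(dir)
  m <- generate_toy_model(maintenance_flux = 0.5, seed = 1)
  prof <- expression_profile(c(gT = 100, g1 = 50), condition = "chain")
  paths <- write_fixtures(m, prof, dir, basename = "maint")
  cfg <- write_config(dir, paths[["json"]], paths[["expression"]],
                      file.path(dir, "out"))
  expect_error(run_sample(cfg, delta = 0), "infeasible at PC")
})

test_that("the command-line entry point is present and parses", {
  cli <- system.file("cli", "eflux.R", package = "efluxpc")
  expect_true(nzchar(cli))
  expect_no_error(parse(cli))
})
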