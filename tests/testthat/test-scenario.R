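# Configuration ingestion (units), table round-trips, the scenario runner
# and the command-line wrapper.

test_that("material cards round-trip through JSON with unit conversion", {
  tmp <- withr::local_tempdir()
  card <- file.path(tmp, "pdms.json")
  write_material_card(pdms_card(), card)
  z <- read_material_card(card)
  expect_s3_class(z, "zener_material")
  expect_equal(z$E0, 2.114e6)
  expect_equal(z$tau, 0.2611)
  # MPa-suffixed keys convert on ingest
  writeLines('{"model":"zener","E0_MPa":2.114,"E1_MPa":0.9365,"tau_s":0.2611}',
             card)
  z2 <- read_material_card(card)
  expect_equal(z2$E0, 2.114e6)
  expect_equal(z2$E1, 0.9365e6)
  # YAML works too
  ycard <- file.path(tmp, "m.yaml")
  writeLines(c("model: maxwell", "E1_MPa: 2.827", "tau_s: 13.38"), ycard)
  m <- read_material_card(ycard)
  expect_s3_class(m, "maxwell_material")
  expect_equal(m$E1, 2.827e6)
})

test_that("records and fields round-trip through delimited text", {
  tmp <- withr::local_tempdir()
  rec <- generate_synthetic_record(pdms_card(), duration = 1,
                                   sample_rate = 20, noise_sd = 0.01,
                                   seed = 4)
  p <- file.path(tmp, "rec.csv")
  write_record(rec, p)
  back <- read_record(p)
  expect_equal(back$t, rec$t)
  expect_equal(back$sigma, rec$sigma)
  expect_equal(back$meta$seed, 4)

  g <- validation_tube()
  f <- simulate_maxwell(maxwell_from_speed(5, g, tau = 2), g,
                        pulse_spec(1, 0.2),
                        simulation_grid(N = 32, t_end = 0.6))
  fp <- file.path(tmp, "field.csv")
  write_field(f, fp)
  fb <- read_field(fp)
  expect_equal(fb$x, f$x)
  expect_equal(fb$t, f$t)
  expect_equal(fb$p, f$p)
})

test_that("spectrum scenarios produce the table, prediction and manifest", {
  tmp <- withr::local_tempdir()
  cfg <- file.path(tmp, "scenario.yaml")
  writeLines(c(
    "output: spectrum",
    "n_max: 10",
    "seed: 3",
    "material:",
    "  model: zener",
    "  E0_MPa: 2.114",
    "  E1_MPa: 0.9365",
    "  tau_s: 0.2611",
    "geometry:",
    "  r_mm: 4",
    "  e_mm: 0.5",
    "  L: 1",
    "  rho: 1000"), cfg)
  man <- run_scenario(cfg, out_dir = file.path(tmp, "out"))
  expect_equal(man$output, "spectrum")
  expect_equal(man$seed, 3)
  sp <- read.csv(file.path(tmp, "out", "spectrum.csv"))
  expect_equal(nrow(sp), 10)
  pred <- jsonlite::read_json(file.path(tmp, "out", "prediction.json"),
                              simplifyVector = TRUE)
  expect_equal(pred$c, 13.808, tolerance = 1e-4)
  expect_true(file.exists(file.path(tmp, "out", "manifest.json")))
})

test_that("field scenarios report the measured decay", {
  tmp <- withr::local_tempdir()
  cfg <- file.path(tmp, "scenario.yaml")
  writeLines(c(
    "output: field",
    "material: {model: maxwell, E1_Pa: 5.0e6, tau_s: 2}",
    "geometry: {r_mm: 10, e_mm: 1, L: 10, rho: 1000}",
    "pulse: {p_max: 1, T: 0.2}",
    "grid: {N: 128}"), cfg)
  man <- run_scenario(cfg, out_dir = file.path(tmp, "out"))
  dec <- jsonlite::read_json(file.path(tmp, "out", "decay.json"),
                             simplifyVector = TRUE)
  # c = 5 m/s for this card/geometry; underdamped tau_fit ~ 2 tau
  expect_equal(dec$tau_fit_s, 4, tolerance = 0.1)
})

test_that("scenario errors are raised for invalid configurations", {
  tmp <- withr::local_tempdir()
  cfg <- file.path(tmp, "bad.yaml")
  writeLines(c("output: spectrum",
               "material: {model: zener, E0_Pa: 1.0e6, E1_Pa: 1.0e6, tau_s: 0.1}",
               "geometry: {r_mm: -4, e_mm: 0.5, L: 1}"), cfg)
  expect_error(run_scenario(cfg, out_dir = tmp))
  cfg2 <- file.path(tmp, "bad2.yaml")
  writeLines("material: {model: zener}", cfg2)
  expect_error(run_scenario(cfg2, out_dir = tmp), "output")
})

test_that("repeated runs with the same seed give identical artifacts", {
  tmp <- withr::local_tempdir()
  cfg <- file.path(tmp, "syn.yaml")
  writeLines(c(
    "output: synthetic",
    "seed: 17",
    "material: {model: zener, E0_MPa: 2.114, E1_MPa: 0.9365, tau_s: 0.2611}",
    "protocol: {noise_sd: 0.02, duration: 2, sample_rate: 50}"), cfg)
  run_scenario(cfg, out_dir = file.path(tmp, "a"))
  run_scenario(cfg, out_dir = file.path(tmp, "b"))
  expect_identical(readLines(file.path(tmp, "a", "record.csv")),
                   readLines(file.path(tmp, "b", "record.csv")))
})

test_that("the command-line wrapper runs a scenario and rejects bad input", {
  tmp <- withr::local_tempdir()
  cli <- system.file("exec", "viscopulse", package = "viscopulse")
  if (cli == "") cli <- file.path(system.file(package = "viscopulse"),
                                  "exec", "viscopulse")
  expect_true(file.exists(cli))
  cfg <- file.path(tmp, "syn.yaml")
  writeLines(c(
    "output: synthetic",
    "seed: 2",
    "material: {model: zener, E0_MPa: 2.114, E1_MPa: 0.9365, tau_s: 0.2611}",
    "protocol: {duration: 1, sample_rate: 20}"), cfg)
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(cli, "make-synthetic", "--config", cfg,
                            "--out", file.path(tmp, "out")),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0L)
  expect_true(file.exists(file.path(tmp, "out", "record.csv")))
  bad <- suppressWarnings(
    system2(rscript, c(cli, "make-synthetic", "--config",
                       file.path(tmp, "missing.yaml")),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2L)
})
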