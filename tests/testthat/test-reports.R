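# End-to-end workflows, report generation and the CLI dispatcher.

test_that("identity workflow calls a synthetic AAV2 triplicate", {
  lib <- panel_library()
  runs <- simulate_triplicate("AAV2", noise_baseline = 20,
                              noise_cv = 0.03)
  rep <- run_identity(lapply(runs, `[[`, "spectra"), lib)
  expect_s3_class(rep, "identity_report")
  expect_equal(rep$call$serotype, "AAV2")
  expect_equal(nrow(rep$call$false_positive_flags), 0)
  expect_equal(length(rep$per_run_matches), 3)
  expect_true(all(c("identity", "deconvolution") %in% names(rep$params)))
})

test_that("empty runs produce a 'none' call with diagnostics, not an error", {
  lib <- panel_library()
  blank <- spectrum_set(list(list(rt = 15, mz = 1000, intensity = 0),
                             list(rt = 16, mz = 1000, intensity = 0)))
  rep <- run_identity(list(blank), lib)
  expect_equal(rep$call$serotype, "none")
  expect_match(rep$call$status, "no serotype")
})

test_that("PTM monitor reuses identity deconvolution and finds oxidation", {
  panel <- synthetic_serotype_panel()
  rt <- synthetic_rt_calibration()
  id_lib <- panel_library()
  specs <- data.frame(serotype = "AAV2", vp = c("VP1", "VP2", "VP3", "VP3"),
                      ptms = I(list(NULL, NULL, NULL, c(oxidation = 1))))
  ptm_lib <- build_component_library(panel["AAV2"], rt_calibration = rt,
                                     proteoform_specs = specs)
  comp <- data.frame(
    label = ptm_lib$label, mass = ptm_lib$theoretical_mass,
    rt_apex = c(21.0, 23.0, 16.5, 16.7), rt_sd = 0.12,
    abundance = c(1, 1, 8.4, 1.6), base_vp = ptm_lib$base_vp)
  runs <- lapply(1:3, function(i)
    simulate_run(simulation_config(comp, seed = 300 + i)))
  dec <- deconvolve_runs(lapply(runs, `[[`, "spectra"))
  id <- run_identity(dec, id_lib)
  expect_equal(id$call$serotype, "AAV2")
  ptm <- run_ptm_monitor(id$deconvolved, ptm_lib)
  expect_s3_class(ptm, "ptm_report")
  expect_equal(nrow(ptm$components), 4)
  ox <- ptm$components[grepl("1x Ox", ptm$components$label), ]
  # configured VP3-Ox share: 1.6 / (8.4 + 1.6) = 16%
  expect_equal(ox$pct_of_vp, 16, tolerance = 0.1)
  expect_s3_class(ptm$stoichiometry, "stoichiometry_result")
})

test_that("reports serialize deterministically with parameter snapshots", {
  lib <- panel_library()
  f <- structure(
    data.frame(neutral_mass = lib$theoretical_mass[1],
               rt_apex = lib$expected_rt[1], area = 100, score = 90,
               n_charge_states = 20L, n_intervals = 40L),
    class = c("deconvolved_features", "data.frame"))
  m <- match_components(f, lib)
  cons <- filter_replicates(list(m))
  call <- call_serotype(cons, lib)
  rep <- structure(list(call = call, consensus = cons,
                        per_run_matches = list(m),
                        params = list(identity = unclass(identity_params())),
                        version = "0.0.0"),
                   class = "identity_report")
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  generate_report(rep, p1)
  generate_report(rep, p2)
  expect_identical(readLines(p1), readLines(p2))
  parsed <- jsonlite::read_json(p1)
  expect_equal(parsed$tool, "capsidms")
  expect_true(!is.null(parsed$results$params$identity$mass_tol_ppm))
  # combined report carries both sections in CSV
  st <- stoichiometry_flr(list(c(VP1 = 1, VP2 = 1, VP3 = 10)))
  pc <- withr::local_tempfile(fileext = ".csv")
  generate_report(list(identity = rep, stoich = st), pc)
  tab <- read.csv(pc)
  expect_setequal(unique(tab$section), c("identity", "stoich"))
})

test_that("stoich and simulate CLI subcommands work end to end", {
  dir <- withr::local_tempdir()
  peaks <- do.call(rbind, lapply(1:3, function(r)
    data.frame(replicate = r, label = c("VP1", "VP2", "VP3"),
               area = c(1, 1, 10) * 1e6)))
  pfile <- file.path(dir, "peaks.csv")
  write.csv(peaks, pfile, row.names = FALSE)
  ofile <- file.path(dir, "stoich.csv")
  out <- capture.output(
    capsidms_main(c("stoich", "--method", "flr", "--peaks", pfile,
                    "--out", ofile)))
  tab <- read.csv(ofile)
  expect_equal(tab$copies[tab$label == "VP3"], 50)
  # simulate subcommand
  cfg <- list(components = list(label = "s", mass = 6e4, rt_apex = 16,
                                rt_sd = 0.1, abundance = 1),
              scan_interval = 0.5)
  cfile <- file.path(dir, "sim.json")
  jsonlite::write_json(cfg, cfile, auto_unbox = TRUE)
  capsidms_main(c("simulate", "--config", cfile, "--out-dir",
                  file.path(dir, "run1"), "--seed", "5"))
  expect_true(file.exists(file.path(dir, "run1", "spectra.csv")))
  expect_true(file.exists(file.path(dir, "run1", "manifest.json")))
})

test_that("identify CLI runs from files and writes a JSON report", {
  dir <- withr::local_tempdir()
  # serotype definition + library config
  panel <- synthetic_serotype_panel()
  defs_json <- lapply(panel["AAV2"], function(d)
    list(name = d$name, vp1_sequence = d$vp1_sequence,
         vp2_start = d$vp2_start, vp3_start = d$vp3_start,
         variant_starts = as.list(d$variant_starts)))
  jsonlite::write_json(unname(defs_json), file.path(dir, "defs.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(
    list(serotypes = "defs.json",
         rt_calibration = as.list(synthetic_rt_calibration())),
    file.path(dir, "lib.json"), auto_unbox = TRUE)
  runs <- simulate_triplicate("AAV2", seed_base = 400)
  run_files <- vapply(1:3, function(i) {
    p <- file.path(dir, sprintf("run%d.csv", i))
    write_spectrum_csv(runs[[i]]$spectra, p)
    p
  }, "")
  ofile <- file.path(dir, "report.json")
  out <- capture.output(
    capsidms_main(c("identify", "--runs", run_files, "--library",
                    file.path(dir, "lib.json"), "--out", ofile)))
  expect_match(paste(out, collapse = " "), "AAV2")
  parsed <- jsonlite::read_json(ofile)
  expect_equal(parsed$results$call$serotype, "AAV2")
})
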