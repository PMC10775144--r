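test_that("derive_vp_sequences returns suffixes of the mature chain", {
  d <- toy_definition()  # translated MAVSTGAPML, mature AVSTGAPML
  ch <- derive_vp_sequences(d)
  expect_equal(ch$VP1, "MAVSTGAPML")
  expect_equal(ch$VP2, "STGAPML")
  expect_equal(ch$VP3, "GAPML")
  expect_equal(nchar(ch$VP1), 10)
  mature <- substring(ch$VP1, 2)
  # suffix property at fixed offsets
  expect_equal(substring(mature, d$vp2_start), ch$VP2)
  expect_equal(substring(mature, d$vp3_start), ch$VP3)
})

test_that("the synthetic AAV2 VP3 starts with the ATGSGAPM stretch", {
  panel <- synthetic_serotype_panel()
  ch <- derive_vp_sequences(panel$AAV2)
  expect_true(startsWith(ch$VP3, "ATGSGAPM"))
  expect_named(ch, c("VP1", "VP2", "VP3", "A211-VP3"))
  mature <- substring(ch$VP1, 2)
  expect_equal(substring(mature, 211), ch[["A211-VP3"]])
})

test_that("vp2_start = 1 yields VP2 identical to mature VP1", {
  d <- serotype_definition("T2", "MAVSTGAPML", vp2_start = 1, vp3_start = 5)
  ch <- derive_vp_sequences(d)
  expect_equal(ch$VP2, substring(d$vp1_sequence, 2))
})

test_that("definition invariants are enforced", {
  expect_error(serotype_definition("X", "MAVSTG", 3, 99), "beyond")
  expect_error(serotype_definition("X", "MAVSTG", 4, 3), "vp2_start")
  expect_error(serotype_definition("X", "MAVBTG", 2, 3), "non-canonical")
})

test_that("N-terminal processing follows the small-residue rule", {
  r <- apply_nterm_processing("MAADGYLPDWLED")
  expect_equal(substr(r$sequence, 1, 3), "AAD")
  expect_true(r$acetyl)
  r3 <- apply_nterm_processing("MATGSGAPM")
  expect_equal(r3$sequence, "ATGSGAPM")
  expect_true(r3$acetyl)
  # bulky position 2: rule does not fire
  rw <- apply_nterm_processing("MWDDD")
  expect_equal(rw$sequence, "MWDDD")
  expect_false(rw$acetyl)
  expect_error(apply_nterm_processing(""), "empty")
})

test_that("processing is idempotent and rule flags are honoured", {
  once <- apply_nterm_processing("MAVSTG")
  twice <- apply_nterm_processing(once$sequence)
  expect_equal(once$sequence, twice$sequence)
  # cleave without acetylate
  r <- apply_nterm_processing("MAVSTG", rule = "cleave_met")
  expect_equal(r$sequence, "AVSTG")
  expect_false(r$acetyl)
  # forced acetylation of a non-Met chain
  r2 <- apply_nterm_processing("AVSTG", force_acetyl = TRUE)
  expect_true(r2$acetyl)
})

test_that("component library has unique labels and ordered masses", {
  lib <- panel_library()
  # 4 serotypes x 3 VPs + 1 variant
  expect_equal(nrow(lib), 13)
  for (st in unique(lib$serotype)) {
    sub <- lib[lib$serotype == st, ]
    expect_false(anyDuplicated(sub$label) > 0)
    m <- function(vp) sub$theoretical_mass[sub$base_vp == vp]
    expect_gt(m("VP1"), m("VP2"))
    expect_gt(m("VP2"), m("VP3"))
  }
  # variant lighter than its VP3
  aav2 <- lib[lib$serotype == "AAV2", ]
  expect_lt(aav2$theoretical_mass[aav2$base_vp == "A211-VP3"],
            aav2$theoretical_mass[aav2$base_vp == "VP3"])
  # RT window defaults: VP3-like 1.00, VP1/VP2 0.60
  expect_true(all(lib$rt_window[lib$base_vp %in% c("VP1", "VP2")] == 0.60))
  expect_true(all(lib$rt_window[!lib$base_vp %in% c("VP1", "VP2")] == 1.00))
})

test_that("library masses equal processed-chain masses plus PTM deltas", {
  # independent oracle: recompute one component by hand
  panel <- synthetic_serotype_panel()
  d <- panel$AAV2
  ch <- derive_vp_sequences(d)
  lib <- panel_library()
  vp3 <- lib[lib$serotype == "AAV2" & lib$base_vp == "VP3", ]
  expect_equal(vp3$theoretical_mass,
               average_mass(ch$VP3, nterm_acetyl = TRUE), tolerance = 1e-9)
  vp2 <- lib[lib$serotype == "AAV2" & lib$base_vp == "VP2", ]
  expect_equal(vp2$theoretical_mass, average_mass(ch$VP2),
               tolerance = 1e-9)  # VP2: no Met start, no acetyl
  vp1 <- lib[lib$serotype == "AAV2" & lib$base_vp == "VP1", ]
  mature <- substring(ch$VP1, 2)
  expect_equal(vp1$theoretical_mass,
               average_mass(mature, nterm_acetyl = TRUE), tolerance = 1e-9)
})

test_that("modified proteoform specs and errors", {
  panel <- synthetic_serotype_panel()
  specs <- data.frame(serotype = "AAV2", vp = c("VP3", "VP3"),
                      ptms = I(list(NULL, c(oxidation = 1))))
  lib <- build_component_library(panel["AAV2"],
                                 rt_calibration = synthetic_rt_calibration(),
                                 proteoform_specs = specs)
  expect_equal(nrow(lib), 2)
  expect_equal(diff(lib$theoretical_mass), 15.999, tolerance = 1e-9)
  expect_match(lib$label[2], "1x Ox")
  bad <- data.frame(serotype = "AAV2", vp = "VP3",
                    ptms = I(list(c(glycation = 1))))
  expect_error(build_component_library(
    panel["AAV2"], rt_calibration = synthetic_rt_calibration(),
    proteoform_specs = bad), "glycation")
  empty <- build_component_library(
    panel["AAV2"], rt_calibration = synthetic_rt_calibration(),
    proteoform_specs = data.frame(serotype = character(),
                                  vp = character()))
  expect_equal(nrow(empty), 0)
})

test_that("serotype definitions round-trip through JSON config", {
  d <- toy_definition()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(
    name = d$name, vp1_sequence = d$vp1_sequence,
    vp2_start = d$vp2_start, vp3_start = d$vp3_start,
    variant_starts = d$variant_starts, nterm_rule = d$nterm_rule)),
    path, auto_unbox = TRUE)
  defs <- read_serotype_definitions(path)
  expect_length(defs, 1)
  expect_equal(defs[[1]]$vp1_sequence, d$vp1_sequence)
  expect_equal(defs[[1]]$vp3_start, d$vp3_start)
})
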