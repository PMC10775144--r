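# Peptide-record filtering, relative PTM abundance, mobile protons,
# sequence coverage.

test_that("filter_peptides applies every threshold and flag exclusion", {
  recs <- rbind(
    pep_record(confidence = 100, ms_area = 2e5, mass_error_ppm = 3),  # keep
    pep_record(confidence = 96, ms_area = 9e4, mass_error_ppm = 2),   # area
    pep_record(confidence = 94.9, ms_area = 2e5),                     # conf
    pep_record(mass_error_ppm = -5.5),                                # ppm
    pep_record(flags = "adduct"),                                     # flag
    pep_record(flags = "gas_phase_ion;nonspecific"))                  # flags
  kept <- filter_peptides(recs)
  expect_equal(nrow(kept), 1)
  # boundary values are inclusive
  edge <- pep_record(confidence = 95, ms_area = 1e5, mass_error_ppm = 5)
  expect_equal(nrow(filter_peptides(edge)), 1)
  # toy table of 6 with 2 violating one threshold each -> 4 survive
  six <- rbind(pep_record(), pep_record(), pep_record(), pep_record(),
               pep_record(confidence = 50), pep_record(ms_area = 10))
  expect_equal(nrow(filter_peptides(six)), 4)
})

test_that("filter_peptides is idempotent and order-independent", {
  set.seed(9)
  recs <- do.call(rbind, lapply(1:20, function(i)
    pep_record(confidence = runif(1, 90, 100),
               ms_area = 10^runif(1, 4, 6),
               mass_error_ppm = runif(1, -8, 8),
               flags = sample(c("", "adduct"), 1, prob = c(0.8, 0.2)))))
  once <- filter_peptides(recs)
  expect_equal(filter_peptides(once), once)
  shuffled <- recs[sample(nrow(recs)), ]
  resorted <- filter_peptides(shuffled)
  expect_setequal(
    do.call(paste, c(resorted[c("confidence", "ms_area")], sep = "_")),
    do.call(paste, c(once[c("confidence", "ms_area")], sep = "_")))
})

test_that("relative_abundance computes per-replicate percentages", {
  # modified area 25, unmodified 75, one replicate -> 25%
  recs <- rbind(
    pep_record(sequence = "QDRDVYLQGPIW", start = 606, end = 617,
               modification = "NH3 loss", site = "Q606", ms_area = 25),
    pep_record(sequence = "QDRDVYLQGPIW", start = 606, end = 617,
               ms_area = 75))
  q <- relative_abundance(recs, "Q606", "NH3 loss")
  expect_equal(q$mean, 25)
  expect_equal(q$sd, 0)
  expect_equal(q$top_peptide, "QDRDVYLQGPIW")
  # all forms modified -> 100%
  all_mod <- pep_record(sequence = "AADGYLPDWLED", start = 1, end = 12,
                        modification = "acetylation", site = "A1",
                        ms_area = 5e5)
  expect_equal(relative_abundance(all_mod, "A1", "acetylation")$mean, 100)
  # no modified forms -> 0%
  expect_equal(relative_abundance(
    pep_record(start = 50, end = 54), "N52", "deamidation")$mean, 0)
  # uncovered site -> explicit no-coverage result
  out <- relative_abundance(pep_record(start = 1, end = 5), "N700",
                            "deamidation")
  expect_false(out$covered)
  expect_true(is.na(out$mean))
})

test_that("abundances over modification states sum to 100% per replicate", {
  set.seed(12)
  for (i in 1:5) {
    a <- runif(3)
    recs <- rbind(
      pep_record(sequence = "ADNGAMKYETF", start = 10, end = 20,
                 modification = "oxidation", site = "M15",
                 ms_area = a[1]),
      pep_record(sequence = "ADNGAMKYETF", start = 10, end = 20,
                 modification = "deamidation", site = "N12",
                 ms_area = a[2]),
      pep_record(sequence = "ADNGAMKYETF", start = 10, end = 20,
                 ms_area = a[3]))
    tot <- relative_abundance(recs, "M15", "oxidation")$mean +
      relative_abundance(recs, "N12", "deamidation")$mean +
      100 * a[3] / sum(a)  # unmodified share
    expect_equal(tot, 100, tolerance = 1e-9)
  }
})

test_that("mobile_protons reproduces the published six-row table", {
  rows <- list(
    list("QERLKEDTSFGGNLGRAVF", 3, 0),
    list("QERLKEDTSF", 2, 0),
    list("QAKKRVLEPLGL", 3, 0),
    list("QAKKRVLEPLGL", 2, 0),
    list("QDRDVYLQGPIW", 2, 1),
    list("QDRDVYL", 2, 1))
  for (r in rows)
    expect_equal(mobile_protons(r[[1]], r[[2]]), r[[3]],
                 label = paste(r[[1]], "z", r[[2]]))
  expect_equal(mobile_protons("AAAA", 1), 1)
})

test_that("mobile_protons agrees with a brute-force residue scan", {
  set.seed(5)
  letters20 <- names(residue_masses()$avg)
  for (i in 1:25) {
    pep <- paste(sample(letters20, sample(5:25, 1), TRUE), collapse = "")
    z <- sample(1:5, 1)
    basic <- sum(vapply(strsplit(pep, "")[[1]],
                        function(r) r %in% c("R", "K", "H"), logical(1)))
    expect_equal(mobile_protons(pep, z), max(0L, z - basic))
  }
})

test_that("sequence_coverage counts residues once and validates bounds", {
  seq10 <- "AAAAAAAAAA"
  expect_equal(sequence_coverage(pep_record(sequence = "AAAAA", start = 1),
                                 seq10), 50)
  # overlapping records: union, not sum
  recs <- rbind(pep_record(sequence = "AAAAA", start = 1),
                pep_record(sequence = "AAAAA", start = 3, end = 7))
  expect_equal(sequence_coverage(recs, seq10), 70)
  # full tiling -> 100
  tiles <- rbind(pep_record(sequence = "AAAAA", start = 1),
                 pep_record(sequence = "AAAAA", start = 6, end = 10))
  expect_equal(sequence_coverage(tiles, seq10), 100)
  expect_error(sequence_coverage(
    pep_record(sequence = "AAAAA", start = 8, end = 12), seq10), "outside")
})

test_that("ptm_site_table reports sites above the floor, sorted", {
  recs <- rbind(
    pep_record(sequence = "AADGYLPDWL", start = 1, end = 10,
               modification = "acetylation", site = "A1", ms_area = 99),
    pep_record(sequence = "AADGYLPDWL", start = 1, end = 10, ms_area = 1),
    pep_record(sequence = "KVMITDEEIRT", start = 20, end = 30,
               modification = "oxidation", site = "M25", ms_area = 0.5),
    pep_record(sequence = "KVMITDEEIRT", start = 20, end = 30,
               ms_area = 99.5))
  tab <- ptm_site_table(recs)
  expect_equal(tab$site, "A1")  # M25 at 0.5% falls below the 1% floor
  expect_equal(tab$mean_abundance, 99)
  tab2 <- ptm_site_table(recs, min_abundance = 0)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$site[1], "A1")
})

test_that("records CSV round trips through read_peptide_records", {
  recs <- rbind(pep_record(site = "Q606", modification = "NH3 loss"),
                pep_record(flags = "adduct"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(recs, path, row.names = FALSE)
  back <- read_peptide_records(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$flags, c("", "adduct"))
  expect_equal(back$modification[1], "NH3 loss")
})
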