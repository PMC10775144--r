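# Shared fixtures.  Everything is generated in code under fixed seeds;
# expensive objects are built once per test session and cached here.

toy_definition <- function() {
  # 10-residue translated chain incl. Met; mature = "AVSTGAPML" (9 aa)
  serotype_definition("TOY", "MAVSTGAPML", vp2_start = 3, vp3_start = 5)
}

panel_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      panel <- synthetic_serotype_panel()
      cache <<- build_component_library(
        panel, rt_calibration = synthetic_rt_calibration())
    }
    cache
  }
})

# One simulated triplicate of a serotype: same species, different seeds.
simulate_triplicate <- function(serotype, seed_base = 100,
                                noise_baseline = 0, noise_cv = 0,
                                abundance = NULL, scan_interval = 0.05) {
  lib <- panel_library()
  comp <- lib[lib$serotype == serotype &
                lib$base_vp %in% c("VP1", "VP2", "VP3"), ]
  comp <- comp[match(c("VP1", "VP2", "VP3"), comp$base_vp), ]
  if (is.null(abundance)) abundance <- c(1, 1, 10)
  lapply(1:3, function(i) {
    simulate_run(simulation_config(
      data.frame(label = comp$label, mass = comp$theoretical_mass,
                 rt_apex = comp$expected_rt, rt_sd = 0.12,
                 abundance = abundance, base_vp = comp$base_vp,
                 stringsAsFactors = FALSE),
      scan_interval = scan_interval,
      noise_baseline = noise_baseline, noise_cv = noise_cv,
      seed = seed_base + i))
  })
}

# Minimal peptide record constructor with sensible defaults.
pep_record <- function(replicate = 1, sequence = "AAAAA", start = 1,
                       end = start + nchar(sequence) - 1,
                       modification = "none", site = "",
                       confidence = 100, ms_area = 2e5,
                       mass_error_ppm = 1, charge = 2, flags = "") {
  data.frame(replicate = replicate, sequence = sequence, start = start,
             end = end, modification = modification, site = site,
             confidence = confidence, ms_area = ms_area,
             mass_error_ppm = mass_error_ppm, charge = charge,
             flags = flags, stringsAsFactors = FALSE)
}
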