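# Seeded simulator for HILIC-FLR-MS capsid runs and peptide-mapping
# tables, with ground-truth manifests.  All randomness is driven by the
# config seed through R's default generator; the ambient RNG state is
# saved and restored, so simulation never perturbs a caller's stream.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else .GlobalEnv$.Random.seed <- old
  })
  set.seed(seed)
  expr
}

#' Simulation configuration for a synthetic HILIC-FLR-MS run
#'
#' @param components data.frame with one row per proteoform: `label`,
#'   `mass` (Da), `rt_apex` (min, inside `rt_limits`), `rt_sd` (Gaussian
#'   chromatographic width, min), `abundance` (relative, > 0) and
#'   optionally `base_vp`.
#' @param charge_center,charge_sd Gaussian charge-envelope centre and
#'   spread (default centred on charge 35).
#' @param scan_range m/z acquisition window, default `c(867, 2400)`.
#' @param scan_interval minutes between MS1 scans.
#' @param rt_limits simulated run window, default `c(13, 28.5)` min.
#' @param noise_baseline additive baseline stick intensity (0 = off).
#' @param noise_cv multiplicative intensity jitter CV (0 = off).
#' @param ms_scale,flr_scale intensity scale factors.
#' @param seed integer RNG seed; the same seed reproduces the run
#'   bit-identically.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(components,
                              charge_center = 35, charge_sd = 4,
                              scan_range = c(867, 2400),
                              scan_interval = 0.05,
                              rt_limits = c(13, 28.5),
                              noise_baseline = 0, noise_cv = 0,
                              ms_scale = 1e6, flr_scale = 1e6,
                              seed = 1L) {
  stopifnot(is.data.frame(components),
            all(c("label", "mass", "rt_apex", "rt_sd", "abundance") %in%
                  names(components)),
            all(components$abundance > 0),
            all(components$rt_apex >= rt_limits[1] &
                  components$rt_apex <= rt_limits[2]))
  structure(list(components = components, charge_center = charge_center,
                 charge_sd = charge_sd, scan_range = scan_range,
                 scan_interval = scan_interval, rt_limits = rt_limits,
                 noise_baseline = noise_baseline, noise_cv = noise_cv,
                 ms_scale = ms_scale, flr_scale = flr_scale,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate one HILIC-FLR-MS run
#'
#' Each proteoform contributes a Gaussian elution profile and a Gaussian
#' multi-charge ESI envelope at `m/z = (M + z * 1.00728) / z`, clipped to
#' the scan range (centroid-style stick spectra). The FLR trace is the
#' abundance-weighted sum of the elution profiles, scaled so each
#' species' FLR peak area equals `abundance * flr_scale`. Optional noise
#' adds baseline sticks at random m/z and multiplicative intensity
#' jitter.
#'
#' @param cfg a [simulation_config()].
#' @return list with `spectra` (a [spectrum_set()]), `flr` (a
#'   [chromatogram()]) and `manifest` (ground truth: per-species mass, RT
#'   apex, FLR area, charge states used, plus the seed).
#' @export
simulate_run <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, {
    proton <- 1.00728
    comp <- cfg$components
    rts <- seq(cfg$rt_limits[1], cfg$rt_limits[2], by = cfg$scan_interval)
    # per-species charge envelope
    envs <- lapply(seq_len(nrow(comp)), function(i) {
      z <- seq.int(max(1L, floor(cfg$charge_center - 4 * cfg$charge_sd)),
                   ceiling(cfg$charge_center + 4 * cfg$charge_sd))
      mz <- (comp$mass[i] + z * proton) / z
      keep <- mz >= cfg$scan_range[1] & mz <= cfg$scan_range[2]
      z <- z[keep]; mz <- mz[keep]
      if (!length(z))
        stop("component '", comp$label[i],
             "' has no charge state inside the scan range")
      w <- stats::dnorm(z, cfg$charge_center, cfg$charge_sd)
      list(z = z, mz = mz, w = w / sum(w))
    })
    scans <- vector("list", length(rts))
    for (k in seq_along(rts)) {
      mz_all <- numeric(); int_all <- numeric()
      for (i in seq_len(nrow(comp))) {
        elut <- stats::dnorm(rts[k], comp$rt_apex[i], comp$rt_sd[i])
        if (elut < 1e-12) next
        e <- envs[[i]]
        inten <- comp$abundance[i] * cfg$ms_scale * elut * e$w
        mz_all <- c(mz_all, e$mz)
        int_all <- c(int_all, inten)
      }
      if (cfg$noise_baseline > 0) {
        n_noise <- 30L
        mz_all <- c(mz_all, stats::runif(n_noise, cfg$scan_range[1],
                                         cfg$scan_range[2]))
        int_all <- c(int_all,
                     cfg$noise_baseline * stats::rexp(n_noise))
      }
      if (cfg$noise_cv > 0 && length(int_all))
        int_all <- int_all *
          pmax(0, 1 + stats::rnorm(length(int_all), 0, cfg$noise_cv))
      o <- order(mz_all)
      scans[[k]] <- list(rt = rts[k], mz = mz_all[o], intensity = int_all[o])
    }
    # FLR: abundance-weighted Gaussian sum; area per species =
    # abundance * flr_scale by construction
    flr <- rep(0, length(rts))
    for (i in seq_len(nrow(comp)))
      flr <- flr + comp$abundance[i] * cfg$flr_scale *
        stats::dnorm(rts, comp$rt_apex[i], comp$rt_sd[i])
    manifest <- list(
      seed = cfg$seed,
      species = data.frame(
        label = comp$label, mass = comp$mass, rt_apex = comp$rt_apex,
        abundance = comp$abundance,
        flr_area = comp$abundance * cfg$flr_scale,
        n_charge_states = vapply(envs, function(e) length(e$z),
                                 integer(1)),
        stringsAsFactors = FALSE))
    list(spectra = spectrum_set(scans, metadata = list(
           scan_range = cfg$scan_range, simulated = TRUE)),
         flr = chromatogram(rts, flr, channel = "FLR"),
         manifest = manifest)
  })
}

#' Write a simulated run to disk
#'
#' Emits the MS1 data (`spectra.mzML` or `spectra.csv`), the FLR trace
#' (`flr.csv`) and the ground-truth manifest (`manifest.json`).
#'
#' @param run result of [simulate_run()].
#' @param out_dir output directory (created if needed).
#' @param spectra_format `"csv-table"` (default) or `"mzML"`.
#' @return invisibly, the paths written.
#' @export
write_simulated_run <- function(run, out_dir,
                                spectra_format = c("csv-table", "mzML")) {
  spectra_format <- match.arg(spectra_format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- if (spectra_format == "mzML") {
    p <- file.path(out_dir, "spectra.mzML"); write_mzml(run$spectra, p); p
  } else {
    p <- file.path(out_dir, "spectra.csv")
    write_spectrum_csv(run$spectra, p); p
  }
  fl <- file.path(out_dir, "flr.csv")
  write_chromatogram_csv(run$flr, fl)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(run$manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(spectra = sp, flr = fl, manifest = mf))
}

#' Simulate a peptide-mapping record table
#'
#' Tiles the protein with contiguous peptides; peptides covering a target
#' site are split into a modified and an unmodified record with the area
#' fraction drawn around the configured true abundance; all other
#' peptides yield one unmodified record. Optionally flags a fixed number
#' of records (adduct flag) to exercise the record filter.
#'
#' @param sequence protein sequence in mature numbering.
#' @param sites data.frame with columns `site` (e.g. `"N56"`),
#'   `modification` and `abundance` (true percent, 0-100); may be empty.
#' @param n_replicates number of replicate files, default 3.
#' @param seed RNG seed.
#' @param peptide_length tile length, default 20 residues.
#' @param base_area mean unsplit peptide MS area, default 1e7 (abundant
#'   peptide scale; forms whose split area falls below the record filter
#'   floor are censored, as on real data).
#' @param noise_sd_pct replicate-to-replicate SD on the modified
#'   percentage, default 0 (exact recovery).
#' @param n_flagged number of records to stamp with an `adduct` flag.
#' @return peptide-record data.frame (see [filter_peptides()]).
#' @export
simulate_peptide_table <- function(sequence, sites = NULL,
                                   n_replicates = 3, seed = 1L,
                                   peptide_length = 20, base_area = 1e7,
                                   noise_sd_pct = 0, n_flagged = 0L) {
  if (!is.null(sites) && nrow(sites))
    stopifnot(all(sites$abundance >= 0 & sites$abundance <= 100))
  .with_seed(seed, {
    n <- nchar(sequence)
    starts <- seq(1L, n, by = peptide_length)
    ends <- pmin(starts + peptide_length - 1L, n)
    rows <- list()
    add <- function(rep, s, e, mod, site, area) {
      pep <- substring(sequence, s, e)
      basics <- sum(strsplit(pep, "")[[1]] %in% c("R", "K", "H"))
      rows[[length(rows) + 1L]] <<- data.frame(
        replicate = rep, sequence = pep, start = s, end = e,
        modification = mod, site = site,
        confidence = 100 - stats::runif(1, 0, 2),
        ms_area = area,
        mass_error_ppm = stats::rnorm(1, 0, 1),
        charge = max(1L, basics + sample(0:1, 1)),
        flags = "", stringsAsFactors = FALSE)
    }
    for (rep in seq_len(n_replicates)) {
      for (i in seq_along(starts)) {
        s <- starts[i]; e <- ends[i]
        covered <- if (is.null(sites) || !nrow(sites)) integer(0) else
          which(.site_position(sites$site) >= s &
                  .site_position(sites$site) <= e)
        if (!length(covered)) {
          add(rep, s, e, "none", "", base_area)
        } else {
          j <- covered[1]  # one target site per tile by construction
          frac <- sites$abundance[j] / 100
          if (noise_sd_pct > 0)
            frac <- min(1, max(0, frac +
                                 stats::rnorm(1, 0, noise_sd_pct / 100)))
          if (frac > 0)
            add(rep, s, e, sites$modification[j], sites$site[j],
                base_area * frac)
          if (frac < 1)
            add(rep, s, e, "none", "", base_area * (1 - frac))
        }
      }
    }
    out <- do.call(rbind, rows)
    if (n_flagged > 0L) {
      idx <- sample(nrow(out), min(n_flagged, nrow(out)))
      out$flags[idx] <- "adduct"
    }
    rownames(out) <- NULL
    out
  })
}

#' Synthetic four-serotype definition panel
#'
#' Deterministically generated stand-in serotype definitions named after
#' AAV2/AAV5/AAV8/AAV9. The sequences are synthetic (random draws from a
#' capsid-like residue composition under a fixed internal seed), not the
#' real capsid sequences; they reproduce the structural layout of the
#' real serotypes — VP2 and VP3 as C-terminal sub-sequences of VP1,
#' Met-initiated VP1/VP3/variant chains with small position-2 residues,
#' an ACG-initiated (Thr) VP2, and for the AAV2-like entry the
#' `ATGSGAPM` VP3 N-terminal stretch with an A211 variant start — so
#' every pipeline stage behaves as it would on real definitions. VP
#' masses differ between the panel members by far more than any matching
#' tolerance.
#'
#' @return named list of [serotype_definition()] objects.
#' @export
synthetic_serotype_panel <- function() {
  specs <- list(
    AAV2 = list(len = 734, vp2 = 138, vp3 = 203, var = 211L, seed = 101),
    AAV5 = list(len = 723, vp2 = 137, vp3 = 193, var = integer(), seed = 102),
    AAV8 = list(len = 737, vp2 = 138, vp3 = 204, var = integer(), seed = 103),
    AAV9 = list(len = 735, vp2 = 138, vp3 = 203, var = integer(), seed = 104))
  # residue pool loosely matching capsid composition (no C to avoid
  # disulfide bookkeeping in toys)
  pool <- strsplit("AAGGSSTTNNQQDDEEPPVVLLIIFFYYWHKRM", "")[[1]]
  out <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    .with_seed(sp$seed, {
      mature <- sample(pool, sp$len, replace = TRUE)
      mature[1] <- "A"                      # acetylated after Met excision
      mature[sp$vp2 - 1L] <- "E"            # VP2: no upstream Met, Thr start
      mature[sp$vp2] <- "T"
      mature[sp$vp3 - 1L] <- "M"            # VP3 initiator Met
      mature[sp$vp3] <- "A"
      if (nm == "AAV2") {
        mature[203:210] <- strsplit("ATGSGAPM", "")[[1]]  # 210 = variant Met
        mature[211] <- "A"
      }
      serotype_definition(
        name = nm,
        vp1_sequence = paste(c("M", mature), collapse = ""),
        vp2_start = sp$vp2, vp3_start = sp$vp3,
        variant_starts = sp$var)
    })
  })
  names(out) <- names(specs)
  out
}

#' Default RT calibration for the synthetic panel
#'
#' Apex retention times (minutes) emulating the elution order seen on
#' HILIC capsid separations — VP3 first, then VP1, then VP2 — with the
#' VP3 variant under the VP3 peak region.
#'
#' @return named numeric vector usable as `rt_calibration` in
#'   [build_component_library()].
#' @export
synthetic_rt_calibration <- function() {
  c(VP3 = 16.5, `A211-VP3` = 16.2, VP1 = 21.0, VP2 = 23.0)
}
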