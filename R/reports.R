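# User-facing workflows: rapid identity testing, serotype-specific PTM
# monitoring, and deterministic report generation.  Both workflows share
# one deconvolution pass per run; only the component target list differs
# (identity = unmodified VPs of every serotype; PTM monitoring = modified
# proteoforms of one serotype), so a sample screened by identity testing
# is reprocessed without re-deconvolution.

.as_spectrum_sets <- function(runs, rt_limits) {
  lapply(runs, function(r) {
    if (inherits(r, "spectrum_set")) r
    else read_spectra(r, rt_limits = rt_limits)
  })
}

#' Deconvolve a set of replicate runs once
#'
#' @param runs list of `spectrum_set` objects or file paths.
#' @param dparams a [deconvolution_params()].
#' @return list of class `deconvolved_runs`: `features` (list of
#'   `deconvolved_features`, one per run), `spectra` (the spectrum sets),
#'   `params`.
#' @export
deconvolve_runs <- function(runs, dparams = deconvolution_params()) {
  spectra <- .as_spectrum_sets(runs, dparams$rt_limits)
  features <- lapply(spectra, deconvolve, p = dparams)
  structure(list(features = features, spectra = spectra,
                 params = dparams),
            class = "deconvolved_runs")
}

#' Run the rapid identity-testing workflow
#'
#' read -> deconvolve -> match against a multi-serotype library of
#' unmodified VPs -> replicate-consensus filter -> serotype call.
#'
#' @param runs list of `spectrum_set` objects or file paths (replicate
#'   injections of one sample), or a prepared [deconvolve_runs()] result.
#' @param lib multi-serotype [build_component_library()] of unmodified
#'   VPs.
#' @param iparams an [identity_params()].
#' @param dparams a [deconvolution_params()] (ignored when `runs` is
#'   already deconvolved).
#' @return list of class `identity_report`: `call` (an `identity_call`),
#'   `consensus`, `per_run_matches`, `deconvolved` (reusable cache),
#'   `params` (full parameter snapshot), `version`.
#' @export
run_identity <- function(runs, lib, iparams = identity_params(),
                         dparams = deconvolution_params()) {
  dec <- if (inherits(runs, "deconvolved_runs")) runs
         else deconvolve_runs(runs, dparams)
  matches <- lapply(seq_along(dec$features), function(i)
    match_components(dec$features[[i]], lib, iparams, replicate = i))
  consensus <- filter_replicates(matches, iparams)
  call <- call_serotype(consensus, lib)
  structure(list(call = call, consensus = consensus,
                 per_run_matches = matches, deconvolved = dec,
                 params = list(identity = unclass(iparams),
                               deconvolution = unclass(dec$params)),
                 version = .pkg_version()),
            class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  print(x$call)
  invisible(x)
}

#' Run the serotype-specific PTM-monitoring workflow
#'
#' Matches a serotype's modified-proteoform component list against the
#' same deconvolved features used for identity testing (no
#' re-deconvolution), reports per-component masses, ppm errors and XIC
#' areas, and the relative abundance of each proteoform within its VP
#' (percent of the VP's summed XIC area).
#'
#' @param runs runs or a [deconvolve_runs()] cache (e.g.
#'   `identity_report$deconvolved`).
#' @param ptm_lib serotype-specific component library including modified
#'   proteoforms.
#' @param iparams an [identity_params()].
#' @param dparams a [deconvolution_params()].
#' @param site_quant optional [ptm_site_table()] result merged into the
#'   report.
#' @param charges charge states used for XIC extraction.
#' @return list of class `ptm_report`: `components` (per-component
#'   consensus with mean XIC area and relative abundance within VP),
#'   `per_run_matches`, `stoichiometry` (MS-method result over the
#'   matched proteoforms), `peptide_sites`, `params`, `version`.
#' @export
run_ptm_monitor <- function(runs, ptm_lib, iparams = identity_params(),
                            dparams = deconvolution_params(),
                            site_quant = NULL, charges = 25:50) {
  dec <- if (inherits(runs, "deconvolved_runs")) runs
         else deconvolve_runs(runs, dparams)
  matches <- lapply(seq_along(dec$features), function(i) {
    m <- match_components(dec$features[[i]], ptm_lib, iparams,
                          replicate = i)
    # XIC area at the component's theoretical mass, within its RT window
    if (nrow(m)) {
      m$xic_area <- vapply(seq_len(nrow(m)), function(j) {
        comp <- ptm_lib[ptm_lib$label == m$label[j], ]
        x <- extract_xic(dec$spectra[[i]], comp$theoretical_mass[1],
                         charges, tol_ppm = iparams$mass_tol_ppm)
        trace_integral(x, rt_window = comp$expected_rt[1] +
                         c(-1, 1) * comp$rt_window[1])
      }, numeric(1))
    } else m$xic_area <- numeric(0)
    m
  })
  consensus <- filter_replicates(matches, iparams)
  all_m <- do.call(rbind, matches)
  if (nrow(consensus)) {
    consensus$mean_xic_area <- vapply(consensus$label, function(l)
      mean(all_m$xic_area[all_m$label == l]), numeric(1))
    # relative proteoform abundance within each VP
    vp_tot <- tapply(consensus$mean_xic_area, consensus$base_vp, sum)
    consensus$pct_of_vp <- round(
      100 * consensus$mean_xic_area / vp_tot[consensus$base_vp], 2)
  } else {
    consensus$mean_xic_area <- numeric(0)
    consensus$pct_of_vp <- numeric(0)
  }
  stoich <- if (nrow(all_m)) {
    keep <- all_m[all_m$label %in% consensus$label, , drop = FALSE]
    if (nrow(keep))
      stoichiometry_ms(data.frame(replicate = keep$replicate,
                                  base_vp = keep$base_vp,
                                  area = keep$xic_area))
  }
  structure(list(components = consensus, per_run_matches = matches,
                 stoichiometry = stoich, peptide_sites = site_quant,
                 params = list(identity = unclass(iparams),
                               deconvolution = unclass(dec$params),
                               xic_charges = charges),
                 version = .pkg_version()),
            class = "ptm_report")
}

#' @export
print.ptm_report <- function(x, ...) {
  cat(sprintf("PTM monitoring report: %d consensus proteoform(s)\n",
              nrow(x$components)))
  if (nrow(x$components)) {
    show <- x$components
    show$mean_mass_error_ppm <- round(show$mean_mass_error_ppm, 1)
    print(show[, c("label", "base_vp", "mean_mass_error_ppm",
                   "mean_xic_area", "pct_of_vp")], row.names = FALSE)
  }
  invisible(x)
}

.pkg_version <- function() {
  as.character(utils::packageVersion("capsidms"))
}

.serialize_results <- function(results) {
  strip <- function(x) {
    if (is.data.frame(x)) {
      x <- as.data.frame(x)
      x$ptms <- NULL
      return(x)
    }
    if (is.list(x)) {
      x <- unclass(x)
      x <- x[!vapply(x, is.function, logical(1))]
      # deterministic key order
      if (!is.null(names(x)) && all(nzchar(names(x))))
        x <- x[order(names(x))]
      return(lapply(x, strip))
    }
    x
  }
  strip(results)
}

#' Write a deterministic analysis report
#'
#' Serializes workflow results (identity, PTM monitoring, stoichiometry,
#' or a named list combining several) with stable key order so identical
#' results yield byte-identical files. JSON carries the full nested
#' structure including the parameter snapshot and tool version; CSV
#' carries the main tabular section of each result.
#'
#' @param results an `identity_report`, `ptm_report`,
#'   `stoichiometry_result`, or named list of them.
#' @param path output file; format from extension unless given.
#' @param format `"json"` or `"csv"`.
#' @return invisibly, `path`.
#' @export
generate_report <- function(results, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "json"
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    payload <- list(tool = "capsidms", version = .pkg_version(),
                    results = .serialize_results(results))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null", pretty = TRUE)
  } else {
    tab <- .main_table(results)
    utils::write.csv(tab, path, row.names = FALSE)
  }
  invisible(path)
}

.main_table <- function(results) {
  if (inherits(results, "identity_report")) {
    out <- results$consensus
    out$serotype_call <- results$call$serotype
    return(out)
  }
  if (inherits(results, "ptm_report")) return(results$components)
  if (inherits(results, "stoichiometry_result")) {
    out <- results$table
    out$method <- results$method
    return(out)
  }
  if (is.list(results)) {
    tabs <- lapply(names(results), function(nm) {
      t <- .main_table(results[[nm]])
      t$section <- nm
      t
    })
    cols <- unique(unlist(lapply(tabs, names)))
    tabs <- lapply(tabs, function(t) {
      t[setdiff(cols, names(t))] <- NA
      t[cols]
    })
    return(do.call(rbind, tabs))
  }
  stop("cannot tabulate results of class ", class(results)[1])
}
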