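# Peptide-mapping record filtering, site-level relative PTM abundance,
# mobile-proton classification and sequence coverage.

#' Peptide-record filter parameters
#'
#' Defaults follow standard peptide-mapping practice for capsid-protein
#' PTM work: confidence >= 95%, average MS area >= 1e5, |mass error| <= 5
#' ppm, and exclusion of adducts, unknown modifications, gas-phase ions
#' and nonspecifically generated peptides.
#'
#' @param min_confidence percent, default 95.
#' @param min_avg_area default 1e5.
#' @param max_abs_ppm default 5.
#' @param exclude_flags character vector of record flags that disqualify.
#' @return list of class `peptide_filter_params`.
#' @export
peptide_filter_params <- function(min_confidence = 95, min_avg_area = 1e5,
                                  max_abs_ppm = 5,
                                  exclude_flags = c("adduct",
                                                    "unknown_modification",
                                                    "gas_phase_ion",
                                                    "nonspecific")) {
  stopifnot(min_confidence > 0, min_avg_area > 0, max_abs_ppm > 0)
  structure(list(min_confidence = min_confidence,
                 min_avg_area = min_avg_area, max_abs_ppm = max_abs_ppm,
                 exclude_flags = exclude_flags),
            class = "peptide_filter_params")
}

.check_records <- function(records) {
  need <- c("replicate", "sequence", "start", "end", "modification",
            "site", "confidence", "ms_area", "mass_error_ppm", "charge")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("peptide records missing column(s): ", paste(miss, collapse = ", "))
  if (!"flags" %in% names(records)) records$flags <- ""
  bad <- which(records$end - records$start + 1L != nchar(records$sequence))
  if (length(bad))
    stop("record ", bad[1], ": span does not match sequence length")
  if (any(records$confidence < 0 | records$confidence > 100))
    stop("confidence must be in [0, 100]")
  records
}

#' Filter peptide-mapping records
#'
#' Keeps records meeting every threshold and carrying none of the excluded
#' flags (the `flags` column holds `;`-separated flag names, empty when
#' clean). The filter is idempotent and order-independent.
#'
#' @param records data.frame of peptide records (columns `replicate`,
#'   `sequence`, `start`, `end`, `modification`, `site`, `confidence`,
#'   `ms_area`, `mass_error_ppm`, `charge`, optional `flags`).
#' @param p a [peptide_filter_params()].
#' @return the surviving records.
#' @export
filter_peptides <- function(records, p = peptide_filter_params()) {
  records <- .check_records(records)
  flagged <- vapply(strsplit(records$flags, ";"), function(f)
    any(trimws(f) %in% p$exclude_flags), logical(1))
  keep <- records$confidence >= p$min_confidence &
    records$ms_area >= p$min_avg_area &
    abs(records$mass_error_ppm) <= p$max_abs_ppm &
    !flagged
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.site_position <- function(site) as.integer(sub("^[A-Za-z]+", "", site))

#' Site-level relative PTM abundance
#'
#' Per replicate, the modified fraction is 100 x (summed MS areas of
#' records covering the site that carry the modification) / (summed MS
#' areas of all records covering the site); the per-replicate values are
#' then averaged. A record covers the site when its `start..end` span
#' contains the site position.
#'
#' @param records filtered peptide records.
#' @param site residue+position label, e.g. `"N56"`.
#' @param modification PTM name to quantify at the site.
#' @return list of class `site_quant`: `site`, `modification`,
#'   `per_replicate` (named percent vector), `mean`, `sd`, `covered`
#'   (FALSE with NA statistics when no record covers the site),
#'   `top_peptide` (sequence of the most abundant modified form).
#' @export
relative_abundance <- function(records, site, modification) {
  records <- .check_records(records)
  pos <- .site_position(site)
  cov <- records[records$start <= pos & records$end >= pos, , drop = FALSE]
  if (!nrow(cov))
    return(structure(list(site = site, modification = modification,
                          per_replicate = numeric(), mean = NA_real_,
                          sd = NA_real_, covered = FALSE,
                          top_peptide = NA_character_),
                     class = "site_quant"))
  is_mod <- cov$modification == modification & cov$site == site
  per_rep <- vapply(split(cov, cov$replicate), function(d) {
    tot <- sum(d$ms_area)
    if (tot == 0) return(0)
    100 * sum(d$ms_area[d$modification == modification & d$site == site]) /
      tot
  }, numeric(1))
  mod_rec <- cov[is_mod, , drop = FALSE]
  top <- if (nrow(mod_rec))
    mod_rec$sequence[which.max(mod_rec$ms_area)] else NA_character_
  structure(list(site = site, modification = modification,
                 per_replicate = per_rep, mean = mean(per_rep),
                 sd = if (length(per_rep) > 1L) stats::sd(per_rep) else 0,
                 covered = TRUE, top_peptide = top),
            class = "site_quant")
}

#' @export
print.site_quant <- function(x, ...) {
  if (!x$covered) {
    cat(sprintf("%s + %s: no coverage\n", x$site, x$modification))
  } else {
    cat(sprintf("%s + %s: %.2f%% (SD %.2f, n=%d) top peptide %s\n",
                x$site, x$modification, x$mean, x$sd,
                length(x$per_replicate), x$top_peptide))
  }
  invisible(x)
}

#' Mobile protons of a peptide at a charge state
#'
#' Charges in excess of the count of basic residues (Arg, Lys, His):
#' `max(0, charge - #RKH)`. Peptides with zero mobile protons favour
#' charge-directed neutral losses such as NH3 loss at N-terminal Gln.
#'
#' @param sequence amino-acid string.
#' @param charge observed charge state, >= 1.
#' @return integer count of mobile protons.
#' @export
#' @examples
#' mobile_protons("QDRDVYLQGPIW", 2)  # 1
mobile_protons <- function(sequence, charge) {
  stopifnot(charge >= 1)
  basic <- sum(strsplit(sequence, "")[[1]] %in% c("R", "K", "H"))
  max(0L, as.integer(charge) - basic)
}

#' Sequence coverage of filtered peptide records
#'
#' Percent of protein residues covered by at least one record; overlapping
#' records count each residue once.
#'
#' @param records filtered peptide records positioned on the same
#'   numbering as `sequence`.
#' @param sequence the protein sequence (mature numbering).
#' @return percent, 0-100.
#' @export
sequence_coverage <- function(records, sequence) {
  records <- .check_records(records)
  n <- nchar(sequence)
  if (nrow(records) &&
      (any(records$start < 1L) || any(records$end > n)))
    stop("record span outside 1..", n)
  covered <- logical(n)
  for (i in seq_len(nrow(records)))
    covered[records$start[i]:records$end[i]] <- TRUE
  100 * sum(covered) / n
}

#' Read peptide records from CSV
#'
#' Expected columns: `replicate,sequence,start,end,modification,site,`
#' `confidence,ms_area,mass_error_ppm,charge,flags` (flags `;`-separated,
#' may be empty).
#'
#' @param path CSV file.
#' @return validated data.frame of peptide records.
#' @export
read_peptide_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  if ("modification" %in% names(df)) df$modification[is.na(df$modification)] <- "none"
  .check_records(df)
}

#' Summarise every modified site in a record table
#'
#' Runs [relative_abundance()] for each distinct (site, modification) pair
#' present (modification != "none"), sorted by mean abundance.
#'
#' @param records filtered peptide records.
#' @param min_abundance report-level floor in percent (sites whose mean
#'   falls below are dropped from the report), default 1.
#' @return data.frame with columns `site`, `modification`, `top_peptide`,
#'   `mean_abundance`, `sd`.
#' @export
ptm_site_table <- function(records, min_abundance = 1) {
  records <- .check_records(records)
  mods <- unique(records[records$modification != "none",
                         c("site", "modification")])
  rows <- lapply(seq_len(nrow(mods)), function(i) {
    q <- relative_abundance(records, mods$site[i], mods$modification[i])
    data.frame(site = q$site, modification = q$modification,
               top_peptide = q$top_peptide,
               mean_abundance = round(q$mean, 2), sd = round(q$sd, 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(site = character(), modification = character(),
                      top_peptide = character(), mean_abundance = numeric(),
                      sd = numeric()))
  out <- out[out$mean_abundance >= min_abundance, , drop = FALSE]
  out <- out[order(-out$mean_abundance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
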