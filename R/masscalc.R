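# Mass arithmetic for intact viral-protein chains and proteoforms.
#
# All intact-level masses are on the average-mass scale (isotope-unresolved
# deconvolution at 59-82 kDa); monoisotopic masses are carried alongside for
# peptide-level work.

#' Standard amino-acid residue mass table
#'
#' Returns the residue mass table used by all mass calculations: the 20
#' canonical amino-acid residue masses (average and monoisotopic, Da), the
#' mass of water added per chain, and the proton mass used for m/z
#' conversion. Values are the standard IUPAC residue masses.
#'
#' @param overrides optional named list; each entry a numeric vector
#'   `c(avg = , mono = )` replacing one residue row, or scalar replacements
#'   for `water_avg`, `water_mono`, `proton`.
#' @return an object of class `residue_mass_table`: a list with elements
#'   `avg` and `mono` (named numeric vectors over the 20 residue letters),
#'   `water_avg`, `water_mono`, and `proton`.
#' @export
#' @examples
#' tab <- residue_masses()
#' tab$avg[["G"]]  # 57.0519
residue_masses <- function(overrides = NULL) {
  avg <- c(
    G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
    T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
    D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
    H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
  mono <- c(
    G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
    D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
    H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  tab <- list(avg = avg, mono = mono,
              water_avg = 18.0153, water_mono = 18.010565,
              proton = 1.00728)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      ov <- overrides[[nm]]
      if (nm %in% names(tab$avg)) {
        if (!is.null(ov[["avg"]]))  tab$avg[[nm]]  <- ov[["avg"]]
        if (!is.null(ov[["mono"]])) tab$mono[[nm]] <- ov[["mono"]]
      } else if (nm %in% c("water_avg", "water_mono", "proton")) {
        tab[[nm]] <- as.numeric(ov)
      } else {
        stop("unknown residue mass override: ", nm)
      }
    }
  }
  stopifnot(all(tab$avg >= tab$mono))
  structure(tab, class = "residue_mass_table")
}

#' Default PTM mass-delta table
#'
#' Average- and monoisotopic-mass shifts for the post-translational
#' modifications monitored on AAV capsid proteins: N-terminal acetylation,
#' Met/Trp oxidation, Asn deamidation, Gln NH3 loss, succinimide formed
#' from Asp by water loss, Ser phosphorylation, and Trp oxidation to
#' kynurenine (+4 Da class shift). Every entry can be overridden or
#' extended via configuration.
#'
#' @param extra optional data.frame with columns `name`, `delta_avg`,
#'   `delta_mono`, `allowed_residues` appended to (or, on name collision,
#'   replacing rows of) the default table.
#' @return data.frame with columns `name`, `delta_avg`, `delta_mono`,
#'   `allowed_residues`.
#' @export
ptm_table <- function(extra = NULL) {
  tab <- data.frame(
    name = c("acetylation", "oxidation", "deamidation", "NH3 loss",
             "succinimide D", "phosphorylation", "kynurenine"),
    delta_avg  = c(42.037, 15.999, 0.985, -17.031, -18.015, 79.980, 3.995),
    delta_mono = c(42.01057, 15.99491, 0.98402, -17.02655, -18.01056,
                   79.96633, 3.99491),
    allowed_residues = c("nterm", "MW", "N", "Q", "D", "STY", "W"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("name", "delta_avg", "delta_mono",
                    "allowed_residues") %in% names(extra)))
    tab <- tab[!(tab$name %in% extra$name), , drop = FALSE]
    tab <- rbind(tab, extra[names(tab)])
  }
  if (anyDuplicated(tab$name)) stop("duplicate PTM names in table")
  stopifnot(all(is.finite(tab$delta_avg)), all(is.finite(tab$delta_mono)))
  rownames(tab) <- NULL
  tab
}

.check_sequence <- function(sequence, masses) {
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!(res %in% names(masses)))
  if (length(bad))
    stop("non-canonical residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Average mass of an amino-acid chain
#'
#' Sum of standard average residue masses plus one water, plus the
#' acetylation delta when the N terminus is acetylated.
#'
#' @param sequence amino-acid string (canonical one-letter codes).
#' @param nterm_acetyl logical; add the N-terminal acetyl group mass.
#' @param table residue mass table from [residue_masses()].
#' @param ptms PTM delta table from [ptm_table()] (source of the acetyl
#'   delta).
#' @param monoisotopic use monoisotopic residue masses instead of average.
#' @return mass in Da. An empty sequence returns the water mass alone, with
#'   a warning (degenerate chain).
#' @export
#' @examples
#' average_mass("ATGSGAPM")   # 690.77
average_mass <- function(sequence, nterm_acetyl = FALSE,
                         table = residue_masses(), ptms = ptm_table(),
                         monoisotopic = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  masses <- if (monoisotopic) table$mono else table$avg
  water <- if (monoisotopic) table$water_mono else table$water_avg
  if (nchar(sequence) == 0L) {
    warning("empty sequence: returning water mass only")
    return(water)
  }
  res <- .check_sequence(sequence, masses)
  m <- sum(masses[res]) + water
  if (nterm_acetyl) {
    ac <- ptms[ptms$name == "acetylation", ]
    m <- m + if (monoisotopic) ac$delta_mono else ac$delta_avg
  }
  m
}

#' Apply PTM mass deltas to a base mass
#'
#' @param base_mass Da.
#' @param ptm_counts named numeric/integer vector or list, PTM name -> count.
#' @param ptms PTM delta table.
#' @param monoisotopic use monoisotopic deltas.
#' @return base mass shifted by `sum(count * delta)`, Da.
#' @export
#' @examples
#' apply_ptm_deltas(59973.78, c(oxidation = 1))  # 59989.78
apply_ptm_deltas <- function(base_mass, ptm_counts, ptms = ptm_table(),
                             monoisotopic = FALSE) {
  ptm_counts <- unlist(ptm_counts)
  if (length(ptm_counts) == 0L) return(base_mass)
  unknown <- setdiff(names(ptm_counts), ptms$name)
  if (length(unknown))
    stop("unknown PTM name(s): ", paste(unknown, collapse = ", "))
  if (any(ptm_counts < 0)) stop("PTM counts must be >= 0")
  deltas <- if (monoisotopic) ptms$delta_mono else ptms$delta_avg
  names(deltas) <- ptms$name
  base_mass + sum(ptm_counts * deltas[names(ptm_counts)])
}

#' Mass of an N-terminally truncated chain
#'
#' Subtracts the summed residue masses of a removed N-terminal stretch from
#' a base chain mass. The chain water is retained and any N-terminal
#' modification is assumed conserved on the new terminus (the truncated
#' variant is itself N-terminally processed).
#'
#' @param base_mass Da, mass of the full chain.
#' @param removed_prefix amino-acid string removed from the N terminus.
#' @param table residue mass table.
#' @param monoisotopic use monoisotopic residue masses.
#' @return truncated mass, Da.
#' @export
#' @examples
#' truncation_mass(59973.78, "ATGSGAPM")  # 59301.03
truncation_mass <- function(base_mass, removed_prefix,
                            table = residue_masses(), monoisotopic = FALSE) {
  stopifnot(nchar(removed_prefix) > 0L)
  masses <- if (monoisotopic) table$mono else table$avg
  res <- .check_sequence(removed_prefix, masses)
  out <- base_mass - sum(masses[res])
  if (out <= 0) stop("truncation removes more mass than the chain holds")
  out
}

#' Parts-per-million mass error
#'
#' @param observed,theoretical masses in Da; `theoretical > 0`.
#' @return object of class `mass_error`: list with `observed`,
#'   `theoretical`, `ppm` (signed), and `ppm_abs` (magnitude, the value
#'   reported in tables, rounded to 1 decimal by [format()]).
#' @export
#' @examples
#' ppm_error(59973.62, 59973.78)$ppm_abs  # 2.668...
ppm_error <- function(observed, theoretical) {
  stopifnot(theoretical > 0)
  ppm <- (observed - theoretical) / theoretical * 1e6
  structure(list(observed = observed, theoretical = theoretical,
                 ppm = ppm, ppm_abs = abs(ppm)),
            class = "mass_error")
}

#' @export
format.mass_error <- function(x, ...) {
  sprintf("%.1f ppm (obs %.2f / theo %.2f Da)",
          round(x$ppm_abs, 1), x$observed, x$theoretical)
}

#' @export
print.mass_error <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
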