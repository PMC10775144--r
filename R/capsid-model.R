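# Serotype definitions, VP chain derivation, N-terminal processing and the
# proteoform component library used for identity testing.
#
# Residue numbering follows the mature-chain convention used on AAV capsid
# proteins: position 1 is the first residue left after the initiator Met of
# VP1 is excised in the cell.  The definition stores the translated VP1
# (initiator Met included) and exposes mature numbering through a fixed
# offset of one.

#' Define an AAV serotype
#'
#' Bundles a serotype's VP1 sequence with the start positions of the
#' shorter capsid proteins. VP2 and VP3 are C-terminal sub-sequences of
#' VP1: each start position is the 1-based index, in mature (Met-cleaved)
#' VP1 numbering, of the first residue of the mature chain (e.g. T138 for
#' VP2, A203 for VP3, A211 for the A211-VP3 variant of AAV2).
#'
#' @param name serotype label, e.g. `"AAV2"`.
#' @param vp1_sequence amino-acid string of translated VP1 including the
#'   initiator Met.
#' @param vp2_start,vp3_start 1-based mature positions where VP2 and VP3
#'   begin.
#' @param variant_starts integer vector of additional start positions
#'   (truncated VP3 variants), possibly empty.
#' @param nterm_rule character subset of `c("cleave_met", "acetylate")`
#'   applied to every Met-initiated chain.
#' @return object of class `serotype_definition`.
#' @export
serotype_definition <- function(name, vp1_sequence, vp2_start, vp3_start,
                                variant_starts = integer(),
                                nterm_rule = c("cleave_met", "acetylate")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vp1_sequence <- toupper(vp1_sequence)
  .check_sequence(vp1_sequence, residue_masses()$avg)
  mature_len <- nchar(vp1_sequence) - 1L
  starts <- c(vp2_start, vp3_start, variant_starts)
  if (any(starts < 1L) || any(starts > mature_len))
    stop("start position beyond sequence length for ", name)
  if (!(vp2_start < vp3_start &&
        (length(variant_starts) == 0L || vp3_start < min(variant_starts))))
    stop("require vp2_start < vp3_start < min(variant_starts)")
  nterm_rule <- match.arg(nterm_rule, several.ok = TRUE)
  structure(list(name = name, vp1_sequence = vp1_sequence,
                 vp2_start = as.integer(vp2_start),
                 vp3_start = as.integer(vp3_start),
                 variant_starts = as.integer(variant_starts),
                 nterm_rule = nterm_rule),
            class = "serotype_definition")
}

#' @export
print.serotype_definition <- function(x, ...) {
  cat(sprintf("serotype %s: VP1 %d aa (translated), VP2 start %d, VP3 start %d",
              x$name, nchar(x$vp1_sequence), x$vp2_start, x$vp3_start))
  if (length(x$variant_starts))
    cat(", variant starts", paste(x$variant_starts, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Read serotype definitions from a JSON config file
#'
#' The config is a JSON array (or single object) with fields `name`,
#' `vp1_sequence` (inline string or `vp1_fasta` path to a FASTA file),
#' `vp2_start`, `vp3_start`, `variant_starts`, `nterm_rule`.
#'
#' @param path JSON file.
#' @return list of `serotype_definition`.
#' @export
read_serotype_definitions <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$name)) cfg <- list(cfg)  # single object
  if (is.data.frame(cfg)) cfg <- split(cfg, seq_len(nrow(cfg)))
  lapply(cfg, function(d) {
    if (is.data.frame(d)) d <- as.list(d)
    seq <- d$vp1_sequence
    if (is.null(seq) && !is.null(d$vp1_fasta))
      seq <- read_fasta_sequence(file.path(dirname(path), d$vp1_fasta))
    serotype_definition(
      name = d$name, vp1_sequence = seq,
      vp2_start = d$vp2_start, vp3_start = d$vp3_start,
      variant_starts = unlist(d$variant_starts) %||% integer(),
      nterm_rule = unlist(d$nterm_rule) %||% c("cleave_met", "acetylate"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the first sequence of a FASTA file as a plain string
#' @param path FASTA file.
#' @return amino-acid string.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (!length(headers)) stop("no FASTA header in ", path)
  from <- headers[1] + 1L
  to <- if (length(headers) > 1L) headers[2] - 1L else length(lines)
  paste(gsub("\\s", "", lines[from:to]), collapse = "")
}

#' Derive VP chain sequences from a serotype definition
#'
#' Returns the translated VP1 (initiator Met retained, pre-processing) and
#' the mature VP2/VP3/variant chains as suffixes of the mature VP1
#' sequence. Variant chains are named `"A<start>-VP3"` style by their
#' first residue.
#'
#' @param def a `serotype_definition`.
#' @return named list of amino-acid strings (`VP1`, `VP2`, `VP3`, one per
#'   variant).
#' @export
derive_vp_sequences <- function(def) {
  stopifnot(inherits(def, "serotype_definition"))
  mature <- substring(def$vp1_sequence, 2L)
  out <- list(VP1 = def$vp1_sequence,
              VP2 = substring(mature, def$vp2_start),
              VP3 = substring(mature, def$vp3_start))
  for (s in def$variant_starts) {
    first <- substring(mature, s, s)
    out[[sprintf("%s%d-VP3", first, s)]] <- substring(mature, s)
  }
  out
}

#' Apply the N-terminal Met-excision / acetylation rule to one chain
#'
#' Initiator Met is removed by Met-aminopeptidases when the residue at
#' position 2 has a small side chain (Ala, Val, Ser, Thr, Cys, Gly or
#' Pro); the exposed residue is then co-translationally acetylated. The
#' operation is idempotent: a chain that no longer starts with Met (or
#' whose position-2 residue is bulky) is returned unchanged.
#'
#' @param sequence amino-acid string, non-empty.
#' @param rule character subset of `c("cleave_met", "acetylate")`.
#' @param force_acetyl acetylate the current N terminus even when the
#'   sequence does not start with Met (used for chains whose initiator Met
#'   was already removed upstream).
#' @return list with `sequence` (processed) and `acetyl` (logical).
#' @export
#' @examples
#' apply_nterm_processing("MATGSGAPM")  # Met cleaved, acetyl TRUE
apply_nterm_processing <- function(sequence,
                                   rule = c("cleave_met", "acetylate"),
                                   force_acetyl = FALSE) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("empty sequence")
  rule <- match.arg(rule, several.ok = TRUE)
  small <- c("A", "V", "S", "T", "C", "G", "P")
  first <- substring(sequence, 1L, 1L)
  second <- substring(sequence, 2L, 2L)
  fired <- FALSE
  if ("cleave_met" %in% rule && first == "M" && second %in% small) {
    sequence <- substring(sequence, 2L)
    fired <- TRUE
  }
  acetyl <- ("acetylate" %in% rule) && (fired || (force_acetyl && first != "M"))
  list(sequence = sequence, acetyl = acetyl)
}

# Is the chain starting at mature position `start` translated from its own
# initiator Met?  TRUE when the mature residue immediately upstream is M
# (the chain's start codon sits inside the VP1 frame); VP2's ACG-initiated
# Thr N terminus has no upstream Met and receives no processing.
.met_initiated <- function(def, start) {
  if (start <= 1L) return(TRUE)  # chain is VP1 itself
  substring(def$vp1_sequence, start, start) == "M"  # translated pos = mature-1
}

# Mature processed sequence + acetyl flag for one named chain of a serotype.
.processed_chain <- function(def, vp_name) {
  chains <- derive_vp_sequences(def)
  if (!vp_name %in% names(chains))
    stop("unknown VP '", vp_name, "' for serotype ", def$name)
  seq <- chains[[vp_name]]
  if (vp_name == "VP1")
    return(apply_nterm_processing(seq, def$nterm_rule))
  start <- if (vp_name == "VP2") def$vp2_start
           else if (vp_name == "VP3") def$vp3_start
           else as.integer(sub("^[A-Z]", "", sub("-VP3$", "", vp_name)))
  if (.met_initiated(def, start)) {
    small <- c("A", "V", "S", "T", "C", "G", "P")
    acetyl <- "acetylate" %in% def$nterm_rule &&
      substring(seq, 1L, 1L) %in% small
    list(sequence = seq, acetyl = acetyl)
  } else {
    list(sequence = seq, acetyl = FALSE)
  }
}

#' Build the proteoform component library
#'
#' One component per requested (serotype, VP, PTM composition): the display
#' label, theoretical average mass (chain mass after N-terminal processing
#' plus PTM deltas), expected retention time and RT window. Default RT
#' windows follow the identity-method convention: +/- 1.00 min for VP3 and
#' its variants, +/- 0.60 min for VP1 and VP2.
#'
#' @param defs list of `serotype_definition`.
#' @param ptms PTM delta table ([ptm_table()]).
#' @param rt_calibration named list `serotype -> named numeric vector
#'   VP -> expected RT (min)`; or a single named numeric vector applied to
#'   every serotype.
#' @param proteoform_specs data.frame with columns `serotype`, `vp` and
#'   optionally `ptms` (list-column of named counts, or a string such as
#'   `"oxidation:1"`; empty = unmodified). When `NULL`, the unmodified
#'   VP1/VP2/VP3 (plus variants) of every definition are used.
#' @param rt_window_vp3,rt_window_other RT half-window defaults in minutes.
#' @return object of class `component_library`: a data.frame with columns
#'   `serotype`, `label`, `base_vp`, `ptms` (list-column),
#'   `theoretical_mass`, `expected_rt`, `rt_window`.
#' @export
build_component_library <- function(defs, ptms = ptm_table(),
                                    rt_calibration,
                                    proteoform_specs = NULL,
                                    rt_window_vp3 = 1.00,
                                    rt_window_other = 0.60) {
  if (inherits(defs, "serotype_definition")) defs <- list(defs)
  names(defs) <- vapply(defs, `[[`, "", "name")
  if (is.null(proteoform_specs)) {
    proteoform_specs <- do.call(rbind, lapply(defs, function(d) {
      vps <- names(derive_vp_sequences(d))
      data.frame(serotype = d$name, vp = vps, stringsAsFactors = FALSE)
    }))
  }
  if (is.null(proteoform_specs$ptms))
    proteoform_specs$ptms <- replicate(nrow(proteoform_specs), NULL)
  if (nrow(proteoform_specs) == 0L)
    return(.component_library(data.frame()))

  rows <- lapply(seq_len(nrow(proteoform_specs)), function(i) {
    st <- proteoform_specs$serotype[i]
    vp <- proteoform_specs$vp[i]
    if (!st %in% names(defs)) stop("unknown serotype in spec: ", st)
    def <- defs[[st]]
    counts <- .parse_ptm_counts(proteoform_specs$ptms[[i]])
    unknown <- setdiff(names(counts), ptms$name)
    if (length(unknown))
      stop("unknown PTM name(s) in spec: ", paste(unknown, collapse = ", "))
    chain <- .processed_chain(def, vp)
    base <- average_mass(chain$sequence, nterm_acetyl = chain$acetyl,
                         ptms = ptms)
    mass <- apply_ptm_deltas(base, counts, ptms = ptms)
    rt_tab <- if (is.list(rt_calibration) && !is.null(rt_calibration[[st]]))
      rt_calibration[[st]] else rt_calibration
    if (!vp %in% names(rt_tab))
      stop("no RT calibration for ", st, " ", vp)
    is_vp3_like <- vp != "VP1" && vp != "VP2"
    data.frame(
      serotype = st,
      label = .component_label(def, vp, chain$acetyl, counts),
      base_vp = vp,
      theoretical_mass = mass,
      expected_rt = unname(rt_tab[[vp]]),
      rt_window = if (is_vp3_like) rt_window_vp3 else rt_window_other,
      stringsAsFactors = FALSE)
  })
  lib <- do.call(rbind, rows)
  lib$ptms <- lapply(seq_len(nrow(proteoform_specs)),
                     function(i) .parse_ptm_counts(proteoform_specs$ptms[[i]]))
  for (st in unique(lib$serotype)) {
    labs <- lib$label[lib$serotype == st]
    if (anyDuplicated(labs))
      stop("duplicate component labels for ", st, ": ",
           paste(labs[duplicated(labs)], collapse = ", "))
  }
  .component_library(lib)
}

.parse_ptm_counts <- function(x) {
  if (is.null(x) || (is.character(x) && !nzchar(x))) return(numeric())
  if (is.character(x)) {
    parts <- strsplit(strsplit(x, ",")[[1]], ":")
    counts <- vapply(parts, function(p)
      if (length(p) == 2L) as.numeric(p[2]) else 1, numeric(1))
    names(counts) <- vapply(parts, function(p) trimws(p[1]), "")
    return(counts)
  }
  unlist(x)
}

# Label in the field's span convention, e.g. "VP3 (203-734)Ac + 1x Ox".
.component_label <- function(def, vp, acetyl, counts) {
  mature_len <- nchar(def$vp1_sequence) - 1L
  start <- switch(vp, VP1 = 1L, VP2 = def$vp2_start, VP3 = def$vp3_start,
                  as.integer(sub("^[A-Z]", "", sub("-VP3$", "", vp))))
  short <- c(oxidation = "Ox", deamidation = "Deam", `NH3 loss` = "-NH3",
             `succinimide D` = "SuccD", phosphorylation = "Phos",
             kynurenine = "Kyn", acetylation = "Ac")
  lab <- sprintf("%s %s (%d-%d)%s", def$name, vp, start, mature_len,
                 if (acetyl) "Ac" else "")
  counts <- counts[counts > 0]
  if (length(counts)) {
    nm <- ifelse(names(counts) %in% names(short),
                 short[names(counts)], names(counts))
    lab <- paste(lab, paste(sprintf("+ %dx %s", as.integer(counts), nm),
                            collapse = " "))
  }
  lab
}

.component_library <- function(df) {
  structure(df, class = c("component_library", "data.frame"))
}

#' @export
print.component_library <- function(x, ...) {
  cat(sprintf("component library: %d components, %d serotype(s)\n",
              nrow(x), length(unique(x$serotype))))
  if (nrow(x)) {
    show <- as.data.frame(x)[, c("label", "theoretical_mass",
                                 "expected_rt", "rt_window")]
    show$theoretical_mass <- round(show$theoretical_mass, 2)
    print(show, row.names = FALSE)
  }
  invisible(x)
}
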