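# Component matching, replicate consensus and serotype calling.

#' Identity-method parameters
#'
#' @param mass_tol_ppm component mass tolerance, default 10 ppm (the
#'   deconvolution merge tolerance; no separate match tolerance is defined
#'   by the reference method, so the value is configurable and echoed in
#'   reports).
#' @param min_score minimum deconvolution score for a feature to count in
#'   replicate consensus, default 60.
#' @param require_all_replicates keep a component only when matched in
#'   every replicate run, default TRUE.
#' @param rt_window_overrides optional named numeric vector, component
#'   label -> RT half-window (min), overriding the library windows.
#' @return list of class `identity_params`.
#' @export
identity_params <- function(mass_tol_ppm = 10, min_score = 60,
                            require_all_replicates = TRUE,
                            rt_window_overrides = NULL) {
  stopifnot(mass_tol_ppm > 0, min_score >= 0, min_score <= 100)
  structure(list(mass_tol_ppm = mass_tol_ppm, min_score = min_score,
                 require_all_replicates = require_all_replicates,
                 rt_window_overrides = rt_window_overrides),
            class = "identity_params")
}

#' Match deconvolved features to library components
#'
#' For every library component, features whose RT apex lies inside the
#' component's closed RT window and whose neutral mass is within the ppm
#' tolerance of the component's theoretical mass are candidates; the
#' highest-area candidate is assigned (ties broken by smaller absolute
#' mass error, then earlier RT). A feature may serve several components
#' when it falls in overlapping windows; such matches are flagged
#' `shared_feature`.
#'
#' @param features a `deconvolved_features` data.frame ([deconvolve()]).
#' @param lib a [build_component_library()] result.
#' @param p an [identity_params()].
#' @param replicate replicate identifier recorded on each match.
#' @return data.frame of class `component_matches`: columns `serotype`,
#'   `label`, `base_vp`, `neutral_mass`, `theoretical_mass`,
#'   `mass_error_ppm`, `rt_apex`, `rt_offset`, `area`, `score`,
#'   `shared_feature`, `replicate`.
#' @export
match_components <- function(features, lib, p = identity_params(),
                             replicate = 1L) {
  if (!nrow(lib)) stop("component library is empty")
  rows <- list()
  used <- integer(0)
  for (i in seq_len(nrow(lib))) {
    comp <- lib[i, ]
    win <- comp$rt_window
    if (!is.null(p$rt_window_overrides) &&
        comp$label %in% names(p$rt_window_overrides))
      win <- p$rt_window_overrides[[comp$label]]
    if (!nrow(features)) next
    dppm <- (features$neutral_mass - comp$theoretical_mass) /
      comp$theoretical_mass * 1e6
    drt <- features$rt_apex - comp$expected_rt
    ok <- which(abs(dppm) <= p$mass_tol_ppm & abs(drt) <= win)
    if (!length(ok)) next
    # highest area, then |ppm|, then earlier RT
    o <- ok[order(-features$area[ok], abs(dppm[ok]), features$rt_apex[ok])]
    j <- o[1]
    used <- c(used, j)
    rows[[length(rows) + 1L]] <- data.frame(
      serotype = comp$serotype, label = comp$label, base_vp = comp$base_vp,
      neutral_mass = features$neutral_mass[j],
      theoretical_mass = comp$theoretical_mass,
      mass_error_ppm = dppm[j], rt_apex = features$rt_apex[j],
      rt_offset = drt[j], area = features$area[j],
      score = features$score[j], feature_row = j,
      replicate = replicate, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(serotype = character(), label = character(),
                      base_vp = character(), neutral_mass = numeric(),
                      theoretical_mass = numeric(),
                      mass_error_ppm = numeric(), rt_apex = numeric(),
                      rt_offset = numeric(), area = numeric(),
                      score = numeric(), feature_row = integer(),
                      replicate = integer(), shared_feature = logical())
    return(structure(out, class = c("component_matches", "data.frame")))
  }
  out <- do.call(rbind, rows)
  out$shared_feature <- duplicated(out$feature_row) |
    duplicated(out$feature_row, fromLast = TRUE)
  rownames(out) <- NULL
  structure(out, class = c("component_matches", "data.frame"))
}

#' Replicate-consensus filtering of component matches
#'
#' A component is retained when it is matched in every replicate run (or,
#' with `require_all_replicates = FALSE`, in at least one) with a feature
#' score at or above `min_score` in each run where it appears.
#'
#' @param match_list list of `component_matches`, one per replicate run.
#' @param p an [identity_params()].
#' @return data.frame with one row per retained component: `serotype`,
#'   `label`, `base_vp`, `n_replicates`, `mean_area`, `mean_mass_error_ppm`,
#'   `min_score`.
#' @export
filter_replicates <- function(match_list, p = identity_params()) {
  stopifnot(length(match_list) >= 1)
  n_runs <- length(match_list)
  all <- do.call(rbind, lapply(seq_along(match_list), function(i) {
    m <- match_list[[i]]
    m$run <- if (nrow(m)) i else integer(0)
    m
  }))
  empty <- data.frame(serotype = character(), label = character(),
                      base_vp = character(), n_replicates = integer(),
                      mean_area = numeric(), mean_mass_error_ppm = numeric(),
                      min_score = numeric())
  if (is.null(all) || !nrow(all)) return(empty)
  all <- all[all$score >= p$min_score, , drop = FALSE]
  if (!nrow(all)) return(empty)
  by_label <- split(all, paste(all$serotype, all$label, sep = "\r"))
  rows <- lapply(by_label, function(d) {
    n <- length(unique(d$run))
    if (p$require_all_replicates && n < n_runs) return(NULL)
    data.frame(serotype = d$serotype[1], label = d$label[1],
               base_vp = d$base_vp[1], n_replicates = n,
               mean_area = mean(d$area),
               mean_mass_error_ppm = mean(d$mass_error_ppm),
               min_score = min(d$score), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$serotype, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call the serotype from a consensus component set
#'
#' A serotype qualifies when all of its unmodified VP1, VP2 and VP3
#' components are present in the consensus. Exactly one qualifying
#' serotype yields a call; zero or several yield `"none"`/`"ambiguous"`.
#' Consensus components belonging to any serotype other than the called
#' one are reported as false-positive flags. Modified proteoforms and
#' VP3 variants contribute to PTM monitoring but are not required for the
#' call.
#'
#' @param consensus output of [filter_replicates()].
#' @param lib the [build_component_library()] the matches were made
#'   against (must contain the unmodified VP sets).
#' @return object of class `identity_call`: list with `serotype`
#'   (`"none"`, `"ambiguous"` or a name), `status`, `evidence` (per
#'   serotype, the matched unmodified VP set), `false_positive_flags`
#'   (data.frame of cross-serotype components), `consensus`.
#' @export
call_serotype <- function(consensus, lib) {
  unmod <- vapply(lib$ptms, function(x) length(x[x > 0]) == 0L, logical(1))
  core <- lib[unmod & lib$base_vp %in% c("VP1", "VP2", "VP3"), , drop = FALSE]
  sero <- unique(lib$serotype)
  evidence <- lapply(sero, function(st) {
    need <- core$label[core$serotype == st]
    have <- intersect(need, consensus$label[consensus$serotype == st])
    list(required = need, matched = have,
         complete = length(need) == 3L && setequal(need, have))
  })
  names(evidence) <- sero
  qualifying <- sero[vapply(evidence, `[[`, logical(1), "complete")]
  if (length(qualifying) == 1L) {
    called <- qualifying
    status <- "identified"
  } else if (length(qualifying) == 0L) {
    called <- "none"
    status <- "no serotype matched its full unmodified VP set"
  } else {
    called <- "ambiguous"
    status <- paste("multiple qualifying serotypes:",
                    paste(qualifying, collapse = ", "))
  }
  fp <- consensus[consensus$serotype != called, , drop = FALSE]
  if (called %in% c("none", "ambiguous"))
    fp <- consensus[0, , drop = FALSE]
  structure(list(serotype = called, status = status, evidence = evidence,
                 false_positive_flags = fp, consensus = consensus),
            class = "identity_call")
}

#' @export
print.identity_call <- function(x, ...) {
  cat("serotype call:", x$serotype, "\n")
  if (x$serotype %in% c("none", "ambiguous")) cat("  ", x$status, "\n")
  cat(sprintf("  consensus components: %d; false-positive flags: %d\n",
              nrow(x$consensus), nrow(x$false_positive_flags)))
  invisible(x)
}
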