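# VP stoichiometry: copies of 60 capsid subunits and ratios of 12
# theoretical copies, apportioned by integrated peak (FLR) or XIC (MS)
# areas.  Averaging order follows the reference convention: areas are
# averaged across replicate runs first, copies/ratios are computed on the
# mean areas.

.check_areas <- function(areas) {
  areas <- unlist(areas)
  if (!length(areas) || all(areas == 0))
    stop("need at least one positive area")
  if (any(areas < 0)) stop("areas must be >= 0")
  areas
}

#' Apportion capsid copies among VP species by area
#'
#' `copies_i = total_copies * area_i / sum(areas)`. The 60-mer capsid
#' convention gives `total_copies = 60`.
#'
#' @param areas named numeric vector or list, label -> area.
#' @param total_copies total subunits to apportion, default 60.
#' @return named numeric vector of copies (unrounded; report at 2
#'   decimals).
#' @export
#' @examples
#' vp_copies(c(VP1 = 3541041.67, VP2 = 2557869.33,
#'             VP3 = 19850718.67, `VP3 prime` = 656673.33))
vp_copies <- function(areas, total_copies = 60) {
  areas <- .check_areas(areas)
  total_copies * areas / sum(areas)
}

#' Apportion the theoretical 12-copy ratio among VP species by area
#'
#' `ratio_i = total_ratio * area_i / sum(areas)`; the 1:1:10 VP1:VP2:VP3
#' convention sums to 12.
#'
#' @param areas named numeric vector or list, label -> area.
#' @param total_ratio total ratio units, default 12.
#' @return named numeric vector of ratios (unrounded).
#' @export
vp_ratios <- function(areas, total_ratio = 12) {
  areas <- .check_areas(areas)
  total_ratio * areas / sum(areas)
}

.stoich_result <- function(method, labels, mean_area, cv, n_replicates) {
  copies <- vp_copies(stats::setNames(mean_area, labels))
  ratios <- vp_ratios(stats::setNames(mean_area, labels))
  tab <- data.frame(label = labels,
                    average_area = mean_area,
                    area_cv_pct = round(cv, 2),
                    copies = round(copies, 2),
                    ratio = round(ratios, 2),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(method = method, table = tab,
                 copies_unrounded = copies, ratios_unrounded = ratios,
                 n_replicates = n_replicates),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf("VP stoichiometry (%s method, %d replicate%s)\n",
              x$method, x$n_replicates, if (x$n_replicates == 1) "" else "s"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' FLR-based VP stoichiometry
#'
#' Per-label mean area and CV%% across replicate runs, then copies of 60
#' and ratios of 12 on the mean areas. Extra species (a VP3-prime-like
#' peak) enter the denominators whenever present.
#'
#' @param peak_areas data.frame with columns `replicate`, `label`, `area`
#'   (one row per labelled FLR peak per run), or a list of named numeric
#'   vectors, one per replicate.
#' @return a `stoichiometry_result` with method `"FLR"`.
#' @export
stoichiometry_flr <- function(peak_areas) {
  df <- .as_area_df(peak_areas)
  labs <- unique(df$label)
  by_rep <- split(df, df$replicate)
  for (d in by_rep)
    if (!setequal(d$label, labs))
      stop("replicates carry inconsistent labels")
  mean_area <- vapply(labs, function(l) mean(df$area[df$label == l]),
                      numeric(1))
  cv <- vapply(labs, function(l) {
    a <- df$area[df$label == l]
    if (length(a) < 2L || mean(a) == 0) 0 else stats::sd(a) / mean(a) * 100
  }, numeric(1))
  .stoich_result("FLR", labs, unname(mean_area), unname(cv),
                 length(by_rep))
}

.as_area_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("replicate", "label", "area") %in% names(x)))
    return(x)
  }
  do.call(rbind, lapply(seq_along(x), function(i)
    data.frame(replicate = i, label = names(x[[i]]),
               area = unname(unlist(x[[i]])), stringsAsFactors = FALSE)))
}

#' MS-based VP stoichiometry from matched proteoform XIC areas
#'
#' XIC areas of all proteoforms of a VP are summed per replicate to
#' represent that VP, the per-VP sums are averaged across replicates, and
#' copies/ratios are computed on the means. Unassigned species (e.g. a
#' VP3-prime region with no confident components) are simply absent.
#'
#' @param proteoform_areas data.frame with columns `replicate`, `base_vp`,
#'   `area` and optionally `label` (one row per matched proteoform per
#'   run).
#' @return a `stoichiometry_result` with method `"MS"`.
#' @export
stoichiometry_ms <- function(proteoform_areas) {
  stopifnot(is.data.frame(proteoform_areas),
            all(c("replicate", "base_vp", "area") %in%
                  names(proteoform_areas)))
  if (!nrow(proteoform_areas)) stop("no matched proteoforms")
  per_rep <- stats::aggregate(area ~ replicate + base_vp,
                              data = proteoform_areas, FUN = sum)
  labs <- sort(unique(per_rep$base_vp))
  mean_area <- vapply(labs, function(l)
    mean(per_rep$area[per_rep$base_vp == l]), numeric(1))
  cv <- vapply(labs, function(l) {
    a <- per_rep$area[per_rep$base_vp == l]
    if (length(a) < 2L || mean(a) == 0) 0 else stats::sd(a) / mean(a) * 100
  }, numeric(1))
  .stoich_result("MS", labs, unname(mean_area), unname(cv),
                 length(unique(per_rep$replicate)))
}
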