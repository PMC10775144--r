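# Charge-ladder deconvolution of intact ESI-MS1 data.
#
# The algorithm is a standard intact-mass charge-ladder search:
#   1. peak-pick every scan inside the RT limits;
#   2. cluster picked peaks across scans into m/z traces and require each
#      trace to be detected in >= min_intervals scans (the chromatographic
#      "detected intervals" filter);
#   3. propose a neutral mass M = z * (m/z - proton) for every trace and
#      every charge in the allowed range;
#   4. single-linkage cluster the proposals at the ppm merge tolerance;
#   5. greedily accept mass clusters in decreasing support, consuming their
#      m/z traces so that charge-assignment harmonics (M/2, 2M) which reuse
#      the same traces cannot survive;
#   6. report neutral mass (intensity-weighted), RT apex, trapezoidal area,
#      number of charge states and a 0-100 quality score.
#
# The score is not comparable to any vendor score; it is calibrated so that
# well-supported envelopes score high (>> 60) and sparse or incoherent
# candidates score low (see the methods vignette).

#' Deconvolution parameters
#'
#' @param charge_range integer range of charge states considered, default
#'   centred on 35.
#' @param mass_range plausible neutral-mass window in Da (proposals outside
#'   are discarded).
#' @param merge_tolerance_ppm mass merge tolerance, default 10 ppm.
#' @param rt_limits processing time limits in minutes, default
#'   `c(13.00, 28.50)`.
#' @param min_intervals minimum number of scans an m/z trace must be
#'   detected in, default 10.
#' @param min_charge_states minimum number of distinct charge states
#'   supporting a feature, default 3.
#' @param proton proton mass for m/z conversion.
#' @param peak_snr scan-level peak threshold as a multiple of the scan's
#'   median absolute intensity deviation above the median.
#' @return list of class `deconvolution_params`.
#' @export
deconvolution_params <- function(charge_range = 20:55,
                                 mass_range = c(1e4, 2e5),
                                 merge_tolerance_ppm = 10,
                                 rt_limits = c(13.00, 28.50),
                                 min_intervals = 10,
                                 min_charge_states = 3,
                                 proton = 1.00728,
                                 peak_snr = 5) {
  stopifnot(merge_tolerance_ppm > 0, rt_limits[1] < rt_limits[2],
            min_intervals >= 1, min_charge_states >= 1)
  structure(list(charge_range = as.integer(charge_range),
                 mass_range = mass_range,
                 merge_tolerance_ppm = merge_tolerance_ppm,
                 rt_limits = rt_limits,
                 min_intervals = as.integer(min_intervals),
                 min_charge_states = as.integer(min_charge_states),
                 proton = proton, peak_snr = peak_snr),
            class = "deconvolution_params")
}

# Scan-level peak picking against a run-global threshold.  Centroid-style
# sparse scans pass through (every point isolated in m/z is its own peak);
# in profile data local maxima above the threshold are kept.
.pick_scan_peaks <- function(mz, intensity, thr) {
  n <- length(mz)
  if (n == 0L) return(list(mz = numeric(), intensity = numeric()))
  keep <- intensity > thr & intensity > 0
  if (n >= 3L) {
    # local maximum among m/z-adjacent points closer than 0.3 Th
    left  <- c(Inf, diff(mz)) < 0.3
    right <- c(diff(mz), Inf) < 0.3
    lower_l <- c(TRUE, intensity[-n] <= intensity[-1])
    lower_r <- c(intensity[-1] <= intensity[-n], TRUE)
    keep <- keep & (!left | lower_l) & (!right | lower_r)
  }
  list(mz = mz[keep], intensity = intensity[keep])
}

# Cluster a sorted numeric vector by relative gap (ppm): single linkage,
# split where the gap between neighbours exceeds tol.
.ppm_cluster <- function(x, tol_ppm) {
  o <- order(x)
  xs <- x[o]
  brk <- which(diff(xs) / xs[-length(xs)] * 1e6 > tol_ppm)
  grp <- rep.int(seq_len(length(brk) + 1L),
                 diff(c(0L, brk, length(xs))))
  ids <- integer(length(x))
  ids[o] <- grp
  ids
}

#' Deconvolve charge-state envelopes to neutral masses
#'
#' @param s a [spectrum_set()].
#' @param p a [deconvolution_params()].
#' @return data.frame of class `deconvolved_features` with columns
#'   `neutral_mass`, `rt_apex`, `area`, `score`, `n_charge_states`,
#'   `n_intervals`; empty (zero rows) when no scans or no features.
#' @export
deconvolve <- function(s, p = deconvolution_params()) {
  rts <- scan_times(s)
  in_win <- which(rts >= p$rt_limits[1] & rts <= p$rt_limits[2])
  empty <- structure(
    data.frame(neutral_mass = numeric(), rt_apex = numeric(),
               area = numeric(), score = numeric(),
               n_charge_states = integer(), n_intervals = integer()),
    class = c("deconvolved_features", "data.frame"))
  if (!length(in_win)) return(empty)

  # run-global noise threshold: robust statistics over all positive
  # intensities in the window (per-scan statistics would treat a clean
  # charge envelope in a sparse centroid scan as its own noise floor)
  all_int <- unlist(lapply(in_win, function(i) {
    x <- s$scans[[i]]$intensity
    x[x > 0]
  }))
  if (!length(all_int)) return(empty)
  thr <- stats::median(all_int) + p$peak_snr * stats::mad(all_int)
  if (!is.finite(thr) || thr <= 0) thr <- 0

  # pooled picked peaks
  pk <- lapply(in_win, function(i) {
    sc <- s$scans[[i]]
    pp <- .pick_scan_peaks(sc$mz, sc$intensity, thr)
    if (!length(pp$mz)) return(NULL)
    data.frame(scan = i, rt = rts[i], mz = pp$mz, intensity = pp$intensity)
  })
  pk <- do.call(rbind, pk)
  if (is.null(pk) || !nrow(pk)) return(empty)

  # m/z traces across scans (cluster at half the merge tolerance on m/z)
  pk$trace <- .ppm_cluster(pk$mz, p$merge_tolerance_ppm)
  tr_n <- tapply(pk$scan, pk$trace, function(x) length(unique(x)))
  good_traces <- as.integer(names(tr_n))[tr_n >= p$min_intervals]
  if (!length(good_traces)) return(empty)
  pk <- pk[pk$trace %in% good_traces, , drop = FALSE]

  traces <- do.call(rbind, lapply(split(pk, pk$trace), function(d)
    data.frame(trace = d$trace[1],
               mz = sum(d$mz * d$intensity) / sum(d$intensity),
               total = sum(d$intensity),
               n_scans = length(unique(d$scan)))))

  # candidate neutral masses
  cand <- do.call(rbind, lapply(p$charge_range, function(z) {
    m <- z * (traces$mz - p$proton)
    keep <- m >= p$mass_range[1] & m <= p$mass_range[2]
    if (!any(keep)) return(NULL)
    data.frame(trace = traces$trace[keep], z = z, mass = m[keep],
               total = traces$total[keep], n_scans = traces$n_scans[keep])
  }))
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand$cluster <- .ppm_cluster(cand$mass, p$merge_tolerance_ppm)

  # summarise clusters, greedy accept consuming traces
  cl <- split(cand, cand$cluster)
  support <- vapply(cl, function(d)
    length(unique(d$z)) * 1e12 + sum(d$total), numeric(1))
  order_cl <- order(support, decreasing = TRUE)
  consumed <- integer(0)
  feats <- list()
  scan_rts <- rts
  dt <- if (length(rts) > 1L) stats::median(diff(rts)) else 1

  for (k in order_cl) {
    d <- cl[[k]]
    d <- d[!(d$trace %in% consumed), , drop = FALSE]
    if (!nrow(d)) next
    zs <- unique(d$z)
    if (length(zs) < p$min_charge_states) next
    if (sum(d$n_scans) < p$min_intervals) next
    mass <- sum(d$mass * d$total) / sum(d$total)
    ppm_spread <- stats::sd(d$mass / mass * 1e6)
    if (!is.finite(ppm_spread)) ppm_spread <- 0

    sub <- pk[pk$trace %in% d$trace, , drop = FALSE]
    prof <- tapply(sub$intensity, sub$scan, sum)
    prof_rt <- scan_rts[as.integer(names(prof))]
    apex <- prof_rt[which.max(prof)]
    area <- sum(prof) * dt
    # saturating charge-count term x coherence term
    score <- 100 * (length(zs) / (length(zs) + 3)) /
      (1 + ppm_spread / (p$merge_tolerance_ppm / 2))
    consumed <- c(consumed, unique(d$trace))
    feats[[length(feats) + 1L]] <- data.frame(
      neutral_mass = mass, rt_apex = apex, area = area,
      score = min(100, max(0, score)),
      n_charge_states = length(zs), n_intervals = sum(d$n_scans))
  }
  if (!length(feats)) return(empty)
  out <- do.call(rbind, feats)
  out <- out[order(-out$area), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("deconvolved_features", "data.frame"))
}

#' @export
print.deconvolved_features <- function(x, ...) {
  cat(sprintf("deconvolved features: %d\n", nrow(x)))
  if (nrow(x)) {
    show <- as.data.frame(x)
    show$neutral_mass <- round(show$neutral_mass, 2)
    show$rt_apex <- round(show$rt_apex, 2)
    show$score <- round(show$score, 1)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Extract an ion chromatogram for a neutral mass
#'
#' Per-scan summed intensity within `tol_ppm` of each theoretical m/z of
#' `target_mass` over the given charge states,
#' `m/z = (M + z * proton) / z`.
#'
#' @param s a [spectrum_set()].
#' @param target_mass neutral mass, Da.
#' @param charges integer vector of charge states, non-empty.
#' @param tol_ppm m/z tolerance in ppm.
#' @param proton proton mass.
#' @return a [chromatogram()] labelled with the target mass.
#' @export
extract_xic <- function(s, target_mass, charges, tol_ppm = 10,
                        proton = 1.00728) {
  stopifnot(length(charges) >= 1)
  targets <- (target_mass + charges * proton) / charges
  rts <- scan_times(s)
  inten <- vapply(s$scans, function(sc) {
    if (!length(sc$mz)) return(0)
    tot <- 0
    for (t in targets) {
      tol <- t * tol_ppm * 1e-6
      lo <- findInterval(t - tol, sc$mz) + 1L
      hi <- findInterval(t + tol, sc$mz)
      if (hi >= lo) tot <- tot + sum(sc$intensity[lo:hi])
    }
    tot
  }, numeric(1))
  chromatogram(rts, inten,
               channel = sprintf("XIC %.2f Da", target_mass))
}

#' Detect and integrate chromatographic peaks
#'
#' Local maxima above a robust noise threshold (median + `snr` * MAD of
#' the trace), valley-to-valley bounds, trapezoidal areas in
#' counts x minutes. Plateau apices resolve to the earliest time point.
#'
#' @param c a [chromatogram()] with at least 3 points.
#' @param snr noise-threshold multiplier, default 5.
#' @param min_points minimum number of points between bounds, default 3.
#' @return data.frame with columns `apex_rt`, `start_rt`, `end_rt`,
#'   `area`, `height`; zero rows when nothing rises above noise.
#' @export
integrate_peaks <- function(c, snr = 5, min_points = 3) {
  n <- length(c$time)
  stopifnot(n >= 3)
  y <- c$intensity
  thr <- stats::median(y) + snr * stats::mad(y)
  if (thr <= 0) thr <- max(y) * 0.01
  # strict-on-left local maxima => plateau apex at earliest point
  is_max <- y > thr &
    y > c(-Inf, y[-n]) &
    y >= c(y[-1], -Inf)
  apices <- which(is_max)
  if (!length(apices))
    return(data.frame(apex_rt = numeric(), start_rt = numeric(),
                      end_rt = numeric(), area = numeric(),
                      height = numeric()))
  peaks <- lapply(apices, function(a) {
    lo <- a
    while (lo > 1L && y[lo - 1L] <= y[lo]) lo <- lo - 1L
    hi <- a
    while (hi < n && y[hi + 1L] <= y[hi]) hi <- hi + 1L
    idx <- lo:hi
    if (length(idx) < min_points) return(NULL)
    area <- sum(diff(c$time[idx]) *
                  (utils::head(y[idx], -1) + utils::tail(y[idx], -1)) / 2)
    if (area <= 0) return(NULL)
    data.frame(apex_rt = c$time[a], start_rt = c$time[lo],
               end_rt = c$time[hi], area = area, height = y[a])
  })
  out <- do.call(rbind, peaks)
  if (is.null(out))
    out <- data.frame(apex_rt = numeric(), start_rt = numeric(),
                      end_rt = numeric(), area = numeric(),
                      height = numeric())
  rownames(out) <- NULL
  out
}

#' Trapezoidal integral of a full chromatogram
#' @param c a [chromatogram()].
#' @param rt_window optional `c(lo, hi)` minutes restricting the integral.
#' @return counts x minutes.
#' @export
trace_integral <- function(c, rt_window = NULL) {
  t <- c$time; y <- c$intensity
  if (!is.null(rt_window)) {
    keep <- t >= rt_window[1] & t <= rt_window[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 2L) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
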