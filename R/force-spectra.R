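## Force-curve processing: AFM adhesion extraction, SMD rupture extraction
## with phase labelling, and boxplot-style comparison of force
## distributions (simulation vs force spectroscopy, with controls).

#' Extract the adhesion force from an AFM retract curve
#'
#' The baseline is the median force over a trailing window of the retract
#' trace; the adhesion force Fad is baseline minus the minimum force
#' (>= 0).  Invariant to additive baseline offsets.
#'
#' @param curve a \code{\linkS4class{ForceCurve}} of kind \code{afm_retract}.
#' @param baseline_window fraction of trailing points used for the baseline.
#' @return Fad in pN.
#' @export
extractAdhesion <- function(curve, baseline_window = 0.2) {
  if (curve@kind != "afm_retract")
    stop("adhesion extraction needs an afm_retract curve", call. = FALSE)
  f <- curve@force[order(curve@abscissa)]
  n <- length(f)
  n_tail <- max(3L, ceiling(baseline_window * n))
  baseline <- stats::median(f[(n - n_tail + 1):n])
  max(0, baseline - min(f))
}

.medianFilter <- function(x, width) {
  if (width <= 1 || length(x) < width) return(x)
  half <- floor(width / 2)
  stats::runmed(x, 2 * half + 1, endrule = "keep")
}

#' Extract the rupture event from an SMD force curve
#'
#' A median-filtered copy of the trace locates the trailing separation
#' plateau (the longest trailing segment whose filtered force stays below
#' \code{plateau_frac} of the global maximum); the rupture force is the
#' maximum of the raw trace before that plateau, so a sharp force apex is
#' not clipped by the smoothing.  Phase
#' boundaries follow the three-phase reading of a pulling trace: complex
#' maintenance up to the force peak, detachment from the peak to the
#' plateau onset, separation afterwards.  A curve with no trailing plateau
#' is flagged unruptured.
#'
#' @param curve a \code{\linkS4class{ForceCurve}} of kind \code{smd}.
#' @param filter_width median filter width, samples (default 5).
#' @param plateau_frac plateau threshold as a fraction of the global
#'   maximum (default 0.1).
#' @return a \code{\linkS4class{RuptureEvent}}.
#' @export
extractRupture <- function(curve, filter_width = 5, plateau_frac = 0.1) {
  if (curve@kind != "smd")
    stop("rupture extraction needs an smd curve", call. = FALSE)
  t <- curve@abscissa
  f <- .medianFilter(curve@force, filter_width)
  fmax <- max(f)
  unruptured <- function() methods::new(
    "RuptureEvent", rupture_force = NA_real_, rupture_time = NA_real_,
    ruptured = FALSE, phases = c(maintenance_end = NA_real_,
                                 detachment_end = NA_real_), meta = list())
  if (fmax <= 0) return(unruptured())
  below <- f < plateau_frac * fmax
  n <- length(f)
  if (!below[n]) return(unruptured())  # no trailing plateau: still bound
  plateau_start <- n
  while (plateau_start > 1 && below[plateau_start - 1])
    plateau_start <- plateau_start - 1
  pre <- seq_len(plateau_start - 1)
  if (!length(pre)) return(unruptured())
  ipk <- pre[which.max(curve@force[pre])]
  methods::new("RuptureEvent", rupture_force = curve@force[ipk],
               rupture_time = t[ipk], ruptured = TRUE,
               phases = c(maintenance_end = t[ipk],
                          detachment_end = t[plateau_start]),
               meta = list(plateau_start_ps = t[plateau_start]))
}

.tukeyStats <- function(x, group) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- x[x >= lo & x <= hi]
  data.frame(group = group, n = length(x), min = min(x), q1 = q[1],
             median = q[2], q3 = q[3], max = max(x),
             whisker_lo = min(inside), whisker_hi = max(inside),
             n_outliers = sum(x < lo | x > hi))
}

#' Compare force distributions (simulation vs AFM, with controls)
#'
#' Tukey boxplot statistics (1.5 x IQR whiskers) per group, the containment
#' fraction of each group's values inside every other group's [min, max]
#' range, whether each group's median lies inside every other group's
#' interquartile box, and pairwise Wilcoxon rank tests with median
#' differences.  A group of identical values degenerates to a zero-width
#' box and is handled.
#'
#' @param smd_forces numeric vector of simulated rupture forces, pN.
#' @param afm_forces numeric vector of AFM adhesion forces, pN.
#' @param controls optional named list of further force vectors.
#' @return a \code{\linkS4class{DistributionComparison}}.
#' @export
compareDistributions <- function(smd_forces, afm_forces, controls = list()) {
  groups <- c(list(smd = smd_forces, afm = afm_forces), controls)
  if (any(vapply(groups, length, integer(1)) < 3))
    stop("every group needs at least 3 values", call. = FALSE)
  stats_df <- do.call(rbind, Map(.tukeyStats, groups, names(groups)))
  rownames(stats_df) <- NULL
  pairs <- expand.grid(a = names(groups), b = names(groups),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  containment <- numeric(0)
  median_in_box <- logical(0)
  for (r in seq_len(nrow(pairs))) {
    a <- groups[[pairs$a[r]]]; b <- groups[[pairs$b[r]]]
    nm <- paste0(pairs$a[r], "_in_", pairs$b[r])
    containment[nm] <- mean(a >= min(b) & a <= max(b))
    qb <- stats::quantile(b, c(0.25, 0.75), names = FALSE)
    median_in_box[nm] <- stats::median(a) >= qb[1] &&
      stats::median(a) <= qb[2]
  }
  test_pairs <- t(utils::combn(names(groups), 2))
  tests <- do.call(rbind, lapply(seq_len(nrow(test_pairs)), function(r) {
    a <- groups[[test_pairs[r, 1]]]; b <- groups[[test_pairs[r, 2]]]
    p <- tryCatch(
      suppressWarnings(stats::wilcox.test(a, b)$p.value),
      error = function(e) NA_real_)
    data.frame(pair = paste(test_pairs[r, 1], test_pairs[r, 2], sep = "-"),
               median_diff = stats::median(a) - stats::median(b),
               p_value = p)
  }))
  methods::new("DistributionComparison", stats = stats_df,
               containment = containment, median_in_box = median_in_box,
               tests = tests)
}

#' Fraction of the full unbinding force carried by a contact subset
#'
#' 100 x subset mean force / full mean force, reported to one decimal and
#' as a rounded integer percentage.
#'
#' @param f_subset_mean mean rupture force of the subset system, pN.
#' @param f_full_mean mean rupture force of the full system, pN (> 0).
#' @return list with \code{pct} (one decimal) and \code{pct_rounded}.
#' @examples
#' forceFraction(780, 1042)  # 74.9, rounding to 75
#' @export
forceFraction <- function(f_subset_mean, f_full_mean) {
  if (!is.finite(f_full_mean) || f_full_mean <= 0)
    stop("the full-system mean force must be positive", call. = FALSE)
  pct <- 100 * f_subset_mean / f_full_mean
  list(pct = round(pct, 1), pct_rounded = as.integer(round(pct)))
}

#' Write a force curve as 2-column CSV
#'
#' Columns are time_ps (smd) or position_nm (afm) and force_pN.
#'
#' @param curve a \code{\linkS4class{ForceCurve}}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeForceCurveCSV <- function(curve, file) {
  utils::write.csv(forceTrace(curve), file, row.names = FALSE)
  invisible(file)
}

#' Read a force curve from 2-column CSV
#'
#' @param file path to a CSV written by \code{\link{writeForceCurveCSV}}.
#' @param kind curve kind (smd, afm_approach, afm_retract); inferred from
#'   the abscissa column name when NULL.
#' @return a \code{\linkS4class{ForceCurve}}.
#' @export
readForceCurveCSV <- function(file, kind = NULL) {
  df <- utils::read.csv(file)
  if (is.null(kind))
    kind <- if (names(df)[1] == "time_ps") "smd" else "afm_retract"
  methods::new("ForceCurve", kind = kind, abscissa = df[[1]],
               force = df$force_pN, meta = list(file = file))
}
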