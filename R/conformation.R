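## Rigid-body superposition and RMSD time series for whole molecules and
## annotated sub-regions.  RMSD is computed in Angstrom; nm values (RMSD/10)
## are reported alongside since force-spectroscopy and MD literature often
## prints nm.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal rotation and translation mapping Q onto P via SVD
#' of the covariance matrix, with the determinant sign corrected so the
#' result is a proper rotation (determinant +1, reflections excluded).
#'
#' @param P,Q n x 3 coordinate matrices (same n).  Three non-collinear
#'   points are needed for a unique rotation; degenerate inputs are allowed
#'   and flagged.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3;
#'   the transform is \code{Q \%*\% t(rotation) + translation}), \code{rmsd}
#'   (Angstrom, after superposition), and \code{degenerate} (TRUE when n < 3
#'   or the points are collinear).
#' @examples
#' P <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
#' Q <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
#' kabschSuperpose(P, Q)$rmsd  # 0.5
#' @export
kabschSuperpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3)
    stop("P and Q must be n x 3 matrices with matching point counts",
         call. = FALSE)
  n <- nrow(P)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(Q0) %*% P0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- n < 3 || sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)
  Qfit <- Q0 %*% t(R)
  rmsd <- sqrt(sum((P0 - Qfit)^2) / n)
  list(rotation = R, translation = as.numeric(cp - cq %*% t(R)),
       rmsd = rmsd, degenerate = degenerate)
}

.rmsdPlain <- function(P, Q) sqrt(sum((P - Q)^2) / nrow(P))

#' RMSD time series of a selection over a trajectory
#'
#' Per-frame RMSD of a selection to the reference (frame 1), with optional
#' Kabsch superposition on the same selection before measuring.  The default
#' atom subset is C-alpha only; \code{mode = "all"} uses every selected atom.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param selection integer atom indices (before the C-alpha filter).
#' @param superpose superpose each frame on the selection first?
#' @param mode \code{"calpha"} (default) restricts the selection to CA
#'   atoms; \code{"all"} keeps every selected atom.
#' @param label selection label carried in the result.
#' @return an \code{\linkS4class{RmsdSeries}}.
#' @export
rmsdSeries <- function(traj, selection, superpose = TRUE,
                       mode = c("calpha", "all"), label = "custom") {
  mode <- match.arg(mode)
  a <- atoms(traj)
  if (!length(selection)) stop("selection is empty", call. = FALSE)
  sel <- selection
  if (mode == "calpha") {
    sel <- sel[a$name[sel] == "CA"]
    if (!length(sel))
      stop("selection has no C-alpha atoms; use mode = \"all\"",
           call. = FALSE)
  }
  nf <- nFrames(traj)
  ref <- frameCoords(traj, 1L)[sel, , drop = FALSE]
  vals <- numeric(nf)
  for (f in seq_len(nf)) {
    fr <- frameCoords(traj, f)[sel, , drop = FALSE]
    vals[f] <- if (superpose) kabschSuperpose(ref, fr)$rmsd
      else .rmsdPlain(ref, fr)
  }
  methods::new("RmsdSeries", rmsd_A = vals, times = traj@times,
               label = label, superposed = superpose,
               mean_A = mean(vals),
               sd_A = if (nf > 1) stats::sd(vals) else 0)
}

#' Write an RMSD series as CSV
#'
#' Columns time_ps, rmsd_A, rmsd_nm.
#'
#' @param series an \code{\linkS4class{RmsdSeries}}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeRmsdCSV <- function(series, file) {
  utils::write.csv(data.frame(time_ps = series@times,
                              rmsd_A = series@rmsd_A,
                              rmsd_nm = series@rmsd_A / 10),
                   file, row.names = FALSE)
  invisible(file)
}
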