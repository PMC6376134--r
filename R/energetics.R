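## Gas-phase molecular-mechanics interface energies: Coulomb electrostatics
## and Lennard-Jones van der Waals terms between two selections, sampled on
## a stride through a trajectory window.  These are the MM Delta-E_elec /
## Delta-E_vdW terms of an MM/PBSA-style decomposition; Poisson-Boltzmann
## and surface-area solvation and entropy terms are deliberately out of
## scope.  Plain cutoff truncation (no Ewald): the inputs are static
## synthetic frames, not periodic solvated systems.

#' Coulomb constant in kcal A mol-1 e-2
#' @export
COULOMB_KCAL <- 332.06

.pairDistances <- function(xyz, ia, ib) {
  d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
              rowSums(xyz[ib, , drop = FALSE]^2), "+") -
    2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
  sqrt(pmax(d2, 0))
}

#' Electrostatic cross-interaction energy
#'
#' Coulomb energy between two selections:
#' sum over cross pairs within the cutoff of
#' 332.06 * qi * qj / (eps_r * rij), in kcal/mol.
#'
#' @param structure a \code{\linkS4class{ComplexStructure}} with charges
#'   assigned (see \code{\link{assignChemistry}}).
#' @param sel_a,sel_b disjoint atom selections.
#' @param dielectric relative permittivity eps_r.
#' @param cutoff pair cutoff, Angstrom (default 12).
#' @param coords optional n x 3 coordinate override.
#' @return energy in kcal/mol.
#' @examples
#' # two unit charges of opposite sign at 3.3206 A give -100 kcal/mol
#' @export
coulombEnergy <- function(structure, sel_a, sel_b, dielectric = 1,
                          cutoff = 12, coords = NULL) {
  a <- atoms(structure)
  if (length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint", call. = FALSE)
  if (is.null(coords)) coords <- as.matrix(a[, c("x", "y", "z")])
  if (anyNA(a$charge[c(sel_a, sel_b)]))
    stop("charges not assigned; run assignChemistry first", call. = FALSE)
  d <- .pairDistances(coords, sel_a, sel_b)
  if (any(d < 0.1))
    stop("atomic clash: cross-selection distance below 0.1 Angstrom",
         call. = FALSE)
  qq <- outer(a$charge[sel_a], a$charge[sel_b])
  sum(ifelse(d < cutoff, COULOMB_KCAL * qq / (dielectric * d), 0))
}

#' Van der Waals (Lennard-Jones) cross-interaction energy
#'
#' Sum over cross pairs within the cutoff of
#' 4 eps [(sigma/r)^12 - (sigma/r)^6] with Lorentz-Berthelot combining
#' (arithmetic sigma, geometric eps), in kcal/mol.
#'
#' @inheritParams coulombEnergy
#' @return energy in kcal/mol.
#' @export
ljEnergy <- function(structure, sel_a, sel_b, cutoff = 12, coords = NULL) {
  a <- atoms(structure)
  if (length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint", call. = FALSE)
  if (is.null(coords)) coords <- as.matrix(a[, c("x", "y", "z")])
  if (anyNA(a$lj_epsilon[c(sel_a, sel_b)]))
    stop("LJ parameters not assigned; run assignChemistry first",
         call. = FALSE)
  d <- .pairDistances(coords, sel_a, sel_b)
  if (any(d < 0.1))
    stop("atomic clash: cross-selection distance below 0.1 Angstrom",
         call. = FALSE)
  eps <- sqrt(outer(a$lj_epsilon[sel_a], a$lj_epsilon[sel_b]))
  sig <- outer(a$lj_sigma[sel_a], a$lj_sigma[sel_b], "+") / 2
  sr6 <- (sig / d)^6
  sum(ifelse(d < cutoff & eps > 0, 4 * eps * (sr6^2 - sr6), 0))
}

#' Energy sampling window arithmetic
#'
#' A window from \code{start} to \code{end} ps sampled every \code{stride}
#' ps yields (end - start) / stride samples (taken at start + stride,
#' start + 2 stride, ..., end); a non-divisible tail is flagged.
#'
#' @param start,end window bounds, ps (end > start).
#' @param stride sampling interval, ps.
#' @return list with \code{start}, \code{end}, \code{stride},
#'   \code{n_samples}, \code{sample_times}, \code{partial_tail}.
#' @examples
#' samplingWindow(53000, 68000, 10)$n_samples  # 1500
#' @export
samplingWindow <- function(start, end, stride) {
  stopifnot(end > start, stride > 0)
  n <- floor((end - start) / stride)
  partial <- abs((end - start) - n * stride) > 1e-9
  list(start = start, end = end, stride = stride, n_samples = as.integer(n),
       sample_times = start + stride * seq_len(n),
       partial_tail = partial)
}

#' Interface energy decomposition over a trajectory window
#'
#' Per-sample electrostatic and van der Waals cross energies between two
#' selections, sampled on the window's stride; frames are matched to the
#' requested sample times (the trajectory must cover the window).
#'
#' @param traj a \code{\linkS4class{Trajectory}} (chemistry assigned on the
#'   topology).
#' @param window a \code{\link{samplingWindow}}.
#' @param sel_a,sel_b disjoint atom selections.
#' @param dielectric relative permittivity.
#' @param cutoff pair cutoff, Angstrom.
#' @return an \code{\linkS4class{EnergyDecomposition}}.
#' @export
interfaceDecomposition <- function(traj, window, sel_a, sel_b,
                                   dielectric = 1, cutoff = 12) {
  if (window$n_samples < 1) stop("empty sampling window", call. = FALSE)
  if (window$start < min(traj@times) - 1e-9 ||
      window$end > max(traj@times) + 1e-9)
    stop("sampling window outside the trajectory time range", call. = FALSE)
  idx <- vapply(window$sample_times,
                function(t) which.min(abs(traj@times - t)), integer(1))
  s <- traj@topology
  E_elec <- E_vdW <- numeric(length(idx))
  for (k in seq_along(idx)) {
    xyz <- frameCoords(traj, idx[k])
    E_elec[k] <- coulombEnergy(s, sel_a, sel_b, dielectric, cutoff, xyz)
    E_vdW[k] <- ljEnergy(s, sel_a, sel_b, cutoff, xyz)
  }
  samples <- data.frame(time_ps = traj@times[idx], E_elec = E_elec,
                        E_vdW = E_vdW)
  methods::new("EnergyDecomposition", samples = samples, summary = c(
    n_samples = length(idx),
    E_elec_mean = mean(E_elec),
    E_elec_sd = if (length(idx) > 1) stats::sd(E_elec) else 0,
    E_vdW_mean = mean(E_vdW),
    E_vdW_sd = if (length(idx) > 1) stats::sd(E_vdW) else 0))
}
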