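## Coarse-grained constant-velocity steered pulling.
##
## The simulator is an overdamped (Brownian) bead-spring analog of the SMD
## protocol: fixed anchor beads, one pulled bead attached to a harmonic
## spring whose anchor moves at constant velocity, and breakable harmonic
## interface bonds (permanently off once their extension exceeds the break
## extension).  Absolute forces are not comparable to all-atom SMD; the
## protocol structure, curve phenomenology and subset/full orderings are.

#' @useDynLib abforce, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Force unit bridge: 1 kcal mol-1 A-1 in pN
#' @export
KCAL_PER_MOL_A_TO_PN <- 69.479

#' Harmonic spring force in pN
#'
#' F = k x extension, converted from kcal mol-1 A-1 to pN.
#'
#' @param k spring constant, kcal mol-1 A-2.
#' @param extension spring extension, Angstrom.
#' @return force in pN.
#' @examples
#' springForce(2.15, 1)  # 149.4 pN
#' @export
springForce <- function(k, extension) {
  k * extension * KCAL_PER_MOL_A_TO_PN
}

#' Convert a per-timestep pulling displacement to A/ps
#'
#' @param step_displacement displacement per integration step, Angstrom.
#' @param timestep_ps integration timestep, ps.
#' @return velocity in A/ps.
#' @examples
#' pullingVelocity(0.00005, 0.002)  # 0.025 A/ps
#' @export
pullingVelocity <- function(step_displacement, timestep_ps) {
  stopifnot(timestep_ps > 0)
  step_displacement / timestep_ps
}

#' Construct a pulling system from explicit beads
#'
#' Low-level constructor; see \code{\link{buildPullingSystem}} for the
#' standard builds from a synthetic complex.  Defaults follow the SMD
#' protocol: spring constant 2.15 kcal mol-1 A-2, pulling velocity
#' 0.025 A/ps (0.00005 A per 2 fs step), timestep 0.002 ps, 310 K.
#'
#' @param positions n x 3 bead coordinates, Angstrom.
#' @param fixed logical vector: beads held immobile.
#' @param pulled index of the bead the moving spring attaches to.
#' @param bonds data.frame (i, j, r0, k, break_ext, breakable); may be empty.
#' @param spring_k,velocity,direction,gamma,temperature,timestep,confine_k
#'   model parameters (see class documentation).
#' @param bead_info optional data.frame describing beads.
#' @return a \code{\linkS4class{PullingSystem}}.
#' @export
pullingSystem <- function(positions, fixed, pulled, bonds = NULL,
                          spring_k = 2.15, velocity = 0.025,
                          direction = c(-1, 0, 0), gamma = 1,
                          temperature = 310, timestep = 0.002,
                          confine_k = 2, bead_info = NULL) {
  positions <- as.matrix(positions)
  if (is.null(bonds))
    bonds <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                        k = numeric(0), break_ext = numeric(0),
                        breakable = logical(0))
  if (is.null(bead_info))
    bead_info <- data.frame(chain = rep(NA_character_, nrow(positions)),
                            resno = NA_integer_, molecule = NA_character_)
  direction <- direction / sqrt(sum(direction^2))
  methods::new("PullingSystem", positions = positions, fixed = fixed,
               pulled = as.integer(pulled), bonds = bonds,
               spring_k = spring_k, velocity = velocity,
               direction = direction, gamma = gamma,
               temperature = temperature, timestep = timestep,
               confine_k = confine_k, bead_info = bead_info)
}

.beadIndex <- function(info, chain, resno) {
  i <- which(info$chain == chain & info$resno == resno)
  if (length(i) != 1)
    stop(sprintf("no unique bead for residue %s_%s", chain, resno),
         call. = FALSE)
  i
}

#' Build a pulling system from a synthetic complex
#'
#' Coarse-grains the complex to one bead per participating residue: the
#' pulled antigen residue, every antigen residue with an interface contact
#' (optionally restricted to a peptide window), their antibody partner
#' residues, and the fixed anchor residues.  Beads are laid out in
#' schematic pulling coordinates (the standard cartoon of an SMD setup):
#' each contact pair sits on the pulling axis at its C-alpha to C-alpha
#' distance from the structure, contact pairs are stacked transversely, the
#' pulled bead is offset behind the antigen beads and the anchors behind
#' the antibody beads.  Scaffold springs (unbreakable, stiffness shared
#' over the arms on the pulled side) tie the antigen contact beads to the
#' pulled bead and each antibody partner bead to its nearest anchor, so the
#' breakable interface bonds load cooperatively along the pulling
#' direction.
#'
#' @param structure a \code{\linkS4class{ComplexStructure}}.
#' @param contacts planted-contact table from \code{\link{makeComplex}}
#'   (columns antigen_pos, partner_chain, partner_resno).
#' @param anchors list of c(chain, resno) pairs fixed in space; default the
#'   last residue of each antibody chain (mimicking the tethered antibody).
#' @param pulled c(chain, resno) of the pulled residue; default the
#'   C-terminal antigen residue.
#' @param window optional c(lo, hi): keep only contacts whose antigen
#'   position lies in the inclusive window (the peptide-only build).
#' @param bond_k interface bond stiffness, kcal mol-1 A-2.
#' @param break_ext interface bond break extension, Angstrom.
#' @param scaffold_k total scaffold stiffness per side, kcal mol-1 A-2.
#' @param hub_offset distance of the pulled bead and anchors behind their
#'   respective sides, Angstrom.
#' @param ... further arguments passed to \code{\link{pullingSystem}}
#'   (spring_k, velocity, temperature, timestep, ...).
#' @return a \code{\linkS4class{PullingSystem}}.
#' @export
buildPullingSystem <- function(structure, contacts, anchors = NULL,
                               pulled = NULL, window = NULL, bond_k = 6,
                               break_ext = 1.6, scaffold_k = 25,
                               hub_offset = 20, ...) {
  a <- atoms(structure)
  ca <- a[a$name == "CA" & a$molecule != "water", ]
  if (!is.null(window))
    contacts <- contacts[contacts$antigen_pos >= window[1] &
                           contacts$antigen_pos <= window[2], , drop = FALSE]
  if (nrow(contacts))
    contacts <- contacts[order(contacts$antigen_pos), , drop = FALSE]
  if (is.null(anchors)) {
    anchors <- list()
    for (ch in c("H", "L")) {
      rs <- ca$resno[ca$chain == ch]
      if (length(rs)) anchors[[length(anchors) + 1]] <- c(ch, max(rs))
    }
  }
  if (is.null(pulled)) {
    ag <- ca[ca$molecule == "antigen", ]
    pulled <- c(ag$chain[which.max(ag$resno)], max(ag$resno))
  }
  key_ca <- paste(ca$chain, ca$resno)
  ca_xyz <- function(chain, resno) {
    i <- match(paste(chain, resno), key_ca)
    if (is.na(i))
      stop(sprintf("pulling system references residue %s_%s without a CA atom",
                   chain, resno), call. = FALSE)
    as.numeric(ca[i, c("x", "y", "z")])
  }
  K <- nrow(contacts)
  info <- list(); pos <- list(); bead_keys <- character(0)
  addBead <- function(chain, resno, molecule, p) {
    info[[length(info) + 1L]] <<- data.frame(
      chain = chain, resno = as.integer(resno), molecule = molecule)
    pos[[length(pos) + 1L]] <<- p
    bead_keys[length(pos)] <<- paste(chain, resno)
    length(pos)
  }
  ## contact pairs on the pulling (x) axis, stacked 2 A apart in y
  ag_idx <- pt_idx <- integer(K)
  d_pair <- numeric(K)
  for (k in seq_len(K)) {
    d_pair[k] <- sqrt(sum((ca_xyz("A", contacts$antigen_pos[k]) -
                             ca_xyz(contacts$partner_chain[k],
                                    contacts$partner_resno[k]))^2))
    yk <- 2 * (k - (K + 1) / 2)
    ag_idx[k] <- addBead("A", contacts$antigen_pos[k], "antigen",
                         c(0, yk, 0))
    pt_idx[k] <- addBead(contacts$partner_chain[k], contacts$partner_resno[k],
                         if (contacts$partner_chain[k] == "H") "heavy_chain"
                         else "light_chain", c(d_pair[k], yk, 0))
  }
  ## pulled bead behind the antigen side (unless it is itself a contact)
  pulled_key <- paste(pulled[1], pulled[2])
  ip <- if (pulled[1] == "A" && as.integer(pulled[2]) %in% contacts$antigen_pos)
    ag_idx[match(as.integer(pulled[2]), contacts$antigen_pos)]
  else {
    mol <- ca$molecule[match(pulled_key, key_ca)]
    if (is.na(mol)) ca_xyz(pulled[1], pulled[2])  # raises the error
    addBead(pulled[1], pulled[2], mol, c(-hub_offset, 0, 0))
  }
  ## anchors behind the antibody side; an anchor that is already a bead
  ## (a contact partner or the pulled residue) is reused, not duplicated
  x_anchor <- (if (K) max(d_pair) else hub_offset) + hub_offset
  anchor_idx <- integer(0)
  for (ai in seq_along(anchors)) {
    p <- anchors[[ai]]
    existing <- match(paste(p[1], p[2]), bead_keys)
    if (!is.na(existing)) {
      anchor_idx <- c(anchor_idx, existing)
      next
    }
    mol <- ca$molecule[match(paste(p[1], p[2]), key_ca)]
    if (is.na(mol)) ca_xyz(p[1], p[2])  # raises the error
    anchor_idx <- c(anchor_idx, addBead(p[1], p[2], mol,
                                        c(x_anchor, 2 * (ai - 1), 0)))
  }
  pos <- do.call(rbind, pos)
  info <- do.call(rbind, info)
  fixed <- rep(FALSE, nrow(pos))
  fixed[anchor_idx] <- TRUE
  if (fixed[ip]) stop("the pulled bead cannot also be fixed", call. = FALSE)

  bonds <- list()
  addBond <- function(i, j, k, bext, brk)
    bonds[[length(bonds) + 1]] <<- data.frame(
      i = i, j = j, r0 = sqrt(sum((pos[i, ] - pos[j, ])^2)), k = k,
      break_ext = bext, breakable = brk)
  for (k in seq_len(K)) {
    addBond(ag_idx[k], pt_idx[k], bond_k, break_ext, TRUE)
    if (ag_idx[k] != ip)
      addBond(ip, ag_idx[k], scaffold_k / K, Inf, FALSE)
    near <- anchor_idx[which.min(colSums((t(pos[anchor_idx, , drop = FALSE]) -
                                            pos[pt_idx[k], ])^2))]
    addBond(pt_idx[k], near, scaffold_k, Inf, FALSE)
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else NULL
  pullingSystem(pos, fixed, ip, bonds, direction = c(-1, 0, 0),
                bead_info = info, ...)
}

#' Run one constant-velocity pulling simulation
#'
#' Integrates the overdamped Langevin dynamics of the system while the
#' spring anchor advances at constant velocity, recording the projected
#' spring force.  Separation is declared when every breakable bond is
#' broken and the pulled bead is \code{sep_dist} past its bound position
#' along the pulling direction; the rupture force is the maximum recorded
#' force before separation.  A run that never separates is returned flagged
#' unruptured, not as an error.
#'
#' @param system a \code{\linkS4class{PullingSystem}}.
#' @param duration simulated time, ps (default 3000 = the 3 ns protocol).
#' @param record_every force-recording interval, ps.
#' @param seed optional integer seed for the thermal noise.
#' @param sep_dist separation distance past the bound position, Angstrom.
#' @param early_stop stop integrating shortly after separation?
#' @param stop_after grace time after separation when early-stopping, ps.
#' @return list with \code{curve} (a \code{\linkS4class{ForceCurve}}, kind
#'   smd) and \code{event} (a \code{\linkS4class{RuptureEvent}}).
#' @export
runPulling <- function(system, duration = 3000, record_every = 0.5,
                       seed = NULL, sep_dist = 10, early_stop = TRUE,
                       stop_after = 50) {
  methods::validObject(system)
  if (!is.null(seed)) set.seed(seed)
  b <- system@bonds
  res <- .cgPull(system@positions, system@fixed, system@pulled,
                 as.integer(b$i), as.integer(b$j), as.numeric(b$r0),
                 as.numeric(b$k), as.numeric(b$break_ext),
                 as.logical(b$breakable), system@spring_k, system@velocity,
                 system@direction, system@gamma, system@temperature,
                 system@timestep, duration, record_every, sep_dist,
                 early_stop, stop_after, system@confine_k)
  curve <- methods::new("ForceCurve", kind = "smd", abscissa = res$time,
                        force = res$force_pN,
                        meta = list(seed = seed,
                                    extension_A = res$extension_A,
                                    separation_time = res$separation_time,
                                    max_force_pN = res$max_force_pN))
  ruptured <- res$separation_time >= 0
  phases <- c(maintenance_end = res$max_force_time,
              detachment_end = if (ruptured) res$separation_time else NA_real_)
  event <- methods::new("RuptureEvent",
                        rupture_force = if (ruptured) res$max_force_pN else NA_real_,
                        rupture_time = if (ruptured) res$max_force_time else NA_real_,
                        ruptured = ruptured, phases = phases,
                        meta = list(seed = seed,
                                    first_break_time = res$first_break_time,
                                    all_broken_time = res$all_broken_time,
                                    separation_time = res$separation_time))
  list(curve = curve, event = event)
}

#' Run replicate pulling simulations
#'
#' Runs \code{n} independent replicates of the same system, each on its own
#' thermal-noise sub-stream derived from the master seed, mirroring the
#' 20 x 3 ns replicate protocol.
#'
#' @param system a \code{\linkS4class{PullingSystem}}.
#' @param n number of replicates (default 20).
#' @param seed master seed.
#' @param ... passed to \code{\link{runPulling}}.
#' @return list with \code{events} (list of RuptureEvent), \code{curves}
#'   (list of ForceCurve) and \code{seeds}.
#' @export
runReplicates <- function(system, n = 20, seed = 1, ...) {
  seeds <- vapply(seq_len(n), function(i) .splitSeed(seed, 100L + i),
                  integer(1))
  runs <- lapply(seeds, function(s) runPulling(system, seed = s, ...))
  list(events = lapply(runs, `[[`, "event"),
       curves = lapply(runs, `[[`, "curve"), seeds = seeds)
}

#' Descriptive statistics over replicate rupture events
#'
#' Unruptured events are excluded from the statistics and counted.
#'
#' @param events list of \code{\linkS4class{RuptureEvent}}.
#' @return list with n, n_unruptured, mean, sd (sample SD), median, q1, q3
#'   of the rupture forces (pN) and mean rupture time (ps).
#' @export
replicateStats <- function(events) {
  ruptured <- Filter(function(e) e@ruptured, events)
  if (length(ruptured) < 2)
    stop("fewer than 2 ruptured events; increase the simulation duration",
         call. = FALSE)
  f <- vapply(ruptured, function(e) e@rupture_force, numeric(1))
  t <- vapply(ruptured, function(e) e@rupture_time, numeric(1))
  q <- stats::quantile(f, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(ruptured), n_unruptured = length(events) - length(ruptured),
       mean = mean(f), sd = stats::sd(f), median = q[2], q1 = q[1], q3 = q[3],
       mean_rupture_time = mean(t))
}
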