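## Generators for every input the pipeline needs: annotated antigen-antibody
## complexes with planted interface contacts, noisy multi-frame trajectories
## with tunable contact persistence, and AFM-style retract curves with planted
## adhesion events.  All generators are pure functions of (spec, seed).

## Evaluate expr under a temporary RNG state seeded from `seed`, restoring
## the caller's stream afterwards.  Sub-streams are derived from the master
## seed by the splitting rule seed * 1000003 + offset (mod 2^31 - 1).
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.splitSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

#' Specification of a synthetic antigen-antibody complex
#'
#' Describes a two-chain interface (plus light chain and a decorative water
#' shell) with planted hydrogen bonds and salt bridges whose geometry
#' satisfies the detection criteria by construction at zero noise: donor and
#' acceptor on the planted distance with the hydrogen on the donor-acceptor
#' axis (H-D-A angle 0), and salt-bridge hydrogens turned well away from the
#' O-N axis so a planted bridge never doubles as a hydrogen bond.
#'
#' @param n_antigen_res,n_heavy_res,n_light_res,n_waters residue/water counts.
#' @param planted_hbonds data.frame (antigen_pos, antibody_pos, distance):
#'   donor-acceptor distances in Angstrom, each within (2.4, 3.5).  Antibody
#'   positions 1..n_heavy_res are on the heavy chain, the rest on the light
#'   chain (position - n_heavy_res).
#' @param planted_saltbridges data.frame (acidic_pos, basic_pos, distance):
#'   O-N distances within (2.5, 3.2); acidic on the antigen, basic on the
#'   antibody (same position convention).
#' @param cdr_windows named list of inclusive position ranges c(start, end)
#'   on the antibody chains, names among l1, l2, l3, h1, h2, h3 (l* on the
#'   light chain, h* on the heavy chain numbering).
#' @param antigen_windows data.frame (label, start, end): peptide windows on
#'   the antigen (inclusive author positions).
#' @param seed integer master seed.
#' @return a list of class \code{complex_spec}.
#' @export
complexSpec <- function(n_antigen_res = 110, n_heavy_res = 60,
                        n_light_res = 60, n_waters = 40,
                        planted_hbonds = NULL, planted_saltbridges = NULL,
                        cdr_windows = NULL, antigen_windows = NULL,
                        seed = 1L) {
  if (is.null(planted_hbonds)) planted_hbonds <- .defaultPlantedHbonds()
  if (is.null(planted_saltbridges)) planted_saltbridges <- .defaultPlantedSaltbridges()
  if (is.null(cdr_windows)) cdr_windows <- .defaultCdrWindows()
  if (is.null(antigen_windows))
    antigen_windows <- data.frame(
      label = c("win_1_22", "win_35_55", "win_92_106"),
      start = c(1L, 35L, 92L), end = c(22L, 55L, 106L))
  spec <- list(n_antigen_res = n_antigen_res, n_heavy_res = n_heavy_res,
               n_light_res = n_light_res, n_waters = n_waters,
               planted_hbonds = planted_hbonds,
               planted_saltbridges = planted_saltbridges,
               cdr_windows = cdr_windows, antigen_windows = antigen_windows,
               seed = as.integer(seed))
  class(spec) <- "complex_spec"
  .validateComplexSpec(spec)
  spec
}

## Default study conditions: 13 planted interface hydrogen bonds at the
## antigen anchor positions of the MOG-like system (ranked order), seven of
## them to CDR partner residues, plus 3 salt bridges.
.defaultPlantedHbonds <- function() {
  data.frame(
    antigen_pos = c(108L, 1L, 104L, 103L, 53L, 33L, 102L, 106L, 107L,
                    52L, 4L, 105L, 40L),
    ## heavy chain h3 = 25..32, h2 = 15..20; l3 = 25..32 on the light
    ## chain (offset +60); the rest framework, so the occupancy-weighted
    ## CDR share of interface bonds sits near 60%
    antibody_pos = c(27L, 28L, 29L, 16L, 17L, 45L, 30L, 48L, 60L + 26L,
                     46L, 47L, 49L, 60L + 40L),
    distance = 2.80 + 0.04 * (0:12)
  )
}

.defaultPlantedSaltbridges <- function() {
  data.frame(acidic_pos = c(10L, 60L, 90L),
             basic_pos = c(12L, 35L, 60L + 35L),
             distance = c(2.9, 3.0, 3.1))
}

.defaultCdrWindows <- function() {
  list(h1 = c(5L, 10L), h2 = c(15L, 20L), h3 = c(25L, 32L),
       l1 = c(5L, 10L), l2 = c(15L, 20L), l3 = c(25L, 32L))
}

.validateComplexSpec <- function(spec) {
  hb <- spec$planted_hbonds; sb <- spec$planted_saltbridges
  if (nrow(hb) && (any(hb$distance <= 2.4) || any(hb$distance >= 3.5)))
    stop("planted hydrogen-bond distances must lie within (2.4, 3.5) Angstrom",
         call. = FALSE)
  if (nrow(sb) && (any(sb$distance <= 2.5) || any(sb$distance >= 3.2)))
    stop("planted salt-bridge distances must lie within (2.5, 3.2) Angstrom",
         call. = FALSE)
  ag <- c(hb$antigen_pos, sb$acidic_pos)
  ab <- c(hb$antibody_pos, sb$basic_pos)
  if (anyDuplicated(ag) || anyDuplicated(ab))
    stop("contradictory planting: the same residue appears in two contacts",
         call. = FALSE)
  n_ab <- spec$n_heavy_res + spec$n_light_res
  if (any(ag < 1 | ag > spec$n_antigen_res) || any(ab < 1 | ab > n_ab))
    stop("planted contact positions outside the chain ranges", call. = FALSE)
  invisible(spec)
}

.abChain <- function(pos, n_heavy) {
  ifelse(pos <= n_heavy, "H", "L")
}
.abResno <- function(pos, n_heavy) {
  ifelse(pos <= n_heavy, pos, pos - n_heavy)
}

#' Generate a synthetic antigen-antibody complex
#'
#' Builds two facing chains (plus a light chain and a sparse water shell)
#' on a regular lattice with planted contact geometries at the specified
#' distances and in-criterion angles; deterministic for a fixed seed.
#' Planted-contact residues carry only the atoms the contact needs (CA plus
#' the donor/acceptor group), filler residues carry a minimal backbone
#' (N with amide H, CA, carbonyl O), so every planted contact is recovered
#' exactly at zero noise and nothing else crosses the interface.
#'
#' @param spec a \code{\link{complexSpec}}.
#' @return list with elements \code{structure}
#'   (\code{\linkS4class{ComplexStructure}}, chemistry assigned),
#'   \code{annotation} (\code{\linkS4class{RegionAnnotation}}) and
#'   \code{contacts} (data.frame describing the planted contacts: type,
#'   antigen position, partner chain/resno, donor/acceptor atom serials,
#'   planted distance, criterion threshold).
#' @export
makeComplex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  .validateComplexSpec(spec)
  n_heavy <- spec$n_heavy_res
  rows <- list()
  serial <- 0L
  add <- function(name, element, resname, chain, resno, molecule, pos) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      chain = chain, resno = as.integer(resno), molecule = molecule,
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
    serial
  }

  hb <- spec$planted_hbonds
  sb <- spec$planted_saltbridges
  ag_contact <- c(hb$antigen_pos, sb$acidic_pos)
  ab_contact <- c(hb$antibody_pos, sb$basic_pos)

  ## filler residues: minimal backbone on a 5 A lattice; antigen plane x=0,
  ## antibody back plane x=8, z=6 (contact partners sit on the z=0 interface
  ## row, keyed to the antigen partner's y so the planted distance holds)
  filler <- function(resno, chain, molecule, base) {
    add("N", "N", "GLY", chain, resno, molecule, base + c(-1, 0, 0))
    add("H", "H", "GLY", chain, resno, molecule, base + c(-2, 0, 0))
    add("CA", "C", "GLY", chain, resno, molecule, base)
    add("O", "O", "GLY", chain, resno, molecule, base + c(1, 0, 0))
  }
  for (i in seq_len(spec$n_antigen_res)) {
    if (i %in% ag_contact) next
    filler(i, "A", "antigen", c(0, 5 * i, 0))
  }
  for (j in seq_len(n_heavy)) {
    if (j %in% ab_contact) next
    filler(j, "H", "heavy_chain", c(9, 5 * j, 6))
  }
  for (j in seq_len(spec$n_light_res)) {
    if ((j + n_heavy) %in% ab_contact) next
    filler(j, "L", "light_chain", c(9, 5 * j, 12))
  }

  contacts <- list()
  ## planted hydrogen bonds: acceptor ASN OD1 on the antigen, donor SER OG
  ## (with HG on the O...O axis) on the antibody
  for (k in seq_len(nrow(hb))) {
    i <- hb$antigen_pos[k]; p <- hb$antibody_pos[k]; d <- hb$distance[k]
    ch <- .abChain(p, n_heavy); rn <- .abResno(p, n_heavy)
    mol <- if (ch == "H") "heavy_chain" else "light_chain"
    y <- 5 * i
    add("CA", "C", "ASN", "A", i, "antigen", c(0, y, 0))
    acc <- add("OD1", "O", "ASN", "A", i, "antigen", c(1.5, y, 0))
    add("CA", "C", "SER", ch, rn, mol, c(8, y, 0))
    don <- add("OG", "O", "SER", ch, rn, mol, c(1.5 + d, y, 0))
    add("HG", "H", "SER", ch, rn, mol, c(0.5 + d, y, 0))
    contacts[[length(contacts) + 1L]] <- data.frame(
      type = "hbond", antigen_pos = i, partner_chain = ch, partner_resno = rn,
      donor_serial = don, acceptor_serial = acc, distance = d, threshold = 3.5)
  }
  ## planted salt bridges: ASP OD1 (antigen) vs LYS NZ (antibody); the NZ
  ## hydrogens are orthogonal to the O-N axis so no hydrogen bond is counted
  for (k in seq_len(nrow(sb))) {
    i <- sb$acidic_pos[k]; p <- sb$basic_pos[k]; d <- sb$distance[k]
    ch <- .abChain(p, n_heavy); rn <- .abResno(p, n_heavy)
    mol <- if (ch == "H") "heavy_chain" else "light_chain"
    y <- 5 * i
    add("CA", "C", "ASP", "A", i, "antigen", c(0, y, 0))
    acc <- add("OD1", "O", "ASP", "A", i, "antigen", c(1.5, y, 0))
    add("OD2", "O", "ASP", "A", i, "antigen", c(0.5, y - 1.3, 0))
    add("CA", "C", "LYS", ch, rn, mol, c(8, y, 0))
    ## NZ hydrogens point 120 degrees away from the O...N axis so the
    ## planted bridge can never double as a hydrogen bond, noise included
    nz <- add("NZ", "N", "LYS", ch, rn, mol, c(1.5 + d, y, 0))
    add("HZ1", "H", "LYS", ch, rn, mol, c(2.0 + d, y + 0.866, 0))
    add("HZ2", "H", "LYS", ch, rn, mol, c(2.0 + d, y - 0.433, 0.75))
    add("HZ3", "H", "LYS", ch, rn, mol, c(2.0 + d, y - 0.433, -0.75))
    contacts[[length(contacts) + 1L]] <- data.frame(
      type = "saltbridge", antigen_pos = i, partner_chain = ch,
      partner_resno = rn, donor_serial = nz, acceptor_serial = acc,
      distance = d, threshold = 3.2)
  }

  atoms <- do.call(rbind, rows)
  ## decorative water shell: odd waters 4-8 A from the interface midplane
  ## (x = 3), even waters hydrogen-bonded to a random filler carbonyl O
  ## (one water H on the O...O axis), all rejection-sampled to stay
  ## >= 2.5 A from everything already placed
  if (spec$n_waters > 0) {
    prot <- as.matrix(atoms[, c("x", "y", "z")])
    filler_o <- which(atoms$name == "O" & atoms$resname == "GLY")
    wat <- .withSeed(.splitSeed(spec$seed, 11L), {
      placed <- 0L; out <- list(); tries <- 0L
      while (placed < spec$n_waters && tries < spec$n_waters * 200L) {
        tries <- tries + 1L
        bonded <- placed %% 2L == 1L && length(filler_o) > 0
        if (bonded) {
          tgt <- prot[sample(filler_o, 1L), ]
          u <- c(1, stats::runif(1, -0.3, 0.3), stats::runif(1, -0.3, 0.3))
          u <- u / sqrt(sum(u^2))
          o <- tgt + u * stats::runif(1, 2.7, 3.3)
          hdir <- -u   # H1 points back at the carbonyl O: angle 0
        } else {
          side <- if (stats::runif(1) < 0.5) -1 else 1
          o <- c(3 + side * stats::runif(1, 4, 8),
                 stats::runif(1, 0, 5 * spec$n_antigen_res),
                 stats::runif(1, -3, 3))
          hdir <- c(0.6, 0.8, 0)
        }
        dmin2 <- min(colSums((t(prot) - o)^2))
        if (length(out))
          dmin2 <- min(dmin2, min(vapply(out, function(w)
            sum((w$o - o)^2), numeric(1))))
        if (dmin2 < 2.5^2) next
        placed <- placed + 1L
        out[[placed]] <- list(o = o, hdir = hdir)
      }
      out
    })
    for (w in seq_along(wat)) {
      o <- wat[[w]]$o; hdir <- wat[[w]]$hdir
      perp <- c(-hdir[2], hdir[1], 0)
      if (sum(perp^2) < 1e-6) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      add("O", "O", "HOH", "W", w, "water", o)
      add("H1", "H", "HOH", "W", w, "water", o + hdir)
      add("H2", "H", "HOH", "W", w, "water", o + perp)
    }
    atoms <- do.call(rbind, rows)
  }

  structure <- assignChemistry(complexStructure(atoms))
  annotation <- .makeAnnotation(spec)
  list(structure = structure, annotation = annotation,
       contacts = if (length(contacts)) do.call(rbind, contacts) else
         data.frame())
}

.makeAnnotation <- function(spec) {
  n_var <- 35L
  n_ch <- c(H = spec$n_heavy_res, L = spec$n_light_res)
  cdr <- list()
  for (nm in names(spec$cdr_windows)) {
    w <- spec$cdr_windows[[nm]]
    ch <- if (startsWith(nm, "h")) "H" else "L"
    hi <- min(w[2], n_var, n_ch[[ch]])
    if (w[1] > hi) next
    cdr[[nm]] <- data.frame(chain = ch, resno = seq.int(w[1], hi))
  }
  reg <- function(ch, from, to) {
    if (from > to) return(NULL)
    data.frame(chain = ch, resno = seq.int(from, to))
  }
  variable <- rbind(reg("H", 1L, min(n_var, n_ch[["H"]])),
                    reg("L", 1L, min(n_var, n_ch[["L"]])))
  constant <- rbind(reg("H", n_var + 1L, n_ch[["H"]]),
                    reg("L", n_var + 1L, n_ch[["L"]]))
  if (is.null(constant))
    constant <- data.frame(chain = character(0), resno = integer(0))
  methods::new("RegionAnnotation", cdr = cdr, variable = variable,
               constant = constant, windows = spec$antigen_windows)
}

#' Specification of a synthetic trajectory
#'
#' @param n_frames number of frames (frame 1 is the input structure).
#' @param frame_interval time between frames, ps.
#' @param noise_sigma per-coordinate Gaussian positional noise, Angstrom.
#' @param contact_persistence probability that a planted contact satisfies
#'   its criterion in a frame; scalar or one value per planted contact.
#' @param drift_amplitude slow global deformation amplitude, Angstrom;
#'   applied as a half-sine over the trajectory along +x.
#' @param drift_selection optional integer atom indices the drift acts on
#'   (default: all atoms when drift_amplitude > 0).
#' @param seed integer seed.
#' @return a list of class \code{trajectory_spec}.
#' @export
trajectorySpec <- function(n_frames = 200L, frame_interval = 100,
                           noise_sigma = 0.1, contact_persistence = 1,
                           drift_amplitude = 0, drift_selection = NULL,
                           seed = 1L) {
  stopifnot(n_frames >= 1, frame_interval > 0, noise_sigma >= 0,
            all(contact_persistence >= 0), all(contact_persistence <= 1),
            drift_amplitude >= 0)
  spec <- list(n_frames = as.integer(n_frames),
               frame_interval = frame_interval, noise_sigma = noise_sigma,
               contact_persistence = contact_persistence,
               drift_amplitude = drift_amplitude,
               drift_selection = drift_selection, seed = as.integer(seed))
  class(spec) <- "trajectory_spec"
  spec
}

#' Generate a noisy trajectory over a constant topology
#'
#' Frame 1 equals the input structure.  Each later frame adds i.i.d.
#' Gaussian noise per coordinate plus an optional slow drift.  Each planted
#' contact is, independently per frame, within-criterion with probability
#' \code{contact_persistence}: in a kept frame the acceptor is placed at the
#' planted distance along the contact axis (so detection is unambiguous
#' under noise); in a broken frame it is displaced along the axis to 1.2x
#' the criterion threshold.
#'
#' @param structure a \code{\linkS4class{ComplexStructure}} (frame 1).
#' @param spec a \code{\link{trajectorySpec}}.
#' @param planted optional planted-contact table from \code{\link{makeComplex}}.
#' @return a \code{\linkS4class{Trajectory}}.
#' @export
makeTrajectory <- function(structure, spec, planted = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  a <- atoms(structure)
  base <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(base); nf <- spec$n_frames
  coords <- array(0, dim = c(n, 3, nf))
  coords[, , 1] <- base
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  p <- spec$contact_persistence
  if (n_planted > 0) {
    p <- if (length(p) == 1) rep(p, n_planted) else p
    if (length(p) != n_planted)
      stop("contact_persistence must be scalar or one value per planted contact",
           call. = FALSE)
    don_idx <- match(planted$donor_serial, a$serial)
    acc_idx <- match(planted$acceptor_serial, a$serial)
    axis <- base[acc_idx, , drop = FALSE] - base[don_idx, , drop = FALSE]
    axis <- axis / sqrt(rowSums(axis^2))
  }
  drift_sel <- spec$drift_selection
  if (is.null(drift_sel)) drift_sel <- seq_len(n)
  .withSeed(.splitSeed(spec$seed, 23L), {
    for (f in seq_len(nf)[-1]) {
      fr <- base + matrix(stats::rnorm(n * 3, sd = spec$noise_sigma), n, 3)
      if (spec$drift_amplitude > 0) {
        shift <- spec$drift_amplitude * sin(pi * (f - 1) / (nf - 1))
        fr[drift_sel, 1] <- fr[drift_sel, 1] + shift
      }
      if (n_planted > 0) {
        keep <- stats::runif(n_planted) < p
        d_target <- ifelse(keep, planted$distance, 1.2 * planted$threshold)
        fr[acc_idx, ] <- fr[don_idx, ] + axis * d_target
      }
      coords[, , f] <- fr
    }
  })
  methods::new("Trajectory", topology = structure, coords = coords,
               times = (seq_len(nf) - 1) * spec$frame_interval)
}

#' Specification of a synthetic AFM retract curve
#'
#' @param adhesion_pN planted adhesion force Fad, pN (>= 0).
#' @param contact_slope contact-regime slope, pN/nm.
#' @param pulloff_position tip-sample position of the pull-off event, nm.
#' @param noise_pN additive Gaussian force noise SD, pN.
#' @param n_points number of points (>= 50).
#' @param seed integer seed.
#' @return a list of class \code{afm_curve_spec}.
#' @export
afmCurveSpec <- function(adhesion_pN = 765, contact_slope = 500,
                         pulloff_position = 20, noise_pN = 10,
                         n_points = 400L, seed = 1L) {
  stopifnot(adhesion_pN >= 0, n_points >= 50, pulloff_position > 0,
            noise_pN >= 0)
  spec <- list(adhesion_pN = adhesion_pN, contact_slope = contact_slope,
               pulloff_position = pulloff_position, noise_pN = noise_pN,
               n_points = as.integer(n_points), seed = as.integer(seed))
  class(spec) <- "afm_curve_spec"
  spec
}

#' Generate a synthetic AFM retract curve
#'
#' Retract trace versus tip-sample position: the contact line descends at
#' \code{contact_slope} through zero into the adhesion branch, reaching
#' -Fad exactly at the pull-off position, where the tip snaps off to a
#' zero-force baseline; additive Gaussian noise throughout.  The grid is
#' adjusted to contain the pull-off position exactly and the descent into
#' the well is steep (the contact slope), so the planted Fad is recovered
#' exactly at zero noise and without bias under noise.
#'
#' @param spec an \code{\link{afmCurveSpec}}.
#' @return a \code{\linkS4class{ForceCurve}} of kind \code{afm_retract}.
#' @export
makeAfmCurve <- function(spec) {
  stopifnot(inherits(spec, "afm_curve_spec"))
  po <- spec$pulloff_position
  z0 <- po - spec$adhesion_pN / spec$contact_slope  # zero-force crossing
  z <- seq(z0 - 0.3 * po, 2 * po, length.out = spec$n_points)
  z[which.min(abs(z - po))] <- po  # pull-off point lands on the grid
  f <- ifelse(z <= po, -spec$contact_slope * (z - z0), 0)
  if (spec$noise_pN > 0)
    f <- f + .withSeed(.splitSeed(spec$seed, 37L),
                       stats::rnorm(length(z), sd = spec$noise_pN))
  methods::new("ForceCurve", kind = "afm_retract", abscissa = z, force = f,
               meta = list(spec = spec))
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeTrajectoryPDB <- function(traj, file) {
  s <- traj@topology
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(traj))) {
    a <- atoms(s)
    a[, c("x", "y", "z")] <- frameCoords(traj, f)
    s2 <- methods::new("ComplexStructure", atoms = a)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- writePDB(s2)
    writeLines(lines[lines != "END"], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
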