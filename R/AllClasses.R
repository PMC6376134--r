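#' @import methods
NULL

.MOLECULE_LABELS <- c("antigen", "heavy_chain", "light_chain", "water")

.ATOM_COLUMNS <- c(
  "serial", "name", "element", "resname", "chain", "resno", "inscode",
  "molecule", "x", "y", "z", "charge", "lj_epsilon", "lj_sigma",
  "role_hydrogen", "role_donor", "role_acceptor", "role_acidic_o",
  "role_basic_n", "hparent"
)

#' ComplexStructure: one coordinate frame of an antigen-antibody complex
#'
#' Atoms are stored as one data.frame (one row per atom) with author (file)
#' residue numbering, molecule labels (\code{antigen}, \code{heavy_chain},
#' \code{light_chain}, \code{water}), coordinates in Angstrom, and chemistry
#' annotation columns (roles, partial charges, Lennard-Jones parameters)
#' populated by \code{\link{assignChemistry}}.
#'
#' @slot atoms data.frame with one row per atom; see \code{\link{atoms}}.
#' @export
setClass("ComplexStructure", representation(atoms = "data.frame"))

setValidity("ComplexStructure", function(object) {
  a <- object@atoms
  msgs <- character()
  missing_cols <- setdiff(.ATOM_COLUMNS, names(a))
  if (length(missing_cols))
    return(paste("atoms is missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(a)) {
    if (anyDuplicated(a$serial)) msgs <- c(msgs, "atom serials must be unique")
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      msgs <- c(msgs, "coordinates must be finite")
    if (!all(a$molecule %in% .MOLECULE_LABELS))
      msgs <- c(msgs, paste("molecule labels must be in:",
                            paste(.MOLECULE_LABELS, collapse = ", ")))
    hyd <- which(a$role_hydrogen)
    if (length(hyd)) {
      if (!all(a$element[hyd] == "H"))
        msgs <- c(msgs, "atoms with role hydrogen must have element H")
      if (anyNA(a$hparent[hyd]))
        msgs <- c(msgs, "atoms with role hydrogen must have a heavy-atom parent")
    }
    if (any(a$role_acidic_o & a$element != "O"))
      msgs <- c(msgs, "acidic_oxygen role only on O atoms")
    if (any(a$role_basic_n & a$element != "N"))
      msgs <- c(msgs, "basic_nitrogen role only on N atoms")
    key <- paste(a$chain, a$resno, a$inscode, a$name)
    if (anyDuplicated(key))
      msgs <- c(msgs, "atom names must be unique within a residue")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' RegionAnnotation: CDR loops, framework regions and peptide windows
#'
#' Named residue sets on a \code{\linkS4class{ComplexStructure}}: the six CDR
#' loops (l1, l2, l3, h1, h2, h3) and the variable/constant split of the
#' antibody, each a data.frame with columns \code{chain} and \code{resno},
#' plus inclusive peptide-position windows on the antigen.
#'
#' @slot cdr named list of data.frames (chain, resno), names among
#'   l1, l2, l3, h1, h2, h3.
#' @slot variable data.frame (chain, resno) of variable-region residues.
#' @slot constant data.frame (chain, resno) of constant-region residues.
#' @slot windows data.frame (label, start, end), inclusive antigen positions.
#' @export
setClass("RegionAnnotation", representation(
  cdr = "list", variable = "data.frame", constant = "data.frame",
  windows = "data.frame"
))

setValidity("RegionAnnotation", function(object) {
  msgs <- character()
  ok_names <- c("l1", "l2", "l3", "h1", "h2", "h3")
  if (length(object@cdr) && !all(names(object@cdr) %in% ok_names))
    msgs <- c(msgs, paste("cdr names must be among:", paste(ok_names, collapse = ", ")))
  for (nm in names(object@cdr)) {
    df <- object@cdr[[nm]]
    if (!all(c("chain", "resno") %in% names(df)))
      msgs <- c(msgs, sprintf("cdr$%s must have chain and resno columns", nm))
  }
  if (nrow(object@variable) && length(object@cdr)) {
    vkey <- paste(object@variable$chain, object@variable$resno)
    for (nm in names(object@cdr)) {
      ckey <- paste(object@cdr[[nm]]$chain, object@cdr[[nm]]$resno)
      if (!all(ckey %in% vkey))
        msgs <- c(msgs, sprintf("cdr set %s is not contained in the variable region", nm))
    }
  }
  w <- object@windows
  if (nrow(w)) {
    if (!all(c("label", "start", "end") %in% names(w)))
      msgs <- c(msgs, "windows must have label/start/end columns")
    else if (any(w$start > w$end))
      msgs <- c(msgs, "window start must be <= end")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Trajectory: ordered coordinate frames over a constant topology
#'
#' @slot topology the \code{\linkS4class{ComplexStructure}} whose atoms the
#'   frames move (frame 1 equals its coordinates for generated trajectories).
#' @slot coords numeric array n_atoms x 3 x n_frames, Angstrom.
#' @slot times numeric vector of frame timestamps, ps.
#' @export
setClass("Trajectory", representation(
  topology = "ComplexStructure", coords = "array", times = "numeric"
))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@topology@atoms))
    return("coords first dimension must match the topology atom count")
  if (d[3] != length(object@times))
    return("times length must match the number of frames")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  TRUE
})

#' ForceCurve: a force trace from pulling simulation or AFM
#'
#' @slot kind one of \code{smd}, \code{afm_approach}, \code{afm_retract}.
#' @slot abscissa time in ps (smd) or tip-sample position in nm (afm);
#'   strictly monotone.
#' @slot force force in pN, same length as abscissa.
#' @slot meta list of provenance metadata (seed, generating spec, ...).
#' @export
setClass("ForceCurve", representation(
  kind = "character", abscissa = "numeric", force = "numeric", meta = "list"
))

setValidity("ForceCurve", function(object) {
  if (!object@kind %in% c("smd", "afm_approach", "afm_retract"))
    return("kind must be smd, afm_approach or afm_retract")
  if (length(object@abscissa) != length(object@force))
    return("abscissa and force must have equal length")
  if (length(object@abscissa) < 2)
    return("a force curve needs at least 2 points")
  dd <- diff(object@abscissa)
  if (!(all(dd > 0) || all(dd < 0)))
    return("abscissa must be strictly monotone")
  TRUE
})

#' RuptureEvent: the unbinding event extracted from a pulling run
#'
#' @slot rupture_force peak force (pN) recorded before full separation;
#'   NA when unruptured.
#' @slot rupture_time time (ps) of that peak; NA when unruptured.
#' @slot ruptured logical; FALSE when the run ended with bonds intact or the
#'   pulled group still bound.
#' @slot phases named numeric vector of phase boundary times (ps):
#'   maintenance_end, detachment_end (complex maintenance / detachment /
#'   separation phases).
#' @slot meta list (replicate seed, system summary).
#' @export
setClass("RuptureEvent", representation(
  rupture_force = "numeric", rupture_time = "numeric", ruptured = "logical",
  phases = "numeric", meta = "list"
))

#' PullingSystem: coarse-grained constant-velocity pulling state
#'
#' One bead per residue; breakable harmonic interface bonds; a harmonic spring
#' whose anchor moves at constant velocity along the pulling direction.
#'
#' @slot positions n x 3 bead coordinates, Angstrom.
#' @slot fixed logical, beads held immobile (anchor residues).
#' @slot pulled integer index of the bead attached to the moving spring.
#' @slot bonds data.frame (i, j, r0, k, break_ext, breakable): harmonic bonds;
#'   breakable bonds are removed permanently once extension exceeds break_ext.
#' @slot spring_k spring constant, kcal mol-1 A-2 (default 2.15).
#' @slot velocity pulling velocity, A/ps (default 0.025).
#' @slot direction unit 3-vector along which the spring anchor moves.
#' @slot gamma friction, kcal mol-1 ps A-2.
#' @slot temperature Kelvin.
#' @slot timestep integration step, ps.
#' @slot confine_k weak harmonic confinement of mobile beads about their
#'   initial positions, acting only perpendicular to the pulling direction
#'   (a crowding surrogate for the surrounding protein matrix);
#'   kcal mol-1 A-2, 0 disables.
#' @slot bead_info data.frame describing each bead (chain, resno, molecule).
#' @export
setClass("PullingSystem", representation(
  positions = "matrix", fixed = "logical", pulled = "integer",
  bonds = "data.frame", spring_k = "numeric", velocity = "numeric",
  direction = "numeric", gamma = "numeric", temperature = "numeric",
  timestep = "numeric", confine_k = "numeric", bead_info = "data.frame"
))

setValidity("PullingSystem", function(object) {
  n <- nrow(object@positions)
  msgs <- character()
  if (ncol(object@positions) != 3) msgs <- c(msgs, "positions must be n x 3")
  if (length(object@fixed) != n) msgs <- c(msgs, "fixed must match bead count")
  if (!any(object@fixed)) msgs <- c(msgs, "at least one bead must be fixed")
  if (length(object@pulled) != 1 || object@pulled < 1 || object@pulled > n)
    msgs <- c(msgs, "exactly one pulled bead index is required")
  else if (object@fixed[object@pulled])
    msgs <- c(msgs, "the pulled bead cannot be fixed")
  if (object@spring_k <= 0) msgs <- c(msgs, "spring_k must be > 0")
  if (object@velocity <= 0) msgs <- c(msgs, "velocity must be > 0")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    msgs <- c(msgs, "direction must be a unit vector")
  if (nrow(object@bonds)) {
    b <- object@bonds
    need <- c("i", "j", "r0", "k", "break_ext", "breakable")
    if (!all(need %in% names(b))) msgs <- c(msgs, "bonds missing columns")
    else if (any(b$i < 1 | b$i > n | b$j < 1 | b$j > n | b$i == b$j))
      msgs <- c(msgs, "bond endpoints out of range")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' InteractionSeries: per-frame contact counts with block averages
#'
#' @slot counts integer per-frame contact counts.
#' @slot times frame timestamps, ps.
#' @slot label selection label (e.g. "antigen-antibody", "protein-water").
#' @slot detector "hbond" or "saltbridge".
#' @slot block_length block length in ps used for block averaging.
#' @slot blocks data.frame (block, t_start, t_end, n_frames, mean, sd, partial).
#' @slot mean,sd overall mean and SD of the per-frame counts.
#' @export
setClass("InteractionSeries", representation(
  counts = "integer", times = "numeric", label = "character",
  detector = "character", block_length = "numeric", blocks = "data.frame",
  mean = "numeric", sd = "numeric"
))

setValidity("InteractionSeries", function(object) {
  if (length(object@counts) != length(object@times))
    return("counts and times must have equal length")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' RmsdSeries: per-frame RMSD to a reference conformation
#'
#' @slot rmsd_A per-frame RMSD, Angstrom (nm values are rmsd_A / 10).
#' @slot times frame timestamps, ps.
#' @slot label selection label (complex, fab, mog, variable, cdr, constant,
#'   custom).
#' @slot superposed logical, whether frames were Kabsch-superposed on the
#'   selection before measuring.
#' @slot mean_A,sd_A summary over frames, Angstrom.
#' @export
setClass("RmsdSeries", representation(
  rmsd_A = "numeric", times = "numeric", label = "character",
  superposed = "logical", mean_A = "numeric", sd_A = "numeric"
))

setValidity("RmsdSeries", function(object) {
  if (length(object@rmsd_A) != length(object@times))
    return("rmsd_A and times must have equal length")
  if (any(object@rmsd_A < -1e-9)) return("RMSD must be non-negative")
  TRUE
})

#' AnchorRanking: antigen residues ranked by hydrogen-bond contribution
#'
#' @slot table data.frame (chain, resno, resname, count) sorted by descending
#'   occupancy-weighted bond count; ties broken by ascending resno.
#' @slot tie_rule character record of the tie rule applied.
#' @export
setClass("AnchorRanking", representation(
  table = "data.frame", tie_rule = "character"
))

setValidity("AnchorRanking", function(object) {
  tb <- object@table
  if (nrow(tb)) {
    if (!all(c("chain", "resno", "count") %in% names(tb)))
      return("table must have chain/resno/count columns")
    if (is.unsorted(rev(tb$count))) return("counts must be non-increasing")
    if (any(tb$count <= 0)) return("zero-count residues must be excluded")
  }
  TRUE
})

#' WindowReport: anchor residues mapped onto peptide windows
#'
#' @slot windows data.frame (label, start, end, n_members).
#' @slot members named list mapping window label to member residue positions.
#' @slot union_members integer positions inside at least one window
#'   (de-duplicated).
#' @slot outside integer positions in the ranking but outside all windows.
#' @export
setClass("WindowReport", representation(
  windows = "data.frame", members = "list", union_members = "integer",
  outside = "integer"
))

#' EnergyDecomposition: gas-phase MM interface energy over a sampling window
#'
#' Electrostatic (Coulomb) and van der Waals (Lennard-Jones) cross-interaction
#' energies between two selections, sampled on a stride through a trajectory
#' window.  These correspond to the molecular-mechanics Delta-E_elec and
#' Delta-E_vdW terms of an MM/PBSA decomposition; solvation and entropy terms
#' are out of scope for this package.
#'
#' @slot samples data.frame (time_ps, E_elec, E_vdW), kcal/mol.
#' @slot summary named numeric: mean/sd of each term and the sample count.
#' @export
setClass("EnergyDecomposition", representation(
  samples = "data.frame", summary = "numeric"
))

#' DistributionComparison: boxplot-style comparison of force distributions
#'
#' @slot stats data.frame of per-group Tukey boxplot statistics (group, n,
#'   min, q1, median, q3, max, whisker_lo, whisker_hi, n_outliers).
#' @slot containment named numeric: for each ordered pair "A_in_B", the
#'   fraction of A values inside B's [min, max] range.
#' @slot median_in_box named logical: for each ordered pair, whether
#'   median(A) lies within B's interquartile box.
#' @slot tests data.frame of pairwise rank-test results (pair,
#'   median_diff, p_value).
#' @export
setClass("DistributionComparison", representation(
  stats = "data.frame", containment = "numeric", median_in_box = "logical",
  tests = "data.frame"
))
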