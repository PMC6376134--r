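#' Atom table of a structure
#'
#' @param x a \code{\linkS4class{ComplexStructure}} or
#'   \code{\linkS4class{Trajectory}}.
#' @return data.frame with one row per atom.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "ComplexStructure", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)

#' Number of atoms
#' @param x a ComplexStructure or Trajectory.
#' @return integer count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ComplexStructure", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])

#' Number of frames in a trajectory
#' @param x a Trajectory.
#' @return integer count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])

#' Frame timestamps (ps)
#' @param x a Trajectory or InteractionSeries or RmsdSeries.
#' @return numeric vector of times in ps.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "InteractionSeries", function(x) x@times)

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "RmsdSeries", function(x) x@times)

#' Coordinates of one frame
#'
#' @param x a Trajectory or ComplexStructure.
#' @param i frame index (1-based; ignored for a single structure).
#' @return n x 3 numeric matrix, Angstrom.
#' @export
setGeneric("frameCoords", function(x, i = 1L) standardGeneric("frameCoords"))

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "Trajectory", function(x, i = 1L) {
  stopifnot(i >= 1, i <= nFrames(x))
  x@coords[, , i, drop = TRUE]
})

#' @rdname frameCoords
#' @export
setMethod("frameCoords", "ComplexStructure", function(x, i = 1L) {
  as.matrix(x@atoms[, c("x", "y", "z")])
})

#' Per-frame values of a series
#' @param x an InteractionSeries (counts) or RmsdSeries (RMSD in Angstrom).
#' @return numeric vector.
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "InteractionSeries", function(x) x@counts)

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "RmsdSeries", function(x) x@rmsd_A)

#' Block statistics of an interaction series
#' @param x an InteractionSeries.
#' @return data.frame (block, t_start, t_end, n_frames, mean, sd, partial).
#' @export
setGeneric("blockStats", function(x) standardGeneric("blockStats"))

#' @rdname blockStats
#' @export
setMethod("blockStats", "InteractionSeries", function(x) x@blocks)

#' Force trace of a curve
#' @param x a ForceCurve.
#' @return data.frame with the abscissa (time_ps or position_nm, by kind) and
#'   force_pN.
#' @export
setGeneric("forceTrace", function(x) standardGeneric("forceTrace"))

#' @rdname forceTrace
#' @export
setMethod("forceTrace", "ForceCurve", function(x) {
  abscissa_name <- if (x@kind == "smd") "time_ps" else "position_nm"
  out <- data.frame(x@abscissa, force_pN = x@force)
  names(out)[1] <- abscissa_name
  out
})

#' Ranking table of an AnchorRanking
#' @param x an AnchorRanking.
#' @return data.frame (chain, resno, resname, count), sorted.
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' @rdname rankingTable
#' @export
setMethod("rankingTable", "AnchorRanking", function(x) x@table)

#' Per-sample energies of an EnergyDecomposition
#' @param x an EnergyDecomposition.
#' @return data.frame (time_ps, E_elec, E_vdW), kcal/mol.
#' @export
setGeneric("energySamples", function(x) standardGeneric("energySamples"))

#' @rdname energySamples
#' @export
setMethod("energySamples", "EnergyDecomposition", function(x) x@samples)
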