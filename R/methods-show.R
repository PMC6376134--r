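setMethod("show", "ComplexStructure", function(object) {
  a <- object@atoms
  cat("ComplexStructure with", nrow(a), "atoms\n")
  if (nrow(a)) {
    tab <- table(a$molecule)
    for (m in names(tab)) {
      nres <- length(unique(paste(a$chain, a$resno, a$inscode)[a$molecule == m]))
      cat(sprintf("  %-12s %4d residues, %5d atoms\n", m, nres, tab[[m]]))
    }
    cat("  chemistry:", if (any(a$role_donor | a$role_acceptor))
      "assigned" else "not assigned", "\n")
  }
})

setMethod("show", "RegionAnnotation", function(object) {
  cat("RegionAnnotation\n")
  if (length(object@cdr)) {
    sizes <- vapply(object@cdr, nrow, integer(1))
    cat("  CDR sets:", paste(sprintf("%s(%d)", names(sizes), sizes),
                             collapse = " "), "\n")
  }
  cat("  variable:", nrow(object@variable), "residues; constant:",
      nrow(object@constant), "residues\n")
  if (nrow(object@windows))
    cat("  windows:", paste(sprintf("%s[%d-%d]", object@windows$label,
        object@windows$start, object@windows$end), collapse = " "), "\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", dim(object@coords)[3], "frames x",
      dim(object@coords)[1], "atoms,",
      sprintf("t = %g..%g ps\n", min(object@times), max(object@times)))
})

setMethod("show", "ForceCurve", function(object) {
  unit <- if (object@kind == "smd") "ps" else "nm"
  cat(sprintf("ForceCurve (%s): %d points, abscissa %g..%g %s, force %g..%g pN\n",
              object@kind, length(object@force), min(object@abscissa),
              max(object@abscissa), unit, min(object@force), max(object@force)))
})

setMethod("show", "RuptureEvent", function(object) {
  if (object@ruptured)
    cat(sprintf("RuptureEvent: %.1f pN at %.1f ps\n",
                object@rupture_force, object@rupture_time))
  else cat("RuptureEvent: unruptured\n")
})

setMethod("show", "PullingSystem", function(object) {
  cat(sprintf(paste0("PullingSystem: %d beads (%d fixed), %d bonds ",
                     "(%d breakable)\n  k = %g kcal/mol/A^2, v = %g A/ps, ",
                     "T = %g K, dt = %g ps\n"),
              nrow(object@positions), sum(object@fixed), nrow(object@bonds),
              sum(object@bonds$breakable), object@spring_k, object@velocity,
              object@temperature, object@timestep))
})

setMethod("show", "InteractionSeries", function(object) {
  cat(sprintf("InteractionSeries [%s, %s]: %d frames, mean %.2f +/- %.2f\n",
              object@detector, object@label, length(object@counts),
              object@mean, object@sd))
})

setMethod("show", "RmsdSeries", function(object) {
  cat(sprintf("RmsdSeries [%s%s]: %d frames, mean %.3f A (%.4f nm) +/- %.3f A\n",
              object@label, if (object@superposed) ", superposed" else "",
              length(object@rmsd_A), object@mean_A, object@mean_A / 10,
              object@sd_A))
})

setMethod("show", "AnchorRanking", function(object) {
  cat("AnchorRanking:", nrow(object@table), "residues\n")
  if (nrow(object@table)) {
    top <- utils::head(object@table, 13)
    cat("  ", paste(sprintf("%s_%d(%d)", top$resname, top$resno, top$count),
                    collapse = " "), "\n")
  }
})

setMethod("show", "WindowReport", function(object) {
  cat("WindowReport\n")
  for (k in seq_len(nrow(object@windows)))
    cat(sprintf("  %s [%d-%d]: %d members\n", object@windows$label[k],
                object@windows$start[k], object@windows$end[k],
                object@windows$n_members[k]))
  cat("  union:", length(object@union_members),
      "| outside all windows:", length(object@outside), "\n")
})

setMethod("show", "EnergyDecomposition", function(object) {
  s <- object@summary
  cat(sprintf(paste0("EnergyDecomposition: %d samples\n  E_elec = %.2f +/- ",
                     "%.2f kcal/mol\n  E_vdW  = %.2f +/- %.2f kcal/mol\n"),
              as.integer(s[["n_samples"]]), s[["E_elec_mean"]],
              s[["E_elec_sd"]], s[["E_vdW_mean"]], s[["E_vdW_sd"]]))
})

setMethod("show", "DistributionComparison", function(object) {
  cat("DistributionComparison of", nrow(object@stats), "groups\n")
  print(object@stats, row.names = FALSE)
})
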