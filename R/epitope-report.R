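## Final-stage epitope statistics (anchor-residue window mapping, force
## fraction) and end-to-end pipeline orchestration: generate -> contacts ->
## rank -> pulling (full + peptide-window subset) -> synthetic AFM ->
## distribution comparison -> force fraction -> machine-readable report.

#' Define a peptide window on the antigen
#'
#' @param label window label (e.g. "MOG_92_106").
#' @param start,end inclusive antigen residue positions, start <= end.
#' @return a one-row data.frame (label, start, end).
#' @export
peptideWindow <- function(label, start, end) {
  stopifnot(start <= end)
  data.frame(label = label, start = as.integer(start), end = as.integer(end))
}

#' Map ranked anchor residues onto peptide windows
#'
#' Window membership is inclusive integer-interval arithmetic on antigen
#' residue positions.  Overlapping windows are allowed: a residue is
#' attributed to every window containing it, while the union count
#' de-duplicates.
#'
#' @param ranking an \code{\linkS4class{AnchorRanking}}, or an integer
#'   vector of antigen residue positions.
#' @param windows data.frame (label, start, end) of peptide windows, e.g.
#'   built with \code{\link{peptideWindow}} and \code{rbind}.
#' @return a \code{\linkS4class{WindowReport}}.
#' @examples
#' anchors <- c(108, 1, 104, 103, 53, 33, 102, 106, 107, 52, 4, 105, 40)
#' w <- rbind(peptideWindow("w1", 1, 22), peptideWindow("w2", 35, 55),
#'            peptideWindow("w3", 92, 106))
#' rep <- mapToWindows(anchors, w)
#' length(rep@union_members)  # 10
#' @export
mapToWindows <- function(ranking, windows) {
  positions <- if (methods::is(ranking, "AnchorRanking"))
    rankingTable(ranking)$resno else as.integer(ranking)
  stopifnot(all(c("label", "start", "end") %in% names(windows)),
            all(windows$start <= windows$end))
  members <- list()
  n_members <- integer(nrow(windows))
  for (k in seq_len(nrow(windows))) {
    m <- positions[positions >= windows$start[k] &
                     positions <= windows$end[k]]
    members[[windows$label[k]]] <- sort(unique(m))
    n_members[k] <- length(unique(m))
  }
  union_members <- sort(unique(unlist(members)))
  outside <- sort(unique(positions[!positions %in% union_members]))
  w <- windows[, c("label", "start", "end")]
  w$n_members <- n_members
  methods::new("WindowReport", windows = w, members = members,
               union_members = as.integer(union_members),
               outside = as.integer(outside))
}

#' Default pipeline configuration
#'
#' The study conditions of the end-to-end analysis: the default synthetic
#' complex (13 planted interface hydrogen bonds at the anchor positions,
#' 3 salt bridges, water shell), a 200-frame trajectory with per-contact
#' persistence decreasing along the planted ranking, 20-replicate pulling
#' of the full interface and of the 92-106 peptide-window subset, and 30
#' synthetic AFM curves around a 765 pN adhesion with two lower-force
#' control groups.
#'
#' @param seed master seed; every random stage derives its own sub-stream.
#' @return a nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    complex = complexSpec(seed = .splitSeed(seed, 1L)),
    trajectory = list(n_frames = 200L, frame_interval = 100,
                      noise_sigma = 0.1,
                      contact_persistence = c(seq(0.95, 0.5, length.out = 13),
                                              rep(0.9, 3))),
    block_length = 4000,
    peptide_window = c(92L, 106L),
    energy = list(start_frac = 0.25, end_frac = 0.75, stride_frames = 2L),
    pulling = list(n_replicates = 20L, duration = 3000, timestep = 0.01,
                   temperature = 310, record_every = 0.5, bond_k = 6,
                   break_ext = 1.6),
    afm = list(n_curves = 30L, adhesion_mean = 765, adhesion_sd = 80,
               noise_pN = 10,
               controls = list(
                 bare_tip = list(n = 12L, mean = 140, sd = 45),
                 unspecific = list(n = 12L, mean = 220, sd = 60)))
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors \code{\link{defaultPipelineConfig}}; omitted entries
#' fall back to the defaults, and the complex spec may be given as a list
#' of \code{\link{complexSpec}} arguments under \code{complex}.
#'
#' @param file path to a YAML configuration.
#' @return a configuration list.
#' @export
readPipelineConfig <- function(file) {
  usr <- yaml::read_yaml(file)
  seed <- if (!is.null(usr$seed)) as.integer(usr$seed) else 1L
  cfg <- defaultPipelineConfig(seed)
  if (!is.null(usr$complex)) {
    args <- usr$complex
    for (f in c("planted_hbonds", "planted_saltbridges", "antigen_windows"))
      if (!is.null(args[[f]])) args[[f]] <- as.data.frame(args[[f]])
    args$seed <- .splitSeed(seed, 1L)
    cfg$complex <- do.call(complexSpec, args)
  }
  for (top in c("trajectory", "pulling", "afm", "energy")) {
    for (nm in names(usr[[top]])) cfg[[top]][[nm]] <- usr[[top]][[nm]]
  }
  for (nm in c("block_length", "peptide_window"))
    if (!is.null(usr[[nm]])) cfg[[nm]] <- usr[[nm]]
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.afmForces <- function(n, mean, sd, noise, seed) {
  adh <- pmax(0, .withSeed(seed, stats::rnorm(n, mean, sd)))
  vapply(seq_len(n), function(i) {
    extractAdhesion(makeAfmCurve(afmCurveSpec(
      adhesion_pN = adh[i], noise_pN = noise,
      seed = .splitSeed(seed, 1000L + i))))
  }, numeric(1))
}

#' Run the full antigen-antibody characterisation pipeline
#'
#' Deterministic end-to-end analysis on synthetic inputs: complex
#' generation, trajectory, interface hydrogen-bond records over all frames,
#' protein-water and salt-bridge count series with block averages, CDR
#' attribution, anchor-residue ranking, peptide-window mapping, RMSD
#' series, interface energy decomposition, replicate pulling of the full
#' interface and of the peptide-window subset, synthetic AFM adhesion
#' extraction, distribution comparison, and the subset force fraction.
#' Identical (config, seed) gives identical output.
#'
#' @param config a configuration list from
#'   \code{\link{defaultPipelineConfig}} or \code{\link{readPipelineConfig}}.
#' @param outdir optional output directory: CSV/JSON artifacts plus a
#'   machine-readable \code{summary.json} are written there.
#' @return list with \code{summary} (plain-list report) and \code{objects}
#'   (the intermediate S4 objects).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir = NULL) {
  seed <- config$seed

  cx <- .stage("generate_complex", makeComplex(config$complex))
  s <- cx$structure; ann <- cx$annotation

  tcfg <- config$trajectory
  traj <- .stage("trajectory", makeTrajectory(s, trajectorySpec(
    n_frames = tcfg$n_frames, frame_interval = tcfg$frame_interval,
    noise_sigma = tcfg$noise_sigma,
    contact_persistence = tcfg$contact_persistence,
    seed = .splitSeed(seed, 2L)), planted = cx$contacts))

  ag <- atomSelect(s, molecule = "antigen")
  ab <- atomSelect(s, molecule = c("heavy_chain", "light_chain"))
  wat <- atomSelect(s, molecule = "water")
  prot <- c(ag, ab)

  records <- .stage("interface_hbonds", {
    out <- lapply(seq_len(nFrames(traj)), function(f)
      detectHBonds(s, ag, ab, coords = frameCoords(traj, f), frame = f))
    do.call(rbind, out)
  })

  pw_series <- .stage("protein_water_series", countSeries(
    traj, "hbond", prot, wat, block_length = config$block_length,
    label = "protein-water"))
  sb_series <- .stage("saltbridge_series", countSeries(
    traj, "saltbridge", ag, ab, block_length = config$block_length,
    label = "antigen-antibody"))

  cdr <- .stage("cdr_fraction", cdrFraction(records, ann))
  ranking <- .stage("anchor_ranking", rankAnchorResidues(records))
  winrep <- .stage("window_mapping", mapToWindows(ranking, ann@windows))

  rmsd_complex <- .stage("rmsd", rmsdSeries(
    traj, c(ag, ab), label = "complex"))
  rmsd_ag <- rmsdSeries(traj, ag, label = "mog")
  rmsd_ab <- rmsdSeries(traj, ab, label = "fab")

  ecfg <- config$energy
  energy <- .stage("energetics", {
    tmax <- max(traj@times)
    win <- samplingWindow(ecfg$start_frac * tmax, ecfg$end_frac * tmax,
                          ecfg$stride_frames * tcfg$frame_interval)
    interfaceDecomposition(traj, win, ag, ab)
  })

  pcfg <- config$pulling
  hb_contacts <- cx$contacts[cx$contacts$type == "hbond", , drop = FALSE]
  buildSys <- function(window) buildPullingSystem(
    s, hb_contacts, window = window, bond_k = pcfg$bond_k,
    break_ext = pcfg$break_ext, temperature = pcfg$temperature,
    timestep = pcfg$timestep)
  full_sys <- .stage("pulling_build", buildSys(NULL))
  sub_sys <- .stage("pulling_build", buildSys(config$peptide_window))
  rep_full <- .stage("pulling_full", runReplicates(
    full_sys, n = pcfg$n_replicates, seed = .splitSeed(seed, 3L),
    duration = pcfg$duration, record_every = pcfg$record_every))
  rep_sub <- .stage("pulling_subset", runReplicates(
    sub_sys, n = pcfg$n_replicates, seed = .splitSeed(seed, 4L),
    duration = pcfg$duration, record_every = pcfg$record_every))
  st_full <- .stage("rupture_stats", replicateStats(rep_full$events))
  st_sub <- .stage("rupture_stats", replicateStats(rep_sub$events))

  acfg <- config$afm
  afm_forces <- .stage("afm", .afmForces(
    acfg$n_curves, acfg$adhesion_mean, acfg$adhesion_sd, acfg$noise_pN,
    .splitSeed(seed, 5L)))
  controls <- lapply(seq_along(acfg$controls), function(k) {
    cc <- acfg$controls[[k]]
    .afmForces(cc$n, cc$mean, cc$sd, acfg$noise_pN,
               .splitSeed(seed, 6L + k))
  })
  names(controls) <- names(acfg$controls)

  smd_sub_forces <- vapply(Filter(function(e) e@ruptured, rep_sub$events),
                           function(e) e@rupture_force, numeric(1))
  comparison <- .stage("compare", compareDistributions(
    smd_sub_forces, afm_forces, controls))
  frac <- .stage("force_fraction", forceFraction(st_sub$mean, st_full$mean))

  summary <- list(
    seed = seed,
    n_interface_hbond_records = nrow(records),
    mean_interface_hbonds_per_frame = nrow(records) / nFrames(traj),
    protein_water_hbonds = list(mean = pw_series@mean, sd = pw_series@sd),
    salt_bridges = list(mean = sb_series@mean, sd = sb_series@sd),
    cdr_fraction = cdr,
    ranking = rankingTable(ranking),
    windows = list(per_window = winrep@windows,
                   union_count = length(winrep@union_members),
                   union_members = winrep@union_members,
                   outside = winrep@outside),
    rmsd_mean_A = c(complex = rmsd_complex@mean_A, mog = rmsd_ag@mean_A,
                    fab = rmsd_ab@mean_A),
    energy = as.list(energy@summary),
    rupture_full = st_full, rupture_subset = st_sub,
    afm = list(n = length(afm_forces), mean = mean(afm_forces),
               sd = stats::sd(afm_forces)),
    comparison = list(stats = comparison@stats,
                      containment = as.list(comparison@containment),
                      median_in_box = as.list(comparison@median_in_box)),
    force_fraction = frac
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeRankingJSON(ranking, file.path(outdir, "ranking.json"))
    writeContactsCSV(records, file.path(outdir, "interface_hbonds.csv"))
    writeContactsCSV(pw_series, file.path(outdir, "protein_water_series.csv"))
    writeContactsCSV(sb_series, file.path(outdir, "saltbridge_series.csv"))
    writeRmsdCSV(rmsd_complex, file.path(outdir, "rmsd_complex.csv"))
    utils::write.csv(energySamples(energy),
                     file.path(outdir, "energy_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(group = "afm", force_pN = afm_forces),
                     file.path(outdir, "afm_forces.csv"), row.names = FALSE)
    writeForceCurveCSV(rep_full$curves[[1]],
                       file.path(outdir, "pulling_full_rep1.csv"))
    writeForceCurveCSV(rep_sub$curves[[1]],
                       file.path(outdir, "pulling_subset_rep1.csv"))
  }

  list(summary = summary,
       objects = list(structure = s, annotation = ann, contacts = cx$contacts,
                      trajectory = traj, records = records,
                      ranking = ranking, window_report = winrep,
                      energy = energy, systems = list(full = full_sys,
                                                      subset = sub_sys),
                      replicates = list(full = rep_full, subset = rep_sub),
                      comparison = comparison))
}
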