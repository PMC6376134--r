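## Geometric detection and counting of hydrogen bonds and salt bridges,
## CDR attribution and anchor-residue ranking.
##
## Criteria follow the geometric convention: a hydrogen bond when the
## donor-acceptor distance is shorter than 3.5 A AND the H-D-A angle (at the
## donor, between D->H and D->A) is shorter than 60 degrees; a salt bridge
## when an acidic-residue oxygen is shorter than 3.2 A from a basic-residue
## nitrogen.  Both thresholds are strict ("shorter than"); boundary equality
## does not count.

#' Contact detection criteria
#'
#' @param hbond_da_max maximum donor-acceptor distance, Angstrom (strict).
#' @param hbond_hda_max maximum H-D-A angle, degrees (strict), measured at
#'   the donor between the D->H and D->A directions.
#' @param saltbridge_on_max maximum acidic-O to basic-N distance, Angstrom
#'   (strict).
#' @param angle_mode \code{"hda"} (default) uses the H-D-A < hbond_hda_max
#'   rule; \code{"dha"} switches to the conventional donor-H-acceptor angle
#'   >= \code{dha_min} rule for cross-checks.
#' @param dha_min minimum D-H-A angle in degrees for \code{angle_mode="dha"}.
#' @return a list of class \code{contact_criteria}.
#' @export
contactCriteria <- function(hbond_da_max = 3.5, hbond_hda_max = 60,
                            saltbridge_on_max = 3.2,
                            angle_mode = c("hda", "dha"), dha_min = 120) {
  stopifnot(hbond_da_max > 0, hbond_hda_max > 0, saltbridge_on_max > 0)
  out <- list(hbond_da_max = hbond_da_max, hbond_hda_max = hbond_hda_max,
              saltbridge_on_max = saltbridge_on_max,
              angle_mode = match.arg(angle_mode), dha_min = dha_min)
  class(out) <- "contact_criteria"
  out
}

.emptyHBonds <- function() {
  data.frame(donor_serial = integer(0), hydrogen_serial = integer(0),
             acceptor_serial = integer(0), donor_chain = character(0),
             donor_resno = integer(0), donor_resname = character(0),
             donor_molecule = character(0), acceptor_chain = character(0),
             acceptor_resno = integer(0), acceptor_resname = character(0),
             acceptor_molecule = character(0), d_DA = numeric(0),
             theta_HDA = numeric(0), frame = integer(0))
}

## one direction: donors drawn from don_pool, acceptors from acc_pool
.hbondsOneWay <- function(a, xyz, don_pool, acc_pool, criteria, frame) {
  don <- don_pool[a$role_donor[don_pool]]
  acc <- acc_pool[a$role_acceptor[acc_pool]]
  if (!length(don) || !length(acc)) return(.emptyHBonds())
  ## map donors to their hydrogens (hydrogens live with the donor atom)
  hyd_all <- which(a$role_hydrogen)
  hyd_of <- split(hyd_all, match(a$hparent[hyd_all], a$serial))
  don_h <- hyd_of[as.character(don)]
  no_h <- vapply(don_h, is.null, logical(1))
  if (any(no_h))
    warning(sum(no_h), " donor atom(s) without an attached hydrogen skipped",
            call. = FALSE)
  don <- don[!no_h]; don_h <- don_h[!no_h]
  if (!length(don)) return(.emptyHBonds())
  dmat <- sqrt(pmax(outer(rowSums(xyz[don, , drop = FALSE]^2),
                          rowSums(xyz[acc, , drop = FALSE]^2), "+") -
                      2 * xyz[don, , drop = FALSE] %*%
                      t(xyz[acc, , drop = FALSE]), 0))
  reskey <- paste(a$chain, a$resno, a$inscode)
  same_res <- outer(reskey[don], reskey[acc], "==")
  hit <- which(dmat < criteria$hbond_da_max & !same_res, arr.ind = TRUE)
  if (!nrow(hit)) return(.emptyHBonds())
  out <- list()
  for (r in seq_len(nrow(hit))) {
    di <- don[hit[r, 1]]; ai <- acc[hit[r, 2]]
    d_da <- dmat[hit[r, 1], hit[r, 2]]
    for (hi in don_h[[hit[r, 1]]]) {
      if (criteria$angle_mode == "hda") {
        v1 <- xyz[hi, ] - xyz[di, ]; v2 <- xyz[ai, ] - xyz[di, ]
        th <- .angleDeg(v1, v2)
        ok <- th < criteria$hbond_hda_max
      } else {
        v1 <- xyz[di, ] - xyz[hi, ]; v2 <- xyz[ai, ] - xyz[hi, ]
        th <- .angleDeg(v1, v2)
        ok <- th >= criteria$dha_min
      }
      if (ok)
        out[[length(out) + 1L]] <- data.frame(
          donor_serial = a$serial[di], hydrogen_serial = a$serial[hi],
          acceptor_serial = a$serial[ai], donor_chain = a$chain[di],
          donor_resno = a$resno[di], donor_resname = a$resname[di],
          donor_molecule = a$molecule[di], acceptor_chain = a$chain[ai],
          acceptor_resno = a$resno[ai], acceptor_resname = a$resname[ai],
          acceptor_molecule = a$molecule[ai], d_DA = d_da, theta_HDA = th,
          frame = frame)
    }
  }
  if (!length(out)) return(.emptyHBonds())
  do.call(rbind, out)
}

.angleDeg <- function(v1, v2) {
  cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cs))) * 180 / pi
}

#' Detect hydrogen bonds between two selections
#'
#' Returns every (donor, hydrogen, acceptor) triple with the donor in one
#' selection and the acceptor in the other (both directions searched) that
#' satisfies both strict criteria.  One residue pair may contribute several
#' simultaneous bonds; each triple counts once.  Donors without an attached
#' hydrogen are skipped with a warning.
#'
#' @param structure a \code{\linkS4class{ComplexStructure}} with chemistry
#'   assigned.
#' @param sel_a,sel_b disjoint integer atom selections (see
#'   \code{\link{atomSelect}}).
#' @param criteria a \code{\link{contactCriteria}}.
#' @param coords optional n x 3 matrix overriding the structure coordinates
#'   (used when scanning trajectory frames).
#' @param frame frame index recorded in the output.
#' @return data.frame of bond records (atom serials, residue identities,
#'   d_DA in Angstrom, theta_HDA in degrees, frame).
#' @examples
#' cx <- makeComplex(complexSpec())
#' ab <- atomSelect(cx$structure, molecule = c("heavy_chain", "light_chain"))
#' ag <- atomSelect(cx$structure, molecule = "antigen")
#' nrow(detectHBonds(cx$structure, ag, ab))  # the 13 planted bonds
#' @export
detectHBonds <- function(structure, sel_a, sel_b,
                         criteria = contactCriteria(), coords = NULL,
                         frame = 1L) {
  a <- atoms(structure)
  if (length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint", call. = FALSE)
  if (is.null(coords)) coords <- as.matrix(a[, c("x", "y", "z")])
  out <- rbind(.hbondsOneWay(a, coords, sel_a, sel_b, criteria, frame),
               .hbondsOneWay(a, coords, sel_b, sel_a, criteria, frame))
  rownames(out) <- NULL
  out
}

#' Detect salt bridges between two selections
#'
#' A salt bridge is counted when an oxygen carrying the acidic-residue role
#' lies strictly closer than the criterion distance to a nitrogen carrying
#' the basic-residue role, with the two atoms in different residues.  Both
#' directions of the selection pair are searched.
#'
#' @inheritParams detectHBonds
#' @return data.frame (oxygen_serial, nitrogen_serial, residue identities,
#'   d_ON, frame).
#' @export
detectSaltBridges <- function(structure, sel_a, sel_b,
                              criteria = contactCriteria(), coords = NULL,
                              frame = 1L) {
  a <- atoms(structure)
  if (length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint", call. = FALSE)
  if (is.null(coords)) coords <- as.matrix(a[, c("x", "y", "z")])
  empty <- data.frame(oxygen_serial = integer(0), nitrogen_serial = integer(0),
                      oxygen_chain = character(0), oxygen_resno = integer(0),
                      oxygen_resname = character(0),
                      oxygen_molecule = character(0),
                      nitrogen_chain = character(0),
                      nitrogen_resno = integer(0),
                      nitrogen_resname = character(0),
                      nitrogen_molecule = character(0),
                      d_ON = numeric(0), frame = integer(0))
  oneway <- function(o_pool, n_pool) {
    os <- o_pool[a$role_acidic_o[o_pool]]
    ns <- n_pool[a$role_basic_n[n_pool]]
    if (!length(os) || !length(ns)) return(empty)
    dmat <- sqrt(pmax(outer(rowSums(coords[os, , drop = FALSE]^2),
                            rowSums(coords[ns, , drop = FALSE]^2), "+") -
                        2 * coords[os, , drop = FALSE] %*%
                        t(coords[ns, , drop = FALSE]), 0))
    reskey <- paste(a$chain, a$resno, a$inscode)
    same_res <- outer(reskey[os], reskey[ns], "==")
    hit <- which(dmat < criteria$saltbridge_on_max & !same_res,
                 arr.ind = TRUE)
    if (!nrow(hit)) return(empty)
    oi <- os[hit[, 1]]; ni <- ns[hit[, 2]]
    data.frame(oxygen_serial = a$serial[oi], nitrogen_serial = a$serial[ni],
               oxygen_chain = a$chain[oi], oxygen_resno = a$resno[oi],
               oxygen_resname = a$resname[oi],
               oxygen_molecule = a$molecule[oi],
               nitrogen_chain = a$chain[ni], nitrogen_resno = a$resno[ni],
               nitrogen_resname = a$resname[ni],
               nitrogen_molecule = a$molecule[ni],
               d_ON = dmat[hit], frame = frame)
  }
  out <- rbind(oneway(sel_a, sel_b), oneway(sel_b, sel_a))
  rownames(out) <- NULL
  out
}

#' Count contacts per frame over a trajectory
#'
#' Applies a contact detector to every frame and returns the per-frame count
#' series with overall and per-block mean and SD.  Blocks of the requested
#' length tile the series; a shorter tail block is flagged partial.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param detector \code{"hbond"} or \code{"saltbridge"}.
#' @param sel_a,sel_b disjoint atom selections on the topology.
#' @param criteria a \code{\link{contactCriteria}}.
#' @param block_length block length in ps for block averaging.
#' @param label selection label carried in the result.
#' @return an \code{\linkS4class{InteractionSeries}}.
#' @export
countSeries <- function(traj, detector = c("hbond", "saltbridge"),
                        sel_a, sel_b, criteria = contactCriteria(),
                        block_length = NULL, label = "") {
  detector <- match.arg(detector)
  nf <- nFrames(traj)
  if (nf == 0) stop("empty trajectory", call. = FALSE)
  s <- traj@topology
  fun <- if (detector == "hbond") detectHBonds else detectSaltBridges
  counts <- integer(nf)
  withCallingHandlers(
    for (f in seq_len(nf))
      counts[f] <- nrow(fun(s, sel_a, sel_b, criteria,
                            coords = frameCoords(traj, f), frame = f)),
    warning = function(w) invokeRestart("muffleWarning"))
  times <- traj@times
  if (is.null(block_length))
    block_length <- max(times) - min(times) + (times[2] - times[1])
  rel <- times - times[1]
  block <- floor(rel / block_length) + 1L
  blocks <- do.call(rbind, lapply(split(seq_len(nf), block), function(ix) {
    data.frame(block = block[ix[1]], t_start = times[ix[1]],
               t_end = times[ix[length(ix)]], n_frames = length(ix),
               mean = mean(counts[ix]),
               sd = if (length(ix) > 1) stats::sd(counts[ix]) else 0,
               partial = FALSE)
  }))
  if (nrow(blocks) > 1) {
    full <- max(blocks$n_frames)
    blocks$partial[nrow(blocks)] <- blocks$n_frames[nrow(blocks)] < full
  }
  methods::new("InteractionSeries", counts = counts, times = times,
               label = label, detector = detector,
               block_length = block_length, blocks = blocks,
               mean = mean(counts),
               sd = if (nf > 1) stats::sd(counts) else 0)
}

#' CDR contribution to antigen-antibody hydrogen bonds
#'
#' Percentage of antigen-antibody hydrogen-bond records (over all frames)
#' whose antibody-side residue belongs to any CDR set, with a per-CDR
#' breakdown and heavy/light chain totals.  With zero bonds the result is an
#' explicit no-contact marker (percentages NA), not 0.
#'
#' @param records hydrogen-bond records from \code{\link{detectHBonds}},
#'   concatenated over frames (antigen on one side, antibody on the other).
#' @param annotation a \code{\linkS4class{RegionAnnotation}} with CDR sets.
#' @return list with \code{total_pct}, \code{per_cdr} (named percentages of
#'   all bonds), \code{per_chain} (heavy/light percentages), \code{n_bonds},
#'   \code{no_contact}.
#' @export
cdrFraction <- function(records, annotation) {
  cdr_names <- c("l1", "l2", "l3", "h1", "h2", "h3")
  if (is.null(records) || !nrow(records))
    return(list(total_pct = NA_real_,
                per_cdr = stats::setNames(rep(NA_real_, 6), cdr_names),
                per_chain = c(heavy = NA_real_, light = NA_real_),
                n_bonds = 0L, no_contact = TRUE))
  ab_is_donor <- records$donor_molecule %in% c("heavy_chain", "light_chain")
  ab_chain <- ifelse(ab_is_donor, records$donor_chain, records$acceptor_chain)
  ab_resno <- ifelse(ab_is_donor, records$donor_resno, records$acceptor_resno)
  ab_mol <- ifelse(ab_is_donor, records$donor_molecule,
                   records$acceptor_molecule)
  if (!all(ab_mol %in% c("heavy_chain", "light_chain")))
    stop("records must have an antibody residue on one side of every bond",
         call. = FALSE)
  n <- nrow(records)
  key <- paste(ab_chain, ab_resno)
  in_any <- rep(FALSE, n)
  per_cdr <- stats::setNames(numeric(6), cdr_names)
  for (nm in cdr_names) {
    set <- annotation@cdr[[nm]]
    hitset <- if (is.null(set) || !nrow(set)) rep(FALSE, n)
      else key %in% paste(set$chain, set$resno)
    per_cdr[nm] <- 100 * sum(hitset) / n
    in_any <- in_any | hitset
  }
  list(total_pct = 100 * sum(in_any) / n, per_cdr = per_cdr,
       per_chain = c(heavy = 100 * sum(ab_mol == "heavy_chain") / n,
                     light = 100 * sum(ab_mol == "light_chain") / n),
       n_bonds = n, no_contact = FALSE)
}

#' Rank antigen anchor residues by hydrogen-bond contribution
#'
#' Aggregates the occupancy-weighted contribution of each antigen residue:
#' its total number of bond records across all frames.  Residues are sorted
#' from highest to lowest contributor; ties are broken by ascending residue
#' number; zero-count residues are excluded.
#'
#' @param records antigen-antibody hydrogen-bond records over a trajectory.
#' @return an \code{\linkS4class{AnchorRanking}}.
#' @export
rankAnchorResidues <- function(records) {
  if (is.null(records) || !nrow(records))
    stop("at least one hydrogen-bond record is required", call. = FALSE)
  ag_is_donor <- records$donor_molecule == "antigen"
  chain <- ifelse(ag_is_donor, records$donor_chain, records$acceptor_chain)
  resno <- ifelse(ag_is_donor, records$donor_resno, records$acceptor_resno)
  resname <- ifelse(ag_is_donor, records$donor_resname,
                    records$acceptor_resname)
  mol <- ifelse(ag_is_donor, records$donor_molecule,
                records$acceptor_molecule)
  keep <- mol == "antigen"
  if (!any(keep))
    stop("no record has an antigen residue on either side", call. = FALSE)
  df <- data.frame(chain = chain[keep], resno = resno[keep],
                   resname = resname[keep])
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df[, c("chain", "resno", "resname")], FUN = sum)
  agg <- agg[order(-agg$count, agg$resno), c("chain", "resno", "resname",
                                             "count")]
  rownames(agg) <- NULL
  methods::new("AnchorRanking", table = agg,
               tie_rule = "descending count, ties by ascending resno")
}

#' Write contact records or a count series as CSV
#'
#' @param x contact records (data.frame) or an InteractionSeries.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeContactsCSV <- function(x, file) {
  if (methods::is(x, "InteractionSeries"))
    x <- data.frame(time_ps = x@times, count = x@counts)
  utils::write.csv(x, file, row.names = FALSE)
  invisible(file)
}

#' Write an anchor ranking as JSON
#'
#' @param ranking an \code{\linkS4class{AnchorRanking}}.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeRankingJSON <- function(ranking, file) {
  jsonlite::write_json(list(tie_rule = ranking@tie_rule,
                            ranking = rankingTable(ranking)),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
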