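## Coordinate/topology data model: fixed-width PDB I/O, residue chemistry
## tables, atom selection.  Author (file) residue numbering is kept verbatim
## throughout; coordinates are Angstrom.

.emptyAtoms <- function(n = 0) {
  data.frame(
    serial = integer(n), name = character(n), element = character(n),
    resname = character(n), chain = character(n), resno = integer(n),
    inscode = character(n), molecule = character(n),
    x = numeric(n), y = numeric(n), z = numeric(n),
    charge = rep(NA_real_, n), lj_epsilon = rep(NA_real_, n),
    lj_sigma = rep(NA_real_, n),
    role_hydrogen = logical(n), role_donor = logical(n),
    role_acceptor = logical(n), role_acidic_o = logical(n),
    role_basic_n = logical(n), hparent = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
}

#' Build a ComplexStructure from an atom table
#'
#' Low-level constructor; most users will get structures from
#' \code{\link{readPDB}} or \code{\link{makeComplex}}.  Missing chemistry
#' columns (roles, charge, LJ parameters) are added empty.
#'
#' @param atoms data.frame with at least serial, name, element, resname,
#'   chain, resno, molecule, x, y, z.
#' @return a \code{\linkS4class{ComplexStructure}}.
#' @export
complexStructure <- function(atoms) {
  tmpl <- .emptyAtoms()
  n <- nrow(atoms)
  defaults <- list(
    inscode = "", charge = NA_real_, lj_epsilon = NA_real_,
    lj_sigma = NA_real_, role_hydrogen = FALSE, role_donor = FALSE,
    role_acceptor = FALSE, role_acidic_o = FALSE, role_basic_n = FALSE,
    hparent = NA_integer_
  )
  for (col in setdiff(names(tmpl), names(atoms))) {
    if (!col %in% names(defaults))
      stop("atom table is missing required column: ", col, call. = FALSE)
    atoms[[col]] <- rep(defaults[[col]], n)
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, names(tmpl)]
  rownames(atoms) <- NULL
  methods::new("ComplexStructure", atoms = atoms)
}

.num <- function(s, lineno, what) {
  v <- suppressWarnings(as.numeric(s))
  bad <- is.na(v) & !grepl("^\\s*$", s) | is.na(v)
  if (any(bad))
    stop(sprintf("malformed %s field in PDB record at line %d", what,
                 lineno[which(bad)[1]]), call. = FALSE)
  v
}

#' Read a PDB-format structure
#'
#' Parses fixed-width ATOM/HETATM records into a
#' \code{\linkS4class{ComplexStructure}}.  Chains are assigned to molecule
#' labels via \code{chainMap}; waters (resname HOH) are routed to the
#' \code{water} molecule regardless of chain.  For alternate locations the
#' highest-occupancy altloc is kept, ties resolved in favour of altloc 'A'.
#' Insertion codes are preserved in residue labelling.
#'
#' @param x path to a PDB file, or PDB-format text (single string or vector
#'   of lines).
#' @param chainMap named character vector mapping chain IDs to labels among
#'   \code{antigen}, \code{heavy_chain}, \code{light_chain}, \code{water},
#'   e.g. \code{c(A = "antigen", H = "heavy_chain", L = "light_chain")}.
#' @return a \code{\linkS4class{ComplexStructure}}.
#' @examples
#' line <- "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C"
#' s <- readPDB(line, chainMap = c(A = "antigen"))
#' atoms(s)[, c("name", "resname", "x", "y", "z")]
#' @export
readPDB <- function(x, chainMap) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x))
    x <- readLines(x)
  else if (length(x) == 1)
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  rec <- substr(x, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM") |
                 trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(sel)) stop("no ATOM/HETATM records found", call. = FALSE)
  ln <- x[sel]
  lineno <- sel
  short <- which(nchar(ln) < 54)
  if (length(short))
    stop(sprintf("truncated ATOM/HETATM record at line %d", lineno[short[1]]),
         call. = FALSE)
  f <- function(a, b) substr(ln, a, b)
  occ_raw <- trimws(f(55, 60))
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[is.na(occ) | occ_raw == ""] <- 1
  a <- data.frame(
    serial = as.integer(.num(f(7, 11), lineno, "serial")),
    name = trimws(f(13, 16)),
    altloc = trimws(f(17, 17)),
    resname = trimws(f(18, 20)),
    chain = trimws(f(22, 22)),
    resno = as.integer(.num(f(23, 26), lineno, "residue number")),
    inscode = trimws(f(27, 27)),
    x = .num(f(31, 38), lineno, "x coordinate"),
    y = .num(f(39, 46), lineno, "y coordinate"),
    z = .num(f(47, 54), lineno, "z coordinate"),
    occ = occ,
    element = trimws(substr(paste0(ln, strrep(" ", 24)), 77, 78)),
    stringsAsFactors = FALSE
  )
  guess <- toupper(substr(gsub("[0-9']", "", a$name), 1, 1))
  a$element <- ifelse(a$element == "", guess, toupper(a$element))
  ## altloc policy: keep highest occupancy; tie -> altloc 'A'
  key <- paste(a$chain, a$resno, a$inscode, a$name, sep = "|")
  ord <- order(key, -a$occ, a$altloc != "A", a$altloc)
  a <- a[ord, ][!duplicated(key[ord]), ]
  a <- a[order(a$serial), ]
  is_water <- a$resname == "HOH"
  mol <- rep(NA_character_, nrow(a))
  mol[is_water] <- "water"
  mapped <- !is_water & a$chain %in% names(chainMap)
  mol[mapped] <- unname(chainMap[a$chain[mapped]])
  if (anyNA(mol)) {
    found <- sort(unique(a$chain[is.na(mol)]))
    stop(sprintf("unmapped chain(s) %s; chains found in file: %s",
                 paste(found, collapse = ", "),
                 paste(sort(unique(a$chain)), collapse = ", ")), call. = FALSE)
  }
  bad <- !mol %in% .MOLECULE_LABELS
  if (any(bad))
    stop(sprintf("chainMap labels must be among: %s",
                 paste(.MOLECULE_LABELS, collapse = ", ")), call. = FALSE)
  a$molecule <- mol
  a$altloc <- NULL
  a$occ <- NULL
  complexStructure(a)
}

#' Write a structure as PDB-format text
#'
#' Standard fixed-width ATOM/HETATM records (waters as HETATM), coordinates
#' to 3 decimals, TER between molecules, terminated by END.
#'
#' @param structure a \code{\linkS4class{ComplexStructure}}.
#' @param file optional path; when given the text is also written there.
#' @return PDB-format text, one string per line (invisibly when \code{file}
#'   is given).
#' @export
writePDB <- function(structure, file = NULL) {
  a <- atoms(structure)
  if (!nrow(a)) stop("cannot write an empty structure", call. = FALSE)
  if (any(a$x > 9999.999 | a$x < -999.999 | a$y > 9999.999 | a$y < -999.999 |
          a$z > 9999.999 | a$z < -999.999))
    stop("coordinate overflows the fixed-width 8.3 PDB field", call. = FALSE)
  mol_order <- intersect(.MOLECULE_LABELS, unique(a$molecule))
  lines <- character(0)
  for (m in mol_order) {
    am <- a[a$molecule == m, ]
    rectype <- if (m == "water") "HETATM" else "ATOM  "
    nm <- ifelse(nchar(am$name) >= 4, substr(am$name, 1, 4),
                 sprintf(" %-3s", am$name))
    lines <- c(lines, sprintf(
      "%s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, am$serial, nm, " ", am$resname, am$chain, am$resno,
      ifelse(am$inscode == "", " ", am$inscode),
      am$x, am$y, am$z, 1.0, 0.0, am$element), "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Load the residue chemistry tables
#'
#' Reads the versioned YAML chemistry configuration shipped with the package
#' (or a user override): hydrogen-bond donor heavy atoms with their bonded
#' hydrogens, acceptor atoms, acidic oxygens (ASP OD1/OD2, GLU OE1/OE2,
#' C-terminal OXT) and basic nitrogens (LYS NZ, ARG NH1/NH2/NE, HIS ND1/NE2),
#' plus partial charges and Lennard-Jones parameters.
#'
#' @param file path to a chemistry YAML file; defaults to the shipped tables.
#' @return a list with elements \code{version}, \code{backbone},
#'   \code{residues}, \code{acidic}, \code{basic}, \code{charges}, \code{lj}.
#' @export
defaultChemistry <- function(file = system.file("extdata", "chemistry.yaml",
                                                package = "abforce")) {
  yaml::read_yaml(file)
}

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Assign hydrogen-bond and salt-bridge chemistry roles
#'
#' Populates, from the chemistry tables, the per-atom roles used by the
#' contact detectors: \code{hydrogen} (with its bonded heavy-atom parent),
#' \code{donor_heavy}, \code{acceptor}, \code{acidic_oxygen} and
#' \code{basic_nitrogen}, plus partial charges and Lennard-Jones parameters
#' for the energy module.  Atoms absent from the tables get empty role sets;
#' an unknown residue name triggers a warning and empty roles, never a
#' failure.  Water O is an acceptor and the donor parent of its two H.
#' The operation is idempotent.
#'
#' @param structure a \code{\linkS4class{ComplexStructure}}.
#' @param tables chemistry tables from \code{\link{defaultChemistry}}.
#' @return the structure with roles, charges and LJ parameters populated.
#' @export
assignChemistry <- function(structure, tables = defaultChemistry()) {
  a <- atoms(structure)
  n <- nrow(a)
  a$role_hydrogen <- a$role_donor <- a$role_acceptor <- FALSE
  a$role_acidic_o <- a$role_basic_n <- FALSE
  a$hparent <- NA_integer_
  a$charge <- 0
  isH <- a$element == "H"
  a$lj_epsilon <- ifelse(isH, tables$lj$hydrogen_epsilon, tables$lj$default_epsilon)
  a$lj_sigma <- ifelse(isH, tables$lj$hydrogen_sigma, tables$lj$default_sigma)

  known <- union(names(tables$residues), .STANDARD_AA)
  unknown <- setdiff(unique(a$resname), c(known, "HOH"))
  if (length(unknown))
    warning("unknown residue name(s), roles left empty: ",
            paste(unknown, collapse = ", "), call. = FALSE)

  ## expand tables into flat lookup frames keyed (resname, atom name)
  don <- list(); acc <- list(); acid <- list(); bas <- list(); chg <- list()
  for (rn in setdiff(known, "HOH")) {
    entry <- tables$residues[[rn]]
    if (is.null(entry)) entry <- list(donors = list(), acceptors = list())
    bb_nh <- !identical(entry$backbone_nh, FALSE)
    d <- entry$donors
    if (bb_nh) d <- c(d, tables$backbone$donors)
    if (length(d))
      don[[rn]] <- data.frame(resname = rn, heavy = rep(names(d), lengths(d)),
                              hyd = unlist(d, use.names = FALSE))
    acc_atoms <- unique(c(unlist(entry$acceptors), unlist(tables$backbone$acceptors)))
    if (length(acc_atoms)) acc[[rn]] <- data.frame(resname = rn, atom = acc_atoms)
    acid_atoms <- unique(c(unlist(tables$acidic[[rn]]), unlist(tables$backbone$acidic)))
    if (length(acid_atoms)) acid[[rn]] <- data.frame(resname = rn, atom = acid_atoms)
    if (!is.null(tables$basic[[rn]]))
      bas[[rn]] <- data.frame(resname = rn, atom = unlist(tables$basic[[rn]]))
    if (!is.null(tables$charges[[rn]]))
      chg[[rn]] <- data.frame(resname = rn, atom = names(tables$charges[[rn]]),
                              q = unlist(tables$charges[[rn]], use.names = FALSE))
  }
  hoh <- tables$residues$HOH
  if (!is.null(hoh)) {
    don$HOH <- data.frame(resname = "HOH", heavy = rep(names(hoh$donors), lengths(hoh$donors)),
                          hyd = unlist(hoh$donors, use.names = FALSE))
    acc$HOH <- data.frame(resname = "HOH", atom = unlist(hoh$acceptors))
  }
  don <- do.call(rbind, don); acc <- do.call(rbind, acc)
  acid <- do.call(rbind, acid); bas <- do.call(rbind, bas)
  chg <- do.call(rbind, chg)

  key <- paste(a$resname, a$name)
  if (!is.null(don)) {
    a$role_donor <- key %in% paste(don$resname, don$heavy)
    ## hydrogens: name listed as a donor's hydrogen for this residue type
    hkey <- paste(don$resname, don$hyd)
    hmatch <- match(key, hkey)
    cand <- which(!is.na(hmatch) & isH)
    if (length(cand)) {
      a$role_hydrogen[cand] <- TRUE
      ## parent: the donor heavy atom in the same residue
      reskey <- paste(a$chain, a$resno, a$inscode)
      for (i in cand) {
        heavy_name <- don$heavy[hmatch[i]]
        j <- which(reskey == reskey[i] & a$name == heavy_name)
        if (length(j) == 1) a$hparent[i] <- a$serial[j]
        else a$role_hydrogen[i] <- FALSE  # orphan hydrogen: no parent present
      }
    }
  }
  if (!is.null(acc)) a$role_acceptor <- key %in% paste(acc$resname, acc$atom)
  if (!is.null(acid)) a$role_acidic_o <- (key %in% paste(acid$resname, acid$atom)) & a$element == "O"
  if (!is.null(bas)) a$role_basic_n <- (key %in% paste(bas$resname, bas$atom)) & a$element == "N"
  if (!is.null(chg)) {
    m <- match(key, paste(chg$resname, chg$atom))
    a$charge <- ifelse(is.na(m), 0, chg$q[m])
  }
  methods::new("ComplexStructure", atoms = a)
}

#' Place idealised hydrogens on bare donor heavy atoms
#'
#' The hydrogen-bond detector needs explicit hydrogens for the H-D-A angle
#' test.  For every donor heavy atom that carries no hydrogen in the
#' structure, one idealised hydrogen is placed 1.0 Angstrom from the donor,
#' directed away from the centroid of the other atoms of the residue (a
#' bisector-style direction); it gets the first hydrogen name the chemistry
#' tables list for that donor.  Chemistry is then re-assigned.
#'
#' @param structure a ComplexStructure with chemistry assigned.
#' @param tables chemistry tables.
#' @return the structure with idealised hydrogens added.
#' @export
addIdealHydrogens <- function(structure, tables = defaultChemistry()) {
  a <- atoms(structure)
  reskey <- paste(a$chain, a$resno, a$inscode)
  donors <- which(a$role_donor)
  new_rows <- list()
  next_serial <- max(a$serial) + 1L
  for (i in donors) {
    entry <- tables$residues[[a$resname[i]]]
    d <- entry$donors
    bb_nh <- !identical(entry$backbone_nh, FALSE)
    if (bb_nh && a$resname[i] != "HOH") d <- c(d, tables$backbone$donors)
    hyd_names <- d[[a$name[i]]]
    if (is.null(hyd_names)) next
    in_res <- which(reskey == reskey[i])
    if (any(a$name[in_res] %in% hyd_names)) next
    others <- setdiff(in_res, i)
    p <- as.numeric(a[i, c("x", "y", "z")])
    dir <- if (length(others)) {
      cen <- colMeans(a[others, c("x", "y", "z"), drop = FALSE])
      v <- p - as.numeric(cen)
      if (sum(v^2) < 1e-12) c(1, 0, 0) else v / sqrt(sum(v^2))
    } else c(1, 0, 0)
    h <- a[i, ]
    h$serial <- next_serial; next_serial <- next_serial + 1L
    h$name <- hyd_names[[1]]; h$element <- "H"
    h[, c("x", "y", "z")] <- p + dir * 1.0
    new_rows[[length(new_rows) + 1]] <- h
  }
  if (length(new_rows)) a <- rbind(a, do.call(rbind, new_rows))
  assignChemistry(complexStructure(a), tables)
}

#' Select atoms of a structure
#'
#' @param structure a ComplexStructure.
#' @param molecule,chain,resno,name,element optional filters (vectors allowed).
#' @param role optional role filter: one of hydrogen, donor, acceptor,
#'   acidic_o, basic_n.
#' @return integer vector of atom row indices.
#' @export
atomSelect <- function(structure, molecule = NULL, chain = NULL, resno = NULL,
                       name = NULL, element = NULL, role = NULL) {
  a <- atoms(structure)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(molecule)) keep <- keep & a$molecule %in% molecule
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(role)) {
    col <- paste0("role_", match.arg(role, c("hydrogen", "donor", "acceptor",
                                             "acidic_o", "basic_n")))
    keep <- keep & a[[col]]
  }
  which(keep)
}
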