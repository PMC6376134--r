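# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately use plain nested loops and explicit formulas,
# no code shared with the package internals they check.

# --- fixture builders -------------------------------------------------------

# a two-residue donor/acceptor pair with full control of D, H, A positions:
# SER OG/HG on the heavy chain, ASN OD1 on the antigen
toyDonorAcceptor <- function(D, H, A) {
  atoms <- data.frame(
    serial = 1:5,
    name = c("CA", "OD1", "CA", "OG", "HG"),
    element = c("C", "O", "C", "O", "H"),
    resname = c("ASN", "ASN", "SER", "SER", "SER"),
    chain = c("A", "A", "H", "H", "H"),
    resno = c(1L, 1L, 1L, 1L, 1L),
    molecule = c("antigen", "antigen", "heavy_chain", "heavy_chain",
                 "heavy_chain"),
    x = c(A[1] + 5, A[1], D[1] + 5, D[1], H[1]),
    y = c(A[2], A[2], D[2] + 5, D[2], H[2]),
    z = c(A[3], A[3], D[3], D[3], H[3])
  )
  assignChemistry(complexStructure(atoms))
}

# a salt-bridge pair: ASP OD1 (antigen) at O, LYS NZ (heavy) at N, with the
# NZ hydrogens far off-axis
toySaltPair <- function(O, N, o_res = "ASP", o_name = "OD1",
                        n_res = "LYS", n_name = "NZ") {
  atoms <- data.frame(
    serial = 1:5,
    name = c("CA", o_name, "CA", n_name, "HZ1"),
    element = c("C", substr(o_name, 1, 1), "C", substr(n_name, 1, 1), "H"),
    resname = c(o_res, o_res, n_res, n_res, n_res),
    chain = c("A", "A", "H", "H", "H"),
    resno = c(1L, 1L, 1L, 1L, 1L),
    molecule = c("antigen", "antigen", "heavy_chain", "heavy_chain",
                 "heavy_chain"),
    x = c(O[1] - 4, O[1], N[1] + 4, N[1], N[1]),
    y = c(O[2], O[2], N[2], N[2], N[2] + 1),
    z = c(O[3], O[3], N[3], N[3], N[3])
  )
  assignChemistry(complexStructure(atoms))
}

# random frame: residues of mixed chemistry scattered in a small box so
# distances straddle the criteria; two molecules for cross-selection
randomContactFrame <- function(seed, n_res = 16, box = 10) {
  set.seed(seed)
  resnames <- sample(c("SER", "ASN", "ASP", "LYS", "GLY", "ARG", "GLU"),
                     n_res, replace = TRUE)
  side_atoms <- list(
    SER = c("OG", "HG"), ASN = c("OD1", "ND2", "HD21", "HD22"),
    ASP = c("OD1", "OD2"), LYS = c("NZ", "HZ1", "HZ2", "HZ3"),
    GLY = character(0), ARG = c("NE", "HE", "NH1", "HH11", "HH12"),
    GLU = c("OE1", "OE2"))
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_res)) {
    half <- i > n_res / 2
    chain <- if (half) "H" else "A"
    mol <- if (half) "heavy_chain" else "antigen"
    resno <- if (half) i - n_res %/% 2 else i
    base <- runif(3, 0, box)
    nm <- c("CA", side_atoms[[resnames[i]]])
    for (an in nm) {
      serial <- serial + 1L
      el <- if (grepl("^H", an)) "H" else substr(an, 1, 1)
      p <- if (an == "CA") base else if (el == "H") {
        # hydrogens sit 1 A from their heavy parent
        parent <- rows[[length(rows)]]
        # walk back to the most recent non-H atom of this residue
        k <- length(rows)
        while (rows[[k]]$element == "H") k <- k - 1
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        c(rows[[k]]$x, rows[[k]]$y, rows[[k]]$z) + u
      } else base + runif(3, -1.5, 1.5)
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = an, element = el, resname = resnames[i],
        chain = chain, resno = as.integer(resno), molecule = mol,
        x = p[1], y = p[2], z = p[3])
    }
  }
  suppressWarnings(assignChemistry(complexStructure(do.call(rbind, rows))))
}

# --- independent detectors --------------------------------------------------

.oracleAngle <- function(a, b, c) {
  # angle at a between a->b and a->c, degrees
  v1 <- b - a; v2 <- c - a
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

oracleHBondKeys <- function(structure, selA, selB, da_max = 3.5,
                            hda_max = 60) {
  a <- atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  keys <- character(0)
  for (dirn in list(c(1, 2), c(2, 1))) {
    don_sel <- list(selA, selB)[[dirn[1]]]
    acc_sel <- list(selA, selB)[[dirn[2]]]
    for (d in don_sel) {
      if (!a$role_donor[d]) next
      hyd <- which(a$role_hydrogen & !is.na(a$hparent) &
                     a$hparent == a$serial[d])
      for (acc in acc_sel) {
        if (!a$role_acceptor[acc]) next
        if (a$chain[d] == a$chain[acc] && a$resno[d] == a$resno[acc] &&
            a$inscode[d] == a$inscode[acc]) next
        if (sqrt(sum((xyz[d, ] - xyz[acc, ])^2)) >= da_max) next
        for (h in hyd) {
          if (.oracleAngle(xyz[d, ], xyz[h, ], xyz[acc, ]) < hda_max)
            keys <- c(keys, paste(a$serial[d], a$serial[h], a$serial[acc]))
        }
      }
    }
  }
  sort(unique(keys))
}

oracleSaltBridgeKeys <- function(structure, selA, selB, on_max = 3.2) {
  a <- atoms(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  keys <- character(0)
  for (o in c(selA, selB)) {
    if (!a$role_acidic_o[o]) next
    nn_sel <- if (o %in% selA) selB else selA
    for (nn in nn_sel) {
      if (!a$role_basic_n[nn]) next
      if (a$chain[o] == a$chain[nn] && a$resno[o] == a$resno[nn]) next
      if (sqrt(sum((xyz[o, ] - xyz[nn, ])^2)) < on_max)
        keys <- c(keys, paste(a$serial[o], a$serial[nn]))
    }
  }
  sort(unique(keys))
}

hbondKeys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$donor_serial, df$hydrogen_serial, df$acceptor_serial))
}

saltKeys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$oxygen_serial, df$nitrogen_serial))
}

# --- rotation-grid superposition oracle (planar point sets) -----------------

gridSuperposeRmsd <- function(P, Q, n_grid = 20000) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = n_grid)) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    rot <- Q0 %*% t(R)
    best <- min(best, sqrt(sum((P0 - rot)^2) / nrow(P)))
  }
  best
}

# small complex spec used by several stochastic tests
smallComplexSpec <- function(K = 10, p_dist = NULL, seed = 7) {
  complexSpec(
    n_antigen_res = 2 * K + 4, n_heavy_res = 2 * K + 4, n_light_res = 0,
    n_waters = 0,
    planted_hbonds = data.frame(
      antigen_pos = 2 * seq_len(K), antibody_pos = 2 * seq_len(K),
      distance = if (is.null(p_dist)) seq(2.7, 3.2, length.out = K)
                 else rep(p_dist, K)),
    planted_saltbridges = data.frame(acidic_pos = integer(0),
                                     basic_pos = integer(0),
                                     distance = numeric(0)),
    cdr_windows = list(), seed = seed)
}
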