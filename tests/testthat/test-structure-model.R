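test_that("single ATOM records parse with exact fixed-width coordinates", {
  line <- "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C"
  s <- readPDB(line, chainMap = c(A = "antigen"))
  a <- atoms(s)
  expect_equal(nrow(a), 1L)
  expect_equal(a$name, "CA")
  expect_equal(a$resname, "GLY")
  expect_identical(c(a$x, a$y, a$z), c(1, 2, 3))
  expect_equal(a$molecule, "antigen")
})

test_that("write/read round trip is the identity on names, numbering and coordinates", {
  cx <- makeComplex(complexSpec(n_antigen_res = 6, n_heavy_res = 6,
                                n_light_res = 4, n_waters = 3,
                                planted_hbonds = data.frame(
                                  antigen_pos = c(2L, 4L),
                                  antibody_pos = c(2L, 9L),
                                  distance = c(2.9, 3.1)),
                                planted_saltbridges = data.frame(
                                  acidic_pos = 6L, basic_pos = 4L,
                                  distance = 3.0),
                                cdr_windows = list(), seed = 3))
  s <- cx$structure
  txt <- writePDB(s)
  s2 <- readPDB(paste(txt, collapse = "\n"),
                chainMap = c(A = "antigen", H = "heavy_chain",
                             L = "light_chain"))
  a1 <- atoms(s); a2 <- atoms(s2)
  expect_equal(nrow(a2), nrow(a1))
  for (col in c("serial", "name", "resname", "chain", "resno"))
    expect_equal(a2[[col]], a1[[col]])
  for (col in c("x", "y", "z"))
    expect_equal(a2[[col]], a1[[col]], tolerance = 1e-3)

  # independent reader agrees on coordinates and atom count
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(txt, tf)
  ref <- bio3d::read.pdb(tf)
  expect_equal(nrow(ref$atom), nrow(a1))
  ord <- order(ref$atom$eleno)  # file order vs serial order
  expect_equal(ref$atom$x[ord], a1$x, tolerance = 1e-3)
  expect_equal(ref$atom$resno[ord], a1$resno)
  expect_equal(trimws(ref$atom$elety[ord]), a1$name)
})

test_that("altloc policy keeps the highest occupancy, ties go to altloc A", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB BGLY A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB AGLY A   1       4.000   0.000   0.000  0.50  0.00           C")
  s <- readPDB(lines, chainMap = c(A = "antigen"))
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$name == "CA"], 2)  # higher occupancy wins
  expect_equal(a$x[a$name == "CB"], 4)  # tie resolved to altloc A
})

test_that("parse errors name the line, unmapped chains are listed", {
  bad <- c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       xxxxx   2.000   3.000  1.00  0.00           C")
  expect_error(readPDB(bad, chainMap = c(A = "antigen")), "line 2")
  good <- bad[1]
  expect_error(readPDB(good, chainMap = c(B = "antigen")), "chains found.*A")
  expect_error(readPDB("REMARK nothing here", chainMap = c(A = "antigen")),
               "no ATOM/HETATM")
})

test_that("writePDB emits HETATM for waters, TER between molecules, and rejects field overflow", {
  cx <- makeComplex(complexSpec(n_antigen_res = 3, n_heavy_res = 3,
                                n_light_res = 0, n_waters = 2,
                                planted_hbonds = data.frame(
                                  antigen_pos = integer(0),
                                  antibody_pos = integer(0),
                                  distance = numeric(0)),
                                planted_saltbridges = data.frame(
                                  acidic_pos = integer(0),
                                  basic_pos = integer(0),
                                  distance = numeric(0)),
                                cdr_windows = list(), seed = 1))
  txt <- writePDB(cx$structure)
  expect_true(any(startsWith(txt, "HETATM")))
  expect_true(all(grepl("HOH", txt[startsWith(txt, "HETATM")])))
  expect_gte(sum(txt == "TER"), 2)
  expect_identical(txt[length(txt)], "END")

  a <- atoms(cx$structure)
  a$x[1] <- 123456
  expect_error(writePDB(complexStructure(a)), "overflow")
})

test_that("chemistry assignment flags titratable roles from the tables and is idempotent", {
  atoms <- data.frame(
    serial = 1:10,
    name = c("N", "H", "CA", "O", "OD1", "OD2", "N", "CA", "NZ", "HZ1"),
    element = c("N", "H", "C", "O", "O", "O", "N", "C", "N", "H"),
    resname = c(rep("ASP", 6), rep("LYS", 4)),
    chain = "A", resno = c(rep(1L, 6), rep(2L, 4)),
    molecule = "antigen",
    x = c(0, -1, 1, 2, 3, 4, 10, 11, 12, 13), y = 0, z = 0)
  s <- assignChemistry(complexStructure(atoms))
  a <- atoms(s)
  expect_true(all(a$role_acidic_o[a$name %in% c("OD1", "OD2")]))
  expect_true(all(a$role_acceptor[a$name %in% c("OD1", "OD2", "O")]))
  expect_true(a$role_basic_n[a$name == "NZ"])
  expect_true(a$role_donor[a$name == "NZ"])
  expect_true(all(a$role_donor[a$name == "N"]))  # backbone amide
  expect_equal(a$charge[a$name == "NZ"], 1)
  expect_equal(sum(a$charge[a$name %in% c("OD1", "OD2")]), -1)
  # hydrogen bookkeeping
  expect_true(a$role_hydrogen[a$name == "HZ1"])
  expect_equal(a$hparent[a$name == "HZ1"], a$serial[a$name == "NZ"])
  # idempotence
  expect_identical(atoms(assignChemistry(s)), a)
})

test_that("unknown residues get empty roles with a warning, never a failure", {
  atoms <- data.frame(serial = 1L, name = "X1", element = "C",
                      resname = "XYZ", chain = "A", resno = 1L,
                      molecule = "antigen", x = 0, y = 0, z = 0)
  expect_warning(s <- assignChemistry(complexStructure(atoms)), "XYZ")
  expect_false(any(atoms(s)$role_donor | atoms(s)$role_acceptor))
})

test_that("water O is an acceptor and the donor parent of its two hydrogens", {
  atoms <- data.frame(
    serial = 1:3, name = c("O", "H1", "H2"), element = c("O", "H", "H"),
    resname = "HOH", chain = "W", resno = 1L, molecule = "water",
    x = c(0, 1, -1), y = 0, z = 0)
  a <- atoms(assignChemistry(complexStructure(atoms)))
  expect_true(a$role_acceptor[1] && a$role_donor[1])
  expect_true(all(a$role_hydrogen[2:3]))
  expect_equal(a$hparent[2:3], c(1L, 1L))
})

test_that("idealised hydrogens are placed 1 A from bare donors and enable detection", {
  atoms <- data.frame(
    serial = 1:2, name = c("CA", "OG"), element = c("C", "O"),
    resname = "SER", chain = "H", resno = 1L, molecule = "heavy_chain",
    x = c(-1.5, 0), y = 0, z = 0)
  s <- assignChemistry(complexStructure(atoms))
  s2 <- addIdealHydrogens(s)
  a <- atoms(s2)
  h <- a[a$role_hydrogen & !is.na(a$hparent), ]
  og <- a[a$name == "OG", ]
  expect_true(any(a$name == "HG"))
  d <- sqrt((h$x[h$name == "HG"] - og$x)^2 + (h$y[h$name == "HG"] - og$y)^2 +
              (h$z[h$name == "HG"] - og$z)^2)
  expect_equal(d, 1, tolerance = 1e-9)
  # the new hydrogen points away from the residue centroid (here, away
  # from CA), so a collinear acceptor on that side is now detectable
  expect_gt(h$x[h$name == "HG"], og$x)
})

test_that("the titratable tables stay within the standard acidic/basic residues", {
  tab <- defaultChemistry()
  expect_true(all(names(tab$acidic) %in% c("ASP", "GLU")))
  expect_true(all(names(tab$basic) %in% c("LYS", "ARG", "HIS")))
  expect_setequal(tab$acidic$ASP, c("OD1", "OD2"))
  expect_setequal(tab$acidic$GLU, c("OE1", "OE2"))
  expect_setequal(tab$basic$LYS, "NZ")
  expect_setequal(tab$basic$ARG, c("NH1", "NH2", "NE"))
  expect_setequal(tab$basic$HIS, c("ND1", "NE2"))
  expect_true("OXT" %in% tab$backbone$acidic)
  # every acidic atom the tables can produce is an oxygen name, every basic
  # one a nitrogen name
  expect_true(all(startsWith(unlist(tab$acidic), "O")))
  expect_true(all(startsWith(unlist(tab$basic), "N")))
})
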