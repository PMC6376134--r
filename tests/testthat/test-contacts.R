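test_that("hydrogen-bond geometry criteria are applied literally", {
  # inside both thresholds: d = 3.4 A, theta(H-D-A) = 0
  s <- toyDonorAcceptor(D = c(0, 0, 0), H = c(1, 0, 0), A = c(3.4, 0, 0))
  sel_a <- atomSelect(s, molecule = "antigen")
  sel_b <- atomSelect(s, molecule = "heavy_chain")
  hb <- detectHBonds(s, sel_a, sel_b)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$d_DA, 3.4)
  expect_equal(hb$theta_HDA, 0)

  # distance boundary fails (3.6 > 3.5)
  s <- toyDonorAcceptor(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0))
  expect_equal(nrow(detectHBonds(s, atomSelect(s, molecule = "antigen"),
                                 atomSelect(s, molecule = "heavy_chain"))), 0)

  # angle fails (theta = 90)
  s <- toyDonorAcceptor(c(0, 0, 0), c(1, 0, 0), c(0, 3.4, 0))
  expect_equal(nrow(detectHBonds(s, atomSelect(s, molecule = "antigen"),
                                 atomSelect(s, molecule = "heavy_chain"))), 0)
})

test_that("criteria are strict at both thresholds and symmetric in the selections", {
  eps <- 1e-6
  for (d in c(3.5 - eps, 3.5, 3.5 + eps)) {
    s <- toyDonorAcceptor(c(0, 0, 0), c(1, 0, 0), c(d, 0, 0))
    a <- atomSelect(s, molecule = "antigen")
    b <- atomSelect(s, molecule = "heavy_chain")
    n_ab <- nrow(detectHBonds(s, a, b))
    expect_equal(n_ab, as.integer(d < 3.5))
    expect_equal(nrow(detectHBonds(s, b, a)), n_ab)  # swap invariance
  }
  th <- 60 * pi / 180
  # the exact-60-degree case is not probed: acos round-off makes a float
  # boundary test meaningless there
  for (dth in c(-1e-4, 1e-4)) {
    ang <- th + dth
    s <- toyDonorAcceptor(c(0, 0, 0), c(cos(ang), sin(ang), 0), c(3, 0, 0))
    n <- nrow(detectHBonds(s, atomSelect(s, molecule = "antigen"),
                           atomSelect(s, molecule = "heavy_chain")))
    expect_equal(n, as.integer(dth < 0))  # strict "<" at the 60 degree rule
  }
})

test_that("the conventional D-H-A angle mode is available as a cross-check", {
  # linear D-H...A arrangement: H-D-A angle 0 (passes default), D-H-A 180
  s <- toyDonorAcceptor(c(0, 0, 0), c(1, 0, 0), c(3.2, 0, 0))
  a <- atomSelect(s, molecule = "antigen")
  b <- atomSelect(s, molecule = "heavy_chain")
  expect_equal(nrow(detectHBonds(s, a, b, contactCriteria(angle_mode = "dha"))), 1)
  # bent at H to 90 degrees: fails the conventional >= 120 rule
  s <- toyDonorAcceptor(c(0, 0, 0), c(1, 0, 0), c(1, 2.5, 0))
  expect_equal(nrow(detectHBonds(s, atomSelect(s, molecule = "antigen"),
                                 atomSelect(s, molecule = "heavy_chain"),
                                 contactCriteria(angle_mode = "dha"))), 0)
})

test_that("salt-bridge detection needs an acidic O / basic N pair strictly below 3.2 A", {
  s <- toySaltPair(O = c(0, 0, 0), N = c(3.1, 0, 0))
  a <- atomSelect(s, molecule = "antigen")
  b <- atomSelect(s, molecule = "heavy_chain")
  sb <- detectSaltBridges(s, a, b)
  expect_equal(nrow(sb), 1)
  expect_equal(sb$d_ON, 3.1)
  expect_equal(nrow(detectSaltBridges(s, b, a)), 1)

  s <- toySaltPair(O = c(0, 0, 0), N = c(3.2, 0, 0))
  expect_equal(nrow(detectSaltBridges(s, atomSelect(s, molecule = "antigen"),
                                      atomSelect(s, molecule = "heavy_chain"))), 0)

  # two acidic oxygens do not form a bridge
  s <- toySaltPair(O = c(0, 0, 0), N = c(2.8, 0, 0), n_res = "ASP",
                   n_name = "OD1")
  expect_equal(nrow(detectSaltBridges(s, atomSelect(s, molecule = "antigen"),
                                      atomSelect(s, molecule = "heavy_chain"))), 0)
})

test_that("detectors agree with the brute-force all-pairs oracle on random frames", {
  for (seed in 1:40) {
    s <- randomContactFrame(seed, n_res = sample(8:20, 1))
    a <- atomSelect(s, molecule = "antigen")
    b <- atomSelect(s, molecule = "heavy_chain")
    hb <- suppressWarnings(detectHBonds(s, a, b))
    expect_identical(hbondKeys(hb), oracleHBondKeys(s, a, b))
    sb <- detectSaltBridges(s, a, b)
    expect_identical(saltKeys(sb), oracleSaltBridgeKeys(s, a, b))
  }
})

test_that("count series report per-frame counts, overall stats, and exact block tiling", {
  cx <- makeComplex(smallComplexSpec(K = 7))
  ag <- atomSelect(cx$structure, molecule = "antigen")
  ab <- atomSelect(cx$structure, molecule = c("heavy_chain", "light_chain"))

  traj <- makeTrajectory(cx$structure,
                         trajectorySpec(n_frames = 10, noise_sigma = 0,
                                        contact_persistence = 1, seed = 1),
                         planted = cx$contacts)
  ser <- countSeries(traj, "hbond", ag, ab)
  expect_equal(seriesValues(ser), rep(7L, 10))
  expect_equal(ser@mean, 7)
  expect_equal(ser@sd, 0)

  traj <- makeTrajectory(cx$structure,
                         trajectorySpec(n_frames = 200, frame_interval = 1,
                                        noise_sigma = 0, seed = 2),
                         planted = cx$contacts)
  ser <- countSeries(traj, "hbond", ag, ab, block_length = 50)
  b <- blockStats(ser)
  expect_equal(nrow(b), 4)
  expect_equal(b$n_frames, rep(50L, 4))
  expect_false(any(b$partial))
  ser2 <- countSeries(traj, "hbond", ag, ab, block_length = 60)
  expect_true(tail(blockStats(ser2)$partial, 1))

  expect_error(countSeries(methods::new("Trajectory",
                                        topology = cx$structure,
                                        coords = array(0, c(nAtoms(cx$structure), 3, 0)),
                                        times = numeric(0)),
                           "hbond", ag, ab), "empty")
})

test_that("persistence 0.5 over 8 contacts gives the binomial mean 4.0", {
  cx <- makeComplex(smallComplexSpec(K = 8))
  traj <- makeTrajectory(cx$structure,
                         trajectorySpec(n_frames = 2000, frame_interval = 1,
                                        noise_sigma = 0,
                                        contact_persistence = 0.5, seed = 3),
                         planted = cx$contacts)
  ag <- atomSelect(cx$structure, molecule = "antigen")
  ab <- atomSelect(cx$structure, molecule = c("heavy_chain", "light_chain"))
  ser <- countSeries(traj, "hbond", ag, ab)
  expect_equal(mean(seriesValues(ser)[-1]), 4.0, tolerance = 0.15 / 4)
})

fakeRecords <- function(ab_chain, ab_resno, ag_resno = seq_along(ab_chain)) {
  n <- length(ab_chain)
  if (n == 0) return(fakeRecords("H", 1L)[0, ])
  data.frame(
    donor_serial = seq_len(n), hydrogen_serial = seq_len(n) + 100,
    acceptor_serial = seq_len(n) + 200,
    donor_chain = ab_chain, donor_resno = ab_resno,
    donor_resname = "SER",
    donor_molecule = ifelse(ab_chain == "H", "heavy_chain", "light_chain"),
    acceptor_chain = "A", acceptor_resno = ag_resno,
    acceptor_resname = "ASN", acceptor_molecule = "antigen",
    d_DA = 3, theta_HDA = 10, frame = 1L)
}

toyAnnotation <- function() {
  methods::new("RegionAnnotation",
               cdr = list(h2 = data.frame(chain = "H", resno = 15:20),
                          h3 = data.frame(chain = "H", resno = 25:32),
                          l3 = data.frame(chain = "L", resno = 25:32)),
               variable = data.frame(chain = rep(c("H", "L"), each = 35),
                                     resno = rep(1:35, 2)),
               constant = data.frame(chain = character(0), resno = integer(0)),
               windows = data.frame(label = character(0), start = integer(0),
                                    end = integer(0)))
}

test_that("CDR fraction is the share of bonds touching any CDR, with breakdowns", {
  ann <- toyAnnotation()
  # 3 in h3, 2 in h2, 1 in l3, 4 outside -> 30/20/10, total 60
  rec <- fakeRecords(c(rep("H", 3), rep("H", 2), "L", rep("H", 2), "L", "L"),
                     c(26, 27, 28, 16, 17, 26, 1, 2, 1, 2))
  res <- cdrFraction(rec, ann)
  expect_equal(res$total_pct, 60)
  expect_equal(unname(res$per_cdr[c("h3", "h2", "l3")]), c(30, 20, 10))
  expect_equal(sum(res$per_cdr), res$total_pct)
  expect_equal(unname(res$per_chain), c(70, 30))

  all_cdr <- fakeRecords(rep("H", 4), c(26, 27, 16, 17))
  expect_equal(cdrFraction(all_cdr, ann)$total_pct, 100)

  none <- cdrFraction(fakeRecords(character(0), integer(0)), ann)
  expect_true(none$no_contact)
  expect_true(is.na(none$total_pct))
})

test_that("anchor ranking orders by count with ties broken by residue number", {
  rec <- fakeRecords(rep("H", 120), rep(1, 120),
                     ag_resno = rep(c(108, 1, 104), c(50, 40, 30)))
  rk <- rankingTable(rankAnchorResidues(rec))
  expect_equal(rk$resno, c(108, 1, 104))
  expect_equal(rk$count, c(50, 40, 30))
  expect_true(all(diff(rk$count) <= 0))

  tie <- fakeRecords(rep("H", 10), rep(1, 10),
                     ag_resno = rep(c(10, 2), c(5, 5)))
  expect_equal(rankingTable(rankAnchorResidues(tie))$resno, c(2, 10))

  expect_error(rankAnchorResidues(fakeRecords(character(0), integer(0))),
               "at least one")
})

test_that("planted per-residue persistence order is recovered from a trajectory", {
  spec <- complexSpec(
    n_antigen_res = 10, n_heavy_res = 10, n_light_res = 0, n_waters = 0,
    planted_hbonds = data.frame(antigen_pos = c(2L, 5L, 8L),
                                antibody_pos = c(2L, 5L, 8L),
                                distance = c(3, 3, 3)),
    planted_saltbridges = data.frame(acidic_pos = integer(0),
                                     basic_pos = integer(0),
                                     distance = numeric(0)),
    cdr_windows = list(), seed = 21)
  cx <- makeComplex(spec)
  traj <- makeTrajectory(cx$structure,
                         trajectorySpec(n_frames = 2000, frame_interval = 1,
                                        noise_sigma = 0,
                                        contact_persistence = c(0.9, 0.7, 0.5),
                                        seed = 22),
                         planted = cx$contacts)
  ag <- atomSelect(cx$structure, molecule = "antigen")
  ab <- atomSelect(cx$structure, molecule = "heavy_chain")
  rec <- do.call(rbind, lapply(seq_len(nFrames(traj)), function(f)
    detectHBonds(cx$structure, ag, ab, coords = frameCoords(traj, f),
                 frame = f)))
  rk <- rankingTable(rankAnchorResidues(rec))
  expect_equal(rk$resno, c(2, 5, 8))  # persistence 0.9 > 0.7 > 0.5
})
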