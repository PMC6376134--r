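# two-bead system: one mobile pulled bead, one fixed, optional single bond
twoBeadSystem <- function(bond = NULL, ...) {
  pullingSystem(rbind(c(0, 0, 0), c(5, 0, 0)), fixed = c(FALSE, TRUE),
                pulled = 1, bonds = bond, direction = c(-1, 0, 0),
                temperature = 0, ...)
}

test_that("spring force converts kcal/mol/A to pN and is linear", {
  expect_equal(springForce(2.15, 0), 0)
  expect_equal(springForce(2.15, 1), 149.4, tolerance = 1e-3)
  expect_equal(springForce(2.15, 2), 2 * springForce(2.15, 1))
  expect_equal(springForce(1, 1), 69.479)
})

test_that("the per-timestep pulling displacement converts to A/ps", {
  expect_identical(pullingVelocity(0.00005, 0.002), 0.025)
  expect_equal(pullingVelocity(0.1, 0.1), 1)
})

test_that("system defaults follow the constant-velocity protocol", {
  s <- twoBeadSystem()
  expect_equal(s@spring_k, 2.15)
  expect_equal(s@velocity, 0.025)
  expect_equal(s@timestep, 0.002)
  s2 <- pullingSystem(rbind(c(0, 0, 0), c(5, 0, 0)), fixed = c(FALSE, TRUE),
                      pulled = 1)
  expect_equal(s2@temperature, 310)
})

test_that("standard builds: 13 interface bonds full, 5 in the 92-106 window", {
  cx <- makeComplex(complexSpec())
  hb <- cx$contacts[cx$contacts$type == "hbond", ]
  full <- buildPullingSystem(cx$structure, hb)
  expect_equal(sum(full@bonds$breakable), 13)
  sub <- buildPullingSystem(cx$structure, hb, window = c(92, 106))
  expect_equal(sum(sub@bonds$breakable), 5)
  sub_bonds <- sub@bead_info[sub@bonds$i[sub@bonds$breakable], ]
  expect_setequal(sub_bonds$resno, c(102, 103, 104, 105, 106))
  # a pulled bead that is also fixed is rejected
  expect_error(buildPullingSystem(cx$structure, hb,
                                  anchors = list(c("A", 110)),
                                  pulled = c("A", 110)), "cannot")
})

test_that("with no bonds at T = 0 the force plateaus at the analytic drag gamma*v", {
  s <- twoBeadSystem()
  run <- runPulling(s, duration = 600, early_stop = FALSE)
  tr <- forceTrace(run$curve)
  plateau <- mean(tail(tr$force_pN, 100))
  expect_equal(plateau, 1 * 0.025 * 69.479, tolerance = 1e-4)
})

test_that("quasi-static single-bond rupture matches the analytic break force", {
  s <- twoBeadSystem(bond = data.frame(i = 1, j = 2, r0 = 5, k = 10,
                                       break_ext = 2, breakable = TRUE))
  run <- runPulling(s, duration = 1500)
  expect_true(run$event@ruptured)
  f_star <- springForce(10, 2)  # 1389.6 pN
  expect_equal(run$event@rupture_force, f_star, tolerance = 0.05)
  # the simulator's recorded maximum matches the curve-level extraction
  ev <- extractRupture(run$curve)
  expect_true(ev@ruptured)
  expect_equal(ev@rupture_force, run$event@rupture_force, tolerance = 0.05)
})

test_that("a run that never separates is flagged unruptured, not an error", {
  s <- twoBeadSystem(bond = data.frame(i = 1, j = 2, r0 = 5, k = 10,
                                       break_ext = 50, breakable = TRUE))
  run <- runPulling(s, duration = 50)
  expect_false(run$event@ruptured)
  expect_true(is.na(run$event@rupture_force))
  expect_error(replicateStats(list(run$event, run$event)), "duration")
})

test_that("rupture force grows with bond count and stiffness, and with velocity", {
  mkParallel <- function(n_bonds, k_bond = 5, v = 0.025) {
    # n bonds side by side between a mobile plate bead and fixed partners
    pos <- rbind(c(0, 0, 0),
                 t(vapply(seq_len(n_bonds),
                          function(i) c(5, 2 * i - n_bonds - 1, 0),
                          numeric(3))))
    r0 <- sqrt(25 + (2 * seq_len(n_bonds) - n_bonds - 1)^2)
    pullingSystem(pos, fixed = c(FALSE, rep(TRUE, n_bonds)), pulled = 1,
                  bonds = data.frame(i = 1, j = 1 + seq_len(n_bonds),
                                     r0 = r0, k = k_bond, break_ext = 1.5,
                                     breakable = TRUE),
                  direction = c(-1, 0, 0), temperature = 0, velocity = v)
  }
  f <- vapply(c(1, 3, 6), function(n)
    runPulling(mkParallel(n), duration = 2500)$event@rupture_force,
    numeric(1))
  expect_true(all(diff(f) > 0))

  f_soft <- runPulling(mkParallel(2, k_bond = 3), duration = 2500)
  f_stiff <- runPulling(mkParallel(2, k_bond = 9), duration = 2500)
  expect_gt(f_stiff$event@rupture_force, f_soft$event@rupture_force)

  f_slow <- runPulling(mkParallel(2, v = 0.025), duration = 2500)
  f_fast <- runPulling(mkParallel(2, v = 0.25), duration = 400)
  expect_gt(f_fast$event@rupture_force, f_slow$event@rupture_force)
})

test_that("at T = 0 the spring work exceeds the released bond energy", {
  s <- twoBeadSystem(bond = data.frame(i = 1, j = 2, r0 = 5, k = 10,
                                       break_ext = 2, breakable = TRUE))
  run <- runPulling(s, duration = 1500, record_every = 0.1)
  tr <- forceTrace(run$curve)
  # W = integral F dx over the anchor path, force back to kcal/mol/A
  w_kcal <- sum(tr$force_pN / 69.479) * 0.025 * 0.1
  released <- 0.5 * 10 * 2^2
  expect_gt(w_kcal, released)
})

test_that("the force curve shows the three-phase shape on a noise-free run", {
  s <- twoBeadSystem(bond = data.frame(i = 1, j = 2, r0 = 5, k = 10,
                                       break_ext = 2, breakable = TRUE))
  run <- runPulling(s, duration = 1500, early_stop = FALSE)
  ev <- extractRupture(run$curve)
  expect_true(ev@ruptured)
  ph <- ev@phases
  expect_lt(ph[["maintenance_end"]], ph[["detachment_end"]])
  tr <- forceTrace(run$curve)
  # rise during maintenance, near-zero drag plateau during separation
  pre <- tr$force_pN[tr$time_ps < ph[["maintenance_end"]]]
  expect_gt(stats::cor(seq_along(pre), pre), 0.99)
  post <- tr$force_pN[tr$time_ps > ph[["detachment_end"]] + 100]
  expect_lt(mean(post), 0.1 * ev@rupture_force)
})

test_that("subset pulls rupture below full-interface pulls across 20 replicates", {
  cx <- makeComplex(complexSpec())
  hb <- cx$contacts[cx$contacts$type == "hbond", ]
  full <- buildPullingSystem(cx$structure, hb, timestep = 0.01)
  sub <- buildPullingSystem(cx$structure, hb, window = c(92, 106),
                            timestep = 0.01)
  rf <- runReplicates(full, n = 20, seed = 101, duration = 3000)
  rs <- runReplicates(sub, n = 20, seed = 202, duration = 3000)
  f_full <- vapply(rf$events, function(e) e@rupture_force, numeric(1))
  f_sub <- vapply(rs$events, function(e) e@rupture_force, numeric(1))
  expect_equal(replicateStats(rf$events)$n, 20)
  w <- stats::wilcox.test(f_sub, f_full, alternative = "less")
  expect_lt(w$p.value, 0.01)
})

test_that("replicate statistics and seeded determinism", {
  ev <- function(f) methods::new("RuptureEvent", rupture_force = f,
                                 rupture_time = 100, ruptured = TRUE,
                                 phases = c(maintenance_end = 100,
                                            detachment_end = 150),
                                 meta = list())
  st <- replicateStats(list(ev(500), ev(500), ev(500)))
  expect_equal(st$mean, 500)
  expect_equal(st$sd, 0)
  st2 <- replicateStats(list(ev(400), ev(600)))
  expect_equal(st2$mean, 500)
  expect_equal(st2$sd, 141.4214, tolerance = 1e-4)

  s <- twoBeadSystem(bond = data.frame(i = 1, j = 2, r0 = 5, k = 5,
                                       break_ext = 1, breakable = TRUE))
  s@temperature <- 310
  r1 <- runReplicates(s, n = 3, seed = 7, duration = 400)
  r2 <- runReplicates(s, n = 3, seed = 7, duration = 400)
  expect_identical(lapply(r1$events, function(e) e@rupture_force),
                   lapply(r2$events, function(e) e@rupture_force))
  expect_identical(r1$curves[[1]]@force, r2$curves[[1]]@force)
})
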