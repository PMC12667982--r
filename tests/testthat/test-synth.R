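test_that("motif implantation is seeded, validated and scanner-clean", {
  s1 <- implantMotifs(seed = 5)
  s2 <- implantMotifs(seed = 5)
  expect_identical(s1$residues, s2$residues)
  expect_false(identical(implantMotifs(seed = 6)$residues, s1$residues))
  # motif-free background scans clean
  bg <- implantMotifs(length = 300, anchors = integer(0), seed = 5)
  expect_equal(nRepeats(scanPseudoRepeats(bg)), 0L)
  expect_length(oracleMotifCandidates(bg$residues), 0)
  expect_error(implantMotifs(anchors = c(100, 104)), "overlapping")
  expect_error(implantMotifs(length = 100, anchors = 95), "anchor")
})

test_that("correlated-trajectory generator hits its target statistics", {
  # target 1: identical displacement series
  t1 <- matrix(1, 2, 2)
  ens1 <- simulateCorrelatedTrajectory(t1, nA = 1, nB = 1, nFrames = 50,
                                       seed = 2)
  d1 <- sweep(ens1@runs[[1]][, 1, ], 2, colMeans(ens1@runs[[1]][, 1, ]))
  d2 <- sweep(ens1@runs[[1]][, 2, ], 2, colMeans(ens1@runs[[1]][, 2, ]))
  expect_equal(d1, d2, tolerance = 1e-8)
  # target 0: independent series at n = 10,000
  t0 <- diag(2)
  ens0 <- simulateCorrelatedTrajectory(t0, nA = 1, nB = 1,
                                       nFrames = 10000, seed = 3)
  c0 <- correlationMatrix(correlationMap(ens0, "A", "B"))[1, 1]
  expect_lt(abs(c0), 0.05)
  # target 0.8 lands in the binormal sampling band
  t8 <- diag(2); t8[1, 2] <- t8[2, 1] <- 0.8
  ens8 <- simulateCorrelatedTrajectory(t8, nA = 1, nB = 1,
                                       nFrames = 10000, seed = 7)
  c8 <- correlationMatrix(correlationMap(ens8, "A", "B"))[1, 1]
  expect_gte(c8, 0.78); expect_lte(c8, 0.82)
  # non-PSD target is rejected
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_error(simulateCorrelatedTrajectory(bad, 2, 1), "semidefinite")
})

test_that("contact fixtures produce exact or Bernoulli frame counts", {
  prs <- data.frame(res_a = "A:1", res_b = "B:2")
  fx <- makeContactFixture("salt_bridge", p = 0.21, nFrames = 200, seed = 1)
  rec <- classifyContacts(fx, prs, type = "salt_bridge")
  expect_equal(rec$occupancy[rec$run == "pooled"], 42 / 200)
  expect_equal(sum(attr(fx, "satisfied")), 42L)
  # p = 0 and p = 1 extremes
  expect_equal(nrow(classifyContacts(
    makeContactFixture("salt_bridge", p = 0, nFrames = 20, seed = 1),
    prs, type = "salt_bridge")), 0L)
  rec1 <- classifyContacts(
    makeContactFixture("salt_bridge", p = 1, nFrames = 20, seed = 1),
    prs, type = "salt_bridge")
  expect_equal(rec1$occupancy, c(1, 1))
  # generated trajectories satisfy the ensemble validity contract
  expect_true(validObject(fx))
})

test_that("dynamic-instability generator honors its rate parameters", {
  # kcat = 0: monotone growth, no events
  g <- simulateDynamicInstability(nTraces = 3, duration_s = 120, kcat = 0,
                                  noise_um = 0, frameInterval_s = 1,
                                  seed = 8)
  expect_equal(nrow(g$events), 0L)
  expect_true(all(vapply(g$traces, function(tr)
    all(diff(tr$position_um) >= -1e-12), logical(1))))
  # vs = 0: no decrease beyond noise
  s0 <- simulateDynamicInstability(nTraces = 3, duration_s = 120, vs = 0,
                                   kcat = 2, noise_um = 0.02,
                                   frameInterval_s = 1, seed = 9)
  expect_true(all(vapply(s0$traces, function(tr)
    min(diff(tr$position_um)) > -0.2, logical(1))))
  # exponential growth-phase holding time: mean ~ 1/kcat
  di <- simulateDynamicInstability(nTraces = 400, duration_s = 300,
                                   kcat = 1, kres = 0, vg = 1,
                                   initialLength_um = 20,
                                   noise_um = 0, seed = 10)
  ev <- di$events
  holds <- unlist(lapply(split(ev, ev$trace), function(d) {
    cat_t <- d$time_s[d$to == "shrinkage"]
    res_t <- c(0, d$time_s[d$to == "growth"])
    # first growth phase per trace: from t=0 to first catastrophe
    if (length(cat_t)) cat_t[1]
  })) / 60
  expect_gt(length(holds), 300)
  se <- sd(holds) / sqrt(length(holds))
  expect_lt(abs(mean(holds) - 1), 3 * se)
})

test_that("track and binding-curve generators match their models", {
  none <- simulateTracks(nMTs = 5, landingRate = 0, seed = 3)
  expect_equal(nrow(none$tracks), 0L)
  expect_equal(nrow(none$mts), 5L)
  # Poisson mean recovery across 100 MTs
  sim <- simulateTracks(nMTs = 100, landingRate = 0.8, seed = 4)
  lam <- 0.8 * sim$mts$length_um[1] * sim$mts$duration_s[1] / 60
  counts <- as.integer(table(factor(sim$tracks$mt_id,
                                    levels = sim$mts$mt_id)))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - lam), 3 * se)
  # noise-free curve reproduces the isotherm exactly
  cv <- simulateBindingCurve(kd = 61, imax = 2, noiseFraction = 0,
                             replicates = 1, seed = 5)
  expect_equal(cv$intensity, 2 * cv$conc_nM / (61 + cv$conc_nM),
               tolerance = 1e-12)
})

test_that("every generator is deterministic per seed and streams are
           independent", {
  expect_identical(simulateBindingCurve(seed = 3),
                   simulateBindingCurve(seed = 3))
  expect_identical(simulateTracks(seed = 3), simulateTracks(seed = 3))
  a <- simulateDynamicInstability(nTraces = 2, duration_s = 60, seed = 3)
  b <- simulateDynamicInstability(nTraces = 2, duration_s = 60, seed = 3)
  expect_identical(a, b)
  e1 <- simulateCorrelatedTrajectory(diag(2), 1, 1, nFrames = 10, seed = 3)
  e2 <- simulateCorrelatedTrajectory(diag(2), 1, 1, nFrames = 10, seed = 3)
  expect_identical(e1@runs, e2@runs)
  # labeled sub-streams differ from each other under one top seed
  expect_false(subSeed(3, "tracks") == subSeed(3, "binding_curve"))
})
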