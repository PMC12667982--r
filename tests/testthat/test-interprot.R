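test_that("degenerate and perfectly correlated motions are recognized", {
  top <- makeCaTopology(2, 2)
  # all frames identical: zero variance everywhere
  arr <- array(rep(c(1, 2, 3, 4), each = 1), c(6, 4, 3))
  for (i in 1:4) for (d in 1:3) arr[, i, d] <- i * 10
  ens <- trajectoryEnsemble(top, arr)
  an <- correlationMap(ens, "A", "B")
  expect_true(all(an@degenerate))
  expect_true(all(correlationMatrix(an) == 0))
  # group B copies group A displacements: c = +1; negated copy: c = -1
  set.seed(1)
  disp <- matrix(rnorm(40 * 3), 40, 3)
  arr2 <- array(0, c(40, 4, 3))
  arr2[, 1, ] <- disp
  arr2[, 2, ] <- 2 * disp        # same direction, scaled
  arr2[, 3, ] <- disp + 100      # copy, offset
  arr2[, 4, ] <- -disp           # negated
  an2 <- correlationMap(trajectoryEnsemble(top, arr2), "A", "B")
  cm <- correlationMatrix(an2)
  expect_equal(cm["A:1", "B:1"], 1, tolerance = 1e-12)
  expect_equal(cm["A:1", "B:2"], -1, tolerance = 1e-12)
  expect_equal(cm["A:2", "B:1"], 1, tolerance = 1e-12)
})

test_that("correlation map matches the sample-statistics oracle", {
  target <- diag(4)
  target[1, 3] <- target[3, 1] <- 0.8
  ens <- simulateCorrelatedTrajectory(target, nA = 2, nB = 2,
                                      nFrames = 10000, seed = 7)
  an <- correlationMap(ens, "A", "B")
  cm <- correlationMatrix(an)
  expect_true(all(abs(cm) <= 1))
  expect_equal(cm["A:1", "B:1"], 0.8, tolerance = 0.02)
  # identical numbers as a textbook sample correlation on the same draws
  X <- ens@runs[[1]]
  for (i in 1:2) for (j in 1:2)
    expect_equal(cm[i, j], oracleSampleCorrelation(X, i, 2 + j),
                 tolerance = 1e-12)
})

test_that("self-map is symmetric with unit diagonal", {
  target <- diag(3); target[1, 2] <- target[2, 1] <- -0.5
  ens <- simulateCorrelatedTrajectory(target, nA = 3, nB = 0,
                                      nFrames = 400, seed = 5)
  an <- correlationMap(ens, "A", "A")
  cm <- correlationMatrix(an)
  expect_lt(max(abs(cm - t(cm))), 1e-12)
  expect_equal(unname(diag(cm)), rep(1, 3), tolerance = 1e-12)
})

test_that("distance filter retains pairs per the brute-force criterion", {
  rules <- contactRules()
  far <- makeContactFixture("salt_bridge", distances = rep(50, 8))
  anF <- correlationMap(far, "A", "B")
  expect_equal(nrow(filterPairs(far, anF, rules)), 0L)
  near <- makeContactFixture("salt_bridge", distances = rep(5, 8))
  anN <- correlationMap(near, "A", "B")
  expect_equal(nrow(filterPairs(near, anN, rules)), 1L)
  # brute-force per-frame minimum heavy-atom distances on a random system
  sys <- randomContactSystem(21, nFrames = 10, spread = 18)
  an <- correlationMap(sys, "A", "B")
  got <- filterPairs(sys, an, rules)
  top <- topology(sys); arr <- sys@runs[[1]]
  heavy <- which(top$element != "H")
  mind <- vapply(seq_len(dim(arr)[1]), function(f) {
    dmin <- Inf
    for (i in intersect(which(top$chain == "A"), heavy))
      for (j in intersect(which(top$chain == "B"), heavy))
        dmin <- min(dmin, sqrt(sum((arr[f, i, ] - arr[f, j, ])^2)))
    dmin
  }, numeric(1))
  should <- mean(mind <= rules$contactFilterCutoff) >=
    rules$contactFilterMinFraction
  expect_equal(nrow(got) == 1L, should)
})

test_that("classifier boundaries straddle every cutoff", {
  pairs <- data.frame(res_a = "A:1", res_b = "B:2")
  # salt bridge at 5.9 vs 6.1 Angstrom
  sb_in <- makeContactFixture("salt_bridge", distances = rep(5.9, 5))
  rec <- classifyContacts(sb_in, pairs, type = "salt_bridge")
  expect_equal(rec$occupancy[rec$run == "pooled"], 1.0)
  sb_out <- makeContactFixture("salt_bridge", distances = rep(6.1, 5))
  expect_equal(nrow(classifyContacts(sb_out, pairs, type = "salt_bridge")),
               0L)
  # hydrogen bond: 3.4 Angstrom passes when linear, fails at 45 degrees
  hb <- makeContactFixture("hydrogen_bond", distances = rep(3.4, 4))
  rec <- classifyContacts(hb, pairs, type = "hydrogen_bond")
  expect_equal(rec$occupancy[rec$run == "pooled"], 1.0)
  expect_false(any(rec$distance_only))
  # rotate the donor hydrogen 45 degrees off the donor-acceptor axis:
  # the D-H...A arrangement is then far from linear and must be rejected
  bent <- hb
  top <- topology(bent)
  h <- which(top$name == "HG")
  og <- which(top$name == "OG")
  a <- which(top$name == "OE1")
  for (f in 1:4)
    bent@runs[[1]][f, h, ] <- bent@runs[[1]][f, og, ] +
      0.96 * c(cos(pi / 4), sin(pi / 4), 0)
  v1 <- bent@runs[[1]][1, og, ] - bent@runs[[1]][1, h, ]
  v2 <- bent@runs[[1]][1, a, ] - bent@runs[[1]][1, h, ]
  dev <- 180 - acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_gt(dev, 30)  # guard: the geometry really is bent
  expect_equal(nrow(classifyContacts(bent, pairs, type = "hydrogen_bond")),
               0L)
  # hydrophobic occupancy equals a per-frame brute-force count
  hp <- makeContactFixture("hydrophobic", p = 0.21, nFrames = 200, seed = 9)
  rec <- classifyContacts(hp, pairs, type = "hydrophobic")
  expect_equal(rec$occupancy[rec$run == "pooled"], 42 / 200)
  oracle <- oracleContactFrames(hp, "A:1", "B:2", "hydrophobic")
  expect_equal(rec$occupancy[rec$run == "pooled"], mean(oracle))
  # repulsive boundary
  rp_in <- makeContactFixture("repulsive", distances = rep(11.9, 5))
  expect_equal(classifyContacts(rp_in, pairs,
                                type = "repulsive")$occupancy[2], 1.0)
  rp_out <- makeContactFixture("repulsive", distances = rep(12.1, 5))
  expect_equal(nrow(classifyContacts(rp_out, pairs, type = "repulsive")),
               0L)
})

test_that("classifier equals the all-pairs oracle on random geometries", {
  pairs <- data.frame(res_a = "A:1", res_b = "B:2")
  types <- c("salt_bridge", "hydrogen_bond", "hydrophobic", "repulsive")
  for (seed in 1:12) {
    sys <- randomContactSystem(seed, nFrames = 8, spread = 14)
    expect_lte(nrow(topology(sys)), 50)
    rec <- classifyContacts(sys, pairs)
    for (tp in types) {
      oracle <- oracleContactFrames(sys, "A:1", "B:2", tp)
      got <- rec$occupancy[rec$type == tp & rec$run == "pooled"]
      if (mean(oracle) > 0) expect_equal(got, mean(oracle))
      else expect_length(got, 0)
    }
  }
})

test_that("Bernoulli occupancy concentrates around p", {
  p <- 0.3; n <- 400
  fx <- makeContactFixture("salt_bridge", p = p, nFrames = n,
                           mode = "bernoulli", seed = 13)
  rec <- classifyContacts(fx, data.frame(res_a = "A:1", res_b = "B:2"),
                          type = "salt_bridge")
  occ <- rec$occupancy[rec$run == "pooled"]
  expect_lt(abs(occ - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("rigid-body motion leaves correlations and contacts unchanged", {
  target <- diag(4); target[1, 4] <- target[4, 1] <- 0.6
  ens <- simulateCorrelatedTrajectory(target, nA = 2, nB = 2,
                                      nFrames = 300, seed = 2)
  cm0 <- correlationMatrix(correlationMap(ens, "A", "B"))
  shifted <- ens
  shifted@runs[[1]] <- sweep(ens@runs[[1]], 3, c(10, -4, 2), "+")
  cm1 <- correlationMatrix(correlationMap(shifted, "A", "B"))
  expect_equal(cm1, cm0, tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rotated <- ens
  arr <- ens@runs[[1]]
  flat <- array(arr, c(dim(arr)[1] * dim(arr)[2], 3)) %*% t(R)
  rotated@runs[[1]] <- array(flat, dim(arr))
  cm2 <- correlationMatrix(correlationMap(rotated, "A", "B"))
  expect_equal(cm2, cm0, tolerance = 1e-9)
  # contacts: translation invariance of occupancies
  fx <- makeContactFixture("salt_bridge", p = 0.4, nFrames = 50, seed = 4)
  prs <- data.frame(res_a = "A:1", res_b = "B:2")
  rec0 <- classifyContacts(fx, prs)
  fx@runs[[1]] <- sweep(fx@runs[[1]], 3, c(-7, 3, 11), "+")
  rec1 <- classifyContacts(fx, prs)
  expect_equal(rec1$occupancy, rec0$occupancy)
})

test_that("interaction summary reports run statistics and type rows", {
  # two runs with occupancies 0.16 and 0.26 -> mean 0.21, population SD 0.05
  d_in <- 5; d_out <- 10
  dists <- c(ifelse(seq_len(50) <= 8, d_in, d_out),
             ifelse(seq_len(50) <= 13, d_in, d_out))
  fx <- makeContactFixture("salt_bridge", distances = dists, nRuns = 2)
  an <- correlationMap(fx, "A", "B")
  rec <- classifyContacts(fx, data.frame(res_a = "A:1", res_b = "B:2"),
                          type = "salt_bridge")
  smry <- interactionSummary(rec, an)
  expect_equal(smry$occupancy_mean, 0.21)
  expect_equal(smry$occupancy_sd, 0.05)
  expect_identical(attr(smry, "sd_convention"), "population")
  # single run: SD zero
  fx1 <- makeContactFixture("salt_bridge", p = 0.5, nFrames = 20, seed = 3)
  rec1 <- classifyContacts(fx1, data.frame(res_a = "A:1", res_b = "B:2"),
                           type = "salt_bridge")
  smry1 <- interactionSummary(rec1, correlationMap(fx1, "A", "B"))
  expect_equal(smry1$occupancy_sd, 0)
  # a pair can carry both an attractive and a repulsive row: a C-terminal
  # lysine (NZ basic, OXT acidic) against a glutamate
  top2 <- makeTopology(serial = 1:6,
                       name = c("CA", "NZ", "OXT", "CA", "OE1", "CB"),
                       resid = c(rep("LYS", 3), rep("GLU", 3)),
                       resno = c(1L, 1L, 1L, 2L, 2L, 2L),
                       chain = c("A", "A", "A", "B", "B", "B"),
                       group = c("A", "A", "A", "B", "B", "B"))
  arr2 <- array(0, c(4, 6, 3))
  for (f in 1:4) {
    arr2[f, 1, ] <- c(-1.5, 0, 0)   # LYS CA
    arr2[f, 2, ] <- c(0, 0, 0)      # NZ
    arr2[f, 3, ] <- c(0, 3, 0)      # OXT
    arr2[f, 4, ] <- c(6.5, 0, 0)    # GLU CA
    arr2[f, 5, ] <- c(5, 0, 0)      # OE1: 5 A from NZ, 5.8 A from OXT
    arr2[f, 6, ] <- c(5.8, 0.6, 0)  # CB
  }
  fx2 <- trajectoryEnsemble(top2, arr2)
  rec2 <- classifyContacts(fx2, data.frame(res_a = "A:1", res_b = "B:2"))
  smry2 <- interactionSummary(rec2, correlationMap(fx2, "A", "B"))
  expect_true(all(c("salt_bridge", "repulsive") %in% smry2$type))
  expect_setequal(
    smry2$class[smry2$type %in% c("salt_bridge", "repulsive")],
    c("attractive", "repulsive"))
})
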