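linTrace <- function(slope_um_s, n = 60, dt = 1, x0 = 10, noise = 0,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) * dt
  data.frame(time_s = t,
             position_um = x0 + slope_um_s * t + rnorm(n, 0, noise))
}

test_that("pure traces segment into a single phase with exact slope", {
  seg <- segmentPhases(linTrace(-0.3))
  ph <- phases(seg)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$type, "shrinkage")
  expect_equal(ph$slope_um_s, -0.3, tolerance = 1e-9)
  flat <- segmentPhases(linTrace(0, noise = 0.002, seed = 1))
  expect_equal(phases(flat)$type, "pause")
  grow <- segmentPhases(linTrace(0.02))
  expect_equal(phases(grow)$type, "growth")
  expect_error(segmentPhases(linTrace(0, n = 5)), "insufficient")
})

test_that("segmentation is invariant to position and time offsets", {
  tr <- linTrace(-0.3, noise = 0.05, seed = 7)
  seg0 <- segmentPhases(tr)
  tr_off <- tr; tr_off$position_um <- tr_off$position_um + 25
  tr_t <- tr; tr_t$time_s <- tr_t$time_s + 1000
  expect_equal(phases(segmentPhases(tr_off))$slope_um_s,
               phases(seg0)$slope_um_s, tolerance = 1e-12)
  expect_equal(phases(segmentPhases(tr_t))$type, phases(seg0)$type)
})

test_that("noise-free piecewise-linear traces are recovered exactly", {
  # growth 0.02 um/s for 50 s, shrinkage -0.3 um/s for 30 s
  t <- 0:79
  pos <- ifelse(t <= 50, 10 + 0.02 * t, 10 + 0.02 * 50 - 0.3 * (t - 50))
  seg <- segmentPhases(data.frame(time_s = t, position_um = pos))
  ph <- phases(seg)
  expect_equal(ph$type, c("growth", "shrinkage"))
  expect_equal(ph$slope_um_s[1], 0.02, tolerance = 1e-9)
  expect_equal(ph$slope_um_s[2], -0.3, tolerance = 1e-9)
  # transition located within one sample of t = 50
  expect_lte(abs(ph$end_s[1] - 50), 1 + 1e-9)
})

test_that("simulated transitions are detected within one window", {
  di <- simulateDynamicInstability(nTraces = 20, duration_s = 600,
                                   vg = 1.5, vs = 0.3, kcat = 0.5,
                                   kres = 3, noise_um = 0.01,
                                   frameInterval_s = 0.2,
                                   initialLength_um = 10, seed = 21)
  window_s <- 15 * 0.2
  hits <- 0L; total <- 0L
  for (i in seq_along(di$traces)) {
    seg <- segmentPhases(di$traces[[i]], window = 15)
    ph <- phases(seg)
    found <- ph$start_s[-1][ph$type[-1] == "shrinkage"]
    ev <- di$events$time_s[di$events$trace == i &
                             di$events$to == "shrinkage"]
    for (e in ev) {
      total <- total + 1L
      if (length(found) && min(abs(found - e)) <= window_s) hits <- hits + 1L
    }
  }
  expect_gt(total, 10)
  expect_gte(hits / total, 0.9)
})

test_that("growth rate converts units and weights by duration", {
  seg <- segmentPhases(linTrace(0.02))
  gr <- growthRate(seg)
  expect_equal(gr$mean, 1.2, tolerance = 1e-9)
  # hand-computed duration weighting over an artificial segmentation
  t <- 0:99
  pos <- ifelse(t <= 30, 0.03 * t,
                ifelse(t <= 60, 0.03 * 30 + 0.001 * (t - 30),
                       0.03 * 30 + 0.001 * 30 + 0.02 * (t - 60)))
  seg2 <- segmentPhases(data.frame(time_s = t, position_um = pos))
  ph <- phases(seg2)[phases(seg2)$type == "growth", ]
  w <- ph$end_s - ph$start_s
  expect_equal(growthRate(seg2)$mean, 60 * sum(ph$slope_um_s * w) / sum(w),
               tolerance = 1e-9)
  # no growth at all: flagged absent
  gr0 <- growthRate(segmentPhases(linTrace(-0.3)))
  expect_true(is.na(gr0$mean))
  expect_equal(gr0$no_growth, 1L)
})

test_that("catastrophe frequency is events per growth minute", {
  # construct a segmentation with 2 catastrophes and 10 min of growth
  t <- seq(0, 660)
  pos <- numeric(length(t))
  x <- 10; v <- rep(0.02, length(t))
  v[t > 290 & t <= 320] <- -0.3
  v[t > 620 & t <= 650] <- -0.3
  v[t > 650] <- 0.02
  for (i in seq_along(t)[-1]) x[i] <- x[i - 1] + v[i]
  seg <- segmentPhases(data.frame(time_s = t, position_um = x))
  cf <- catastropheFrequency(seg)
  expect_equal(cf$events, 2L)
  expect_equal(cf$frequency_per_min, cf$events / cf$growth_time_min)
  expect_equal(cf$growth_time_min, 10, tolerance = 0.05)
  # monotone growth: zero events
  cf0 <- catastropheFrequency(segmentPhases(linTrace(0.02)))
  expect_equal(cf0$events, 0L)
  expect_equal(cf0$frequency_per_min, 0)
  # all-shrinkage: undefined, flagged
  cfs <- catastropheFrequency(segmentPhases(linTrace(-0.3)))
  expect_true(cfs$undefined)
})

test_that("hazard-rate and depolymerization recovery from simulation", {
  di <- simulateDynamicInstability(nTraces = 100, duration_s = 600,
                                   kcat = 0.5, kres = 3, noise_um = 0.01,
                                   frameInterval_s = 0.2,
                                   initialLength_um = 10, seed = 31)
  segs <- lapply(di$traces, segmentPhases, window = 15)
  cf <- catastropheFrequency(segs)
  # against the exact event log: estimator error is detection-limited,
  # well under 10% of the realized rate
  realized <- realizedCatastropheFreq(di, 100, 600)
  expect_lt(abs(cf$frequency_per_min - realized), 0.1 * realized)
  # and against the generative hazard, within sampling + detection slack
  se <- sqrt(cf$events) / cf$growth_time_min
  expect_lt(abs(cf$frequency_per_min - 0.5), 3 * se + 0.05 * 0.5)
  # depolymerization-only traces at 0.3 um/s with 0.1 um noise
  sh <- simulateDynamicInstability(nTraces = 50, duration_s = 30, vg = 0,
                                   vs = 0.3, kcat = 0, kres = 0,
                                   noise_um = 0.1, frameInterval_s = 0.2,
                                   initialLength_um = 12,
                                   state0 = "shrinkage", seed = 32)
  dp <- depolymerizationRate(lapply(sh$traces, segmentPhases))
  expect_equal(dp$n, 50L)
  expect_lt(abs(dp$mean - 0.3), 3 * dp$se)
  # mixed trace uses only shrinkage segments
  t <- 0:79
  pos <- ifelse(t <= 50, 10 + 0.02 * t, 11 - 0.3 * (t - 50))
  dpm <- depolymerizationRate(segmentPhases(data.frame(time_s = t,
                                                       position_um = pos)))
  expect_equal(dpm$mean, 0.3, tolerance = 1e-6)
})

test_that("catastrophe estimator is consistent at growing trace counts", {
  for (n in c(25L, 100L, 400L)) {
    di <- simulateDynamicInstability(nTraces = n, duration_s = 300,
                                     vg = 1.5, vs = 0.3, kcat = 0.5,
                                     kres = 3, noise_um = 0.01,
                                     frameInterval_s = 0.2,
                                     initialLength_um = 10, seed = 41)
    est <- catastropheFrequency(lapply(di$traces, segmentPhases,
                                       window = 15))$frequency_per_min
    realized <- realizedCatastropheFreq(di, n, 300)
    # estimator tracks the per-realization ground truth at every n;
    # the residual is the sub-resolution event floor (< 10%)
    expect_lt(abs(est - realized), 0.1 * realized)
    if (n == 400L) expect_lt(abs(est - 0.5), 0.1)
  }
})
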