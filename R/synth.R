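#' Derive a reproducible sub-seed for a labeled generator stream
#'
#' A single top-level seed fans out to per-generator streams keyed by a
#' fixed label, so adding one generator never perturbs the draws of
#' another.
#'
#' @param seed top-level integer seed.
#' @param label generator label.
#' @return integer sub-seed in \[0, 2^31).
#' @export
subSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h * 101) %% 2147483647)
}

# Default MAP9 MT-binding-domain study conditions: Phi/W/K anchors of the
# five pseudo-repeats and the Phi identities at those anchors.
MAP9_ANCHORS <- c(429L, 473L, 516L, 560L, 603L)
MAP9_PHI <- c("Y", "F", "F", "V", "Y")

#' Generate a protein sequence with implanted PhiXXWXXXK repeats
#'
#' Background residues are drawn from the 20-letter alphabet; any
#' accidental W/K pair at offset 4 (which could seed a spurious motif
#' window) is rejected and resampled before the motifs are implanted.
#' Positions are given in author numbering; the sequence itself starts at
#' `numberingOffset`.
#'
#' @param length sequence length in residues.
#' @param anchors Phi anchor positions (author numbering); defaults to the
#'   five repeats of the MAP9 MT-binding domain.
#' @param phi Phi identities, recycled along `anchors`.
#' @param numberingOffset author number of the first residue.
#' @param seed integer seed.
#' @param id sequence id.
#' @return a `ProteinSequence`.
#' @export
implantMotifs <- function(length = 700L, anchors = MAP9_ANCHORS,
                          phi = MAP9_PHI, numberingOffset = 1L,
                          seed = 1L, id = "synthetic_map") {
  anchors <- as.integer(sort(anchors))
  if (length(anchors) > 1L && any(diff(anchors) < 8L))
    stop("overlapping anchors: consecutive anchors must be >= 8 apart")
  idx <- anchors - numberingOffset + 1L
  if (length(idx) && (min(idx) < 1L || max(idx) + 7L > length))
    stop("anchors must satisfy anchor + 7 <= last residue")
  withr_seed <- subSeed(seed, "implant_motifs")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(withr_seed)
  bg <- sample(AA_ALPHABET20, length, replace = TRUE)
  # reject accidental W..K at offset 4 anywhere in the background
  repeat {
    i <- seq_len(max(length - 4L, 0L))
    bad <- i[bg[i] == "W" & bg[i + 4L] == "K"]
    if (!length(bad)) break
    bg[bad + 4L] <- sample(setdiff(AA_ALPHABET20, "K"), length(bad),
                           replace = TRUE)
  }
  phi <- rep_len(phi, length(anchors))
  for (k in seq_along(idx)) {
    bg[idx[k]] <- phi[k]
    bg[idx[k] + 3L] <- "W"
    bg[idx[k] + 7L] <- "K"
    # keep non-anchor window positions free of W/K so only the implanted
    # anchors define the motif
    xpos <- idx[k] + c(1L, 2L, 4L, 5L, 6L)
    redraw <- bg[xpos] %in% c("W", "K")
    if (any(redraw))
      bg[xpos[redraw]] <- sample(setdiff(AA_ALPHABET20, c("W", "K")),
                                 sum(redraw), replace = TRUE)
  }
  proteinSequence(id, paste(bg, collapse = ""), numberingOffset)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' C-alpha-only topology template for two groups
#'
#' @param nA,nB residue counts of the two chains/groups (chains A and B).
#' @param groupNames names for the two analysis groups.
#' @return topology data.frame of `nA + nB` CA atoms.
#' @export
makeCaTopology <- function(nA, nB, groupNames = c("A", "B")) {
  n <- nA + nB
  makeTopology(serial = seq_len(n),
               name = rep("CA", n),
               resid = rep("ALA", n),
               resno = c(seq_len(nA), seq_len(nB)),
               chain = rep(c("A", "B"), c(nA, nB)),
               element = rep("C", n),
               group = rep(groupNames, c(nA, nB)))
}

#' Simulate a trajectory with prescribed C-alpha cross-correlations
#'
#' Per-frame displacements of every residue are zero-mean Gaussian with
#' the requested correlation matrix, drawn independently for the x, y and
#' z components so the displacement-vector correlation (the quantity
#' [correlationMap()] estimates) equals the target as the frame count
#' grows. Base positions are spread 50 Angstrom apart so residues never
#' collide.
#'
#' @param target symmetric positive-semidefinite correlation matrix over
#'   all `nA + nB` residues (entries in \[-1, 1\], unit diagonal).
#' @param nA,nB residues in groups A and B.
#' @param nFrames frames to draw.
#' @param amplitude displacement standard deviation per axis (Angstrom).
#' @param seed integer seed.
#' @return a [TrajectoryEnsemble-class] with one run.
#' @export
simulateCorrelatedTrajectory <- function(target, nA, nB, nFrames = 1000L,
                                         amplitude = 1, seed = 1L) {
  m <- nA + nB
  stopifnot(nrow(target) == m, ncol(target) == m)
  if (max(abs(target - t(target))) > 1e-8)
    stop("target correlation matrix must be symmetric")
  if (any(abs(target) > 1 + 1e-12))
    stop("target correlations must lie in [-1, 1]")
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("target correlation matrix must be positive semidefinite")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subSeed(seed, "correlated_trajectory"))
  base <- cbind(seq_len(m) * 50, 0, 0)
  Sigma <- amplitude^2 * target
  arr <- array(NA_real_, c(nFrames, m, 3L))
  for (d in 1:3) {
    disp <- MASS::mvrnorm(nFrames, mu = rep(0, m), Sigma = Sigma)
    arr[, , d] <- sweep(disp, 2, base[, d], "+")
  }
  trajectoryEnsemble(makeCaTopology(nA, nB), arr, runLabels = "sim")
}

# Minimal residue templates used by the contact fixtures: local atom
# offsets (Angstrom) relative to the residue origin; the "probe" atom is
# the one placed on the prescribed inter-residue distance.
FIXTURE_RESIDUES <- list(
  LYS = list(atoms = c("CA", "CB", "NZ", "HZ1"),
             offsets = rbind(c(-1.5, 0, 0), c(-0.8, 0.6, 0),
                             c(0, 0, 0), c(0.4, 0.8, 0)),
             probe = "NZ"),
  GLU = list(atoms = c("CA", "CB", "OE1"),
             offsets = rbind(c(1.5, 0, 0), c(0.8, -0.6, 0), c(0, 0, 0)),
             probe = "OE1"),
  LEU = list(atoms = c("CA", "CB", "CD1"),
             offsets = rbind(c(-1.5, 0, 0), c(-0.8, 0.5, 0), c(0, 0, 0)),
             probe = "CD1"),
  ILE = list(atoms = c("CA", "CB", "CD1"),
             offsets = rbind(c(1.5, 0, 0), c(0.8, -0.5, 0), c(0, 0, 0)),
             probe = "CD1"),
  SER = list(atoms = c("CA", "OG", "HG"),
             offsets = rbind(c(-1.4, 0, 0), c(0, 0, 0), c(0.96, 0, 0)),
             probe = "OG"))

contactPairTemplates <- list(
  salt_bridge  = list(resA = "LYS", resB = "GLU"),
  hydrogen_bond = list(resA = "SER", resB = "GLU"),
  hydrophobic  = list(resA = "LEU", resB = "ILE"),
  repulsive    = list(resA = "LYS", resB = "LYS"))

#' Build a two-residue trajectory fixture with prescribed contact occupancy
#'
#' Places one residue pair whose criterion atoms sit at `inDistance` in
#' exactly `round(p * nFrames)` frames (chosen deterministically from the
#' seed) and at `outDistance` otherwise, so a classifier counting frames
#' must recover the occupancy exactly. For hydrogen bonds the donor
#' hydrogen is placed on the donor-acceptor axis, making the arrangement
#' exactly linear in the satisfied frames.
#'
#' @param type interaction type, one of `"salt_bridge"`,
#'   `"hydrogen_bond"`, `"hydrophobic"`, `"repulsive"`.
#' @param p target occupancy in \[0, 1\] (ignored when `distances` given).
#' @param nFrames number of frames.
#' @param inDistance criterion-atom distance in satisfied frames; default
#'   1 Angstrom inside the class cutoff.
#' @param outDistance distance in unsatisfied frames; default 4 Angstrom
#'   outside the cutoff.
#' @param distances optional explicit per-frame distance schedule
#'   overriding the occupancy mode.
#' @param nRuns split the frames into this many equal runs.
#' @param mode `"exact"` places the criterion in exactly
#'   `round(p * nFrames)` frames (for testing classifier counting);
#'   `"bernoulli"` draws each frame independently with probability `p`
#'   (for testing statistical error bars).
#' @param seed integer seed (placement of satisfied frames).
#' @return a [TrajectoryEnsemble-class]; the satisfied-frame mask is in
#'   attribute `satisfied`.
#' @export
makeContactFixture <- function(type, p = NULL, nFrames = 200L,
                               inDistance = NULL, outDistance = NULL,
                               distances = NULL, nRuns = 1L,
                               mode = c("exact", "bernoulli"), seed = 1L) {
  mode <- match.arg(mode)
  tpl <- contactPairTemplates[[type]]
  if (is.null(tpl)) stop("unknown interaction type '", type, "'")
  cutoff <- switch(type, salt_bridge = 6, hydrogen_bond = 3.5,
                   hydrophobic = 8, repulsive = 12)
  if (is.null(inDistance)) inDistance <- if (type == "hydrogen_bond") 2.9
                                         else cutoff - 1
  if (is.null(outDistance)) outDistance <- cutoff + 4
  if (is.null(distances)) {
    if (is.null(p) || p < 0 || p > 1) stop("occupancy p must be in [0, 1]")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(subSeed(seed, paste0("contact_", type)))
    if (mode == "exact") {
      satisfied <- rep(FALSE, nFrames)
      satisfied[sample.int(nFrames, round(p * nFrames))] <- TRUE
    } else {
      satisfied <- stats::runif(nFrames) < p
    }
    distances <- ifelse(satisfied, inDistance, outDistance)
  } else {
    nFrames <- length(distances)
    satisfied <- distances <= cutoff
  }
  if (any(distances < 0)) stop("requested distances must be >= 0")

  ra <- FIXTURE_RESIDUES[[tpl$resA]]; rb <- FIXTURE_RESIDUES[[tpl$resB]]
  atoms <- c(ra$atoms, rb$atoms)
  top <- makeTopology(
    serial = seq_along(atoms), name = atoms,
    resid = rep(c(tpl$resA, tpl$resB), c(length(ra$atoms), length(rb$atoms))),
    resno = rep(c(1L, 2L), c(length(ra$atoms), length(rb$atoms))),
    chain = rep(c("A", "B"), c(length(ra$atoms), length(rb$atoms))),
    group = rep(c("A", "B"), c(length(ra$atoms), length(rb$atoms))))

  nA <- length(ra$atoms)
  arr <- array(NA_real_, c(nFrames, nrow(top), 3L))
  for (f in seq_len(nFrames)) {
    # residue A probe at origin; residue B probe at (d, 0, 0)
    arr[f, seq_len(nA), ] <- ra$offsets
    arr[f, nA + seq_len(nrow(rb$offsets)), ] <-
      sweep(rb$offsets, 2, c(distances[f], 0, 0), "+")
  }
  runs <- splitFrames(arr, nRuns)
  ens <- trajectoryEnsemble(top, runs,
                            runLabels = sprintf("run%d", seq_len(nRuns)))
  attr(ens, "satisfied") <- satisfied
  ens
}

splitFrames <- function(arr, nRuns) {
  nf <- dim(arr)[1]
  cut <- split(seq_len(nf), rep(seq_len(nRuns), each = ceiling(nf / nRuns),
                                length.out = nf))
  lapply(cut, function(idx) arr[idx, , , drop = FALSE])
}

#' Simulate microtubule dynamic instability tip traces
#'
#' Two-state continuous-time process: growth at `vg` (um/min) switching to
#' shrinkage with hazard `kcat` (1/min); shrinkage at `vs` (um/s)
#' switching back with hazard `kres` (1/min). Length is floored at the
#' seed (0); hitting the seed during shrinkage forces regrowth. The exact
#' transition times are returned in an event log. Sampled positions get
#' additive Gaussian localization noise.
#'
#' Defaults emulate the in vitro imaging conditions of the study system:
#' 5-s frame interval, 0.05-um localization precision, growth of order
#' 1.5 um/min, shrinkage 0.3 um/s, catastrophe 0.5 per minute of growth,
#' no stochastic rescue (regrowth only from the seed).
#'
#' @param nTraces number of traces.
#' @param duration_s trace duration, seconds.
#' @param vg growth velocity, um/min.
#' @param vs shrinkage speed, um/s (positive number).
#' @param kcat catastrophe rate, 1/min.
#' @param kres rescue rate, 1/min.
#' @param noise_um Gaussian localization noise SD, um.
#' @param frameInterval_s sampling interval, seconds.
#' @param initialLength_um starting length beyond the seed, um.
#' @param state0 initial state, `"growth"` or `"shrinkage"`.
#' @param seed integer seed.
#' @return list with `traces` (list of data.frames `time_s`,
#'   `position_um`) and `events` (data.frame `trace`, `time_s`, `from`,
#'   `to`).
#' @export
simulateDynamicInstability <- function(nTraces = 30L, duration_s = 600,
                                       vg = 1.5, vs = 0.3, kcat = 0.5,
                                       kres = 0, noise_um = 0.05,
                                       frameInterval_s = 5,
                                       initialLength_um = 2,
                                       state0 = "growth", seed = 1L) {
  stopifnot(vg >= 0, vs >= 0, kcat >= 0, kres >= 0, noise_um >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subSeed(seed, "dynamic_instability"))
  vg_s <- vg / 60          # um/s
  kcat_s <- kcat / 60      # 1/s
  kres_s <- kres / 60
  traces <- vector("list", nTraces)
  events <- list()
  for (tr in seq_len(nTraces)) {
    t <- 0; len <- initialLength_um; state <- state0
    bk_t <- c(0); bk_len <- c(len); bk_state <- c(state)
    while (t < duration_s) {
      if (state == "growth") {
        dwell <- if (kcat_s > 0) stats::rexp(1, kcat_s) else Inf
        t2 <- min(t + dwell, duration_s)
        len <- len + vg_s * (t2 - t)
        if (t2 < duration_s) {
          events[[length(events) + 1L]] <-
            data.frame(trace = tr, time_s = t2, from = "growth",
                       to = "shrinkage")
          state <- "shrinkage"
        }
        t <- t2
      } else {
        dwell <- if (kres_s > 0) stats::rexp(1, kres_s) else Inf
        t_zero <- if (vs > 0) len / vs else Inf
        t2 <- min(t + dwell, t + t_zero, duration_s)
        len <- max(len - vs * (t2 - t), 0)
        if (t2 < duration_s) {
          events[[length(events) + 1L]] <-
            data.frame(trace = tr, time_s = t2, from = "shrinkage",
                       to = "growth")
          state <- "growth"
        }
        t <- t2
      }
      bk_t <- c(bk_t, t); bk_len <- c(bk_len, len); bk_state <- c(bk_state,
                                                                  state)
    }
    times <- seq(0, duration_s, by = frameInterval_s)
    pos <- stats::approx(bk_t, bk_len, xout = times, rule = 2)$y
    pos <- pos + stats::rnorm(length(pos), 0, noise_um)
    traces[[tr]] <- data.frame(time_s = times, position_um = pos)
  }
  list(traces = traces,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(trace = integer(0), time_s = numeric(0),
                                from = character(0), to = character(0)))
}

#' Simulate single-molecule tracks and their microtubules
#'
#' Track counts per MT are Poisson with mean
#' `landingRate * length_um * duration_min`; run lengths are exponential
#' with mean `meanRunLength_um`; velocity is constant at `velocity_um_s`.
#' Start times and positions are uniform over the observation.
#'
#' @param nMTs number of microtubules.
#' @param landingRate events per um per minute.
#' @param meanRunLength_um mean exponential run length.
#' @param velocity_um_s motor velocity.
#' @param mtLength_um MT length (recycled over MTs).
#' @param duration_s observation time per MT.
#' @param seed integer seed.
#' @return list with `tracks` and `mts` data.frames (see
#'   [validateTracks()]).
#' @export
simulateTracks <- function(nMTs = 30L, landingRate = 1.0,
                           meanRunLength_um = 5, velocity_um_s = 0.5,
                           mtLength_um = 10, duration_s = 120,
                           seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subSeed(seed, "tracks"))
  mts <- data.frame(mt_id = sprintf("mt%03d", seq_len(nMTs)),
                    length_um = rep_len(mtLength_um, nMTs),
                    duration_s = rep_len(duration_s, nMTs),
                    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nMTs)) {
    lam <- landingRate * mts$length_um[i] * mts$duration_s[i] / 60
    k <- stats::rpois(1, lam)
    if (!k) next
    len <- stats::rexp(k, 1 / meanRunLength_um)
    t0 <- stats::runif(k, 0, mts$duration_s[i])
    x0 <- stats::runif(k, 0, mts$length_um[i])
    rows[[length(rows) + 1L]] <- data.frame(
      mt_id = mts$mt_id[i], start_s = t0, end_s = t0 + len / velocity_um_s,
      start_um = x0, end_um = x0 + len, stringsAsFactors = FALSE)
  }
  tracks <- if (length(rows)) do.call(rbind, rows)
            else data.frame(mt_id = character(0), start_s = numeric(0),
                            end_s = numeric(0), start_um = numeric(0),
                            end_um = numeric(0))
  list(tracks = tracks, mts = mts)
}

#' Simulate a Langmuir binding curve with multiplicative noise
#'
#' Intensities are `Imax * c / (Kd + c) * (1 + eps)` with Gaussian `eps`
#' of the stated fractional SD, one draw per replicate MT.
#'
#' @param kd dissociation constant, nM.
#' @param imax saturation intensity.
#' @param conc_nM concentration series, nM.
#' @param noiseFraction multiplicative noise SD (e.g. 0.15).
#' @param replicates MTs measured per concentration.
#' @param seed integer seed.
#' @return data.frame with columns `conc_nM`, `intensity`, `replicate`.
#' @export
simulateBindingCurve <- function(kd = 61, imax = 1,
                                 conc_nM = c(10, 25, 50, 100, 250, 500),
                                 noiseFraction = 0.15, replicates = 30L,
                                 seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subSeed(seed, "binding_curve"))
  conc <- rep(conc_nM, each = replicates)
  mu <- imax * conc / (kd + conc)
  eps <- stats::rnorm(length(conc), 0, noiseFraction)
  data.frame(conc_nM = conc, intensity = pmax(mu * (1 + eps), 0),
             replicate = rep(seq_len(replicates), times = length(conc_nM)))
}
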