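# Independent brute-force oracles used across the suite. These are written
# as plain loops, deliberately separate from the package implementations.

# Exhaustive sliding-window motif scan: tests every position for the W/K
# offsets and the Phi class, character by character.
oracleMotifCandidates <- function(residues, phiClass = c("F","Y","W","L","I","V","M")) {
  n <- nchar(residues)
  hits <- integer(0)
  if (n >= 8) for (i in 1:(n - 7)) {
    if (substr(residues, i, i) %in% phiClass &&
        substr(residues, i + 3, i + 3) == "W" &&
        substr(residues, i + 7, i + 7) == "K")
      hits <- c(hits, i)
  }
  hits
}

oraclePhiScore <- function(letter) {
  if (letter %in% c("F", "Y")) 1
  else if (letter == "W") 0.8
  else if (letter %in% c("L", "I", "V", "M")) 0.6
  else 0.5
}

# Greedy overlap resolution written independently: repeatedly take the
# highest-scoring (left-most on ties) candidate and drop overlaps.
oracleResolveOverlaps <- function(residues, cand) {
  scores <- vapply(cand, function(i) oraclePhiScore(substr(residues, i, i)),
                   numeric(1))
  chosen <- integer(0)
  while (length(cand)) {
    best <- order(-scores, cand)[1]
    chosen <- c(chosen, cand[best])
    keep <- abs(cand - cand[best]) > 7
    cand <- cand[keep]; scores <- scores[keep]
  }
  sort(chosen)
}

# Per-frame, all-atom-pair contact oracle for one residue pair. Uses the
# package's chemical class tables (constants) but counts geometry with
# explicit loops.
oracleContactFrames <- function(ens, resA, resB, type,
                                rules = contactRules()) {
  top <- topology(ens)
  nf <- nFrames(ens)
  runs <- ens@runs
  frameCoord <- function(f) {
    off <- 0
    for (arr in runs) {
      if (f <= off + dim(arr)[1]) return(arr[f - off, , , drop = TRUE])
      off <- off + dim(arr)[1]
    }
  }
  parse <- function(lbl) {
    p <- strsplit(lbl, ":")[[1]]
    which(top$chain == p[1] & top$resno == as.integer(p[2]))
  }
  ia <- parse(resA); ib <- parse(resB)
  cs <- atomClassSets()
  basicN <- selectAtoms(top, "basic_nitrogens", cs)
  acidO <- selectAtoms(top, "acidic_oxygens", cs)
  scC <- selectAtoms(top, "sidechain_carbons", cs)
  donors <- selectAtoms(top, "hbond_donors", cs)
  accs <- selectAtoms(top, "hbond_acceptors", cs)
  hasH <- any(top$element == "H")
  out <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- frameCoord(f)
    d <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    hit <- FALSE
    if (type == "salt_bridge") {
      for (i in ia) for (j in ib)
        if (((i %in% basicN && j %in% acidO) ||
             (i %in% acidO && j %in% basicN)) &&
            d(i, j) <= rules$saltBridgeCutoff) hit <- TRUE
    } else if (type == "hydrophobic") {
      for (i in intersect(ia, scC)) for (j in intersect(ib, scC))
        if (d(i, j) <= rules$hydrophobicCutoff) hit <- TRUE
    } else if (type == "repulsive") {
      for (i in ia) for (j in ib)
        if (((i %in% basicN && j %in% basicN) ||
             (i %in% acidO && j %in% acidO)) &&
            d(i, j) <= rules$repulsiveCutoff) hit <- TRUE
    } else if (type == "hydrogen_bond") {
      dirs <- list(c(1, 2), c(2, 1))
      for (dir in dirs) {
        dIdx <- intersect(if (dir[1] == 1) ia else ib, donors)
        aIdx <- intersect(if (dir[2] == 1) ia else ib, accs)
        for (i in dIdx) for (j in aIdx) {
          if (d(i, j) > rules$hbondDistance) next
          if (!hasH) { hit <- TRUE; next }
          hs <- wrapmap:::donorHydrogens(top, i)
          for (h in hs) {
            v1 <- xyz[i, ] - xyz[h, ]; v2 <- xyz[j, ] - xyz[h, ]
            ang <- acos(max(min(sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2)), 1), -1)) *
              180 / pi
            if (180 - ang <= rules$hbondAngle) hit <- TRUE
          }
        }
      }
    }
    out[f] <- hit
  }
  out
}

# Textbook sample displacement-vector correlation between two residues
# given frames x residues x 3 coordinate arrays.
oracleSampleCorrelation <- function(X, i, j) {
  xi <- X[, i, , drop = TRUE]; xj <- X[, j, , drop = TRUE]
  xi <- sweep(xi, 2, colMeans(xi)); xj <- sweep(xj, 2, colMeans(xj))
  sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
}

# Realized catastrophe frequency of a simulated ensemble, computed from
# the generator's exact event log (events per minute of realized growth).
realizedCatastropheFreq <- function(di, nTraces, duration_s) {
  shrink_s <- 0; n_ev <- 0
  for (i in seq_len(nTraces)) {
    ev <- di$events[di$events$trace == i, ]
    t <- 0; st <- "growth"
    for (k in seq_len(nrow(ev))) {
      if (st == "shrinkage") shrink_s <- shrink_s + ev$time_s[k] - t
      t <- ev$time_s[k]; st <- ev$to[k]
    }
    if (st == "shrinkage") shrink_s <- shrink_s + duration_s - t
    n_ev <- n_ev + sum(ev$to == "shrinkage")
  }
  n_ev / ((nTraces * duration_s - shrink_s) / 60)
}

# Minimal helper: a random small topology of real residue types with
# random coordinates for classifier property tests.
randomContactSystem <- function(seed, nFrames = 12, spread = 14) {
  set.seed(seed)
  resids <- sample(c("LYS", "GLU", "LEU", "ILE", "SER", "ARG", "ASP"), 2,
                   replace = TRUE)
  tmpl <- list(
    LYS = c("CA", "CB", "CD", "CE", "NZ"),
    GLU = c("CA", "CB", "CG", "CD", "OE1", "OE2"),
    ASP = c("CA", "CB", "CG", "OD1", "OD2"),
    ARG = c("CA", "CB", "CD", "NE", "NH1", "NH2"),
    LEU = c("CA", "CB", "CG", "CD1", "CD2"),
    ILE = c("CA", "CB", "CG1", "CD1"),
    SER = c("CA", "CB", "OG"))
  atoms <- c(tmpl[[resids[1]]], tmpl[[resids[2]]])
  nA <- length(tmpl[[resids[1]]])
  top <- makeTopology(
    serial = seq_along(atoms), name = atoms,
    resid = rep(resids, c(nA, length(atoms) - nA)),
    resno = rep(c(1L, 2L), c(nA, length(atoms) - nA)),
    chain = rep(c("A", "B"), c(nA, length(atoms) - nA)),
    group = rep(c("A", "B"), c(nA, length(atoms) - nA)))
  arr <- array(stats::runif(nFrames * nrow(top) * 3, 0, spread),
               c(nFrames, nrow(top), 3))
  trajectoryEnsemble(top, arr)
}
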