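#' Geometric contact-classification rules
#'
#' Distance/angle criteria for the four interaction classes and the
#' residue-pair distance filter applied between the correlation map and
#' classification. Defaults: salt bridge, basic nitrogen to acidic oxygen
#' within 6 Angstrom; hydrogen bond, donor-acceptor distance <= 3.5
#' Angstrom with the D-H...A arrangement within 30 degrees of linear;
#' hydrophobic, side-chain carbon pair within 8 Angstrom; repulsive,
#' like-charged class pair (N-N or O-O) within 12 Angstrom. The pair
#' filter retains residue pairs whose minimum heavy-atom distance is
#' within `contactFilterCutoff` in at least `contactFilterMinFraction` of
#' frames.
#'
#' @param saltBridgeCutoff,hbondDistance,hydrophobicCutoff,repulsiveCutoff
#'   distances in Angstrom.
#' @param hbondAngle maximum deviation from linearity of D-H...A, degrees.
#' @param contactFilterCutoff,contactFilterMinFraction pair-filter
#'   threshold (Angstrom) and minimum frame fraction.
#' @return list of class `ContactRules`.
#' @export
contactRules <- function(saltBridgeCutoff = 6, hbondDistance = 3.5,
                         hbondAngle = 30, hydrophobicCutoff = 8,
                         repulsiveCutoff = 12,
                         contactFilterCutoff = 12,
                         contactFilterMinFraction = 0.10) {
  vals <- c(saltBridgeCutoff, hbondDistance, hbondAngle, hydrophobicCutoff,
            repulsiveCutoff, contactFilterCutoff)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all cutoffs must be positive")
  structure(list(saltBridgeCutoff = saltBridgeCutoff,
                 hbondDistance = hbondDistance, hbondAngle = hbondAngle,
                 hydrophobicCutoff = hydrophobicCutoff,
                 repulsiveCutoff = repulsiveCutoff,
                 contactFilterCutoff = contactFilterCutoff,
                 contactFilterMinFraction = contactFilterMinFraction),
            class = "ContactRules")
}

resLabel <- function(chain, resno) paste0(chain, ":", resno)

# Residues of a group that carry a C-alpha atom; warns about those that
# do not (they are excluded from the correlation map).
groupCalphaResidues <- function(top, group) {
  in_group <- top$group == group
  res <- unique(top[in_group, c("chain", "resno", "resid")])
  ca_idx <- integer(nrow(res))
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    j <- which(in_group & top$chain == res$chain[i] &
                 top$resno == res$resno[i] & top$name == "CA")
    if (length(j)) { ca_idx[i] <- j[1]; keep[i] <- TRUE }
    else warning("residue ", resLabel(res$chain[i], res$resno[i]),
                 " in group '", group, "' has no CA atom; excluded")
  }
  res <- res[keep, , drop = FALSE]
  res$ca_idx <- ca_idx[keep]
  res$label <- resLabel(res$chain, res$resno)
  res
}

# frames x residues matrices of Cα coordinates, pooled across runs
pooledCalpha <- function(ensemble, ca_idx) {
  mats <- lapply(ensemble@runs, function(arr) arr[, ca_idx, , drop = FALSE])
  do.call(abind3, mats)
}

abind3 <- function(...) {
  pieces <- list(...)
  nf <- vapply(pieces, function(x) dim(x)[1], integer(1))
  out <- array(NA_real_, c(sum(nf), dim(pieces[[1]])[2], 3L))
  at <- 0L
  for (p in pieces) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Inter-group C-alpha correlation map
#'
#' First step of the three-step correlation method: the covariance of the
#' C-alpha configuration vector about its trajectory mean,
#' `C = <(R - <R>)(R - <R>)^T>`, restricted to the inter-group block and
#' normalized per residue pair with the displacement-vector inner product
#' (the dynamic cross-correlation convention):
#' `c_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`.
#' Frames of all runs are concatenated. Residues with zero displacement
#' variance get correlation 0 and a degeneracy flag.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param groupA,groupB group names in the ensemble topology.
#' @return a [CorrelationAnalysis-class].
#' @export
correlationMap <- function(ensemble, groupA, groupB) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  top <- ensemble@topology
  resA <- groupCalphaResidues(top, groupA)
  resB <- groupCalphaResidues(top, groupB)
  if (!nrow(resA) || !nrow(resB))
    stop("both groups need at least one residue with a CA atom")
  if (nFrames(ensemble) < 2L)
    stop("insufficient data: correlation needs at least 2 frames")
  A <- pooledCalpha(ensemble, resA$ca_idx)  # frames x nA x 3
  B <- pooledCalpha(ensemble, resB$ca_idx)
  nf <- dim(A)[1]
  num <- matrix(0, nrow(resA), nrow(resB))
  varA <- numeric(nrow(resA)); varB <- numeric(nrow(resB))
  # centered coordinate matrices per dimension
  cen <- function(M) sweep(M, 2, colMeans(M))
  for (d in 1:3) {
    Ad <- cen(matrix(A[, , d], nrow = nf))
    Bd <- cen(matrix(B[, , d], nrow = nf))
    num <- num + crossprod(Ad, Bd)
    varA <- varA + colSums(Ad^2)
    varB <- varB + colSums(Bd^2)
  }
  degA <- varA <= 1e-12 * nf
  degB <- varB <= 1e-12 * nf
  den <- sqrt(outer(pmax(varA, .Machine$double.eps),
                    pmax(varB, .Machine$double.eps)))
  cm <- num / den
  deg <- outer(degA, degB, "|")
  cm[deg] <- 0
  cm <- pmin(pmax(cm, -1), 1)
  dimnames(cm) <- list(resA$label, resB$label)
  dimnames(deg) <- dimnames(cm)
  new("CorrelationAnalysis",
      residuesA = resA, residuesB = resB,
      correlation = cm, degenerate = deg,
      nFrames = as.integer(nf),
      groupA = groupA, groupB = groupB)
}

# per-frame minimum distance between two atom sets, pooled frames
pairMinDistance <- function(coords, idxA, idxB) {
  nf <- dim(coords)[1]
  mind <- rep(Inf, nf)
  for (i in idxA) for (j in idxB) {
    d2 <- (coords[, i, 1] - coords[, j, 1])^2 +
          (coords[, i, 2] - coords[, j, 2])^2 +
          (coords[, i, 3] - coords[, j, 3])^2
    mind <- pmin(mind, d2)
  }
  sqrt(mind)
}

residueAtoms <- function(top, label, heavyOnly = TRUE) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  idx <- which(top$chain == parts[1] & top$resno == as.integer(parts[2]))
  if (heavyOnly) idx <- idx[top$element[idx] != "H"]
  idx
}

#' Distance-filter residue pairs of a correlation analysis
#'
#' Second step of the three-step method: a residue pair is retained iff its
#' minimum inter-residue heavy-atom distance is within
#' `contactFilterCutoff` in at least `contactFilterMinFraction` of the
#' pooled frames. The result is sorted by `|c|` descending.
#'
#' @param ensemble the [TrajectoryEnsemble-class] the analysis came from.
#' @param analysis a [CorrelationAnalysis-class].
#' @param rules a `ContactRules` list, see [contactRules()].
#' @return data.frame with columns `res_a`, `res_b`, `c`, `degenerate`,
#'   `frac_within`.
#' @export
filterPairs <- function(ensemble, analysis, rules = contactRules()) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"),
            is(analysis, "CorrelationAnalysis"))
  top <- ensemble@topology
  coords <- do.call(abind3, ensemble@runs)
  nf <- dim(coords)[1]
  resA <- analysis@residuesA; resB <- analysis@residuesB
  atomsA <- lapply(resA$label, residueAtoms, top = top)
  atomsB <- lapply(resB$label, residueAtoms, top = top)
  rows <- list()
  for (i in seq_len(nrow(resA))) for (j in seq_len(nrow(resB))) {
    md <- pairMinDistance(coords, atomsA[[i]], atomsB[[j]])
    frac <- mean(md <= rules$contactFilterCutoff)
    if (frac >= rules$contactFilterMinFraction)
      rows[[length(rows) + 1L]] <- data.frame(
        res_a = resA$label[i], res_b = resB$label[j],
        c = analysis@correlation[i, j],
        degenerate = analysis@degenerate[i, j],
        frac_within = frac, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(res_a = character(0), res_b = character(0),
                      c = numeric(0), degenerate = logical(0),
                      frac_within = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$c), out$res_a, out$res_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-frame logical: any atom pair across the two index sets within cutoff
anyPairWithin <- function(coords, idxA, idxB, cutoff) {
  if (!length(idxA) || !length(idxB))
    return(rep(FALSE, dim(coords)[1]))
  pairMinDistance(coords, idxA, idxB) <= cutoff
}

# H-bond per-frame test for one donor/acceptor direction
hbondFrames <- function(coords, top, donorIdx, accIdx, rules) {
  nf <- dim(coords)[1]
  hit <- rep(FALSE, nf)
  distOnly <- !any(top$element == "H")
  for (d in donorIdx) {
    hs <- donorHydrogens(top, d)
    for (a in accIdx) {
      dda <- sqrt((coords[, d, 1] - coords[, a, 1])^2 +
                  (coords[, d, 2] - coords[, a, 2])^2 +
                  (coords[, d, 3] - coords[, a, 3])^2)
      ok <- dda <= rules$hbondDistance
      if (!distOnly && length(hs)) {
        angOk <- rep(FALSE, nf)
        for (h in hs) {
          # deviation from linearity of D-H...A
          v1 <- coords[, d, ] - coords[, h, ]
          v2 <- coords[, a, ] - coords[, h, ]
          cosang <- rowSums(v1 * v2) /
            (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
          ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
          angOk <- angOk | (180 - ang) <= rules$hbondAngle
        }
        ok <- ok & angOk
      } else if (!distOnly && !length(hs)) {
        ok <- rep(FALSE, nf)  # donor without modeled hydrogens
      }
      hit <- hit | ok
    }
  }
  attr(hit, "distance_only") <- distOnly
  hit
}

#' Classify residue-pair contacts and compute occupancy fractions
#'
#' Third step of the three-step method. For each retained residue pair and
#' frame: a salt bridge exists iff any basic-nitrogen / acidic-oxygen atom
#' pair is within the salt-bridge cutoff; a hydrogen bond iff any
#' donor-acceptor pair (either direction) satisfies the distance criterion
#' and, when hydrogens are present, the near-linearity criterion (distance
#' only plus a `distance_only` flag otherwise); a hydrophobic contact iff
#' any side-chain carbon pair is within the hydrophobic cutoff; a
#' repulsive pair iff any like-charged class pair (basic N with basic N,
#' or acidic O with acidic O) is within the repulsive cutoff. Occupancy is
#' the fraction of frames satisfying the criterion, reported per run and
#' pooled over concatenated runs; types with zero pooled occupancy are
#' omitted.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param pairs data.frame with `res_a`, `res_b` labels (e.g. from
#'   [filterPairs()]).
#' @param rules a `ContactRules` list.
#' @param type one of `"all"`, `"salt_bridge"`, `"hydrogen_bond"`,
#'   `"hydrophobic"`, `"repulsive"`.
#' @param classSets atom-class definitions, see [atomClassSets()].
#' @return data.frame with one row per (pair, type, run) plus a pooled row
#'   per (pair, type): columns `res_a`, `res_b`, `type`, `run`,
#'   `n_frames`, `occupancy`, `distance_only`.
#' @export
classifyContacts <- function(ensemble, pairs, rules = contactRules(),
                             type = "all", classSets = atomClassSets()) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  types <- if (identical(type, "all"))
    c("salt_bridge", "hydrogen_bond", "hydrophobic", "repulsive") else type
  if (!nrow(pairs))
    return(emptyContactFrame())
  top <- ensemble@topology
  coords <- do.call(abind3, ensemble@runs)
  run_of_frame <- rep(seq_along(ensemble@runs),
                      vapply(ensemble@runs, function(x) dim(x)[1],
                             integer(1)))
  basicN <- selectAtoms(top, "basic_nitrogens", classSets)
  acidO <- selectAtoms(top, "acidic_oxygens", classSets)
  scC <- selectAtoms(top, "sidechain_carbons", classSets)
  donors <- selectAtoms(top, "hbond_donors", classSets)
  accs <- selectAtoms(top, "hbond_acceptors", classSets)

  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    ia <- residueAtoms(top, pairs$res_a[r], heavyOnly = FALSE)
    ib <- residueAtoms(top, pairs$res_b[r], heavyOnly = FALSE)
    if (!length(ia) || !length(ib))
      stop("configuration error: no atoms for residue ",
           if (!length(ia)) pairs$res_a[r] else pairs$res_b[r])
    for (tp in types) {
      distOnly <- FALSE
      per_frame <- switch(tp,
        salt_bridge = anyPairWithin(coords, intersect(ia, basicN),
                                    intersect(ib, acidO),
                                    rules$saltBridgeCutoff) |
                      anyPairWithin(coords, intersect(ia, acidO),
                                    intersect(ib, basicN),
                                    rules$saltBridgeCutoff),
        hydrophobic = anyPairWithin(coords, intersect(ia, scC),
                                    intersect(ib, scC),
                                    rules$hydrophobicCutoff),
        repulsive = anyPairWithin(coords, intersect(ia, basicN),
                                  intersect(ib, basicN),
                                  rules$repulsiveCutoff) |
                    anyPairWithin(coords, intersect(ia, acidO),
                                  intersect(ib, acidO),
                                  rules$repulsiveCutoff),
        hydrogen_bond = {
          h1 <- hbondFrames(coords, top, intersect(ia, donors),
                            intersect(ib, accs), rules)
          h2 <- hbondFrames(coords, top, intersect(ib, donors),
                            intersect(ia, accs), rules)
          distOnly <- attr(h1, "distance_only")
          h1 | h2
        })
      pooled <- mean(per_frame)
      if (pooled <= 0) next
      for (k in seq_along(ensemble@runs)) {
        in_run <- run_of_frame == k
        rows[[length(rows) + 1L]] <- data.frame(
          res_a = pairs$res_a[r], res_b = pairs$res_b[r], type = tp,
          run = ensemble@runLabels[k], n_frames = sum(in_run),
          occupancy = mean(per_frame[in_run]),
          distance_only = distOnly, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        res_a = pairs$res_a[r], res_b = pairs$res_b[r], type = tp,
        run = "pooled", n_frames = length(per_frame), occupancy = pooled,
        distance_only = distOnly, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyContactFrame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

emptyContactFrame <- function() {
  data.frame(res_a = character(0), res_b = character(0),
             type = character(0), run = character(0),
             n_frames = integer(0), occupancy = numeric(0),
             distance_only = logical(0))
}

#' Attractive/repulsive interaction summary for heat-map export
#'
#' Joins classified contacts with the signed correlation map: one row per
#' (residue pair, interaction type) with mean and population SD of the
#' per-run occupancies, the pooled occupancy, the signed correlation, and
#' the attractive (salt bridge / hydrogen bond / hydrophobic) versus
#' repulsive classification. The repulsive class reflects the like-charge
#' distance criterion; the signed correlation is carried alongside rather
#' than being required to be negative. The SD convention (population, over
#' runs) is recorded in the `sd_convention` attribute; with a single run
#' the SD is 0.
#'
#' @param records contact records from [classifyContacts()].
#' @param analysis the matching [CorrelationAnalysis-class].
#' @return data.frame with columns `res_a`, `res_b`, `type`, `class`,
#'   `correlation`, `occupancy_mean`, `occupancy_sd`, `occupancy_pooled`,
#'   `n_runs`.
#' @export
interactionSummary <- function(records, analysis) {
  stopifnot(is(analysis, "CorrelationAnalysis"))
  if (!nrow(records))
    return(structure(data.frame(), sd_convention = "population"))
  per_run <- records[records$run != "pooled", , drop = FALSE]
  pooled <- records[records$run == "pooled", , drop = FALSE]
  key <- interaction(per_run$res_a, per_run$res_b, per_run$type, drop = TRUE)
  rows <- lapply(split(per_run, key), function(d) {
    occ <- d$occupancy
    i <- match(d$res_a[1], analysis@residuesA$label)
    j <- match(d$res_b[1], analysis@residuesB$label)
    pl <- pooled$occupancy[pooled$res_a == d$res_a[1] &
                             pooled$res_b == d$res_b[1] &
                             pooled$type == d$type[1]]
    data.frame(
      res_a = d$res_a[1], res_b = d$res_b[1], type = d$type[1],
      class = if (d$type[1] == "repulsive") "repulsive" else "attractive",
      correlation = if (!is.na(i) && !is.na(j))
        analysis@correlation[i, j] else NA_real_,
      occupancy_mean = mean(occ),
      occupancy_sd = sqrt(mean((occ - mean(occ))^2)),
      occupancy_pooled = pl[1],
      n_runs = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$res_a, out$res_b, out$type), , drop = FALSE]
  structure(out, sd_convention = "population")
}

#' Long-format export of a correlation map
#'
#' @param analysis a [CorrelationAnalysis-class].
#' @param path optional TSV output path.
#' @return data.frame with columns `res_a`, `res_b`, `c`,
#'   `degenerate_flag` (written to `path` when given).
#' @export
correlationTable <- function(analysis, path = NULL) {
  stopifnot(is(analysis, "CorrelationAnalysis"))
  cm <- analysis@correlation
  out <- data.frame(
    res_a = rep(rownames(cm), times = ncol(cm)),
    res_b = rep(colnames(cm), each = nrow(cm)),
    c = as.vector(cm),
    degenerate_flag = as.vector(analysis@degenerate),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' @rdname accessors
#' @export
setMethod("correlationMatrix", "CorrelationAnalysis",
          function(object) object@correlation)

setMethod("show", "CorrelationAnalysis", function(object) {
  cat(sprintf(
    "CorrelationAnalysis: %s x %s, %d x %d residues, %d frames\n",
    object@groupA, object@groupB, nrow(object@correlation),
    ncol(object@correlation), object@nFrames))
})
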