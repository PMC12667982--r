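#' Read protein sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] returning a list of
#' plain protein-sequence records (`id`, `residues`, `numbering_offset`).
#' An integer `offset=<n>` token in a FASTA header sets the author numbering
#' of the first residue (default 1), so detected anchors can be reported in
#' the construct's own numbering.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return list of records, each a list with `id`, `residues` and
#'   `numbering_offset`.
#' @export
readProteinSequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  lapply(seq_along(aa), function(i) {
    header <- names(aa)[i]
    tokens <- strsplit(header, "\\s+")[[1]]
    off <- 1L
    hit <- grep("^offset=", tokens, value = TRUE)
    if (length(hit)) off <- as.integer(sub("^offset=", "", hit[1]))
    proteinSequence(id = tokens[1],
                    residues = as.character(aa[[i]]),
                    numberingOffset = off)
  })
}

#' Construct a validated protein-sequence record
#'
#' @param id sequence identifier.
#' @param residues one-letter amino-acid string (20-letter alphabet plus X).
#' @param numberingOffset 1-based author numbering of the first residue.
#' @return a list with class `ProteinSequence`.
#' @export
proteinSequence <- function(id, residues, numberingOffset = 1L) {
  residues <- toupper(residues)
  if (!nzchar(residues))
    stop("empty sequence: '", id, "' has no residues")
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% c(AA_ALPHABET20, "X"))
  if (length(bad))
    stop(sprintf("unknown residue letter '%s' at position %d of '%s'",
                 chars[bad[1]], bad[1], id))
  if (numberingOffset < 1L)
    stop("numberingOffset must be >= 1")
  structure(list(id = as.character(id), residues = residues,
                 numbering_offset = as.integer(numberingOffset)),
            class = "ProteinSequence")
}

# Default Phi class and per-letter scores: full weight for the aromatic
# residues observed in most repeats, reduced weight for other hydrophobics
# (one repeat uses valine at the Phi position).
PHI_CLASS_DEFAULT <- c("F", "Y", "W", "L", "I", "V", "M")
PHI_SCORES <- c(F = 1, Y = 1, W = 0.8, L = 0.6, I = 0.6, V = 0.6, M = 0.6)

phiScore <- function(letter) {
  s <- PHI_SCORES[letter]
  s[is.na(s)] <- 0.5  # non-default Phi letters admitted by the user
  unname(s)
}

#' Scan a protein sequence for PhiXXWXXXK pseudo-repeats
#'
#' Finds every window where a hydrophobic residue (the Phi class) is
#' followed by an invariant tryptophan at +3 and an invariant lysine at +7,
#' scores the candidates, resolves overlaps greedily (higher score first,
#' ties to the left-most candidate) and groups the surviving repeats into
#' chains whose inter-repeat spacers fall inside `spacerRange`. Tryptophan
#' and lysine are strict requirements: substituting either abolishes the
#' repeat, mirroring the alanine / charge-reversal mutants that abolish
#' lattice binding.
#'
#' All positions are reported in the sequence's own author numbering
#' (`numbering_offset`-based).
#'
#' @param seq a `ProteinSequence` (see [proteinSequence()]), or a plain
#'   character string (offset 1 assumed).
#' @param phiClass character vector of residues accepted at the Phi
#'   position.
#' @param spacerRange length-2 integer vector, the inclusive range of
#'   allowed spacers (residues strictly between one repeat's K and the next
#'   repeat's Phi) for two repeats to share a chain.
#' @param minScore minimum Phi match score for a candidate to be kept.
#' @return a [RepeatTable-class] object.
#' @export
scanPseudoRepeats <- function(seq,
                              phiClass = PHI_CLASS_DEFAULT,
                              spacerRange = c(30L, 45L),
                              minScore = 0.5) {
  if (is.character(seq) && length(seq) == 1L)
    seq <- proteinSequence("seq", seq)
  stopifnot(inherits(seq, "ProteinSequence"))
  if (spacerRange[1] < 0L) stop("spacerRange lower bound must be >= 0")
  chars <- strsplit(seq$residues, "")[[1]]
  n <- length(chars)
  off <- seq$numbering_offset

  # vectorized candidate detection on 0-based internal indices
  cand <- integer(0)
  if (n >= 8L) {
    i <- seq_len(n - 7L)
    hit <- chars[i] %in% phiClass & chars[i + 3L] == "W" & chars[i + 7L] == "K"
    cand <- i[hit]
  }
  score <- phiScore(chars[cand])
  keep <- score >= minScore
  cand <- cand[keep]; score <- score[keep]

  # greedy overlap resolution: repeatedly accept the best-scoring
  # (left-most on ties) candidate, discarding candidates overlapping it
  sel <- logical(length(cand))
  avail <- rep(TRUE, length(cand))
  while (any(avail)) {
    idx <- which(avail)
    best <- idx[order(-score[idx], cand[idx])][1]
    sel[best] <- TRUE
    avail[abs(cand - cand[best]) <= 7L] <- FALSE
  }
  cand <- cand[sel]; score <- score[sel]
  o <- order(cand)
  cand <- cand[o]; score <- score[o]

  phi_pos <- cand + off - 1L
  m <- length(cand)
  if (m > 1L) {
    spacer <- phi_pos[-1L] - (phi_pos[-m] + 7L) - 1L
    linked <- spacer >= spacerRange[1] & spacer <= spacerRange[2]
    chain_id <- cumsum(c(1L, as.integer(!linked)))
    spacer_to_next <- c(ifelse(linked, spacer, NA_integer_), NA_integer_)
  } else {
    spacer <- integer(0)
    chain_id <- rep(1L, m)
    spacer_to_next <- rep(NA_integer_, m)
  }

  rp <- data.frame(
    repeat_index = seq_len(m),
    phi_pos = as.integer(phi_pos),
    trp_pos = as.integer(phi_pos + 3L),
    lys_pos = as.integer(phi_pos + 7L),
    phi_identity = if (m) chars[cand] else character(0),
    score = as.numeric(score),
    chain_id = as.integer(chain_id),
    spacer_to_next = as.integer(spacer_to_next),
    stringsAsFactors = FALSE)

  new("RepeatTable",
      sequenceId = seq$id,
      repeats = rp,
      spacers = as.integer(spacer),
      params = list(phiClass = phiClass, spacerRange = as.integer(spacerRange),
                    minScore = minScore))
}

#' Spacer lengths between consecutive repeats
#'
#' Residues strictly between one repeat's lysine and the next repeat's Phi:
#' `phi_pos[i+1] - lys_pos[i] - 1`. Fewer than two repeats yields an empty
#' vector.
#'
#' @param table a [RepeatTable-class].
#' @return integer vector of length `nRepeats(table) - 1` (or empty).
#' @export
spacerLengths <- function(table) {
  stopifnot(is(table, "RepeatTable"))
  rp <- table@repeats
  if (nrow(rp) < 2L) return(integer(0))
  as.integer(rp$phi_pos[-1L] - rp$lys_pos[-nrow(rp)] - 1L)
}

#' Phi-to-Phi repeat period statistics
#'
#' @param table a [RepeatTable-class] with at least two repeats.
#' @return list with `periods` (successive Phi-to-Phi distances, residues),
#'   `mean`, `min`, `max`.
#' @export
repeatPeriod <- function(table) {
  stopifnot(is(table, "RepeatTable"))
  rp <- table@repeats
  if (nrow(rp) < 2L)
    stop("insufficient data: repeat period needs at least 2 repeats")
  per <- diff(rp$phi_pos)
  list(periods = as.integer(per), mean = mean(per),
       min = min(per), max = max(per))
}

#' Summarize repeat chains, longest first
#'
#' @param table a [RepeatTable-class].
#' @return data.frame with one row per chain (`chain_id`, `n_repeats`,
#'   `first_phi`, `last_lys`), ordered by decreasing chain length then
#'   position.
#' @export
chainTable <- function(table) {
  stopifnot(is(table, "RepeatTable"))
  rp <- table@repeats
  if (!nrow(rp))
    return(data.frame(chain_id = integer(0), n_repeats = integer(0),
                      first_phi = integer(0), last_lys = integer(0)))
  sp <- split(rp, rp$chain_id)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(chain_id = d$chain_id[1], n_repeats = nrow(d),
               first_phi = min(d$phi_pos), last_lys = max(d$lys_pos))))
  out <- out[order(-out$n_repeats, out$first_phi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a repeat table as TSV
#'
#' @param table a [RepeatTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeRepeatTable <- function(table, path) {
  stopifnot(is(table, "RepeatTable"))
  rp <- table@repeats
  out <- cbind(sequence_id = rep(table@sequenceId, nrow(rp)), rp)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname accessors
#' @export
setMethod("sequenceId", "RepeatTable", function(object) object@sequenceId)

#' @rdname accessors
#' @export
setMethod("repeatAnchors", "RepeatTable", function(object) object@repeats)

#' @rdname accessors
#' @export
setMethod("nRepeats", "RepeatTable", function(object) nrow(object@repeats))

setMethod("show", "RepeatTable", function(object) {
  cat(sprintf("RepeatTable for '%s': %d repeat(s)\n",
              object@sequenceId, nRepeats(object)))
  if (nRepeats(object)) {
    cat(sprintf("  anchors (Phi/W/K): %s\n",
                paste(sprintf("%s%d/W%d/K%d", object@repeats$phi_identity,
                              object@repeats$phi_pos, object@repeats$trp_pos,
                              object@repeats$lys_pos), collapse = ", ")))
    if (length(object@spacers))
      cat("  spacers:", paste(object@spacers, collapse = "/"), "\n")
  }
})
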