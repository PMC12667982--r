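#' @import methods
NULL

AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

#' Table of detected pseudo-repeats on one protein sequence
#'
#' Holds the PhiXXWXXXK pseudo-repeats detected on a single sequence: the
#' 1-based anchor positions of the hydrophobic Phi residue, the invariant
#' tryptophan at Phi+3 and the invariant lysine at Phi+7, a match score, a
#' chain id grouping repeats whose spacers fall inside the allowed window,
#' and the spacer lengths (residues strictly between one repeat's K and the
#' next repeat's Phi).
#'
#' @slot sequenceId single character, the source sequence id.
#' @slot repeats data.frame with columns `repeat_index`, `phi_pos`,
#'   `trp_pos`, `lys_pos`, `phi_identity`, `score`, `chain_id`,
#'   `spacer_to_next` (NA for the last repeat of a chain).
#' @slot spacers integer vector of length `nrow(repeats) - 1` (empty when
#'   fewer than two repeats), the inter-repeat spacers in residues.
#' @slot params list of scan parameters used (phi class, spacer range,
#'   minimum score).
#' @exportClass RepeatTable
setClass("RepeatTable",
  slots = c(sequenceId = "character",
            repeats = "data.frame",
            spacers = "integer",
            params = "list"))

setValidity("RepeatTable", function(object) {
  msgs <- character()
  rp <- object@repeats
  if (length(object@sequenceId) != 1L)
    msgs <- c(msgs, "sequenceId must be a single string")
  need <- c("repeat_index", "phi_pos", "trp_pos", "lys_pos",
            "phi_identity", "score")
  if (!all(need %in% names(rp)))
    msgs <- c(msgs, "repeats is missing required columns")
  if (nrow(rp) > 0L && all(need %in% names(rp))) {
    if (any(rp$trp_pos != rp$phi_pos + 3L))
      msgs <- c(msgs, "trp_pos must equal phi_pos + 3")
    if (any(rp$lys_pos != rp$phi_pos + 7L))
      msgs <- c(msgs, "lys_pos must equal phi_pos + 7")
    if (is.unsorted(rp$phi_pos, strictly = TRUE))
      msgs <- c(msgs, "repeats must be sorted by phi_pos")
    if (nrow(rp) > 1L &&
        any(rp$phi_pos[-1L] <= rp$lys_pos[-nrow(rp)]))
      msgs <- c(msgs, "repeats must not overlap (phi_pos > previous lys_pos)")
  }
  if (nrow(rp) > 1L && length(object@spacers) != nrow(rp) - 1L)
    msgs <- c(msgs, "length(spacers) must be n_repeats - 1")
  if (length(msgs)) msgs else TRUE
})

#' Microtubule lattice geometry
#'
#' Parameters of the cylindrical tubulin lattice at the radius where a MAP
#' helix sits: protofilament count, binding radius, axial dimer repeat and
#' the per-protofilament axial stagger of the lattice helix.
#'
#' @slot nProtofilaments integer, >= 8.
#' @slot bindingRadius numeric, Angstrom.
#' @slot dimerAxialRepeat numeric, Angstrom (length of an alpha-beta dimer).
#' @slot lateralStagger numeric, Angstrom axial offset per protofilament.
#' @exportClass MicrotubuleLattice
setClass("MicrotubuleLattice",
  slots = c(nProtofilaments = "integer",
            bindingRadius = "numeric",
            dimerAxialRepeat = "numeric",
            lateralStagger = "numeric"))

setValidity("MicrotubuleLattice", function(object) {
  msgs <- character()
  if (object@nProtofilaments < 8L)
    msgs <- c(msgs, "nProtofilaments must be >= 8")
  if (!is.finite(object@bindingRadius) || object@bindingRadius <= 0)
    msgs <- c(msgs, "bindingRadius must be > 0")
  if (!is.finite(object@dimerAxialRepeat) || object@dimerAxialRepeat <= 0)
    msgs <- c(msgs, "dimerAxialRepeat must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Idealized alpha-helix model of a MAP microtubule-binding domain
#'
#' @slot nResidues integer number of helical residues.
#' @slot risePerResidue numeric, Angstrom per residue (canonical 1.5).
#' @slot nRepeats integer number of tubulin-binding pseudo-repeats.
#' @slot repeatPeriodResidues numeric, mean Phi-to-Phi period in residues.
#' @exportClass HelixModel
setClass("HelixModel",
  slots = c(nResidues = "integer",
            risePerResidue = "numeric",
            nRepeats = "integer",
            repeatPeriodResidues = "numeric"))

setValidity("HelixModel", function(object) {
  msgs <- character()
  if (object@nResidues < 0L) msgs <- c(msgs, "nResidues must be >= 0")
  if (object@risePerResidue <= 0) msgs <- c(msgs, "risePerResidue must be > 0")
  if (object@nRepeats < 1L) msgs <- c(msgs, "nRepeats must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Wrap geometry of a repeat-bearing helix on the lattice
#'
#' @slot siteArcSpacing numeric, Angstrom of arc between adjacent
#'   protofilament binding sites.
#' @slot reachableProtofilaments integer, protofilaments one helix spans.
#' @slot mapsPerCircumference integer, helices needed to tile the
#'   circumference.
#' @slot sites data.frame with one row per repeat: `repeat_index`,
#'   `protofilament`, `axial_offset_A`, `arc_mismatch_A` (NA for the first
#'   repeat, which has no preceding period).
#' @exportClass WrapGeometry
setClass("WrapGeometry",
  slots = c(siteArcSpacing = "numeric",
            reachableProtofilaments = "integer",
            mapsPerCircumference = "integer",
            sites = "data.frame"))

#' Multi-run coordinate trajectory of labeled molecular groups
#'
#' Topology plus one coordinate array per run. The topology is a data.frame
#' with one row per atom (serial, name, element, resid, resno, chain, group);
#' every atom belongs to exactly one named analysis group or to `"other"`.
#'
#' @slot topology data.frame of atoms.
#' @slot runs list of numeric arrays, each `frames x atoms x 3` (Angstrom).
#' @slot runLabels character vector naming the runs.
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  slots = c(topology = "data.frame",
            runs = "list",
            runLabels = "character"))

setValidity("TrajectoryEnsemble", function(object) {
  msgs <- character()
  top <- object@topology
  need <- c("serial", "name", "element", "resid", "resno", "chain", "group")
  if (!all(need %in% names(top)))
    msgs <- c(msgs, "topology is missing required columns")
  if (length(object@runs) < 1L)
    msgs <- c(msgs, "at least one run is required")
  if (length(object@runLabels) != length(object@runs))
    msgs <- c(msgs, "runLabels must match runs in length")
  for (i in seq_along(object@runs)) {
    x <- object@runs[[i]]
    if (!is.array(x) || length(dim(x)) != 3L) {
      msgs <- c(msgs, sprintf("run %d is not a frames x atoms x 3 array", i))
      next
    }
    if (dim(x)[2] != nrow(top))
      msgs <- c(msgs, sprintf("run %d atom count differs from topology", i))
    if (dim(x)[3] != 3L)
      msgs <- c(msgs, sprintf("run %d last dimension must be 3", i))
    if (dim(x)[1] < 1L)
      msgs <- c(msgs, sprintf("run %d has no frames", i))
    if (anyNA(x) || any(!is.finite(x)))
      msgs <- c(msgs, sprintf("run %d has non-finite coordinates", i))
  }
  if (length(msgs)) msgs else TRUE
})

#' Inter-group C-alpha correlation analysis
#'
#' Normalized dynamic cross-correlation of C-alpha displacement vectors
#' between two analysis groups, computed over the frames of all runs
#' concatenated. Residues whose displacement variance is zero are flagged
#' degenerate and reported with correlation 0.
#'
#' @slot residuesA,residuesB data.frame of residues (label, chain, resno)
#'   entering the rows/columns of the map.
#' @slot correlation numeric matrix, rows = group A residues, columns =
#'   group B residues, entries in \[-1, 1\].
#' @slot degenerate logical matrix of the same shape, TRUE where either
#'   residue had zero variance.
#' @slot nFrames integer, frames pooled across runs.
#' @slot groupA,groupB group names.
#' @exportClass CorrelationAnalysis
setClass("CorrelationAnalysis",
  slots = c(residuesA = "data.frame",
            residuesB = "data.frame",
            correlation = "matrix",
            degenerate = "matrix",
            nFrames = "integer",
            groupA = "character",
            groupB = "character"))

setValidity("CorrelationAnalysis", function(object) {
  msgs <- character()
  cm <- object@correlation
  if (any(abs(cm) > 1 + 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "correlations must lie in [-1, 1]")
  if (!identical(dim(cm), dim(object@degenerate)))
    msgs <- c(msgs, "degenerate flags must match correlation dimensions")
  if (length(msgs)) msgs else TRUE
})

#' Phase segmentation of a microtubule tip trace
#'
#' Contiguous, non-overlapping growth / shrinkage / pause phases covering a
#' tip trace, each with a least-squares slope and its standard error.
#'
#' @slot phases data.frame with columns `type`, `start_s`, `end_s`,
#'   `start_idx`, `end_idx`, `slope_um_s`, `slope_se`.
#' @slot trace data.frame with columns `time_s`, `position_um`.
#' @slot params list of segmentation parameters.
#' @exportClass PhaseSegmentation
setClass("PhaseSegmentation",
  slots = c(phases = "data.frame",
            trace = "data.frame",
            params = "list"))

setValidity("PhaseSegmentation", function(object) {
  ph <- object@phases
  msgs <- character()
  if (nrow(ph)) {
    if (!all(ph$type %in% c("growth", "shrinkage", "pause")))
      msgs <- c(msgs, "phase types must be growth/shrinkage/pause")
    if (any(ph$end_s <= ph$start_s))
      msgs <- c(msgs, "phases must have positive duration")
    if (nrow(ph) > 1L && any(abs(ph$start_s[-1L] - ph$end_s[-nrow(ph)]) > 1e-9))
      msgs <- c(msgs, "phases must be contiguous")
  }
  if (length(msgs)) msgs else TRUE
})
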