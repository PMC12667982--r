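#' Construct a microtubule lattice model
#'
#' Defaults describe the 14-protofilament taxol-stabilized lattice used for
#' structure determination: dimer axial repeat 82 Angstrom and a binding
#' radius chosen so that the arc between adjacent protofilament sites equals
#' the mean repeat period of the MAP helix (43.5 residues x 1.5 Angstrom =
#' 65.25 Angstrom, radius about 145.4 Angstrom). The binding radius is a
#' free model parameter: no radius is measured directly, so the default
#' encodes the self-consistency of repeat period and site spacing.
#'
#' @param nProtofilaments integer, number of protofilaments (>= 8).
#' @param bindingRadius radius (Angstrom) of the cylinder on which the MAP
#'   helix sits; `NULL` picks the default described above.
#' @param dimerAxialRepeat axial length of an alpha-beta tubulin dimer
#'   (Angstrom).
#' @param lateralStagger axial offset per protofilament of the lattice
#'   helix (Angstrom); default 9.2 (three-start B-lattice monomer stagger).
#' @return a [MicrotubuleLattice-class].
#' @export
microtubuleLattice <- function(nProtofilaments = 14L,
                               bindingRadius = NULL,
                               dimerAxialRepeat = 82,
                               lateralStagger = 9.2) {
  nProtofilaments <- as.integer(nProtofilaments)
  if (is.null(bindingRadius))
    bindingRadius <- 43.5 * 1.5 * nProtofilaments / (2 * pi)
  new("MicrotubuleLattice",
      nProtofilaments = nProtofilaments,
      bindingRadius = as.numeric(bindingRadius),
      dimerAxialRepeat = as.numeric(dimerAxialRepeat),
      lateralStagger = as.numeric(lateralStagger))
}

#' Construct an idealized MAP helix model
#'
#' @param nResidues helical residue count (the MT-binding domain helix is
#'   about 200 residues, i.e. 300 Angstrom at the canonical rise).
#' @param risePerResidue Angstrom per residue, canonical alpha-helix 1.5.
#' @param nRepeats number of tubulin-binding pseudo-repeats on the helix.
#' @param repeatPeriodResidues mean Phi-to-Phi period in residues.
#' @return a [HelixModel-class].
#' @export
helixModel <- function(nResidues = 200L, risePerResidue = 1.5,
                       nRepeats = 5L, repeatPeriodResidues = 43.5) {
  if (nResidues < 0) stop("nResidues must be >= 0")
  new("HelixModel",
      nResidues = as.integer(nResidues),
      risePerResidue = as.numeric(risePerResidue),
      nRepeats = as.integer(nRepeats),
      repeatPeriodResidues = as.numeric(repeatPeriodResidues))
}

#' Helix model derived from a detected repeat table
#'
#' @param table a [RepeatTable-class] with >= 2 repeats.
#' @param risePerResidue Angstrom per residue.
#' @param nResidues helix length in residues; default spans the repeats
#'   rounded up to the canonical 200-residue domain when larger.
#' @return a [HelixModel-class].
#' @export
helixFromRepeats <- function(table, risePerResidue = 1.5, nResidues = NULL) {
  per <- repeatPeriod(table)
  rp <- repeatAnchors(table)
  if (is.null(nResidues))
    nResidues <- max(200L, max(rp$lys_pos) - min(rp$phi_pos) + 1L)
  helixModel(nResidues = nResidues, risePerResidue = risePerResidue,
             nRepeats = nRepeats(table), repeatPeriodResidues = per$mean)
}

#' Arc spacing between adjacent protofilament binding sites
#'
#' Circumference at the binding radius divided evenly among protofilaments:
#' `2 * pi * bindingRadius / nProtofilaments`.
#'
#' @param lattice a [MicrotubuleLattice-class].
#' @return arc spacing in Angstrom.
#' @export
siteArcSpacing <- function(lattice) {
  stopifnot(is(lattice, "MicrotubuleLattice"))
  2 * pi * lattice@bindingRadius / lattice@nProtofilaments
}

#' Contour length of the helix
#'
#' @param helix a [HelixModel-class].
#' @return contour length in Angstrom (`nResidues * risePerResidue`).
#' @export
helixContourLength <- function(helix) {
  stopifnot(is(helix, "HelixModel"))
  helix@nResidues * helix@risePerResidue
}

#' Number of protofilaments a helix can span
#'
#' The helix reaches `floor(contour / spacing) + 1` sites (the starting
#' protofilament counts), capped by the number of binding repeats it
#' carries.
#'
#' @param helix a [HelixModel-class].
#' @param spacing arc spacing between sites (Angstrom), e.g.
#'   [siteArcSpacing()].
#' @return integer protofilament span.
#' @export
protofilamentSpan <- function(helix, spacing) {
  stopifnot(is(helix, "HelixModel"))
  if (!is.finite(spacing) || spacing <= 0)
    stop("spacing must be > 0")
  span <- floor(helixContourLength(helix) / spacing) + 1
  as.integer(min(helix@nRepeats, span))
}

#' MAPs needed to tile the full circumference
#'
#' @param lattice a [MicrotubuleLattice-class].
#' @param span protofilaments covered by one MAP (>= 1).
#' @return integer, `ceiling(nProtofilaments / span)`.
#' @export
mapsPerCircumference <- function(lattice, span) {
  stopifnot(is(lattice, "MicrotubuleLattice"))
  if (span < 1) stop("span must be >= 1")
  if (span > lattice@nProtofilaments)
    stop("span cannot exceed the number of protofilaments")
  as.integer(ceiling(lattice@nProtofilaments / span))
}

#' Place detected repeats on the lattice and report arc mismatch
#'
#' Repeat i is assigned protofilament `(i - 1) mod nProtofilaments`; its
#' axial offset accumulates the per-protofilament lateral stagger; its arc
#' mismatch is the difference between the preceding Phi-to-Phi period
#' stretched along the helix (`period * risePerResidue`) and the lattice
#' site arc spacing. The first repeat has no preceding period, so its
#' mismatch is reported absent (NA).
#'
#' @param lattice a [MicrotubuleLattice-class].
#' @param helix a [HelixModel-class].
#' @param table a [RepeatTable-class] with >= 1 repeat.
#' @return a [WrapGeometry-class].
#' @export
wrapRepeats <- function(lattice, helix, table) {
  stopifnot(is(lattice, "MicrotubuleLattice"), is(helix, "HelixModel"),
            is(table, "RepeatTable"))
  rp <- repeatAnchors(table)
  if (!nrow(rp))
    stop("insufficient data: wrap geometry needs at least 1 repeat")
  spacing <- siteArcSpacing(lattice)
  span <- protofilamentSpan(helix, spacing)
  maps <- mapsPerCircumference(lattice, span)
  pf <- (seq_len(nrow(rp)) - 1L) %% lattice@nProtofilaments
  periods <- c(NA_real_, diff(rp$phi_pos))
  sites <- data.frame(
    repeat_index = rp$repeat_index,
    protofilament = as.integer(pf),
    axial_offset_A = pf * lattice@lateralStagger,
    arc_mismatch_A = periods * helix@risePerResidue - spacing)
  new("WrapGeometry",
      siteArcSpacing = spacing,
      reachableProtofilaments = span,
      mapsPerCircumference = maps,
      sites = sites)
}

#' @rdname accessors
#' @export
setMethod("wrapSites", "WrapGeometry", function(object) object@sites)

setMethod("show", "WrapGeometry", function(object) {
  cat(sprintf(paste0("WrapGeometry: arc spacing %.1f A, spans %d ",
                     "protofilament(s), %d MAP(s) per circumference\n"),
              object@siteArcSpacing, object@reachableProtofilaments,
              object@mapsPerCircumference))
})

setMethod("show", "MicrotubuleLattice", function(object) {
  cat(sprintf(paste0("MicrotubuleLattice: %d protofilaments, radius %.1f A,",
                     " dimer repeat %.1f A\n"),
              object@nProtofilaments, object@bindingRadius,
              object@dimerAxialRepeat))
})

setMethod("show", "HelixModel", function(object) {
  cat(sprintf("HelixModel: %d residues (%.0f A), %d repeats, period %.1f\n",
              object@nResidues, helixContourLength(object),
              object@nRepeats, object@repeatPeriodResidues))
})
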