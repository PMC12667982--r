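#' Build a topology data.frame
#'
#' @param serial atom serial numbers.
#' @param name atom names (PDB convention, e.g. "CA", "NZ").
#' @param resid residue names (three-letter, e.g. "LYS").
#' @param resno residue numbers (author numbering).
#' @param chain chain identifiers.
#' @param element chemical elements; inferred from the first letter of the
#'   atom name when missing.
#' @param group per-atom analysis-group label; `"other"` when missing.
#' @return data.frame with the topology columns used across the package.
#' @export
makeTopology <- function(serial, name, resid, resno, chain,
                         element = NULL, group = NULL) {
  n <- length(name)
  if (is.null(element)) element <- substr(gsub("[0-9']", "", name), 1, 1)
  if (is.null(group)) group <- rep("other", n)
  top <- data.frame(serial = as.integer(serial), name = as.character(name),
                    element = toupper(as.character(element)),
                    resid = as.character(resid), resno = as.integer(resno),
                    chain = as.character(chain),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  dup <- duplicated(top[, c("chain", "resno", "name")])
  if (any(dup))
    stop("duplicate atom (chain, resno, name): ",
         paste(top$name[dup][1], top$resno[dup][1], top$chain[dup][1]))
  top
}

#' Assign analysis groups from chain / residue-range selectors
#'
#' @param top topology data.frame.
#' @param groups named list; each element a list with `chain` (character
#'   vector) and optionally `resno` (integer vector of residue numbers).
#'   Atoms matched by no selector get group `"other"`; an atom matched by
#'   two selectors is an error.
#' @return the topology with its `group` column filled in.
#' @export
assignGroups <- function(top, groups) {
  lab <- rep("other", nrow(top))
  for (g in names(groups)) {
    sel <- groups[[g]]
    if (!all(sel$chain %in% top$chain))
      stop("configuration error: chain '",
           setdiff(sel$chain, top$chain)[1], "' for group '", g,
           "' not present in topology")
    hit <- top$chain %in% sel$chain
    if (!is.null(sel$resno)) hit <- hit & top$resno %in% sel$resno
    clash <- hit & lab != "other"
    if (any(clash))
      stop("atom assigned to two groups: '", lab[clash][1], "' and '", g, "'")
    lab[hit] <- g
  }
  top$group <- lab
  top
}

#' Read topology and frames from multi-model PDB files
#'
#' A single-model PDB supplies the topology; each file contributes one run
#' whose MODEL records are the frames. All files must share the same atom
#' list. Atom and residue order/numbering are preserved.
#'
#' @param paths character vector of PDB paths, one per run.
#' @param groups optional group mapping passed to [assignGroups()].
#' @param runLabels labels for the runs; defaults to file base names.
#' @return a [TrajectoryEnsemble-class].
#' @export
readTrajectory <- function(paths, groups = NULL, runLabels = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(runLabels)) runLabels <- basename(paths)
  runs <- vector("list", length(paths))
  top <- NULL
  for (k in seq_along(paths)) {
    checkModelAtomCounts(paths[k])
    pdb <- bio3d::read.pdb(paths[k], multi = TRUE, verbose = FALSE)
    a <- pdb$atom
    this_top <- makeTopology(serial = a$eleno, name = a$elety,
                             resid = a$resid, resno = a$resno,
                             chain = ifelse(is.na(a$chain), "A", a$chain),
                             element = if (all(nzchar(trimws(a$elesy))))
                               trimws(a$elesy) else NULL)
    if (is.null(top)) {
      top <- this_top
    } else if (nrow(this_top) != nrow(top) ||
               !all(this_top$name == top$name & this_top$resno == top$resno)) {
      stop("format error: run file '", paths[k],
           "' does not match the topology of the first file")
    }
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * nrow(this_top))
      stop("format error in '", paths[k], "': model ",
           which(apply(xyz, 1, function(r) sum(!is.na(r))) !=
                   3L * nrow(this_top))[1],
           " has an inconsistent atom count")
    nf <- nrow(xyz)
    arr <- array(NA_real_, c(nf, nrow(this_top), 3L))
    for (d in 1:3) arr[, , d] <- xyz[, seq(d, ncol(xyz), by = 3L), drop = FALSE]
    runs[[k]] <- arr
  }
  if (!is.null(groups)) top <- assignGroups(top, groups)
  new("TrajectoryEnsemble", topology = top, runs = runs,
      runLabels = as.character(runLabels))
}

# Models of a multi-model PDB must all contain the same number of atom
# records; reports the first offending model by index.
checkModelAtomCounts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  starts <- which(rec == "MODEL ")
  if (length(starts) < 2L) return(invisible(TRUE))
  ends <- which(rec == "ENDMDL")
  counts <- vapply(seq_along(starts), function(i) {
    sum(rec[starts[i]:ends[i]] %in% c("ATOM  ", "HETATM"))
  }, integer(1))
  bad <- which(counts != counts[1])
  if (length(bad))
    stop("format error in '", path, "': model ", bad[1],
         " has ", counts[bad[1]], " atoms but model 1 has ", counts[1])
  invisible(TRUE)
}

#' Build a trajectory ensemble from in-memory pieces
#'
#' @param top topology data.frame (see [makeTopology()]).
#' @param runs list of `frames x atoms x 3` arrays.
#' @param runLabels optional run labels.
#' @return a [TrajectoryEnsemble-class].
#' @export
trajectoryEnsemble <- function(top, runs, runLabels = NULL) {
  if (is.array(runs) && length(dim(runs)) == 3L) runs <- list(runs)
  if (is.null(runLabels)) runLabels <- sprintf("run%d", seq_along(runs))
  new("TrajectoryEnsemble", topology = top, runs = runs,
      runLabels = as.character(runLabels))
}

#' Write one run of an ensemble as a multi-model PDB
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param path output path.
#' @param run index or label of the run to write.
#' @return `path`, invisibly.
#' @export
writeTrajectoryPDB <- function(ensemble, path, run = 1L) {
  stopifnot(is(ensemble, "TrajectoryEnsemble"))
  if (is.character(run)) run <- match(run, ensemble@runLabels)
  top <- ensemble@topology
  arr <- ensemble@runs[[run]]
  nf <- dim(arr)[1]; na <- dim(arr)[2]
  xyz <- matrix(NA_real_, nf, 3L * na)
  for (d in 1:3) xyz[, seq(d, ncol(xyz), by = 3L)] <- arr[, , d]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      top$serial, formatC(top$name, width = -4), top$resid, top$chain,
      top$resno, arr[f, , 1], arr[f, , 2], arr[f, , 3], top$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- chemical atom-class sets -------------------------------------------

# Side-chain donor heavy atoms and the names of their bonded hydrogens.
HBOND_DONORS <- list(
  backbone = list(N = "H"),
  SER = list(OG  = "HG"),  THR = list(OG1 = "HG1"), TYR = list(OH = "HH"),
  CYS = list(SG  = "HG"),  TRP = list(NE1 = "HE1"),
  LYS = list(NZ  = c("HZ1", "HZ2", "HZ3")),
  ARG = list(NE  = "HE", NH1 = c("HH11", "HH12"), NH2 = c("HH21", "HH22")),
  ASN = list(ND2 = c("HD21", "HD22")), GLN = list(NE2 = c("HE21", "HE22")),
  HIS = list(ND1 = "HD1", NE2 = "HE2"))

HBOND_ACCEPTORS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD")

#' Default chemical atom-class sets
#'
#' Atom selectors used by the contact classifiers. Basic nitrogens default
#' to Lys NZ and Arg NE/NH1/NH2; histidine is excluded unless
#' `includeHis = TRUE` (its protonation state is generally unknown). Acidic
#' oxygens are Asp OD1/OD2, Glu OE1/OE2 and the C-terminal carboxylate
#' OXT. Side-chain carbons are all carbon atoms other than the backbone C
#' and CA (glycine therefore contributes none). Donors/acceptors follow
#' standard residue templates.
#'
#' @param includeHis logical; count His ND1/NE2 as basic nitrogens.
#' @return list of class-definition tables consumed by [selectAtoms()].
#' @export
atomClassSets <- function(includeHis = FALSE) {
  basic <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
  if (includeHis) basic$HIS <- c("ND1", "NE2")
  list(basic_nitrogens = basic,
       acidic_oxygens = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                             .any = "OXT"),
       hbond_donors = HBOND_DONORS,
       hbond_acceptors = HBOND_ACCEPTORS)
}

#' Select atom indices by chemical class
#'
#' @param top topology data.frame.
#' @param class one of `"basic_nitrogens"`, `"acidic_oxygens"`,
#'   `"sidechain_carbons"`, `"hbond_donors"`, `"hbond_acceptors"`,
#'   `"heavy"`, `"calpha"`.
#' @param classSets class definitions, see [atomClassSets()].
#' @return sorted integer vector of row indices into `top`.
#' @export
selectAtoms <- function(top, class, classSets = atomClassSets()) {
  sel <- switch(class,
    calpha = top$name == "CA" & top$element == "C",
    heavy = top$element != "H",
    sidechain_carbons = top$element == "C" & !top$name %in% c("C", "CA"),
    basic_nitrogens = matchClassTable(top, classSets$basic_nitrogens),
    acidic_oxygens = matchClassTable(top, classSets$acidic_oxygens),
    hbond_donors = matchDonorTable(top, classSets$hbond_donors),
    hbond_acceptors = matchAcceptorTable(top, classSets$hbond_acceptors),
    stop("configuration error: unknown atom class '", class, "'"))
  sort(which(sel))
}

matchClassTable <- function(top, tab) {
  sel <- rep(FALSE, nrow(top))
  for (res in names(tab)) {
    if (res == ".any") sel <- sel | top$name %in% tab[[res]]
    else sel <- sel | (top$resid == res & top$name %in% tab[[res]])
  }
  sel
}

matchDonorTable <- function(top, tab) {
  sel <- top$name %in% names(tab$backbone) & top$element == "N"
  for (res in setdiff(names(tab), "backbone"))
    sel <- sel | (top$resid == res & top$name %in% names(tab[[res]]))
  sel
}

matchAcceptorTable <- function(top, tab) {
  sel <- top$name %in% tab$backbone & top$element == "O"
  for (res in setdiff(names(tab), "backbone"))
    sel <- sel | (top$resid == res & top$name %in% tab[[res]])
  sel
}

# Hydrogens bonded to a donor heavy atom, looked up from the template.
donorHydrogens <- function(top, donorIdx, tab = HBOND_DONORS) {
  res <- top$resid[donorIdx]; nm <- top$name[donorIdx]
  hn <- if (nm == "N") tab$backbone$N
        else if (!is.null(tab[[res]]) && nm %in% names(tab[[res]]))
          tab[[res]][[nm]]
        else character(0)
  which(top$chain == top$chain[donorIdx] & top$resno == top$resno[donorIdx] &
          top$name %in% hn)
}

# ---- MD run metadata ----------------------------------------------------

#' Configured molecular-dynamics run plan
#'
#' The simulation plan analyzed by the correlation/contact stages: eight
#' 125-ns runs of the MAP-decorated lattice alone, eight 700-ns runs with
#' kinesin-3 motor domains bound, and eight 500-ns runs with kinesin-1.
#'
#' @return data.frame with columns `system`, `run_id`, `duration_ns`.
#' @export
mdRunTable <- function() {
  data.frame(
    system = rep(c("map9_mt", "map9_mt_kinesin3", "map9_mt_kinesin1"),
                 each = 8L),
    run_id = c(letters[1:8], letters[9:16], letters[17:24]),
    duration_ns = rep(c(125, 700, 500), each = 8L),
    stringsAsFactors = FALSE)
}

#' Total simulated time for a system
#'
#' @param runTable data.frame as returned by [mdRunTable()].
#' @param system system label; `NULL` sums everything.
#' @return total duration in microseconds.
#' @export
totalSimulationTime <- function(runTable = mdRunTable(), system = NULL) {
  if (!is.null(system)) runTable <- runTable[runTable$system %in% system, ]
  sum(runTable$duration_ns) / 1000
}

#' @rdname accessors
#' @export
setMethod("topology", "TrajectoryEnsemble", function(object) object@topology)

#' @rdname accessors
#' @export
setMethod("runLabels", "TrajectoryEnsemble", function(object) object@runLabels)

#' @rdname accessors
#' @export
setMethod("nRuns", "TrajectoryEnsemble", function(object) length(object@runs))

#' @rdname accessors
#' @export
setMethod("nFrames", "TrajectoryEnsemble", function(object)
  sum(vapply(object@runs, function(x) dim(x)[1], integer(1))))

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf("TrajectoryEnsemble: %d atoms, %d run(s), %d frame(s) total\n",
              nrow(object@topology), nRuns(object), nFrames(object)))
  gr <- table(object@topology$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(gr), gr), collapse = ", "),
      "\n")
})
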