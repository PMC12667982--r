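#' Run an analysis pipeline from a configuration
#'
#' Executes the requested stages in order, writing machine-readable
#' results (TSV/JSON) plus a `run_info.json` recording the package
#' version, seed and the full parameter set, so every output embeds the
#' configuration that produced it. The same configuration and seed
#' reproduce byte-identical outputs.
#'
#' Supported stages and their parameters:
#' \describe{
#'   \item{`scan_motifs`}{`fasta`, optional `spacer_min`, `spacer_max`,
#'     `min_score`; writes `motifs.tsv`.}
#'   \item{`lattice_map`}{`anchors` (integer vector) or `motifs_tsv`;
#'     optional lattice/helix overrides `n_protofilaments`,
#'     `binding_radius`, `rise_per_residue`; writes `wrap_geometry.tsv`.}
#'   \item{`md_correlate`}{`pdb` (character vector of run files),
#'     `groups`, `group_a`, `group_b`; writes `correlation.tsv`.}
#'   \item{`md_contacts`}{as `md_correlate` plus optional `rules`
#'     overrides; writes `contacts.tsv` and `interaction_summary.tsv`.}
#'   \item{`motility_stats`}{`tracks_tsv`, `mts_tsv`; writes
#'     `motility.json`.}
#'   \item{`fit_kd`}{`binding_tsv`; writes `binding_fit.json`.}
#'   \item{`mt_dynamics`}{`traces_dir` (one TSV per trace with columns
#'     `time_s`, `position_um`) and optional segmentation overrides;
#'     writes `mt_dynamics.json`.}
#'   \item{`simulate`}{`generator` plus that generator's parameters;
#'     writes the generator's native format (FASTA / multi-model PDB /
#'     TSV).}
#' }
#'
#' @param config named list (or path to a YAML file) with `outdir`,
#'   optional `seed` (default 1), and `stages`, a list of stage
#'   configurations each carrying a `stage` name.
#' @return character vector of files written, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir),
            length(config$stages) >= 1L)
  outdir <- config$outdir
  seed <- config$seed %||% 1L
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (st in config$stages) {
    fn <- switch(st$stage,
                 scan_motifs = stageScanMotifs,
                 lattice_map = stageLatticeMap,
                 md_correlate = stageMdCorrelate,
                 md_contacts = stageMdContacts,
                 motility_stats = stageMotilityStats,
                 fit_kd = stageFitKd,
                 mt_dynamics = stageMtDynamics,
                 simulate = stageSimulate,
                 stop("unknown pipeline stage '", st$stage, "'"))
    written <- c(written, fn(st, outdir, seed))
  }
  info <- list(package = "wrapmap",
               version = as.character(utils::packageVersion("wrapmap")),
               seed = seed, config = config)
  info_path <- file.path(outdir, "run_info.json")
  jsonlite::write_json(info, info_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(written, info_path))
}

writeJSONResult <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

stageScanMotifs <- function(st, outdir, seed) {
  seqs <- readProteinSequences(st$fasta)
  out <- file.path(outdir, st$out %||% "motifs.tsv")
  tabs <- lapply(seqs, function(s) {
    tb <- scanPseudoRepeats(
      s, spacerRange = c(st$spacer_min %||% 30L, st$spacer_max %||% 45L),
      minScore = st$min_score %||% 0.5)
    rp <- repeatAnchors(tb)
    if (nrow(rp)) cbind(sequence_id = sequenceId(tb), rp)
  })
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  all <- if (length(tabs)) do.call(rbind, tabs)
         else data.frame(sequence_id = character(0))
  utils::write.table(all, out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

stageLatticeMap <- function(st, outdir, seed) {
  if (!is.null(st$motifs_tsv)) {
    m <- utils::read.delim(st$motifs_tsv)
    anchors <- m$phi_pos
  } else anchors <- st$anchors
  seq_stub <- implantMotifs(length = max(anchors) + 10L, anchors = anchors,
                            seed = seed)
  tb <- scanPseudoRepeats(seq_stub)
  lat <- microtubuleLattice(
    nProtofilaments = st$n_protofilaments %||% 14L,
    bindingRadius = st$binding_radius)
  hel <- helixFromRepeats(tb, risePerResidue = st$rise_per_residue %||% 1.5)
  wg <- wrapRepeats(lat, hel, tb)
  out <- file.path(outdir, st$out %||% "wrap_geometry.tsv")
  sites <- wrapSites(wg)
  sites$site_arc_spacing_A <- wg@siteArcSpacing
  sites$reachable_protofilaments <- wg@reachableProtofilaments
  sites$maps_per_circumference <- wg@mapsPerCircumference
  utils::write.table(sites, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out
}

pipelineEnsemble <- function(st) {
  readTrajectory(st$pdb, groups = st$groups)
}

stageMdCorrelate <- function(st, outdir, seed) {
  ens <- pipelineEnsemble(st)
  an <- correlationMap(ens, st$group_a, st$group_b)
  out <- file.path(outdir, st$out %||% "correlation.tsv")
  correlationTable(an, out)
  out
}

stageMdContacts <- function(st, outdir, seed) {
  ens <- pipelineEnsemble(st)
  an <- correlationMap(ens, st$group_a, st$group_b)
  rules <- do.call(contactRules, st$rules %||% list())
  pairs <- filterPairs(ens, an, rules)
  rec <- classifyContacts(ens, pairs, rules)
  out1 <- file.path(outdir, "contacts.tsv")
  utils::write.table(rec, out1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out2 <- file.path(outdir, "interaction_summary.tsv")
  utils::write.table(interactionSummary(rec, an), out2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(out1, out2)
}

stageMotilityStats <- function(st, outdir, seed) {
  tracks <- utils::read.delim(st$tracks_tsv)
  mts <- utils::read.delim(st$mts_tsv)
  rf <- runFrequency(tracks, mts,
                     minDisplacement = st$min_displacement %||% 0.5,
                     minDuration = st$min_duration %||% 0.6)
  rs <- runStats(tracks)
  writeJSONResult(
    list(run_frequency = rf[c("mean", "sd", "n_mts")],
         run_length_um = list(mean = rs$mean_length, sd = rs$sd_length),
         velocity_um_s = list(mean = rs$mean_velocity,
                              sd = rs$sd_velocity),
         n_tracks = rs$n_tracks),
    file.path(outdir, st$out %||% "motility.json"))
}

stageFitKd <- function(st, outdir, seed) {
  curve <- utils::read.delim(st$binding_tsv)
  fit <- fitLangmuir(curve)
  writeJSONResult(list(kd_nM = fit$kd, kd_se_nM = fit$kd_se,
                       imax = fit$imax, imax_se = fit$imax_se,
                       converged = fit$converged),
                  file.path(outdir, st$out %||% "binding_fit.json"))
}

stageMtDynamics <- function(st, outdir, seed) {
  files <- sort(list.files(st$traces_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  segs <- lapply(files, function(f)
    segmentPhases(utils::read.delim(f),
                  growthMin = st$growth_min %||% 0.2,
                  shrinkMax = st$shrink_max %||% -3,
                  window = st$window %||% 5L,
                  minDuration = st$min_duration %||% 3L))
  gr <- growthRate(segs)
  cf <- catastropheFrequency(segs)
  dp <- depolymerizationRate(segs)
  writeJSONResult(
    list(growth_rate_um_min = gr[c("mean", "sd", "n")],
         catastrophe = cf[c("events", "growth_time_min",
                            "frequency_per_min", "convention")],
         depolymerization_um_s = dp[c("mean", "sd", "se", "n")]),
    file.path(outdir, st$out %||% "mt_dynamics.json"))
}

stageSimulate <- function(st, outdir, seed) {
  seed <- st$seed %||% seed
  switch(st$generator,
    motifs = {
      s <- implantMotifs(length = st$length %||% 700L,
                         anchors = st$anchors %||% MAP9_ANCHORS,
                         phi = st$phi %||% MAP9_PHI, seed = seed)
      out <- file.path(outdir, "synthetic_sequence.fasta")
      writeLines(c(paste0(">", s$id, " offset=", s$numbering_offset),
                   s$residues), out)
      out
    },
    tracks = {
      sim <- simulateTracks(nMTs = st$n_mts %||% 30L,
                            landingRate = st$landing_rate %||% 1.0,
                            seed = seed)
      o1 <- file.path(outdir, "tracks.tsv")
      o2 <- file.path(outdir, "mts.tsv")
      utils::write.table(sim$tracks, o1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      utils::write.table(sim$mts, o2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      c(o1, o2)
    },
    binding = {
      curve <- simulateBindingCurve(kd = st$kd %||% 61,
                                    noiseFraction = st$noise %||% 0.15,
                                    seed = seed)
      out <- file.path(outdir, "binding.tsv")
      utils::write.table(curve, out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out
    },
    dynamics = {
      sim <- simulateDynamicInstability(nTraces = st$n_traces %||% 30L,
                                        seed = seed)
      dir.create(file.path(outdir, "traces"), showWarnings = FALSE)
      outs <- vapply(seq_along(sim$traces), function(i) {
        f <- file.path(outdir, "traces", sprintf("trace%03d.tsv", i))
        utils::write.table(sim$traces[[i]], f, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        f
      }, character(1))
      ev <- file.path(outdir, "traces", "events.tsv")
      utils::write.table(sim$events, ev, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      c(outs, ev)
    },
    trajectory = {
      m <- st$n_residues %||% 4L
      target <- diag(m)
      ens <- simulateCorrelatedTrajectory(target, nA = m %/% 2,
                                          nB = m - m %/% 2,
                                          nFrames = st$n_frames %||% 100L,
                                          seed = seed)
      out <- file.path(outdir, "trajectory.pdb")
      writeTrajectoryPDB(ens, out)
      out
    },
    stop("unknown generator '", st$generator, "'"))
}
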