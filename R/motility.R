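#' Validate single-molecule track and microtubule tables
#'
#' Tracks are one row per scored trajectory: `mt_id`, `start_s`, `end_s`
#' (seconds) and `start_um`, `end_um` (position along the MT axis,
#' micrometers). MT records are one row per filament: `mt_id`,
#' `length_um`, `duration_s` (observation time).
#'
#' @param tracks data.frame of tracks.
#' @param mts data.frame of MT records.
#' @return invisibly TRUE; stops on malformed input.
#' @export
validateTracks <- function(tracks, mts = NULL) {
  need <- c("mt_id", "start_s", "end_s", "start_um", "end_um")
  if (!all(need %in% names(tracks)))
    stop("tracks must have columns ", paste(need, collapse = ", "))
  if (any(tracks$end_s <= tracks$start_s))
    stop("data error: track with non-positive duration")
  if (!is.null(mts)) {
    if (!all(c("mt_id", "length_um", "duration_s") %in% names(mts)))
      stop("mts must have columns mt_id, length_um, duration_s")
    if (any(mts$length_um <= 0) || any(mts$duration_s <= 0))
      stop("data error: MT with non-positive length or duration")
    unknown <- setdiff(tracks$mt_id, mts$mt_id)
    if (length(unknown))
      stop("data error: track references unknown mt_id '", unknown[1], "'")
  }
  invisible(TRUE)
}

#' Run frequency per microtubule
#'
#' Number of processive runs on each MT divided by its length and the
#' observation time: events per micrometer per minute. A track counts as
#' processive when its displacement and duration meet the thresholds
#' (defaults 0.5 um and 0.6 s; set both to 0 to count every track).
#' MTs with zero runs contribute 0 and enter the summary.
#'
#' @param tracks track data.frame (see [validateTracks()]).
#' @param mts MT record data.frame.
#' @param minDisplacement minimum |end - start| displacement (um).
#' @param minDuration minimum track duration (s).
#' @return list with `per_mt` (data.frame `mt_id`, `n_runs`,
#'   `frequency_per_um_min`) and `mean`, `sd`, `n_mts` across MTs.
#' @export
runFrequency <- function(tracks, mts, minDisplacement = 0.5,
                         minDuration = 0.6) {
  validateTracks(tracks, mts)
  disp <- abs(tracks$end_um - tracks$start_um)
  dur <- tracks$end_s - tracks$start_s
  keep <- disp >= minDisplacement & dur >= minDuration
  counts <- table(factor(tracks$mt_id[keep], levels = mts$mt_id))
  freq <- as.numeric(counts) / (mts$length_um * (mts$duration_s / 60))
  per_mt <- data.frame(mt_id = mts$mt_id, n_runs = as.integer(counts),
                       frequency_per_um_min = freq,
                       stringsAsFactors = FALSE)
  list(per_mt = per_mt, mean = mean(freq),
       sd = if (length(freq) > 1) stats::sd(freq) else 0,
       n_mts = nrow(mts))
}

#' Run length and velocity statistics
#'
#' Run length is the absolute displacement of a track; velocity is run
#' length over duration. Zero-duration tracks are excluded with a warning.
#'
#' @param tracks track data.frame.
#' @return list with `per_track` (data.frame `mt_id`, `run_length_um`,
#'   `velocity_um_s`) and summary means/SDs (`NA` for an empty set).
#' @export
runStats <- function(tracks) {
  if (!nrow(tracks))
    return(list(per_track = data.frame(mt_id = character(0),
                                       run_length_um = numeric(0),
                                       velocity_um_s = numeric(0)),
                mean_length = NA_real_, sd_length = NA_real_,
                mean_velocity = NA_real_, sd_velocity = NA_real_,
                n_tracks = 0L))
  dur <- tracks$end_s - tracks$start_s
  zero <- dur <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-duration track(s) excluded")
    tracks <- tracks[!zero, , drop = FALSE]
    dur <- dur[!zero]
  }
  len <- abs(tracks$end_um - tracks$start_um)
  vel <- len / dur
  list(per_track = data.frame(mt_id = tracks$mt_id, run_length_um = len,
                              velocity_um_s = vel, stringsAsFactors = FALSE),
       mean_length = mean(len), sd_length = stats::sd(len),
       mean_velocity = mean(vel), sd_velocity = stats::sd(vel),
       n_tracks = length(len))
}

#' Fit a Langmuir binding isotherm
#'
#' Least-squares fit of the single-site equilibrium model
#' `I(c) = Imax * c / (Kd + c)` to per-MT intensity measurements, giving
#' the dissociation constant Kd with its standard error from the fit's
#' parameter covariance. Initialization: Imax from the largest
#' per-concentration mean, Kd from the concentration whose mean intensity
#' is nearest half-maximum; Kd is bounded positive.
#'
#' @param curve data.frame with columns `conc_nM` and `intensity`.
#' @return list of class `BindingFit` with `kd`, `kd_se`, `imax`,
#'   `imax_se`, `converged` and the underlying `fit` object.
#' @export
fitLangmuir <- function(curve) {
  stopifnot(all(c("conc_nM", "intensity") %in% names(curve)))
  if (length(unique(curve$conc_nM)) < 3L)
    stop("at least 3 distinct concentrations are required")
  if (any(curve$conc_nM < 0)) stop("concentrations must be >= 0")
  if (any(curve$intensity < 0)) stop("intensities must be non-negative")
  if (all(curve$intensity == 0))
    stop("degenerate data: all intensities are zero")
  means <- tapply(curve$intensity, curve$conc_nM, mean)
  concs <- as.numeric(names(means))
  imax0 <- max(means)
  kd0 <- concs[which.min(abs(means - imax0 / 2))]
  if (kd0 <= 0) kd0 <- max(concs[concs > 0][1], 1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(intensity ~ imax * conc_nM / (kd + conc_nM),
                      data = curve,
                      start = list(imax = imax0, kd = kd0),
                      lower = c(imax = 0, kd = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Langmuir fit failed to converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  structure(list(kd = unname(co["kd", "Estimate"]),
                 kd_se = unname(co["kd", "Std. Error"]),
                 imax = unname(co["imax", "Estimate"]),
                 imax_se = unname(co["imax", "Std. Error"]),
                 converged = fit$convInfo$isConv %||% TRUE,
                 fit = fit),
            class = "BindingFit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.BindingFit <- function(x, ...) {
  cat(sprintf("Langmuir fit: Kd = %.3g +/- %.2g nM, Imax = %.3g +/- %.2g\n",
              x$kd, x$kd_se, x$imax, x$imax_se))
  invisible(x)
}
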