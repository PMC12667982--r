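#' Segment a microtubule tip trace into growth / shrinkage / pause phases
#'
#' A centered sliding-window least-squares velocity is computed at every
#' sample (uniform sampling assumed; edge samples take the nearest interior
#' window), classified against the two velocity thresholds, adjacent
#' same-type samples merged into phases, and phases shorter than the
#' minimum duration absorbed into their neighbors. Each final phase gets a
#' least-squares slope and slope SE refit over its own samples.
#'
#' Default thresholds separate the two regimes by about an order of
#' magnitude on each side: growth above +0.2 um/min, shrinkage below
#' -3 um/min (growth is of order 1 um/min while shrinkage is of order
#' 0.3 um/s = 18 um/min), with everything between scored as pause.
#'
#' @param trace data.frame with columns `time_s`, `position_um`, or a list
#'   with those elements.
#' @param growthMin minimum velocity for growth (um/min).
#' @param shrinkMax maximum velocity for shrinkage (um/min, negative).
#' @param window sliding-window width in samples (odd; default 5).
#' @param minDuration minimum phase length in samples (default 3).
#' @return a [PhaseSegmentation-class].
#' @export
segmentPhases <- function(trace, growthMin = 0.2, shrinkMax = -3,
                          window = 5L, minDuration = 3L) {
  tr <- data.frame(time_s = trace$time_s, position_um = trace$position_um)
  n <- nrow(tr)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < 2L * window)
    stop("insufficient data: trace must have at least 2 x window samples")
  if (is.unsorted(tr$time_s, strictly = TRUE))
    stop("times must be strictly increasing")
  dt <- diff(tr$time_s)
  if (max(dt) > 1.5 * min(dt))
    stop("trace must be uniformly sampled (within tolerance)")
  dt <- stats::median(dt)

  # vectorized centered-window slope: slope_t = sum(w_k * x_{t+k}) with
  # w_k = k / (dt * sum k^2), k = -h..h
  h <- (window - 1L) %/% 2L
  k <- seq(-h, h)
  w <- k / (dt * sum(k^2))
  v <- as.numeric(stats::filter(tr$position_um, rev(w), sides = 2))
  # nearest interior value at the edges
  v[seq_len(h)] <- v[h + 1L]
  v[(n - h + 1L):n] <- v[n - h]

  v_min <- v * 60  # um/min for threshold comparison
  cls <- ifelse(v_min > growthMin, "growth",
                ifelse(v_min < shrinkMax, "shrinkage", "pause"))

  # merge adjacent same-type samples; absorb short phases into neighbors
  r <- rle(cls)
  repeat {
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < minDuration)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    into <- if (i == 1L) 2L
            else if (i == length(r$lengths)) i - 1L
            else if (r$lengths[i - 1L] >= r$lengths[i + 1L]) i - 1L
            else i + 1L
    r$values[i] <- r$values[into]
    r <- rle(inverse.rle(r))
  }
  cls <- inverse.rle(r)
  r <- rle(cls)

  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  # contiguous phase boundaries: each phase ends where the next begins
  start_s <- tr$time_s[starts]
  end_s <- c(tr$time_s[starts[-1L]], tr$time_s[n])
  phases <- data.frame(type = r$values,
                       start_s = start_s, end_s = end_s,
                       start_idx = starts, end_idx = ends,
                       slope_um_s = NA_real_, slope_se = NA_real_,
                       stringsAsFactors = FALSE)
  for (p in seq_len(nrow(phases))) {
    idx <- phases$start_idx[p]:phases$end_idx[p]
    tt <- tr$time_s[idx] - mean(tr$time_s[idx])
    xx <- tr$position_um[idx]
    sxx <- sum(tt^2)
    slope <- sum(tt * (xx - mean(xx))) / sxx
    res <- xx - mean(xx) - slope * tt
    df <- length(idx) - 2L
    phases$slope_um_s[p] <- slope
    phases$slope_se[p] <- if (df > 0) sqrt(sum(res^2) / df / sxx) else 0
  }
  new("PhaseSegmentation", phases = phases, trace = tr,
      params = list(growthMin = growthMin, shrinkMax = shrinkMax,
                    window = window, minDuration = minDuration))
}

segList <- function(segs) {
  if (is(segs, "PhaseSegmentation")) list(segs) else segs
}

phaseDurations <- function(ph) ph$end_s - ph$start_s

#' Growth rate across traces
#'
#' Per-trace time-weighted mean slope of growth phases, converted to
#' um/min, then summarized (mean, SD) across traces. Traces without growth
#' phases are flagged and excluded from the summary.
#'
#' @param segs a [PhaseSegmentation-class] or a list of them.
#' @return list with `per_trace` (um/min, NA where a trace had no growth),
#'   `mean`, `sd`, `n`, `no_growth` (count of flagged traces).
#' @export
growthRate <- function(segs) {
  segs <- segList(segs)
  per <- vapply(segs, function(s) {
    ph <- s@phases[s@phases$type == "growth", , drop = FALSE]
    if (!nrow(ph)) return(NA_real_)
    w <- phaseDurations(ph)
    60 * sum(ph$slope_um_s * w) / sum(w)
  }, numeric(1))
  ok <- !is.na(per)
  list(per_trace = per,
       mean = if (any(ok)) mean(per[ok]) else NA_real_,
       sd = if (sum(ok) > 1) stats::sd(per[ok]) else 0,
       n = sum(ok), no_growth = sum(!ok))
}

#' Catastrophe frequency
#'
#' Number of transitions into shrinkage (from growth or pause) divided by
#' the total time spent in growth, in events per minute, pooled over the
#' supplied traces. The normalization convention (per growth time) is
#' recorded in the result.
#'
#' @param segs a [PhaseSegmentation-class] or a list of them.
#' @return list with `events`, `growth_time_min`, `frequency_per_min`
#'   (NA with a flag when no growth time was observed), and `convention`.
#' @export
catastropheFrequency <- function(segs) {
  segs <- segList(segs)
  events <- 0L
  growth_s <- 0
  for (s in segs) {
    ph <- s@phases
    if (nrow(ph) > 1L)
      events <- events + sum(ph$type[-1L] == "shrinkage" &
                               ph$type[-nrow(ph)] %in% c("growth", "pause"))
    growth_s <- growth_s + sum(phaseDurations(ph[ph$type == "growth", ,
                                                 drop = FALSE]))
  }
  if (growth_s <= 0)
    return(list(events = events, growth_time_min = 0,
                frequency_per_min = NA_real_, undefined = TRUE,
                convention = "per growth time"))
  list(events = as.integer(events), growth_time_min = growth_s / 60,
       frequency_per_min = events / (growth_s / 60), undefined = FALSE,
       convention = "per growth time")
}

#' Rescue frequency (shrinkage to growth transitions per shrinkage time)
#'
#' @param segs a [PhaseSegmentation-class] or a list of them.
#' @return list with `events`, `shrink_time_min`, `frequency_per_min`.
#' @export
rescueFrequency <- function(segs) {
  segs <- segList(segs)
  events <- 0L
  shrink_s <- 0
  for (s in segs) {
    ph <- s@phases
    if (nrow(ph) > 1L)
      events <- events + sum(ph$type[-1L] == "growth" &
                               ph$type[-nrow(ph)] == "shrinkage")
    shrink_s <- shrink_s + sum(phaseDurations(ph[ph$type == "shrinkage", ,
                                                 drop = FALSE]))
  }
  list(events = as.integer(events), shrink_time_min = shrink_s / 60,
       frequency_per_min = if (shrink_s > 0) events / (shrink_s / 60)
                           else NA_real_)
}

#' Depolymerization rate across traces
#'
#' Per-trace time-weighted |slope| of shrinkage phases (um/s), summarized
#' across traces. Traces without shrinkage phases are flagged and excluded.
#'
#' @param segs a [PhaseSegmentation-class] or a list of them.
#' @return list with `per_trace` (um/s), `mean`, `sd`, `se`, `n`,
#'   `no_shrinkage`.
#' @export
depolymerizationRate <- function(segs) {
  segs <- segList(segs)
  per <- vapply(segs, function(s) {
    ph <- s@phases[s@phases$type == "shrinkage", , drop = FALSE]
    if (!nrow(ph)) return(NA_real_)
    w <- phaseDurations(ph)
    abs(sum(ph$slope_um_s * w) / sum(w))
  }, numeric(1))
  ok <- !is.na(per)
  n <- sum(ok)
  sd <- if (n > 1) stats::sd(per[ok]) else 0
  list(per_trace = per,
       mean = if (n) mean(per[ok]) else NA_real_,
       sd = sd, se = if (n) sd / sqrt(n) else NA_real_,
       n = n, no_shrinkage = sum(!ok))
}

#' @rdname accessors
#' @export
setMethod("phases", "PhaseSegmentation", function(object) object@phases)

setMethod("show", "PhaseSegmentation", function(object) {
  ph <- object@phases
  cat(sprintf("PhaseSegmentation: %d phase(s) over %.1f s\n",
              nrow(ph), max(ph$end_s) - min(ph$start_s)))
  tab <- table(ph$type)
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
})
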