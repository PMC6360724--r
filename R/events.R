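# Demi-plie event extraction from saute trials: pelvis-height minima,
# consistent-triplet selection, per-event value extraction.

#' Detect per-cycle pelvis-height minima
#'
#' Local minima of the (filtered) pelvis height series separated by at least
#' `min_cycle_s`; plateau ties resolve to the earliest frame. When two
#' candidate minima fall closer than the separation, the lower one wins.
#'
#' @param pelvis_height Numeric series (mm).
#' @param rate Sampling rate, Hz.
#' @param min_cycle_s Minimum separation between minima, seconds. The
#'   pipeline default is 0.4 x the beat period at the configured tempo.
#' @return Integer frame indices (1-based), strictly increasing.
#' @export
detect_minima <- function(pelvis_height, rate, min_cycle_s) {
  if (min_cycle_s <= 0) stop("min_cycle_s must be positive", call. = FALSE)
  h <- pelvis_height
  n <- length(h)
  if (n < 3L) stop("event error: series too short", call. = FALSE)
  # strict drop before, no rise until the next strict change (earliest frame
  # of any plateau)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (h[i] < h[i - 1L]) {
      j <- i
      while (j < n && h[j + 1L] == h[j]) j <- j + 1L
      if (j < n && h[j + 1L] > h[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) stop("event error: no local minima found", call. = FALSE)
  min_gap <- round(min_cycle_s * rate)
  keep <- integer(0)
  for (c in cand[order(h[cand])]) {       # lowest first
    if (!length(keep) || all(abs(keep - c) >= min_gap)) keep <- c(keep, c)
  }
  sort(keep)
}

#' Peak-to-trough excursion per detected cycle
#'
#' For each minimum, the mean of the preceding and following local peak
#' heights (series ends count as peaks) minus the minimum height.
#'
#' @param pelvis_height Numeric series (mm).
#' @param minima Frame indices from [detect_minima()].
#' @return Numeric excursions (mm), one per minimum.
#' @export
cycle_excursions <- function(pelvis_height, minima) {
  h <- pelvis_height
  bounds <- c(1L, minima, length(h))
  vapply(seq_along(minima), function(i) {
    before <- max(h[bounds[i]:minima[i]])
    after <- max(h[minima[i]:bounds[i + 2L]])
    (before + after) / 2 - h[minima[i]]
  }, numeric(1))
}

#' Select three consecutive cycles with consistent excursions
#'
#' Returns the consecutive triplet of cycles minimising the coefficient of
#' variation of excursion; ties break to the earliest triplet.
#'
#' @param excursions Numeric per-cycle excursions (mm).
#' @return Integer indices (1-based) of the three chosen cycles.
#' @export
select_consistent_triplet <- function(excursions) {
  k <- length(excursions)
  if (k < 3L) stop("event error: fewer than 3 cycles", call. = FALSE)
  cv <- vapply(seq_len(k - 2L), function(i) {
    e <- excursions[i:(i + 2L)]
    stats::sd(e) / mean(e)
  }, numeric(1))
  i <- which.min(cv)                      # which.min takes the earliest tie
  i:(i + 2L)
}

#' Build the event set for a saute trial
#'
#' @param pelvis_height Filtered pelvis height series (mm).
#' @param rate Sampling rate, Hz.
#' @param tempo_bpm Saute tempo (beats per minute); one saute per beat.
#' @param min_cycle_s Minimum cycle separation; default 0.4 x beat period.
#' @param min_relative_depth Minima whose excursion is below this fraction of
#'   the deepest cycle's excursion are discarded as noise dips.
#' @return An object of class `"event_set"`: `minima_frames`, `excursions`,
#'   `selected` (3 consecutive cycle indices), `selected_frames`.
#' @export
detect_events <- function(pelvis_height, rate, tempo_bpm = 95,
                          min_cycle_s = 0.4 * 60 / tempo_bpm,
                          min_relative_depth = 0.25) {
  minima <- detect_minima(pelvis_height, rate, min_cycle_s)
  exc <- cycle_excursions(pelvis_height, minima)
  # shallow dips (noise near the top of a cycle) are not sautes: keep only
  # minima whose excursion reaches a fraction of the deepest cycle
  keep <- exc >= min_relative_depth * max(exc)
  if (!all(keep)) {
    minima <- minima[keep]
    exc <- cycle_excursions(pelvis_height, minima)
  }
  sel <- select_consistent_triplet(exc)
  structure(list(minima_frames = minima, excursions = exc, selected = sel,
                 selected_frames = minima[sel], rate = rate),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat("<event_set>", length(x$minima_frames), "minima; selected cycles",
      paste(x$selected, collapse = ","), "at frames",
      paste(x$selected_frames, collapse = ","), "\n")
  invisible(x)
}

#' Average kinematic values over the three selected demi-plies
#'
#' Samples each series at the three selected minimum frames and returns the
#' arithmetic mean of the three values per variable.
#'
#' @param angles An [trial_angles()] result (or any named list of per-frame
#'   numeric series).
#' @param events A [detect_events()] result.
#' @return Named numeric vector of per-variable means.
#' @export
extract_at_events <- function(angles, events) {
  frames <- events$selected_frames
  vapply(names(angles), function(v) {
    s <- angles[[v]]
    if (any(frames > length(s)))
      stop("index error: event frame outside series '", v, "'", call. = FALSE)
    mean(s[frames])
  }, numeric(1))
}
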