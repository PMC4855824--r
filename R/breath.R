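#' Global impedance waveform of a frame sequence
#'
#' The per-frame sum of all pixels: the standard functional-EIT global
#' signal, on which breathing appears as a quasi-periodic oscillation.
#'
#' @param seq a [frame_sequence()].
#' @return Numeric vector of length T; element t is the pixel sum of frame t.
#' @export
global_signal <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  apply(seq$frames, 1, sum)
}

new_breath_marks <- function(end_insp_idx, end_exp_idx, shortfall = FALSE) {
  structure(list(end_insp_idx = as.integer(end_insp_idx),
                 end_exp_idx = as.integer(end_exp_idx),
                 shortfall = isTRUE(shortfall)),
            class = "breath_marks")
}

#' @export
print.breath_marks <- function(x, ...) {
  cat(sprintf("<breath_marks> %d end-inspiratory, %d end-expiratory marks%s\n",
              length(x$end_insp_idx), length(x$end_exp_idx),
              if (x$shortfall) " (shortfall: fewer breaths than requested)" else ""))
  invisible(x)
}

# Candidate extrema of a series by sign change of successive differences.
# Flat runs inherit the preceding slope so plateau tops/bottoms yield one
# mark (at the start of the plateau); monotone leading/trailing segments
# (incomplete half-breaths) produce no marks. Returns data.frame(idx, type)
# with type +1 = maximum, -1 = minimum, in index order.
local_extrema <- function(s) {
  d <- sign(diff(s))
  # carry the previous non-zero slope through flat segments
  if (length(d) > 0) {
    nz <- d != 0
    if (any(nz)) {
      filled <- d
      last <- 0
      for (i in seq_along(filled)) {
        if (filled[i] == 0) filled[i] <- last else last <- filled[i]
      }
      d <- filled
    }
  }
  idx <- integer(0); type <- integer(0)
  for (i in seq_len(length(d) - 1L)) {
    if (d[i] > 0 && d[i + 1L] < 0) { idx <- c(idx, i + 1L); type <- c(type, 1L) }
    if (d[i] < 0 && d[i + 1L] > 0) { idx <- c(idx, i + 1L); type <- c(type, -1L) }
  }
  data.frame(idx = idx, type = type)
}

# Drop the lowest-excursion adjacent extremum pair until all remaining
# peak-trough excursions reach `prom`. Removing an adjacent (peak, trough)
# pair preserves alternation.
prune_prominence <- function(ext, s, prom) {
  repeat {
    if (nrow(ext) < 2L) break
    exc <- abs(diff(s[ext$idx]))
    k <- which.min(exc)
    if (exc[k] >= prom) break
    ext <- ext[-c(k, k + 1L), , drop = FALSE]
  }
  ext
}

# Enforce a minimum frame spacing between consecutive same-type marks by
# discarding the weaker peak (or shallower trough) together with one
# intervening opposite mark, keeping alternation intact.
prune_spacing <- function(ext, s, min_gap) {
  repeat {
    peaks <- which(ext$type == 1L)
    troughs <- which(ext$type == -1L)
    viol <- NULL
    if (length(peaks) >= 2L) {
      g <- diff(ext$idx[peaks])
      j <- which(g < min_gap)
      if (length(j)) viol <- peaks[c(j[1], j[1] + 1L)]
    }
    if (is.null(viol) && length(troughs) >= 2L) {
      g <- diff(ext$idx[troughs])
      j <- which(g < min_gap)
      if (length(j)) viol <- troughs[c(j[1], j[1] + 1L)]
    }
    if (is.null(viol)) break
    a <- viol[1]; b <- viol[2]
    is_peak <- ext$type[a] == 1L
    weaker <- if (is_peak) {
      if (s[ext$idx[a]] <= s[ext$idx[b]]) a else b
    } else {
      if (s[ext$idx[a]] >= s[ext$idx[b]]) a else b
    }
    between <- setdiff(seq(a, b), c(a, b))
    drop2 <- if (length(between)) {
      if (is_peak) between[which.max(s[ext$idx[between]])]
      else between[which.min(s[ext$idx[between]])]
    } else integer(0)
    ext <- ext[-c(weaker, drop2), , drop = FALSE]
  }
  ext
}

#' Detect breaths on a global impedance waveform
#'
#' Locates alternating end-inspiratory maxima and end-expiratory minima.
#' The signal is first smoothed with a centred moving average (window
#' 0.25 s) to suppress cardiac oscillation and sensor noise; candidate
#' extrema are then pruned so that every peak-to-trough excursion reaches
#' `min_prominence_frac` of the signal's dynamic range and consecutive
#' same-type marks are at least `min_breath_s` apart. Each retained mark is
#' finally mapped to the nearest raw-signal extremum within the smoothing
#' window, so downstream averaging uses genuinely recorded frames.
#'
#' Prominence is relative to the dynamic range, which makes detection
#' invariant under positive affine transforms of the signal.
#'
#' @param signal numeric global-impedance series (see [global_signal()]).
#' @param sample_rate_hz sampling rate of the series, in frames per second.
#' @param min_breath_s minimum breath duration in seconds (default 1.0,
#'   supporting respiratory rates up to 60/min).
#' @param min_prominence_frac minimum peak-to-trough excursion as a fraction
#'   of the global dynamic range, in (0, 1); default 0.15.
#' @return A `breath_marks` object with fields `end_insp_idx` and
#'   `end_exp_idx` (1-based frame indices into the unsmoothed signal).
#' @export
detect_breaths <- function(signal, sample_rate_hz, min_breath_s = 1.0,
                           min_prominence_frac = 0.15) {
  if (!is.numeric(signal) || length(signal) < 2L)
    stop("`signal` must be a numeric series of length >= 2", call. = FALSE)
  if (min_prominence_frac <= 0 || min_prominence_frac >= 1)
    stop("`min_prominence_frac` must lie in (0, 1)", call. = FALSE)
  if (length(signal) < 2 * min_breath_s * sample_rate_hz)
    stop("signal too short: need at least two breath durations of data",
         call. = FALSE)
  rng <- diff(range(signal))
  if (rng == 0)
    stop("breath detection failed: signal has zero dynamic range (constant)",
         call. = FALSE)

  half <- max(0L, floor(0.25 * sample_rate_hz / 2))
  win <- 2L * half + 1L  # odd, centred window of ~0.25 s
  s <- if (win > 1L) {
    # partial windows at the edges: mean over the available samples
    cs <- cumsum(c(0, signal))
    n <- length(signal)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else signal

  ext <- local_extrema(s)
  prom <- min_prominence_frac * (max(s) - min(s))
  ext <- prune_prominence(ext, s, prom)
  ext <- prune_spacing(ext, s, min_breath_s * sample_rate_hz)
  if (nrow(ext) < 2L || !any(ext$type == 1L) || !any(ext$type == -1L))
    stop(paste("fewer than one complete breath detected;",
               "review min_breath_s / min_prominence_frac or the recording"),
         call. = FALSE)

  # refine each mark to the raw-signal extremum within the smoothing window
  n <- length(signal)
  refine <- function(i, type) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    seg <- signal[lo:hi]
    lo - 1L + if (type > 0) which.max(seg) else which.min(seg)
  }
  ext$idx <- mapply(refine, ext$idx, ext$type)
  ext <- ext[order(ext$idx), , drop = FALSE]
  ext <- ext[!duplicated(ext$idx), , drop = FALSE]
  new_breath_marks(ext$idx[ext$type == 1L], ext$idx[ext$type == -1L])
}

#' Select the final n breaths from detected marks
#'
#' Analysis of a PEEP step uses the last breaths of the step, when the lung
#' has equilibrated at the new pressure; the reference protocol selects five
#' consecutive breaths at the end of each step. Taking the tail of each
#' alternating list preserves alternation.
#'
#' @param marks a `breath_marks` object.
#' @param n number of breaths to keep (default 5).
#' @return A `breath_marks` with at most `n` marks per list; if fewer than
#'   `n` breaths are available, all are returned and the `shortfall` flag is
#'   set in the result.
#' @export
select_last_n <- function(marks, n = 5) {
  stopifnot(inherits(marks, "breath_marks"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  ni <- length(marks$end_insp_idx); ne <- length(marks$end_exp_idx)
  if (ni == 0L && ne == 0L)
    stop("cannot select breaths from empty marks", call. = FALSE)
  short <- ni < n || ne < n
  new_breath_marks(utils::tail(marks$end_insp_idx, n),
                   utils::tail(marks$end_exp_idx, n),
                   shortfall = short)
}
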