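# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default archetype layout for the synthetic lung phantom
#'
#' Two elliptical lungs on the pixel grid (row 1 = ventral edge, supine
#' convention), stratified by depth the way lavage injury distributes in a
#' supine subject: ventral lung prone to overdistension, mid lung normal,
#' dorsal lung recruitable, and the most dorsal band cyclically collapsing
#' at low PEEP. Everything outside the ellipses is non-lung.
#'
#' @param height,width grid dimensions (default 32 x 32).
#' @return Character matrix of archetype names: `"non_lung"`, `"normal"`,
#'   `"overdistending"`, `"recruitable"`, `"cyclic_low_peep"`.
#' @export
default_archetype_map <- function(height = 32, width = 32) {
  map <- matrix("non_lung", height, width)
  r0 <- 0.55 * height
  ra <- 0.32 * height
  ca <- 0.18 * width
  centers <- c(0.3, 0.7) * width
  for (r in seq_len(height)) for (c in seq_len(width)) {
    inside <- any(((r - r0) / ra)^2 + ((c - centers) / ca)^2 <= 1)
    if (!inside) next
    depth <- (r - (r0 - ra)) / (2 * ra)  # 0 = ventral rim, 1 = dorsal rim
    map[r, c] <-
      if (depth < 0.30) "overdistending"
      else if (depth < 0.60) "normal"
      else if (depth < 0.80) "recruitable"
      else "cyclic_low_peep"
  }
  map
}

# depth fraction within the lung ellipse for pressure gradients (0 at the
# ventral rim, 1 at the dorsal rim); used by the default pressure maps
depth_fraction <- function(height) {
  r0 <- 0.55 * height
  ra <- 0.32 * height
  (seq_len(height) - (r0 - ra)) / (2 * ra)
}

#' Configuration of the synthetic EIT PEEP-trial phantom
#'
#' Every pixel follows `signal(t) = a(PEEP) + b(PEEP) * w(t) + noise`, where
#' `w(t)` is a raised sinusoid in `[0, 1]` at the respiratory rate (so `a`
#' is the end-expiratory aeration level relative to the trial baseline and
#' `b` the tidal amplitude), and the archetype of the pixel dictates how
#' `a` and `b` move with PEEP:
#' * `normal` — aerated and ventilated at every PEEP (`a > 0`, `b > 0`);
#'   `a` rises linearly with PEEP.
#' * `overdistending` — behaves normally up to its overdistension onset
#'   pressure; above it the pixel stops ventilating (`b = 0`) while its
#'   end-expiratory aeration stays high.
#' * `recruitable` — airless and unventilated (`a = b = 0`) below its
#'   opening pressure; normal at and above it.
#' * `cyclic_low_peep` — ventilated but airless at end-expiration (`a = 0`,
#'   `b > 0`) below its opening pressure (tidal collapse/reopening);
#'   normal at and above it.
#' * `non_lung` — `a = b = 0` at every PEEP.
#'
#' Transitions are hard switches at the stated pressures, which keeps the
#' ground-truth labels unambiguous. `opening_pressure` and
#' `overdistension_onset` accept a scalar or an `H x W` matrix; the default
#' maps grade the pressures with depth (dorsal units open at higher PEEP,
#' deeper ventral units overdistend later), which yields gradually
#' monotone region sizes across the trial.
#'
#' @param height,width grid (default 32 x 32).
#' @param sample_rate_hz frame rate (default 40).
#' @param rr_bpm respiratory rate, breaths/min (default 30).
#' @param step_duration_s recording length per PEEP step (default 30 s,
#'   i.e. 15 breaths at the default rate — analysis uses only the final
#'   five, so longer recordings add no information).
#' @param peep_levels strictly increasing PEEP labels in cmH2O
#'   (default 0 to 30 by 3).
#' @param archetype_map character `H x W` matrix of archetype names;
#'   default [default_archetype_map()].
#' @param opening_pressure cmH2O at which recruitable / cyclic pixels open;
#'   scalar or matrix. Default: depth-graded 7-19 (recruitable band) and
#'   12-36 (cyclic band; the most dorsal units never open within a
#'   0-30 cmH2O trial, so every category stays represented at every
#'   analyzed step).
#' @param overdistension_onset cmH2O above which overdistending pixels stop
#'   ventilating; scalar or matrix. Default: depth-graded 6-18.
#' @param aeration_amplitude end-expiratory aeration scale `a` (arbitrary
#'   relative-impedance units; default 2).
#' @param tidal_amplitude tidal oscillation scale `b` (default 1).
#' @param noise_sd Gaussian sensor noise SD per pixel per frame (default
#'   0.05, i.e. 5 % of the tidal amplitude).
#' @param cardiac_amplitude optional cardiac oscillation amplitude added to
#'   lung pixels (default 0 = off).
#' @param cardiac_hz cardiac frequency (default 1.5 Hz, ~90 bpm).
#' @param subject_id subject label for the generated sequences.
#' @param seed integer seed; all randomness derives from it (step k uses
#'   `seed + k - 1`).
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(height = 32, width = 32,
                           sample_rate_hz = 40, rr_bpm = 30,
                           step_duration_s = 30,
                           peep_levels = seq(0, 30, by = 3),
                           archetype_map = NULL,
                           opening_pressure = NULL,
                           overdistension_onset = NULL,
                           aeration_amplitude = 2,
                           tidal_amplitude = 1,
                           noise_sd = 0.05,
                           cardiac_amplitude = 0,
                           cardiac_hz = 1.5,
                           subject_id = "phantom",
                           seed = 1L) {
  if (is.null(archetype_map)) archetype_map <- default_archetype_map(height, width)
  if (!is.matrix(archetype_map) || !all(dim(archetype_map) == c(height, width)))
    stop("`archetype_map` must be an H x W character matrix", call. = FALSE)
  known <- c("non_lung", "normal", "overdistending", "recruitable",
             "cyclic_low_peep")
  if (!all(archetype_map %in% known))
    stop("unknown archetype name(s): ",
         paste(unique(archetype_map[!archetype_map %in% known]), collapse = ", "),
         call. = FALSE)
  if (any(diff(peep_levels) <= 0))
    stop("`peep_levels` must be strictly increasing", call. = FALSE)
  if (noise_sd < 0 || tidal_amplitude < 0 || aeration_amplitude < 0 ||
      cardiac_amplitude < 0)
    stop("amplitudes and noise_sd must be non-negative", call. = FALSE)

  expand <- function(x, default_map) {
    if (is.null(x)) default_map
    else if (length(x) == 1L) matrix(x, height, width)
    else if (is.matrix(x) && all(dim(x) == c(height, width))) x
    else stop("pressure parameters must be a scalar or an H x W matrix",
              call. = FALSE)
  }
  depth <- depth_fraction(height)
  open_default <- matrix(NA_real_, height, width)
  onset_default <- matrix(NA_real_, height, width)
  for (r in seq_len(height)) {
    d <- depth[r]
    open_default[r, ] <- if (!is.na(d) && d >= 0.80) 12 + 24 * min(1, (d - 0.80) / 0.20)
                         else 7 + 12 * min(1, max(0, (d - 0.60) / 0.20))
    onset_default[r, ] <- 6 + 12 * min(1, max(0, d / 0.30))
  }
  structure(list(height = height, width = width,
                 sample_rate_hz = sample_rate_hz, rr_bpm = rr_bpm,
                 step_duration_s = step_duration_s,
                 peep_levels = peep_levels,
                 archetype_map = archetype_map,
                 opening_pressure = expand(opening_pressure, open_default),
                 overdistension_onset = expand(overdistension_onset, onset_default),
                 aeration_amplitude = aeration_amplitude,
                 tidal_amplitude = tidal_amplitude,
                 noise_sd = noise_sd,
                 cardiac_amplitude = cardiac_amplitude,
                 cardiac_hz = cardiac_hz,
                 subject_id = subject_id,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# noiseless per-pixel amplitudes at one PEEP: list(a = H x W, b = H x W)
archetype_amplitudes <- function(config, peep) {
  h <- config$height; w <- config$width
  pmax_level <- max(config$peep_levels)
  a_norm <- config$aeration_amplitude * (0.2 + 0.8 * peep / pmax_level)
  a <- matrix(0, h, w); b <- matrix(0, h, w)
  m <- config$archetype_map
  open <- peep >= config$opening_pressure
  od <- peep > config$overdistension_onset

  sel <- m == "normal"
  a[sel] <- a_norm; b[sel] <- config$tidal_amplitude
  sel <- m == "overdistending"
  a[sel] <- a_norm
  b[sel] <- ifelse(od[sel], 0, config$tidal_amplitude)
  sel <- m == "recruitable"
  a[sel] <- ifelse(open[sel], a_norm, 0)
  b[sel] <- ifelse(open[sel], config$tidal_amplitude, 0)
  sel <- m == "cyclic_low_peep"
  a[sel] <- ifelse(open[sel], a_norm, 0)
  b[sel] <- config$tidal_amplitude
  list(a = a, b = b)
}

#' Generate a labelled synthetic EIT PEEP trial
#'
#' Produces one frame sequence per PEEP level plus the ground-truth masks
#' obtained by applying the classification definitions to the noiseless
#' amplitudes `a` (end-expiratory image) and `b` (tidal image) at the
#' given thresholds. Frames are emitted already referenced to the trial
#' baseline, as an EIT device does, so [analyze_trial()] with
#' `rebase_mode = "none"` recovers the ground truth exactly at zero noise.
#'
#' @param config a [phantom_config()].
#' @param th [thresholds()] used to derive the ground-truth labels.
#' @param reference_peep_cmH2O reference step for the ground-truth recruited
#'   masks (default 6).
#' @return List with `sequences` (list of [frame_sequence()]s, one per PEEP
#'   level) and `truth` (a `ground_truth`: per-level masks `lung_ee`,
#'   `lung_tidal`, `overinflated`, `cyclic`, `recruited`).
#' @export
generate_phantom <- function(config = phantom_config(), th = thresholds(),
                             reference_peep_cmH2O = 6) {
  stopifnot(inherits(config, "phantom_config"))
  fs <- config$sample_rate_hz
  nt <- max(2L, round(config$step_duration_s * fs))
  tvec <- (seq_len(nt) - 1L) / fs
  w <- 0.5 * (1 - cos(2 * pi * (config$rr_bpm / 60) * tvec))  # in [0, 1]
  cardiac <- if (config$cardiac_amplitude > 0)
    config$cardiac_amplitude * sin(2 * pi * config$cardiac_hz * tvec) else NULL
  npx <- config$height * config$width
  lung <- config$archetype_map != "non_lung"

  sequences <- vector("list", length(config$peep_levels))
  amps <- lapply(config$peep_levels, archetype_amplitudes, config = config)
  for (k in seq_along(config$peep_levels)) {
    a <- amps[[k]]$a; b <- amps[[k]]$b
    # frames[t, p] = a_p + b_p * w(t) (+ cardiac on lung pixels) + noise
    flat <- outer(w, as.vector(b)) +
      matrix(as.vector(a), nt, npx, byrow = TRUE)
    if (!is.null(cardiac))
      flat[, as.vector(lung)] <- flat[, as.vector(lung)] + cardiac
    if (config$noise_sd > 0)
      flat <- flat + with_seed(config$seed + k - 1L,
                               matrix(stats::rnorm(nt * npx, sd = config$noise_sd),
                                      nt, npx))
    frames <- array(flat, c(nt, config$height, config$width))
    sequences[[k]] <- frame_sequence(frames, fs, config$subject_id,
                                     config$peep_levels[k])
  }

  truth_one <- function(amp) {
    ee <- amp$a > th$ee_frac * max(amp$a)
    tv <- amp$b > th$tidal_frac * max(amp$b)
    list(lung_ee = ee, lung_tidal = tv,
         overinflated = ee & !tv, cyclic = tv & !ee)
  }
  masks <- lapply(amps, truth_one)
  ref_k <- which(config$peep_levels == reference_peep_cmH2O)
  ref_ee <- if (length(ref_k) == 1L) masks[[ref_k]]$lung_ee else NULL
  for (k in seq_along(masks)) {
    masks[[k]]$recruited <- if (is.null(ref_ee)) NULL
      else recruited_mask(masks[[k]]$lung_ee, ref_ee)
  }
  names(masks) <- as.character(config$peep_levels)
  truth <- structure(list(peep_levels = config$peep_levels,
                          reference_peep_cmH2O =
                            if (is.null(ref_ee)) NA_real_ else reference_peep_cmH2O,
                          masks = masks),
                     class = "ground_truth")
  list(sequences = sequences, truth = truth)
}

#' Add seeded Gaussian sensor noise to a frame sequence
#'
#' @param seq a [frame_sequence()].
#' @param noise_sd noise standard deviation; `0` returns the input unchanged.
#' @param seed integer seed for reproducibility.
#' @return A new [frame_sequence()] with independent N(0, noise_sd) noise on
#'   every pixel of every frame.
#' @export
corrupt <- function(seq, noise_sd, seed = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd == 0) return(seq)
  noise <- with_seed(seed, array(stats::rnorm(length(seq$frames), sd = noise_sd),
                                 dim(seq$frames)))
  frame_sequence(seq$frames + noise, seq$sample_rate_hz, seq$subject_id,
                 seq$peep_cmH2O)
}

#' Dice overlap between two masks
#'
#' `2 |A & B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of one shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must share one shape", call. = FALSE)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
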