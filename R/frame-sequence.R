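#' Construct an EIT frame sequence
#'
#' A frame sequence is the unit of analysis for one PEEP step: a time-ordered
#' stack of reconstructed relative-impedance images on a fixed pixel grid
#' (default 32 x 32 = 1024 pixels), recorded at a known frame rate.
#' Values are relative impedance in arbitrary units and may be negative.
#'
#' @param frames numeric 3-D array `T x H x W` (time, row, column). Row 1 is
#'   the ventral (anterior) edge in the supine display convention.
#' @param sample_rate_hz frames per second; must be positive. Default 40.
#' @param subject_id subject identifier string.
#' @param peep_cmH2O non-negative PEEP label for this step, in cmH2O.
#' @return An object of class `frame_sequence` with fields `frames`,
#'   `sample_rate_hz`, `subject_id`, `peep_cmH2O`, `height`, `width`.
#' @examples
#' fs <- frame_sequence(array(rnorm(5 * 4 * 4), c(5, 4, 4)), 40, "pig01", 6)
#' dim(fs$frames)
#' @export
frame_sequence <- function(frames, sample_rate_hz = 40, subject_id = "subject",
                           peep_cmH2O = 0) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (time x height x width)", call. = FALSE)
  if (dim(frames)[1] < 1L)
    stop("frame sequence must contain at least one frame (T >= 1)", call. = FALSE)
  if (!is.numeric(frames) || anyNA(frames) || any(!is.finite(frames)))
    stop("`frames` must be finite numeric values", call. = FALSE)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a single positive number", call. = FALSE)
  if (!is.numeric(peep_cmH2O) || length(peep_cmH2O) != 1L || peep_cmH2O < 0)
    stop("`peep_cmH2O` must be a single non-negative number", call. = FALSE)
  structure(
    list(frames = frames,
         sample_rate_hz = as.numeric(sample_rate_hz),
         subject_id = as.character(subject_id),
         peep_cmH2O = as.numeric(peep_cmH2O),
         height = dim(frames)[2],
         width = dim(frames)[3]),
    class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> subject %s, PEEP %g cmH2O: %d frames of %dx%d at %g Hz\n",
              x$subject_id, x$peep_cmH2O, dim(x$frames)[1], x$height, x$width,
              x$sample_rate_hz))
  invisible(x)
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)

#' Read an EIT frame sequence from a delimited matrix and JSON sidecar
#'
#' The matrix file holds one frame per row with `H * W` comma-separated
#' pixel values in row-major order (no header, period decimal separator).
#' The JSON sidecar declares the geometry and acquisition metadata.
#'
#' @param path path to the frame matrix (CSV, T rows x H*W columns).
#' @param sidecar path to the JSON metadata file with keys `subject_id`,
#'   `peep_cmH2O`, `sample_rate_hz`, `height`, `width` (and, informatively,
#'   `pixel_order`, always `"row-major"`).
#' @return A [frame_sequence()].
#' @seealso [write_frames()] for the inverse operation.
#' @export
read_frames <- function(path, sidecar) {
  if (!file.exists(sidecar))
    stop("sidecar file not found: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("subject_id", "peep_cmH2O", "sample_rate_hz", "height", "width")) {
    if (is.null(meta[[key]]))
      stop("sidecar is missing required metadata key '", key, "'", call. = FALSE)
  }
  h <- as.integer(meta$height)
  w <- as.integer(meta$width)
  if (!file.exists(path))
    stop("frame matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L)
    stop("frame matrix file is empty: ", path, call. = FALSE)
  npx <- h * w
  frames <- array(NA_real_, c(length(lines), h, w))
  for (t in seq_along(lines)) {
    cells <- strsplit(lines[t], ",", fixed = TRUE)[[1]]
    if (length(cells) != npx)
      stop(sprintf("row %d has %d values but the sidecar declares %d pixels (%d x %d)",
                   t, length(cells), npx, h, w), call. = FALSE)
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals))
      stop(sprintf("row %d contains non-numeric cell(s): %s", t,
                   paste(utils::head(cells[is.na(vals)], 3), collapse = ", ")),
           call. = FALSE)
    # row-major: pixel (r, c) is element (r - 1) * W + c of the line
    frames[t, , ] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  }
  frame_sequence(frames,
                 sample_rate_hz = meta$sample_rate_hz,
                 subject_id = meta$subject_id,
                 peep_cmH2O = meta$peep_cmH2O)
}

#' Write an EIT frame sequence to a delimited matrix and JSON sidecar
#'
#' Inverse of [read_frames()]: values are written with full precision
#' (17 significant digits) so that a read/write round trip reproduces the
#' array exactly.
#'
#' @param seq a [frame_sequence()].
#' @param path output path for the frame matrix CSV.
#' @param sidecar output path for the JSON metadata.
#' @return Invisibly, the input sequence.
#' @export
write_frames <- function(seq, path, sidecar) {
  stopifnot(inherits(seq, "frame_sequence"))
  tt <- dim(seq$frames)[1]
  rows <- vapply(seq_len(tt), function(t) {
    # row-major flatten: t(frame) unrolled column-wise == frame row-wise
    paste(format(as.vector(t(seq$frames[t, , , drop = TRUE])),
                 digits = 17, scientific = FALSE, trim = TRUE),
          collapse = ",")
  }, character(1))
  ok <- tryCatch({ writeLines(rows, path); TRUE },
                 error = function(e) stop("cannot write frame matrix to '",
                                          path, "': ", conditionMessage(e),
                                          call. = FALSE))
  jsonlite::write_json(
    list(subject_id = seq$subject_id,
         peep_cmH2O = seq$peep_cmH2O,
         sample_rate_hz = seq$sample_rate_hz,
         height = seq$height,
         width = seq$width,
         pixel_order = "row-major"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(seq)
}

#' Re-reference a frame sequence against its minimum-sum baseline frame
#'
#' Relative-impedance images are only meaningful against a baseline.
#' `rebase` locates the single frame whose global pixel sum is minimal
#' (earliest frame on ties) and subtracts that frame pixel-wise from every
#' frame, so the global signal of the result attains exactly zero at the
#' baseline index. This mirrors the device convention of reconstructing
#' against the frame with the lowest impedance; see [analyze_trial()] for
#' how the baseline is chosen across a multi-step PEEP trial.
#'
#' @param seq a [frame_sequence()].
#' @param baseline optional `H x W` numeric matrix to subtract instead of the
#'   sequence's own minimum-sum frame (used for trial-wide re-referencing).
#' @return A new [frame_sequence()] with the baseline subtracted.
#' @export
rebase <- function(seq, baseline = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (is.null(baseline)) {
    sums <- global_signal(seq)
    base_idx <- which.min(sums)  # which.min takes the earliest on ties
    baseline <- seq$frames[base_idx, , , drop = TRUE]
    dim(baseline) <- c(seq$height, seq$width)
  }
  if (!all(dim(baseline) == c(seq$height, seq$width)))
    stop("baseline shape does not match the sequence grid", call. = FALSE)
  out <- seq$frames - rep(baseline, each = dim(seq$frames)[1])
  frame_sequence(out, seq$sample_rate_hz, seq$subject_id, seq$peep_cmH2O)
}

#' Read an ancillary physiology table
#'
#' One row per PEEP step with columns such as `peep_cmH2O`, `pao2_fio2`
#' (mmHg), `pawp_mmHg`, `map_mmHg`, `cvp_mmHg`, `hr_bpm`, `pplat_cmH2O`,
#' `vt_ml_per_kg`, `crs_ml_per_cmH2O`. Only `peep_cmH2O` is mandatory; other
#' columns are kept as supplied.
#'
#' @param path CSV file with a header row.
#' @param subject_id optional subject identifier attached as an attribute.
#' @return A data.frame ordered by PEEP with attribute `subject_id`.
#' @export
read_ancillary <- function(path, subject_id = NULL) {
  tab <- utils::read.csv(path, check.names = TRUE)
  if (!"peep_cmH2O" %in% names(tab))
    stop("ancillary table must contain a 'peep_cmH2O' column", call. = FALSE)
  if (anyDuplicated(tab$peep_cmH2O))
    stop("ancillary PEEP values must be unique per subject", call. = FALSE)
  num <- tab[vapply(tab, is.numeric, logical(1))]
  if (any(!is.finite(as.matrix(num))))
    stop("ancillary table contains non-finite values", call. = FALSE)
  if ("pao2_fio2" %in% names(tab) && any(tab$pao2_fio2 <= 0, na.rm = TRUE))
    stop("pao2_fio2 must be positive where present", call. = FALSE)
  tab <- tab[order(tab$peep_cmH2O), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(subject_id)) attr(tab, "subject_id") <- subject_id
  tab
}
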