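#' Configuration for an incremental PEEP trial analysis
#'
#' @param reference_peep_cmH2O PEEP step against which recruitment is
#'   measured (default 6 cmH2O: at lower levels the end-expiratory signal
#'   amplitude can be comparable to reconstruction noise, so a slightly
#'   higher reference is more robust).
#' @param th a [thresholds()] object.
#' @param n_breaths breaths averaged per step (default 5).
#' @param rebase_mode how sequences are re-referenced before analysis:
#'   `"none"` (default) trusts the device's own referencing — input images
#'   are already relative impedance against a trial baseline; `"trial"`
#'   subtracts the minimum-sum frame of the lowest-PEEP step from every
#'   step, mirroring devices that reconstruct against the lowest-impedance
#'   frame at zero PEEP; `"step"` re-references each step to its own
#'   minimum-sum frame (this zeroes the end-expiratory level within each
#'   step and is only meaningful for tidal-image work).
#' @param min_breath_s,min_prominence_frac breath-detector parameters, see
#'   [detect_breaths()].
#' @return A `trial_config` object.
#' @export
trial_config <- function(reference_peep_cmH2O = 6,
                         th = thresholds(),
                         n_breaths = 5,
                         rebase_mode = c("none", "trial", "step"),
                         min_breath_s = 1.0,
                         min_prominence_frac = 0.15) {
  rebase_mode <- match.arg(rebase_mode)
  stopifnot(inherits(th, "thresholds"), n_breaths >= 1)
  structure(list(reference_peep_cmH2O = reference_peep_cmH2O,
                 th = th, n_breaths = n_breaths, rebase_mode = rebase_mode,
                 min_breath_s = min_breath_s,
                 min_prominence_frac = min_prominence_frac),
            class = "trial_config")
}

analyze_one_step <- function(seq, config) {
  sig <- global_signal(seq)
  marks <- detect_breaths(sig, seq$sample_rate_hz,
                          min_breath_s = config$min_breath_s,
                          min_prominence_frac = config$min_prominence_frac)
  n_available <- length(marks$end_insp_idx)
  sel <- select_last_n(marks, config$n_breaths)
  status <- status_images(seq, sel)
  masks <- classify_step(status, config$th)
  list(masks = masks, status = status,
       qc = list(breaths_used = length(sel$end_insp_idx),
                 breaths_available = n_available,
                 shortfall = sel$shortfall,
                 n_negative_tidal = masks$n_negative_tidal))
}

#' Analyze a full incremental PEEP trial
#'
#' Runs the whole pipeline on an ordered set of per-PEEP-step frame
#' sequences: optional re-referencing, breath detection, selection of the
#' final breaths, status-image averaging and pixel classification. The
#' recruited category of every step is computed against the end-expiratory
#' lung region of the reference step, and all percentages share one
#' denominator: the size of the end-expiratory lung region at the highest
#' PEEP step ("total lung pixels"). Steps at or below the reference are
#' processed for QC but withheld from the primary table.
#'
#' @param sequences list of [frame_sequence()] objects, one per PEEP step
#'   (any order; they are sorted by PEEP). PEEP labels must be unique and
#'   one must equal the reference PEEP.
#' @param config a [trial_config()].
#' @return A `trial_result` with fields `subject_id`,
#'   `reference_peep_cmH2O`, `total_lung_pixels`, `reference_lung_ee`,
#'   `steps` (list of `step_result`s strictly above the reference, ascending
#'   PEEP), and `below_reference` (QC-only summaries of the lower steps).
#'   Each `step_result` carries `peep_cmH2O`, `masks`, `counts`,
#'   `percentages`, `qc` and a `failed` flag.
#' @export
analyze_trial <- function(sequences, config = trial_config()) {
  if (length(sequences) < 2L)
    stop("a trial needs at least two PEEP steps", call. = FALSE)
  for (s in sequences) stopifnot(inherits(s, "frame_sequence"))
  peeps <- vapply(sequences, function(s) s$peep_cmH2O, numeric(1))
  if (anyDuplicated(peeps))
    stop("PEEP labels must be unique across steps", call. = FALSE)
  ord <- order(peeps)
  sequences <- sequences[ord]; peeps <- peeps[ord]
  ref <- config$reference_peep_cmH2O
  ref_pos <- which(peeps == ref)
  if (length(ref_pos) != 1L)
    stop("no step with the reference PEEP (", ref, " cmH2O) is present",
         call. = FALSE)

  if (config$rebase_mode == "trial") {
    lowest <- sequences[[1]]
    base_idx <- which.min(global_signal(lowest))
    baseline <- lowest$frames[base_idx, , , drop = TRUE]
    dim(baseline) <- c(lowest$height, lowest$width)
    sequences <- lapply(sequences, rebase, baseline = baseline)
  } else if (config$rebase_mode == "step") {
    sequences <- lapply(sequences, rebase)
  }

  per_step <- lapply(sequences, function(s) {
    tryCatch(analyze_one_step(s, config),
             error = function(e) list(failed = conditionMessage(e)))
  })

  ref_step <- per_step[[ref_pos]]
  if (!is.null(ref_step$failed))
    stop("reference step failed to analyze: ", ref_step$failed, call. = FALSE)
  ref_lung_ee <- ref_step$masks$lung_ee

  # denominator: end-expiratory lung region at the highest (analyzable) step
  top <- length(per_step)
  while (top >= 1L && !is.null(per_step[[top]]$failed)) top <- top - 1L
  if (top < 1L) stop("no step could be analyzed", call. = FALSE)
  total_lung <- sum(per_step[[top]]$masks$lung_ee)
  if (total_lung == 0L)
    stop("end-expiratory lung region at the highest PEEP step is empty",
         call. = FALSE)

  make_step <- function(i) {
    st <- per_step[[i]]
    if (!is.null(st$failed)) {
      return(structure(list(peep_cmH2O = peeps[i], masks = NULL,
                            counts = NULL, percentages = NULL,
                            qc = list(error = st$failed), failed = TRUE),
                       class = "step_result"))
    }
    masks <- st$masks
    masks$recruited <- recruited_mask(masks$lung_ee, ref_lung_ee)
    counts <- c(lung_ee = sum(masks$lung_ee),
                lung_tidal = sum(masks$lung_tidal),
                overinflated = sum(masks$overinflated),
                cyclic = sum(masks$cyclic),
                recruited = sum(masks$recruited))
    pct <- 100 * counts[c("overinflated", "cyclic", "recruited")] / total_lung
    qc <- st$qc
    if (counts[["lung_ee"]] == 0L) qc$empty_lung_ee <- TRUE
    structure(list(peep_cmH2O = peeps[i], masks = masks, counts = counts,
                   percentages = pct, qc = qc,
                   failed = counts[["lung_ee"]] == 0L),
              class = "step_result")
  }

  all_steps <- lapply(seq_along(per_step), make_step)
  above <- peeps > ref
  structure(
    list(subject_id = sequences[[1]]$subject_id,
         reference_peep_cmH2O = ref,
         total_lung_pixels = total_lung,
         reference_lung_ee = ref_lung_ee,
         steps = all_steps[above],
         below_reference = lapply(all_steps[!above], function(s)
           list(peep_cmH2O = s$peep_cmH2O, qc = s$qc,
                counts = s$counts, failed = isTRUE(s$failed)))),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> subject %s: %d steps above reference PEEP %g cmH2O, %d total lung pixels\n",
              x$subject_id, length(x$steps), x$reference_peep_cmH2O,
              x$total_lung_pixels))
  print(percentages(x), row.names = FALSE)
  invisible(x)
}

#' Per-step category percentages of a trial
#'
#' Each category count is expressed as a percentage of the trial-wide
#' total lung pixels (the end-expiratory lung region at the highest PEEP),
#' which makes percentages comparable across steps and less dependent on
#' the lung-definition threshold.
#'
#' @param result a `trial_result` from [analyze_trial()].
#' @return data.frame with columns `peep_cmH2O`, `overinflated_pct`,
#'   `cyclic_pct`, `recruited_pct` (one row per analyzed step).
#' @export
percentages <- function(result) {
  stopifnot(inherits(result, "trial_result"))
  if (result$total_lung_pixels <= 0)
    stop("total lung pixels must be positive", call. = FALSE)
  ok <- !vapply(result$steps, function(s) isTRUE(s$failed), logical(1))
  steps <- result$steps[ok]
  data.frame(
    peep_cmH2O = vapply(steps, function(s) s$peep_cmH2O, numeric(1)),
    overinflated_pct = vapply(steps, function(s) s$percentages[["overinflated"]], numeric(1)),
    cyclic_pct = vapply(steps, function(s) s$percentages[["cyclic"]], numeric(1)),
    recruited_pct = vapply(steps, function(s) s$percentages[["recruited"]], numeric(1)))
}

# run-length encoding of a logical matrix for compact JSON masks
rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), values = as.logical(r$values), lengths = r$lengths)
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(list(values = as.logical(enc$values),
                        lengths = as.integer(enc$lengths)))
  matrix(v, nrow = enc$dim[1], ncol = enc$dim[2])
}

step_to_json <- function(s) {
  if (isTRUE(s$failed) && is.null(s$masks)) {
    return(list(peep_cmH2O = s$peep_cmH2O, failed = TRUE, qc = s$qc))
  }
  list(peep_cmH2O = s$peep_cmH2O,
       counts = as.list(s$counts),
       percentages = as.list(s$percentages),
       qc = s$qc,
       failed = isTRUE(s$failed),
       masks = lapply(s$masks[c("lung_ee", "lung_tidal", "overinflated",
                                "cyclic", "recruited")], rle_encode_mask),
       n_negative_tidal = s$masks$n_negative_tidal)
}

json_to_step <- function(j) {
  masks <- lapply(j$masks, rle_decode_mask)
  masks$n_negative_tidal <- j$n_negative_tidal
  class(masks) <- "zone_masks"
  structure(list(peep_cmH2O = j$peep_cmH2O,
                 masks = masks,
                 counts = unlist(j$counts),
                 percentages = unlist(j$percentages),
                 qc = j$qc,
                 failed = isTRUE(j$failed)),
            class = "step_result")
}

#' Export a trial result to CSV and JSON
#'
#' Writes `summary.csv` (one row per analyzed step: PEEP, counts,
#' percentages, QC) and `trial.json` (schema-versioned full result with
#' run-length-encoded boolean masks). [read_trial()] inverts the JSON
#' export.
#'
#' @param result a `trial_result`.
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
export_results <- function(result, out_dir) {
  stopifnot(inherits(result, "trial_result"))
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  ok <- !vapply(result$steps, function(s) isTRUE(s$failed) && is.null(s$counts),
                logical(1))
  rows <- lapply(result$steps[ok], function(s) {
    data.frame(peep_cmH2O = s$peep_cmH2O,
               overinflated = s$counts[["overinflated"]],
               cyclic = s$counts[["cyclic"]],
               recruited = s$counts[["recruited"]],
               lung_ee = s$counts[["lung_ee"]],
               lung_tidal = s$counts[["lung_tidal"]],
               overinflated_pct = s$percentages[["overinflated"]],
               cyclic_pct = s$percentages[["cyclic"]],
               recruited_pct = s$percentages[["recruited"]],
               breaths_used = s$qc$breaths_used,
               shortfall = s$qc$shortfall,
               n_negative_tidal = s$qc$n_negative_tidal,
               failed = isTRUE(s$failed))
  })
  summary_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peep_cmH2O = numeric(0), overinflated = integer(0),
               cyclic = integer(0), recruited = integer(0),
               lung_ee = integer(0), lung_tidal = integer(0),
               overinflated_pct = numeric(0), cyclic_pct = numeric(0),
               recruited_pct = numeric(0), breaths_used = integer(0),
               shortfall = logical(0), n_negative_tidal = integer(0),
               failed = logical(0))
  csv_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(summary_tab, csv_path, row.names = FALSE)

  doc <- list(schema = "eitzones-trial/1",
              subject_id = result$subject_id,
              reference_peep_cmH2O = result$reference_peep_cmH2O,
              total_lung_pixels = result$total_lung_pixels,
              reference_lung_ee = rle_encode_mask(result$reference_lung_ee),
              steps = lapply(result$steps, step_to_json),
              below_reference = result$below_reference)
  json_path <- file.path(out_dir, "trial.json")
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(summary = csv_path, trial = json_path))
}

#' Read a trial result back from its JSON export
#'
#' @param path path to a `trial.json` written by [export_results()].
#' @return A `trial_result`.
#' @export
read_trial <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(doc$schema) || !startsWith(doc$schema, "eitzones-trial/"))
    stop("not an eitzones trial document: ", path, call. = FALSE)
  structure(
    list(subject_id = doc$subject_id,
         reference_peep_cmH2O = doc$reference_peep_cmH2O,
         total_lung_pixels = doc$total_lung_pixels,
         reference_lung_ee = rle_decode_mask(
           lapply(doc$reference_lung_ee, unlist)),
         steps = lapply(doc$steps, function(j) {
           j$masks <- lapply(j$masks, function(m) lapply(m, unlist))
           json_to_step(j)
         }),
         below_reference = doc$below_reference),
    class = "trial_result")
}
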