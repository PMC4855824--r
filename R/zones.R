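#' Classification thresholds for lung-region delineation
#'
#' Both lung regions are delineated relative to the maximum of the image
#' being thresholded. The end-expiratory threshold is set 5 percentage
#' points above the tidal threshold by default because end-expiratory
#' images are dynamic and carry more noise than tidal (difference) images.
#'
#' @param ee_frac fraction of the end-expiratory image maximum (default 0.25).
#' @param tidal_frac fraction of the tidal image maximum (default 0.20).
#' @return A `thresholds` object.
#' @export
thresholds <- function(ee_frac = 0.25, tidal_frac = 0.20) {
  for (v in c(ee_frac, tidal_frac))
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop("threshold fractions must be single numbers in (0, 1)", call. = FALSE)
  structure(list(ee_frac = ee_frac, tidal_frac = tidal_frac),
            class = "thresholds")
}

#' Averaged status images of one PEEP step
#'
#' Averages the frames at the selected end-inspiratory and end-expiratory
#' marks (averaging suppresses uncorrelated noise) and forms the tidal
#' image as their pixel-wise difference. No thresholding is applied here.
#'
#' @param seq a [frame_sequence()].
#' @param marks a `breath_marks` object (typically after [select_last_n()]).
#' @return A `status_images` object with `H x W` matrices `end_insp`,
#'   `end_exp` and `tidal` satisfying `tidal + end_exp == end_insp`.
#' @export
status_images <- function(seq, marks) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(marks, "breath_marks"))
  tt <- dim(seq$frames)[1]
  idx <- c(marks$end_insp_idx, marks$end_exp_idx)
  if (length(marks$end_insp_idx) == 0L || length(marks$end_exp_idx) == 0L)
    stop("marks must contain at least one index of each kind", call. = FALSE)
  if (any(idx < 1L) || any(idx > tt))
    stop("breath mark index out of range for this sequence", call. = FALSE)
  avg <- function(ids) {
    m <- apply(seq$frames[ids, , , drop = FALSE], c(2, 3), mean)
    dim(m) <- c(seq$height, seq$width)
    m
  }
  ei <- avg(marks$end_insp_idx)
  ee <- avg(marks$end_exp_idx)
  structure(list(end_insp = ei, end_exp = ee, tidal = ei - ee),
            class = "status_images")
}

#' @export
print.status_images <- function(x, ...) {
  cat(sprintf("<status_images> %d x %d; tidal range [%.3g, %.3g]\n",
              nrow(x$tidal), ncol(x$tidal), min(x$tidal), max(x$tidal)))
  invisible(x)
}

#' Threshold an image relative to its own maximum
#'
#' A pixel belongs to the lung region when its value is strictly higher
#' than `frac` times the image maximum ("higher than" means strict
#' inequality, so a pixel exactly at the threshold is excluded). The
#' maximum is taken over the whole image unless `roi` restricts it.
#' Because the threshold is relative to the image's own maximum, the mask
#' is invariant under positive rescaling of the image.
#'
#' @param image numeric `H x W` matrix of finite values.
#' @param frac threshold fraction in (0, 1).
#' @param roi optional logical matrix restricting where the maximum is
#'   taken (off-lung artefact guard); default `NULL` uses the whole image.
#' @return Logical `H x W` mask.
#' @export
lung_mask <- function(image, frac, roi = NULL) {
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image)))
    stop("`image` must be a finite numeric matrix", call. = FALSE)
  if (frac <= 0 || frac >= 1)
    stop("`frac` must lie in (0, 1)", call. = FALSE)
  mx <- if (is.null(roi)) max(image) else {
    if (!identical(dim(roi), dim(image)))
      stop("`roi` shape does not match the image", call. = FALSE)
    if (!any(roi)) stop("`roi` selects no pixels", call. = FALSE)
    max(image[roi])
  }
  if (mx <= 0)
    stop("no positive signal in image; check baseline re-referencing",
         call. = FALSE)
  image > frac * mx
}

#' Classify one PEEP step into lung-region categories
#'
#' Applies the relative thresholds to the averaged end-expiratory and tidal
#' images and derives the two within-step pathological categories by set
#' difference:
#' * **overinflated** — aerated at end-expiration but not ventilated
#'   tidally (`lung_ee` minus `lung_tidal`): regions holding air that does
#'   not participate in the breath;
#' * **cyclic** (tidally recruited/derecruited) — ventilated during the
#'   breath but collapsed at end-expiration (`lung_tidal` minus `lung_ee`):
#'   alveoli that reopen and collapse each cycle.
#'
#' The recruited category needs a reference step; see [recruited_mask()].
#'
#' @param status a `status_images` object.
#' @param th a [thresholds()] object.
#' @param roi optional region-of-interest passed to [lung_mask()].
#' @return A `zone_masks` object with logical matrices `lung_ee`,
#'   `lung_tidal`, `overinflated`, `cyclic` (no `recruited` yet) plus
#'   `n_negative_tidal`, the count of paradoxical (negative) tidal pixels
#'   reported as a QC metric.
#' @export
classify_step <- function(status, th = thresholds(), roi = NULL) {
  stopifnot(inherits(status, "status_images"), inherits(th, "thresholds"))
  lung_ee <- lung_mask(status$end_exp, th$ee_frac, roi)
  lung_tidal <- lung_mask(status$tidal, th$tidal_frac, roi)
  structure(
    list(lung_ee = lung_ee,
         lung_tidal = lung_tidal,
         overinflated = lung_ee & !lung_tidal,
         cyclic = lung_tidal & !lung_ee,
         recruited = NULL,
         n_negative_tidal = sum(status$tidal < 0)),
    class = "zone_masks")
}

#' Pixels recruited relative to a reference PEEP step
#'
#' A pixel is recruited when it belongs to the end-expiratory lung region
#' at the current PEEP but not at the reference PEEP: aeration gained by
#' raising the pressure. Recruited pixels may overlap with overinflated
#' pixels; the definitions are independent and counts are reported per
#' category without de-duplication.
#'
#' @param current_lung_ee logical end-expiratory lung mask at the current step.
#' @param reference_lung_ee logical end-expiratory lung mask at the reference
#'   step (same shape).
#' @return Logical mask `current_lung_ee & !reference_lung_ee`.
#' @export
recruited_mask <- function(current_lung_ee, reference_lung_ee) {
  if (!identical(dim(current_lung_ee), dim(reference_lung_ee)))
    stop("current and reference masks must share one shape", call. = FALSE)
  current_lung_ee & !reference_lung_ee
}

#' @export
print.zone_masks <- function(x, ...) {
  cat(sprintf("<zone_masks> lung_ee %d | lung_tidal %d | overinflated %d | cyclic %d | recruited %s\n",
              sum(x$lung_ee), sum(x$lung_tidal), sum(x$overinflated),
              sum(x$cyclic),
              if (is.null(x$recruited)) "n/a" else sum(x$recruited)))
  invisible(x)
}
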