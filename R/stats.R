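#' Pearson product-moment correlation with exact t-based p-value
#'
#' Thin, validating wrapper around [stats::cor.test()]: the two-sided
#' p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param x,y numeric series of equal length `n >= 3`, each with nonzero
#'   variance.
#' @return List with elements `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L)
    stop("need at least 3 paired observations (n >= 3)", call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("series must not contain missing values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: a series has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlate region pixel counts with an ancillary physiology variable
#'
#' For each subject, the per-step pixel count of one region category is
#' correlated (Pearson) with a physiology column across that subject's
#' analyzed PEEP steps, matching on PEEP. Per-subject coefficients are
#' summarized as group mean and SD. Counts are the default unit; set
#' `use_percentages = TRUE` to correlate the percentage of total lung
#' pixels instead.
#'
#' The optional `group_test` performs a one-sample t-test on Fisher
#' z-transformed per-subject coefficients against zero correlation. It is
#' offered as one plausible group-level summary test, not a canonical one,
#' since the per-subject r values are not independent draws from a simple
#' model of the trial.
#'
#' @param trials list of `trial_result`s (one per subject).
#' @param ancillary list of ancillary data.frames (see [read_ancillary()]),
#'   matched to `trials` by position.
#' @param category one of `"overinflated"`, `"cyclic"`, `"recruited"`.
#' @param variable name of the ancillary column, e.g. `"pao2_fio2"`.
#' @param use_percentages correlate percentages instead of raw counts.
#' @param group_test also report the Fisher-z one-sample t-test.
#' @return A `correlation_result` with `per_subject_r`, `per_subject_p`,
#'   `per_subject_n`, `group_mean_r`, `group_sd_r` (NA with a single
#'   subject) and optionally `group_test`.
#' @export
correlate_trials <- function(trials, ancillary,
                             category = c("recruited", "overinflated", "cyclic"),
                             variable = "pao2_fio2",
                             use_percentages = FALSE,
                             group_test = FALSE) {
  category <- match.arg(category)
  if (length(trials) != length(ancillary))
    stop("`trials` and `ancillary` must have equal length", call. = FALSE)
  rs <- ps <- ns <- numeric(0)
  subjects <- character(0)
  skipped <- character(0)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]; anc <- ancillary[[i]]
    stopifnot(inherits(tr, "trial_result"), is.data.frame(anc))
    if (!variable %in% names(anc))
      stop("ancillary table for subject '", tr$subject_id,
           "' lacks column '", variable, "'", call. = FALSE)
    ok <- !vapply(tr$steps, function(s) isTRUE(s$failed) && is.null(s$counts),
                  logical(1))
    steps <- tr$steps[ok]
    peep <- vapply(steps, function(s) s$peep_cmH2O, numeric(1))
    val <- if (use_percentages)
      vapply(steps, function(s) s$percentages[[category]], numeric(1))
    else
      vapply(steps, function(s) s$counts[[category]], numeric(1))
    m <- match(peep, anc$peep_cmH2O)
    keep <- !is.na(m) & !is.na(anc[[variable]][m])
    if (sum(keep) < 3L) {
      warning("subject '", tr$subject_id,
              "' skipped: fewer than 3 matched PEEP steps", call. = FALSE)
      skipped <- c(skipped, tr$subject_id)
      next
    }
    pc <- pearson_cor(val[keep], anc[[variable]][m][keep])
    rs <- c(rs, pc$r); ps <- c(ps, pc$p); ns <- c(ns, pc$n)
    subjects <- c(subjects, tr$subject_id)
  }
  if (length(rs) == 0L)
    stop("no subject had enough matched steps to correlate", call. = FALSE)
  out <- list(category = category, variable = variable,
              subjects = subjects, skipped = skipped,
              per_subject_r = rs, per_subject_p = ps, per_subject_n = ns,
              group_mean_r = mean(rs),
              group_sd_r = if (length(rs) >= 2L) stats::sd(rs) else NA_real_)
  if (group_test && length(rs) >= 2L) {
    z <- atanh(pmin(pmax(rs, -1 + 1e-12), 1 - 1e-12))
    tt <- stats::t.test(z, mu = 0)
    out$group_test <- list(method = "one-sample t on Fisher-z(r)",
                           t = unname(tt$statistic), df = unname(tt$parameter),
                           p = tt$p.value)
  }
  structure(out, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s pixels vs %s: r = %.3f %s (n = %d subjects)\n",
              x$category, x$variable, x$group_mean_r,
              if (is.na(x$group_sd_r)) "(single subject)"
              else sprintf("± %.3f", x$group_sd_r),
              length(x$per_subject_r)))
  invisible(x)
}

#' Quasi-static respiratory system compliance
#'
#' Standard bedside definition: tidal volume over the driving pressure,
#' `Crs = VT / (Pplat - PEEP)`, in ml/cmH2O.
#'
#' @param vt_ml tidal volume in ml (> 0).
#' @param pplat_cmH2O plateau pressure in cmH2O.
#' @param peep_cmH2O PEEP in cmH2O; must be below `pplat_cmH2O`.
#' @return Compliance in ml/cmH2O (vectorized).
#' @export
crs <- function(vt_ml, pplat_cmH2O, peep_cmH2O) {
  if (any(vt_ml <= 0))
    stop("tidal volume must be positive", call. = FALSE)
  if (any(pplat_cmH2O <= peep_cmH2O))
    stop("plateau pressure must exceed PEEP", call. = FALSE)
  vt_ml / (pplat_cmH2O - peep_cmH2O)
}
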