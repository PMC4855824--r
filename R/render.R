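#' Color palette for classified-region maps
#'
#' Display convention: overinflated regions white, recruited blue, tidally
#' recruited/derecruited (cyclic) red, lung outline yellow, background
#' black. Unclassified lung interior is drawn dark gray so the outline
#' reads against it.
#'
#' @param overinflated,recruited,cyclic,outline,background,lung hex color
#'   strings; all category colors must be distinct.
#' @return A `palette` object.
#' @export
zone_palette <- function(overinflated = "#FFFFFF", recruited = "#2060FF",
                         cyclic = "#FF2020", outline = "#FFFF00",
                         background = "#000000", lung = "#404040") {
  cols <- c(overinflated = overinflated, recruited = recruited,
            cyclic = cyclic, outline = outline, background = background,
            lung = lung)
  if (anyDuplicated(cols[c("overinflated", "recruited", "cyclic",
                           "background")]))
    stop("category colors must be distinct", call. = FALSE)
  structure(as.list(cols), class = "palette")
}

# 3 x 5 bitmap glyphs (rows of 3 bits, top to bottom) for annotations;
# drawn directly into the raster so output stays byte-deterministic
glyphs3x5 <- list(
  "0" = c("111","101","101","101","111"),
  "1" = c("010","110","010","010","111"),
  "2" = c("111","001","111","100","111"),
  "3" = c("111","001","111","001","111"),
  "4" = c("101","101","111","001","001"),
  "5" = c("111","100","111","001","111"),
  "6" = c("111","100","111","101","111"),
  "7" = c("111","001","010","010","010"),
  "8" = c("111","101","111","101","111"),
  "9" = c("111","101","111","001","111"),
  "." = c("000","000","000","000","010"),
  "%" = c("101","001","010","100","101"),
  " " = c("000","000","000","000","000"),
  "O" = c("111","101","101","101","111"),
  "V" = c("101","101","101","101","010"),
  "R" = c("110","101","110","101","101"),
  "C" = c("111","100","100","100","111"),
  "Y" = c("101","101","010","010","010"),
  "E" = c("111","100","110","100","111"))

draw_text <- function(img, text, row0, col0, ts, rgb_col) {
  chars <- strsplit(text, "")[[1]]
  h <- dim(img)[1]; w <- dim(img)[2]
  for (k in seq_along(chars)) {
    g <- glyphs3x5[[chars[k]]]
    if (is.null(g)) g <- glyphs3x5[[" "]]
    for (gr in 1:5) {
      bits <- strsplit(g[gr], "")[[1]] == "1"
      for (gc in 1:3) {
        if (!bits[gc]) next
        rr <- row0 + (gr - 1L) * ts + seq_len(ts) - 1L
        cc <- col0 + ((k - 1L) * 4L + gc - 1L) * ts + seq_len(ts) - 1L
        rr <- rr[rr >= 1 & rr <= h]; cc <- cc[cc >= 1 & cc <= w]
        if (length(rr) && length(cc))
          for (ch in 1:3) img[rr, cc, ch] <- rgb_col[ch]
      }
    }
  }
  img
}

outline_of <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  inner <- pad[2:(h + 1), 2:(w + 1)]
  nb <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
        pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  inner & !nb  # region pixels with at least one 4-neighbour outside
}

upscale <- function(m, scale) m[rep(seq_len(nrow(m)), each = scale),
                                rep(seq_len(ncol(m)), each = scale)]

#' Render a classified-region map
#'
#' Paints each pixel by category with precedence
#' overinflated > cyclic > recruited > lung background (the precedence is
#' purely a display choice for the rare overlapping pixels — counts are
#' unaffected; overinflation wins because it is the safety-critical
#' finding). The union of the end-expiratory and tidal lung regions is
#' outlined, and per-category percentages are printed beneath the map.
#' Upscaling is nearest-neighbour so every display pixel is attributable
#' to one image pixel; output is byte-deterministic.
#'
#' @param step a `step_result` from [analyze_trial()].
#' @param palette a [zone_palette()].
#' @param scale integer upscaling factor (>= 1, default 8).
#' @param path optional output PNG path; when `NULL` nothing is written.
#' @return Invisibly, the rendered RGB array (`H' x W' x 3` in `[0, 1]`).
#' @export
render_map <- function(step, palette = zone_palette(), scale = 8, path = NULL) {
  stopifnot(inherits(step, "step_result"), inherits(palette, "palette"))
  if (scale < 1 || scale != round(scale))
    stop("`scale` must be a positive integer", call. = FALSE)
  m <- step$masks
  if (is.null(m)) stop("step has no masks (failed step)", call. = FALSE)
  h <- nrow(m$lung_ee); w <- ncol(m$lung_ee)
  empty <- matrix(FALSE, h, w)
  ovr <- if (is.null(m$overinflated)) empty else m$overinflated
  cyc <- if (is.null(m$cyclic)) empty else m$cyclic
  rec <- if (is.null(m$recruited)) empty else m$recruited
  lung_union <- m$lung_ee | m$lung_tidal
  edge <- outline_of(lung_union)

  col2rgb01 <- function(hex) as.vector(grDevices::col2rgb(hex)) / 255
  pal <- lapply(palette, col2rgb01)

  # category index map, low to high precedence
  cat_idx <- matrix(1L, h, w)                 # background
  cat_idx[lung_union] <- 2L                   # lung interior
  cat_idx[edge] <- 3L                         # outline
  cat_idx[rec] <- 4L
  cat_idx[cyc] <- 5L
  cat_idx[ovr] <- 6L
  colors <- rbind(pal$background, pal$lung, pal$outline, pal$recruited,
                  pal$cyclic, pal$overinflated)

  big <- upscale(cat_idx, scale)
  strip_ts <- max(1L, floor(w * scale / (4L * 10L)))
  strip_h <- 3L * (6L * strip_ts) + 2L * strip_ts
  img <- array(0, c(nrow(big) + strip_h, ncol(big), 3))
  for (ch in 1:3) {
    plane <- matrix(pal$background[ch], dim(img)[1], dim(img)[2])
    plane[seq_len(nrow(big)), ] <- matrix(colors[big, ch], nrow(big), ncol(big))
    img[, , ch] <- plane
  }

  pct <- function(x) if (is.null(step$percentages)) 0 else x
  fmt <- function(v) sprintf("%.1f%%", v)
  labels <- c(paste("OVR", fmt(pct(step$percentages[["overinflated"]]))),
              paste("CYC", fmt(pct(step$percentages[["cyclic"]]))),
              paste("REC", fmt(if (is.null(step$masks$recruited)) 0
                               else pct(step$percentages[["recruited"]]))))
  label_cols <- list(pal$overinflated, pal$cyclic, pal$recruited)
  for (i in 1:3) {
    img <- draw_text(img, labels[i],
                     row0 = nrow(big) + strip_ts + (i - 1L) * 6L * strip_ts + 1L,
                     col0 = strip_ts + 1L, ts = strip_ts,
                     rgb_col = label_cols[[i]])
  }
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
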