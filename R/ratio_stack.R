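#' Build a 340:380 ratio stack from the two excitation channels
#'
#' Divides the 340 nm channel by the 380 nm channel pixel-wise, masking
#' pixels whose 380 nm intensity does not exceed `bg_threshold` (default 0,
#' i.e. only zero-denominator pixels are masked; background masking is
#' opt-in). The raw ratio is kept unclipped for measurement; the `clip_lo` /
#' `clip_hi` limits are applied only when rendering a display stack with
#' [render_display()].
#'
#' @param ch340,ch380 matrices (single frame) or h x w x n arrays with
#'   identical dimensions; non-negative intensities.
#' @param clip_lo,clip_hi display clipping limits (ratio units); defaults
#'   0.5 / 2.0.
#' @param bg_threshold pixels with `ch380 <= bg_threshold` are masked.
#' @param pixel_size_um,frame_interval_s optional calibration carried along
#'   for trace extraction.
#' @return a `ratio_stack` object: list with `ratio` (h x w x n, `NA` at
#'   masked pixels), `mask` (logical, `TRUE` where valid), clip limits and
#'   calibration.
#' @export
compute_ratio_stack <- function(ch340, ch380, clip_lo = 0.5, clip_hi = 2.0,
                                bg_threshold = 0,
                                pixel_size_um = NULL, frame_interval_s = NULL) {
  ch340 <- as_stack_array(ch340)
  ch380 <- as_stack_array(ch380)
  if (!identical(dim(ch340), dim(ch380))) {
    stop("channel dimensions differ: 340 is ", paste(dim(ch340), collapse = "x"),
         ", 380 is ", paste(dim(ch380), collapse = "x"))
  }
  if (any(ch340 < 0) || any(ch380 < 0)) stop("negative intensities")
  if (clip_lo >= clip_hi) stop("clip_lo must be < clip_hi")
  mask <- ch380 > bg_threshold
  ratio <- array(NA_real_, dim = dim(ch340))
  ratio[mask] <- ch340[mask] / ch380[mask]
  structure(
    list(ratio = ratio, mask = mask, clip_lo = clip_lo, clip_hi = clip_hi,
         bg_threshold = bg_threshold,
         pixel_size_um = pixel_size_um, frame_interval_s = frame_interval_s),
    class = "ratio_stack"
  )
}

#' @export
print.ratio_stack <- function(x, ...) {
  d <- dim(x$ratio)
  cat(sprintf("<ratio_stack> %d x %d px, %d frame(s); clip [%g, %g]; %.1f%% masked\n",
              d[1], d[2], d[3], x$clip_lo, x$clip_hi, 100 * mean(!x$mask)))
  invisible(x)
}

as_stack_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("expected a matrix or an h x w x n array")
  }
  storage.mode(x) <- "double"
  x
}

#' Render a ratio stack for display
#'
#' Maps the ratio linearly to the 16-bit range — `clip_lo` to 0, `clip_hi`
#' to 65535 — clamping values outside the limits, then applies a 16-entry
#' false-color look-up table for the RGB preview. Masked pixels render as 0
#' (black).
#'
#' @param stack a `ratio_stack`.
#' @param lut_name look-up table for the RGB preview; `"16colors"` (a 16-step
#'   blue-to-red-to-white scale) or `"gray"`.
#' @param overlay optional matrix/array (same spatial size) of logical or
#'   0/1 values painted white over the RGB preview, used to show the
#'   counterstained macrophages.
#' @return list with `display` (h x w x n, integer 0..65535) and `rgb`
#'   (h x w x 3 x n, integer 0..255).
#' @export
render_display <- function(stack, lut_name = "16colors", overlay = NULL) {
  stopifnot(inherits(stack, "ratio_stack"))
  lo <- stack$clip_lo; hi <- stack$clip_hi
  r <- stack$ratio
  r[!stack$mask] <- lo
  r <- pmin(pmax(r, lo), hi)
  disp <- round((r - lo) / (hi - lo) * 65535)
  disp <- array(as.integer(disp), dim = dim(r))
  lut <- display_lut(lut_name)
  bin <- pmin(disp %/% 4096L + 1L, 16L)  # 65536 / 16 = 4096 per bin
  d <- dim(disp)
  rgb <- array(0L, dim = c(d[1], d[2], 3L, d[3]))
  for (ch in 1:3) rgb[, , ch, ] <- array(lut[bin, ch], dim = d)
  if (!is.null(overlay)) {
    ov <- as_stack_array(overlay) > 0
    if (!identical(dim(ov)[1:2], d[1:2])) stop("overlay dimensions differ")
    if (dim(ov)[3] == 1L && d[3] > 1L) ov <- array(ov, dim = c(d[1:2], d[3]))
    for (ch in 1:3) {
      x <- rgb[, , ch, ]
      x[ov] <- 255L
      rgb[, , ch, ] <- x
    }
  }
  list(display = disp, rgb = rgb)
}

display_lut <- function(lut_name) {
  switch(lut_name,
    "16colors" = matrix(as.integer(c(
        1,   1, 171,    1,   1, 224,    0, 110, 255,    1, 171, 254,
        1, 224, 254,    1, 254, 212,    1, 254, 160,    1, 254,  60,
       95, 254,   1,  146, 254,   1,  194, 254,   1,  254, 254,   1,
      254, 224,   3,  254, 141,   1,  250,  94,   1,  245,  21,   1
    )), ncol = 3, byrow = TRUE),
    "gray" = matrix(as.integer(round(seq(0, 255, length.out = 16))),
                    ncol = 3, nrow = 16)[, c(1, 1, 1)],
    stop("unknown LUT: ", lut_name)
  )
}

#' Extract a per-track calcium trace from a ratio stack
#'
#' For every track sample, averages the unclipped ratio over the circular
#' region of interest (default 20 px diameter, matching a manual tracking
#' point) centred on the nearest pixel to the track position. A pixel
#' belongs to the ROI iff its centre lies within `roi_diameter_px / 2` of
#' the ROI centre (no area weighting). Samples whose ROI falls entirely on
#' masked pixels or outside the image are flagged `dropped` with `NA` ratio,
#' not treated as errors.
#'
#' @param stack a `ratio_stack` with `pixel_size_um` set (or positions
#'   already in pixels via `positions_in_px = TRUE`).
#' @param track data frame with columns `track_id`, `frame` (0-based),
#'   `t_s`, `x_um`, `y_um`.
#' @param roi_diameter_px circular ROI diameter in pixels.
#' @param positions_in_px treat `x_um`/`y_um` as pixel coordinates.
#' @return the track data frame with columns `ratio` and `dropped` added.
#' @export
extract_trace <- function(stack, track, roi_diameter_px = 20,
                          positions_in_px = FALSE) {
  stopifnot(inherits(stack, "ratio_stack"))
  req <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(req, names(track))
  if (length(miss)) stop("track table missing column(s): ",
                         paste(miss, collapse = ", "))
  px <- if (positions_in_px) 1 else stack$pixel_size_um
  if (is.null(px)) stop("stack has no pixel_size_um; pass positions_in_px = TRUE")
  d <- dim(stack$ratio)
  rad <- roi_diameter_px / 2
  irad <- ceiling(rad)
  off <- expand.grid(dx = -irad:irad, dy = -irad:irad)
  off <- off[off$dx^2 + off$dy^2 <= rad^2, ]
  cx <- as.integer(round(track$x_um / px))  # 0-based pixel centres
  cy <- as.integer(round(track$y_um / px))
  n <- nrow(track)
  ratio <- rep(NA_real_, n)
  dropped <- rep(TRUE, n)
  for (i in seq_len(n)) {
    f <- track$frame[i] + 1L
    if (f < 1L || f > d[3]) next
    xs <- cx[i] + off$dx; ys <- cy[i] + off$dy
    ok <- xs >= 0L & xs < d[2] & ys >= 0L & ys < d[1]
    if (!any(ok)) next
    vals <- stack$ratio[cbind(ys[ok] + 1L, xs[ok] + 1L, f)]
    vals <- vals[!is.na(vals)]
    if (length(vals)) {
      ratio[i] <- mean(vals)
      dropped[i] <- FALSE
    }
  }
  track$ratio <- ratio
  track$dropped <- dropped
  track
}
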