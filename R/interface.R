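#' Conjugate annotation
#'
#' Manual annotations replacing on-screen tracing of a conjugate image:
#' membrane polylines for interface and remaining surface (intact staining),
#' and a T-cell centre plus interface direction for the four-ROI
#' polarization analysis (permeabilized staining). All coordinates are
#' pixels, 0-based, x right / y down, pixel centres at integer coordinates.
#'
#' @param interface,rest polylines (n x 2 matrices of x, y) tracing the
#'   membrane at the cell-cell interface and over the remaining T cell
#'   surface; each needs at least 2 vertices.
#' @param width_px membrane trace width (default 10 px).
#' @param center T-cell centre (length-2, px) for polarization.
#' @param direction unit vector (length-2) pointing from the T-cell centre
#'   towards the interface.
#' @param roi_size_px side of the four square ROIs (default 50 px, i.e.
#'   3.37 um at the default pixel size).
#' @param roi_offset_px centre-to-ROI-centre distance (default one ROI size).
#' @param pixel_size_um pixel calibration (default 3.37/50 um).
#' @return a `conjugate_annotation` object.
#' @export
conjugate_annotation <- function(interface = NULL, rest = NULL, width_px = 10,
                                 center = NULL, direction = NULL,
                                 roi_size_px = 50, roi_offset_px = roi_size_px,
                                 pixel_size_um = 3.37 / 50) {
  chk_poly <- function(p, what) {
    if (is.null(p)) return(NULL)
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 2) stop(what, " polyline needs >= 2 x,y vertices")
    storage.mode(p) <- "double"
    unname(p)
  }
  if (width_px < 1) stop("width_px must be >= 1")
  if (!is.null(direction)) {
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("direction must be a non-zero vector")
    direction <- direction / nrm
  }
  structure(list(interface = chk_poly(interface, "interface"),
                 rest = chk_poly(rest, "rest"),
                 width_px = width_px, center = center, direction = direction,
                 roi_size_px = roi_size_px, roi_offset_px = roi_offset_px,
                 pixel_size_um = pixel_size_um),
            class = "conjugate_annotation")
}

# Logical h x w matrix: pixel centres within width/2 (perpendicular
# distance) of the polyline. Each pixel counted once however many segments
# cover it.
polyline_band_pixels <- function(dim_hw, polyline, width_px) {
  h <- dim_hw[1]; w <- dim_hw[2]
  band <- matrix(FALSE, h, w)
  half <- width_px / 2
  for (s in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[s, ]; b <- polyline[s + 1L, ]
    x0 <- max(0L, floor(min(a[1], b[1]) - half))
    x1 <- min(w - 1L, ceiling(max(a[1], b[1]) + half))
    y0 <- max(0L, floor(min(a[2], b[2]) - half))
    y1 <- min(h - 1L, ceiling(max(a[2], b[2]) + half))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) 0 else
      pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1)
    d2 <- (px - (a[1] + tt * ab[1]))^2 + (py - (a[2] + tt * ab[2]))^2
    hit <- d2 <= half^2
    band[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <-
      band[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] | hit
  }
  band
}

#' Mean intensity along a membrane trace
#'
#' Mean of the pixels whose centres lie within `width_px / 2` perpendicular
#' distance of the polyline, each pixel counted once — a deterministic
#' analogue of a 10-pixel-wide manual membrane trace.
#'
#' @param image intensity matrix.
#' @param polyline n x 2 matrix of x, y pixel coordinates (0-based).
#' @param width_px trace width.
#' @return mean intensity (MFI) over the band.
#' @export
membrane_profile_mfi <- function(image, polyline, width_px = 10) {
  band <- polyline_band_pixels(dim(image), as.matrix(polyline), width_px)
  if (!any(band)) stop("membrane trace covers no pixels inside the image")
  mean(image[band])
}

#' Marker accumulation ratio at the cell-cell interface
#'
#' Interface-band MFI divided by the MFI over the remaining T-cell surface
#' band. Pixels covered by both bands are assigned to the interface and
#' excluded from the rest band. A ratio above 1 indicates capping of the
#' marker at the conjugate junction.
#'
#' @param image intensity matrix (single confocal section).
#' @param annotation a [conjugate_annotation()] with both polylines.
#' @return the accumulation ratio (scalar).
#' @export
accumulation_ratio <- function(image, annotation) {
  stopifnot(inherits(annotation, "conjugate_annotation"))
  if (is.null(annotation$interface) || is.null(annotation$rest)) {
    stop("annotation needs both interface and rest polylines")
  }
  bi <- polyline_band_pixels(dim(image), annotation$interface, annotation$width_px)
  br <- polyline_band_pixels(dim(image), annotation$rest, annotation$width_px)
  br <- br & !bi
  if (!any(bi)) stop("interface band covers no pixels")
  if (!any(br)) stop("rest band covers no pixels")
  mfi_rest <- mean(image[br])
  if (mfi_rest <= 0) {
    stop("rest-surface MFI is <= 0; accumulation ratio undefined ",
         "(check background handling)")
  }
  mean(image[bi]) / mfi_rest
}

#' Four-ROI polarization of total staining
#'
#' Places four square ROIs around the T-cell centre — at the interface,
#' opposite it (away), and either side — and expresses each ROI's MFI as a
#' percentage of the four-ROI sum. `front_back` is %interface - %away and
#' `side_side` is %side1 - %side2 (signed; side1 is +90 degrees from the
#' interface direction). ROI membership is tested in the rotated frame so
#' the squares stay aligned with the interface axis.
#'
#' @param image intensity matrix.
#' @param annotation a [conjugate_annotation()] with `center` and
#'   `direction` set.
#' @return list with `percent` (named length-4, sums to 100), `front_back`,
#'   `side_side`, and `mfi` (raw ROI means).
#' @export
polarization_rois <- function(image, annotation) {
  stopifnot(inherits(annotation, "conjugate_annotation"))
  if (is.null(annotation$center) || is.null(annotation$direction)) {
    stop("annotation needs center and direction for polarization ROIs")
  }
  u <- annotation$direction
  perp <- c(-u[2], u[1])  # +90 degrees
  s <- annotation$roi_size_px
  off <- annotation$roi_offset_px
  ctr <- annotation$center
  centers <- list(interface = ctr + off * u, away = ctr - off * u,
                  side1 = ctr + off * perp, side2 = ctr - off * perp)
  h <- nrow(image); w <- ncol(image)
  mfi <- vapply(centers, function(rc) {
    x0 <- max(0L, floor(rc[1] - s)); x1 <- min(w - 1L, ceiling(rc[1] + s))
    y0 <- max(0L, floor(rc[2] - s)); y1 <- min(h - 1L, ceiling(rc[2] + s))
    if (x0 > x1 || y0 > y1) stop("an ROI lies fully outside the image")
    xs <- x0:x1; ys <- y0:y1
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE) - rc[1]
    py <- matrix(ys, length(ys), length(xs)) - rc[2]
    q1 <- px * u[1] + py * u[2]
    q2 <- px * perp[1] + py * perp[2]
    inside <- abs(q1) <= s / 2 & abs(q2) <= s / 2
    if (!any(inside)) stop("an ROI lies fully outside the image")
    n_expect <- (floor(s / 2) * 2 + 1)^2
    if (sum(inside) < n_expect * 0.99) warning("ROI clipped at image border")
    mean(image[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)][inside])
  }, 1.0)
  pct <- 100 * mfi / sum(mfi)
  list(percent = pct,
       front_back = unname(pct["interface"] - pct["away"]),
       side_side = unname(pct["side1"] - pct["side2"]),
       mfi = mfi)
}
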