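#' Simulate an annotated conjugate image with known interface enrichment
#'
#' Draws a circular T-cell membrane whose interface arc (facing the
#' macrophage) carries `enrichment_k` times the staining intensity of the
#' remaining membrane, together with the ground-truth annotation. With no
#' noise, the accumulation ratio of the generated image is exactly
#' `enrichment_k`.
#'
#' @param enrichment_k true interface/rest intensity ratio (> 0).
#' @param image_size height/width in px.
#' @param center T-cell centre (x, y px); default image centre.
#' @param radius_px membrane circle radius.
#' @param interface_halfangle half-opening of the interface arc (rad).
#' @param direction_angle angle (rad) from the centre towards the interface
#'   (0 = +x).
#' @param width_px membrane band width.
#' @param base_intensity staining intensity on the non-interface membrane
#'   (counts; also the Poisson rate there, so 400 gives SNR ~ 20).
#' @param noise `"none"` or `"poisson"`.
#' @return list with `image` (matrix) and `annotation`
#'   (a [conjugate_annotation()] carrying polylines, centre and direction).
#' @export
simulate_conjugate <- function(enrichment_k, image_size = c(220, 220),
                               center = NULL, radius_px = 60,
                               interface_halfangle = pi / 4,
                               direction_angle = 0, width_px = 10,
                               base_intensity = 400,
                               noise = c("none", "poisson")) {
  if (enrichment_k <= 0) stop("enrichment_k must be > 0")
  noise <- match.arg(noise)
  if (is.null(center)) center <- (rev(image_size) - 1) / 2
  arc <- function(a0, a1, step = pi / 180) {
    ang <- seq(a0, a1, length.out = max(2L, ceiling((a1 - a0) / step) + 1L))
    cbind(center[1] + radius_px * cos(ang), center[2] + radius_px * sin(ang))
  }
  iface <- arc(direction_angle - interface_halfangle,
               direction_angle + interface_halfangle)
  rest <- arc(direction_angle + interface_halfangle,
              direction_angle + 2 * pi - interface_halfangle)
  ann <- conjugate_annotation(
    interface = iface, rest = rest, width_px = width_px,
    center = center,
    direction = c(cos(direction_angle), sin(direction_angle))
  )
  # paint by the same band-membership rule used for measurement, with
  # overlap pixels assigned to the interface, so the noiseless ratio is
  # exactly enrichment_k
  bi <- polyline_band_pixels(image_size, iface, width_px)
  br <- polyline_band_pixels(image_size, rest, width_px) & !bi
  img <- matrix(0, image_size[1], image_size[2])
  img[br] <- base_intensity
  img[bi] <- enrichment_k * base_intensity
  if (noise == "poisson") img[] <- stats::rpois(length(img), img)
  list(image = img, annotation = ann)
}
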