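test_that("membrane MFI over a band equals brute-force pixel enumeration", {
  u <- matrix(100, 30, 30)
  horiz <- cbind(c(5, 24), c(14, 14))
  expect_equal(membrane_profile_mfi(u, horiz, 10), 100)

  # vertical step image: left half 10, right half 250
  step <- cbind(matrix(10, 26, 13), matrix(250, 26, 13))
  poly <- cbind(c(6, 20), c(12, 12))
  expect_equal(membrane_profile_mfi(step, poly, 7),
               oracle_band_mean(step, poly, 7), tolerance = 1e-12)

  # width-1 trace over a 1-px bright line
  line <- matrix(0, 20, 20); line[11, ] <- 500
  lp <- cbind(c(0, 19), c(10, 10))
  expect_equal(membrane_profile_mfi(line, lp, 1), 500)

  expect_error(membrane_profile_mfi(u, cbind(c(500, 600), c(500, 500)), 4),
               "no pixels")
})

test_that("band pixels match the oracle on bent polylines", {
  set.seed(60)
  img <- matrix(runif(35 * 35, 0, 100), 35, 35)
  bent <- cbind(c(4, 15, 28, 30), c(5, 20, 18, 4))
  for (w in c(3, 10)) {
    expect_equal(membrane_profile_mfi(img, bent, w),
                 oracle_band_mean(img, bent, w), tolerance = 1e-12)
  }
})

test_that("accumulation ratio: uniform, enriched, and degenerate cases", {
  u <- matrix(42, 40, 40)
  ann <- conjugate_annotation(interface = cbind(c(10, 30), c(10, 10)),
                              rest = cbind(c(10, 30), c(30, 30)))
  expect_equal(accumulation_ratio(u, ann), 1.0)

  sc <- simulate_conjugate(3)
  expect_equal(accumulation_ratio(sc$image, sc$annotation), 3, tolerance = 1e-6)

  z <- u; z[25:40, ] <- 0  # rest band all zero
  expect_error(accumulation_ratio(z, ann), "undefined")
  expect_error(accumulation_ratio(u, conjugate_annotation(
    interface = cbind(c(1, 2), c(1, 1)))), "both")
})

test_that("accumulation ratio is scale invariant and offset moves it to 1", {
  sc <- simulate_conjugate(3)
  r0 <- accumulation_ratio(sc$image, sc$annotation)
  expect_equal(accumulation_ratio(sc$image * 11.7, sc$annotation), r0,
               tolerance = 1e-9)
  r_off <- accumulation_ratio(sc$image + 200, sc$annotation)
  expect_lt(r_off, r0)
  expect_gt(r_off, 1)
  sc_lo <- simulate_conjugate(0.5)
  r_lo <- accumulation_ratio(sc_lo$image, sc_lo$annotation)
  expect_gt(accumulation_ratio(sc_lo$image + 200, sc_lo$annotation), r_lo)
})

test_that("polarization ROIs: uniform image gives 25/25/25/25 and zero polarity", {
  u <- matrix(9, 200, 200)
  ann <- conjugate_annotation(center = c(100, 100), direction = c(1, 0),
                              roi_size_px = 20)
  p <- polarization_rois(u, ann)
  expect_equal(unname(p$percent), rep(25, 4), tolerance = 1e-9)
  expect_equal(p$front_back, 0, tolerance = 1e-9)
  expect_equal(p$side_side, 0, tolerance = 1e-9)
  expect_equal(sum(p$percent), 100, tolerance = 1e-9)
})

test_that("all intensity in the interface ROI gives 100% front polarity", {
  img <- matrix(0, 200, 200)
  # interior of the interface ROI (centre +20 on x); adjacent ROIs share an
  # inclusive boundary row/column, so stay one pixel clear of the edges
  img[92:110, 112:130] <- 50
  ann <- conjugate_annotation(center = c(100, 100), direction = c(1, 0),
                              roi_size_px = 20)
  p <- polarization_rois(img, ann)
  expect_equal(unname(p$percent["interface"]), 100)
  expect_equal(p$front_back, 100)
  expect_error(polarization_rois(img, conjugate_annotation(
    center = c(-500, -500), direction = c(1, 0), roi_size_px = 20)),
    "outside")
})

test_that("gradient percentages equal brute-force ROI sums; rotation invariant", {
  img <- matrix(rep(seq(0, 100, length.out = 240), each = 240), 240, 240,
                byrow = FALSE)  # gradient along x
  ann <- conjugate_annotation(center = c(120, 120), direction = c(1, 0),
                              roi_size_px = 20)
  p <- polarization_rois(img, ann)
  roi_mean <- function(cx, cy, s) {
    xs <- (cx - s / 2):(cx + s / 2); ys <- (cy - s / 2):(cy + s / 2)
    mean(img[ys + 1, xs + 1])
  }
  hand <- c(roi_mean(140, 120, 20), roi_mean(100, 120, 20),
            roi_mean(120, 140, 20), roi_mean(120, 100, 20))
  expect_equal(unname(p$percent), 100 * hand / sum(hand), tolerance = 1e-9)
  expect_gt(p$front_back, 0)
  expect_equal(p$side_side, 0, tolerance = 1e-9)

  # rotate image and annotation together by 90 degrees: outputs unchanged
  img90 <- t(img)[240:1, ]                       # counter-clockwise rotation
  ann90 <- conjugate_annotation(center = c(120, 119), direction = c(0, -1),
                                roi_size_px = 20)
  p90 <- polarization_rois(img90, ann90)
  expect_equal(unname(p90$percent), unname(p$percent), tolerance = 1e-9)
})

test_that("noisy enrichment recovery stays within 5% over repeated conjugates", {
  set.seed(61)
  meds <- sapply(c(1.5, 2, 3), function(k) {
    median(replicate(40, {
      s <- simulate_conjugate(k, noise = "poisson")
      accumulation_ratio(s$image, s$annotation)
    }))
  })
  expect_true(all(abs(meds - c(1.5, 2, 3)) / c(1.5, 2, 3) < 0.05))
})
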