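test_that("z-scoring is definitional and drops constant columns", {
  expect_equal(as.vector(scale_features(cbind(a = c(1, 2, 3), b = c(0, 5, 1))))[1:3],
               c(-1, 0, 1))
  set.seed(50)
  x <- matrix(rnorm(200, 5, 3), 20)
  sx <- scale_features(x)
  expect_true(all(abs(colMeans(sx)) < 1e-12))
  expect_true(all(abs(apply(sx, 2, sd) - 1) < 1e-12))
  xc <- cbind(x, const = 7)
  colnames(xc) <- c(paste0("V", 1:10), "const")
  expect_warning(s2 <- scale_features(xc), "const")
  expect_equal(ncol(s2), 10)
  expect_error(scale_features(x[1, , drop = FALSE]), "at least 2")
})

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(51)
  x <- matrix(rnorm(15), 5, 3)
  p <- run_pca(x)
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(p$sdev^2, ev[ev > 1e-12], tolerance = 1e-9)
  # orthonormal loadings, decorrelated zero-mean scores
  L <- p$loadings
  expect_equal(crossprod(L), diag(ncol(L)), tolerance = 1e-9,
               ignore_attr = TRUE)
  sc <- p$scores
  expect_true(all(abs(colMeans(sc)) < 1e-9))
  cv <- cov(sc)
  expect_true(all(abs(cv[upper.tri(cv)]) < 1e-9))
  expect_equal(sum(p$var_explained), 100)
  # all variance on one column
  y <- cbind(c(-2, 0, 2, 4), 1)
  colnames(y) <- c("a", "b")
  suppressWarnings(py <- run_pca(y))
  expect_equal(py$var_explained[1], 100)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(L))) expect_gt(L[which.max(abs(L[, j])), j], 0)
})

test_that("LDA separates, predicts, and matches MASS on the same data", {
  set.seed(52)
  # two classes 10 sd apart on one measure: perfect resubstitution
  x <- rbind(cbind(rnorm(20), rnorm(20)), cbind(rnorm(20, 10), rnorm(20)))
  colnames(x) <- c("m1", "m2")
  g <- rep(c("a", "b"), each = 20)
  r <- run_lda(scale_features(x), g)
  expect_equal(r$accuracy_overall, 100)
  expect_lte(ncol(r$scalings), 1)

  # four classes: at most 3 discriminants, cross-check with MASS::lda
  x4 <- do.call(rbind, lapply(0:3, function(k) matrix(rnorm(150, k * 1.5), 30)))
  colnames(x4) <- paste0("m", 1:5)
  g4 <- rep(letters[1:4], each = 30)
  sx <- scale_features(x4)
  r4 <- run_lda(sx, g4)
  expect_lte(ncol(r4$scalings), 3)
  m <- MASS::lda(sx, grouping = g4)
  expect_equal(as.character(r4$predicted), as.character(predict(m)$class))
  # scalings agree up to sign/order
  for (j in 1:ncol(r4$scalings)) {
    expect_gt(abs(cor(r4$scalings[, j], m$scaling[, j])), 1 - 1e-6)
  }
  expect_equal(unname(r4$accuracy_overall),
               100 * mean(predict(m)$class == g4))

  # singular within-class scatter without the ridge errors; ridge rescues
  xs <- cbind(x4[, 1], x4[, 1], x4[, 2])
  colnames(xs) <- c("a", "b", "c")
  expect_message(rs <- run_lda(suppressWarnings(scale(xs)), g4), "ridge")
  expect_true(rs$ridge_applied)
})

test_that("permuted labels give accuracy near the majority-class frequency", {
  set.seed(53)
  x <- matrix(rnorm(120 * 4), 120)
  colnames(x) <- paste0("m", 1:4)
  g <- rep(c("a", "b"), c(84, 36))  # majority 70%
  acc <- replicate(50, run_lda(scale_features(x), sample(g))$accuracy_overall)
  expect_lt(abs(mean(acc) - 70), 5)
})

test_that("confidence ellipses have the chi-square geometry and coverage", {
  set.seed(54)
  iso <- matrix(rnorm(4000), ncol = 2)
  e <- confidence_ellipse(iso)
  expect_false(e$degenerate)
  expect_equal(e$radii[1]^2, qchisq(0.95, 2), tolerance = 0.15)
  expect_equal(e$radii[1] / e$radii[2], 1, tolerance = 0.1)

  # scaling the points scales the axes
  e2 <- confidence_ellipse(iso * 2)
  expect_equal(e2$radii, e$radii * 2, tolerance = 1e-9)

  # Monte-Carlo coverage ~95% (ellipse from true parameters via large n)
  big <- matrix(rnorm(20000), ncol = 2) %*% chol(matrix(c(2, 0.7, 0.7, 1), 2))
  eb <- confidence_ellipse(big)
  Sinv <- solve(eb$cov)
  d2 <- rowSums((sweep(big, 2, eb$center) %*% Sinv) *
                sweep(big, 2, eb$center))
  expect_lt(abs(mean(d2 <= qchisq(0.95, 2)) - 0.95), 0.01)

  # collinear points flagged degenerate
  line <- cbind(1:10, (1:10) * 2)
  expect_true(confidence_ellipse(line)$degenerate)
  expect_error(confidence_ellipse(iso[1:2, ]), "n >= 3")

  # outline points lie on the boundary quadratic
  pts <- ellipse_points(eb, 25)
  q <- rowSums((sweep(pts, 2, eb$center) %*% Sinv) * sweep(pts, 2, eb$center))
  expect_equal(q, rep(qchisq(0.95, 2), 25), tolerance = 1e-9)
})
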