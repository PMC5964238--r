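#' Z-score a feature matrix column-wise
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator). Zero-variance columns cannot be scaled and are
#' dropped with a warning.
#'
#' @param x numeric matrix or data frame of features (rows = cells).
#' @return scaled matrix with attributes `center`, `scale`, and
#'   `dropped_columns`.
#' @export
scale_features <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("features must be numeric")
  if (nrow(x) < 2) stop("need at least 2 observations to scale")
  if (anyNA(x)) stop("missing values in the feature matrix; handle exclusions first")
  sds <- apply(x, 2, stats::sd)
  drop <- sds == 0
  if (any(drop)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  ctr <- colMeans(x)
  out <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sds
  attr(out, "dropped_columns") <- names(drop)[drop]
  out
}

#' Principal component analysis of the scaled measure table
#'
#' Thin wrapper around the singular value decomposition (`stats::prcomp`)
#' returning orthonormal loadings, scores, and percentage variance
#' explained. Each loading vector is oriented so its largest-magnitude
#' element is positive, making biplots reproducible across platforms.
#'
#' @param x scaled feature matrix (see [scale_features()]).
#' @return list with `scores`, `loadings`, `var_explained` (percent, sums to
#'   100 over the retained components), and `sdev`.
#' @export
run_pca <- function(x) {
  x <- as.matrix(x)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- pr$sdev > max(pr$sdev) * 1e-10
  load <- pr$rotation[, keep, drop = FALSE]
  scores <- pr$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- 100 * pr$sdev[keep]^2 / sum(pr$sdev[keep]^2)
  list(scores = scores, loadings = load, var_explained = ve,
       sdev = pr$sdev[keep])
}

#' Fisher linear discriminant analysis of calcium signature groups
#'
#' Solves the generalized eigenproblem on the between-class and pooled
#' within-class scatter of the scaled measures, giving at most
#' (number of classes - 1) discriminants scaled to unit within-class
#' variance. Observations are classified from Gaussian class posteriors
#' with a shared covariance (computed in discriminant space) and
#' proportional priors by default; resubstitution accuracy is reported
#' overall and per class. A ridge `ridge * mean(diag(W))` is added to the
#' within-class scatter only if it is numerically singular, and this is
#' recorded in the result.
#'
#' @param x scaled feature matrix.
#' @param labels class label per row (factor or character).
#' @param priors `NULL` for priors proportional to class frequencies, or a
#'   named vector over the classes.
#' @param ridge relative ridge used when the within-class scatter is
#'   singular.
#' @param tol eigenvalue tolerance for rank decisions.
#' @return an `lda_result` list: `scalings` (p x d), `scores`, `predicted`,
#'   `confusion`, `accuracy_overall` and `accuracy_by_class` (percent),
#'   `class_means` (in discriminant space), `priors`, `svd` (discriminant
#'   eigenvalues), `ridge_applied`.
#' @export
run_lda <- function(x, labels, priors = NULL, ridge = 1e-8, tol = 1e-10) {
  x <- as.matrix(x)
  g <- factor(labels)
  g <- droplevels(g)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  if (any(table(g) < 2)) stop("every class needs at least 2 members")
  n <- nrow(x); p <- ncol(x); k <- nlevels(g)
  mu <- colMeans(x)
  cls_means <- do.call(rbind, lapply(levels(g), function(l) colMeans(x[g == l, , drop = FALSE])))
  rownames(cls_means) <- levels(g)
  nc <- as.numeric(table(g))
  # pooled within-class scatter (unbiased) and between-class scatter
  W <- matrix(0, p, p)
  for (i in seq_len(k)) {
    xi <- sweep(x[g == levels(g)[i], , drop = FALSE], 2, cls_means[i, ])
    W <- W + crossprod(xi)
  }
  W <- W / (n - k)
  B <- crossprod(sqrt(nc) * sweep(cls_means, 2, mu)) / (k - 1)
  ew <- eigen(W, symmetric = TRUE)
  ridge_applied <- FALSE
  if (min(ew$values) < tol * max(ew$values)) {
    W <- W + diag(ridge * mean(diag(W)), p)
    ew <- eigen(W, symmetric = TRUE)
    ridge_applied <- TRUE
    if (min(ew$values) < tol * max(ew$values)) {
      stop("within-class scatter is singular even after ridge regularization")
    }
    message("run_lda: ridge regularization applied to within-class scatter")
  }
  # whiten, then diagonalize the between scatter
  Whalf <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  eb <- eigen(Whalf %*% B %*% Whalf, symmetric = TRUE)
  d <- min(k - 1, sum(eb$values > tol * max(eb$values)))
  scal <- Whalf %*% eb$vectors[, seq_len(d), drop = FALSE]
  colnames(scal) <- paste0("LD", seq_len(d))
  rownames(scal) <- colnames(x)
  for (j in seq_len(d)) {      # sign convention: largest element positive
    if (scal[which.max(abs(scal[, j])), j] < 0) scal[, j] <- -scal[, j]
  }
  scores <- x %*% scal
  means_ld <- cls_means %*% scal
  if (is.null(priors)) {
    pri <- nc / n
  } else {
    pri <- priors[levels(g)]
    if (anyNA(pri)) stop("priors must be named over all classes")
    pri <- pri / sum(pri)
  }
  # Gaussian posteriors with identity covariance in discriminant space
  # (the scalings have unit within-class variance by construction)
  d2 <- sapply(seq_len(k), function(i) {
    rowSums(sweep(scores, 2, means_ld[i, ])^2)
  })
  post <- exp(-d2 / 2 + matrix(log(pri), n, k, byrow = TRUE))
  post <- post / rowSums(post)
  pred <- factor(levels(g)[max.col(-d2 + matrix(log(pri) * 2, n, k, byrow = TRUE))],
                 levels = levels(g))
  conf <- table(observed = g, predicted = pred)
  acc_cls <- 100 * diag(conf) / rowSums(conf)
  structure(list(scalings = scal, scores = scores, predicted = pred,
                 posterior = post, confusion = conf,
                 accuracy_overall = 100 * mean(pred == g),
                 accuracy_by_class = acc_cls,
                 class_means = means_ld, priors = pri,
                 svd = eb$values[seq_len(d)], ridge_applied = ridge_applied),
            class = "lda_result")
}

#' @export
print.lda_result <- function(x, ...) {
  cat(sprintf("<lda_result> %d discriminants; overall resubstitution accuracy %.1f%%\n",
              ncol(x$scalings), x$accuracy_overall))
  cat("per-class accuracy (%):\n")
  print(round(x$accuracy_by_class, 1))
  invisible(x)
}

#' 95% confidence ellipse of a 2-D score cloud
#'
#' Ellipse from the group mean and covariance at the chi-square(2 df)
#' quantile of `level` — the standard normal-theory confidence region drawn
#' around each class in discriminant biplots.
#'
#' @param xy n x 2 matrix of scores for one group (n >= 3).
#' @param level confidence level.
#' @return list with `center`, `radii` (semi-axes, descending), `angle_rad`
#'   (orientation of the major axis), `cov`, and `degenerate` (TRUE when the
#'   points are collinear).
#' @export
confidence_ellipse <- function(xy, level = 0.95) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 3) stop("need an n x 2 matrix with n >= 3")
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  degenerate <- e$values[2] < 1e-12 * max(e$values[1], 1e-300)
  list(center = ctr, radii = sqrt(pmax(e$values, 0) * q),
       angle_rad = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = S, degenerate = degenerate)
}

#' Points of a confidence ellipse outline
#'
#' @param ellipse result of [confidence_ellipse()].
#' @param n number of outline points.
#' @return n x 2 matrix tracing the ellipse.
#' @export
ellipse_points <- function(ellipse, n = 100) {
  th <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$angle_rad
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  t(ellipse$center + R %*% rbind(ellipse$radii[1] * cos(th),
                                 ellipse$radii[2] * sin(th)))
}
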