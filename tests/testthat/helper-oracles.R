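# Independent brute-force oracles. These deliberately re-derive every
# quantity with plain loops, not by calling package internals.

make_track <- function(t_s, x, y, ratio = NULL, id = 1L) {
  df <- data.frame(track_id = id, frame = seq_along(t_s) - 1L,
                   t_s = t_s, x_um = x, y_um = y)
  if (!is.null(ratio)) df$ratio <- ratio
  df
}

random_small_track <- function(id, n = NULL) {
  n <- if (is.null(n)) sample(8:30, 1) else n
  t <- cumsum(c(0, runif(n - 1, 5, 15)))
  make_track(t, cumsum(rnorm(n, 0, 3)), cumsum(rnorm(n, 0, 3)),
             ratio = 0.6 + rexp(n, 2), id = id)
}

# segment-wise motility summary used by the oracle
oracle_segment <- function(t, x, y) {
  n <- length(t)
  len <- 0
  for (i in 2:n) len <- len + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  euclid <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  list(len = len, euclid = euclid,
       mi = if (len == 0) 1 else euclid / len,
       speed = len / (t[n] - t[1]))
}

# all thirteen measures, by hand
oracle_measures <- function(tr, b, r2b_band = 0.20, mobile_thr = 2,
                            min_points = 3) {
  t <- tr$t_s; r <- tr$ratio; x <- tr$x_um; y <- tr$y_um
  n <- length(t)
  dur <- t[n] - t[1]
  i_max <- which(r == max(r))[1]
  lev <- (1 + r2b_band) * b
  r2b <- 0
  for (i in 2:n) if (r[i - 1] > lev && r[i] <= lev) r2b <- r2b + 1
  auc <- 0
  for (i in 2:n) {
    auc <- auc + (t[i] - t[i - 1]) *
      (max(r[i - 1] - b, 0) + max(r[i] - b, 0)) / 2
  }
  mobile <- 0; len <- 0; cum_at_max <- 0
  for (i in 2:n) {
    step <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
    len <- len + step
    if (i <= i_max) cum_at_max <- cum_at_max + step
    if (step / (t[i] - t[i - 1]) * 60 > mobile_thr) mobile <- mobile + 1
  }
  pre <- if (i_max >= 2) oracle_segment(t[1:i_max], x[1:i_max], y[1:i_max])
  post <- if (i_max <= n - 1) oracle_segment(t[i_max:n], x[i_max:n], y[i_max:n])
  rat <- function(a, q) {
    if (is.null(pre) || is.null(post) || post[[q]] == 0) NA_real_
    else pre[[q]] / post[[q]]
  }
  list(mobile_fraction = mobile / (n - 1),
       track_duration_s = dur, t_max_s = t[i_max],
       pct_track_length_at_max = if (len == 0) 0 else 100 * cum_at_max / len,
       r2b = r2b, min_ratio = min(r), max_ratio = max(r),
       median_ratio = median(r), auc_ratio = auc / dur,
       length_ratio = rat(pre, "len"), speed_ratio = rat(pre, "speed"),
       mi_ratio = rat(pre, "mi"), euclid_ratio = rat(pre, "euclid"),
       excluded_few_points = i_max < min_points || (n - i_max + 1) < min_points)
}

# greedy nearest matching, re-derived with explicit scans
oracle_match <- function(acute, basal) {
  ord <- order(acute$t_max_s, acute$track_id)
  used <- rep(FALSE, nrow(basal))
  out <- NULL
  for (i in ord) {
    best <- NA; bestd <- Inf
    for (j in seq_len(nrow(basal))) {
      if (used[j]) next
      d <- abs(basal$t_max_s[j] - acute$t_max_s[i])
      if (d < bestd || (d == bestd && !is.na(best) &&
                        basal$track_id[j] < basal$track_id[best])) {
        best <- j; bestd <- d
      }
    }
    out <- rbind(out, data.frame(
      acute_id = acute$track_id[i],
      basal_id = if (is.na(best)) NA_real_ else basal$track_id[best],
      delta_t_max_s = if (is.na(best)) NA_real_ else bestd))
    if (!is.na(best)) used[best] <- TRUE
  }
  out
}

# exact two-sided Fisher p by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  sets <- combn(na + nb, na)
  U_all <- apply(sets, 2, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  p_le <- mean(U_all <= U_obs + 1e-9)
  p_ge <- mean(U_all >= U_obs - 1e-9)
  list(U = U_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# pixel set within width/2 of a polyline, by scanning every pixel
oracle_band_mean <- function(img, poly, width) {
  vals <- c()
  for (yy in 0:(nrow(img) - 1)) {
    for (xx in 0:(ncol(img) - 1)) {
      dmin <- Inf
      for (s in seq_len(nrow(poly) - 1)) {
        a <- poly[s, ]; bb <- poly[s + 1, ]
        ab <- bb - a; l2 <- sum(ab^2)
        tt <- if (l2 == 0) 0 else
          min(max(((xx - a[1]) * ab[1] + (yy - a[2]) * ab[2]) / l2, 0), 1)
        d <- sqrt((xx - a[1] - tt * ab[1])^2 + (yy - a[2] - tt * ab[2])^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= width / 2) vals <- c(vals, img[yy + 1, xx + 1])
    }
  }
  mean(vals)
}
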