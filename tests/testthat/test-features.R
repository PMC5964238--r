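test_that("duration filter keeps >= 5 min tracks, boundary inclusive", {
  long <- make_track((0:120) * 10, rep(0, 121), rep(0, 121), id = 1)   # 1200 s
  short <- make_track((0:19) * 10, rep(0, 20), rep(0, 20), id = 2)     # 190 s
  edge <- make_track((0:30) * 10, rep(0, 31), rep(0, 31), id = 3)      # 300 s
  all3 <- rbind(long, short, edge)
  parts <- filter_tracks(all3)
  expect_setequal(unique(parts$kept$track_id), c(1, 3))
  expect_setequal(unique(parts$excluded$track_id), 2)
  expect_equal(nrow(parts$kept) + nrow(parts$excluded), nrow(all3))
})

test_that("baseline pools the ten lowest-range tracks", {
  mk <- function(id, vals) make_track(seq_along(vals) * 10, vals * 0,
                                      vals * 0, ratio = vals, id = id)
  # 10 constant tracks at 0.80 plus 2 high-range tracks
  tracks <- do.call(rbind, c(
    lapply(1:10, function(i) mk(i, rep(0.80, 5))),
    list(mk(11, c(0.8, 2, 0.8, 2, 0.8)), mk(12, c(0.5, 1.8, 0.5, 1.8, 0.5)))
  ))
  b <- compute_baseline(tracks)
  expect_equal(b$value, 0.80)
  expect_equal(b$n_tracks_used, 10)
  expect_false(any(c(11, 12) %in% b$selection$track_id))

  # fewer than 10 tracks: pooled median of all
  four <- do.call(rbind, lapply(1:4, function(i) mk(i, rep(c(0.7, 0.8, 0.9, 1.0)[i], 6))))
  expect_equal(compute_baseline(four)$value, 0.85)
  expect_error(compute_baseline(four[0, ]), "no tracks")
})

test_that("baseline equals the brute-force sort/pool/median on random tracks", {
  set.seed(21)
  for (rep in 1:5) {
    tracks <- do.call(rbind, lapply(1:15, random_small_track))
    b <- compute_baseline(tracks)
    rng <- sapply(split(tracks$ratio, tracks$track_id), function(r) max(r) - min(r))
    ids <- as.numeric(names(sort(rng)[1:10]))
    expect_equal(b$value, median(tracks$ratio[tracks$track_id %in% ids]),
                 tolerance = 1e-12)
  }
})

test_that("calcium measures: hand-counted crossings and hand trapezoid", {
  b <- 0.8
  # constant at baseline
  flat <- make_track((0:40) * 10, rep(0, 41), rep(0, 41), ratio = rep(b, 41))
  ca <- calcium_measures(flat, b)
  expect_equal(ca$auc_ratio, 0)
  expect_equal(ca$r2b, 0)
  expect_equal(c(ca$min_ratio, ca$max_ratio, ca$median_ratio), rep(b, 3))

  # rises above 1.2 x baseline and returns, twice
  r <- c(0.8, 0.8, 1.3, 1.3, 0.85, 0.8, 1.5, 0.9, 0.8, 0.8)
  two <- make_track((0:9) * 10, rep(0, 10), rep(0, 10), ratio = r)
  expect_equal(calcium_measures(two, b)$r2b, 2)

  # square pulse 0.8 -> 1.8: hand trapezoid on the sampled polyline
  rp <- c(0.8, 0.8, 1.8, 1.8, 1.8, 0.8, 0.8)
  pulse <- make_track((0:6) * 10, rep(0, 7), rep(0, 7), ratio = rp)
  # deviations 0,0,1,1,1,0,0 above baseline: trapezoids 0,5,10,10,5,0 over 60 s
  hand <- (10 * (0 + 1) / 2 + 10 * (1 + 1) / 2 + 10 * (1 + 1) / 2 +
           10 * (1 + 0) / 2) / 60
  expect_equal(calcium_measures(pulse, b)$auc_ratio, hand)
  expect_equal(calcium_measures(pulse, b)$t_max_s, 20)  # first occurrence
})

test_that("auc components respond separately to appended baseline samples", {
  b <- 0.8
  r <- c(0.8, 1.6, 1.6, 0.8)
  tr <- make_track((0:3) * 10, rep(0, 4), rep(0, 4), ratio = r)
  tr2 <- make_track((0:7) * 10, rep(0, 8), rep(0, 8),
                    ratio = c(r, rep(b, 4)))  # 40 s more of pure baseline
  a1 <- calcium_measures(tr, b)
  a2 <- calcium_measures(tr2, b)
  expect_equal(a1$auc_ratio * 30, a2$auc_ratio * 70)  # integral unchanged
  expect_lt(a2$auc_ratio, a1$auc_ratio)               # denominator grew
})

test_that("motility measures: straight line, loop, threshold conversion", {
  straight <- make_track((0:10) * 10, (0:10) * 2, rep(0, 11))
  mo <- motility_measures(straight)
  expect_equal(mo$mi, 1.0)
  expect_equal(mo$track_length_um, 20)
  expect_equal(mo$speed_um_s, 0.2)

  th <- seq(0, 2 * pi, length.out = 9)
  loop <- make_track((0:8) * 10, 5 * cos(th), 5 * sin(th))
  ml <- motility_measures(loop)
  expect_equal(ml$euclid_um, 0, tolerance = 1e-9)
  expect_equal(ml$mi, 0, tolerance = 1e-9)

  # steps of 0.5 um per 10 s frame = 3 um/min > 2 um/min threshold
  mf <- motility_measures(make_track((0:9) * 10, (0:9) * 0.5, rep(0, 10)))
  expect_equal(mf$mobile_fraction, 1.0)
  mf2 <- motility_measures(make_track((0:9) * 10, (0:9) * 0.3, rep(0, 10)))
  expect_equal(mf2$mobile_fraction, 0.0)  # 1.8 um/min below threshold
})

test_that("pre/post ratios: symmetry, arrest, and the few-points rule", {
  # symmetric out-and-back path with t_max at the turning point
  x <- c(0:5, 4:0); t <- (0:10) * 10
  r <- c(rep(0.8, 5), 1.6, rep(0.8, 5))
  sym <- make_track(t, x, rep(0, 11), ratio = r)
  pp <- prepost_ratios(sym, t_max_s = 50)
  expect_equal(pp$length_ratio, 1.0)
  expect_equal(pp$speed_ratio, 1.0)
  expect_false(pp$excluded_few_points)

  # pre Euclidean 30 um, post 3 um
  xr <- c(0, 10, 20, 30, 31, 32, 33)
  arr <- make_track((0:6) * 10, xr, rep(0, 7))
  expect_equal(prepost_ratios(arr, t_max_s = 30)$euclid_ratio, 10.0)

  # t_max at 2nd sample -> fewer than three pre datapoints
  expect_true(prepost_ratios(arr, t_max_s = 10)$excluded_few_points)

  # zero post movement: ratio undefined, not infinite
  frozen <- make_track((0:6) * 10, c(0, 5, 10, 15, 15, 15, 15), rep(0, 7))
  pf <- prepost_ratios(frozen, t_max_s = 30)
  expect_true(is.na(pf$length_ratio))
  expect_true(is.na(pf$euclid_ratio))
})

test_that("all thirteen measures match the brute-force oracle on random tracks", {
  set.seed(77)
  for (rep in 1:50) {
    tr <- random_small_track(rep)
    b <- runif(1, 0.5, 1.0)
    f <- compute_features(tr, baseline = b, min_duration_s = 0)
    o <- oracle_measures(tr, b)
    for (m in names(o)[names(o) != "excluded_few_points"]) {
      if (is.na(o[[m]])) {
        expect_true(is.na(f[[m]]), label = paste(m, "NA, rep", rep))
      } else {
        expect_equal(f[[m]], o[[m]], tolerance = 1e-9,
                     label = paste(m, "rep", rep))
      }
    }
    expect_equal(f$excluded_few_points, o$excluded_few_points)
  }
})

test_that("Euclidean <= track length and MI in [0, 1] on random tracks", {
  set.seed(31)
  for (rep in 1:40) {
    mo <- motility_measures(random_small_track(rep))
    expect_lte(mo$euclid_um, mo$track_length_um + 1e-12)
    expect_gte(mo$mi, 0)
    expect_lte(mo$mi, 1)
  }
})

test_that("matched-control selection is greedy nearest with stated tie rule", {
  acute <- data.frame(track_id = c(101, 102), t_max_s = c(100, 200))
  basal <- data.frame(track_id = c(1, 2, 3), t_max_s = c(110, 190, 500))
  m <- match_controls(acute, basal)
  expect_equal(m$basal_id[m$acute_id == 101], 1)
  expect_equal(m$basal_id[m$acute_id == 102], 2)

  # one candidate -> it is matched; pool exhausted -> unmatched flagged
  m1 <- match_controls(acute, basal[1, ])
  expect_true(m1$matched[m1$acute_id == 101])
  expect_false(m1$matched[m1$acute_id == 102])

  # equidistant candidates resolve to the lower track id
  tie <- match_controls(data.frame(track_id = 5, t_max_s = 100),
                        data.frame(track_id = c(9, 4), t_max_s = c(110, 90)))
  expect_equal(tie$basal_id, 4)
})

test_that("matching equals the exhaustive oracle and never reuses a control", {
  set.seed(9)
  for (rep in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:10, 1)
    acute <- data.frame(track_id = 100 + 1:na, t_max_s = round(runif(na, 0, 600)))
    basal <- data.frame(track_id = 1:nb, t_max_s = round(runif(nb, 0, 600)))
    m <- match_controls(acute, basal)
    o <- oracle_match(acute, basal)
    mo <- merge(m, o, by = "acute_id")
    expect_equal(mo$basal_id.x, mo$basal_id.y)
    used <- m$basal_id[!is.na(m$basal_id)]
    expect_equal(anyDuplicated(used), 0)
  }
})

test_that("greedy matching beats the average random pairing on |delta t_max|", {
  # greedy-by-ascending-t_max is not globally optimal, so it can lose to a
  # lucky random pairing on single instances; the sanity statement that holds
  # is that it beats random pairing on aggregate, and by a wide margin
  set.seed(12)
  greedy_tot <- rand_tot <- numeric(100)
  for (rep in 1:100) {
    n <- 6
    acute <- data.frame(track_id = 100 + 1:n, t_max_s = runif(n, 0, 600))
    basal <- data.frame(track_id = 1:n, t_max_s = runif(n, 0, 600))
    m <- match_controls(acute, basal)
    greedy_tot[rep] <- sum(m$delta_t_max_s)
    rand_tot[rep] <- mean(replicate(50,
      sum(abs(acute$t_max_s - basal$t_max_s[sample(n)]))))
  }
  expect_lt(mean(greedy_tot), mean(rand_tot))
  expect_gte(mean(greedy_tot <= rand_tot + 1e-9), 0.9)
})
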