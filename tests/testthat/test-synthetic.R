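test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(mixture = c(flat = 0.7, transient = 0.2,
                                      low = 0.2, high = 0.1)), "sum to 1")
  expect_error(sim_config(frame_interval_s = 0), "frame_interval_s")
  expect_error(sim_config(n_tcells = -1), "counts")
  expect_error(sim_config(mixture = c(a = 1)), "named")
})

test_that("trace templates realize their class", {
  flat <- simulate_trace("flat", baseline = 0.8)
  expect_length(flat, 121)
  expect_true(all(flat == 0.8))

  high <- simulate_trace("high", baseline = 0.8, onset_s = 120)
  expect_equal(max(high), 2.2)
  t <- (0:120) * 10
  expect_true(all(high[t > 140] >= 1))  # sustained above 1 after the peak

  tran <- simulate_trace("transient", baseline = 0.8, onset_s = 100,
                         n_frames = 61)
  expect_true(all(tail(tran, 10) <= 1.2 * 0.8))  # returned to baseline band

  low <- simulate_trace("low", baseline = 0.8, onset_s = 100)
  expect_lt(max(low), 1.5)
  expect_true(all(tail(low, 50) > 1.2 * 0.8))

  expect_error(simulate_trace("sideways"), "unknown signature label")
})

test_that("noiseless templates round-trip through the classifier", {
  set.seed(5)
  for (L in signature_levels <- c("flat", "transient", "low", "high")) {
    for (onset in c(60, 300, 550)) {
      tr <- simulate_trace(L, baseline = 0.8, onset_s = onset)
      expect_identical(as.character(classify_signature(tr, 0.8)), L)
    }
  }
})

test_that("simulated tracks honour mixture, arrest, and determinism", {
  mix1 <- c(flat = 1, transient = 0, low = 0, high = 0)
  cfg <- sim_config(n_tcells = 15, n_frames = 40, field_size_um = c(150, 150),
                    mixture = mix1, noise_sd = 0, seed = 3)
  s <- simulate_tracks(cfg)
  expect_true(all(s$truth$label == "flat"))
  expect_true(all(s$tracks$ratio == 0.8))

  # arrest speed 0: no movement at all after onset
  cfg2 <- sim_config(n_tcells = 10, n_frames = 60, field_size_um = c(200, 200),
                     mixture = c(flat = 0, transient = 0, low = 0, high = 1),
                     arrest_speed_um_min = 0, speed_cv = 0, noise_sd = 0, seed = 4)
  s2 <- simulate_tracks(cfg2)
  for (id in s2$truth$track_id) {
    tr <- s2$tracks[s2$tracks$track_id == id, ]
    post <- tr[tr$t_s >= s2$truth$onset_s[s2$truth$track_id == id], ]
    d <- sqrt(diff(post$x_um)^2 + diff(post$y_um)^2)
    expect_true(all(d == 0))
  }

  cfg3 <- sim_config(n_tcells = 25, n_frames = 50, seed = 42)
  expect_identical(simulate_tracks(cfg3), simulate_tracks(cfg3))
  expect_warning(out <- simulate_tracks(sim_config(n_tcells = 0)), "empty")
  expect_equal(nrow(out$tracks), 0)
})

test_that("rendered movies reproduce the true ratio exactly without noise", {
  cfg <- sim_config(n_tcells = 1, n_frames = 25, field_size_um = c(60, 60),
                    noise_sd = 0, seed = 8,
                    mixture = c(flat = 0, transient = 0, low = 0, high = 1))
  s <- simulate_tracks(cfg)
  # overwrite the trace with a ramp 0.8 -> 2.0 to probe the forward model
  ramp <- seq(0.8, 2.0, length.out = 25)
  s$tracks$ratio <- ramp
  mov <- render_timelapse(s$tracks, cfg)
  st <- compute_ratio_stack(mov$ch340, mov$ch380, pixel_size_um = mov$pixel_size_um)
  ex <- extract_trace(st, s$tracks[, 1:5])
  expect_false(any(ex$dropped))
  expect_lt(max(abs(ex$ratio - ramp)), 1e-3)
  # single static frame at ratio exactly 1
  one <- make_track(0, 30, 30, ratio = 1)
  cfg1 <- sim_config(n_tcells = 1, n_frames = 2, field_size_um = c(60, 60), seed = 1)
  mov1 <- render_timelapse(one, cfg1)
  st1 <- compute_ratio_stack(mov1$ch340[, , 1], mov1$ch380[, , 1],
                             pixel_size_um = mov1$pixel_size_um)
  expect_equal(extract_trace(st1, one)$ratio, 1.0, tolerance = 1e-6)
  # background (380 == 0) is masked, so it cannot dilute the ROI mean
  expect_true(all(is.na(st1$ratio[1:5, 1:5, 1])))
})

test_that("conjugate generator gives the configured enrichment exactly", {
  for (k in c(1, 3)) {
    sc <- simulate_conjugate(k)
    expect_equal(accumulation_ratio(sc$image, sc$annotation), k,
                 tolerance = 1e-6)
  }
  expect_error(simulate_conjugate(0), "> 0")
  expect_error(simulate_conjugate(-2), "> 0")
})

test_that("flow generator hits its configured fractions and ratios", {
  set.seed(6)
  fl <- simulate_flow_events(1000, dead_frac = 0, conjugate_frac = 0.08,
                             small_pulse_frac = 0)
  expect_equal(conjugate_frequency(fl$pre), 8.0)
  # post identical to pre => 100%
  expect_equal(relative_calcium(fl$post, fl$post), 100)
  # no conjugates => empty-gate condition
  none <- simulate_flow_events(500, conjugate_frac = 0)
  expect_error(relative_calcium(none$pre, none$post), "empty")
  expect_error(simulate_flow_events(100, dead_frac = 1.5), "fractions")
})

test_that("classified label frequencies recover the configured mixture", {
  cfg <- sim_config(n_tcells = 500, seed = 3)  # default low-noise setting
  s <- simulate_tracks(cfg)
  lab <- classify_traces(s$tracks, compute_baseline(s$tracks))
  freq <- prop.table(table(lab$label))
  for (L in names(cfg$mixture)) {
    expect_lt(abs(freq[[L]] - cfg$mixture[[L]]), 0.03)
  }
})
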