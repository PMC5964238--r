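#' Simulate a single-cell calcium trace of a given signature class
#'
#' Noiseless templates satisfy the corresponding classification rule by
#' construction: `flat` stays at baseline; `transient` rises and decays back
#' to baseline; `low` rises to a sustained level below the 'high' criteria;
#' `high` rises above 2 and settles to a plateau above 1.
#'
#' @param label one of `"flat"`, `"transient"`, `"low"`, `"high"`.
#' @param n_frames,frame_interval_s sampling grid.
#' @param baseline resting 340:380 ratio.
#' @param onset_s signaling onset time (s); ignored for `flat`.
#' @param params list of template parameters; defaults taken from
#'   [sim_config()] (`high_peak`, `high_plateau`, `transient_peak`,
#'   `low_level`, `rise_s`, `transient_decay_tau_s`, `high_decay_tau_s`).
#' @param noise_sd additive Gaussian noise sd (ratio units); uses the
#'   current RNG state.
#' @return numeric vector of length `n_frames` (the 340:380 trace).
#' @export
simulate_trace <- function(label, n_frames = 121L, frame_interval_s = 10,
                           baseline = 0.8, onset_s = 120,
                           params = list(), noise_sd = 0) {
  if (!is.character(label) || length(label) != 1 ||
      !label %in% signature_levels()) {
    stop("unknown signature label: ", paste(label, collapse = ", "))
  }
  p <- utils::modifyList(list(high_peak = 2.2, high_plateau = 1.4,
                              transient_peak = 1.3, low_level = 1.35,
                              rise_s = 20, transient_decay_tau_s = 60,
                              high_decay_tau_s = 120), params)
  t <- (seq_len(n_frames) - 1L) * frame_interval_s
  r <- rep(baseline, n_frames)
  if (label != "flat") {
    peak <- switch(label, transient = p$transient_peak, low = p$low_level,
                   high = p$high_peak)
    t_peak <- onset_s + p$rise_s
    rising <- t > onset_s & t < t_peak
    r[rising] <- baseline + (peak - baseline) * (t[rising] - onset_s) / p$rise_s
    after <- t >= t_peak
    r[after] <- switch(label,
      transient = baseline + (peak - baseline) *
        exp(-(t[after] - t_peak) / p$transient_decay_tau_s),
      low = peak,
      high = p$high_plateau + (peak - p$high_plateau) *
        exp(-(t[after] - t_peak) / p$high_decay_tau_s)
    )
  }
  if (noise_sd > 0) r <- r + stats::rnorm(n_frames, 0, noise_sd)
  r
}

#' Simulate tracked T cells with signaling-coupled motility
#'
#' Cells are assigned signature labels by the configured mixture
#' (deterministic largest-remainder counts), move as persistent random walks
#' before signaling onset, and — for `high` cells and a configurable
#' fraction of `low` cells — become confined ("corralled") within
#' `confine_radius_um` of the onset position afterwards, with per-step speed
#' switched to `arrest_speed_um_min`. Positions reflect back into the field.
#' The same config (including its seed) always produces identical output.
#'
#' @param config a [sim_config()].
#' @return list with `tracks` (data frame: `track_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`, `ratio` — the true noisy trace) and `truth` (data
#'   frame: `track_id`, `label`, `onset_s`, `arrested`).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_tcells
  if (n == 0) {
    warning("n_tcells = 0: returning empty tracks")
    return(list(
      tracks = data.frame(track_id = integer(), frame = integer(),
                          t_s = numeric(), x_um = numeric(), y_um = numeric(),
                          ratio = numeric()),
      truth = data.frame(track_id = integer(), label = character(),
                         onset_s = numeric(), arrested = logical())
    ))
  }
  mix <- config$mixture[signature_levels()]
  counts <- allocate_counts(n, mix)
  labels <- rep(signature_levels(), counts)
  labels <- sample(labels)  # shuffle so label does not encode track_id order
  # onset late enough margin for the class template to express itself within
  # the assay: sustained classes need a few samples above threshold,
  # transients also the decay back to baseline (~3 time constants)
  total_s <- (config$n_frames - 1) * config$frame_interval_s
  onset_hi <- function(label) {
    margin <- config$rise_s + switch(label,
      transient = 3 * config$transient_decay_tau_s + 2 * config$frame_interval_s,
      3 * config$frame_interval_s)
    max(config$onset_range_s[1], min(config$onset_range_s[2], total_s - margin))
  }
  onset <- ifelse(labels == "flat", NA_real_,
                  stats::runif(n, config$onset_range_s[1],
                               vapply(labels, onset_hi, 1.0)))
  arrested <- labels == "high"
  low_idx <- which(labels == "low")
  if (length(low_idx) && config$arrest_low_fraction > 0) {
    n_arrest <- round(config$arrest_low_fraction * length(low_idx))
    if (n_arrest > 0) {
      arrested[sample(low_idx, n_arrest)] <- TRUE
    }
  }
  nf <- config$n_frames
  dt <- config$frame_interval_s
  fw <- config$field_size_um
  margin <- 3 * config$cell_sigma_um
  step_mean <- config$basal_speed_um_min * dt / 60
  step_arrest <- config$arrest_speed_um_min * dt / 60
  shape <- if (config$speed_cv > 0) 1 / config$speed_cv^2 else Inf

  tracks <- vector("list", n)
  traces <- matrix(NA_real_, nrow = nf, ncol = n)
  for (i in seq_len(n)) {
    x <- numeric(nf); y <- numeric(nf)
    x[1] <- stats::runif(1, margin, fw[1] - margin)
    y[1] <- stats::runif(1, margin, fw[2] - margin)
    heading <- stats::runif(1, 0, 2 * pi)
    anchor <- c(NA_real_, NA_real_)
    for (f in 2:nf) {
      t_now <- (f - 1) * dt
      in_arrest <- arrested[i] && !is.na(onset[i]) && t_now >= onset[i]
      if (in_arrest && is.na(anchor[1])) anchor <- c(x[f - 1], y[f - 1])
      mean_step <- if (in_arrest) step_arrest else step_mean
      step <- if (is.finite(shape) && mean_step > 0) {
        stats::rgamma(1, shape = shape, scale = mean_step / shape)
      } else mean_step
      heading <- heading + stats::rnorm(1, 0, config$turn_sd_rad)
      px <- x[f - 1] + step * cos(heading)
      py <- y[f - 1] + step * sin(heading)
      # confinement: re-aim towards the onset anchor, keeping step length
      if (in_arrest &&
          sqrt((px - anchor[1])^2 + (py - anchor[2])^2) > config$confine_radius_um) {
        heading <- atan2(anchor[2] - y[f - 1], anchor[1] - x[f - 1]) +
          stats::rnorm(1, 0, 0.3)
        px <- x[f - 1] + step * cos(heading)
        py <- y[f - 1] + step * sin(heading)
      }
      # field boundary: re-aim towards the field centre
      if (px < margin || px > fw[1] - margin || py < margin || py > fw[2] - margin) {
        heading <- atan2(fw[2] / 2 - y[f - 1], fw[1] / 2 - x[f - 1]) +
          stats::rnorm(1, 0, 0.3)
        px <- x[f - 1] + step * cos(heading)
        py <- y[f - 1] + step * sin(heading)
      }
      x[f] <- min(max(px, 0), fw[1])
      y[f] <- min(max(py, 0), fw[2])
    }
    traces[, i] <- simulate_trace(labels[i], nf, dt,
                                  baseline = config$baseline,
                                  onset_s = if (is.na(onset[i])) 0 else onset[i],
                                  params = config[c("high_peak", "high_plateau",
                                                    "transient_peak", "low_level",
                                                    "rise_s", "transient_decay_tau_s",
                                                    "high_decay_tau_s")],
                                  noise_sd = config$noise_sd)
    tracks[[i]] <- data.frame(track_id = i, frame = 0:(nf - 1L),
                              t_s = (0:(nf - 1L)) * dt,
                              x_um = x, y_um = y, ratio = traces[, i])
  }
  list(
    tracks = do.call(rbind, tracks),
    truth = data.frame(track_id = seq_len(n), label = labels,
                       onset_s = onset, arrested = arrested)
  )
}

#' Cell-frame collision flags
#'
#' Marks track samples whose measurement could be contaminated by a
#' neighbouring cell: any other cell centre within `radius_um` at that
#' frame. Rendering permits overlapping cells (they add), so extraction
#' fidelity is only guaranteed on collision-free samples.
#'
#' @param tracks track table from [simulate_tracks()].
#' @param radius_um contamination radius. For rendered movies the footprint
#'   is truncated at 3 sigma and both blob and ROI centres are rounded to
#'   the pixel grid, so
#'   `3 * cell_sigma_um + (roi_diameter_px / 2 + 2) * pixel_size_um`
#'   is a safe bound.
#' @return logical vector along the rows of `tracks`.
#' @export
collision_flags <- function(tracks, radius_um) {
  flags <- logical(nrow(tracks))
  for (f in unique(tracks$frame)) {
    idx <- which(tracks$frame == f)
    if (length(idx) < 2) next
    d <- as.matrix(stats::dist(cbind(tracks$x_um[idx], tracks$y_um[idx])))
    diag(d) <- Inf
    flags[idx] <- apply(d, 1, min) < radius_um
  }
  flags
}
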