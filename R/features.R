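#' Exclude short tracks
#'
#' Tracks shorter than 5 minutes are excluded from all analysis. The
#' boundary is inclusive: a track lasting exactly `min_duration_s` is kept.
#'
#' @param tracks track table (`track_id`, `frame`, `t_s`, `x_um`, `y_um`,
#'   `ratio`), possibly many tracks.
#' @param min_duration_s minimum duration (last minus first timestamp).
#' @return list with `kept` and `excluded` track tables (exhaustive
#'   partition).
#' @export
filter_tracks <- function(tracks, min_duration_s = 300) {
  dur <- tapply(tracks$t_s, tracks$track_id, function(t) max(t) - min(t))
  keep_ids <- as.numeric(names(dur))[dur >= min_duration_s]
  keep <- tracks$track_id %in% keep_ids
  list(kept = tracks[keep, , drop = FALSE],
       excluded = tracks[!keep, , drop = FALSE])
}

#' Baseline 340:380 ratio from the quietest tracks
#'
#' The baseline is the median of the pooled sample values of the ten tracks
#' with the smallest 340:380 range (max minus min); all tracks are used if
#' fewer than ten are available. Range ties are broken by track id so the
#' selection is deterministic.
#'
#' @param tracks kept track table with a `ratio` column.
#' @param n_tracks how many low-range tracks to pool.
#' @param method `"pooled"` (median of all pooled samples, default) or
#'   `"per_track_median"` (median of the selected tracks' medians).
#' @return a `calcium_baseline` object: `value`, `n_tracks_used`, and the
#'   `selection` table (track id and ratio range).
#' @export
compute_baseline <- function(tracks, n_tracks = 10, method = c("pooled", "per_track_median")) {
  if (is.null(tracks) || nrow(tracks) == 0) stop("no tracks to compute a baseline from")
  method <- match.arg(method)
  rng <- tapply(tracks$ratio, tracks$track_id, function(r) max(r) - min(r))
  sel <- data.frame(track_id = as.numeric(names(rng)), range = as.numeric(rng))
  sel <- sel[order(sel$range, sel$track_id), , drop = FALSE]
  sel <- utils::head(sel, n_tracks)
  pooled <- tracks$ratio[tracks$track_id %in% sel$track_id]
  value <- if (method == "pooled") {
    stats::median(pooled)
  } else {
    stats::median(tapply(tracks$ratio[tracks$track_id %in% sel$track_id],
                         tracks$track_id[tracks$track_id %in% sel$track_id],
                         stats::median))
  }
  structure(list(value = unname(value), n_tracks_used = nrow(sel),
                 selection = sel, method = method),
            class = "calcium_baseline")
}

#' @export
print.calcium_baseline <- function(x, ...) {
  cat(sprintf("<calcium_baseline> %.4f (median of %d lowest-range tracks, %s)\n",
              x$value, x$n_tracks_used, x$method))
  invisible(x)
}

#' Calcium measures of a single track
#'
#' Computes the calcium-derived per-cell measures: track duration, extreme
#' and median 340:380 values, time of the maximum (first occurrence on
#' plateaus), the number of returns to baseline (R2B: downward crossings of
#' the `(1 + r2b_band) * baseline` level), and the baseline-referenced,
#' duration-normalized area under the curve.
#'
#' @param track one track's table (`t_s`, `ratio`).
#' @param baseline baseline ratio value (scalar or `calcium_baseline`).
#' @param r2b_band one-sided band above baseline defining a return
#'   (default +20%).
#' @param signed_auc if `TRUE`, dips below baseline subtract from the area;
#'   default uses only the positive part, so rises are not cancelled.
#' @return named list: `track_duration_s`, `t_max_s`, `min_ratio`,
#'   `max_ratio`, `median_ratio`, `r2b`, `auc_ratio`.
#' @export
calcium_measures <- function(track, baseline, r2b_band = 0.20,
                             signed_auc = FALSE) {
  b <- baseline_value(baseline)
  r <- track$ratio
  t <- track$t_s
  dur <- max(t) - min(t)
  i_max <- which.max(r)
  level <- (1 + r2b_band) * b
  above <- r > level
  r2b <- sum(above[-length(above)] & !above[-1])
  dev <- if (signed_auc) r - b else pmax(r - b, 0)
  auc <- trapezoid(t, dev) / dur
  list(track_duration_s = dur, t_max_s = t[i_max],
       min_ratio = min(r), max_ratio = max(r), median_ratio = stats::median(r),
       r2b = r2b, auc_ratio = auc)
}

baseline_value <- function(baseline) {
  b <- if (inherits(baseline, "calcium_baseline")) baseline$value else baseline
  if (!is.numeric(b) || length(b) != 1 || b <= 0) stop("baseline must be a positive scalar")
  b
}

trapezoid <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Motility measures of a single track
#'
#' Per-step displacements give the mobile fraction (steps faster than
#' `mobile_speed_threshold`, in um/min), total track length, Euclidean
#' (straight-line) displacement, meandering index (Euclidean / length,
#' defined as 1 for a zero-length track), mean speed (um/s), and — when
#' `t_max_s` is supplied — the percentage of track length accumulated by the
#' time of the calcium maximum (0 for a zero-length track).
#'
#' @param track one track's table (`t_s`, `x_um`, `y_um`).
#' @param mobile_speed_threshold speed cut for the mobile fraction (um/min).
#' @param t_max_s time of maximum 340:380 ratio (s), for
#'   `pct_track_length_at_max`.
#' @return named list: `mobile_fraction`, `track_length_um`, `euclid_um`,
#'   `mi`, `speed_um_s`, `pct_track_length_at_max`.
#' @export
motility_measures <- function(track, mobile_speed_threshold = 2, t_max_s = NULL) {
  if (nrow(track) < 2) stop("a track needs at least 2 samples")
  dx <- diff(track$x_um); dy <- diff(track$y_um); dt <- diff(track$t_s)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  step <- sqrt(dx^2 + dy^2)
  speed_per_min <- step / dt * 60
  len <- sum(step)
  euclid <- sqrt((track$x_um[nrow(track)] - track$x_um[1])^2 +
                 (track$y_um[nrow(track)] - track$y_um[1])^2)
  dur <- track$t_s[nrow(track)] - track$t_s[1]
  pct_at_max <- NA_real_
  if (!is.null(t_max_s)) {
    i <- which(track$t_s == t_max_s)[1]
    if (is.na(i)) stop("t_max_s does not match a track sample time")
    pct_at_max <- if (len == 0) 0 else 100 * sum(step[seq_len(i - 1)]) / len
  }
  list(mobile_fraction = mean(speed_per_min > mobile_speed_threshold),
       track_length_um = len, euclid_um = euclid,
       mi = if (len == 0) 1 else euclid / len,
       speed_um_s = len / dur,
       pct_track_length_at_max = pct_at_max)
}

#' Pre/post ratios of motility measures around the calcium maximum
#'
#' Splits the track at the time of the 340:380 maximum (the sample at the
#' maximum terminates the pre segment and starts the post segment) and
#' forms pre/post ratios of track length, speed, meandering index and
#' Euclidean displacement. A zero post-segment value makes the affected
#' ratio `NA` (undefined), never infinite. Tracks with fewer than
#' `min_points` samples in either segment are flagged `excluded_few_points`.
#'
#' @param track one track's table.
#' @param t_max_s split time (s); must be a sample time of the track.
#' @param min_points minimum samples per segment (default 3).
#' @param mobile_speed_threshold passed through to [motility_measures()].
#' @return named list: `length_ratio`, `speed_ratio`, `mi_ratio`,
#'   `euclid_ratio`, `excluded_few_points`.
#' @export
prepost_ratios <- function(track, t_max_s, min_points = 3,
                           mobile_speed_threshold = 2) {
  i <- which(track$t_s == t_max_s)[1]
  if (is.na(i)) stop("t_max_s does not match a track sample time")
  pre <- track[seq_len(i), , drop = FALSE]
  post <- track[i:nrow(track), , drop = FALSE]
  few <- nrow(pre) < min_points || nrow(post) < min_points
  if (nrow(pre) < 2 || nrow(post) < 2) {
    return(list(length_ratio = NA_real_, speed_ratio = NA_real_,
                mi_ratio = NA_real_, euclid_ratio = NA_real_,
                excluded_few_points = TRUE))
  }
  mp <- motility_measures(pre, mobile_speed_threshold)
  mq <- motility_measures(post, mobile_speed_threshold)
  sratio <- function(a, b) if (is.na(b) || b == 0) NA_real_ else a / b
  list(length_ratio = sratio(mp$track_length_um, mq$track_length_um),
       speed_ratio = sratio(mp$speed_um_s, mq$speed_um_s),
       mi_ratio = sratio(mp$mi, mq$mi),
       euclid_ratio = sratio(mp$euclid_um, mq$euclid_um),
       excluded_few_points = few)
}

#' The thirteen per-cell measures
#'
#' Applies the duration filter, computes (or accepts) the baseline, and
#' returns one row per track with the thirteen calcium/motility measures
#' plus exclusion flags. Tracks failing the duration filter are retained as
#' rows flagged `excluded_short` with `NA` measures; the fewer-than-three-
#' datapoints rule flags only the four pre/post ratio measures' validity
#' (`excluded_few_points`), the other nine measures are still reported.
#'
#' @param tracks track table (may hold many tracks; needs `ratio`).
#' @param baseline baseline value or `calcium_baseline`; computed from the
#'   kept tracks when `NULL`.
#' @param min_duration_s duration filter (s).
#' @param r2b_band,mobile_speed_threshold,min_points,signed_auc passed to
#'   the per-track measure functions.
#' @return data frame with columns `track_id`, the 13 measures
#'   (`mobile_fraction`, `track_duration_s`, `t_max_s`,
#'   `pct_track_length_at_max`, `r2b`, `min_ratio`, `max_ratio`,
#'   `median_ratio`, `auc_ratio`, `length_ratio`, `speed_ratio`, `mi_ratio`,
#'   `euclid_ratio`), flags `excluded_short`, `excluded_few_points`, and the
#'   `baseline` attribute.
#' @export
compute_features <- function(tracks, baseline = NULL, min_duration_s = 300,
                             r2b_band = 0.20, mobile_speed_threshold = 2,
                             min_points = 3, signed_auc = FALSE) {
  parts <- filter_tracks(tracks, min_duration_s)
  if (is.null(baseline)) baseline <- compute_baseline(parts$kept)
  b <- baseline_value(baseline)
  measure_names <- feature_measure_names()
  one <- function(track, short) {
    if (short) {
      row <- as.list(rep(NA_real_, length(measure_names)))
      names(row) <- measure_names
      return(c(list(track_id = track$track_id[1]), row,
               list(excluded_short = TRUE, excluded_few_points = NA)))
    }
    ca <- calcium_measures(track, b, r2b_band, signed_auc)
    mo <- motility_measures(track, mobile_speed_threshold, t_max_s = ca$t_max_s)
    pp <- prepost_ratios(track, ca$t_max_s, min_points, mobile_speed_threshold)
    list(track_id = track$track_id[1],
         mobile_fraction = mo$mobile_fraction,
         track_duration_s = ca$track_duration_s,
         t_max_s = ca$t_max_s,
         pct_track_length_at_max = mo$pct_track_length_at_max,
         r2b = ca$r2b, min_ratio = ca$min_ratio, max_ratio = ca$max_ratio,
         median_ratio = ca$median_ratio, auc_ratio = ca$auc_ratio,
         length_ratio = pp$length_ratio, speed_ratio = pp$speed_ratio,
         mi_ratio = pp$mi_ratio, euclid_ratio = pp$euclid_ratio,
         excluded_short = FALSE,
         excluded_few_points = pp$excluded_few_points)
  }
  rows <- c(
    lapply(split(parts$kept, parts$kept$track_id), one, short = FALSE),
    lapply(split(parts$excluded, parts$excluded$track_id), one, short = TRUE)
  )
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out <- out[order(out$track_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "baseline") <- b
  out
}

feature_measure_names <- function() {
  c("mobile_fraction", "track_duration_s", "t_max_s",
    "pct_track_length_at_max", "r2b", "min_ratio", "max_ratio",
    "median_ratio", "auc_ratio", "length_ratio", "speed_ratio", "mi_ratio",
    "euclid_ratio")
}

#' Match basal control cells to acute signaling cells by onset time
#'
#' Each acute cell (maximum 340:380 at or above the responder threshold) is
#' paired with the basal cell (maximum at or below the threshold) whose time
#' of calcium maximum is closest, without replacement. Acute cells are
#' processed in ascending `t_max_s`; equidistant candidates resolve to the
#' lower track id. Acute cells left without a candidate when the basal pool
#' is exhausted are flagged unmatched (`basal_id` of `NA`). The matching
#' controls for the gradual slowing of the perfusion flow: each pair
#' experiences the same flow history around its split point.
#'
#' @param acute,basal feature tables (need `track_id`, `t_max_s`).
#' @return data frame `acute_id`, `basal_id`, `delta_t_max_s`, `matched`.
#' @export
match_controls <- function(acute, basal) {
  if (nrow(acute) == 0) stop("no acute cells to match")
  acute <- acute[order(acute$t_max_s, acute$track_id), , drop = FALSE]
  avail <- basal[order(basal$track_id), , drop = FALSE]
  out <- data.frame(acute_id = acute$track_id, basal_id = NA_real_,
                    delta_t_max_s = NA_real_, matched = FALSE)
  for (i in seq_len(nrow(acute))) {
    if (nrow(avail) == 0) break
    d <- abs(avail$t_max_s - acute$t_max_s[i])
    j <- which(d == min(d))[1]  # avail sorted by id, so ties pick lower id
    out$basal_id[i] <- avail$track_id[j]
    out$delta_t_max_s[i] <- d[j]
    out$matched[i] <- TRUE
    avail <- avail[-j, , drop = FALSE]
  }
  out
}
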