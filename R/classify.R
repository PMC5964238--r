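#' Classifier parameters for calcium signatures
#'
#' Operational thresholds for the rule-based signature classifier. The
#' published thresholds are the 'high' criteria (onset above 1.5 sustained
#' above 1, or exceeding 2) and the responder threshold of 1; the rise band
#' and spike rejection make the originally visual "rise" judgement
#' operational and are declared defaults, not published values.
#'
#' @param responder_threshold population responder cut on the maximum ratio.
#' @param high_onset onset level of the sustained 'high' rule.
#' @param high_sustain level the trace must stay above after onset.
#' @param high_absolute maximum-ratio level that is 'high' outright.
#' @param rise_band relative band above baseline defining a rise/return
#'   (default +20%, one-sided since calcium excursions are positive).
#' @param spike_max_frames excursions of at most this many consecutive
#'   frames count as sharp spikes, not rises.
#' @param sustain_tolerance_frames dips below `high_sustain` tolerated by
#'   the sustained rule (default 0, strict).
#' @return a `classifier_params` list.
#' @export
classifier_params <- function(responder_threshold = 1.0, high_onset = 1.5,
                              high_sustain = 1.0, high_absolute = 2.0,
                              rise_band = 0.20, spike_max_frames = 2L,
                              sustain_tolerance_frames = 0L) {
  if (!(high_absolute >= high_onset && high_onset >= high_sustain &&
        high_sustain > 0)) {
    stop("need high_absolute >= high_onset >= high_sustain > 0")
  }
  if (rise_band <= 0) stop("rise_band must be > 0")
  structure(list(responder_threshold = responder_threshold,
                 high_onset = high_onset, high_sustain = high_sustain,
                 high_absolute = high_absolute, rise_band = rise_band,
                 spike_max_frames = as.integer(spike_max_frames),
                 sustain_tolerance_frames = as.integer(sustain_tolerance_frames)),
            class = "classifier_params")
}

#' Classify one calcium trace into flat / transient / low / high
#'
#' Deterministic rule order:
#' 1. *flat* — no rise: no excursion above `(1 + rise_band) * baseline`
#'    lasting more than `spike_max_frames` frames;
#' 2. *high* — maximum above `high_absolute`, or a first crossing of
#'    `high_onset` after which every sample stays above `high_sustain`
#'    (allowing at most `sustain_tolerance_frames` below);
#' 3. *transient* — a rise followed by at least one return to the baseline
#'    band;
#' 4. *low* — everything else (a rise that neither returned to baseline nor
#'    met the 'high' criteria).
#'
#' @param trace numeric 340:380 trace (already duration-filtered).
#' @param baseline baseline ratio (scalar or `calcium_baseline`).
#' @param params a [classifier_params()].
#' @return the label (character scalar) with attribute `rule` naming the
#'   rule that fired.
#' @export
classify_signature <- function(trace, baseline, params = classifier_params()) {
  if (length(trace) == 0 || !is.numeric(trace)) stop("empty trace")
  b <- baseline_value(baseline)
  level <- (1 + params$rise_band) * b
  above <- trace > level
  runs <- rle(above)
  rise_runs <- runs$values & runs$lengths > params$spike_max_frames
  if (!any(rise_runs)) {
    return(structure("flat", rule = "no_rise"))
  }
  if (max(trace) > params$high_absolute) {
    return(structure("high", rule = "max_gt_absolute"))
  }
  onset <- which(trace > params$high_onset)[1]
  if (!is.na(onset)) {
    below <- sum(trace[onset:length(trace)] <= params$high_sustain)
    if (below <= params$sustain_tolerance_frames) {
      return(structure("high", rule = "sustained_above"))
    }
  }
  # a qualifying rise run that ends before the trace does has returned
  ends <- cumsum(runs$lengths)
  if (any(rise_runs & ends < length(trace))) {
    return(structure("transient", rule = "return_to_baseline"))
  }
  structure("low", rule = "otherwise")
}

#' Classify every track's trace
#'
#' @param tracks track table with `track_id` and `ratio`.
#' @param baseline baseline ratio (scalar or `calcium_baseline`).
#' @param params a [classifier_params()].
#' @return data frame `track_id`, `label` (factor over the four classes),
#'   `rule_fired`.
#' @export
classify_traces <- function(tracks, baseline, params = classifier_params()) {
  ids <- unique(tracks$track_id)
  labs <- character(length(ids)); rules <- character(length(ids))
  for (k in seq_along(ids)) {
    lab <- classify_signature(tracks$ratio[tracks$track_id == ids[k]],
                              baseline, params)
    labs[k] <- lab
    rules[k] <- attr(lab, "rule")
  }
  data.frame(track_id = ids,
             label = factor(labs, levels = signature_levels()),
             rule_fired = rules)
}

#' Responder counts by condition
#'
#' Counts tracks whose maximum 340:380 ratio reaches the responder threshold
#' (inclusive) versus not, per condition — the population-level 2 x 2 table
#' behind the responder-frequency comparison.
#'
#' @param features feature table with `max_ratio`.
#' @param condition condition tag per row (e.g. `"+sAgs"` / `"-sAgs"`).
#' @param threshold responder threshold on the maximum ratio (default 1).
#' @return 2 x k integer table, rows `above` / `below`.
#' @export
responder_counts <- function(features, condition, threshold = 1.0) {
  ok <- !is.na(features$max_ratio)
  status <- factor(ifelse(features$max_ratio[ok] >= threshold, "above", "below"),
                   levels = c("above", "below"))
  table(status = status, condition = condition[ok])
}

#' Two-sided Fisher's exact test on a 2 x 2 table
#'
#' Exact two-sided p-value by the minimum-likelihood method (the sum over
#' tables with hypergeometric probability at most the observed one), as
#' implemented in `stats::fisher.test`.
#'
#' @param tab 2 x 2 matrix/table of non-negative integer counts.
#' @return list with `p_value` and the `table`.
#' @export
fishers_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2 x 2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a table margin is all zero; the test is undefined")
  }
  list(p_value = stats::fisher.test(tab)$p.value, table = tab)
}

#' Mann-Whitney U test (two-sided)
#'
#' U statistic with midrank ties. The p-value is exact when both groups have
#' at most `exact_max` values and no ties occur; otherwise the tie-corrected
#' normal approximation (with continuity correction) is used.
#'
#' @param a,b numeric value vectors for the two groups.
#' @param exact_max largest per-group size for the exact enumeration.
#' @return list with `U` (for group `a`), `p_value`, `exact`.
#' @export
mann_whitney <- function(a, b, exact_max = 8L) {
  if (length(a) == 0 || length(b) == 0) stop("both groups need at least one value")
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
  list(U = unname(U), p_value = p, exact = exact)
}

#' Signature frequency table per condition
#'
#' @param labels signature labels (character or factor over the four
#'   classes).
#' @param condition condition tag per label; a single tag is recycled.
#' @return matrix of percentages (classes x conditions), each column summing
#'   to 100.
#' @export
signature_frequencies <- function(labels, condition = "all") {
  labels <- factor(as.character(labels), levels = signature_levels())
  if (anyNA(labels)) stop("labels must be among: ",
                          paste(signature_levels(), collapse = ", "))
  if (length(condition) == 1) condition <- rep(condition, length(labels))
  counts <- table(label = labels, condition = condition)
  100 * prop.table(counts, margin = 2)
}
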