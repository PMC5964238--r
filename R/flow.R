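#' Gating thresholds for flow event tables
#'
#' The original gates were placed from compensation controls, not reported
#' numerically; thresholds are therefore explicit configuration. Defaults
#' match the scale of [simulate_flow_events()].
#'
#' @param dapi live/dead cut: events with `DAPI < dapi` are live.
#' @param pkh26,did positive cuts for the two lipophilic membrane dyes
#'   (inclusive: `>=` is positive).
#' @param pulse_width minimum pulse width (exclusive: `>` passes) selecting
#'   conjugate-sized events.
#' @return named list of thresholds.
#' @export
flow_thresholds <- function(dapi = 1000, pkh26 = 1000, did = 1000,
                            pulse_width = 100) {
  list(dapi = dapi, pkh26 = pkh26, did = did, pulse_width = pulse_width)
}

flow_channels <- function() c("PKH26", "DiD", "Fluo2", "DAPI", "pulse_width")

#' Gate a flow event table
#'
#' Nested gates: live = DAPI-negative; conjugate = live and double-positive
#' for both membrane dyes (PKH26+DiD+ quadrant); signal = conjugate with
#' pulse width above the minimum (excluding small double-positive events
#' arising from dye transfer).
#'
#' @param table data frame with columns `PKH26`, `DiD`, `Fluo2`, `DAPI`,
#'   `pulse_width` (one row per event).
#' @param thresholds a [flow_thresholds()].
#' @return list of logical index vectors `live`, `conjugate`, `signal`, plus
#'   `counts`.
#' @export
gate_events <- function(table, thresholds = flow_thresholds()) {
  miss <- setdiff(flow_channels(), names(table))
  if (length(miss)) stop("event table missing channel(s): ",
                         paste(miss, collapse = ", "))
  live <- table$DAPI < thresholds$dapi
  conjugate <- live & table$PKH26 >= thresholds$pkh26 & table$DiD >= thresholds$did
  signal <- conjugate & table$pulse_width > thresholds$pulse_width
  list(live = live, conjugate = conjugate, signal = signal,
       counts = c(events = nrow(table), live = sum(live),
                  conjugate = sum(conjugate), signal = sum(signal)))
}

#' Conjugate frequency (% of live events in the PKH26+DiD+ quadrant)
#'
#' @inheritParams gate_events
#' @return percentage (0-100).
#' @export
conjugate_frequency <- function(table, thresholds = flow_thresholds()) {
  g <- gate_events(table, thresholds)
  if (g$counts["live"] == 0) stop("no live events: conjugate frequency undefined")
  100 * unname(g$counts["conjugate"] / g$counts["live"])
}

#' Calcium signal relative to the ionomycin maximum
#'
#' Mean Fluo-2 fluorescence of gated events in the first acquisition,
#' expressed as a percentage of the same gate in the tandem post-ionomycin
#' acquisition of the same sample.
#'
#' @param pre,post event tables before and after ionomycin addition.
#' @param thresholds a [flow_thresholds()].
#' @param gate which gate the MFI is taken over: `"signal"` (conjugate with
#'   pulse-width selection, the default) or `"conjugate"`.
#' @param mfi `"arithmetic"` (default) or `"geometric"` mean.
#' @return percentage of the ionomycin maximum.
#' @export
relative_calcium <- function(pre, post, thresholds = flow_thresholds(),
                             gate = c("signal", "conjugate"),
                             mfi = c("arithmetic", "geometric")) {
  gate <- match.arg(gate)
  mfi <- match.arg(mfi)
  gp <- gate_events(pre, thresholds)[[gate]]
  gq <- gate_events(post, thresholds)[[gate]]
  if (!any(gp) || !any(gq)) {
    stop("empty '", gate, "' gate in ", if (!any(gp)) "pre" else "post",
         " acquisition: relative calcium undefined")
  }
  avg <- if (mfi == "arithmetic") mean else function(x) exp(mean(log(x)))
  100 * avg(pre$Fluo2[gp]) / avg(post$Fluo2[gq])
}

#' Simulate a pre/post-ionomycin pair of flow event tables
#'
#' Event class counts (dead, conjugate, small-pulse conjugate) are allocated
#' deterministically from the fractions; only the intensities are random.
#' The post-ionomycin table contains the same events with conjugate Fluo-2
#' raised to the ionomycin maximum, so the generated relative calcium equals
#' `relative_level` up to the (shared) sampling of per-event maxima.
#'
#' @param n_events number of events per acquisition.
#' @param dead_frac fraction of DAPI-positive events.
#' @param conjugate_frac fraction of live events that are PKH26+DiD+.
#' @param small_pulse_frac fraction of conjugate events with pulse width
#'   below the selection gate.
#' @param relative_level true pre-ionomycin calcium as a fraction of the
#'   ionomycin maximum.
#' @param fluo2_max mean ionomycin-maximum Fluo-2 intensity.
#' @param cv lognormal coefficient of variation of per-event Fluo-2 maxima.
#' @param thresholds gates the intensities are drawn to respect.
#' @return list with `pre` and `post` event tables (data frames with an
#'   `acquisition` tag) and `truth` (the configured fractions).
#' @export
simulate_flow_events <- function(n_events = 10000L, dead_frac = 0.05,
                                 conjugate_frac = 0.08,
                                 small_pulse_frac = 0.10,
                                 relative_level = 0.25, fluo2_max = 10000,
                                 cv = 0.3, thresholds = flow_thresholds()) {
  for (f in c(dead_frac, conjugate_frac, small_pulse_frac)) {
    if (f < 0 || f > 1) stop("fractions must be in [0, 1]")
  }
  if (relative_level < 0) stop("relative_level must be >= 0")
  n <- as.integer(n_events)
  n_dead <- round(n * dead_frac)
  n_live <- n - n_dead
  n_conj <- round(n_live * conjugate_frac)
  n_small <- round(n_conj * small_pulse_frac)
  dead <- c(rep(TRUE, n_dead), rep(FALSE, n_live))
  conj <- c(rep(FALSE, n_dead), rep(TRUE, n_conj), rep(FALSE, n_live - n_conj))
  small <- c(rep(FALSE, n_dead), rep(TRUE, n_small), rep(FALSE, n - n_dead - n_small))
  neg <- function(m, thr) exp(stats::runif(m, log(thr / 20), log(thr * 0.8)))
  pos <- function(m, thr) exp(stats::runif(m, log(thr * 2), log(thr * 50)))
  tab <- data.frame(
    PKH26 = ifelse(conj, pos(n, thresholds$pkh26), neg(n, thresholds$pkh26)),
    DiD = ifelse(conj, pos(n, thresholds$did), neg(n, thresholds$did)),
    Fluo2 = 0,
    DAPI = ifelse(dead, pos(n, thresholds$dapi), neg(n, thresholds$dapi)),
    pulse_width = ifelse(small, stats::runif(n, 50, thresholds$pulse_width),
                         stats::runif(n, thresholds$pulse_width + 10,
                                      thresholds$pulse_width + 100))
  )
  sdlog <- sqrt(log(1 + cv^2))
  fmax <- fluo2_max * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  base <- 0.02 * fluo2_max * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  pre <- tab; post <- tab
  pre$Fluo2 <- ifelse(conj, relative_level * fmax, base)
  post$Fluo2 <- ifelse(conj, fmax, base)
  pre$acquisition <- "pre"
  post$acquisition <- "post_ionomycin"
  list(pre = pre, post = post,
       truth = list(dead_frac = dead_frac, conjugate_frac = conjugate_frac,
                    small_pulse_frac = small_pulse_frac,
                    relative_level = relative_level))
}
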