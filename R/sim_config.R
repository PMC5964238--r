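#' Simulation configuration for the synthetic co-culture assay
#'
#' The defaults state the imaging world the pipeline was built for: a
#' 470 x 470 um field imaged every 10 s for 20 min (121 frames), containing
#' about 107 T cells (and nominally 198 macrophages) at high density, with
#' single-cell calcium signatures drawn from four archetypes (flat,
#' transient, low, high) and signaling-coupled arrest of motility.
#'
#' @param field_size_um width/height of the imaged field (length-2, um).
#' @param frame_interval_s imaging interval (s).
#' @param n_frames number of frames (121 frames x 10 s ~ 20 min).
#' @param n_tcells,n_mdms cell counts per field.
#' @param mixture named proportions over the four signature classes; must
#'   sum to 1.
#' @param basal_speed_um_min mean crawling speed before signaling onset.
#' @param arrest_speed_um_min mean speed after onset for arresting cells.
#'   The default equals the basal speed: arrested cells are "corralled" —
#'   confined near the onset position with preserved path length — rather
#'   than stopped, which is the behaviour the motility-ratio analysis is
#'   designed to detect.
#' @param turn_sd_rad per-frame heading change sd (persistence; smaller =
#'   straighter paths).
#' @param speed_cv per-step speed coefficient of variation.
#' @param confine_radius_um confinement radius around the onset position for
#'   arrested cells.
#' @param arrest_low_fraction fraction of 'low' cells that arrest (all
#'   'high' cells arrest).
#' @param baseline resting 340:380 ratio.
#' @param onset_range_s uniform window for the signaling onset time.
#' @param high_peak,high_plateau peak and sustained plateau ratio of the
#'   'high' template.
#' @param transient_peak peak ratio of the 'transient' template.
#' @param low_level sustained ratio of the 'low' template.
#' @param rise_s linear rise time from baseline to peak (s).
#' @param transient_decay_tau_s exponential decay time constant of the
#'   transient return to baseline (s).
#' @param high_decay_tau_s decay constant from the high peak to its plateau.
#' @param noise_sd additive Gaussian noise on the ratio trace (ratio units).
#' @param pixel_size_um camera pixel size for rendering (0.92 um gives a
#'   512 x 512 field).
#' @param cell_sigma_um Gaussian footprint sigma of a rendered T cell.
#' @param cell_peak_intensity peak 340-channel emission at ratio 1 (counts).
#' @param background constant background added to both channels (counts).
#' @param poisson_noise,read_noise_sd photon-counting / Gaussian read noise
#'   on rendered images (off by default so unit fixtures are exact).
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated `sim_config` object (list).
#' @export
sim_config <- function(field_size_um = c(470, 470),
                       frame_interval_s = 10,
                       n_frames = 121L,
                       n_tcells = 107L,
                       n_mdms = 198L,
                       mixture = c(flat = 0.63, transient = 0.15,
                                   low = 0.12, high = 0.10),
                       basal_speed_um_min = 15,
                       arrest_speed_um_min = 15,
                       turn_sd_rad = 0.5,
                       speed_cv = 0.4,
                       confine_radius_um = 4,
                       arrest_low_fraction = 0.5,
                       baseline = 0.8,
                       onset_range_s = c(60, 600),
                       high_peak = 2.2,
                       high_plateau = 1.4,
                       transient_peak = 1.3,
                       low_level = 1.35,
                       rise_s = 20,
                       transient_decay_tau_s = 60,
                       high_decay_tau_s = 120,
                       noise_sd = 0.02,
                       pixel_size_um = 0.92,
                       cell_sigma_um = 2.5,
                       cell_peak_intensity = 8000,
                       background = 0,
                       poisson_noise = FALSE,
                       read_noise_sd = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_frames <- as.integer(n_frames)
  cfg$n_tcells <- as.integer(n_tcells)
  cfg$n_mdms <- as.integer(n_mdms)
  cfg$seed <- as.integer(seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

signature_levels <- function() c("flat", "transient", "low", "high")

validate_sim_config <- function(cfg) {
  if (length(cfg$field_size_um) != 2 || any(cfg$field_size_um <= 0)) {
    stop("field_size_um must be two positive numbers")
  }
  if (cfg$frame_interval_s <= 0) stop("frame_interval_s must be > 0")
  if (cfg$n_frames < 2) stop("n_frames must be >= 2")
  if (cfg$n_tcells < 0 || cfg$n_mdms < 0) stop("cell counts must be >= 0")
  mx <- cfg$mixture
  if (is.null(names(mx)) || !setequal(names(mx), signature_levels())) {
    stop("mixture must be named over: ", paste(signature_levels(), collapse = ", "))
  }
  if (any(mx < 0) || abs(sum(mx) - 1) > 1e-9) {
    stop("mixture proportions must be >= 0 and sum to 1")
  }
  if (cfg$pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (cfg$arrest_low_fraction < 0 || cfg$arrest_low_fraction > 1) {
    stop("arrest_low_fraction must be in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %g x %g um field, %d frames @ %g s, %d T cells, seed %d\n",
              x$field_size_um[1], x$field_size_um[2], x$n_frames,
              x$frame_interval_s, x$n_tcells, x$seed))
  cat("  mixture:", paste(sprintf("%s %.2f", names(x$mixture), x$mixture),
                          collapse = ", "), "\n")
  invisible(x)
}

# Deterministic integer split of n by proportions (largest remainder).
allocate_counts <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
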