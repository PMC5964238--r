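#' Run the end-to-end analysis pipeline
#'
#' Executes the stages simulate (or load) -> ratio -> extract -> features ->
#' classify -> match -> mva, writing every stage output under `out_dir`
#' together with a JSON manifest recording the package version, seed,
#' parameter hash and output list. Given the same inputs and seed the run is
#' deterministic and its feature CSV byte-identical. A stage failure aborts
#' with the stage name and cause; outputs of the failed stage keep a
#' `.partial` suffix.
#'
#' @param config a `run_config` (see [read_run_config()]), a `sim_config`,
#'   or a plain list accepted by [read_run_config()]'s schema.
#' @param out_dir output directory (overrides the config's).
#' @return invisible list with the manifest and the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (inherits(config, "sim_config")) {
    config <- run_config_from_list(list(sim = unclass(config), seed = config$seed))
  } else if (!inherits(config, "run_config")) {
    config <- run_config_from_list(config)
  }
  if (!is.null(out_dir)) config$out_dir <- out_dir
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage <- function(name, files, fun) {
    partial <- file.path(config$out_dir, paste0(files, ".partial"))
    final <- file.path(config$out_dir, files)
    res <- tryCatch(fun(partial), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    file.rename(partial, final)
    outputs <<- c(outputs, final)
    res
  }

  # --- simulate / load -------------------------------------------------------
  if (is.null(config$input_tracks)) {
    sim <- stage("simulate", c("tracks.csv", "ground_truth.csv"), function(p) {
      s <- simulate_tracks(config$sim)
      write_tracks(s$tracks, p[1])
      write_tracks(s$truth, p[2])
      s
    })
    tracks <- sim$tracks
  } else {
    tracks <- read_tracks(config$input_tracks)
    sim <- NULL
  }

  # --- ratio stack + trace extraction ---------------------------------------
  if (!is.null(config$input_ch340) || (is.null(config$input_tracks) && config$render)) {
    rs <- stage("ratio", "ratio_summary.json", function(p) {
      if (!is.null(config$input_ch340)) {
        ch340 <- read_tiff(config$input_ch340, as_array = TRUE)
        ch380 <- read_tiff(config$input_ch380, as_array = TRUE)
        px <- config$sim$pixel_size_um
        dt <- config$sim$frame_interval_s
      } else {
        mov <- render_timelapse(tracks, config$sim)
        ch340 <- mov$ch340; ch380 <- mov$ch380
        px <- mov$pixel_size_um; dt <- mov$frame_interval_s
      }
      st <- compute_ratio_stack(ch340, ch380, pixel_size_um = px,
                                frame_interval_s = dt)
      jsonlite::write_json(list(frames = dim(st$ratio)[3],
                                masked_fraction = mean(!st$mask)),
                           p, auto_unbox = TRUE)
      st
    })
    traces <- stage("extract", "traces.csv", function(p) {
      out <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(tr) {
        extract_trace(rs, tr[setdiff(names(tr), c("ratio", "dropped"))],
                      roi_diameter_px = config$roi_diameter_px)
      }))
      rownames(out) <- NULL
      write_tracks(out, p)
      out
    })
    measured <- traces[!traces$dropped, setdiff(names(traces), "dropped")]
  } else {
    # tracks already carry ratio values (simulated traces or tracker export)
    if (!"ratio" %in% names(tracks)) {
      stop("stage 'extract' failed: tracks carry no ratio and no channel stacks were given")
    }
    measured <- tracks
  }

  # --- features --------------------------------------------------------------
  feats <- stage("features", c("features.csv", "baseline.json"), function(p) {
    f <- compute_features(measured)
    write_tracks(f, p[1])
    jsonlite::write_json(list(baseline = attr(f, "baseline")), p[2],
                         auto_unbox = TRUE, digits = NA)
    f
  })
  baseline <- attr(feats, "baseline")

  # --- classification --------------------------------------------------------
  labels <- stage("classify", c("labels.csv", "frequencies.csv"), function(p) {
    kept <- filter_tracks(measured)$kept
    lab <- classify_traces(kept, baseline, config$classifier)
    write_tracks(lab, p[1])
    freq <- signature_frequencies(lab$label)
    utils::write.csv(as.data.frame(freq), p[2], row.names = FALSE)
    lab
  })

  # --- matched controls ------------------------------------------------------
  matching <- stage("match", "matching.csv", function(p) {
    ok <- !feats$excluded_short
    thr <- config$classifier$responder_threshold
    acute <- feats[ok & feats$max_ratio >= thr, ]
    basal <- feats[ok & feats$max_ratio <= thr, ]
    m <- if (nrow(acute) > 0 && nrow(basal) > 0) {
      match_controls(acute, basal)
    } else {
      data.frame(acute_id = numeric(), basal_id = numeric(),
                 delta_t_max_s = numeric(), matched = logical())
    }
    write_tracks(m, p)
    m
  })

  # --- multivariate ----------------------------------------------------------
  mva <- stage("mva", c("lda_summary.json", "pca_loadings.csv"), function(p) {
    ok <- !feats$excluded_short & !feats$excluded_few_points &
      stats::complete.cases(feats[, feature_measure_names()])
    fm <- as.matrix(feats[ok, feature_measure_names()])
    lab <- labels$label[match(feats$track_id[ok], labels$track_id)]
    res <- list(n_obs = nrow(fm))
    if (nrow(fm) >= 8 && nlevels(droplevels(lab)) >= 2 &&
        all(table(droplevels(lab)) >= 2)) {
      sx <- suppressWarnings(scale_features(fm))
      pca <- run_pca(sx)
      lda <- run_lda(sx, droplevels(lab))
      utils::write.csv(data.frame(measure = rownames(pca$loadings),
                                  pca$loadings), p[2], row.names = FALSE)
      res <- c(res, list(
        pca_var_explained = pca$var_explained,
        lda_accuracy_overall = lda$accuracy_overall,
        lda_accuracy_by_class = as.list(lda$accuracy_by_class)))
      res_full <- list(pca = pca, lda = lda)
    } else {
      utils::write.csv(data.frame(), p[2], row.names = FALSE)
      res$note <- "too few complete observations or classes for PCA/LDA"
      res_full <- NULL
    }
    jsonlite::write_json(res, p[1], auto_unbox = TRUE, digits = NA)
    c(res_full, list(summary = res))
  })

  manifest <- list(
    package = "furatrack",
    version = as.character(utils::packageVersion("furatrack")),
    seed = config$seed,
    parameter_hash = config_hash(config),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, tracks = tracks, features = feats,
                 labels = labels, matching = matching, mva = mva,
                 truth = if (!is.null(sim)) sim$truth))
}

# md5 of the canonical JSON serialization of all effective parameters
config_hash <- function(config) {
  eff <- list(sim = unclass(config$sim), classifier = unclass(config$classifier),
              thresholds = config$thresholds, seed = config$seed,
              roi_diameter_px = config$roi_diameter_px, render = config$render,
              input_tracks = config$input_tracks,
              input_ch340 = config$input_ch340, input_ch380 = config$input_ch380)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(eff, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}
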