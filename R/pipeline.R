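# End-to-end pipeline orchestration with a single YAML configuration,
# deterministic seeding and a JSON run manifest.

default_config <- function() {
  list(
    seed = 1,
    paths = list(out_dir = "aeropheno_run"),
    design = list(n_hybrids = 10, rates = c(0, 10, 20, 40, 80, 160), reps = 3),
    geometry = list(rows_per_plot = 2, row_spacing = 0.75, row_length = 4,
                    stations_per_row = 17, plot_gap_x = 0.3, plot_gap_y = 1.0),
    sensor = list(gsd = 0.06, frame_width = 2048, frame_height = 1536,
                  overlap = 0.3, gain = 5e-5),
    scene = list(crown_width = 0.5, margin = 2, rgb_width = 48,
                 rgb_height = 48),
    model = list(),
    processing = list(roi_buffer = 0.2, veg_threshold = "auto",
                      reference_rate = 160,
                      hue_gf_low = 60, hue_ggf_low = 80, hue_high = 180,
                      cv_window = 15, cv_threshold = 25,
                      fieldvar_mask = "vegetation",
                      fieldvar_veg_threshold = 0.3),
    analysis = list(strata_low = c(0, 10), strata_high = c(80, 160),
                    rank_rates = c(0, 10, 20))
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown config key: ", paste0(path, k))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config key ", paste0(path, k), " must be a mapping")
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, rejects unknown keys
#' and range-checks the values.  A missing seed gets the default (1) and a
#' message.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return a complete, validated config list of class \code{pipeline_config}.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (is.null(config$seed)) message("no seed in config; using default seed 1")
  cfg <- merge_config(default_config(), config)
  with(cfg$processing, {
    if (!(0 <= hue_gf_low && hue_gf_low <= hue_ggf_low &&
          hue_ggf_low <= hue_high && hue_high <= 360))
      stop("invalid hue bounds: need 0 <= gf_low <= ggf_low <= high <= 360")
    if (!identical(veg_threshold, "auto") && !identical(veg_threshold, "otsu") &&
        !is.numeric(veg_threshold))
      stop("veg_threshold must be numeric, \"otsu\" or \"auto\"")
  })
  stopifnot(cfg$sensor$gsd > 0, cfg$sensor$overlap >= 0,
            cfg$sensor$overlap < 0.9, cfg$sensor$gain > 0,
            cfg$processing$cv_window >= 3,
            cfg$processing$cv_threshold > 0,
            cfg$design$n_hybrids >= 2, cfg$design$reps >= 1)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

# Deterministic per-stage substream of the root seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

cfg_model <- function(cfg) do.call(response_model, cfg$model)

cfg_geometry <- function(cfg) do.call(plot_geometry, cfg$geometry)

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream artifact ", basename(path),
         "; run stage '", stage, "' first")
  path
}

read_layout_artifacts <- function(out, cfg) {
  plots <- utils::read.csv(need_artifact(file.path(out, "layout_plots.csv"),
                                         "simulate"),
                           stringsAsFactors = FALSE)
  rows <- utils::read.csv(need_artifact(file.path(out, "layout_rows.csv"),
                                        "simulate"),
                          stringsAsFactors = FALSE)
  structure(list(plots = plots, rows = rows, geometry = cfg_geometry(cfg),
                 field_origin = c(0, 0)), class = "trial_layout")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (\code{simulate} -> \code{preprocess} -> \code{extract} -> \code{indices};
#' \code{fieldvar} and \code{analyze} consume earlier outputs), writing every
#' intermediate artifact under \code{paths$out_dir} together with a JSON
#' manifest of parameters, seeds, per-stage timings, warnings and output
#' checksums.  All randomness derives from the root seed through named
#' per-stage substreams, so re-running an identical config reproduces the
#' artifacts bit for bit.
#'
#' @param config a \code{pipeline_config} (or anything
#'   \code{\link{validate_config}} accepts).
#' @param stages character subset of
#'   \code{c("simulate","preprocess","extract","indices","fieldvar","analyze")}.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "preprocess", "extract",
                                    "indices", "fieldvar", "analyze")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  all_stages <- c("simulate", "preprocess", "extract", "indices", "fieldvar",
                  "analyze")
  stages <- all_stages[all_stages %in% match.arg(stages, all_stages,
                                                 several.ok = TRUE)]
  out <- cfg$paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "aeropheno",
                   version = as.character(utils::packageVersion("aeropheno")),
                   seed = cfg$seed, stages = stages, parameters = unclass(cfg),
                   artifacts = list(), timings = list(), warnings = list())
  wlog <- character(0)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    withCallingHandlers(fun(), warning = function(w) {
      wlog <<- c(wlog, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    layout <- generate_layout(cfg$design$n_hybrids, cfg$design$rates,
                              cfg$design$reps, cfg_geometry(cfg),
                              seed = stage_seed(cfg$seed, "layout"))
    model <- cfg_model(cfg)
    truth <- simulate_plot_truth(layout, model,
                                 seed = stage_seed(cfg$seed, "truth"))
    utils::write.csv(layout$plots, file.path(out, "layout_plots.csv"),
                     row.names = FALSE)
    utils::write.csv(layout$rows, file.path(out, "layout_rows.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out, "truth.csv"), row.names = FALSE)
    rend <- render_multispectral(
      layout, truth, gsd = cfg$sensor$gsd,
      frame_size = c(cfg$sensor$frame_width, cfg$sensor$frame_height),
      overlap = cfg$sensor$overlap, crown_width = cfg$scene$crown_width,
      margin = cfg$scene$margin, model = model, gain = cfg$sensor$gain,
      seed = stage_seed(cfg$seed, "render"))
    dir.create(file.path(out, "frames"), showWarnings = FALSE)
    for (i in seq_along(rend$frames))
      write_raster(rend$frames[[i]],
                   file.path(out, "frames", sprintf("frame_%03d.tif", i)),
                   type = "uint16")
    write_raster(rend$truth_raster, file.path(out, "truth_raster.tif"))
    jsonlite::write_json(
      list(gain = as.list(rend$calibration$gain),
           offset = as.list(rend$calibration$offset),
           source = rend$calibration$source),
      file.path(out, "calibration.json"), auto_unbox = TRUE, digits = NA)
    dir.create(file.path(out, "rgb"), showWarnings = FALSE)
    for (i in seq_len(nrow(truth))) {
      img <- render_rgb(truth[i, ],
                        image_size = c(cfg$scene$rgb_width,
                                       cfg$scene$rgb_height),
                        seed = stage_seed(cfg$seed, paste0("rgb", i)))
      png::writePNG(img, file.path(out, "rgb",
                                   paste0(truth$plot_id[i], ".png")))
    }
  })

  if ("preprocess" %in% stages) run_stage("preprocess", function() {
    fdir <- need_artifact(file.path(out, "frames"), "simulate")
    files <- sort(list.files(fdir, pattern = "\\.tif$", full.names = TRUE))
    cal <- jsonlite::read_json(need_artifact(file.path(out, "calibration.json"),
                                             "simulate"),
                               simplifyVector = TRUE)
    model <- calibration_model(gain = unlist(cal$gain),
                               offset = unlist(cal$offset),
                               source = cal$source)
    processed <- lapply(files, function(f) {
      calibrate(demosaic_cfa(read_raster(f)), model)
    })
    mosaic <- mosaic_frames(processed)
    write_raster(mosaic, file.path(out, "field_mosaic.tif"))
  })

  if ("extract" %in% stages) run_stage("extract", function() {
    mosaic <- read_raster(need_artifact(file.path(out, "field_mosaic.tif"),
                                        "preprocess"))
    layout <- read_layout_artifacts(out, cfg)
    vt <- cfg$processing$veg_threshold
    if (identical(vt, "auto")) {
      rois <- auto_rows(mosaic, layout, buffer = cfg$processing$roi_buffer)
      spectra <- extract_spectra(mosaic, rois)
    } else {
      rois <- auto_rows(mosaic, layout, buffer = cfg$processing$roi_buffer)
      rois$entries$veg_threshold <- NULL
      spectra <- extract_spectra(mosaic, rois, veg_rule = vt)
    }
    write_roi(rois, file.path(out, "roi.geojson"))
    utils::write.csv(spectra, file.path(out, "spectra.csv"), row.names = FALSE)
  })

  if ("indices" %in% stages) run_stage("indices", function() {
    spectra <- utils::read.csv(need_artifact(file.path(out, "spectra.csv"),
                                             "extract"),
                               stringsAsFactors = FALSE)
    layout <- read_layout_artifacts(out, cfg)
    rgbdir <- file.path(out, "rgb")
    fractions <- NULL
    if (dir.exists(rgbdir)) {
      pr <- cfg$processing
      fr <- lapply(layout$plots$plot_id, function(pid) {
        f <- file.path(rgbdir, paste0(pid, ".png"))
        if (!file.exists(f))
          return(data.frame(plot_id = pid, gf = NA_real_, ggf = NA_real_))
        gfr <- green_fractions(png::readPNG(f),
                               gf_bounds = c(pr$hue_gf_low, pr$hue_high),
                               ggf_bounds = c(pr$hue_ggf_low, pr$hue_high))
        data.frame(plot_id = pid, gf = gfr$gf, ggf = gfr$ggf)
      })
      fractions <- do.call(rbind, fr)
    }
    idx <- build_index_table(spectra, fractions, layout,
                             reference_rate = cfg$processing$reference_rate)
    utils::write.csv(idx, file.path(out, "indices.csv"), row.names = FALSE)
  })

  if ("fieldvar" %in% stages) run_stage("fieldvar", function() {
    mosaic <- read_raster(need_artifact(file.path(out, "field_mosaic.tif"),
                                        "preprocess"))
    nd <- ndvi_matrix(mosaic)
    if (identical(cfg$processing$fieldvar_mask, "vegetation"))
      nd[nd < cfg$processing$fieldvar_veg_threshold] <- NA
    summ <- summarize_field(nd)
    utils::write.csv(data.frame(mean = summ$mean, min = summ$min,
                                max = summ$max, sd = summ$sd, cv = summ$cv,
                                n = summ$n),
                     file.path(out, "fieldvar_summary.csv"),
                     row.names = FALSE)
    ndg <- geogrid(list(ndvi = nd), x0 = mosaic$transform$x0,
                   y0 = mosaic$transform$y0, gsd = mosaic$transform$gsd)
    cvmap <- variability_map(ndg, window = cfg$processing$cv_window)
    write_raster(cvmap, file.path(out, "local_cv.tif"))
    zones <- flag_zones(cvmap, cfg$processing$cv_threshold)
    write_zones(zones, file.path(out, "zones.geojson"))
  })

  if ("analyze" %in% stages) run_stage("analyze", function() {
    idx <- utils::read.csv(need_artifact(file.path(out, "indices.csv"),
                                         "indices"), stringsAsFactors = FALSE)
    truth <- utils::read.csv(need_artifact(file.path(out, "truth.csv"),
                                           "simulate"),
                             stringsAsFactors = FALSE)
    d <- merge(idx, truth[c("plot_id", "yield")], by = "plot_id")
    bs <- fit_broken_stick(d$n_rate, d$csi)
    utils::write.csv(data.frame(t(coef(bs)), rss = bs$rss,
                                single_line = bs$single_line),
                     file.path(out, "broken_stick.csv"), row.names = FALSE)
    strata <- list(all = NULL, low = cfg$analysis$strata_low,
                   high = cfg$analysis$strata_high)
    cors <- correlate_by_stratum(
      d, pairs = list(c("ndvi", "yield"), c("nsi", "yield"),
                      c("csi", "yield")), strata = strata)
    utils::write.csv(cors, file.path(out, "correlations.csv"),
                     row.names = FALSE)
    ranking <- rank_genotypes(d, rates = cfg$analysis$rank_rates)
    utils::write.csv(ranking, file.path(out, "ranking.csv"),
                     row.names = FALSE)
    rep <- c(
      "aeropheno analysis report",
      "=========================",
      sprintf("plots: %d   reference rate: %g kg/ha", nrow(idx),
              cfg$processing$reference_rate),
      "",
      "Senescence broken-stick response (CSI ~ N rate):",
      if (bs$single_line) "  single-line fallback" else
        sprintf("  breakpoint %g kg/ha; slopes %.4g / %.4g %%/kg; rss %.4g",
                bs$breakpoint, bs$slope_low, bs$slope_high, bs$rss),
      "",
      "Correlations with grain yield:",
      sprintf("  %-6s %-6s r=%6.3f %-3s (n=%d)", cors$var_a, cors$stratum,
              cors$r, cors$stars, cors$n),
      "",
      "Low-N tolerance ranking (mean NSI at low rates, ascending):",
      sprintf("  %2d. %s (%s) mean NSI %.3f", ranking$rank,
              ranking$hybrid_id, ranking$tolerance_class, ranking$mean_nsi))
    writeLines(rep, file.path(out, "report.txt"))
  })

  arts <- list.files(out, recursive = TRUE, full.names = TRUE)
  arts <- arts[basename(arts) != "manifest.json"]
  sums <- tools::md5sum(arts)
  manifest$artifacts <- lapply(seq_along(arts), function(i)
    list(path = sub(paste0("^", out, "/?"), "", arts[i]),
         md5 = unname(sums[i])))
  manifest$warnings <- as.list(wlog)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
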