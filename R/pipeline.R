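#' Configuration-driven pipeline runner
#'
#' Executes any subset of the analysis stages from a single configuration
#' (YAML file or equivalent list): `simulate` (synthetic movie, dwell table,
#' cell images and spike-in counts with ground truth), `localize`, `track`,
#' `kinetics`, `enrich`, and `spikein`. Every stage writes CSV/TIFF artifacts
#' into `out_dir` and the run finishes with a machine-readable
#' `run_log.json` recording the configuration, seed and per-stage
#' input/output counts, so any run is reproducible from its log.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Unknown keys are an error. See [example_run_config()] for the
#'   layout.
#' @param stages Character vector of stages to run, or `"all"`.
#' @param seed Integer seed overriding the config's `seed`; propagated to
#'   every stochastic stage.
#' @param out_dir Output directory overriding the config's `out_dir`.
#' @param verbose Emit progress messages.
#' @return Invisibly, the run log list.
#' @export
run_pipeline <- function(config, stages = "all", seed = NULL, out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config error: file '%s' does not exist", config),
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "out_dir", "simulate", "localize", "track", "kinetics",
             "enrich", "spikein")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop(sprintf("config error: unknown keys: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(seed)) seed <- config$seed %||% 1L
  seed <- as.integer(seed)
  if (is.null(out_dir)) out_dir <- config$out_dir %||% stop(
    "config error: out_dir required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("simulate", "localize", "track", "kinetics", "enrich",
                  "spikein")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop(sprintf("config error: unknown stage(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  # input paths referenced by requested stages must exist up front
  check_inputs(config, stages, out_dir)

  say <- function(...) if (verbose) message(sprintf(...))
  log <- list(seed = seed, out_dir = out_dir, stages = stages,
              config = config, stage_log = list())
  paths <- list(
    movie = file.path(out_dir, "movie.tif"),
    truth = file.path(out_dir, "ground_truth.csv"),
    dwell_sim = file.path(out_dir, "simulated_dwells.csv"),
    locs = file.path(out_dir, "localizations.csv"),
    tracks = file.path(out_dir, "tracks.csv"),
    dwells = file.path(out_dir, "dwells.csv"),
    survival = file.path(out_dir, "survival.csv"),
    fit = file.path(out_dir, "kinetics_summary.csv"),
    scores = file.path(out_dir, "enrichment_scores.csv"),
    cellimg = function(i) file.path(out_dir, sprintf("cell_%02d.tif", i)),
    spike_counts = file.path(out_dir, "spikein_counts.csv"),
    scaling = file.path(out_dir, "spikein_scaling.csv"))

  sim_cfg <- config$simulate %||% list()
  mv_cfg <- NULL

  if ("simulate" %in% stages) {
    say("stage simulate")
    sl <- list()
    if (!is.null(sim_cfg$movie)) {
      mv_cfg <- movie_config_from_list(sim_cfg$movie)
      sim <- simulate_movie(mv_cfg, seed = seed)
      write_frame_stack(sim$stack, paths$movie)
      write_ground_truth(sim$truth, paths$truth)
      sl$movie <- list(n_frames = dim(sim$stack)[3],
                       n_molecules = nrow(sim$truth$molecules),
                       n_renderings = nrow(sim$truth$detections))
    }
    if (!is.null(sim_cfg$dwells)) {
      kc <- do.call(kinetic_config, sim_cfg$dwells$config %||% list())
      dw <- simulate_dwell_times(kc, n = sim_cfg$dwells$n %||% 5000,
                                 seed = seed)
      write.csv(dw, paths$dwell_sim, row.names = FALSE)
      sl$dwells <- list(n = nrow(dw))
    }
    if (!is.null(sim_cfg$cell_images)) {
      for (i in seq_along(sim_cfg$cell_images)) {
        cc <- do.call(cell_image_config, sim_cfg$cell_images[[i]])
        img <- simulate_cell_image(cc, seed = seed + i)
        lim <- max(img$h2b, img$halo, 1)
        tiff::writeTIFF(list(img$h2b / lim, img$halo / lim), paths$cellimg(i),
                        bits.per.sample = 32L)
      }
      sl$cell_images <- list(n = length(sim_cfg$cell_images))
    }
    if (!is.null(sim_cfg$spikein)) {
      sp <- sim_cfg$spikein
      samples <- do.call(rbind, lapply(sp$samples, as.data.frame))
      sc <- spikein_sim_config(samples, total_reads = sp$total_reads %||% 1e6,
                               constant = sp$constant %||% 1e5,
                               reference = sp$reference %||%
                                 samples$sample[samples$condition == "asynchronous"][1],
                               seed = seed)
      counts <- simulate_spikein_counts(sc, seed = seed)
      write.csv(counts, paths$spike_counts, row.names = FALSE)
      sl$spikein <- list(n_samples = nrow(counts))
    }
    log$stage_log$simulate <- sl
  }

  if ("localize" %in% stages) {
    say("stage localize")
    lc <- config$localize %||% list()
    movie_path <- lc$movie %||% paths$movie
    stack <- read_frame_stack(movie_path,
                              frame_interval = lc$frame_interval %||% 0.2,
                              pixel_size = lc$pixel_size %||% 0.16)
    dp <- do.call(detection_params,
                  lc[intersect(names(lc), c("loc_error", "psf_sigma",
                                            "deflation_loops", "window"))])
    locs <- localize_stack(stack, dp)
    write_localizations(locs, paths$locs)
    log$stage_log$localize <- list(n_frames = dim(stack)[3],
                                   n_localizations = nrow(locs))
  }

  if ("track" %in% stages) {
    say("stage track")
    tc <- config$track %||% list()
    locs <- read_localizations(tc$localizations %||% paths$locs)
    tp <- do.call(tracking_params,
                  tc[intersect(names(tc), c("d_max", "max_gaps",
                                            "max_competitors", "radius_factor"))])
    tracks <- link_localizations(locs, tp,
                                 frame_interval = tc$frame_interval %||% 0.2)
    write_tracks(tracks, paths$tracks)
    log$stage_log$track <- list(n_localizations = nrow(locs),
                                n_tracks = length(tracks))
  }

  if ("kinetics" %in% stages) {
    say("stage kinetics")
    kc <- config$kinetics %||% list()
    fi <- kc$frame_interval %||% 0.2
    if (!is.null(kc$dwells) || file.exists(paths$dwell_sim) &&
        is.null(kc$use_tracks)) {
      dw_tab <- read.csv(kc$dwells %||% paths$dwell_sim)
      dw <- dw_tab$dwell
    } else {
      tracks <- read_tracks(kc$tracks %||% paths$tracks)
      dw_tab <- extract_dwells(tracks, fi, kc$n_frames_movie %||% 1000,
                               min_frames = kc$min_frames %||% 3L)
      write.csv(dw_tab, paths$dwells, row.names = FALSE)
      dw <- dw_tab$dwell[!dw_tab$censored]
    }
    curve <- build_survival(dw, min_n = kc$min_n %||% 10L)
    write.csv(data.frame(time = curve$times, survival = curve$survival),
              paths$survival, row.names = FALSE)
    fit <- fit_biexponential(curve)
    row <- data.frame(n_dwells = curve$n, f_fast = fit$f, k_fast = fit$k_fast,
                      k_slow = fit$k_slow, collapsed = fit$collapsed,
                      t0 = fit$t0, t_1pct = time_to_fraction(fit, 0.01))
    if (!is.null(kc$k_h2b)) {
      corr <- correct_photobleach(fit$k_slow, kc$k_h2b)
      row$k_corrected <- corr$k_corrected
      row$residence_time <- corr$residence_time
    }
    write.csv(row, paths$fit, row.names = FALSE)
    log$stage_log$kinetics <- list(n_dwells = curve$n, k_slow = fit$k_slow)
  }

  if ("enrich" %in% stages) {
    say("stage enrich")
    ec <- config$enrich %||% list()
    img_paths <- ec$images %||% {
      n <- length(sim_cfg$cell_images %||% list())
      if (n == 0) stop("config error: enrich stage needs images", call. = FALSE)
      vapply(seq_len(n), paths$cellimg, "")
    }
    rows <- lapply(seq_along(img_paths), function(i) {
      ch <- read_cell_image(img_paths[[i]])
      masks <- segment_masks(ch$h2b, ch$halo,
                             smooth_sigma = ec$smooth_sigma %||% 2,
                             min_area = ec$min_area %||% 50)
      sc <- enrichment_score(ch$halo, masks,
                             background = ec$background %||% 0)
      data.frame(cell = i, score = sc$score,
                 chromatin_mean = sc$chromatin_mean, cell_mean = sc$cell_mean)
    })
    scores <- do.call(rbind, rows)
    write.csv(scores, paths$scores, row.names = FALSE)
    log$stage_log$enrich <- list(n_cells = nrow(scores))
  }

  if ("spikein" %in% stages) {
    say("stage spikein")
    sc_cfg <- config$spikein %||% list()
    counts <- read_spikein_counts(
      sc_cfg$counts %||% paths$spike_counts,
      constant = sc_cfg$constant %||% sim_cfg$spikein$constant,
      reference = sc_cfg$reference %||% sim_cfg$spikein$reference)
    tab <- compute_scaling(counts)
    write.csv(as.data.frame(tab), paths$scaling, row.names = FALSE)
    if (!is.null(sc_cfg$site_counts)) {
      m <- read.csv(sc_cfg$site_counts, check.names = FALSE)
      norm <- normalize_counts(m, tab)
      write.csv(norm, file.path(out_dir, "normalized_counts.csv"),
                row.names = FALSE)
    }
    log$stage_log$spikein <- list(n_samples = nrow(tab))
  }

  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

movie_config_from_list <- function(lst) {
  kin <- do.call(kinetic_config, lst$kinetic %||% list())
  rest <- lst[setdiff(names(lst), "kinetic")]
  do.call(movie_config, c(rest, list(kinetic = kin)))
}

check_inputs <- function(config, stages, out_dir) {
  need <- character()
  if ("localize" %in% stages && !is.null(config$localize$movie))
    need <- c(need, config$localize$movie)
  if ("track" %in% stages && !is.null(config$track$localizations))
    need <- c(need, config$track$localizations)
  if ("kinetics" %in% stages) {
    if (!is.null(config$kinetics$dwells)) need <- c(need, config$kinetics$dwells)
    if (!is.null(config$kinetics$tracks)) need <- c(need, config$kinetics$tracks)
  }
  if ("enrich" %in% stages && !is.null(config$enrich$images))
    need <- c(need, unlist(config$enrich$images))
  if ("spikein" %in% stages) {
    if (!is.null(config$spikein$counts)) need <- c(need, config$spikein$counts)
    if (!is.null(config$spikein$site_counts))
      need <- c(need, config$spikein$site_counts)
  }
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop(sprintf("config error: missing input path(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' A small self-contained example run configuration
#'
#' A configuration whose `all` run completes in seconds: a short low-density
#' movie, a simulated dwell table, two synthetic cells and a four-sample
#' spike-in table.
#'
#' @param out_dir Output directory to embed in the config.
#' @return A named list accepted by [run_pipeline()].
#' @export
example_run_config <- function(out_dir = tempfile("mitodwell_run_")) {
  list(
    seed = 1L,
    out_dir = out_dir,
    simulate = list(
      movie = list(width = 64, height = 64, spot_amplitude = 150,
                   background_sd = 8,
                   kinetic = list(frac_fast = 0.3, k_fast = 1, k_slow = 0.1,
                                  k_bleach = 0.05, n_frames = 60,
                                  n_molecules = 8)),
      dwells = list(n = 2000,
                    config = list(frac_fast = 0.4, k_fast = 1, k_slow = 0.15,
                                  k_bleach = 0.04)),
      cell_images = list(list(chromatin_to_cell_ratio = 2),
                         list(chromatin_to_cell_ratio = 0.7)),
      spikein = list(
        samples = list(
          list(sample = "async_1", condition = "asynchronous", fly_fraction = 0.10),
          list(sample = "mitotic_1", condition = "mitotic", fly_fraction = 0.05),
          list(sample = "async_2", condition = "asynchronous", fly_fraction = 0.11),
          list(sample = "mitotic_2", condition = "mitotic", fly_fraction = 0.06)),
        total_reads = 2e5, constant = 1e5, reference = "async_1")),
    localize = list(),
    track = list(),
    kinetics = list(),
    enrich = list(),
    spikein = list())
}
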