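#' Kinetic configuration for the two-state dwell-time simulator
#'
#' Describes the generative model for bound-molecule dwell times: a mixture of
#' a fast (transient/non-specific) and a slow (specific) dissociating
#' population, observed through single-step photobleaching and frame
#' discretization at the imaging interval.
#'
#' @param frac_fast Fraction of molecules in the fast-dissociating component,
#'   in `[0, 1]`.
#' @param k_fast Fast dissociation rate (1/s). Must satisfy
#'   `k_fast >= k_slow > 0` whenever `frac_fast > 0`.
#' @param k_slow Slow dissociation rate (1/s); must be `> 0`.
#' @param k_bleach Photobleaching rate (1/s); `>= 0`. A bleaching event ends
#'   the observed dwell exactly like an unbinding event.
#' @param frame_interval Time between frames (s). Default 0.2 s (5 Hz).
#' @param n_frames Number of frames in a movie. Default 1000.
#' @param n_molecules Number of molecules rendered per simulated movie.
#' @param seed Integer seed recorded with the configuration.
#' @return A list of class `kinetic_config`.
#' @seealso [simulate_dwell_times()], [movie_config()]
#' @export
kinetic_config <- function(frac_fast = 0, k_fast = 1, k_slow = 0.1,
                           k_bleach = 0, frame_interval = 0.2,
                           n_frames = 1000, n_molecules = 50, seed = 1L) {
  cfg <- list(frac_fast = frac_fast, k_fast = k_fast, k_slow = k_slow,
              k_bleach = k_bleach, frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              n_molecules = as.integer(n_molecules), seed = as.integer(seed))
  validate_kinetic_config(cfg)
  structure(cfg, class = "kinetic_config")
}

validate_kinetic_config <- function(cfg) {
  if (!is.numeric(cfg$frac_fast) || cfg$frac_fast < 0 || cfg$frac_fast > 1)
    stop("invalid kinetic config: frac_fast must be in [0, 1]", call. = FALSE)
  if (!is.numeric(cfg$k_slow) || cfg$k_slow <= 0)
    stop("invalid kinetic config: k_slow must be > 0", call. = FALSE)
  if (cfg$frac_fast > 0 && (!is.numeric(cfg$k_fast) || cfg$k_fast < cfg$k_slow))
    stop("invalid kinetic config: need k_fast >= k_slow > 0 when frac_fast > 0",
         call. = FALSE)
  if (cfg$k_bleach < 0)
    stop("invalid kinetic config: k_bleach must be >= 0", call. = FALSE)
  if (cfg$frame_interval <= 0)
    stop("invalid kinetic config: frame_interval must be > 0", call. = FALSE)
  invisible(cfg)
}

#' Simulate observed dwell times under the two-exponential binding model
#'
#' Each molecule is assigned to the fast component with probability
#' `frac_fast`, draws a bound lifetime from `Exponential(k_component)` and an
#' independent bleaching time from `Exponential(k_bleach)`; the observed dwell
#' is the minimum of the two. When `discretize = TRUE` the dwell is recorded
#' as `floor(dwell / frame_interval)` frame intervals (the track-duration
#' convention: a molecule seen in `n` consecutive frames has duration
#' `(n - 1) * frame_interval`), and dwells spanning fewer than `min_frames`
#' frames are dropped, mimicking the minimum track length a detector can
#' report.
#'
#' @param config A [kinetic_config()].
#' @param n Number of molecules to draw (`>= 1`).
#' @param seed Integer seed; identical seeds give identical output.
#' @param min_frames Minimum number of frames a molecule must span to be
#'   reported (a track needs at least 2 consecutive detections). Set to 0 to
#'   keep every draw.
#' @param discretize If `FALSE`, return continuous dwell times with no frame
#'   discretization or minimum-length filtering (useful for testing the
#'   fitting stage in isolation).
#' @return A data.frame with columns `dwell` (s), `n_frames` (frames spanned;
#'   `NA` when `discretize = FALSE`), `component` (`"fast"` or `"slow"`), and
#'   `bleached` (whether bleaching, not unbinding, ended the observation).
#' @examples
#' d <- simulate_dwell_times(kinetic_config(k_slow = 0.1), n = 1000, seed = 7)
#' mean(d$dwell)
#' @export
simulate_dwell_times <- function(config, n, seed = config$seed,
                                 min_frames = 2L, discretize = TRUE) {
  validate_kinetic_config(config)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  comp <- ifelse(runif(n) < config$frac_fast, "fast", "slow")
  rate <- ifelse(comp == "fast", config$k_fast, config$k_slow)
  life <- rexp(n, rate)
  bleach <- if (config$k_bleach > 0) rexp(n, config$k_bleach) else rep(Inf, n)
  obs <- pmin(life, bleach)
  bleached <- bleach < life
  if (!discretize) {
    return(data.frame(dwell = obs, n_frames = NA_integer_, component = comp,
                      bleached = bleached, stringsAsFactors = FALSE))
  }
  dt <- config$frame_interval
  nfr <- floor(obs / dt) + 1L  # frames spanned; duration = (nfr - 1) * dt
  keep <- nfr >= max(1L, as.integer(min_frames))
  data.frame(dwell = (nfr[keep] - 1L) * dt, n_frames = as.integer(nfr[keep]),
             component = comp[keep], bleached = bleached[keep],
             stringsAsFactors = FALSE)
}

#' Movie configuration for the single-molecule movie simulator
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size Pixel size (um/pixel).
#' @param psf_sigma Gaussian PSF standard deviation (pixels).
#' @param background_mean,background_sd Gaussian camera background (intensity
#'   units).
#' @param spot_amplitude Peak amplitude of a rendered molecule above
#'   background.
#' @param diffusion_free Diffusion coefficient of unbound molecules (um^2/s),
#'   used only for the positions of occasionally detected free molecules.
#' @param p_detect_free Probability per frame that a free (motion-blurred)
#'   molecule still produces a diffraction-limited spot. Free molecules at
#'   200 ms exposure blur into the background, so this is small.
#' @param kinetic A [kinetic_config()] controlling binding/bleaching.
#' @return A list of class `movie_config`.
#' @export
movie_config <- function(width = 128, height = 128, pixel_size = 0.16,
                         psf_sigma = 1.2, background_mean = 100,
                         background_sd = 10, spot_amplitude = 120,
                         diffusion_free = 2, p_detect_free = 0.05,
                         kinetic = kinetic_config()) {
  if (psf_sigma <= 0) stop("invalid movie config: psf_sigma must be > 0", call. = FALSE)
  if (spot_amplitude <= 0) stop("invalid movie config: spot_amplitude must be > 0", call. = FALSE)
  if (p_detect_free < 0 || p_detect_free > 1)
    stop("invalid movie config: p_detect_free must be in [0, 1]", call. = FALSE)
  validate_kinetic_config(kinetic)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, psf_sigma = psf_sigma,
                 background_mean = background_mean, background_sd = background_sd,
                 spot_amplitude = spot_amplitude, diffusion_free = diffusion_free,
                 p_detect_free = p_detect_free, kinetic = kinetic),
            class = "movie_config")
}

#' Construct a frame stack
#'
#' A `frame_stack` is a time-ordered stack of grayscale frames with its
#' physical calibration, the common currency between the simulator, the
#' detector and TIFF i/o.
#'
#' @param frames Numeric array `(rows, cols, frames)` or a list of matrices.
#' @param frame_interval Time between frame starts (s).
#' @param pixel_size Pixel size (um/pixel).
#' @param exposure Exposure time (s); must satisfy
#'   `frame_interval >= exposure > 0`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, frame_interval = 0.2, pixel_size = 0.16,
                        exposure = frame_interval) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  stopifnot(length(dim(frames)) == 3L)
  if (!(frame_interval >= exposure && exposure > 0))
    stop("need frame_interval >= exposure > 0", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size, exposure = exposure),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_stack: %d x %d px, %d frames, %.3g s/frame, %.3g um/px\n",
              d[2], d[1], d[3], x$frame_interval, x$pixel_size))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

# Adds one Gaussian spot (peak amplitude a, sd sigma) to matrix img at
# (x, y) in 0-based pixel-center coordinates. Returns the modified matrix.
add_gaussian_spot <- function(img, x, y, a, sigma) {
  h <- nrow(img); w <- ncol(img)
  half <- ceiling(4 * sigma)
  r0 <- max(0, round(y) - half); r1 <- min(h - 1, round(y) + half)
  c0 <- max(0, round(x) - half); c1 <- min(w - 1, round(x) + half)
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  gy <- exp(-((rows - y)^2) / (2 * sigma^2))
  gx <- exp(-((cols - x)^2) / (2 * sigma^2))
  img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + a * outer(gy, gx)
  img
}

#' Simulate a single-molecule movie with ground truth
#'
#' Bound molecules appear as immobile diffraction-limited Gaussian spots for
#' the duration of their bound interval (ended by unbinding, bleaching or the
#' end of the movie); free molecules diffuse and are rendered only with
#' probability `p_detect_free` per frame. Gaussian camera background is added
#' to every frame. The returned ground truth records every rendered spot, so
#' detection and tracking can be scored exactly.
#'
#' Each molecule binds once, at a uniformly drawn frame; before binding and
#' after unbinding (if unbleached) it is free. Bound positions are strictly
#' immobile; localization error arises only at the measurement stage.
#'
#' @param config A [movie_config()].
#' @param seed Integer seed.
#' @param bind_at_start If `TRUE`, every molecule is already bound at frame 0
#'   (useful for constructing movies of permanently bound spots); otherwise
#'   binding frames are uniform over the movie.
#' @return A list with elements `stack` (a [frame_stack()]), `truth` (list of
#'   `molecules` — one row per molecule with its bound interval, bleach frame
#'   and censoring flag — and `detections` — one row per rendered spot), and
#'   `config`.
#' @export
simulate_movie <- function(config, seed = config$kinetic$seed,
                           bind_at_start = FALSE) {
  stopifnot(inherits(config, "movie_config"))
  set.seed(as.integer(seed))
  kin <- config$kinetic
  nf <- kin$n_frames; dt <- kin$frame_interval
  nm <- kin$n_molecules
  w <- config$width; h <- config$height
  margin <- ceiling(4 * config$psf_sigma) + 1

  if (nm > 0) {
    comp <- ifelse(runif(nm) < kin$frac_fast, "fast", "slow")
    rate <- ifelse(comp == "fast", kin$k_fast, kin$k_slow)
    x0 <- runif(nm, margin, w - 1 - margin)
    y0 <- runif(nm, margin, h - 1 - margin)
    bind_frame <- if (bind_at_start) rep(0L, nm) else
      sample.int(nf, nm, replace = TRUE) - 1L
    life <- rexp(nm, rate)
    bleach <- if (kin$k_bleach > 0) rexp(nm, kin$k_bleach) else rep(Inf, nm)
    end_obs <- pmin(life, bleach)
    last_frame_raw <- bind_frame + floor(end_obs / dt)
    censored <- last_frame_raw >= nf - 1L
    unbind_frame <- pmin(last_frame_raw, nf - 1L)
    bleach_frame <- ifelse(bleach < life, bind_frame + floor(bleach / dt), NA)
    molecules <- data.frame(
      molecule_id = seq_len(nm), component = comp, x_px = x0, y_px = y0,
      bind_frame = as.integer(bind_frame),
      unbind_frame = as.integer(unbind_frame),
      bleach_frame = as.integer(bleach_frame), censored = censored,
      stringsAsFactors = FALSE)
    # nearest-neighbour crowding check on bound positions
    if (nm >= 2) {
      dmat <- as.matrix(stats::dist(cbind(x0, y0)))
      diag(dmat) <- Inf
      if (mean(apply(dmat, 1, min)) < 2 * config$psf_sigma)
        warning("spot density high: mean nearest-neighbour distance < 2*psf_sigma; tracking may be ambiguous")
    }
  } else {
    molecules <- data.frame(molecule_id = integer(), component = character(),
                            x_px = numeric(), y_px = numeric(),
                            bind_frame = integer(), unbind_frame = integer(),
                            bleach_frame = integer(), censored = logical(),
                            stringsAsFactors = FALSE)
  }

  det <- vector("list", nm)
  step_sd <- sqrt(2 * config$diffusion_free * dt) / config$pixel_size
  for (i in seq_len(nm)) {
    m <- molecules[i, ]
    bound_frames <- m$bind_frame:m$unbind_frame
    rec <- data.frame(molecule_id = i, frame = bound_frames,
                      x_px = m$x_px, y_px = m$y_px, state = "bound",
                      stringsAsFactors = FALSE)
    # free-phase detections: before binding, and after unbinding if unbleached
    free_frames <- integer()
    if (m$bind_frame > 0) free_frames <- c(free_frames, 0:(m$bind_frame - 1L))
    if (!m$censored && is.na(m$bleach_frame) && m$unbind_frame < kin$n_frames - 1L)
      free_frames <- c(free_frames, (m$unbind_frame + 1L):(kin$n_frames - 1L))
    if (length(free_frames)) {
      seen <- free_frames[runif(length(free_frames)) < config$p_detect_free]
      if (length(seen)) {
        # diffusive positions: per-frame random walk anchored at the binding
        # site — backward in time before binding, forward after unbinding
        steps_away <- ifelse(seen < m$bind_frame, m$bind_frame - seen,
                             seen - m$unbind_frame)
        fx <- m$x_px + rnorm(length(seen), 0, step_sd * sqrt(steps_away))
        fy <- m$y_px + rnorm(length(seen), 0, step_sd * sqrt(steps_away))
        fx <- pmin(pmax(fx, margin), w - 1 - margin)
        fy <- pmin(pmax(fy, margin), h - 1 - margin)
        rec <- rbind(rec, data.frame(molecule_id = i, frame = seen,
                                     x_px = fx, y_px = fy, state = "free",
                                     stringsAsFactors = FALSE))
      }
    }
    det[[i]] <- rec
  }
  detections <- if (nm > 0) do.call(rbind, det) else
    data.frame(molecule_id = integer(), frame = integer(), x_px = numeric(),
               y_px = numeric(), state = character(), stringsAsFactors = FALSE)
  detections <- detections[order(detections$frame, detections$molecule_id), ,
                           drop = FALSE]
  rownames(detections) <- NULL

  frames <- array(rnorm(h * w * nf, config$background_mean,
                        config$background_sd), dim = c(h, w, nf))
  if (nrow(detections)) {
    by_frame <- split(detections, detections$frame)
    for (fr in names(by_frame)) {
      f <- as.integer(fr)
      sub <- by_frame[[fr]]
      img <- frames[, , f + 1L]
      for (k in seq_len(nrow(sub)))
        img <- add_gaussian_spot(img, sub$x_px[k], sub$y_px[k],
                                 config$spot_amplitude, config$psf_sigma)
      frames[, , f + 1L] <- img
    }
  }
  stack <- frame_stack(frames, frame_interval = dt,
                       pixel_size = config$pixel_size, exposure = dt)
  list(stack = stack,
       truth = list(molecules = molecules, detections = detections),
       config = config)
}

#' Configuration for the synthetic two-channel mitotic cell image
#'
#' The synthetic cell is an ellipse; the condensed mitotic chromatin is a
#' smaller ellipse inside it. The H2B channel is bright only over chromatin.
#' The HaloTag channel has mean `cell_mean * chromatin_to_cell_ratio` over
#' chromatin and a compensating level over the rest of the cell such that the
#' whole-cell mean is exactly `cell_mean`; the true enrichment score is
#' therefore `log2(chromatin_to_cell_ratio)`.
#'
#' @param size `c(rows, cols)` of the image.
#' @param cell_center,cell_axes Center and semi-axes (pixels) of the cell
#'   ellipse.
#' @param chromatin_center,chromatin_axes Center and semi-axes of the
#'   chromatin ellipse; must lie inside the cell.
#' @param cell_mean Whole-cell mean HaloTag intensity.
#' @param chromatin_to_cell_ratio Target ratio of chromatin mean to
#'   whole-cell mean (`> 0`).
#' @param h2b_level H2B channel intensity over chromatin.
#' @param noise_sd Gaussian noise sd added to both channels.
#' @param outside_level Intensity outside the cell (both channels).
#' @param seed Integer seed.
#' @return A list of class `cell_image_config`.
#' @export
cell_image_config <- function(size = c(160, 160), cell_center = c(80, 80),
                              cell_axes = c(60, 50),
                              chromatin_center = c(80, 80),
                              chromatin_axes = c(28, 22),
                              cell_mean = 200, chromatin_to_cell_ratio = 1,
                              h2b_level = 800, noise_sd = 5,
                              outside_level = 10, seed = 1L) {
  if (chromatin_to_cell_ratio <= 0)
    stop("invalid cell image config: chromatin_to_cell_ratio must be > 0",
         call. = FALSE)
  cfg <- structure(list(size = as.integer(size), cell_center = cell_center,
                        cell_axes = cell_axes,
                        chromatin_center = chromatin_center,
                        chromatin_axes = chromatin_axes, cell_mean = cell_mean,
                        chromatin_to_cell_ratio = chromatin_to_cell_ratio,
                        h2b_level = h2b_level, noise_sd = noise_sd,
                        outside_level = outside_level, seed = as.integer(seed)),
                   class = "cell_image_config")
  m <- ellipse_mask(cfg$size, chromatin_center, chromatin_axes)
  cm <- ellipse_mask(cfg$size, cell_center, cell_axes)
  if (any(m & !cm))
    stop("invalid cell image config: chromatin region must lie inside the cell",
         call. = FALSE)
  cfg
}

ellipse_mask <- function(size, center, axes) {
  r <- matrix(seq_len(size[1]), size[1], size[2])
  c <- matrix(seq_len(size[2]), size[1], size[2], byrow = TRUE)
  ((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1
}

#' Simulate a two-channel mitotic cell image with known enrichment
#'
#' @param config A [cell_image_config()].
#' @param seed Integer seed (defaults to the one in `config`).
#' @return A list with `h2b` and `halo` intensity matrices, `masks` (logical
#'   `chromatin` and `cell` matrices — the ground truth), and `true_score`
#'   (`log2(chromatin_to_cell_ratio)`).
#' @export
simulate_cell_image <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cell_image_config"))
  set.seed(as.integer(seed))
  sz <- config$size
  cell <- ellipse_mask(sz, config$cell_center, config$cell_axes)
  chromatin <- ellipse_mask(sz, config$chromatin_center, config$chromatin_axes)
  a_cell <- sum(cell); a_chr <- sum(chromatin)
  ratio <- config$chromatin_to_cell_ratio
  # level on cell outside chromatin so that the whole-cell mean is cell_mean
  rest_level <- config$cell_mean * (a_cell - ratio * a_chr) / (a_cell - a_chr)
  if (rest_level <= 0)
    stop("invalid cell image config: ratio too large for the chromatin area (non-cell remainder would need negative intensity)",
         call. = FALSE)
  halo <- matrix(config$outside_level, sz[1], sz[2])
  halo[cell] <- rest_level
  halo[chromatin] <- config$cell_mean * ratio
  h2b <- matrix(config$outside_level, sz[1], sz[2])
  h2b[chromatin] <- config$h2b_level
  if (config$noise_sd > 0) {
    halo <- halo + matrix(rnorm(prod(sz), 0, config$noise_sd), sz[1], sz[2])
    h2b <- h2b + matrix(rnorm(prod(sz), 0, config$noise_sd), sz[1], sz[2])
  }
  list(h2b = h2b, halo = halo,
       masks = list(chromatin = chromatin, cell = cell),
       true_score = log2(ratio))
}

#' Configuration for synthetic spike-in read counts
#'
#' @param samples A data.frame with columns `sample`, `condition` (each
#'   `"asynchronous"` or `"mitotic"`) and `fly_fraction` (true fraction of
#'   reads aligning to the spike-in genome, in `(0, 1)`).
#' @param total_reads Total reads per sample (scalar or per-sample vector).
#' @param constant Arbitrary scaling constant: 100000 for 10% spike-in,
#'   200000 for 20%.
#' @param reference Name of the asynchronous reference sample whose scaling
#'   is anchored to 1; must appear exactly once in `samples`.
#' @param seed Integer seed.
#' @return A list of class `spikein_sim_config`.
#' @export
spikein_sim_config <- function(samples, total_reads = 1e6, constant = 1e5,
                               reference = samples$sample[samples$condition == "asynchronous"][1],
                               seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("sample", "condition", "fly_fraction") %in% names(samples)))
  if (!all(samples$condition %in% c("asynchronous", "mitotic")))
    stop("invalid spike-in config: condition must be 'asynchronous' or 'mitotic'",
         call. = FALSE)
  if (any(samples$fly_fraction <= 0 | samples$fly_fraction >= 1))
    stop("invalid spike-in config: fly fractions must be in (0, 1)", call. = FALSE)
  if (is.na(reference) || sum(samples$sample == reference) != 1)
    stop("invalid spike-in config: exactly one reference sample required",
         call. = FALSE)
  structure(list(samples = samples,
                 total_reads = rep_len(total_reads, nrow(samples)),
                 constant = constant, reference = reference,
                 seed = as.integer(seed)),
            class = "spikein_sim_config")
}

#' Simulate per-sample spike-in (fly-aligned) read counts
#'
#' Draws each sample's fly-aligned read count from
#' `Binomial(total_reads, fly_fraction)`; with `sampling = FALSE` the
#' expected counts are used deterministically.
#'
#' @param config A [spikein_sim_config()].
#' @param seed Integer seed.
#' @param sampling If `FALSE`, use expected counts (no sampling noise).
#' @return A data.frame (`sample`, `condition`, `fly_reads`) carrying the
#'   scaling `constant` and `reference` sample name as attributes; feed it to
#'   [compute_scaling()].
#' @export
simulate_spikein_counts <- function(config, seed = config$seed, sampling = TRUE) {
  stopifnot(inherits(config, "spikein_sim_config"))
  set.seed(as.integer(seed))
  n <- nrow(config$samples)
  counts <- if (sampling)
    rbinom(n, size = round(config$total_reads), prob = config$samples$fly_fraction)
  else round(config$total_reads * config$samples$fly_fraction)
  out <- data.frame(sample = config$samples$sample,
                    condition = config$samples$condition,
                    fly_reads = as.numeric(counts), stringsAsFactors = FALSE)
  attr(out, "constant") <- config$constant
  attr(out, "reference") <- config$reference
  out
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Intensities are stored as 32-bit floats normalized to `[0, 1]` (divided by
#' the stack maximum), the float-TIFF convention. Detection is invariant to
#' this global rescaling, so the normalization does not affect downstream
#' analysis.
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  scale <- max(stack$frames, 1)
  pages <- lapply(seq_len(dim(stack$frames)[3]),
                  function(i) pmax(stack$frames[, , i], 0) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' @param path TIFF file path.
#' @param frame_interval,pixel_size,exposure Physical calibration to attach
#'   (TIFF carries none).
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_interval = 0.2, pixel_size = 0.16,
                             exposure = frame_interval) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  frame_stack(pages, frame_interval = frame_interval, pixel_size = pixel_size,
              exposure = exposure)
}

#' Write ground-truth spot renderings to CSV
#'
#' @param truth The `truth` element returned by [simulate_movie()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  det <- merge(truth$detections,
               truth$molecules[, c("molecule_id", "component")],
               by = "molecule_id", sort = FALSE)
  det <- det[order(det$frame, det$molecule_id), ]
  write.csv(det[, c("molecule_id", "frame", "x_px", "y_px", "state", "component")],
            path, row.names = FALSE)
  invisible(path)
}
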