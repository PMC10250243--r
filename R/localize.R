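#' Detection parameters for MTT-style spot finding
#'
#' @param loc_error Per-pixel false-positive probability of the detection
#'   test under the background-only null. Default `10^-6.25`, the standard
#'   stringency for slow-tracking single-molecule data.
#' @param psf_sigma Fixed Gaussian PSF standard deviation (pixels); not
#'   fitted per spot (the PSF width is set by the diffraction limit).
#' @param deflation_loops Number of deflation iterations: fitted spots are
#'   subtracted and the residual re-tested to recover overlapping spots.
#' @param window Side of the square fitting window (pixels, odd).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(loc_error = 10^-6.25, psf_sigma = 1.2,
                             deflation_loops = 3L, window = 9L) {
  if (loc_error <= 0 || loc_error >= 1)
    stop("loc_error must be in (0, 1)", call. = FALSE)
  if (deflation_loops < 0) stop("deflation_loops must be >= 0", call. = FALSE)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  structure(list(loc_error = loc_error, psf_sigma = psf_sigma,
                 deflation_loops = as.integer(deflation_loops),
                 window = window),
            class = "detection_params")
}

# Gaussian PSF template over a (2*half+1)^2 window, peak-normalized,
# centered at offset (dy, dx) from the window center.
psf_template <- function(half, sigma, dy = 0, dx = 0) {
  g <- seq(-half, half)
  outer(exp(-(g - dy)^2 / (2 * sigma^2)), exp(-(g - dx)^2 / (2 * sigma^2)))
}

# Matched-filter z statistic image. For each pixel, the least-squares
# amplitude of a centered PSF over (image - bg) is a_hat = (G * I') / sum(G^2);
# under the Gaussian null a_hat ~ N(0, sd^2 / sum(G^2)), so
# z = a_hat * sqrt(sum(G^2)) / sd is standard normal. Computed by convolution.
glrt_z_image <- function(img, bg, noise_sd, sigma) {
  half <- ceiling(3 * sigma)
  g <- psf_template(half, sigma)
  num <- EBImage::filter2(img - bg, g / sum(g^2), boundary = "replicate")
  num * sqrt(sum(g^2)) / noise_sd
}

# Least-squares fit of A * PSF(center) + b on a square window with fixed
# sigma. win is the window matrix; returns NULL on failure.
fit_gaussian_window <- function(win, sigma) {
  half <- (nrow(win) - 1L) / 2L
  idx <- seq(-half, half)
  rss_fun <- function(p) {
    # p = (dy, dx, log A, b)
    mod <- p[4] + exp(p[3]) * psf_template(half, sigma, p[1], p[2])
    sum((win - mod)^2)
  }
  # moment start: brightest pixel
  pk <- which(win == max(win), arr.ind = TRUE)[1, ]
  a0 <- max(win) - median(win)
  if (!is.finite(a0) || a0 <= 0) return(NULL)
  p0 <- c(pk[1] - half - 1, pk[2] - half - 1, log(a0), median(win))
  fit <- tryCatch(optim(p0, rss_fun, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  if (abs(p[1]) > half || abs(p[2]) > half) return(NULL)  # wandered off window
  list(dy = p[1], dx = p[2], amplitude = exp(p[3]), background = p[4],
       rss = fit$value, converged = fit$convergence == 0)
}

#' Detect diffraction-limited spots in one frame
#'
#' Each pixel is tested with a generalized-likelihood-ratio statistic for
#' "Gaussian spot + flat background" against "background only", with the
#' per-frame background mean and noise sd estimated robustly (median / MAD).
#' The threshold is the normal quantile implied by `loc_error` as a per-pixel
#' false-alarm probability. Candidate local maxima are refined by
#' least-squares Gaussian fitting (amplitude, background, sub-pixel center;
#' PSF width fixed), then `deflation_loops` rounds of subtracting fitted
#' spots and re-testing the residual recover overlapping spots. Duplicates
#' within one PSF sigma are merged, keeping the higher test statistic (ties:
#' lower row, then column).
#'
#' @param frame Numeric matrix (one image frame; finite values).
#' @param params A [detection_params()].
#' @return A data.frame with one row per spot: `x_px`, `y_px` (0-based pixel
#'   coordinates, pixel (0,0) = top-left pixel center), `amplitude`,
#'   `background`, `stat`.
#' @export
detect_frame <- function(frame, params = detection_params()) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  empty <- data.frame(x_px = numeric(), y_px = numeric(),
                      amplitude = numeric(), background = numeric(),
                      stat = numeric())
  noise_sd <- mad(frame)
  if (noise_sd == 0) return(empty)  # constant frame: nothing to test
  bg <- median(frame)
  zthr <- qnorm(1 - params$loc_error)
  sigma <- params$psf_sigma
  half_w <- (params$window - 1L) / 2L
  h <- nrow(frame); w <- ncol(frame)
  work <- frame
  spots <- list()
  for (loop in 0:params$deflation_loops) {
    z <- glrt_z_image(work, bg, noise_sd, sigma)
    cand <- which(z > zthr & z == local_max3(z), arr.ind = TRUE)
    if (!nrow(cand)) break
    added <- 0L
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; c <- cand[k, 2]
      if (r - half_w < 1 || r + half_w > h || c - half_w < 1 || c + half_w > w)
        next  # window must fit in frame
      win <- work[(r - half_w):(r + half_w), (c - half_w):(c + half_w)]
      fit <- fit_gaussian_window(win, sigma)
      if (is.null(fit) || !fit$converged || fit$amplitude <= 0) next
      y <- (r - 1) + fit$dy
      x <- (c - 1) + fit$dx
      if (x < 0 || x > w - 1 || y < 0 || y > h - 1) next
      spots[[length(spots) + 1L]] <- data.frame(
        x_px = x, y_px = y, amplitude = fit$amplitude,
        background = fit$background, stat = z[r, c])
      added <- added + 1L
    }
    if (added == 0L || loop == params$deflation_loops) break
    # deflation: subtract everything fitted so far from the original frame
    work <- frame
    for (s in spots)
      work <- add_gaussian_spot(work, s$x_px, s$y_px, -s$amplitude, sigma)
  }
  if (!length(spots)) return(empty)
  out <- do.call(rbind, spots)
  merge_duplicates(out, sigma)
}

# 3x3 neighbourhood maximum (replicated borders), used for local-max tests.
local_max3 <- function(z) {
  mx <- z
  h <- nrow(z); w <- ncol(z)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- z[pmin(pmax(seq_len(h) + dr, 1), h),
                 pmin(pmax(seq_len(w) + dc, 1), w)]
    mx <- pmax(mx, shifted)
  }
  mx
}

# Merge detections closer than sigma: keep the higher test statistic,
# ties broken by lower row then column.
merge_duplicates <- function(spots, sigma) {
  ord <- order(-spots$stat, spots$y_px, spots$x_px)
  spots <- spots[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(spots))
  for (i in seq_len(nrow(spots))) {
    if (!keep[i]) next
    if (i < nrow(spots)) {
      j <- (i + 1):nrow(spots)
      d2 <- (spots$x_px[j] - spots$x_px[i])^2 + (spots$y_px[j] - spots$y_px[i])^2
      keep[j][d2 < sigma^2] <- FALSE
    }
  }
  out <- spots[keep, , drop = FALSE]
  out <- out[order(out$y_px, out$x_px), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Localize spots in every frame of a stack
#'
#' Applies [detect_frame()] independently per frame and converts positions to
#' micrometers via the stack's pixel size.
#'
#' @param stack A [frame_stack()].
#' @param params A [detection_params()].
#' @param progress_every Log a progress message every this many frames
#'   (0 disables).
#' @return A data.frame with columns `frame` (0-based), `x_px`, `y_px`,
#'   `x_um`, `y_um`, `amplitude`, `background`, `stat`.
#' @export
localize_stack <- function(stack, params = detection_params(),
                           progress_every = 0L) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- dim(stack$frames)[3]
  if (nf == 0) stop("empty stack", call. = FALSE)
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    det <- detect_frame(stack$frames[, , f], params)
    if (nrow(det)) det$frame <- f - 1L
    out[[f]] <- det
    if (progress_every > 0 && f %% progress_every == 0)
      message(sprintf("localized frame %d/%d (%d spots)", f, nf, nrow(det)))
  }
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    out <- data.frame(frame = integer(), x_px = numeric(), y_px = numeric(),
                      amplitude = numeric(), background = numeric(),
                      stat = numeric())
  out$x_um <- out$x_px * stack$pixel_size
  out$y_um <- out$y_px * stack$pixel_size
  rownames(out) <- NULL
  out[, c("frame", "x_px", "y_px", "x_um", "y_um", "amplitude", "background",
          "stat")]
}

#' Write / read localization tables
#'
#' CSV columns: `frame` (0-based), `x_um`, `y_um`, `amplitude`, `background`,
#' `stat`. Pixel (0,0) is the top-left pixel center.
#'
#' @param locs Localization data.frame from [localize_stack()].
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_localizations <- function(locs, path) {
  write.csv(locs[, c("frame", "x_um", "y_um", "amplitude", "background", "stat")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_localizations
#' @param pixel_size Pixel size (um/px) used to recover pixel coordinates.
#' @export
read_localizations <- function(path, pixel_size = NULL) {
  locs <- read.csv(path)
  if (!is.null(pixel_size)) {
    locs$x_px <- locs$x_um / pixel_size
    locs$y_px <- locs$y_um / pixel_size
  }
  locs
}
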