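#' Segment whole-cell and chromatin masks from a two-channel cell image
#'
#' The whole-cell mask is the largest connected component of an Otsu
#' threshold applied to the smoothed sum of the two channels; the chromatin
#' mask is an Otsu threshold on the smoothed H2B channel restricted to the
#' cell mask. Both masks are cleaned by hole-filling and removal of small
#' specks, and the chromatin mask is intersected with the cell mask.
#'
#' This automated segmentation stands in for hand-drawn ImageJ regions;
#' hand-drawn masks can be supplied directly to [enrichment_score()] (see
#' [read_roi_masks()]).
#'
#' @param h2b,halo Two registered intensity matrices of equal size.
#' @param smooth_sigma Gaussian smoothing sd (pixels) before thresholding.
#' @param min_area Connected components smaller than this (pixels) are
#'   removed.
#' @return A list of class `region_masks`: logical matrices `chromatin` and
#'   `cell` with `chromatin` a subset of `cell`.
#' @export
segment_masks <- function(h2b, halo, smooth_sigma = 2, min_area = 50) {
  stopifnot(is.matrix(h2b), is.matrix(halo), all(dim(h2b) == dim(halo)),
            all(is.finite(h2b)), all(is.finite(halo)))
  # log intensity for the cell mask: the dim cell body and the bright
  # chromatin then fall on the same side of the Otsu split, so the threshold
  # separates cell from background rather than chromatin from everything
  cell <- threshold_largest(h2b + halo, smooth_sigma, min_area, log_scale = TRUE)
  if (is.null(cell))
    stop("segmentation failure: no cell region found", call. = FALSE)
  chrom <- threshold_largest(h2b, smooth_sigma, min_area, within = cell)
  if (is.null(chrom))
    stop("segmentation failure: no chromatin region found", call. = FALSE)
  chrom <- chrom & cell
  if (!any(chrom))
    stop("segmentation failure: chromatin mask empty after cleaning",
         call. = FALSE)
  structure(list(chromatin = chrom, cell = cell), class = "region_masks")
}

# Otsu threshold of a smoothed image (optionally only over `within` pixels),
# cleaned: fill holes, drop components < min_area, keep largest. NULL if
# nothing survives.
threshold_largest <- function(img, smooth_sigma, min_area, within = NULL,
                              log_scale = FALSE) {
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
  if (log_scale) {
    # normalize before the log so the transform (hence the mask) is exactly
    # invariant to global gain and offset changes
    rg <- range(sm)
    if (diff(rg) <= 0) return(NULL)
    sm <- log((sm - rg[1]) / diff(rg) + 1e-3)
  }
  vals <- if (is.null(within)) sm else sm[within]
  rng <- range(vals)
  if (diff(rng) <= 0) return(NULL)
  scaled <- (sm - rng[1]) / diff(rng)
  scaled[scaled < 0] <- 0; scaled[scaled > 1] <- 1
  thr <- EBImage::otsu(EBImage::Image(if (is.null(within)) scaled
                                      else replace(scaled, !within, 0)),
                       range = c(0, 1))
  mask <- scaled > thr
  if (!is.null(within)) mask <- mask & within
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::fillHull(lab)
  sizes <- table(as.vector(lab))
  sizes <- sizes[names(sizes) != "0"]
  sizes <- sizes[sizes >= min_area]
  if (!length(sizes)) return(NULL)
  keep <- as.integer(names(sizes)[which.max(sizes)])
  as.matrix(lab) == keep
}

#' Chromatin enrichment score of a HaloTag channel
#'
#' The score is `log2(chromatin mean / whole-cell mean)` of the HaloTag
#' channel: 0 for a factor distributed like the cell average, positive for
#' chromosome coating, negative for exclusion from mitotic chromatin.
#'
#' @param halo HaloTag-channel intensity matrix.
#' @param masks A `region_masks` object ([segment_masks()]), or any list with
#'   logical `chromatin` and `cell` matrices.
#' @param background Either a number subtracted from the channel before
#'   averaging, or `"mode"` to estimate it as the intensity mode of the
#'   image. Default 0 (no subtraction).
#' @return A list of class `enrichment_score`: `score`, `chromatin_mean`,
#'   `cell_mean`.
#' @export
enrichment_score <- function(halo, masks, background = 0) {
  stopifnot(is.matrix(halo))
  chrom <- masks$chromatin; cell <- masks$cell
  stopifnot(is.logical(chrom), is.logical(cell), all(dim(chrom) == dim(halo)))
  if (any(chrom & !cell))
    stop("invalid masks: chromatin must lie inside the cell", call. = FALSE)
  if (!any(chrom) || !any(cell))
    stop("invalid masks: empty region", call. = FALSE)
  bg <- if (identical(background, "mode")) image_mode(halo) else background
  cm <- mean(halo[chrom]) - bg
  wm <- mean(halo[cell]) - bg
  if (cm <= 0 || wm <= 0)
    stop(sprintf("undefined score: non-positive mean after background subtraction (chromatin %.3g, cell %.3g)",
                 cm, wm), call. = FALSE)
  structure(list(score = log2(cm / wm), chromatin_mean = cm, cell_mean = wm),
            class = "enrichment_score")
}

#' @export
print.enrichment_score <- function(x, ...) {
  cat(sprintf("chromatin enrichment score: %.3f (chromatin mean %.4g / cell mean %.4g)\n",
              x$score, x$chromatin_mean, x$cell_mean))
  invisible(x)
}

# Intensity mode via kernel density peak.
image_mode <- function(img) {
  d <- density(as.vector(img), n = 512)
  d$x[which.max(d$y)]
}

#' Read hand-drawn region masks from a CSV of pixel coordinates
#'
#' Import path for ROIs exported from ImageJ or similar: a CSV with columns
#' `region` (`"chromatin"` or `"cell"`), `row`, `col` (1-based pixel
#' indices).
#'
#' @param path CSV path.
#' @param dim Image dimensions `c(rows, cols)`.
#' @return A `region_masks` list.
#' @export
read_roi_masks <- function(path, dim) {
  df <- read.csv(path)
  stopifnot(all(c("region", "row", "col") %in% names(df)))
  mk <- function(region) {
    m <- matrix(FALSE, dim[1], dim[2])
    sub <- df[df$region == region, ]
    m[cbind(sub$row, sub$col)] <- TRUE
    m
  }
  structure(list(chromatin = mk("chromatin"), cell = mk("cell")),
            class = "region_masks")
}

#' Compare enrichment scores between constructs
#'
#' Averages per-cell scores within each biological replicate and runs a
#' two-tailed t-test between constructs on those replicate means (never on
#' individual cells); per-cell points are retained for plotting.
#'
#' @param scores A data.frame with columns `construct`, `replicate`, `score`
#'   (one row per cell).
#' @param var_equal Equal-variance t statistic (default) or Welch.
#' @return A list of class `construct_comparison`: `replicate_means`
#'   (construct x replicate), `summary` (per-construct mean/SEM of replicate
#'   means), `pairwise` (data.frame of construct pairs with mean difference
#'   and p-value), `cells` (the input).
#' @export
compare_constructs <- function(scores, var_equal = TRUE) {
  stopifnot(all(c("construct", "replicate", "score") %in% names(scores)))
  agg <- aggregate(score ~ construct + replicate, scores, mean)
  sem <- function(x) if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
  summ <- do.call(rbind, lapply(split(agg, agg$construct), function(d) {
    data.frame(construct = d$construct[1], mean_score = mean(d$score),
               sem = sem(d$score), n_replicates = nrow(d))
  }))
  rownames(summ) <- NULL
  constructs <- unique(agg$construct)
  pw <- NULL
  if (length(constructs) >= 2) {
    pairs <- utils::combn(constructs, 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(p) {
      a <- agg$score[agg$construct == p[1]]
      b <- agg$score[agg$construct == p[2]]
      if (length(a) < 2 || length(b) < 2) {
        data.frame(construct_a = p[1], construct_b = p[2],
                   difference = mean(a) - mean(b), p_value = NA_real_,
                   note = "single replicate: test unavailable")
      } else {
        tt <- t.test(a, b, var.equal = var_equal)
        data.frame(construct_a = p[1], construct_b = p[2],
                   difference = mean(a) - mean(b), p_value = tt$p.value,
                   note = "")
      }
    }))
  }
  structure(list(replicate_means = agg, summary = summ, pairwise = pw,
                 cells = scores),
            class = "construct_comparison")
}

#' @export
print.construct_comparison <- function(x, ...) {
  cat("Chromatin enrichment by construct (replicate-averaged)\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$pairwise)) {
    cat("pairwise two-tailed t-tests on replicate means:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Strip plot of per-cell enrichment scores by construct
#'
#' @param x A `construct_comparison`.
#' @param ... Passed to [plot()].
#' @export
plot.construct_comparison <- function(x, ...) {
  cells <- x$cells
  constructs <- unique(cells$construct)
  at <- seq_along(constructs)
  xpos <- match(cells$construct, constructs) +
    runif(nrow(cells), -0.15, 0.15)
  plot(xpos, cells$score, xaxt = "n", xlab = "", xlim = c(0.5, length(at) + 0.5),
       ylab = "chromatin enrichment score (log2)", pch = 16,
       col = adjustcolor("grey30", 0.6), ...)
  graphics::axis(1, at = at, labels = constructs)
  means <- x$summary$mean_score[match(constructs, x$summary$construct)]
  points(at, means, pch = "-", cex = 4, col = "red3")
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Read a two-channel cell image from TIFF
#'
#' @param path Multi-page TIFF with the two channels as pages, or two paths
#'   (H2B first, Halo second).
#' @param channel_order Page order: `c("h2b", "halo")` by default.
#' @return A list with matrices `h2b` and `halo`.
#' @export
read_cell_image <- function(path, channel_order = c("h2b", "halo")) {
  if (length(path) == 2) {
    pages <- lapply(path, function(p) {
      pg <- tiff::readTIFF(p)
      if (length(dim(pg)) == 3L) pg[, , 1] else pg
    })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  }
  if (length(pages) < 2) stop("need two channels", call. = FALSE)
  setNames(pages[1:2], channel_order)[c("h2b", "halo")]
}
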