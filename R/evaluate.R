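#' Score localizations against simulation ground truth
#'
#' Matches detections to ground-truth renderings frame by frame (greedy
#' nearest-neighbour within `tol_px`) and reports recall, precision and the
#' position RMSE of the matched pairs.
#'
#' @param locs Localization data.frame from [localize_stack()] (needs
#'   `frame`, `x_px`, `y_px`).
#' @param truth The `truth` element of [simulate_movie()].
#' @param tol_px Match tolerance (pixels).
#' @param states Ground-truth states to score against (default `"bound"`:
#'   free-molecule renderings are rare singletons and are excluded from both
#'   sides of the comparison).
#' @return List with `recall`, `precision`, `rmse_px`, `n_true`, `n_det`,
#'   `n_matched`.
#' @export
score_localizations <- function(locs, truth, tol_px = 0.5, states = "bound") {
  gt <- truth$detections[truth$detections$state %in% states, , drop = FALSE]
  n_true <- nrow(gt); n_det <- nrow(locs)
  matched <- 0L; sqerr <- numeric()
  used_det <- rep(FALSE, n_det)
  for (f in unique(gt$frame)) {
    g <- gt[gt$frame == f, , drop = FALSE]
    di <- which(locs$frame == f & !used_det)
    if (!length(di)) next
    for (k in seq_len(nrow(g))) {
      avail <- di[!used_det[di]]
      if (!length(avail)) break
      d2 <- (locs$x_px[avail] - g$x_px[k])^2 + (locs$y_px[avail] - g$y_px[k])^2
      j <- which.min(d2)
      if (d2[j] <= tol_px^2) {
        matched <- matched + 1L
        sqerr <- c(sqerr, d2[j])
        used_det[avail[j]] <- TRUE
      }
    }
  }
  # detections on frames where free spots were rendered shouldn't count as
  # false positives when scoring bound spots only
  if (!identical(states, c("bound", "free"))) {
    free <- truth$detections[!truth$detections$state %in% states, , drop = FALSE]
    fp_excuse <- 0L
    for (k in seq_len(nrow(free))) {
      di <- which(locs$frame == free$frame[k] & !used_det)
      if (!length(di)) next
      d2 <- (locs$x_px[di] - free$x_px[k])^2 + (locs$y_px[di] - free$y_px[k])^2
      j <- which.min(d2)
      if (d2[j] <= tol_px^2) { used_det[di[j]] <- TRUE; fp_excuse <- fp_excuse + 1L }
    }
    n_det <- n_det - fp_excuse
  }
  list(recall = if (n_true) matched / n_true else NA_real_,
       precision = if (n_det) matched / n_det else NA_real_,
       rmse_px = if (length(sqerr)) sqrt(mean(sqerr)) else NA_real_,
       n_true = n_true, n_det = n_det, n_matched = matched)
}

#' Score recovered tracks against ground-truth bound intervals
#'
#' A ground-truth bound interval counts as recovered when exactly one track
#' lies at its position (median distance within `tol_px`), overlaps it in
#' time, and has a duration within `max_frame_error` frames of the true
#' bound duration.
#'
#' @param tracks Track list from [link_localizations()].
#' @param truth The `truth` element of [simulate_movie()].
#' @param pixel_size Pixel size (um/px) used to map track coordinates back
#'   to pixels.
#' @param min_frames Only ground-truth intervals spanning at least this many
#'   frames are scored (shorter ones are below the tracking floor).
#' @param tol_px Position tolerance (pixels).
#' @param max_frame_error Allowed absolute duration error (frames).
#' @return List with `fraction_recovered`, `n_intervals`, `n_recovered`, and
#'   the per-interval detail data.frame.
#' @export
score_track_recovery <- function(tracks, truth, pixel_size,
                                 min_frames = 2L, tol_px = 1,
                                 max_frame_error = 1L) {
  mol <- truth$molecules
  mol$span <- mol$unbind_frame - mol$bind_frame + 1L
  mol <- mol[mol$span >= min_frames, , drop = FALSE]
  if (!nrow(mol))
    return(list(fraction_recovered = NA_real_, n_intervals = 0L,
                n_recovered = 0L, detail = NULL))
  t_x <- vapply(tracks, function(tr) median(tr$x_um) / pixel_size, 1)
  t_y <- vapply(tracks, function(tr) median(tr$y_um) / pixel_size, 1)
  t_start <- vapply(tracks, function(tr) min(tr$frame), 1)
  t_end <- vapply(tracks, function(tr) max(tr$frame), 1)
  detail <- do.call(rbind, lapply(seq_len(nrow(mol)), function(i) {
    m <- mol[i, ]
    near <- which((t_x - m$x_px)^2 + (t_y - m$y_px)^2 <= tol_px^2 &
                    t_end >= m$bind_frame & t_start <= m$unbind_frame)
    ok <- FALSE; dur_err <- NA_integer_
    if (length(near) == 1L) {
      dur_err <- abs((t_end[near] - t_start[near]) -
                       (m$unbind_frame - m$bind_frame))
      ok <- dur_err <= max_frame_error
    }
    data.frame(molecule_id = m$molecule_id, span = m$span,
               n_candidate_tracks = length(near),
               duration_error_frames = dur_err, recovered = ok)
  }))
  list(fraction_recovered = mean(detail$recovered),
       n_intervals = nrow(detail), n_recovered = sum(detail$recovered),
       detail = detail)
}
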