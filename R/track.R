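#' Tracking parameters
#'
#' @param d_max Maximal expected diffusion constant (um^2/s). Default 0.5,
#'   the standard slow-tracking setting for chromatin-bound molecules.
#' @param max_gaps Maximum number of consecutive missing frames a track may
#'   bridge (default 1).
#' @param max_competitors Candidate sources considered per target
#'   localization, nearest first (default 5).
#' @param radius_factor Multiplier on the nominal 2-D diffusion search radius
#'   `sqrt(4 * d_max * dt * (1 + gap))` (default 3, a safety factor).
#' @return A list of class `tracking_params`.
#' @export
tracking_params <- function(d_max = 0.5, max_gaps = 1L, max_competitors = 5L,
                            radius_factor = 3) {
  if (d_max <= 0) stop("d_max must be > 0", call. = FALSE)
  if (max_gaps < 0) stop("max_gaps must be >= 0", call. = FALSE)
  if (max_competitors < 1) stop("max_competitors must be >= 1", call. = FALSE)
  structure(list(d_max = d_max, max_gaps = as.integer(max_gaps),
                 max_competitors = as.integer(max_competitors),
                 radius_factor = radius_factor),
            class = "tracking_params")
}

# Square linear-assignment problem, shortest augmenting path with potentials
# (Jonker-Volgenant style), O(n^3). cost may contain Inf for forbidden pairs
# provided a finite perfect matching exists. Returns, for each row, the
# assigned column.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  if (n == 0) return(integer())
  BIG <- .Machine$double.xmax / 4
  a <- cost
  a[!is.finite(a)] <- BIG
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)      # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i; j0 <- n + 1  # virtual column n+1 holds the new row
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j]) next
        cur <- a[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == n + 1) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0) ans[p[j]] <- j
  ans
}

# Per-frame matching of active track ends (sources) to new localizations
# (targets). cost_ok is a finite cost matrix entry for admissible pairs, Inf
# otherwise; unmatched sources/targets pair with dummies at cost `birth`.
# Returns an integer vector: for each source, the matched target index or NA.
match_frame <- function(cost, birth) {
  ns <- nrow(cost); nt <- ncol(cost)
  if (ns == 0 || nt == 0) return(rep(NA_integer_, ns))
  n <- ns + nt
  big <- matrix(Inf, n, n)
  big[seq_len(ns), seq_len(nt)] <- cost
  for (i in seq_len(ns)) big[i, nt + i] <- birth            # source -> unmatched
  for (j in seq_len(nt)) big[ns + j, j] <- birth            # target -> new track
  big[(ns + 1):n, (nt + 1):n] <- 0                          # dummy-dummy free
  asg <- solve_assignment(big)
  out <- asg[seq_len(ns)]
  out[out > nt] <- NA_integer_
  out
}

#' Link per-frame localizations into tracks
#'
#' Frame-to-frame assignment minimizing total squared displacement among
#' candidate pairs within the diffusion-limited search radius
#' `r = radius_factor * sqrt(4 * d_max * frame_interval * (1 + gap))`, where
#' `gap` is the number of frames a track end has gone undetected. Per target
#' at most `max_competitors` nearest candidate sources are considered; the
#' per-frame assignment is the globally optimal bipartite matching. Track
#' ends persist `max_gaps` frames before terminating; bridged frames are
#' flagged as gaps. Tracks need at least 2 localizations.
#'
#' @param locs Localization data.frame (from [localize_stack()]) with columns
#'   `frame`, `x_um`, `y_um`, sorted by frame.
#' @param params A [tracking_params()].
#' @param frame_interval Time between frames (s).
#' @return A list of tracks; each track is a data.frame with columns `frame`,
#'   `x_um`, `y_um`, `gap` (TRUE for interpolated gap rows) plus attribute
#'   `loc_rows` (row indices of `locs` used).
#' @export
link_localizations <- function(locs, params = tracking_params(),
                               frame_interval = 0.2) {
  if (is.null(locs) || nrow(locs) == 0) return(list())
  locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  by_frame <- split(seq_len(nrow(locs)), locs$frame)

  active <- list()    # each: list(rows, x, y, end_frame)
  done <- list()
  f_min <- min(frames); f_max <- max(frames)
  for (f in f_min:f_max) {
    rows <- by_frame[[as.character(f)]]
    nt <- length(rows)
    # retire tracks whose ends are too old to bridge
    if (length(active)) {
      age <- vapply(active, function(tr) f - tr$end_frame - 1L, 1L)
      retire <- age > params$max_gaps
      done <- c(done, active[retire])
      active <- active[!retire]
    }
    if (nt == 0) next
    tx <- locs$x_um[rows]; ty <- locs$y_um[rows]
    ns <- length(active)
    matched_t <- rep(FALSE, nt)
    if (ns > 0) {
      cost <- matrix(Inf, ns, nt)
      for (i in seq_len(ns)) {
        tr <- active[[i]]
        gap <- f - tr$end_frame - 1L
        r <- params$radius_factor *
          sqrt(4 * params$d_max * frame_interval * (1 + gap))
        d2 <- (tx - tr$x)^2 + (ty - tr$y)^2
        ok <- d2 <= r^2
        cost[i, ok] <- d2[ok]
      }
      # per-target competitor cap: keep the max_competitors nearest sources
      for (j in seq_len(nt)) {
        fin <- which(is.finite(cost[, j]))
        if (length(fin) > params$max_competitors) {
          drop <- fin[order(cost[fin, j])][-seq_len(params$max_competitors)]
          cost[drop, j] <- Inf
        }
      }
      r_max2 <- (params$radius_factor *
                   sqrt(4 * params$d_max * frame_interval *
                          (1 + params$max_gaps)))^2
      asg <- match_frame(cost, birth = r_max2 + 1)
      for (i in seq_len(ns)) {
        j <- asg[i]
        if (!is.na(j) && is.finite(cost[i, j])) {
          tr <- active[[i]]
          tr$rows <- c(tr$rows, rows[j])
          tr$x <- tx[j]; tr$y <- ty[j]; tr$end_frame <- f
          active[[i]] <- tr
          matched_t[j] <- TRUE
        }
      }
    }
    for (j in which(!matched_t)) {
      active[[length(active) + 1L]] <-
        list(rows = rows[j], x = tx[j], y = ty[j], end_frame = f)
    }
  }
  done <- c(done, active)
  done <- Filter(function(tr) length(tr$rows) >= 2L, done)
  # order tracks by start frame then first localization row for determinism
  starts <- vapply(done, function(tr) locs$frame[tr$rows[1]], 1)
  firsts <- vapply(done, function(tr) tr$rows[1], 1)
  done <- done[order(starts, firsts)]
  lapply(seq_along(done), function(i) {
    tr <- done[[i]]
    fr <- locs$frame[tr$rows]
    df <- data.frame(frame = fr, x_um = locs$x_um[tr$rows],
                     y_um = locs$y_um[tr$rows], gap = FALSE)
    # insert gap rows (linear interpolation) for bridged frames
    full <- min(fr):max(fr)
    miss <- setdiff(full, fr)
    if (length(miss)) {
      gx <- approx(fr, df$x_um, xout = miss)$y
      gy <- approx(fr, df$y_um, xout = miss)$y
      df <- rbind(df, data.frame(frame = miss, x_um = gx, y_um = gy, gap = TRUE))
      df <- df[order(df$frame), ]
    }
    rownames(df) <- NULL
    attr(df, "loc_rows") <- tr$rows
    attr(df, "track_id") <- i
    df
  })
}

#' Detect and track a whole movie
#'
#' Runs [localize_stack()] then [link_localizations()] and logs a summary
#' (spot count, track count, track-length distribution).
#'
#' @param stack A [frame_stack()].
#' @param det A [detection_params()].
#' @param trk A [tracking_params()].
#' @param quiet Suppress the summary message.
#' @return The track list from [link_localizations()].
#' @export
track_movie <- function(stack, det = detection_params(),
                        trk = tracking_params(), quiet = FALSE) {
  locs <- localize_stack(stack, det)
  tracks <- link_localizations(locs, trk, stack$frame_interval)
  if (!quiet) {
    lens <- vapply(tracks, nrow, 1L)
    message(sprintf("track_movie: %d localizations -> %d tracks (median length %s frames)",
                    nrow(locs), length(tracks),
                    if (length(lens)) median(lens) else NA))
  }
  tracks
}

#' Write / read track tables
#'
#' CSV columns: `track_id`, `frame` (0-based), `x_um`, `y_um`, `gap_flag`.
#'
#' @param tracks Track list from [link_localizations()].
#' @param path CSV path.
#' @export
write_tracks <- function(tracks, path) {
  if (!length(tracks)) {
    write.csv(data.frame(track_id = integer(), frame = integer(),
                         x_um = numeric(), y_um = numeric(),
                         gap_flag = logical()), path, row.names = FALSE)
    return(invisible(path))
  }
  df <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track_id = i, frame = tr$frame, x_um = tr$x_um,
               y_um = tr$y_um, gap_flag = tr$gap)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$track_id), function(d) {
    out <- data.frame(frame = d$frame, x_um = d$x_um, y_um = d$y_um,
                      gap = as.logical(d$gap_flag))
    rownames(out) <- NULL
    out
  })
}
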