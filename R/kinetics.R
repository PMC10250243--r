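#' Extract dwell records from tracks
#'
#' One record per track of at least `min_frames` detections-spanned frames.
#' Dwell duration follows the track-duration convention
#' `(last frame - first frame) * frame_interval`; gap-bridged frames count as
#' bound time (the molecule is presumed bound throughout a bridged gap).
#' Tracks that reach the movie's final frame are right-censored and flagged;
#' censored records are excluded from survival analysis downstream.
#'
#' @param tracks Track list from [link_localizations()] / [read_tracks()].
#' @param frame_interval Time between frames (s).
#' @param n_frames_movie Number of frames in the movie (for censoring).
#' @param min_frames Minimum spanned frames to keep a track (default 3,
#'   i.e. dwells shorter than two frame intervals are discarded).
#' @param condition,replicate,cell Optional labels attached to every record.
#' @return A data.frame with columns `track_id`, `dwell` (s), `n_frames`,
#'   `censored`, plus any labels.
#' @export
extract_dwells <- function(tracks, frame_interval, n_frames_movie,
                           min_frames = 3L, condition = NA_character_,
                           replicate = NA, cell = NA) {
  if (min_frames < 2) stop("min_frames must be >= 2", call. = FALSE)
  if (!length(tracks))
    return(data.frame(track_id = integer(), dwell = numeric(),
                      n_frames = integer(), censored = logical(),
                      condition = character(), replicate = integer(),
                      cell = integer()))
  rec <- lapply(seq_along(tracks), function(i) {
    fr <- tracks[[i]]$frame
    span <- max(fr) - min(fr) + 1L
    data.frame(track_id = i, dwell = (span - 1L) * frame_interval,
               n_frames = span,
               censored = max(fr) >= n_frames_movie - 1L)
  })
  out <- do.call(rbind, rec)
  out <- out[out$n_frames >= min_frames, , drop = FALSE]
  out$condition <- condition
  out$replicate <- replicate
  out$cell <- cell
  rownames(out) <- NULL
  out
}

#' Build an empirical survival curve from dwell times
#'
#' `S(t) = (number of dwells >= t) / n`, evaluated at each observed dwell
#' duration. By construction `S` at the minimum duration is 1 and the curve
#' is non-increasing. Censored records (if the input is a dwell table) are
#' excluded.
#'
#' @param dwells Numeric vector of dwell times (s), or a data.frame from
#'   [extract_dwells()] (its `censored` rows are dropped).
#' @param min_n Minimum number of usable dwells (default 10).
#' @return An object of class `survival_curve`: list with `times`,
#'   `survival`, `n`, and the raw `dwells` (kept for maximum-likelihood
#'   fitting).
#' @export
build_survival <- function(dwells, min_n = 10L) {
  if (is.data.frame(dwells)) {
    dw <- dwells$dwell[!isTRUE_vec(dwells$censored)]
  } else dw <- as.numeric(dwells)
  dw <- dw[is.finite(dw)]
  if (length(dw) < min_n)
    stop(sprintf("insufficient data: %d uncensored dwells (need >= %d)",
                 length(dw), min_n), call. = FALSE)
  srt <- sort(dw)
  times <- unique(srt)
  n <- length(dw)
  # (# dwells >= t) = n - (# dwells < t), via binary search on the sorted vector
  surv <- (n - findInterval(times, srt, left.open = TRUE)) / n
  structure(list(times = times, survival = surv, n = n, dwells = dw),
            class = "survival_curve")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve: %d dwells, t in [%.3g, %.3g] s\n",
              x$n, min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.survival_curve <- function(x, log = "y", ...) {
  plot(x$times, x$survival, log = log, xlab = "dwell time (s)",
       ylab = "fraction still bound", pch = 16, cex = 0.5, ...)
  invisible(x)
}

biexp_survival <- function(t, f, k_fast, k_slow, t0) {
  f * exp(-k_fast * (t - t0)) + (1 - f) * exp(-k_slow * (t - t0))
}

#' Fit the two-exponential dissociation model to a survival curve
#'
#' Fits \deqn{S(t) = f e^{-k_{fast}(t - t_0)} + (1-f) e^{-k_{slow}(t - t_0)}}
#' with `f` in `[0, 1]` and `k_fast >= k_slow > 0` by least squares on the
#' empirical survival values (default) or by maximum likelihood on the raw
#' dwell times (`method = "mle"`, a cross-check mode). Optimization runs from
#' a grid of log-spaced rate-pair starts; parameters are transformed
#' (logit fraction, log rates with an ordering constraint) so every start is
#' feasible. If the best fit has `k_fast / k_slow < 1.5` or `f` outside
#' `[0.01, 0.99]` the two components are not distinguishable: the model is
#' refit as a single exponential and flagged `collapsed`, with `k_slow`
#' carrying the single rate.
#'
#' The slow component is the apparent dissociation rate `k_off`: the fast
#' component absorbs transient, non-specific binding, and the specific,
#' long-lived interactions the residence time refers to dissociate at the
#' slow rate. See [correct_photobleach()] for the H2B-based bleaching
#' correction.
#'
#' @param curve A [build_survival()] object.
#' @param t0 Origin shift: the minimum resolvable dwell (default: the
#'   curve's first time point).
#' @param method `"ls"` (least squares on survival values) or `"mle"`
#'   (maximum likelihood on raw dwells).
#' @param max_points For `"ls"`, curves with more distinct time points are
#'   thinned to this many (rank-uniform) before fitting; keeps dense
#'   continuous-time curves cheap without changing the fit materially.
#' @param n_starts Number of multi-start rate pairs per fraction start.
#' @return An object of class `biexp_fit` with elements `f`, `k_fast`,
#'   `k_slow`, `rss`, `converged`, `collapsed`, `t0`, `method`, `n`, and the
#'   fitted `curve`. Methods: [print()], [summary()], [coef()], [predict()],
#'   [plot()], [residuals()], [simulate()].
#' @examples
#' set.seed(1)
#' dw <- rexp(2000, 0.2)
#' fit <- fit_biexponential(build_survival(dw), t0 = 0)
#' coef(fit)
#' @export
fit_biexponential <- function(curve, t0 = NULL,
                              method = c("ls", "mle"),
                              max_points = 2000L, n_starts = 4L) {
  stopifnot(inherits(curve, "survival_curve"))
  method <- match.arg(method)
  if (is.null(t0)) t0 <- min(curve$times)
  tt <- curve$times; ss <- curve$survival
  if (method == "ls" && length(tt) > max_points) {
    idx <- unique(round(seq(1, length(tt), length.out = max_points)))
    tt <- tt[idx]; ss <- ss[idx]
  }
  dw <- curve$dwells

  # objective in transformed coordinates:
  # theta = (qlogis(f), log k_slow, log(k_fast/k_slow - 1))
  untrans <- function(th) {
    f <- plogis(th[1]); ks <- exp(th[2]); kf <- ks * (1 + exp(th[3]))
    c(f = f, k_fast = kf, k_slow = ks)
  }
  obj_ls <- function(th) {
    p <- untrans(th)
    sum((ss - biexp_survival(tt, p[1], p[2], p[3], t0))^2)
  }
  obj_mle <- function(th) {
    p <- untrans(th)
    x <- pmax(dw - t0, 0)
    dens <- p[1] * p[2] * exp(-p[2] * x) + (1 - p[1]) * p[3] * exp(-p[3] * x)
    -sum(log(pmax(dens, 1e-300)))
  }
  obj <- if (method == "ls") obj_ls else obj_mle

  # crude single-rate scale from the curve for start placement
  k_scale <- {
    i <- which(ss <= exp(-1))[1]
    if (is.na(i)) 1 / max(tt[length(tt)] - t0, 1e-6) else 1 / max(tt[i] - t0, 1e-6)
  }
  ks_starts <- k_scale * exp(seq(log(0.2), log(1.5), length.out = n_starts))
  ratio_starts <- c(5, 20)
  f_starts <- c(0.3, 0.7)
  best <- NULL
  for (ks in ks_starts) for (rt in ratio_starts) for (f0 in f_starts) {
    th0 <- c(qlogis(f0), log(ks), log(rt - 1))
    fit <- tryCatch(optim(th0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop(sprintf("fit failure: no optimizer start converged (%d points, t0=%g)",
                 length(tt), t0), call. = FALSE)
  p <- untrans(best$par)
  collapsed <- (p["k_fast"] / p["k_slow"] < 1.5) ||
    p["f"] < 0.01 || p["f"] > 0.99
  if (collapsed) {
    # single-exponential refit
    if (method == "ls") {
      sobj <- function(lk) sum((ss - exp(-exp(lk) * (tt - t0)))^2)
    } else {
      sobj <- function(lk) {
        k <- exp(lk); x <- pmax(dw - t0, 0)
        -sum(log(k) - k * x)
      }
    }
    sfit <- optimize(sobj, interval = log(k_scale) + c(-6, 6))
    k1 <- exp(sfit$minimum)
    p <- c(f = 0, k_fast = k1, k_slow = k1)
    rss <- if (method == "ls") sfit$objective else
      sum((ss - exp(-k1 * (tt - t0)))^2)
  } else {
    # relabel so the reported f is the weight of the faster component
    rss <- if (method == "ls") best$value else
      sum((ss - biexp_survival(tt, p["f"], p["k_fast"], p["k_slow"], t0))^2)
  }
  structure(list(f = unname(p["f"]), k_fast = unname(p["k_fast"]),
                 k_slow = unname(p["k_slow"]), rss = unname(rss),
                 converged = TRUE, collapsed = unname(collapsed), t0 = t0,
                 method = method, n = curve$n, curve = curve),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, digits = 4, ...) {
  cat("Two-exponential survival fit",
      if (x$collapsed) "(collapsed to single exponential)", "\n")
  cat(sprintf("  n = %d dwells, t0 = %.3g s, method = %s\n", x$n, x$t0, x$method))
  if (x$collapsed) {
    cat(sprintf("  k = %.*g 1/s\n", digits, x$k_slow))
  } else {
    cat(sprintf("  f(fast) = %.*g, k_fast = %.*g 1/s, k_slow = %.*g 1/s\n",
                digits, x$f, digits, x$k_fast, digits, x$k_slow))
  }
  cat(sprintf("  apparent k_off (slow component) = %.*g 1/s, rss = %.3g\n",
              digits, x$k_slow, x$rss))
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...) {
  c(f = object$f, k_fast = object$k_fast, k_slow = object$k_slow)
}

#' @export
summary.biexp_fit <- function(object, ...) {
  out <- list(fit = object,
              k_apparent = object$k_slow,
              mean_dwell_slow = 1 / object$k_slow,
              t_1pct = time_to_fraction(object, 0.01))
  class(out) <- "summary.biexp_fit"
  out
}

#' @export
print.summary.biexp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  1/k_apparent = %.4g s (uncorrected), time to 1%% bound = %.4g s\n",
              x$mean_dwell_slow, x$t_1pct))
  invisible(x)
}

#' @export
predict.biexp_fit <- function(object, times = object$curve$times, ...) {
  biexp_survival(times, object$f, object$k_fast, object$k_slow, object$t0)
}

#' @export
residuals.biexp_fit <- function(object, ...) {
  object$curve$survival - predict(object, object$curve$times)
}

#' @export
plot.biexp_fit <- function(x, log = "y", ...) {
  plot(x$curve, log = log, ...)
  tt <- seq(min(x$curve$times), max(x$curve$times), length.out = 400)
  lines(tt, predict(x, tt), col = "red3", lwd = 2)
  legend("topright", bty = "n",
         legend = c("empirical", sprintf("fit: k_off = %.3g 1/s", x$k_slow)),
         col = c("black", "red3"), pch = c(16, NA), lty = c(NA, 1))
  invisible(x)
}

#' Simulate dwell times from a fitted two-exponential model
#'
#' @param object A `biexp_fit`.
#' @param nsim Number of dwells to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Numeric vector of `nsim` dwell times (s), shifted by the fit's
#'   `t0`.
#' @export
simulate.biexp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  comp_fast <- runif(nsim) < object$f
  rate <- ifelse(comp_fast, object$k_fast, object$k_slow)
  object$t0 + rexp(nsim, rate)
}

#' Time at which the fitted survival model reaches a given bound fraction
#'
#' Solves `S(t) = p` for the fitted two-exponential model. Collapsed
#' (single-exponential) fits use the closed form
#' `t = t0 + ln(1/p) / k_slow`; otherwise the root is found by bisection to a
#' relative tolerance of 1e-6. The time to 1% bound (`p = 0.01`) is the
#' headline dwell statistic alongside the residence time.
#'
#' @param fit A [fit_biexponential()] object.
#' @param p Target bound fraction, `0 < p <= 1`.
#' @param t0 Origin shift (defaults to the fit's own).
#' @return Time (s).
#' @export
time_to_fraction <- function(fit, p = 0.01, t0 = fit$t0) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (p <= 0 || p > 1) stop("p must be in (0, 1]", call. = FALSE)
  if (p == 1) return(t0)
  if (fit$collapsed || fit$f == 0)
    return(t0 + log(1 / p) / fit$k_slow)
  if (fit$f == 1) return(t0 + log(1 / p) / fit$k_fast)
  g <- function(t) biexp_survival(t, fit$f, fit$k_fast, fit$k_slow, t0) - p
  lo <- t0
  hi <- t0 + log(1 / p) / fit$k_slow  # S(hi) <= p always
  # bisection to relative tolerance 1e-6
  while ((hi - lo) > 1e-6 * max(hi, 1e-12)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Photobleaching correction of an apparent dissociation rate
#'
#' The apparent `k_off` of a chromatin-bound factor is inflated by
#' fluorophore bleaching. Subtracting the apparent `k_off` of an H2B control
#' — which barely exchanges on the imaging timescale, so its spot
#' disappearance rate is essentially the bleaching rate — yields the
#' corrected dissociation rate; its inverse is the residence time.
#'
#' @param k_apparent Apparent `k_off` of the factor (1/s, slow fit
#'   component).
#' @param k_h2b Apparent `k_off` of the H2B-Halo control (1/s).
#' @return List with `k_corrected` (1/s) and `residence_time` (s).
#' @examples
#' correct_photobleach(0.20, 0.05)  # k = 0.15 /s, residence 6.67 s
#' @export
correct_photobleach <- function(k_apparent, k_h2b) {
  if (k_apparent <= 0 || k_h2b < 0)
    stop("rates must be positive", call. = FALSE)
  k <- k_apparent - k_h2b
  if (k <= 0)
    stop(sprintf("correction invalid: k_apparent (%.4g) <= k_h2b (%.4g); the factor appears at least as stable as the H2B control",
                 k_apparent, k_h2b), call. = FALSE)
  list(k_corrected = k, residence_time = 1 / k)
}

#' Summarize and compare kinetic replicates across conditions
#'
#' Takes per-replicate kinetic summaries (typically one per biological
#' replicate per condition) and produces condition means with SEM over
#' replicates — never over cells — the mitosis/interphase ratios of residence
#' time and time-to-1%-bound, and a two-tailed t-test on the replicate means.
#'
#' @param summaries A data.frame with columns `replicate`, `condition`
#'   (`"interphase"` or `"mitosis"`), and any of `k_corrected`,
#'   `residence_time`, `t_1pct`.
#' @param var_equal Use the equal-variance t statistic (default TRUE, the
#'   standard two-tailed t-test); FALSE gives Welch.
#' @return An object of class `condition_comparison`: per-condition
#'   mean/SEM table, `ratio_residence`, `ratio_t1pct`, per-replicate ratios
#'   when replicates pair across conditions, and t-test p-values per metric.
#' @export
summarize_conditions <- function(summaries, var_equal = TRUE) {
  stopifnot(all(c("replicate", "condition") %in% names(summaries)))
  conds <- c("interphase", "mitosis")
  if (!all(summaries$condition %in% conds))
    stop("condition must be 'interphase' or 'mitosis'", call. = FALSE)
  metrics <- intersect(c("k_corrected", "residence_time", "t_1pct"),
                       names(summaries))
  sem <- function(x) if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
  tab <- do.call(rbind, lapply(conds, function(cc) {
    sub <- summaries[summaries$condition == cc, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(condition = cc, metric = m, mean = mean(sub[[m]]),
                 sem = sem(sub[[m]]), n_replicates = nrow(sub))
    }))
  }))
  gv <- function(m, cc) summaries[[m]][summaries$condition == cc]
  ratio_of <- function(m) {
    if (!m %in% metrics) return(NA_real_)
    mean(gv(m, "mitosis")) / mean(gv(m, "interphase"))
  }
  tests <- lapply(setNames(metrics, metrics), function(m) {
    a <- gv(m, "interphase"); b <- gv(m, "mitosis")
    if (length(a) < 2 || length(b) < 2)
      return(list(p = NA_real_, note = "single replicate: test unavailable"))
    tt <- t.test(b, a, var.equal = var_equal)
    list(p = tt$p.value, estimate = unname(diff(rev(tt$estimate))), note = NULL)
  })
  per_rep <- NULL
  reps_i <- summaries$replicate[summaries$condition == "interphase"]
  reps_m <- summaries$replicate[summaries$condition == "mitosis"]
  paired <- intersect(reps_i, reps_m)
  if (length(paired) && "residence_time" %in% metrics) {
    per_rep <- vapply(paired, function(r) {
      summaries$residence_time[summaries$condition == "mitosis" &
                                 summaries$replicate == r][1] /
        summaries$residence_time[summaries$condition == "interphase" &
                                   summaries$replicate == r][1]
    }, 1)
    names(per_rep) <- paired
  }
  structure(list(table = tab,
                 ratio_residence = ratio_of("residence_time"),
                 ratio_t1pct = ratio_of("t_1pct"),
                 per_replicate_ratio = per_rep,
                 tests = tests),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("Condition comparison (replicate-level)\n")
  print(x$table, row.names = FALSE)
  if (is.finite(x$ratio_residence))
    cat(sprintf("mitosis / interphase residence-time ratio: %.3f\n",
                x$ratio_residence))
  if (is.finite(x$ratio_t1pct))
    cat(sprintf("mitosis / interphase time-to-1%% ratio:     %.3f\n",
                x$ratio_t1pct))
  for (m in names(x$tests)) {
    p <- x$tests[[m]]$p
    cat(sprintf("t-test (%s): p = %s\n", m,
                if (is.na(p)) x$tests[[m]]$note else format.pval(p, digits = 3)))
  }
  invisible(x)
}

#' One-call kinetic summary for a replicate
#'
#' Builds the survival curve, fits the two-exponential model, applies the
#' H2B photobleaching correction, and returns the replicate-level summary
#' row used by [summarize_conditions()].
#'
#' @param dwells Dwell vector or table for the factor.
#' @param k_h2b Apparent `k_off` of the matched H2B control (1/s).
#' @param condition,replicate Labels for the output row.
#' @param ... Passed to [fit_biexponential()].
#' @return A one-row data.frame: `replicate`, `condition`, `k_apparent`,
#'   `k_h2b`, `k_corrected`, `residence_time`, `t_1pct`.
#' @export
kinetic_summary <- function(dwells, k_h2b, condition = NA_character_,
                            replicate = NA, ...) {
  fit <- fit_biexponential(build_survival(dwells), ...)
  corr <- correct_photobleach(fit$k_slow, k_h2b)
  data.frame(replicate = replicate, condition = condition,
             k_apparent = fit$k_slow, k_h2b = k_h2b,
             k_corrected = corr$k_corrected,
             residence_time = corr$residence_time,
             t_1pct = time_to_fraction(fit, 0.01))
}
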