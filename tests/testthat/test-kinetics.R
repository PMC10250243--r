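make_track <- function(frames) data.frame(frame = frames, x_um = 1, y_um = 1,
                                          gap = FALSE)

test_that("dwell extraction applies the duration convention, threshold and censoring", {
  tracks <- list(make_track(10:30),        # 4.0 s at 5 Hz
                 make_track(0:1),          # 2 frames: below min_frames = 3
                 make_track(95:99))        # reaches the final frame: censored
  dw <- extract_dwells(tracks, frame_interval = 0.2, n_frames_movie = 100,
                       min_frames = 3)
  expect_identical(nrow(dw), 2L)
  expect_equal(dw$dwell[dw$track_id == 1], 4.0)
  expect_false(dw$censored[dw$track_id == 1])
  expect_true(dw$censored[dw$track_id == 3])
  # censored records are excluded from the survival input
  expect_error(build_survival(dw, min_n = 2), "insufficient data")
  expect_error(extract_dwells(tracks, 0.2, 100, min_frames = 1), "min_frames")
})

test_that("survival curves match hand counts and the Glivenko-Cantelli limit", {
  s <- build_survival(c(0.4, 0.4, 0.8, 1.2), min_n = 4)
  expect_equal(s$times, c(0.4, 0.8, 1.2))
  expect_equal(s$survival, c(1, 0.5, 0.25))
  # all dwells equal: a single-step curve
  s1 <- build_survival(rep(2, 12))
  expect_identical(length(s1$times), 1L)
  expect_equal(s1$survival, 1)
  # 1e5 exponential draws: sup |S_emp - exp(-0.2 t)| < 0.01
  set.seed(601)
  dw <- rexp(1e5, 0.2)
  se <- build_survival(dw)
  expect_lt(max(abs(se$survival - exp(-0.2 * se$times))), 0.01)
  expect_true(all(diff(se$survival) <= 0))
  expect_equal(se$survival[1], 1)
  expect_error(build_survival(rexp(5, 1)), "insufficient data")
})

test_that("two-exponential fit recovers mixture parameters and collapses on pure decay", {
  cfg <- kinetic_config(frac_fast = 0.5, k_fast = 1, k_slow = 0.1)
  d <- simulate_dwell_times(cfg, n = 1e5, seed = 602, discretize = FALSE)
  fit <- fit_biexponential(build_survival(d$dwell), t0 = 0)
  expect_false(fit$collapsed)
  expect_lt(abs(fit$f - 0.5) / 0.5, 0.05)
  expect_lt(abs(fit$k_fast - 1) / 1, 0.05)
  expect_lt(abs(fit$k_slow - 0.1) / 0.1, 0.05)
  # pure single exponential: collapsed, rate within 3%
  set.seed(603)
  fit1 <- fit_biexponential(build_survival(rexp(5e4, 0.2)), t0 = 0)
  expect_true(fit1$collapsed)
  expect_lt(abs(fit1$k_slow - 0.2) / 0.2, 0.03)
  # f = 0 reduces the model to a single exponential analytically
  expect_equal(mitodwell:::biexp_survival(3, 0, 5, 0.2, 0), exp(-0.2 * 3))
})

test_that("maximum-likelihood mode cross-checks the least-squares fit", {
  cfg <- kinetic_config(frac_fast = 0.4, k_fast = 0.8, k_slow = 0.08)
  d <- simulate_dwell_times(cfg, n = 3e4, seed = 604, discretize = FALSE)
  curve <- build_survival(d$dwell)
  ls <- fit_biexponential(curve, t0 = 0, method = "ls")
  ml <- fit_biexponential(curve, t0 = 0, method = "mle")
  expect_lt(abs(ls$k_slow - ml$k_slow) / ml$k_slow, 0.05)
  expect_lt(abs(ls$k_fast - ml$k_fast) / ml$k_fast, 0.10)
})

test_that("fitting is invariant to uniform time-unit rescaling", {
  cfg <- kinetic_config(frac_fast = 0.5, k_fast = 1, k_slow = 0.1)
  d <- simulate_dwell_times(cfg, n = 2e4, seed = 605, discretize = FALSE)
  f1 <- fit_biexponential(build_survival(d$dwell), t0 = 0)
  f2 <- fit_biexponential(build_survival(d$dwell * 10), t0 = 0)  # e.g. ds -> s
  expect_equal(f2$k_slow * 10, f1$k_slow, tolerance = 0.02)
  expect_equal(f2$k_fast * 10, f1$k_fast, tolerance = 0.02)
  expect_equal(f2$f, f1$f, tolerance = 0.02)
})

test_that("time_to_fraction: closed form, boundary, monotonicity, grid oracle", {
  col <- structure(list(f = 0, k_fast = 0.2, k_slow = 0.2, collapsed = TRUE,
                        t0 = 0), class = "biexp_fit")
  expect_equal(time_to_fraction(col, 0.01), log(100) / 0.2, tolerance = 1e-9)
  expect_equal(time_to_fraction(col, 1), 0)
  fit <- structure(list(f = 0.5, k_fast = 1, k_slow = 0.1, collapsed = FALSE,
                        t0 = 0), class = "biexp_fit")
  # dense-grid oracle for the bisection root
  grid <- seq(0, log(100) / 0.1, by = 1e-4)
  sv <- mitodwell:::biexp_survival(grid, 0.5, 1, 0.1, 0)
  t_grid <- grid[which(sv <= 0.01)[1]]
  expect_lt(abs(time_to_fraction(fit, 0.01) - t_grid), 1e-4)
  # strictly decreasing in p
  ps <- c(0.5, 0.1, 0.05, 0.01)
  ts <- vapply(ps, function(p) time_to_fraction(fit, p), 1)
  expect_true(all(diff(ts) > 0))
  expect_error(time_to_fraction(fit, 0), "p must be")
})

test_that("photobleach correction subtracts the H2B rate and rejects impossible input", {
  corr <- correct_photobleach(0.20, 0.05)
  expect_equal(corr$k_corrected, 0.15)
  expect_equal(corr$residence_time, 1 / 0.15)
  expect_equal(corr$residence_time * corr$k_corrected, 1)
  expect_equal(correct_photobleach(0.2, 0)$residence_time, 5)
  expect_error(correct_photobleach(0.04, 0.05), "correction invalid")
})

test_that("condition summary reproduces hand-computed means, SEMs and ratios", {
  df <- data.frame(replicate = rep(1:3, 2),
                   condition = rep(c("interphase", "mitosis"), each = 3),
                   residence_time = c(20, 18, 19, 8, 9, 7))
  cmp <- summarize_conditions(df)
  expect_equal(cmp$ratio_residence, 8 / 19)
  tab <- cmp$table
  expect_equal(tab$mean[tab$condition == "interphase"], 19)
  expect_equal(tab$sem[tab$condition == "interphase"], sd(c(20, 18, 19)) / sqrt(3))
  expect_equal(tab$sem[tab$condition == "mitosis"], 1 / sqrt(3))
  expect_equal(unname(cmp$per_replicate_ratio), c(8 / 20, 9 / 18, 7 / 19))
  expect_lt(cmp$tests$residence_time$p, 0.01)
  # identical conditions: ratio 1, p ~ 1 (needs unequal variance guard off)
  df2 <- data.frame(replicate = rep(1:3, 2),
                    condition = rep(c("interphase", "mitosis"), each = 3),
                    residence_time = rep(c(10, 11, 12), 2))
  cmp2 <- summarize_conditions(df2)
  expect_equal(cmp2$ratio_residence, 1)
  expect_gt(cmp2$tests$residence_time$p, 0.99)
  # single replicate: means reported, test flagged unavailable
  df1 <- df[c(1, 4), ]
  cmp1 <- summarize_conditions(df1)
  expect_true(is.na(cmp1$tests$residence_time$p))
  expect_match(cmp1$tests$residence_time$note, "unavailable")
})

test_that("biexp_fit methods are coherent with the fitted model", {
  set.seed(606)
  d <- simulate_dwell_times(kinetic_config(frac_fast = 0.5, k_fast = 1,
                                           k_slow = 0.1),
                            n = 2e4, seed = 607, discretize = FALSE)
  fit <- fit_biexponential(build_survival(d$dwell), t0 = 0)
  expect_named(coef(fit), c("f", "k_fast", "k_slow"))
  expect_equal(predict(fit, fit$t0), 1)
  expect_lt(mean(abs(residuals(fit))), 0.01)
  # simulate() round-trip: refitting simulated dwells recovers the model
  dw2 <- simulate(fit, nsim = 5e4, seed = 608)
  fit2 <- fit_biexponential(build_survival(dw2), t0 = 0)
  expect_lt(abs(fit2$k_slow - fit$k_slow) / fit$k_slow, 0.1)
  s <- summary(fit)
  expect_equal(s$t_1pct, time_to_fraction(fit, 0.01))
})
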