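test_that("dwell-time sampler matches exponential means, with and without bleaching", {
  # mean of Exponential(0.1) is 10 s
  d1 <- simulate_dwell_times(kinetic_config(frac_fast = 0, k_slow = 0.1),
                             n = 1e5, seed = 101, discretize = FALSE)
  expect_lt(abs(mean(d1$dwell) - 10) / 10, 0.02)
  # bleaching at the same rate: min of two Exp(0.1) draws is Exp(0.2), mean 5 s
  d2 <- simulate_dwell_times(kinetic_config(frac_fast = 0, k_slow = 0.1,
                                            k_bleach = 0.1),
                             n = 1e5, seed = 102, discretize = FALSE)
  expect_lt(abs(mean(d2$dwell) - 5) / 5, 0.02)
  expect_true(any(d2$bleached))
  # discretized durations are geometric on the frame grid: conditional on
  # spanning >= 2 frames, E[dwell] = dt + dt / (exp(k dt) - 1)
  k <- 0.2; dt <- 0.2
  d3 <- simulate_dwell_times(kinetic_config(frac_fast = 0, k_slow = 0.1,
                                            k_bleach = 0.1),
                             n = 1e5, seed = 103)
  expect_lt(abs(mean(d3$dwell) - (dt + dt / (exp(k * dt) - 1))) /
              (dt + dt / (exp(k * dt) - 1)), 0.02)
  expect_true(all(d3$dwell >= dt))            # min 2 frames spanned
})

test_that("dwell-time sampler is seed-deterministic and validates its config", {
  cfg <- kinetic_config(frac_fast = 0.4, k_fast = 1, k_slow = 0.1,
                        k_bleach = 0.05)
  expect_identical(simulate_dwell_times(cfg, n = 1, seed = 7),
                   simulate_dwell_times(cfg, n = 1, seed = 7))
  expect_identical(simulate_dwell_times(cfg, n = 500, seed = 8),
                   simulate_dwell_times(cfg, n = 500, seed = 8))
  expect_error(kinetic_config(frac_fast = 0.5, k_fast = 0.05, k_slow = 0.1),
               "invalid kinetic config")
  expect_error(kinetic_config(k_slow = 0), "invalid kinetic config")
  expect_error(kinetic_config(frame_interval = 0), "invalid kinetic config")
  expect_error(simulate_dwell_times(cfg, n = 0), "n must be")
})

test_that("empirical survival converges to the mixture-exponential form at frame multiples", {
  cfg <- kinetic_config(frac_fast = 0.5, k_fast = 1, k_slow = 0.1,
                        k_bleach = 0.05)
  d <- simulate_dwell_times(cfg, n = 2e5, seed = 103, min_frames = 0)
  s <- build_survival(d$dwell)
  grid <- s$times[s$times <= 20]
  model <- with(cfg, frac_fast * exp(-(k_fast + k_bleach) * grid) +
                  (1 - frac_fast) * exp(-(k_slow + k_bleach) * grid))
  expect_lt(max(abs(s$survival[s$times <= 20] - model)), 0.01)
})

test_that("movie ground truth and rendered spot counts agree frame by frame", {
  mv <- oracle_movie(seed = 21, n_frames = 60, n_molecules = 10)
  sim <- mv$sim
  # every ground-truth rendering sits inside a bound interval of its molecule
  det <- sim$truth$detections
  mol <- sim$truth$molecules
  bound <- det[det$state == "bound", ]
  m <- mol[match(bound$molecule_id, mol$molecule_id), ]
  expect_true(all(bound$frame >= m$bind_frame & bound$frame <= m$unbind_frame))
  # spot-count self-consistency: brightest-pixel excess matches rendering count
  counts_truth <- table(factor(det$frame, levels = 0:59))
  for (f in c(0, 15, 40)) {
    img <- sim$stack$frames[, , f + 1]
    sub <- det[det$frame == f, ]
    if (nrow(sub)) {
      # each rendered spot produces a local intensity well above background
      vals <- mapply(function(x, y) img[round(y) + 1, round(x) + 1],
                     sub$x_px, sub$y_px)
      expect_true(all(vals > 100 + 5 * 10))
    }
  }
  expect_identical(sum(counts_truth), nrow(det))
})

test_that("movie simulator handles the empty and immobile-bright edge cases", {
  kc0 <- kinetic_config(n_frames = 10, n_molecules = 0)
  sim0 <- simulate_movie(movie_config(width = 64, height = 64, kinetic = kc0),
                         seed = 1)
  expect_identical(nrow(sim0$truth$molecules), 0L)
  expect_identical(nrow(sim0$truth$detections), 0L)
  expect_identical(dim(sim0$stack)[3], 10L)
  # 5 immobile never-bleaching molecules bound from frame 0: 5 spots per
  # frame at fixed positions, and detection finds them all
  kc5 <- kinetic_config(frac_fast = 0, k_slow = 1e-6, k_bleach = 0,
                        n_frames = 20, n_molecules = 5)
  sim5 <- simulate_movie(movie_config(width = 96, height = 96,
                                      spot_amplitude = 200, background_sd = 5,
                                      p_detect_free = 0, kinetic = kc5),
                         seed = 2, bind_at_start = TRUE)
  expect_true(all(table(sim5$truth$detections$frame) == 5))
  expect_identical(nrow(unique(sim5$truth$detections[, c("x_px", "y_px")])), 5L)
  expect_true(all(sim5$truth$molecules$censored))
  det <- detect_frame(sim5$stack$frames[, , 1])
  expect_identical(nrow(det), 5L)
})

test_that("movie simulation is seed-deterministic and frame stacks round-trip TIFF", {
  mv1 <- oracle_movie(seed = 33, n_frames = 8, n_molecules = 4, width = 64,
                      height = 64)
  mv2 <- oracle_movie(seed = 33, n_frames = 8, n_molecules = 4, width = 64,
                      height = 64)
  expect_identical(mv1$sim$stack$frames, mv2$sim$stack$frames)
  expect_identical(mv1$sim$truth, mv2$sim$truth)
  path <- withr::local_tempfile(fileext = ".tif")
  write_frame_stack(mv1$sim$stack, path)
  back <- read_frame_stack(path, frame_interval = 0.2, pixel_size = 0.16)
  sc <- max(mv1$sim$stack$frames)
  expect_equal(back$frames * sc, mv1$sim$stack$frames, tolerance = 1e-6)
})

test_that("synthetic cell images hit their designed enrichment exactly", {
  expect_equal(simulate_cell_image(
    cell_image_config(chromatin_to_cell_ratio = 1))$true_score, 0)
  expect_equal(simulate_cell_image(
    cell_image_config(chromatin_to_cell_ratio = 2))$true_score, 1)
  # noiseless construction: measured score on true masks is exact
  img <- simulate_cell_image(
    cell_image_config(chromatin_to_cell_ratio = 0.5, noise_sd = 0), seed = 4)
  sc <- enrichment_score(img$halo, img$masks)
  expect_equal(sc$score, -1, tolerance = 1e-12)
  # whole-cell mean is cell_mean by construction
  expect_equal(mean(img$halo[img$masks$cell]), 200, tolerance = 1e-9)
  expect_error(cell_image_config(chromatin_to_cell_ratio = 0),
               "invalid cell image config")
  expect_error(cell_image_config(chromatin_axes = c(80, 80)),
               "inside the cell")
})

test_that("spike-in count simulator is deterministic and validates its config", {
  samples <- data.frame(
    sample = c("async", "mito_a", "mito_b"),
    condition = c("asynchronous", "mitotic", "mitotic"),
    fly_fraction = c(0.10, 0.05, 0.08))
  cfg <- spikein_sim_config(samples, total_reads = 1e6, constant = 1e5)
  c1 <- simulate_spikein_counts(cfg, seed = 5)
  expect_identical(c1, simulate_spikein_counts(cfg, seed = 5))
  expect_identical(attr(c1, "reference"), "async")
  # deterministic mode: counts are the expectations
  c0 <- simulate_spikein_counts(cfg, sampling = FALSE)
  expect_equal(c0$fly_reads, c(1e5, 5e4, 8e4))
  expect_error(spikein_sim_config(transform(samples, fly_fraction = c(0, .5, .5))),
               "invalid spike-in config")
  expect_error(
    spikein_sim_config(data.frame(sample = "m", condition = "mitotic",
                                  fly_fraction = 0.1)),
    "reference")
})
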