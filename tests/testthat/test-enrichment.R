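test_that("automated masks overlap the true regions with Jaccard >= 0.9", {
  for (r in c(2, 0.7)) {
    img <- simulate_cell_image(
      cell_image_config(chromatin_to_cell_ratio = r, noise_sd = 10), seed = 71)
    m <- segment_masks(img$h2b, img$halo)
    expect_gte(jaccard(m$cell, img$masks$cell), 0.9)
    expect_gte(jaccard(m$chromatin, img$masks$chromatin), 0.9)
    expect_true(all(m$chromatin[m$chromatin] & m$cell[m$chromatin]))
  }
  expect_error(segment_masks(matrix(0, 64, 64), matrix(0, 64, 64)),
               "segmentation failure")
})

test_that("segmentation masks are invariant to a global intensity doubling", {
  img <- simulate_cell_image(
    cell_image_config(chromatin_to_cell_ratio = 2, noise_sd = 0), seed = 72)
  m1 <- segment_masks(img$h2b, img$halo)
  m2 <- segment_masks(2 * img$h2b, 2 * img$halo)
  expect_identical(m1$cell, m2$cell)
  expect_identical(m1$chromatin, m2$chromatin)
})

test_that("enrichment score matches its definition on constructed inputs", {
  masks <- list(chromatin = ellipse <- mitodwell:::ellipse_mask(c(64, 64), c(32, 32), c(10, 10)),
                cell = mitodwell:::ellipse_mask(c(64, 64), c(32, 32), c(25, 25)))
  # uniform intensity: score identically 0
  expect_equal(enrichment_score(matrix(7, 64, 64), masks)$score, 0)
  # chromatin mean exactly twice the whole-cell mean: score 1
  halo <- matrix(0, 64, 64)
  a_cell <- sum(masks$cell); a_chr <- sum(masks$chromatin)
  rest <- (a_cell - 2 * a_chr) / (a_cell - a_chr)   # cell mean 1, chromatin 2
  halo[masks$cell] <- rest
  halo[masks$chromatin] <- 2
  expect_equal(enrichment_score(halo, masks)$score, 1, tolerance = 1e-12)
  # score is invariant to multiplying the channel by a constant
  expect_equal(enrichment_score(5 * halo, masks)$score, 1, tolerance = 1e-12)
  expect_error(enrichment_score(matrix(0, 64, 64), masks), "undefined score")
  bad <- list(chromatin = !masks$cell, cell = masks$cell)
  expect_error(enrichment_score(matrix(1, 64, 64), bad), "invalid masks")
})

test_that("measured scores on noisy synthetic cells converge to log2(ratio)", {
  for (r in c(2, 0.7)) {
    scores <- vapply(1:5, function(s) {
      img <- simulate_cell_image(
        cell_image_config(chromatin_to_cell_ratio = r, noise_sd = 5), seed = s)
      enrichment_score(img$halo, img$masks)$score
    }, 1)
    expect_lt(max(abs(scores - log2(r))), 0.05)
  }
})

test_that("enrichment ordering coating > neutral > excluded holds in every run", {
  for (s in 1:5) {
    sc <- vapply(c(2, 1, 0.7), function(r) {
      img <- simulate_cell_image(
        cell_image_config(chromatin_to_cell_ratio = r, noise_sd = 8), seed = s)
      enrichment_score(img$halo, segment_masks(img$h2b, img$halo))$score
    }, 1)
    expect_true(sc[1] > sc[2] && sc[2] > sc[3])
  }
})

test_that("construct comparison averages replicates and matches the t distribution", {
  # replicate means 1.0/1.1/0.9 vs -0.5/-0.4/-0.6: difference 1.5,
  # equal-variance t on n = 3 vs 3
  mk <- function(construct, means) do.call(rbind, lapply(seq_along(means),
    function(r) data.frame(construct = construct, replicate = r,
                           score = means[r] + c(-0.2, 0, 0.2))))
  scores <- rbind(mk("wt", c(1.0, 1.1, 0.9)), mk("mut", c(-0.5, -0.4, -0.6)))
  cmp <- compare_constructs(scores)
  pw <- cmp$pairwise
  expect_equal(abs(pw$difference), 1.5)
  t_hand <- 1.5 / sqrt(0.1^2 * (1 / 3 + 1 / 3))
  expect_equal(pw$p_value, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-9)
  # permuting cells within replicates changes nothing
  perm <- scores[sample(nrow(scores)), ]
  cmp2 <- compare_constructs(perm)
  expect_equal(cmp2$pairwise$p_value, pw$p_value)
  expect_equal(sort(cmp2$summary$mean_score), sort(cmp$summary$mean_score))
  # identical constructs: difference 0, p > 0.99
  same <- rbind(mk("a", c(1, 1.1, 0.9)), mk("b", c(1, 1.1, 0.9)))
  expect_gt(compare_constructs(same)$pairwise$p_value, 0.99)
  # single replicate: flagged, no p-value
  one <- rbind(data.frame(construct = "a", replicate = 1, score = 1),
               data.frame(construct = "b", replicate = 1, score = 0))
  expect_true(is.na(compare_constructs(one)$pairwise$p_value))
})
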