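async_mito_counts <- function(fly_async, fly_mito) {
  data.frame(sample = c("async", "mitotic"),
             condition = c("asynchronous", "mitotic"),
             fly_reads = c(fly_async, fly_mito))
}

test_that("scaling values follow constant / fly_reads anchored to the reference", {
  tab <- compute_scaling(async_mito_counts(50000, 25000), constant = 1e5,
                         reference = "async")
  expect_equal(tab$raw_scaling, c(2, 4))
  expect_equal(tab$scaling, c(1, 2))
  # equal fly counts across samples: all scalings 1
  eq <- compute_scaling(
    data.frame(sample = c("a", "b", "c"),
               condition = c("asynchronous", "mitotic", "mitotic"),
               fly_reads = rep(4e4, 3)),
    constant = 1e5, reference = "a")
  expect_equal(eq$scaling, rep(1, 3))
  expect_error(compute_scaling(async_mito_counts(0, 100), constant = 1e5,
                               reference = "async"), "zero fly reads")
  expect_error(compute_scaling(async_mito_counts(1, 1), constant = 1e5,
                               reference = "nope"), "missing reference")
})

test_that("normalized scalings are invariant to the choice of constant", {
  for (const in c(1e5, 2e5, 7)) {
    tab <- compute_scaling(async_mito_counts(50000, 25000), constant = const,
                           reference = "async")
    expect_equal(tab$scaling, c(1, 2))
  }
  # reference scaling is exactly 1 for arbitrary random count tables
  set.seed(81)
  for (i in 1:10) {
    n <- sample(2:6, 1)
    counts <- data.frame(
      sample = paste0("s", 1:n),
      condition = c("asynchronous", rep("mitotic", n - 1)),
      fly_reads = sample(1e3:1e6, n))
    tab <- compute_scaling(counts, constant = 1e5, reference = "s1")
    expect_identical(tab$scaling[1], 1)
  }
})

test_that("count normalization scales columns, preserves ranks and the reference", {
  tab <- compute_scaling(async_mito_counts(50000, 25000), constant = 1e5,
                         reference = "async")
  m <- matrix(c(10, 100, 40, 5, 50, 80), ncol = 2,
              dimnames = list(NULL, c("async", "mitotic")))
  norm <- normalize_counts(m, tab)
  expect_equal(norm[, "async"], m[, "async"])        # reference unchanged
  expect_equal(norm[, "mitotic"], 2 * m[, "mitotic"])
  expect_equal(normalize_counts(2 * m, tab), 2 * norm)  # linearity
  expect_identical(order(norm[, "mitotic"]), order(m[, "mitotic"]))
  # identity when all scalings are 1
  tab1 <- compute_scaling(async_mito_counts(3e4, 3e4), constant = 1e5,
                          reference = "async")
  expect_equal(normalize_counts(m, tab1), m)
  expect_error(normalize_counts(cbind(m, extra = 1:3), tab),
               "sample mismatch.*extra")
})

test_that("site tables round-trip BED and keep 0-based half-open coordinates", {
  sites <- data.frame(chrom = c("chr1", "chr2"), start = c(0L, 150L),
                      end = c(100L, 500L))
  path <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, path)
  back <- read_sites_bed(path)
  expect_equal(back, sites)
  # data.frame input to normalize_counts carries coordinates through
  tab <- compute_scaling(async_mito_counts(50000, 25000), constant = 1e5,
                         reference = "async")
  df <- cbind(sites[1:2, ], async = c(10, 20), mitotic = c(5, 8))
  norm <- normalize_counts(df, tab)
  expect_equal(norm$chrom, sites$chrom[1:2])
  expect_equal(norm$mitotic, c(10, 16))
  sp <- scatter_pairs(norm, "async", "mitotic")
  expect_named(sp, c("chrom", "start", "end", "asynchronous", "mitotic"))
})

test_that("simulated counts flow through scaling with near-true values", {
  samples <- data.frame(
    sample = c("async", "mitotic"),
    condition = c("asynchronous", "mitotic"),
    fly_fraction = c(0.10, 0.05))
  cfg <- spikein_sim_config(samples, total_reads = 1e6, constant = 1e5,
                            reference = "async")
  tab <- compute_scaling(simulate_spikein_counts(cfg, seed = 82))
  # true scaling ratio is 0.10 / 0.05 = 2; binomial noise at n = 1e6 is small
  expect_lt(abs(tab$scaling[2] - 2) / 2, 0.02)
  # deterministic mode is exact
  tab0 <- compute_scaling(simulate_spikein_counts(cfg, sampling = FALSE))
  expect_equal(tab0$scaling, c(1, 2))
})
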