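# Shared oracles and fixture builders (everything is generated in code).

# Exhaustive-permutation solution of a square assignment problem; the
# brute-force oracle for the O(n^3) solver (n <= 6).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    val <- sum(cost[cbind(seq_len(n), p)])
    if (val < best) best <- val
  }
  best
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# A small bound-only movie with well-separated immobile molecules: the
# standard fixture for detection/tracking oracles.
oracle_movie <- function(seed, n_frames = 150, n_molecules = 15,
                         width = 128, height = 128, snr = 12,
                         k_slow = 0.08, k_bleach = 0.04, frac_fast = 0.3) {
  kc <- kinetic_config(frac_fast = frac_fast, k_fast = 1, k_slow = k_slow,
                       k_bleach = k_bleach, n_frames = n_frames,
                       n_molecules = n_molecules)
  mc <- movie_config(width = width, height = height,
                     spot_amplitude = snr * 10, background_sd = 10,
                     p_detect_free = 0, kinetic = kc)
  list(sim = suppressWarnings(simulate_movie(mc, seed = seed)), config = mc)
}

# Hand-built localization table: one immobile spot per position, present in
# the given frames.
loc_table <- function(frames, x_um, y_um) {
  data.frame(frame = frames, x_um = x_um, y_um = y_um,
             x_px = x_um / 0.16, y_px = y_um / 0.16,
             amplitude = 100, background = 0, stat = 10)
}
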