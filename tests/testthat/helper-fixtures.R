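# Shared helpers: small deterministic images, polygons and scenes used
# across the suite.

make_counts <- function(values, nr, nc) {
  matrix(as.integer(values), nr, nc)
}

random_count_image <- function(nr = 32, nc = 32, lambda = 5) {
  matrix(rpois(nr * nc, lambda), nr, nc)
}

square_polygon <- function(r0, r1, c0, c1) {
  rbind(c(r0, c0), c(r0, c1), c(r1, c1), c(r1, c0))
}

small_scene_config <- function(seed = 1, n_spines = 40, ...) {
  scene_config(field_shape = c(448L, 448L), n_spines = n_spines,
               n_axon_tracks = 2L, seed = seed, ...)
}

# Brute-force Otsu oracle: exhaustive search of between-class variance over
# every candidate threshold, written independently of the implementation.
otsu_bruteforce <- function(px, candidates = 0:255) {
  px <- as.vector(px)
  n <- length(px)
  best_t <- NA_integer_; best_v <- -Inf
  for (t in candidates) {
    lo <- px[px <= t]; hi <- px[px > t]
    if (length(lo) == 0 || length(hi) == 0) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}
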