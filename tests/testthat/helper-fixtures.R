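# Shared fixtures and independent oracles.

# a plausible measured corner set with a visible warp on every axis
warped_corners <- function() {
  corner_set(c10 = c(100.15, -1.34, 0.13),
             c01 = c(0.80, -63.10, -0.05),
             c11 = c(101.00, -64.40, 0.21))
}

# corners lying exactly on a plane (c11 = c10 + c01 - c00)
planar_corners <- function() {
  corner_set(c10 = c(99, 0, 0.1), c01 = c(0, -63, -0.2),
             c11 = c(99, -63, -0.1))
}

# roll a matrix circularly: content moves down by dy rows, right by dx
roll_mat <- function(m, dy, dx) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(p) - 1 - dx) %% p) + 1]
}

rms <- function(a, b) sqrt(mean((a - b)^2))

# mean local sharpness per tile (nt x nt grid)
tile_sharpness <- function(img, nt = 4, window = 5L) {
  sm <- local_sharpness(img, window)
  rr <- split(seq_len(nrow(sm)), cut(seq_len(nrow(sm)), nt, labels = FALSE))
  cc <- split(seq_len(ncol(sm)), cut(seq_len(ncol(sm)), nt, labels = FALSE))
  vapply(cc, function(cj) vapply(rr, function(ri) mean(sm[ri, cj]),
                                 numeric(1)), numeric(length(rr)))
}

# Exhaustive segmentation oracle: enumerate every partition of 1..n into
# stacks of 1..n_z data records, each optionally terminated by a
# candidate sentinel, score with the package's objective, return all
# lexicographically optimal partitions. Independent of the dynamic
# alignment: plain recursion over all structures.
oracle_segment <- function(sizes, n_z, candidates) {
  n <- length(sizes)
  is_cand <- rep(FALSE, n); is_cand[candidates] <- TRUE
  results <- list()
  recurse <- function(pos, acc) {
    if (pos > n) {
      results[[length(results) + 1L]] <<-
        do.call(rbind, lapply(acc, as.data.frame))
      return(invisible())
    }
    for (g in seq_len(n_z)) {
      last <- pos + g - 1L
      if (last > n) break
      # without sentinel
      recurse(last + 1L, c(acc, list(list(from = pos, to = last,
                                          sentinel = NA_integer_))))
      # with sentinel
      s <- last + 1L
      if (s <= n && is_cand[s])
        recurse(s + 1L, c(acc, list(list(from = pos, to = last,
                                         sentinel = s))))
    }
  }
  recurse(1L, list())
  scored <- lapply(results, function(st)
    platescan:::.score_partition(sizes, st, n_z))
  keep <- !vapply(scored, is.null, logical(1))
  results <- results[keep]; scored <- scored[keep]
  best <- scored[[1L]]
  for (sc in scored) if (platescan:::.obj_better(sc, best)) best <- sc
  opt <- vapply(scored, function(sc) identical(sc, best), logical(1))
  list(best = best, partitions = results[opt])
}

# sizes for k stacks of n_z sharp images followed by a small sentinel
toy_sizes <- function(k = 3, n_z = 5,
                      data = c(100, 105, 110, 104, 99), sentinel = 40) {
  rep(c(data[seq_len(n_z)], sentinel), k)
}
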