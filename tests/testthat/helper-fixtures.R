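# Shared fixtures: everything is generated in code, no files.

# small cortex: fast enough for unit tests, still exercises every area
tiny_cortex <- function() {
  build_cortex(v1_dim = c(6, 6), xs_dim = c(4, 4), spacing_mm = 1,
               v1_spacing_mm = 2)
}

tiny_movie <- function() make_bar_stimulus(grid_n = 32)

# truth with no subject jitter and clean signal, for exact-recovery checks
clean_truth <- function(widths_on_grid = FALSE) {
  offs <- if (widths_on_grid)
    c(V2d = 0, V2v = 0.6, V3d = 1.4, V3v = 2.2, hV4 = 3.0, LO = 4.0, TO = 5.0)
  else NULL
  make_group_truth("control", slope_mm_per_level = if (widths_on_grid) 0 else NULL,
                   area_offsets = offs, base_width_mm = 1,
                   subject_jitter_sd = 0, noise_sd = 0, drift_amp = 0)
}

# independent all-pairs shortest-path oracle (Floyd-Warshall on the edge graph)
floyd_warshall_oracle <- function(mesh, roi_idx) {
  n <- length(roi_idx)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  f <- mesh$faces
  edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(1, 3)]))
  for (k in seq_len(nrow(edges))) {
    i <- match(edges[k, 1], roi_idx)
    j <- match(edges[k, 2], roi_idx)
    if (is.na(i) || is.na(j)) next
    w <- sqrt(sum((mesh$vertices[edges[k, 1], ] - mesh$vertices[edges[k, 2], ])^2))
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n)) for (i in seq_len(n))
    d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

# enumeration oracle for the rank-sum null: all n1-subsets of ranks 1..n
rank_sum_enum_oracle <- function(n1, n2) {
  sums <- combn(n1 + n2, n1, sum)
  tab <- table(sums)
  data.frame(w = as.numeric(names(tab)), prob = as.numeric(tab) / length(sums))
}

# enumeration oracle for the signed-rank null: all 2^n sign patterns
signed_rank_enum_oracle <- function(n) {
  w <- vapply(0:(2^n - 1), function(mask)
    sum(which(bitwAnd(mask, 2^(0:(n - 1))) > 0)), numeric(1))
  tab <- table(w)
  data.frame(w = as.numeric(names(tab)), prob = as.numeric(tab) / 2^n)
}

# Lehmer-code permutation enumerator, independent of the package's own
lehmer_permutations <- function(n) {
  t(vapply(0:(factorial(n) - 1), function(idx) {
    avail <- seq_len(n)
    p <- integer(n)
    for (i in seq_len(n)) {
      f <- factorial(n - i)
      d <- idx %/% f
      idx <- idx %% f
      p[i] <- avail[d + 1]
      avail <- avail[-(d + 1)]
    }
    p
  }, integer(n)))
}
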