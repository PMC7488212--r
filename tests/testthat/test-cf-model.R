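test_that("geodesic distances: trivial cases and oracle equivalence", {
  strip <- build_flat_patch("V1", 3, 2)          # 1 mm edges
  d <- geodesic_distances(strip, 1:3)            # bottom row
  expect_equal(d[1, 3], 2)                       # path sum along the row
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d, t(d))

  d1 <- geodesic_distances(strip, 2)
  expect_equal(unname(d1), matrix(0, 1, 1))

  patch <- build_flat_patch("V1", 6, 5)          # 30 vertices
  roi <- seq_len(30)
  got <- geodesic_distances(patch, roi)
  expect_equal(unname(got), floyd_warshall_oracle(patch, roi), tolerance = 1e-12)
})

test_that("disconnected ROI is rejected naming the components", {
  cx <- tiny_cortex()
  roi <- c(area_units(cx, "V1"), area_units(cx, "V2d"))
  expect_error(geodesic_distances(cx, roi), "2 components")
})

test_that("size grid is the stated 51-value progression", {
  g <- sigma_grid()
  expect_length(g, 51)
  expect_equal(g[1], 0.0001)
  expect_equal(g[51], 10)
  expect_equal(g[2:51], 0.2 * (1:50))
  expect_true(all(diff(g) > 0))
})

test_that("CF weights: closed form, point-CF limit, validation", {
  w <- cf_weights(c(0, 1), 1)
  expect_equal(w[1] / w[2], exp(1 / 2))          # ratio e^{-1/2} pre-normalization
  expect_equal(sum(w), 1)
  expect_equal(which.max(cf_weights(c(2, 0, 3), 0.7)), 2)
  # sigma = 0.0001 with spacing >= 0.5 mm: effectively one-on-one
  w0 <- cf_weights(c(0, 0.5, 1, 2), 0.0001)
  expect_gte(w0[1], 1 - 1e-12)
  expect_error(cf_weights(c(0, 1), 0), "sigma")
})

test_that("fit_cf: identity target and generator self-consistency", {
  patch <- build_flat_patch("V1", 5, 5)
  d <- geodesic_distances(patch, 1:25)
  set.seed(42)
  S <- matrix(rnorm(128 * 25), 128)
  # identity: target is one source column
  f <- fit_cf(S[, 7], S, d)
  expect_equal(f$v0_index, 7)
  expect_equal(f$sigma_mm, 0.0001)
  expect_equal(f$ve, 1, tolerance = 1e-12)
  # exact Gaussian mixture at an on-grid size
  y <- S %*% cf_weights(d[13, ], 0.4)
  f2 <- fit_cf(y, S, d)
  expect_equal(f2$sigma_mm, 0.4)
  expect_equal(f2$v0_index, 13)
  expect_equal(f2$ve, 1, tolerance = 1e-12)
})

test_that("fit_cf equals a brute-force search (grid optimality)", {
  patch <- build_flat_patch("V1", 4, 4)
  d <- geodesic_distances(patch, 1:16)
  set.seed(77)
  S <- matrix(rnorm(60 * 16), 60)
  Y <- S %*% sapply(c(2, 9), function(v) cf_weights(d[v, ], 1.3)) +
    matrix(rnorm(60 * 2, 0, 0.3), 60)
  got <- fit_cf(Y, S, d)
  # independent brute-force loop with the same tie convention
  Yc <- scale(Y, scale = FALSE); Sc <- scale(S, scale = FALSE)
  for (j in 1:2) {
    best <- c(ve = -1, sigma = NA, v0 = NA)
    tss <- sum(Yc[, j]^2)
    for (sg in sigma_grid()) for (v in 1:16) {
      p <- drop(Sc %*% cf_weights(d[v, ], sg))
      cc <- sum(p * Yc[, j])
      ve <- if (cc > 0) cc^2 / (sum(p^2) * tss) else 0
      if (ve > best["ve"]) best <- c(ve = ve, sigma = sg, v0 = v)
    }
    expect_equal(got$ve[j], unname(best["ve"]), tolerance = 1e-10)
    expect_equal(got$sigma_mm[j], unname(best["sigma"]))
    expect_equal(got$v0_index[j], unname(best["v0"]))
  }
})

test_that("white-noise targets stay below the VE threshold", {
  patch <- build_flat_patch("V1", 4, 4)
  d <- geodesic_distances(patch, 1:16)
  set.seed(123)
  S <- matrix(rnorm(128 * 16), 128)
  ves <- vapply(1:100, function(i) fit_cf(rnorm(128), S, d)$ve, numeric(1))
  expect_gte(mean(ves < 0.20), 0.95)
})

test_that("zero-variance targets are flagged, not fitted", {
  patch <- build_flat_patch("V1", 3, 3)
  d <- geodesic_distances(patch, 1:9)
  S <- matrix(rnorm(50 * 9), 50)
  f <- fit_cf(rep(2, 50), S, d)
  expect_equal(f$note, "zero_variance")
  expect_true(is.na(f$ve))
})

test_that("noiseless recovery has v0 within 1 mm and sigma within one step", {
  cx <- tiny_cortex()
  truth <- clean_truth()                          # off-grid widths
  ts <- preprocess_run(simulate_stimulus_run(cx, truth, tiny_movie(), seed = 5,
                                             noise_sd = 0, drift_amp = 0,
                                             feedback_frac = 0))
  v1 <- area_units(cx, "V1")
  d_v1 <- geodesic_distances(cx, v1)
  tab <- cf_fit_table(cx, ts, "V1", "V3d")
  w_true <- truth$widths$w_fwd[truth$widths$area == "V3d"]
  expect_gte(mean(abs(tab$sigma_mm - w_true) <= 0.2 + 1e-9), 0.95)
  # true center: retinotopically corresponding V1 unit
  xi <- area_units(cx, "V3d")
  for (k in seq_along(xi)) {
    d2 <- (cx$units$vf_x[xi[k]] - cx$units$vf_x[v1])^2 +
      (cx$units$vf_y[xi[k]] - cx$units$vf_y[v1])^2
    true_v0 <- which.min(d2)
    expect_lte(d_v1[true_v0, tab$v0_index[k]], 1 + 1e-9)
  }
})

test_that("median VE degrades monotonically with noise", {
  cx <- tiny_cortex()
  truth <- clean_truth()
  mv <- tiny_movie()
  med_ve <- vapply(c(0, 0.5, 1, 2), function(ns) {
    ves <- vapply(1:3, function(s) {
      ts <- preprocess_run(simulate_stimulus_run(cx, truth, mv, seed = 20 + s,
                                                 noise_sd = ns, drift_amp = 0,
                                                 feedback_frac = 0))
      median(cf_fit_table(cx, ts, "V1", "V2d")$ve)
    }, numeric(1))
    mean(ves)
  }, numeric(1))
  expect_true(all(diff(med_ve) <= 1e-9))
})

test_that("sampling extent: calibration, point CF, all-ipsilateral error", {
  patch <- build_flat_patch("V1", 9, 9, spacing_mm = 1)
  d <- geodesic_distances(patch, 1:81)
  contra <- rep(TRUE, 81)
  center <- 41                                    # patch middle
  expect_equal(sampling_extent(d[center, ], 1.5, contra), 1.5)
  expect_lt(sampling_extent(d[center, ], 0.0001, contra), 1e-3)
  expect_error(sampling_extent(d[center, ], 1, !contra), "ipsilateral")
})

test_that("border-straddling CF matches a dense truncation oracle", {
  m <- build_flat_patch("V1", 11, 6, ipsi_rows = 5)  # rows 7..11 ipsilateral
  n <- nrow(m$units)
  d <- geodesic_distances(m, seq_len(n))
  contra <- m$units$hemifield == "contralateral"
  v0 <- 6 * 11 - 5                                 # top contralateral row, mid x
  for (sigma in c(1, 2)) {
    got <- sampling_extent(d[v0, ], sigma, contra)
    # continuous oracle: integrate the Gaussian over the patch rectangle,
    # truncated at the half-cell boundary between contra and ipsi rows
    c0 <- m$vertices[v0, 1:2]
    h <- 0.02
    xs <- seq(-0.5, 10.5, by = h); ys <- seq(-0.5, 10.5, by = h)
    X <- rep(xs, times = length(ys)); Y <- rep(ys, each = length(xs))
    g <- exp(-((X - c0[1])^2 + (Y - c0[2])^2) / (2 * sigma^2))
    keep_contra <- Y <= 5.5                        # contra rows at y = 0..5
    r2 <- (X - c0[1])^2 + (Y - c0[2])^2
    rms_all <- sqrt(sum(g * r2) / sum(g))
    rms_c <- sqrt(sum(g[keep_contra] * r2[keep_contra]) / sum(g[keep_contra]))
    expect_equal(got, sigma * rms_c / rms_all, tolerance = 0.01)
  }
})
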