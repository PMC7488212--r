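test_that("hierarchy levels match the published ordering", {
  expect_equal(hierarchy_level("V1"), 0)
  expect_equal(hierarchy_level(c("V2", "V2d", "V2v")), c(1, 1, 1))
  expect_equal(hierarchy_level(c("V3", "V3d", "V3v")), c(2, 2, 2))
  expect_equal(hierarchy_level("hV4"), 3)
  expect_equal(hierarchy_level("LO"), 3.5)
  expect_equal(hierarchy_level("TO"), 5.5)
  expect_error(hierarchy_level("MT"), "unknown area")
})

test_that("voxel selection applies the three exclusion rules", {
  tab <- data.frame(
    ve = c(0.19, 0.9, 0.9, 0.5, NA),
    sigma_mm = c(1.0, 0.0001, 1.0, 2.0, 1.0),
    target_ecc_deg = c(3, 3, 8.0, 7.5, 2),
    sampling_extent_mm = 1:5
  )
  sel <- select_voxels(tab)
  expect_equal(nrow(sel$kept), 1)
  expect_equal(sel$kept$sampling_extent_mm, 4)   # boundary 7.5 deg inclusive
  expect_equal(unname(sel$tallies),
               c(1, 1, 1, 1))                    # ve, point_cf, ecc, invalid
  # boundary inclusivity on both ends and the >= threshold
  tab2 <- data.frame(ve = c(0.20, 0.5), sigma_mm = c(1, 1),
                     target_ecc_deg = c(0.5, 7.5), sampling_extent_mm = c(1, 2))
  expect_equal(nrow(select_voxels(tab2)$kept), 2)
})

test_that("lower weighted median matches the cumulative-weight oracle", {
  expect_equal(weighted_median(c(1, 2, 3)), 2)
  expect_equal(weighted_median(7, 5), 7)
  expect_equal(weighted_median(c(1, 2, 3), c(0.2, 0.2, 0.6)), 3)
  expect_equal(weighted_median(c(3, 1, 2), c(0.6, 0.2, 0.2)), 3) # order-free
  # equal weights reduce to the lower ordinary median
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1))
    expect_equal(weighted_median(x), sort(x)[ceiling(length(x) / 2)])
  }
  expect_error(weighted_median(numeric(0)), "empty")
  expect_error(weighted_median(1:3, c(0, 0, 0)), "weights")
})

test_that("convergence magnitude is the signed extent difference", {
  expect_equal(convergence_magnitude(3, 1), 2)
  expect_equal(convergence_magnitude(1.7, 1.7), 0)
  expect_equal(convergence_magnitude(1, 3), -2)
  expect_error(convergence_magnitude(Inf, 1), "finite")
})

test_that("hierarchy slope: collinear and degenerate cases", {
  rec <- function(areas, vals)
    data.frame(area = areas, convergence_magnitude = vals)
  both <- c("V2", "V3", "hV4", "LO", "TO")
  f <- fit_hierarchy_slope(rec(both, rep(2.5, 5)), "both")
  expect_equal(f$slope, 0)
  expect_equal(f$intercept, 2.5)
  f2 <- fit_hierarchy_slope(rec(both, 1.61 * hierarchy_level(both)), "both")
  expect_equal(f2$slope, 1.61)
  expect_equal(f2$intercept, 0, tolerance = 1e-12)
  f3 <- fit_hierarchy_slope(rec(c("V2d", "V3d", "TO"), c(1, 2, 5.5)), "dorsal")
  expect_equal(f3$slope, 1)
  expect_equal(f3$intercept, 0, tolerance = 1e-12)
  expect_error(fit_hierarchy_slope(rec("V2d", 1), "dorsal"), "distinct")
})

test_that("summaries are invariant to voxel order", {
  set.seed(8)
  tab <- data.frame(ve = runif(40, 0.1, 1), sigma_mm = sample(sigma_grid(), 40, TRUE),
                    target_ecc_deg = runif(40, 0, 8),
                    sampling_extent_mm = runif(40, 0, 5))
  a <- summarize_fits(tab)
  b <- summarize_fits(tab[sample(40), ])
  expect_equal(a, b)
})

test_that("bias audit: identical groups give corrected p of 1", {
  at <- expand.grid(subject = 1:6, group = c("a", "b"), area = c("V2d", "TO"),
                    stringsAsFactors = FALSE)
  at$convergence_magnitude <- rep(1:6, length.out = nrow(at))
  at$d_median_ve <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), length.out = nrow(at))
  at$d_n_voxels <- rep(1:6, length.out = nrow(at))
  at$d_prop_point_cf <- 0.1
  at$d_mean_ecc <- rep(c(2, 2, 3, 3, 4, 4), length.out = nrow(at))
  out <- bias_audit(at)
  expect_true(all(out$p_corrected == 1))
  expect_true(all(is.na(out$rho)))               # no Spearman when nothing is significant
  expect_error(bias_audit(at[, -5]), "missing variables")
})

test_that("bias audit flags a planted voxel-count difference", {
  hits <- matrix(NA, 20, 4)
  for (s in 1:20) {
    set.seed(400 + s)
    at <- data.frame(subject = 1:14,
                     group = rep(c("control", "patient"), c(8, 6)),
                     area = "V3d",
                     convergence_magnitude = rnorm(14))
    at$d_median_ve <- rnorm(14, 0, 0.05)
    at$d_n_voxels <- rnorm(14, 0, 10) + c(rep(0, 8), rep(60, 6)) # planted
    at$d_prop_point_cf <- rnorm(14, 0, 0.03)
    at$d_mean_ecc <- rnorm(14, 0, 0.3)
    out <- bias_audit(at, mc_seed = s)
    hits[s, ] <- out$significant[match(c("d_median_ve", "d_n_voxels",
                                         "d_prop_point_cf", "d_mean_ecc"),
                                       out$variable)]
  }
  expect_gte(mean(hits[, 2]), 0.9)               # planted variable flagged
  expect_lte(mean(hits[, c(1, 3, 4)]), 0.1)      # others rarely
})

test_that("Spearman follow-up runs only for significant variables", {
  set.seed(99)
  at <- data.frame(subject = 1:14, group = rep(c("a", "b"), c(8, 6)),
                   area = "V2d", convergence_magnitude = rnorm(14))
  at$d_median_ve <- rnorm(14, 0, 0.05)
  at$d_n_voxels <- c(rnorm(8, 0, 5), rnorm(6, 100, 5))
  at$d_prop_point_cf <- rnorm(14, 0, 0.02)
  at$d_mean_ecc <- rnorm(14, 0, 0.2)
  out <- bias_audit(at)
  expect_true(out$significant[out$variable == "d_n_voxels"])
  expect_false(is.na(out$rho[out$variable == "d_n_voxels"]))
  expect_true(all(is.na(out$rho[!out$significant])))
})
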