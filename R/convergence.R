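# Aggregation of CF fits into sampling-extent summaries, convergence
# magnitudes, and hierarchy-slope fits.

.hier_levels <- c(V1 = 0, V2 = 1, V2d = 1, V2v = 1, V3 = 2, V3d = 2, V3v = 2,
                  hV4 = 3, LO = 3.5, TO = 5.5)

# area sets per stream (composite V2/V3 for "both", subdivisions for the
# individual streams)
.stream_areas <- list(
  both = c("V2", "V3", "hV4", "LO", "TO"),
  dorsal = c("V2d", "V3d", "TO"),
  ventral = c("V2v", "V3v", "hV4", "LO")
)

#' Hierarchical level of a visual area
#'
#' V1 = 0, V2 (d/v) = 1, V3 (d/v) = 2, hV4 = 3, LO = 3.5, TO = 5.5 (LO and
#' TO are the averages of their LO1/LO2 and TO1/TO2 sublevels).
#' @param area area name.
#' @export
hierarchy_level <- function(area) {
  lev <- .hier_levels[area]
  assert_that(!anyNA(lev), "unknown area name '%s'",
              paste(area[is.na(lev)], collapse = ", "))
  unname(lev)
}

#' Voxel selection for sampling-extent summaries
#'
#' Keeps rows with `ve >= ve_min`, `sigma_mm > 0.0001` (point CFs indicate a
#' one-on-one connection, not a connective field area), and target
#' eccentricity inside `ecc_window` (bounds inclusive). Rows with NA fits
#' (zero-variance targets) are dropped first. Exclusion reasons are tallied
#' with priority ve, then point-CF, then eccentricity.
#'
#' @param cf_table a CF table with `ve`, `sigma_mm`, `target_ecc_deg`.
#' @param ve_min variance-explained threshold (default 0.20, inclusive).
#' @param ecc_window eccentricity window in degrees (default `c(0.5, 7.5)`).
#' @return list: `kept` (filtered table), `tallies` (named counts:
#'   `ve`, `point_cf`, `eccentricity`, `invalid`).
#' @export
select_voxels <- function(cf_table, ve_min = 0.20, ecc_window = c(0.5, 7.5)) {
  stopifnot(all(c("ve", "sigma_mm", "target_ecc_deg") %in% names(cf_table)))
  invalid <- is.na(cf_table$ve)
  t <- cf_table[!invalid, , drop = FALSE]
  fail_ve <- t$ve < ve_min
  fail_pt <- t$sigma_mm <= 0.0001
  fail_ecc <- t$target_ecc_deg < ecc_window[1] | t$target_ecc_deg > ecc_window[2]
  reason <- rep("kept", nrow(t))
  reason[fail_ecc] <- "eccentricity"
  reason[fail_pt] <- "point_cf"
  reason[fail_ve] <- "ve"
  list(
    kept = t[reason == "kept", , drop = FALSE],
    tallies = c(ve = sum(reason == "ve"),
                point_cf = sum(reason == "point_cf"),
                eccentricity = sum(reason == "eccentricity"),
                invalid = sum(invalid))
  )
}

#' Lower weighted median
#'
#' Smallest value whose cumulative weight reaches half the total weight (no
#' interpolation); equals the lower ordinary median when all weights are
#' equal.
#' @param values numeric vector.
#' @param weights non-negative weights, not all zero.
#' @export
weighted_median <- function(values, weights = rep(1, length(values))) {
  assert_that(length(values) > 0, "weighted_median of empty input")
  assert_that(length(values) == length(weights), "lengths differ")
  assert_that(all(weights >= 0) && sum(weights) > 0,
              "weights must be non-negative and not all zero")
  o <- order(values)
  cw <- cumsum(weights[o])
  values[o][which(cw >= sum(weights) / 2)[1]]
}

#' Convergence magnitude
#'
#' Forward minus backward sampling extent, `SE(V1 -> x) - SE(x -> V1)`;
#' positive values indicate convergence from V1 to area x, negative values
#' divergence.
#' @param se_fwd,se_back sampling extents in mm.
#' @export
convergence_magnitude <- function(se_fwd, se_back) {
  assert_that(all(is.finite(se_fwd)) && all(is.finite(se_back)),
              "sampling extents must be finite")
  se_fwd - se_back
}

#' Summarize a CF table into a sampling-extent summary
#'
#' Applies [select_voxels()] and computes the VE-weighted median sampling
#' extent plus the audit variables (included-voxel count, point-CF
#' proportion among eccentricity-window voxels, median VE, mean target
#' eccentricity).
#' @inheritParams select_voxels
#' @return one-row data frame (`weighted_median_se`, `n_voxels_included`,
#'   `proportion_point_cf`, `median_ve`, `mean_target_ecc`); NA summary
#'   values when no voxel survives.
#' @export
summarize_fits <- function(cf_table, ve_min = 0.20, ecc_window = c(0.5, 7.5)) {
  sel <- select_voxels(cf_table, ve_min, ecc_window)
  k <- sel$kept
  valid <- cf_table[!is.na(cf_table$ve), , drop = FALSE]
  in_ecc <- valid$target_ecc_deg >= ecc_window[1] &
    valid$target_ecc_deg <= ecc_window[2]
  data.frame(
    weighted_median_se = if (nrow(k)) weighted_median(k$sampling_extent_mm, k$ve) else NA_real_,
    n_voxels_included = nrow(k),
    proportion_point_cf = if (any(in_ecc)) mean(valid$sigma_mm[in_ecc] <= 0.0001) else NA_real_,
    median_ve = if (nrow(k)) stats::median(k$ve) else NA_real_,
    mean_target_ecc = if (nrow(k)) mean(k$target_ecc_deg) else NA_real_
  )
}

#' OLS slope of convergence magnitude along the hierarchy
#'
#' Regresses a subject's convergence magnitudes on hierarchy level over the
#' stream's area set (`both`: V2, V3, hV4, LO, TO; `dorsal`: V2d, V3d, TO;
#' `ventral`: V2v, V3v, hV4, LO).
#' @param records data frame with `area` and `convergence_magnitude`.
#' @param stream one of `"both"`, `"dorsal"`, `"ventral"`.
#' @return data frame row: `stream`, `slope`, `intercept`, `n_areas`.
#' @export
fit_hierarchy_slope <- function(records, stream = c("both", "dorsal", "ventral")) {
  stream <- match.arg(stream)
  areas <- .stream_areas[[stream]]
  r <- records[records$area %in% areas & !is.na(records$convergence_magnitude), ]
  lev <- hierarchy_level(r$area)
  assert_that(length(unique(lev)) >= 2,
              "stream %s has < 2 distinct hierarchy levels with data", stream)
  fit <- stats::lm.fit(cbind(1, lev), r$convergence_magnitude)
  data.frame(stream = stream, slope = unname(fit$coefficients[2]),
             intercept = unname(fit$coefficients[1]), n_areas = nrow(r),
             stringsAsFactors = FALSE)
}

#' Bias-variable audit
#'
#' For each area and each direction-difference variable (V1->x minus x->V1
#' differences of median VE, included-voxel count, point-CF proportion, and
#' mean target eccentricity), compares groups with the exact rank-sum test,
#' Bonferroni-corrected over the audited variables. For every variable whose
#' corrected p falls below `alpha`, the Spearman correlation between that
#' variable and the convergence magnitude across all subjects is computed,
#' Bonferroni-corrected over the number of correlations assessed.
#'
#' @param audit_table data frame with columns `subject`, `group` (two
#'   levels), `area`, `convergence_magnitude`, and the audited variables.
#' @param variables names of the audited difference variables.
#' @param alpha significance level on corrected p-values.
#' @param mc_seed seed for the Monte-Carlo tie fallback of the rank-sum test.
#' @return data frame: one row per area x variable with test and (where
#'   assessed) correlation results.
#' @export
bias_audit <- function(audit_table,
                       variables = c("d_median_ve", "d_n_voxels",
                                     "d_prop_point_cf", "d_mean_ecc"),
                       alpha = 0.05, mc_seed = 1) {
  missing_vars <- setdiff(variables, names(audit_table))
  assert_that(length(missing_vars) == 0, "audit table is missing variables: %s",
              paste(missing_vars, collapse = ", "))
  groups <- sort(unique(audit_table$group))
  assert_that(length(groups) == 2, "bias audit needs exactly two groups")
  m <- length(variables)
  rows <- list()
  for (area in unique(audit_table$area)) {
    at <- audit_table[audit_table$area == area, ]
    for (v in variables) {
      x <- at[[v]][at$group == groups[1]]
      y <- at[[v]][at$group == groups[2]]
      tst <- rank_sum_test(x = x, y = y, correction_m = m, mc_seed = mc_seed)
      rows[[length(rows) + 1]] <- data.frame(
        area = area, variable = v, W = tst$statistic,
        p_raw = tst$p_raw, p_corrected = tst$p_corrected,
        significant = tst$p_corrected < alpha,
        rho = NA_real_, rho_p_raw = NA_real_, rho_p_corrected = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  sig <- which(out$significant)
  for (i in sig) {
    at <- audit_table[audit_table$area == out$area[i], ]
    sp <- spearman_corr(at[[out$variable[i]]], at$convergence_magnitude)
    out$rho[i] <- sp$rho
    out$rho_p_raw[i] <- sp$p
    out$rho_p_corrected[i] <- bonferroni(sp$p, length(sig))
  }
  out
}
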