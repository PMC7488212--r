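# Ground-truth coupling regimes for the synthetic cortex.
#
# The generator couples areas through Gaussian kernels on the source
# surface: the forward kernel (V1 -> x) has width base + diff(x), the
# backward kernel (x -> V1) has width base, so the forward-backward width
# difference -- the quantity the convergence-magnitude statistic estimates
# -- equals diff(x) = slope * hierarchy_level(x) + offset(x).

#' Group-regime ground truth for the synthetic cortex
#'
#' Control regime: the forward-backward kernel width difference increases
#' linearly with hierarchy level at `slope_mm_per_level` (default 1.61
#' mm/level). Patient regime: flat slope (default 0) with a V1-V3d offset of
#' 4.45 mm. All defaults are overridable.
#'
#' @param group `"control"` or `"patient"`.
#' @param seed integer seed stored with the regime (subject-level jitter is
#'   derived from it).
#' @param slope_mm_per_level convergence slope; `NULL` picks the group
#'   default.
#' @param base_width_mm backward (feedback) kernel width, shared by all
#'   areas.
#' @param area_offsets named numeric vector of per-area additive width
#'   offsets (mm); `NULL` picks the group default.
#' @param subject_jitter_sd sd (mm) of between-subject Gaussian jitter
#'   applied to every kernel width by [subject_truth()].
#' @param feedback_frac fraction of each V1 series generated from
#'   extrastriate latents through the backward kernel.
#' @param noise_sd additive white-noise sd, in units of the clean-signal
#'   global RMS.
#' @param drift_amp maximum absolute amplitude of the random linear drift.
#' @param areas extrastriate areas covered by the regime.
#' @return a `cf_truth` list with a `widths` table (area, level, w_fwd,
#'   w_bwd, diff).
#' @export
make_group_truth <- function(group = c("control", "patient"), seed = 1,
                             slope_mm_per_level = NULL, base_width_mm = 1,
                             area_offsets = NULL, subject_jitter_sd = 0.3,
                             feedback_frac = 0.2, noise_sd = 0.25,
                             drift_amp = 0.5,
                             areas = c("V2d", "V2v", "V3d", "V3v", "hV4", "LO", "TO")) {
  group <- match.arg(group)
  if (is.null(slope_mm_per_level))
    slope_mm_per_level <- if (group == "control") 1.61 else 0
  if (is.null(area_offsets))
    area_offsets <- if (group == "control") c() else c(V3d = 4.45)
  lev <- vapply(areas, hierarchy_level, numeric(1))
  off <- vapply(areas, function(a) unname(area_offsets[a] %||% NA_real_), numeric(1))
  off[is.na(off)] <- 0
  diffs <- slope_mm_per_level * lev + off
  widths <- data.frame(
    area = areas, level = lev,
    w_fwd = base_width_mm + diffs, w_bwd = base_width_mm, diff = diffs,
    stringsAsFactors = FALSE, row.names = NULL
  )
  assert_that(all(widths$w_fwd > 0) && all(widths$w_bwd > 0),
              "kernel widths must be > 0")
  structure(list(group = group, seed = as.integer(seed),
                 slope_mm_per_level = slope_mm_per_level,
                 base_width_mm = base_width_mm, widths = widths,
                 subject_jitter_sd = subject_jitter_sd,
                 feedback_frac = feedback_frac, noise_sd = noise_sd,
                 drift_amp = drift_amp),
            class = "cf_truth")
}

#' Per-subject realization of a group regime
#'
#' Jitters every kernel width by `N(0, subject_jitter_sd^2)` (truncated
#' below at 0.15 mm so widths stay positive and resolvable on the size
#' grid), deterministically from `subject_seed`.
#' @param truth a `cf_truth`.
#' @param subject_seed integer.
#' @export
subject_truth <- function(truth, subject_seed) {
  with_seed(subject_seed, {
    w <- truth$widths
    w$w_fwd <- pmax(0.15, w$w_fwd + stats::rnorm(nrow(w), 0, truth$subject_jitter_sd))
    w$w_bwd <- pmax(0.15, w$w_bwd + stats::rnorm(nrow(w), 0, truth$subject_jitter_sd))
    w$diff <- w$w_fwd - w$w_bwd
    out <- truth
    out$widths <- w
    out$subject_seed <- as.integer(subject_seed)
    out
  })
}

truth_width <- function(truth, area, direction = c("fwd", "bwd")) {
  direction <- match.arg(direction)
  row <- truth$widths[truth$widths$area == area, ]
  assert_that(nrow(row) == 1, "no ground-truth kernel for area %s", area)
  if (direction == "fwd") row$w_fwd else row$w_bwd
}
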