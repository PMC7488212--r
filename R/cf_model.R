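# Circular Gaussian connective-field model on the source-region cortical
# surface. A target unit's series is predicted as gain * sum_i w_i s_i(t)
# with w_i = exp(-d(v0, i)^2 / (2 sigma^2)) normalized to sum 1, d geodesic
# distance on the source surface. Fitting is an exhaustive search over all
# source units v0 and the fixed size grid.

.cf_dist_cache <- new.env(parent = emptyenv())

#' Geodesic distance matrix of a source region
#'
#' Shortest-path distances over the mesh edge graph (Euclidean edge
#' lengths), restricted to the ROI's vertices. Results are cached per
#' (mesh hash, ROI) pair; editing the mesh changes its hash and invalidates
#' the cache.
#' @param mesh a `cf_mesh`.
#' @param roi integer vertex indices of the region.
#' @return symmetric matrix (mm) with unit ids as dimnames.
#' @export
geodesic_distances <- function(mesh, roi) {
  key <- content_key(mesh$hash, roi)
  hit <- .cf_dist_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- roi_graph(mesh, roi)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- table(comp$membership)
    stop_cf("ROI is disconnected: %d components of sizes %s",
            comp$no, paste(sizes, collapse = ", "))
  }
  d <- igraph::distances(g, algorithm = "dijkstra")
  ids <- as.character(mesh$units$unit_id[roi])
  dimnames(d) <- list(ids, ids)
  .cf_dist_cache[[key]] <- d
  d
}

#' Candidate CF size grid
#'
#' The fixed search grid: 0.0001 mm (the point-CF sentinel, "effectively a
#' one-on-one connection") followed by 0.2, 0.4, ..., 10 mm; 51 values.
#' @return strictly increasing numeric vector of length 51.
#' @export
sigma_grid <- function() c(0.0001, 0.2 * seq_len(50))

#' Normalized circular Gaussian CF weights
#' @param distances_from_v0 geodesic distances (mm) from the CF center.
#' @param sigma CF size in mm (> 0).
#' @return weights summing to 1.
#' @export
cf_weights <- function(distances_from_v0, sigma) {
  assert_that(sigma > 0, "sigma must be > 0")
  w <- exp(-distances_from_v0^2 / (2 * sigma^2))
  w / sum(w)
}

#' Fit connective fields by exhaustive search
#'
#' For every target column, searches all (v0, sigma) pairs; the gain is the
#' non-negative least-squares scalar for each candidate regressor, and the
#' returned fit maximizes variance explained `VE = max(0, 1 - RSS/TSS)`
#' (columns are centered first). VE ties break toward smaller sigma, then
#' smaller v0 index, so outputs are deterministic.
#'
#' @param target_series numeric matrix (time x targets), or vector.
#' @param source_series numeric matrix (time x source units), column order
#'   matching `distances`.
#' @param distances square geodesic distance matrix of the source ROI.
#' @param grid candidate sigmas (default [sigma_grid()]).
#' @param target_ids,source_ids optional unit ids for labeling.
#' @param source_roi label stored in the output.
#' @return data frame with one row per target: `target_unit`, `source_roi`,
#'   `v0` (source unit id), `sigma_mm`, `gain`, `ve`, and `note`
#'   (`"zero_variance"` rows carry NA fits and are excluded downstream).
#' @export
fit_cf <- function(target_series, source_series, distances,
                   grid = sigma_grid(), target_ids = NULL, source_ids = NULL,
                   source_roi = NA_character_) {
  Y <- as.matrix(target_series)
  S <- as.matrix(source_series)
  assert_that(nrow(Y) == nrow(S), "target and source series lengths differ")
  assert_that(ncol(S) == nrow(distances) && nrow(distances) == ncol(distances),
              "distance matrix does not match source series")
  target_ids <- target_ids %||% colnames(Y) %||% seq_len(ncol(Y))
  source_ids <- source_ids %||% rownames(distances) %||% seq_len(ncol(S))

  Y <- scale(Y, center = TRUE, scale = FALSE)
  S <- scale(S, center = TRUE, scale = FALSE)
  k <- ncol(Y)
  tss <- colSums(Y^2)
  dead <- tss <= 1e-12 * nrow(Y)

  best_ve <- rep(-1, k); best_sigma <- rep(NA_real_, k)
  best_v0 <- rep(NA_integer_, k); best_gain <- rep(NA_real_, k)
  d2 <- distances^2
  for (sigma in sort(grid)) {
    W <- exp(-d2 / (2 * sigma^2))           # rows: candidate v0
    W <- W / rowSums(W)
    P <- S %*% t(W)                          # time x n_v0
    pp <- colSums(P^2)
    C <- crossprod(P, Y)                     # n_v0 x k
    ve <- C^2 / (outer(pmax(pp, 1e-300), pmax(tss, 1e-300)))
    ve[C <= 0] <- 0
    idx <- max.col(t(ve), ties.method = "first")  # first max -> smallest v0
    cand <- ve[cbind(idx, seq_len(k))]
    upd <- cand > best_ve & !dead                 # strict: earlier sigma wins ties
    if (any(upd)) {
      best_ve[upd] <- cand[upd]
      best_sigma[upd] <- sigma
      best_v0[upd] <- idx[upd]
      best_gain[upd] <- pmax(0, C[cbind(idx, seq_len(k))] / pp[idx])[upd]
    }
  }
  best_ve[dead] <- NA_real_
  best_ve[!dead] <- pmin(1, pmax(0, best_ve[!dead]))
  data.frame(
    target_unit = as.vector(target_ids), source_roi = source_roi,
    v0 = ifelse(is.na(best_v0), NA, as.vector(source_ids)[best_v0]),
    v0_index = best_v0,
    sigma_mm = best_sigma, gain = best_gain, ve = best_ve,
    note = ifelse(dead, "zero_variance", ""),
    stringsAsFactors = FALSE
  )
}

#' Sampling extent: CF size corrected for ipsilateral representations
#'
#' The correction truncates the CF profile to contralateral source units:
#' `SE = sigma * RMS_contra / RMS_all`, where `RMS_contra` is the weighted
#' RMS geodesic distance from v0 over contralateral units (weights
#' restricted and renormalized) and `RMS_all` over all units. When no
#' ipsilateral unit carries weight above 1e-6, SE = sigma exactly. This
#' truncated-RMS policy is this package's documented stand-in; alternative
#' policies can be passed via `policy`.
#'
#' @param distances_from_v0 geodesic distances (mm) from the fitted center.
#' @param sigma fitted CF size (mm, > 0).
#' @param contralateral logical vector flagging contralateral source units.
#' @param policy correction policy; only `"truncated_rms"` is built in.
#' @return sampling extent in mm.
#' @export
sampling_extent <- function(distances_from_v0, sigma, contralateral,
                            policy = "truncated_rms") {
  assert_that(policy == "truncated_rms", "unknown correction policy '%s'", policy)
  assert_that(sigma > 0, "sampling extent needs sigma > 0")
  w <- exp(-distances_from_v0^2 / (2 * sigma^2))
  w <- w / sum(w)
  if (sum(w[contralateral]) <= 1e-12)
    stop_cf("CF support is entirely ipsilateral; sampling extent undefined")
  if (all(w[!contralateral] <= 1e-6)) return(sigma)
  rms_all <- sqrt(sum(w * distances_from_v0^2) / sum(w))
  wc <- w[contralateral]
  rms_c <- sqrt(sum(wc * distances_from_v0[contralateral]^2) / sum(wc))
  if (rms_all <= 1e-12) return(sigma)
  sigma * rms_c / rms_all
}

#' Fit a full CF table for one direction (source ROI -> target ROI)
#'
#' Convenience wrapper running [fit_cf()] on all target-ROI units with the
#' given source ROI, then attaching sampling extents and target
#' eccentricities.
#' @param mesh a `cf_mesh`.
#' @param ts a preprocessed `cf_ts` covering all mesh units.
#' @param source_area,target_area area labels (composites allowed for the
#'   target only; a composite source would have a disconnected surface).
#' @param grid candidate sigmas.
#' @return CF table data frame (schema of [fit_cf()] plus
#'   `sampling_extent_mm`, `target_ecc_deg`, `direction`).
#' @export
cf_fit_table <- function(mesh, ts, source_area, target_area,
                         grid = sigma_grid()) {
  src <- area_units(mesh, source_area)
  tgt <- area_units(mesh, target_area)
  d <- geodesic_distances(mesh, src)
  cols_src <- match(mesh$units$unit_id[src], ts$unit_ids)
  cols_tgt <- match(mesh$units$unit_id[tgt], ts$unit_ids)
  assert_that(!anyNA(cols_src) && !anyNA(cols_tgt),
              "time series is missing units of %s/%s", source_area, target_area)
  fits <- fit_cf(ts$data[, cols_tgt, drop = FALSE],
                 ts$data[, cols_src, drop = FALSE], d, grid = grid,
                 target_ids = mesh$units$unit_id[tgt],
                 source_ids = mesh$units$unit_id[src],
                 source_roi = source_area)
  contra <- mesh$units$hemifield[src] == "contralateral"
  fits$sampling_extent_mm <- vapply(seq_len(nrow(fits)), function(i) {
    if (is.na(fits$sigma_mm[i])) return(NA_real_)
    sampling_extent(d[fits$v0_index[i], ], fits$sigma_mm[i], contra)
  }, numeric(1))
  fits$target_ecc_deg <- mesh$units$ecc_deg[tgt]
  fits$direction <- paste0(source_area, "->", target_area)
  fits
}
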