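# Forward simulation of stimulus-driven and resting-state BOLD runs on the
# synthetic cortex. The inter-area generative model matches the CF fitting
# model exactly: an extrastriate unit's neural drive is the normalized
# Gaussian-kernel-weighted sum (in geodesic distance on the V1 surface,
# centered on the retinotopically corresponding V1 unit) of V1 drives.

# Nearest source unit in visual-field coordinates, for each target unit.
retinotopic_correspondence <- function(mesh, target_idx, source_idx) {
  tu <- mesh$units[target_idx, ]
  su <- mesh$units[source_idx, ]
  d2 <- outer(tu$vf_x, su$vf_x, `-`)^2 + outer(tu$vf_y, su$vf_y, `-`)^2
  apply(d2, 1, which.min)
}

# Row-stochastic coupling matrix (n_target x n_source): row t holds the CF
# weights of width `width_mm` centered on target t's corresponding source
# unit, over the source geodesic distance matrix.
coupling_matrix <- function(dist_source, corr_idx, width_mm) {
  assert_that(width_mm > 0, "kernel width must be > 0")
  t(vapply(corr_idx, function(c0) cf_weights(dist_source[c0, ], width_mm),
           numeric(ncol(dist_source))))
}

new_cf_ts <- function(data, tr, condition, unit_ids) {
  assert_that(tr > 0, "TR must be > 0")
  colnames(data) <- as.character(unit_ids)
  structure(list(data = data, tr = tr, condition = condition,
                 unit_ids = unit_ids), class = "cf_ts")
}

#' @export
print.cf_ts <- function(x, ...) {
  cat(sprintf("<cf_ts> %d volumes x %d units, TR %g s, condition %s\n",
              nrow(x$data), ncol(x$data), x$tr, x$condition))
  invisible(x)
}

# shared noise model: global rescale to unit RMS, then white noise + linear drift
add_noise <- function(y, noise_sd, drift_amp) {
  rms <- sqrt(mean(y^2))
  if (rms > 0) y <- y / rms
  n <- nrow(y)
  if (noise_sd > 0) y <- y + matrix(stats::rnorm(length(y), 0, noise_sd), n)
  if (drift_amp > 0) {
    slopes <- stats::runif(ncol(y), -drift_amp, drift_amp)
    y <- y + outer(seq(-1, 1, length.out = n), slopes)
  }
  y
}

default_prf_size <- function(ecc_deg) 0.5 + 0.2 * ecc_deg

#' Simulate a stimulus-driven BOLD run
#'
#' V1 units respond through the pRF forward model to the bar movie;
#' extrastriate units pool V1 drives through the forward Gaussian kernel on
#' the V1 surface; a configurable fraction of each V1 series is generated
#' from extrastriate drives through the backward kernels (feedback mixing).
#' All neural series are convolved with the double-gamma HRF and sampled at
#' the movie's step duration (TR 1.5 s by default), then receive white noise
#' and a random linear drift.
#'
#' @param mesh a `cf_mesh` from [build_cortex()].
#' @param truth a `cf_truth` (per-subject realization recommended).
#' @param movie a `cf_movie`; defaults to the standard bar stimulus.
#' @param noise_sd,drift_amp,feedback_frac override the values in `truth`.
#' @param seed integer seed; output is a pure function of arguments + seed.
#' @param prf_size_fun maps eccentricity (deg) to pRF sd (deg).
#' @return a `cf_ts` (`volumes x units`, all mesh units, TR =
#'   `movie$step_dur_s`).
#' @export
simulate_stimulus_run <- function(mesh, truth, movie = NULL,
                                  noise_sd = NULL, drift_amp = NULL,
                                  feedback_frac = NULL, seed = 1,
                                  prf_size_fun = default_prf_size) {
  movie <- movie %||% make_bar_stimulus()
  noise_sd <- noise_sd %||% truth$noise_sd
  drift_amp <- drift_amp %||% truth$drift_amp
  f <- feedback_frac %||% truth$feedback_frac
  with_seed(seed, {
    areas <- truth$widths$area
    v1 <- area_units(mesh, "V1")
    dist_v1 <- geodesic_distances(mesh, v1)
    u <- mesh$units
    n_t <- ncol(movie$frames)

    drive_v1 <- t(prf_response(cbind(u$vf_x[v1], u$vf_y[v1]),
                               prf_size_fun(u$ecc_deg[v1]), movie)) # T x nV1

    neural <- matrix(0, n_t, nrow(u))
    drive_xs <- list()
    for (a in areas) {
      xi <- area_units(mesh, a)
      corr <- retinotopic_correspondence(mesh, xi, v1)
      W <- coupling_matrix(dist_v1, corr, truth_width(truth, a, "fwd"))
      drive_xs[[a]] <- drive_v1 %*% t(W)
      neural[, xi] <- drive_xs[[a]]
    }
    if (f > 0) {
      fb <- matrix(0, n_t, length(v1))
      for (a in areas) {
        xi <- area_units(mesh, a)
        dist_x <- geodesic_distances(mesh, xi)
        corr_b <- retinotopic_correspondence(mesh, v1, xi)
        K <- coupling_matrix(dist_x, corr_b, truth_width(truth, a, "bwd"))
        fb <- fb + drive_xs[[a]] %*% t(K)
      }
      fb <- fb / length(areas)
      neural[, v1] <- (1 - f) * drive_v1 + f * fb
    } else {
      neural[, v1] <- drive_v1
    }

    bold <- convolve_hrf(neural, movie$step_dur_s)
    bold <- add_noise(bold, noise_sd, drift_amp)
    new_cf_ts(bold, movie$step_dur_s, "stimulus", u$unit_id)
  })
}

#' Simulate a resting-state BOLD run
#'
#' A spatially smooth, temporally band-limited (< `f_max` Hz) latent field
#' over visual-field coordinates is sampled at every unit's visual-field
#' position. Each area's latent mixes a field shared by all areas with an
#' independent area-local field of the same construction (`local_frac`
#' variance share), so corresponding units across areas are correlated but
#' not copies. Each area's series then mixes its own latent sample with the
#' kernel-propagated latent of the coupled area: extrastriate units receive
#' `feedback_frac` of the forward-kernel-pooled V1 latent, and V1 units
#' receive `feedback_frac` of the backward-kernel-pooled extrastriate
#' latents. Noise as in stimulus runs.
#'
#' @inheritParams simulate_stimulus_run
#' @param n_volumes run length (default 240 volumes, i.e. 8 min at TR 2 s).
#' @param tr repetition time in seconds (default 2).
#' @param latent_grid_n latent field grid points per axis.
#' @param spatial_sd_deg spatial correlation scale of the latent field.
#' @param sample_sd_deg sd of the Gaussian with which units sample the field.
#' @param ar_coef AR(1) coefficient of the latent dynamics.
#' @param f_max temporal band limit (Hz).
#' @param local_frac variance share of each area's independent local field.
#' @export
simulate_rest_run <- function(mesh, truth, n_volumes = 240, tr = 2.0,
                              noise_sd = NULL, drift_amp = NULL,
                              feedback_frac = NULL, seed = 1,
                              latent_grid_n = 12, spatial_sd_deg = 1,
                              sample_sd_deg = 0.5, ar_coef = 0.8, f_max = 0.1,
                              local_frac = 0.3) {
  assert_that(n_volumes >= 16, "resting run needs >= 16 volumes")
  noise_sd <- noise_sd %||% truth$noise_sd
  drift_amp <- drift_amp %||% truth$drift_amp
  # rest coupling share: without stimulus drive the propagated inter-area
  # component is comparatively stronger than the stimulus-condition feedback
  # mixing, so rest defaults to 0.5 rather than truth$feedback_frac
  f <- feedback_frac %||% 0.5
  with_seed(seed, {
    areas <- truth$widths$area
    u <- mesh$units
    v1 <- area_units(mesh, "V1")
    dist_v1 <- geodesic_distances(mesh, v1)

    # latent grid over the full stimulus field
    gx <- seq(-8, 8, length.out = latent_grid_n)
    G <- as.matrix(expand.grid(x = gx, y = gx))
    J <- nrow(G)
    d2 <- as.matrix(stats::dist(G))^2
    smooth_field <- function() {
      L <- matrix(stats::rnorm(n_volumes * J), n_volumes, J)
      for (t in 2:n_volumes) L[t, ] <- ar_coef * L[t - 1, ] + L[t, ]
      L <- fft_lowpass(L, tr, f_max)
      L %*% exp(-d2 / (2 * spatial_sd_deg^2))
    }
    shared <- smooth_field()
    locals <- lapply(c(list(V1 = NULL), stats::setNames(vector("list", length(areas)), areas)),
                     function(x) smooth_field())

    sample_field <- function(idx, L) {
      S <- exp(-(outer(u$vf_x[idx], G[, 1], `-`)^2 +
                   outer(u$vf_y[idx], G[, 2], `-`)^2) / (2 * sample_sd_deg^2))
      S <- S / rowSums(S)
      L %*% t(S)
    }
    area_latent <- function(idx, who)
      sqrt(1 - local_frac) * sample_field(idx, shared) +
        sqrt(local_frac) * sample_field(idx, locals[[who]])

    lat_v1 <- area_latent(v1, "V1")
    neural <- matrix(0, n_volumes, nrow(u))
    fb <- matrix(0, n_volumes, length(v1))
    for (a in areas) {
      xi <- area_units(mesh, a)
      lat_x <- area_latent(xi, a)
      corr_f <- retinotopic_correspondence(mesh, xi, v1)
      Wf <- coupling_matrix(dist_v1, corr_f, truth_width(truth, a, "fwd"))
      neural[, xi] <- (1 - f) * lat_x + f * (lat_v1 %*% t(Wf))
      dist_x <- geodesic_distances(mesh, xi)
      corr_b <- retinotopic_correspondence(mesh, v1, xi)
      Kb <- coupling_matrix(dist_x, corr_b, truth_width(truth, a, "bwd"))
      fb <- fb + lat_x %*% t(Kb)
    }
    neural[, v1] <- (1 - f) * lat_v1 + f * fb / length(areas)

    bold <- add_noise(neural, noise_sd, drift_amp)
    new_cf_ts(bold, tr, "rest", u$unit_id)
  })
}

# zero out Fourier components at or above f_max (keeps DC; drift/DC are
# handled by the preprocessing stage)
fft_lowpass <- function(x, tr, f_max) {
  n <- nrow(x)
  fr <- (seq_len(n) - 1) / (n * tr)
  fr <- pmin(fr, 1 / tr - fr)
  keep <- fr < f_max
  Re(stats::mvfft(stats::mvfft(x) * keep, inverse = TRUE)) / n
}

#' Simulate a cohort of subjects from one group regime
#'
#' Each subject gets a jittered realization of the group's kernel widths
#' (see [subject_truth()]) and an independent run; all seeds derive from
#' `seed`.
#'
#' @param group `"control"` or `"patient"`.
#' @param n_subjects cohort size (paper design: 8 controls, 6 patients).
#' @param condition `"stimulus"` or `"rest"`.
#' @param mesh a `cf_mesh`; defaults to [build_cortex()] defaults.
#' @param seed master seed.
#' @param truth optional `cf_truth` overriding [make_group_truth()] defaults.
#' @param ... passed to the run simulator.
#' @return list with `mesh`, `truth`, and `subjects` (list of `id`,
#'   `truth` (subject realization), `ts`).
#' @export
simulate_cohort <- function(group, n_subjects, condition = "stimulus",
                            mesh = NULL, seed = 1, truth = NULL, ...) {
  mesh <- mesh %||% build_cortex()
  truth <- truth %||% make_group_truth(group, seed = seed)
  movie <- if (condition == "stimulus") make_bar_stimulus() else NULL
  subjects <- lapply(seq_len(n_subjects), function(i) {
    s_seed <- derive_seed(seed, i)
    tr_i <- subject_truth(truth, s_seed)
    ts <- if (condition == "stimulus")
      simulate_stimulus_run(mesh, tr_i, movie = movie, seed = derive_seed(s_seed, 1), ...)
    else
      simulate_rest_run(mesh, tr_i, seed = derive_seed(s_seed, 1), ...)
    list(id = sprintf("%s_%02d", group, i), truth = tr_i, ts = ts)
  })
  list(mesh = mesh, truth = truth, group = group, subjects = subjects)
}
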