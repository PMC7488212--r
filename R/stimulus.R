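# Drifting-bar aperture movie and the pRF forward model that drives the
# synthetic V1 responses.

#' Drifting-bar stimulus movie
#'
#' Binary bar apertures on a square visual-field grid. The bar is
#' `radius_deg / 4` wide, sweeps perpendicular to its orientation in
#' `n_steps` steps of `step_deg`, for each of `length(orientations)` bar
#' orientations and `directions_per_orientation` motion directions, so the
#' movie has `orientations x directions x n_steps` frames (128 with the
#' defaults). Pixels beyond `radius_deg` eccentricity are always zero.
#'
#' @param radius_deg stimulus radius in degrees (default 8).
#' @param n_steps sweep steps per direction (default 16).
#' @param step_deg step size in degrees (default 1).
#' @param step_dur_s duration of each step in seconds (default 1.5).
#' @param orientations bar orientations in degrees.
#' @param directions_per_orientation motion directions per orientation.
#' @param grid_n pixels per axis of the visual-field grid.
#' @return a `cf_movie`: `frames` is an `n_pix x n_frames` binary matrix,
#'   `px_x`/`px_y` the pixel-center coordinates (degrees), `sweep` a frame
#'   metadata table.
#' @export
make_bar_stimulus <- function(radius_deg = 8, n_steps = 16, step_deg = 1,
                              step_dur_s = 1.5,
                              orientations = c(0, 45, 90, 135),
                              directions_per_orientation = 2,
                              grid_n = 64) {
  assert_that(radius_deg > 0, "radius_deg must be > 0")
  assert_that(n_steps >= 1, "n_steps must be >= 1")
  assert_that(step_dur_s > 0, "step_dur_s must be > 0")
  px <- 2 * radius_deg / grid_n
  ax <- seq(-radius_deg + px / 2, radius_deg - px / 2, length.out = grid_n)
  X <- rep(ax, times = grid_n)
  Y <- rep(ax, each = grid_n)
  inside <- (X^2 + Y^2) <= radius_deg^2
  width <- radius_deg / 4
  positions <- step_deg * (seq_len(n_steps) - (n_steps + 1) / 2)

  n_frames <- length(orientations) * directions_per_orientation * n_steps
  frames <- matrix(0, nrow = grid_n^2, ncol = n_frames)
  sweep <- data.frame(frame = seq_len(n_frames), orientation = NA_real_,
                      direction = NA_integer_, step = NA_integer_)
  k <- 0L
  for (ori in orientations) {
    # bar long axis at `ori`; sweep along the normal
    theta_n <- (ori + 90) * pi / 180
    u <- X * cos(theta_n) + Y * sin(theta_n)
    for (dir in seq_len(directions_per_orientation)) {
      ord <- if (dir %% 2 == 1) seq_len(n_steps) else rev(seq_len(n_steps))
      for (s in seq_len(n_steps)) {
        k <- k + 1L
        pos <- positions[ord[s]]
        frames[, k] <- as.numeric(abs(u - pos) <= width / 2 & inside)
        sweep$orientation[k] <- ori
        sweep$direction[k] <- dir
        sweep$step[k] <- s
      }
    }
  }
  structure(list(frames = frames, px_x = X, px_y = Y, px_area = px^2,
                 radius_deg = radius_deg, bar_width_deg = width,
                 step_dur_s = step_dur_s, sweep = sweep, grid_n = grid_n),
            class = "cf_movie")
}

#' pRF neural drive for one or many population receptive fields
#'
#' The drive of a pRF to each frame is the overlap integral of an isotropic
#' 2D Gaussian (unit total volume) with the binary aperture, so a full-field
#' aperture yields a drive of ~1 and an empty aperture 0.
#'
#' @param prf_center numeric length-2 `(x, y)` in degrees, or an `n x 2`
#'   matrix of centers.
#' @param prf_size Gaussian sd in degrees (> 0), scalar or length `n`.
#' @param movie a `cf_movie`.
#' @return drive vector (one pRF) or `n x n_frames` matrix.
#' @export
prf_response <- function(prf_center, prf_size, movie) {
  centers <- if (is.matrix(prf_center)) prf_center else matrix(prf_center, nrow = 1)
  assert_that(all(prf_size > 0), "prf_size must be > 0")
  sizes <- rep_len(prf_size, nrow(centers))
  far <- sqrt(rowSums(centers^2)) > 2 * movie$radius_deg
  if (any(far))
    warning(sprintf("%d pRF center(s) beyond twice the stimulus radius; drives may be ~0",
                    sum(far)))
  # G: n_prf x n_pix, each row a normalized Gaussian times pixel area
  dx2 <- outer(centers[, 1], movie$px_x, `-`)^2
  dy2 <- outer(centers[, 2], movie$px_y, `-`)^2
  G <- exp(-(dx2 + dy2) / (2 * sizes^2)) / (2 * pi * sizes^2) * movie$px_area
  drive <- G %*% movie$frames
  if (!is.matrix(prf_center)) drop(drive) else drive
}
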