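# Synthetic cortical geometry: flat triangulated patches with a retinotopic
# chart. One unit (voxel/vertex) per mesh vertex; the CF model only ever
# consumes geodesic distances, which flat patches exercise fully.

VISUAL_AREAS <- c("V1", "V2d", "V2v", "V3d", "V3v", "hV4", "LO", "TO")
COMPOSITE_AREAS <- list(V2 = c("V2d", "V2v"), V3 = c("V3d", "V3v"))

new_surface_mesh <- function(vertices, faces, units) {
  structure(list(
    vertices = vertices, faces = faces, units = units,
    hash = content_key(as.numeric(vertices), as.numeric(faces),
                       units$unit_id, units$area)
  ), class = "cf_mesh")
}

#' @export
print.cf_mesh <- function(x, ...) {
  cat(sprintf("<cf_mesh> %d vertices, %d faces, areas: %s\n",
              nrow(x$vertices), nrow(x$faces),
              paste(unique(x$units$area), collapse = ", ")))
  invisible(x)
}

#' Build a flat triangulated cortical patch with a retinotopic chart
#'
#' Constructs a regular `nx` by `ny` grid of units at `spacing_mm` intervals,
#' triangulated into `2*(nx-1)*(ny-1)` faces, and assigns each vertex a
#' visual-field position: log-eccentricity runs linearly along the x axis of
#' the patch and polar angle along the y axis. Units are contralateral by
#' default; `ipsi_rows` appends extra rows whose polar angle crosses the
#' vertical meridian (|polar| > 90 deg) and which are flagged ipsilateral,
#' giving the patch an ipsilateral margin strip.
#'
#' @param area area label for every unit (one of `V1, V2d, V2v, V3d, V3v,
#'   hV4, LO, TO`).
#' @param nx,ny grid dimensions; `nx * ny >= 4` required.
#' @param spacing_mm inter-vertex spacing in mm (default 1).
#' @param ecc_range eccentricity coverage in degrees, within (0, 8].
#' @param polar_range polar-angle coverage in degrees of the contralateral
#'   rows; must stay within [-90, 90].
#' @param hemi hemisphere label.
#' @param ipsi_rows number of extra ipsilateral rows appended beyond
#'   `polar_range[2]`.
#' @param origin 3-vector offset of the patch in space (mm).
#' @param unit_offset first unit id minus one (used when assembling several
#'   patches into one cortex).
#' @return a `cf_mesh` whose `units` data frame carries the region labeling
#'   (`area`, `hemi`) and retinotopic map (`ecc_deg`, `polar_deg`,
#'   `hemifield`, plus visual-field Cartesian coordinates `vf_x`, `vf_y`).
#' @export
build_flat_patch <- function(area, nx, ny, spacing_mm = 1,
                             ecc_range = c(0.5, 8), polar_range = c(-80, 80),
                             hemi = "left", ipsi_rows = 0L,
                             origin = c(0, 0, 0), unit_offset = 0L) {
  assert_that(area %in% VISUAL_AREAS, "unknown area '%s'", area)
  assert_that(nx >= 2 && ny >= 2, "patch needs at least a 2x2 grid (>= 4 units)")
  assert_that(spacing_mm > 0, "spacing_mm must be > 0")
  assert_that(ecc_range[1] > 0 && ecc_range[2] <= 8 && diff(ecc_range) > 0,
              "degenerate or out-of-range eccentricity coverage [%g, %g]; need 0 < lo < hi <= 8",
              ecc_range[1], ecc_range[2])
  assert_that(polar_range[1] >= -90 && polar_range[2] <= 90 &&
                diff(polar_range) > 0,
              "contralateral polar coverage must be within [-90, 90] degrees")

  ny_tot <- ny + ipsi_rows
  ix <- rep(seq_len(nx), times = ny_tot)
  iy <- rep(seq_len(ny_tot), each = nx)
  vertices <- cbind(
    x = origin[1] + (ix - 1) * spacing_mm,
    y = origin[2] + (iy - 1) * spacing_mm,
    z = origin[3] + 0
  )

  # two triangles per grid cell
  cell <- expand.grid(cx = seq_len(nx - 1), cy = seq_len(ny_tot - 1))
  v00 <- (cell$cy - 1) * nx + cell$cx
  v10 <- v00 + 1L
  v01 <- v00 + nx
  v11 <- v01 + 1L
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  colnames(faces) <- c("a", "b", "c")

  ecc <- exp(seq(log(ecc_range[1]), log(ecc_range[2]), length.out = nx))[ix]
  polar_step <- diff(polar_range) / max(ny - 1, 1)
  polar_axis <- c(seq(polar_range[1], polar_range[2], length.out = ny),
                  if (ipsi_rows > 0)
                    polar_range[2] + polar_step * seq_len(ipsi_rows) +
                      pmax(0, 90 - polar_range[2]) + 1)
  polar <- polar_axis[iy]
  hemifield <- ifelse(abs(polar) <= 90, "contralateral", "ipsilateral")

  units <- data.frame(
    unit_id = unit_offset + seq_len(nx * ny_tot),
    area = area, hemi = hemi,
    ecc_deg = ecc, polar_deg = polar, hemifield = hemifield,
    vf_x = ecc * cos(polar * pi / 180),
    vf_y = ecc * sin(polar * pi / 180),
    stringsAsFactors = FALSE
  )
  mesh <- new_surface_mesh(vertices, faces, units)
  validate_mesh(mesh)
  mesh
}

#' Validate surface-mesh invariants
#'
#' Checks that every face references valid vertices, that all edges have
#' strictly positive length, and that the subgraph of each labeled region is
#' connected.
#' @param mesh a `cf_mesh`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  nv <- nrow(mesh$vertices)
  assert_that(all(mesh$faces >= 1 & mesh$faces <= nv),
              "face references vertex outside 1..%d", nv)
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
  assert_that(all(len > 0), "mesh contains zero-length edges")
  for (a in unique(mesh$units$area)) {
    roi <- which(mesh$units$area == a)
    g <- roi_graph(mesh, roi)
    comp <- igraph::components(g)
    assert_that(comp$no == 1, "region %s is disconnected (%d components)",
                a, comp$no)
  }
  invisible(TRUE)
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# igraph of the mesh edge graph restricted to the given vertex indices,
# with Euclidean edge lengths as weights.
roi_graph <- function(mesh, roi_idx) {
  e <- mesh_edges(mesh)
  keep <- e[, 1] %in% roi_idx & e[, 2] %in% roi_idx
  e <- e[keep, , drop = FALSE]
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  remap <- match(as.vector(t(e)), roi_idx)
  g <- igraph::make_empty_graph(n = length(roi_idx), directed = FALSE)
  g <- igraph::add_edges(g, remap, weight = w)
  g
}

#' Assemble a synthetic visual cortex (V1 plus extrastriate patches)
#'
#' Builds one flat patch per area, spatially offset so patches are disjoint,
#' all sharing the same retinotopic coverage so that inter-area retinotopic
#' correspondence is well defined.
#'
#' @param v1_dim `c(nx, ny)` grid of the V1 patch.
#' @param xs_dim `c(nx, ny)` grid of every extrastriate patch.
#' @param areas extrastriate areas to include.
#' @param spacing_mm inter-vertex spacing of extrastriate patches.
#' @param v1_spacing_mm inter-vertex spacing of the V1 patch. The default
#'   (2 mm) makes V1 span 24 mm so that forward kernels up to the 10 mm
#'   grid maximum remain identifiable, while extrastriate patches keep 1 mm
#'   spacing to resolve the ~1 mm backward kernels.
#' @param ecc_range shared eccentricity coverage (degrees).
#' @param ipsi_rows ipsilateral margin rows per patch.
#' @return a single `cf_mesh` containing all patches.
#' @export
build_cortex <- function(v1_dim = c(13, 13), xs_dim = c(6, 6),
                         areas = c("V2d", "V2v", "V3d", "V3v", "hV4", "LO", "TO"),
                         spacing_mm = 1, v1_spacing_mm = 2,
                         ecc_range = c(0.5, 7.5), ipsi_rows = 0L) {
  dims <- c(list(V1 = v1_dim), stats::setNames(rep(list(xs_dim), length(areas)), areas))
  meshes <- list()
  offset <- 0L
  for (i in seq_along(dims)) {
    a <- names(dims)[i]
    d <- dims[[i]]
    meshes[[a]] <- build_flat_patch(
      a, d[1], d[2],
      spacing_mm = if (a == "V1") v1_spacing_mm else spacing_mm,
      ecc_range = ecc_range,
      ipsi_rows = ipsi_rows, origin = c(0, 0, (i - 1) * 100), unit_offset = offset)
    offset <- offset + nrow(meshes[[a]]$vertices)
  }
  vertices <- do.call(rbind, lapply(meshes, `[[`, "vertices"))
  nv <- vapply(meshes, function(m) nrow(m$vertices), integer(1))
  shift <- cumsum(c(0L, nv[-length(nv)]))
  faces <- do.call(rbind, Map(function(m, s) m$faces + s, meshes, shift))
  units <- do.call(rbind, lapply(meshes, `[[`, "units"))
  rownames(units) <- NULL
  new_surface_mesh(vertices, faces, units)
}

#' Unit indices of an area (composites V2/V3 resolve to their subdivisions)
#' @param mesh a `cf_mesh`.
#' @param area area label, possibly composite (`V2`, `V3`).
#' @return integer vertex indices.
#' @export
area_units <- function(mesh, area) {
  labs <- if (area %in% names(COMPOSITE_AREAS)) COMPOSITE_AREAS[[area]] else area
  idx <- which(mesh$units$area %in% labs)
  assert_that(length(idx) > 0, "no units labeled %s", area)
  idx
}
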