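# Plain-text file formats: ASCII OBJ meshes, TSV unit tables (labels +
# retinotopy), TSV time-series matrices with a JSON sidecar carrying TR and
# condition, and a JSON run configuration.

#' Write / read a surface mesh as ASCII OBJ
#'
#' `v x y z` records in mm and 1-based `f i j k` records. Unit metadata is
#' not part of OBJ; pair with [write_units_tsv()].
#' @param mesh a `cf_mesh`.
#' @param path file path.
#' @export
write_mesh_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_mesh_obj
#' @param units_path optional units TSV to restore labels and retinotopy.
#' @export
read_mesh_obj <- function(path, units_path = NULL) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vl, " +"), function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, " +"), function(p) as.integer(p[2:4])))
  colnames(vertices) <- c("x", "y", "z")
  colnames(faces) <- c("a", "b", "c")
  units <- if (!is.null(units_path)) read_units_tsv(units_path)
  else data.frame(unit_id = seq_len(nrow(vertices)), area = "V1",
                  hemi = "left", ecc_deg = NA_real_, polar_deg = NA_real_,
                  hemifield = "contralateral", vf_x = NA_real_, vf_y = NA_real_)
  new_surface_mesh(vertices, faces, units)
}

#' Write / read the unit table (labels + retinotopy) as TSV
#' @param mesh a `cf_mesh`.
#' @param path file path.
#' @export
write_units_tsv <- function(mesh, path) {
  utils::write.table(mesh$units, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_units_tsv
#' @export
read_units_tsv <- function(path) {
  u <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "area", "hemi", "ecc_deg", "polar_deg", "hemifield")
  missing <- setdiff(need, names(u))
  assert_that(length(missing) == 0, "units TSV missing columns: %s",
              paste(missing, collapse = ", "))
  if (is.null(u$vf_x)) {
    u$vf_x <- u$ecc_deg * cos(u$polar_deg * pi / 180)
    u$vf_y <- u$ecc_deg * sin(u$polar_deg * pi / 180)
  }
  u
}

#' Write / read a time-series matrix as TSV with a JSON sidecar
#'
#' Volumes in rows, units in columns (headers = unit ids); the sidecar
#' `<path>.json` records TR and condition.
#' @param ts a `cf_ts`.
#' @param path file path of the TSV.
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(format(ts$data, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = ts$tr, condition = ts$condition),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  x <- as.matrix(utils::read.delim(path, check.names = FALSE))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_cf_ts(x, side$tr, side$condition, as.integer(colnames(x)))
}

#' Run configuration with the analysis constants
#'
#' Defaults reproduce the stated analysis constants: VE threshold 0.20,
#' eccentricity window `[0.5, 7.5]` deg, size grid 0.0001 + 0.2..10 mm,
#' detrend-only filtering for stimulus and 0.01-0.1 Hz bandpass for rest,
#' Bonferroni factor 3 for the stream comparisons and 9 for the area
#' comparisons.
#' @param ... overrides of any default field.
#' @return a `cf_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    condition = "stimulus",
    ve_min = 0.20,
    ecc_window = c(0.5, 7.5),
    sigma_grid = sigma_grid(),
    band_rest = c(0.01, 0.1),
    streams = c("both", "dorsal", "ventral"),
    bonferroni_streams = 3L,
    bonferroni_areas = 9L,
    areas = c("V2", "V2d", "V2v", "V3", "V3d", "V3v", "hV4", "LO", "TO"),
    n_controls = 8L,
    n_patients = 6L,
    v1_dim = c(13, 13),
    xs_dim = c(6, 6),
    seed = 1L,
    paths = NULL,
    tr = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  assert_that(length(unknown) == 0, "unknown config fields: %s",
              paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "cf_config")
}

#' Load and cross-validate a real-data (or exported synthetic) dataset
#'
#' Reads the mesh (OBJ), unit table (TSV) and time series (TSV + sidecar)
#' named in `config$paths` (fields `mesh`, `units`, `timeseries`), checks
#' that every time-series column has a label and retinotopic entry, and that
#' the sidecar TR matches `config$tr` when both are set.
#' @param config a `cf_config` with non-NULL `paths`.
#' @return list `mesh`, `ts`.
#' @export
load_dataset <- function(config) {
  p <- config$paths
  assert_that(!is.null(p), "config$paths is not set")
  for (f in c("mesh", "units", "timeseries"))
    assert_that(file.exists(p[[f]] %||% ""), "missing %s file: %s", f, p[[f]] %||% "<unset>")
  mesh <- read_mesh_obj(p$mesh, units_path = p$units)
  message(sprintf("loaded mesh: %d vertices, %d faces", nrow(mesh$vertices),
                  nrow(mesh$faces)))
  ts <- read_timeseries_tsv(p$timeseries)
  message(sprintf("loaded time series: %d volumes x %d units (TR %g s, %s)",
                  nrow(ts$data), ncol(ts$data), ts$tr, ts$condition))
  orphan <- setdiff(ts$unit_ids, mesh$units$unit_id)
  assert_that(length(orphan) == 0,
              "time-series unit(s) without retinotopy/label entry: %s",
              paste(utils::head(orphan, 5), collapse = ", "))
  assert_that(nrow(mesh$units) == nrow(mesh$vertices),
              "units TSV rows (%d) do not match mesh vertices (%d)",
              nrow(mesh$units), nrow(mesh$vertices))
  if (!is.null(config$tr))
    assert_that(isTRUE(all.equal(config$tr, ts$tr)),
                "TR mismatch: config says %g s, sidecar says %g s", config$tr, ts$tr)
  list(mesh = mesh, ts = ts)
}

#' Export one simulated subject to disk
#' @param mesh a `cf_mesh`; `ts` a `cf_ts`; `dir` output directory.
#' @param ts,dir see above.
#' @export
write_dataset <- function(mesh, ts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh_obj(mesh, file.path(dir, "mesh.obj"))
  write_units_tsv(mesh, file.path(dir, "units.tsv"))
  write_timeseries_tsv(ts, file.path(dir, "timeseries.tsv"))
  invisible(dir)
}
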