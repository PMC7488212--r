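# End-to-end pipeline: per-subject CF analysis in both directions, cohort
# aggregation, group inference, bias audit, and reporting.

LEAF_AREAS <- c("V2d", "V2v", "V3d", "V3v", "hV4", "LO", "TO")

#' Per-subject connective-field analysis in both directions
#'
#' Fits V1 -> x and x -> V1 CF tables for every leaf extrastriate area,
#' assembles composite V2/V3 tables as the union of their d/v fits, and
#' produces the sampling-extent summaries, convergence magnitudes, and
#' hierarchy-slope fits for the requested streams.
#'
#' @param mesh a `cf_mesh`.
#' @param ts a preprocessed `cf_ts`.
#' @param config a `cf_config`.
#' @param subject subject identifier stored in the outputs.
#' @return list: `cf_tables` (named `direction:area`), `summaries`,
#'   `convergence`, `slopes`, `audit_row` (direction differences of the
#'   audit variables per area).
#' @export
analyze_subject <- function(mesh, ts, config = run_config(), subject = "s1") {
  leaf <- intersect(LEAF_AREAS, unique(mesh$units$area))
  tables <- list()
  for (a in leaf) {
    tables[[paste0("fwd:", a)]] <- cf_fit_table(mesh, ts, "V1", a,
                                                grid = config$sigma_grid)
    tables[[paste0("bwd:", a)]] <- cf_fit_table(mesh, ts, a, "V1",
                                                grid = config$sigma_grid)
  }
  for (comp in names(COMPOSITE_AREAS)) {
    parts <- intersect(COMPOSITE_AREAS[[comp]], leaf)
    if (length(parts) == 2) {
      tables[[paste0("fwd:", comp)]] <- rbind(tables[[paste0("fwd:", parts[1])]],
                                              tables[[paste0("fwd:", parts[2])]])
      tables[[paste0("bwd:", comp)]] <- rbind(tables[[paste0("bwd:", parts[1])]],
                                              tables[[paste0("bwd:", parts[2])]])
    }
  }
  areas <- intersect(config$areas, sub("^fwd:", "", grep("^fwd:", names(tables), value = TRUE)))

  summaries <- do.call(rbind, lapply(areas, function(a) {
    rbind(
      cbind(subject = subject, direction = "V1->x", area = a,
            summarize_fits(tables[[paste0("fwd:", a)]], config$ve_min, config$ecc_window)),
      cbind(subject = subject, direction = "x->V1", area = a,
            summarize_fits(tables[[paste0("bwd:", a)]], config$ve_min, config$ecc_window))
    )
  }))

  convergence <- do.call(rbind, lapply(areas, function(a) {
    fwd <- summaries[summaries$area == a & summaries$direction == "V1->x", ]
    bwd <- summaries[summaries$area == a & summaries$direction == "x->V1", ]
    cm <- if (is.na(fwd$weighted_median_se) || is.na(bwd$weighted_median_se))
      NA_real_ else convergence_magnitude(fwd$weighted_median_se, bwd$weighted_median_se)
    data.frame(subject = subject, area = a, convergence_magnitude = cm,
               stringsAsFactors = FALSE)
  }))

  slopes <- do.call(rbind, lapply(config$streams, function(s)
    cbind(subject = subject, fit_hierarchy_slope(convergence, s))))

  audit_row <- do.call(rbind, lapply(areas, function(a) {
    fwd <- summaries[summaries$area == a & summaries$direction == "V1->x", ]
    bwd <- summaries[summaries$area == a & summaries$direction == "x->V1", ]
    data.frame(subject = subject, area = a,
               convergence_magnitude =
                 convergence$convergence_magnitude[convergence$area == a],
               d_median_ve = fwd$median_ve - bwd$median_ve,
               d_n_voxels = fwd$n_voxels_included - bwd$n_voxels_included,
               d_prop_point_cf = fwd$proportion_point_cf - bwd$proportion_point_cf,
               d_mean_ecc = fwd$mean_target_ecc - bwd$mean_target_ecc,
               stringsAsFactors = FALSE)
  }))

  list(cf_tables = tables, summaries = summaries, convergence = convergence,
       slopes = slopes, audit_row = audit_row)
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates control and patient cohorts under the group regimes (or
#' analyzes supplied cohorts), preprocesses by condition, runs the
#' per-subject CF analysis, and performs the group inference: per stream a
#' signed-rank test of each group's slope against zero and a rank-sum test
#' between groups (Bonferroni 3), per area a rank-sum test of convergence
#' magnitude between groups (Bonferroni 9), plus the bias-variable audit.
#'
#' @param config a `cf_config`.
#' @param cohorts optional list of two cohorts from [simulate_cohort()]
#'   (bypasses simulation).
#' @param out_dir optional directory for TSV outputs and provenance JSON.
#' @return list: `summaries`, `convergence`, `slopes`, `slope_tests`,
#'   `area_tests`, `audit`, `config`.
#' @export
run_pipeline <- function(config = run_config(), cohorts = NULL, out_dir = NULL) {
  if (is.null(cohorts)) {
    mesh <- build_cortex(v1_dim = config$v1_dim, xs_dim = config$xs_dim)
    cohorts <- list(
      simulate_cohort("control", config$n_controls, config$condition,
                      mesh = mesh, seed = config$seed),
      simulate_cohort("patient", config$n_patients, config$condition,
                      mesh = mesh, seed = derive_seed(config$seed, 999))
    )
  }
  res <- list(summaries = NULL, convergence = NULL, slopes = NULL, audit_in = NULL)
  for (coh in cohorts) {
    for (s in coh$subjects) {
      ts <- preprocess_run(s$ts, config$band_rest[1], config$band_rest[2])
      out <- analyze_subject(coh$mesh, ts, config, subject = s$id)
      grp <- coh$group
      res$summaries <- rbind(res$summaries, cbind(group = grp, out$summaries))
      res$convergence <- rbind(res$convergence, cbind(group = grp, out$convergence))
      res$slopes <- rbind(res$slopes, cbind(group = grp, out$slopes))
      res$audit_in <- rbind(res$audit_in, cbind(group = grp, out$audit_row))
    }
  }

  m_s <- config$bonferroni_streams
  slope_tests <- do.call(rbind, lapply(config$streams, function(st) {
    sl <- res$slopes[res$slopes$stream == st, ]
    ctrl <- sl$slope[sl$group == "control"]
    pat <- sl$slope[sl$group == "patient"]
    row <- function(label, tst) data.frame(
      stream = st, comparison = label, method = tst$method, W = tst$statistic,
      p_raw = tst$p_raw, p_corrected = tst$p_corrected, stringsAsFactors = FALSE)
    rbind(
      row("control_vs_0", signed_rank_test(values = ctrl, correction_m = m_s)),
      row("patient_vs_0", signed_rank_test(values = pat, correction_m = m_s)),
      row("control_vs_patient",
          rank_sum_test(x = ctrl, y = pat, correction_m = m_s,
                        mc_seed = config$seed))
    )
  }))

  m_a <- config$bonferroni_areas
  area_tests <- do.call(rbind, lapply(unique(res$convergence$area), function(a) {
    cv <- res$convergence[res$convergence$area == a, ]
    ctrl <- cv$convergence_magnitude[cv$group == "control"]
    pat <- cv$convergence_magnitude[cv$group == "patient"]
    if (anyNA(c(ctrl, pat))) return(NULL)
    tst <- rank_sum_test(x = ctrl, y = pat, correction_m = m_a,
                         mc_seed = config$seed)
    data.frame(area = a, method = tst$method, W = tst$statistic,
               p_raw = tst$p_raw, p_corrected = tst$p_corrected,
               stringsAsFactors = FALSE)
  }))

  audit <- bias_audit(res$audit_in, mc_seed = config$seed)

  results <- list(summaries = res$summaries, convergence = res$convergence,
                  slopes = res$slopes, slope_tests = slope_tests,
                  area_tests = area_tests, audit = audit, config = config)
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  wr(results$summaries, "summaries")
  wr(results$convergence, "convergence")
  wr(results$slopes, "slopes")
  wr(results$slope_tests, "slope_tests")
  wr(results$area_tests, "area_tests")
  wr(results$audit, "audit")
  cfg <- unclass(results$config)
  cfg$sigma_grid <- NULL
  jsonlite::write_json(
    list(config = cfg, config_hash = content_key(unlist(results$config)),
         package_version = as.character(utils::packageVersion("cfhier"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Bootstrap standard error of the median
#'
#' Seeded nonparametric bootstrap (default 10^4 resamples); `NA` for
#' samples of fewer than 2 values (documented degenerate case).
#' @param x numeric vector.
#' @param n_boot resamples.
#' @param seed integer seed.
#' @export
bootstrap_se_median <- function(x, n_boot = 1e4, seed = 1) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  with_seed(seed, {
    meds <- matrixStats_colMedians(matrix(x[sample.int(n, n * n_boot, replace = TRUE)],
                                          nrow = n))
    stats::sd(meds)
  })
}

# small local stand-in to avoid a matrixStats dependency
matrixStats_colMedians <- function(m) apply(m, 2, stats::median)

#' Human-readable cohort report
#'
#' Per area and per stream, group medians with bootstrap standard errors of
#' the median, mirroring the "median +/- standard error of the median"
#' reporting format.
#' @param results output of [run_pipeline()].
#' @param seed bootstrap seed.
#' @param n_boot bootstrap resamples.
#' @return list of data frames `areas`, `streams` (also printed).
#' @export
report_results <- function(results, seed = 1, n_boot = 1e4) {
  fmt <- function(df, value_col, by_cols) {
    combos <- unique(df[by_cols])
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      sel <- rep(TRUE, nrow(df))
      for (cc in by_cols) sel <- sel & df[[cc]] == combos[[cc]][i]
      v <- df[[value_col]][sel]
      v <- v[!is.na(v)]
      cbind(combos[i, , drop = FALSE],
            median = if (length(v)) stats::median(v) else NA_real_,
            se_median = bootstrap_se_median(v, n_boot = n_boot, seed = seed),
            n = length(v))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  }
  areas <- fmt(results$convergence, "convergence_magnitude", c("group", "area"))
  streams <- fmt(results$slopes, "slope", c("group", "stream"))
  cat("Convergence magnitude (mm), median +/- SE of median:\n")
  for (i in seq_len(nrow(areas)))
    cat(sprintf("  %-8s %-4s %6.2f +/- %.2f (n = %d)\n", areas$group[i],
                areas$area[i], areas$median[i], areas$se_median[i], areas$n[i]))
  cat("Hierarchy slope (mm/level), median +/- SE of median:\n")
  for (i in seq_len(nrow(streams)))
    cat(sprintf("  %-8s %-8s %6.2f +/- %.2f (n = %d)\n", streams$group[i],
                streams$stream[i], streams$median[i], streams$se_median[i],
                streams$n[i]))
  invisible(list(areas = areas, streams = streams))
}
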