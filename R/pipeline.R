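#' Run configuration
#'
#' One bundle of every tunable the pipeline exposes, with documented
#' defaults.  Unknown keys are rejected.  Configurations round-trip
#' through JSON via [read_config()]/[write_config()].
#'
#' @param ... Named overrides of the defaults: `mz_tol` (Da), `rt_tol`
#'   (min), `min_snr`, `smooth_window` (points), `lod_multiplier`,
#'   `fold_cutoff`, `rt_match_tol` (min), `intensity_floor`,
#'   `zone3_depth` (um), `reversal_rule` (`"window"`/`"adjacent"`),
#'   `min_step` (um), `min_duration`/`max_duration` (min), `seed`.
#' @return A list of class `pg_config`.
#' @export
pg_config <- function(...) {
  defaults <- list(
    mz_tol = 0.5, rt_tol = 0.05,
    min_snr = 10, smooth_window = 5,
    lod_multiplier = 3, fold_cutoff = 1.5, rt_match_tol = 0.1,
    intensity_floor = 0.05,
    zone3_depth = 50, reversal_rule = "window", min_step = 0.5,
    min_duration = 2.5, max_duration = 21,
    seed = NULL)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "),
          class = "pgsperm_config_error")
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  for (k in c("mz_tol", "rt_tol", "min_snr", "rt_match_tol"))
    assert_number(cfg[[k]], k, positive = TRUE)
  if (!cfg$reversal_rule %in% c("window", "adjacent"))
    stopf("reversal_rule must be 'window' or 'adjacent'",
          class = "pgsperm_config_error")
  structure(cfg, class = "pg_config")
}

#' @rdname pg_config
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  pg_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' @rdname pg_config
#' @param config A `pg_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

cfg_library <- function(library_path, config) {
  if (is.null(library_path)) {
    table2_standards(mz_tol = config$mz_tol, rt_tol = config$rt_tol)
  } else {
    read_standard_library(library_path, mz_tol = config$mz_tol,
                          rt_tol = config$rt_tol)
  }
}

#' Annotate a spectra file against a standards library
#'
#' Reads spectra (MGF or CSV, by extension), classifies each against
#' the library, and writes one annotation row per spectrum as TSV.
#'
#' @param spectra_path Input MGF or CSV file.
#' @param out_path Output TSV path (optional).
#' @param library_path Standards library (TSV/JSON); default the
#'   packaged synthetic-standards table.
#' @param config A [pg_config()].
#' @return The annotation data frame, invisibly when `out_path` is set.
#' @export
annotate_spectra_file <- function(spectra_path, out_path = NULL,
                                  library_path = NULL,
                                  config = pg_config()) {
  lib <- cfg_library(library_path, config)
  spectra <- if (grepl("\\.mgf$", spectra_path, ignore.case = TRUE))
    read_spectra_mgf(spectra_path) else read_spectra_csv(spectra_path)
  ann <- annotate_spectra(spectra, lib)
  if (!is.null(out_path)) {
    write_tsv(ann, out_path)
    return(invisible(ann))
  }
  ann
}

#' Quantify compounds across replicate MRM runs
#'
#' Reads replicate chromatograms, fits the calibration curve from a
#' `concentration,area` CSV, detects and integrates peaks, matches them
#' to library compounds, converts areas to concentrations, and reports
#' per-compound replicate means and SDs with in-range flags.  Duplicate
#' run labels are suffixed with a warning.
#'
#' @param chromatogram_paths Character vector of chromatogram CSV files.
#' @param calibration_path CSV with columns `concentration`, `area`
#'   (>= 3 levels).
#' @param out_path Optional output TSV.
#' @param library_path Optional standards library; default packaged.
#' @param config A [pg_config()].
#' @return A data frame with one row per compound: mean and SD
#'   concentration, per-run values, in-range flag.
#' @export
quantify_runs_file <- function(chromatogram_paths, calibration_path,
                               out_path = NULL, library_path = NULL,
                               config = pg_config()) {
  lib <- cfg_library(library_path, config)
  if (!file.exists(calibration_path))
    parse_error("calibration file not found: %s", calibration_path)
  cal <- utils::read.csv(calibration_path, stringsAsFactors = FALSE)
  curve <- fit_calibration(cal)
  runs <- lapply(chromatogram_paths, read_chromatogram_csv)
  labels <- vapply(runs, `[[`, character(1), "run_label")
  if (anyDuplicated(labels)) {
    warning("duplicate run labels; suffixing")
    labels <- make.unique(labels, sep = "#")
    for (i in seq_along(runs)) runs[[i]]$run_label <- labels[i]
  }
  rows <- do.call(rbind, lapply(runs, function(ch) {
    pk <- detect_peaks(ch, min_snr = config$min_snr,
                       smooth_window = config$smooth_window)
    pk <- match_peaks(pk, ch, lib, rt_match_tol = config$rt_match_tol)
    pk <- pk[!is.na(pk$matched_standard), , drop = FALSE]
    if (nrow(pk) == 0L) return(NULL)
    q <- quantify(pk$area, curve)
    data.frame(run_label = ch$run_label, compound = pk$matched_standard,
               area = pk$area, concentration = q$concentration,
               in_range = q$in_range, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(run_label = character(0),
                                        compound = character(0),
                                        area = numeric(0),
                                        concentration = numeric(0),
                                        in_range = logical(0))
  agg <- do.call(rbind, lapply(split(rows, rows$compound), function(g) {
    av <- average_replicates(g$concentration,
                             n_injections = nrow(g), n_extractions = 1)
    data.frame(compound = g$compound[1L], n_runs = nrow(g),
               mean_concentration = av$mean, sd_concentration = av$sd,
               all_in_range = all(g$in_range), stringsAsFactors = FALSE)
  }))
  if (is.null(agg)) agg <- data.frame(compound = character(0),
                                      n_runs = integer(0),
                                      mean_concentration = numeric(0),
                                      sd_concentration = numeric(0),
                                      all_in_range = logical(0))
  rownames(agg) <- NULL
  attr(agg, "per_run") <- rows
  if (!is.null(out_path)) {
    write_tsv(agg, out_path)
    return(invisible(agg))
  }
  agg
}

#' Score a tracks file
#'
#' Reads tracks and geometry, applies the track-duration filter,
#' computes per-track motility metrics and the per-gonad zone
#' distribution of track endpoints, and optionally writes both as TSV
#' (`<out_prefix>_metrics.tsv`, `<out_prefix>_zones.tsv`).
#'
#' @param tracks_path Tracks CSV.
#' @param geometry_path Geometry JSON (single object or per-gonad map).
#' @param out_prefix Optional output path prefix.
#' @param config A [pg_config()].
#' @return A list with `metrics`, `zones`, `rejections`.
#' @export
track_metrics_file <- function(tracks_path, geometry_path,
                               out_prefix = NULL, config = pg_config()) {
  tracks <- read_tracks_csv(tracks_path)
  geom <- read_geometry_json(geometry_path)
  if (!inherits(geom, "pg_geometry")) {
    gonads <- unique(vapply(tracks, `[[`, character(1), "gonad_id"))
    missing <- setdiff(gonads, names(geom))
    if (length(missing))
      validation_error("no geometry for gonad(s): %s",
                       paste(missing, collapse = ", "))
  }
  flt <- filter_tracks(tracks, config$min_duration, config$max_duration)
  metrics <- track_metrics(flt$tracks, geom, min_step = config$min_step,
                           rule = config$reversal_rule)
  ends <- lapply(flt$tracks, function(tr)
    tr$positions[nrow(tr$positions), , drop = FALSE])
  by_gonad <- split(ends, vapply(flt$tracks, `[[`, character(1), "gonad_id"))
  by_gonad <- lapply(by_gonad, function(x) do.call(rbind, x))
  zones <- zone_distribution(by_gonad, geom)
  if (!is.null(out_prefix)) {
    write_tsv(metrics, paste0(out_prefix, "_metrics.tsv"))
    write_tsv(zones$per_gonad, paste0(out_prefix, "_zones.tsv"))
  }
  list(metrics = metrics, zones = zones, rejections = flt$rejections)
}

#' End-to-end demonstration workflow
#'
#' Simulates wild-type, fat-1 and glp-4 MRM bundles (F2 and F3
#' transitions, three replicates each), a five-level calibration
#' series, and wild-type plus guidance-null track sets; then runs every
#' analysis stage (annotation of the packaged worm compounds, peak
#' detection, quantification, strain comparison, track metrics, zone
#' distribution) and writes a summary.  Deterministic given a seed.
#'
#' @param out_dir Output directory for TSV/JSON artifacts, or `NULL`
#'   for no files.
#' @param seed Integer seed.
#' @param n_tracks Tracks per motility preset.
#' @param config A [pg_config()].
#' @return A list of summary quantities (invisibly when writing files).
#' @export
run_demo <- function(out_dir = NULL, seed = 1, n_tracks = 50,
                     config = pg_config()) {
  t2 <- table2_standards(mz_tol = config$mz_tol, rt_tol = config$rt_tol)
  t3 <- table3_compounds(mz_tol = config$mz_tol, rt_tol = config$rt_tol)
  tr_f2 <- transition(353, 193, "F2 353/193")
  tr_f3 <- transition(351, 193, "F3 351/193")

  ann <- annotate_spectra(library_as_spectra(t3), t2)

  sim_runs <- function(preset_name, tr, seeds) lapply(seeds, function(s)
    simulate_mrm(strain_preset(preset_name), tr, lib = t3,
                 seed = s)$chromatogram)
  base <- as.integer(seed) * 1000L
  wt_f2 <- sim_runs("wild_type", tr_f2, base + 1:3)
  glp_f2 <- sim_runs("glp-4", tr_f2, base + 4:6)
  fat1_f2 <- sim_runs("fat-1", tr_f2, base + 7:9)
  wt_f3 <- sim_runs("wild_type", tr_f3, base + 10:12)
  fat1_f3 <- sim_runs("fat-1", tr_f3, base + 13:15)

  cal <- simulate_calibration(seed = base + 20L)
  curve <- fit_calibration(cal)

  cepgf2_conc <- function(runs) {
    vapply(runs, function(ch) {
      pk <- detect_peaks(ch, config$min_snr, config$smooth_window)
      pk <- match_peaks(pk, ch, t3, config$rt_match_tol)
      j <- match("CePGF2", pk$matched_standard)
      if (is.na(j)) 0 else quantify(pk$area[j], curve)$concentration
    }, numeric(1))
  }
  wt_conc <- average_replicates(cepgf2_conc(wt_f2))
  glp_conc <- average_replicates(cepgf2_conc(glp_f2))
  fat1_conc <- average_replicates(cepgf2_conc(fat1_f2))

  cmp_glp <- compare_strains(wt_f2, glp_f2, t3, config$min_snr,
                             config$smooth_window, config$rt_match_tol,
                             config$fold_cutoff, config$lod_multiplier)
  cmp_fat1 <- compare_strains(c(wt_f2, wt_f3), c(fat1_f2, fat1_f3), t3,
                              config$min_snr, config$smooth_window,
                              config$rt_match_tol, config$fold_cutoff,
                              config$lod_multiplier)

  geom <- uterus_geometry(zone3_depth = config$zone3_depth)
  wt_tr <- simulate_tracks(motility_preset("wild_type"), geom,
                           n = n_tracks, duration = 60, seed = base + 30L)
  null_tr <- simulate_tracks(motility_preset("guidance_null"), geom,
                             n = n_tracks, duration = 60, seed = base + 31L)
  endpoint_zone3 <- function(sim) {
    ends <- t(vapply(sim$tracks, function(tr)
      tr$positions[nrow(tr$positions), ], numeric(2)))
    mean(assign_zone(ends, geom) == 3L)
  }
  wt_metrics <- track_metrics(wt_tr$tracks, geom,
                              min_step = config$min_step,
                              rule = config$reversal_rule)
  null_metrics <- track_metrics(null_tr$tracks, geom,
                                min_step = config$min_step,
                                rule = config$reversal_rule)
  dv_test <- compare_groups(wt_metrics$directional_velocity,
                            null_metrics$directional_velocity)

  summary <- list(
    seed = seed,
    annotation = ann,
    n_f_series = sum(ann$series %in% c("F1", "F2", "F3", "F18")),
    calibration_r = curve$r,
    cepgf2_wt = wt_conc$mean, cepgf2_glp4 = glp_conc$mean,
    cepgf2_fat1 = fat1_conc$mean,
    glp4_reduction_pct = 100 * (1 - glp_conc$mean / wt_conc$mean),
    fat1_fold = fat1_conc$mean / wt_conc$mean,
    comparison_glp4 = cmp_glp, comparison_fat1 = cmp_fat1,
    wt_zone3_fraction = endpoint_zone3(wt_tr),
    null_zone3_fraction = endpoint_zone3(null_tr),
    directional_velocity_p = dv_test$p_value)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(ann, file.path(out_dir, "annotation.tsv"))
    write_tsv(cmp_glp, file.path(out_dir, "comparison_glp4.tsv"))
    write_tsv(cmp_fat1, file.path(out_dir, "comparison_fat1.tsv"))
    write_tsv(wt_metrics, file.path(out_dir, "metrics_wild_type.tsv"))
    write_tsv(null_metrics, file.path(out_dir, "metrics_guidance_null.tsv"))
    scalars <- summary[c("seed", "n_f_series", "calibration_r",
                         "cepgf2_wt", "cepgf2_glp4", "cepgf2_fat1",
                         "glp4_reduction_pct", "fat1_fold",
                         "wt_zone3_fraction", "null_zone3_fraction",
                         "directional_velocity_p")]
    jsonlite::write_json(scalars, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(summary))
  }
  summary
}
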