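#' MRM transitions and chromatograms
#'
#' A `pg_transition` is a Q1/Q3 parent-to-product mass transition, e.g.
#' 353/193 monitors the F2 prostaglandin class, 355/311 the F1 class,
#' 351/193 or 351/191 the F3 class, 351/189 the D/E/H-series
#' intermediates and 369/193 hydroxylated F2 species.
#'
#' @param q1 Parent m/z selected in the first quadrupole.
#' @param q3 Product m/z selected in the third quadrupole (< q1).
#' @param label Free-text label, e.g. `"F2 353/193"`.
#' @return An object of class `pg_transition`.
#' @export
transition <- function(q1, q3, label = sprintf("%s/%s", format(q1), format(q3))) {
  assert_number(q1, "q1", positive = TRUE)
  assert_number(q3, "q3", positive = TRUE)
  if (q3 >= q1) validation_error("q3 must be below q1 (got %s/%s)",
                                 format(q1), format(q3))
  structure(list(q1 = q1, q3 = q3, label = label), class = "pg_transition")
}

#' @export
print.pg_transition <- function(x, ...) {
  cat(sprintf("<pg_transition> %s (Q1 %s / Q3 %s)\n", x$label,
              format(x$q1), format(x$q3)))
  invisible(x)
}

#' @rdname transition
#' @param times Strictly increasing, uniformly spaced time grid (minutes).
#' @param intensities Non-negative signal (counts per second), same
#'   length as `times`.
#' @param run_label,batch_id Run provenance labels.
#' @return `chromatogram()` returns an object of class `pg_chromatogram`.
#' @export
chromatogram <- function(transition, times, intensities,
                         run_label = "run", batch_id = "default") {
  stopifnot(inherits(transition, "pg_transition"))
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities))
    validation_error("times and intensities must have equal length")
  if (length(times) < 2L)
    validation_error("a chromatogram needs at least 2 points")
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    validation_error("time grid must be strictly increasing and uniform")
  if (any(intensities < 0))
    validation_error("intensities must be non-negative")
  structure(
    list(transition = transition, times = times, intensities = intensities,
         run_label = run_label, batch_id = batch_id),
    class = "pg_chromatogram")
}

#' @export
print.pg_chromatogram <- function(x, ...) {
  cat(sprintf("<pg_chromatogram> %s  %s  %d points, %.2f-%.2f min, max %.0f cps\n",
              x$run_label, x$transition$label, length(x$times),
              min(x$times), max(x$times), max(x$intensities)))
  invisible(x)
}

#' @export
plot.pg_chromatogram <- function(x, ...) {
  graphics::plot(x$times, x$intensities, type = "l",
                 xlab = "retention time (min)", ylab = "intensity (cps)",
                 main = sprintf("%s  %s", x$run_label, x$transition$label),
                 ...)
  invisible(x)
}

#' Detect peaks in an MRM chromatogram
#'
#' Smooths the trace with a centred moving average, estimates the
#' baseline as the median intensity and the noise as 1.4826 x MAD,
#' reports local maxima whose baseline-subtracted height reaches
#' `min_snr` times the noise, and integrates each peak between bounds
#' found by descending from the apex to 5\% of the apex-above-baseline
#' height or to a local minimum, whichever comes first.  The area is the
#' trapezoidal integral of the baseline-subtracted raw signal between
#' the bounds.
#'
#' @param chrom A [chromatogram()].
#' @param min_snr Minimum signal-to-noise ratio for a reported peak.
#' @param smooth_window Moving-average window (points, made odd).
#' @return A data frame of class `pg_peaks` with columns `rt_apex`,
#'   `height`, `area`, `left`, `right`, `snr`, `matched_standard`, and
#'   attributes `baseline` and `noise`.
#' @export
detect_peaks <- function(chrom, min_snr = 10, smooth_window = 5) {
  stopifnot(inherits(chrom, "pg_chromatogram"))
  n <- length(chrom$times)
  smooth_window <- max(1L, as.integer(smooth_window))
  if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
  if (n < 2L * smooth_window)
    validation_error("chromatogram too short for smoothing window %d",
                     smooth_window)
  y <- as.numeric(stats::filter(chrom$intensities,
                                rep(1 / smooth_window, smooth_window),
                                sides = 2))
  half <- smooth_window %/% 2L
  if (half > 0) {             # pad the filter's NA edges with raw values
    y[seq_len(half)] <- chrom$intensities[seq_len(half)]
    y[(n - half + 1L):n] <- chrom$intensities[(n - half + 1L):n]
  }
  baseline <- stats::median(y)
  noise <- max(stats::mad(y), .Machine$double.eps)

  apex <- which(diff(sign(diff(y))) < 0) + 1L       # strict local maxima
  apex <- apex[(y[apex] - baseline) / noise >= min_snr]
  if (length(apex) == 0L)
    return(empty_peaks(baseline, noise))

  out <- lapply(apex, function(i) {
    cut <- baseline + 0.05 * (y[i] - baseline)
    l <- i
    while (l > 1L && y[l - 1L] > cut && y[l - 1L] <= y[l]) l <- l - 1L
    r <- i
    while (r < n && y[r + 1L] > cut && y[r + 1L] <= y[r]) r <- r + 1L
    seg <- l:r
    bsub <- pmax(chrom$intensities[seg] - baseline, 0)
    area <- sum(diff(chrom$times[seg]) *
                  (bsub[-length(bsub)] + bsub[-1L]) / 2)
    data.frame(rt_apex = chrom$times[i],
               height = chrom$intensities[i] - baseline,
               area = area,
               left = chrom$times[l], right = chrom$times[r],
               snr = (y[i] - baseline) / noise,
               matched_standard = NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[res$area > 0, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, baseline = baseline, noise = noise,
            class = c("pg_peaks", "data.frame"))
}

empty_peaks <- function(baseline = 0, noise = 0) {
  structure(
    data.frame(rt_apex = numeric(0), height = numeric(0), area = numeric(0),
               left = numeric(0), right = numeric(0), snr = numeric(0),
               matched_standard = character(0), stringsAsFactors = FALSE),
    baseline = baseline, noise = noise, class = c("pg_peaks", "data.frame"))
}

#' Match detected peaks to library standards
#'
#' A library compound responds to a transition when its parent mass lies
#' within `mz_tol` of Q1 and its product-ion list contains an ion within
#' `mz_tol` of Q3.  Each responding compound claims the nearest detected
#' peak within `rt_match_tol` of its library RT.
#'
#' @param peaks A `pg_peaks` data frame from [detect_peaks()].
#' @param chrom The chromatogram the peaks came from (for its transition).
#' @param lib A [pg_library()].
#' @param rt_match_tol Peak-to-library RT matching window (minutes).
#' @return `peaks` with `matched_standard` filled in where a compound
#'   claimed the peak.
#' @export
match_peaks <- function(peaks, chrom, lib, rt_match_tol = 0.1) {
  stopifnot(inherits(lib, "pg_library"), inherits(chrom, "pg_chromatogram"))
  comps <- transition_compounds(lib, chrom$transition)
  if (nrow(peaks) == 0L || length(comps) == 0L) return(peaks)
  for (e in comps) {
    if (is.na(e$rt_min)) next
    d <- abs(peaks$rt_apex - e$rt_min)
    d[!is.na(peaks$matched_standard)] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= rt_match_tol)
      peaks$matched_standard[j] <- e$name
  }
  peaks
}

# library entries that respond to a Q1/Q3 transition
transition_compounds <- function(lib, transition) {
  Filter(function(e) {
    abs(e$parent_mz - transition$q1) <= lib$mz_tol &&
      any(abs(e$product_ions - transition$q3) <= lib$mz_tol)
  }, lib$entries)
}

#' Fit an external-standard calibration curve
#'
#' Ordinary least squares of peak area on concentration over the
#' calibration levels (e.g. the 0.1, 1, 10, 100, 1000 ng/ml serial
#' dilution of a PGF2a stock), with the Pearson correlation coefficient
#' reported as the linearity figure of merit (acceptable curves show
#' r > 0.99).
#'
#' @param levels A data frame with columns `concentration` (ng/ml,
#'   strictly positive, >= 3 distinct values) and `area`, or a numeric
#'   vector of concentrations when `area` is given separately.
#' @param area Peak areas when `levels` is a bare numeric vector.
#' @return An object of class `pg_calibration` with components `levels`,
#'   `slope`, `intercept`, `r`, `range` and the underlying `lm` fit.
#' @seealso [quantify()], [simulate_calibration()]
#' @export
fit_calibration <- function(levels, area = NULL) {
  if (is.numeric(levels) && !is.null(area))
    levels <- data.frame(concentration = levels, area = area)
  if (!is.data.frame(levels) ||
      !all(c("concentration", "area") %in% names(levels)))
    validation_error("levels must have columns 'concentration' and 'area'")
  conc <- as.numeric(levels$concentration)
  if (any(!is.finite(conc)) || any(conc <= 0))
    validation_error("calibration concentrations must be positive")
  if (length(unique(conc)) < 3L)
    validation_error("calibration needs >= 3 distinct concentration levels")
  fit <- stats::lm(area ~ concentration, data = levels)
  r <- stats::cor(levels$concentration, levels$area)
  structure(
    list(levels = levels,
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r = r, range = range(conc), fit = fit),
    class = "pg_calibration")
}

#' @export
print.pg_calibration <- function(x, ...) {
  cat(sprintf("<pg_calibration> %d levels, %g-%g ng/ml\n",
              nrow(x$levels), x$range[1], x$range[2]))
  cat(sprintf("  area = %.6g + %.6g * conc;  r = %.6f\n",
              x$intercept, x$slope, x$r))
  invisible(x)
}

#' @export
coef.pg_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.pg_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata))
    newdata <- data.frame(concentration = newdata)
  object$intercept + object$slope * newdata$concentration
}

#' @export
residuals.pg_calibration <- function(object, ...) stats::residuals(object$fit)

#' @export
plot.pg_calibration <- function(x, ...) {
  graphics::plot(x$levels$concentration, x$levels$area, log = "xy",
                 xlab = "concentration (ng/ml)", ylab = "peak area",
                 main = sprintf("calibration curve (r = %.4f)", x$r), ...)
  pr <- sort(x$levels$concentration)
  graphics::lines(pr, x$intercept + x$slope * pr, lty = 2)
  invisible(x)
}

#' Quantify a peak against a calibration curve
#'
#' Inverts the calibration line: concentration = (area - intercept) /
#' slope.  Negative estimates are clamped to zero (flagged), and
#' estimates outside the calibrated concentration range are flagged as
#' out of range.
#'
#' @param area Peak area(s), or a `pg_peaks` data frame (its `area`
#'   column is used).
#' @param curve A [fit_calibration()] object with non-zero slope.
#' @return A data frame with columns `concentration` (ng/ml),
#'   `in_range` and `clamped`.
#' @export
quantify <- function(area, curve) {
  stopifnot(inherits(curve, "pg_calibration"))
  if (inherits(area, "pg_peaks") || is.data.frame(area)) area <- area$area
  if (curve$slope == 0)
    stopf("degenerate calibration curve: zero slope",
          class = "pgsperm_degenerate_curve")
  conc <- (area - curve$intercept) / curve$slope
  clamped <- conc < 0
  conc[clamped] <- 0
  in_range <- conc >= curve$range[1] & conc <= curve$range[2] & !clamped
  data.frame(concentration = conc, in_range = in_range, clamped = clamped)
}

#' Average replicate concentration measurements
#'
#' Arithmetic mean and sample standard deviation over replicate
#' measurements (the reference design is three MRM injections over two
#' independent extractions).
#'
#' @param measurements Numeric vector of concentrations (>= 1 value).
#' @param n_injections,n_extractions Replication design, recorded in the
#'   output.
#' @return A list with `mean`, `sd` (0 with `sd_defined = FALSE` for a
#'   single measurement), `n` and `design`.
#' @export
average_replicates <- function(measurements, n_injections = 3,
                               n_extractions = 2) {
  measurements <- as.numeric(measurements)
  if (length(measurements) == 0L || any(!is.finite(measurements)))
    validation_error("measurements must be a non-empty finite vector")
  single <- length(measurements) == 1L
  list(mean = mean(measurements),
       sd = if (single) 0 else stats::sd(measurements),
       sd_defined = !single,
       n = length(measurements),
       design = c(n_injections = n_injections,
                  n_extractions = n_extractions))
}

#' Retention-time alignment between batches
#'
#' Estimates the RT offset of a target run relative to a reference run
#' as the median apex-time difference over peaks matched to the same
#' standards.  Adding the returned offset to reference RTs (or
#' subtracting it from the target) makes the batches comparable; a
#' slight RT shift between runs acquired on different days is expected.
#'
#' @param reference_peaks,target_peaks `pg_peaks` data frames whose
#'   `matched_standard` columns share at least one standard.
#' @return The RT offset in minutes (target minus reference).
#' @export
align_rt <- function(reference_peaks, target_peaks) {
  ref <- reference_peaks[!is.na(reference_peaks$matched_standard), ]
  tgt <- target_peaks[!is.na(target_peaks$matched_standard), ]
  shared <- intersect(ref$matched_standard, tgt$matched_standard)
  if (length(shared) == 0L)
    stopf("no shared standards between runs; cannot align",
          class = "pgsperm_alignment_error")
  d <- vapply(shared, function(s)
    tgt$rt_apex[match(s, tgt$matched_standard)] -
      ref$rt_apex[match(s, ref$matched_standard)], numeric(1))
  stats::median(d)
}

#' Compare two strains compound-by-compound
#'
#' Detects and integrates peaks in replicate MRM runs from two groups
#' sharing the same transitions, matches peaks to library compounds, and
#' reports per-compound mean areas, the B/A fold change and a
#' qualitative call.  A compound is treated as present in a group when
#' it is detected (above the limit of detection, baseline + 3 x noise)
#' in more than half of the group's runs.  Folds at or above
#' `fold_cutoff` are called `ELEVATED`, at or below `1/fold_cutoff`
#' `REDUCED`, otherwise `UNCHANGED`; compounds present in only one group
#' are `ABSENT_IN_B` / `ABSENT_IN_A`.  Compounds below the LOD in both
#' groups are reported as `UNCHANGED` with `fold_change = NA`.
#'
#' @param runs_A,runs_B Lists of [chromatogram()] objects (replicates,
#'   possibly over several transitions).
#' @param lib A [pg_library()].
#' @param min_snr,smooth_window Peak-detection parameters.
#' @param rt_match_tol Peak-to-library RT matching window (minutes).
#' @param fold_cutoff Fold-change threshold for ELEVATED/REDUCED calls.
#' @param lod_multiplier The LOD is `lod_multiplier` x noise above
#'   baseline (default 3).
#' @return A data frame of class `pg_strain_comparison` with columns
#'   `compound`, `transition`, `area_A`, `area_B`, `fold_change`,
#'   `call`.
#' @export
compare_strains <- function(runs_A, runs_B, lib, min_snr = 10,
                            smooth_window = 5, rt_match_tol = 0.1,
                            fold_cutoff = 1.5, lod_multiplier = 3) {
  stopifnot(inherits(lib, "pg_library"))
  lab <- function(runs) sort(unique(vapply(runs, function(x)
    x$transition$label, character(1))))
  if (!identical(lab(runs_A), lab(runs_B)))
    validation_error("run sets must share the same transitions")

  measure <- function(runs) {
    rows <- lapply(runs, function(ch) {
      pk <- detect_peaks(ch, min_snr = min_snr, smooth_window = smooth_window)
      pk <- match_peaks(pk, ch, lib, rt_match_tol = rt_match_tol)
      lod_height <- lod_multiplier * attr(pk, "noise")
      comps <- transition_compounds(lib, ch$transition)
      data.frame(
        compound = vapply(comps, `[[`, character(1), "name"),
        transition = ch$transition$label,
        area = vapply(comps, function(e) {
          j <- match(e$name, pk$matched_standard)
          if (is.na(j) || pk$height[j] < lod_height) 0 else pk$area[j]
        }, numeric(1)),
        detected = vapply(comps, function(e) {
          j <- match(e$name, pk$matched_standard)
          !is.na(j) && pk$height[j] >= lod_height
        }, logical(1)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  mA <- measure(runs_A); mB <- measure(runs_B)
  key <- unique(rbind(mA[c("compound", "transition")],
                      mB[c("compound", "transition")]))
  res <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sel <- function(m) m$compound == key$compound[i] &
      m$transition == key$transition[i]
    a <- mA[sel(mA), ]; b <- mB[sel(mB), ]
    pres_a <- nrow(a) > 0 && mean(a$detected) > 0.5
    pres_b <- nrow(b) > 0 && mean(b$detected) > 0.5
    area_a <- if (nrow(a)) mean(a$area) else 0
    area_b <- if (nrow(b)) mean(b$area) else 0
    fold <- if (pres_a && pres_b) area_b / area_a else NA_real_
    call <- if (pres_a && !pres_b) "ABSENT_IN_B"
      else if (!pres_a && pres_b) "ABSENT_IN_A"
      else if (!pres_a && !pres_b) "UNCHANGED"
      else if (fold >= fold_cutoff) "ELEVATED"
      else if (fold <= 1 / fold_cutoff) "REDUCED"
      else "UNCHANGED"
    data.frame(compound = key$compound[i], transition = key$transition[i],
               area_A = area_a, area_B = area_b, fold_change = fold,
               call = call, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  class(res) <- c("pg_strain_comparison", "data.frame")
  res
}
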