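#' Strain presets for MRM simulation
#'
#' Named parameter bundles encoding the qualitative prostaglandin
#' patterns of the reference strains as per-compound relative abundances
#' (wild type = 1) over the packaged worm-compound library:
#' \describe{
#'   \item{wild_type}{all classes present (abundance 1).}
#'   \item{fat-1}{no EPA, hence no F3 compounds; elevated AA drives
#'     CePGF2 x4 and CePGF2b x2.}
#'   \item{fat-4}{no AA and no EPA: CePGF2, CePGF2b and the F3 class
#'     absent.}
#'   \item{fat-1 fat-4}{as fat-4, plus elevated DGLA drives the F1
#'     class x3.}
#'   \item{fat-3}{20-carbon PUFA synthesis lost: all library compounds
#'     near zero (the compensating 18:3n3-derived species at m/z 327
#'     has no reference library entry and is not simulated).}
#'   \item{glp-4}{germline-deficient: F2 and F3 compounds at 0.25
#'     (a ~75\% reduction).}
#'   \item{cyp-31A2}{all classes elevated x2.}
#' }
#' Abundances the reference measurements do not constrain default to 1.
#'
#' @param name Preset name (see above).
#' @param lib The compound library the abundances refer to (default the
#'   packaged worm compounds).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param baseline_cps Mean Poisson baseline (counts per second).
#' @return An object of class `pg_strain_preset`.
#' @export
strain_preset <- function(name, lib = table3_compounds(), noise_cv = 0.05,
                          baseline_cps = 20) {
  stopifnot(inherits(lib, "pg_library"))
  if (noise_cv < 0 || noise_cv > 0.5)
    validation_error("noise_cv must lie in [0, 0.5]")
  nms <- vapply(lib$entries, `[[`, character(1), "name")
  series <- vapply(lib$entries, `[[`, character(1), "series")
  ab <- rep(1, length(nms))
  names(ab) <- nms
  known <- c("wild_type", "fat-1", "fat-4", "fat-1 fat-4", "fat-3",
             "glp-4", "cyp-31A2")
  if (!name %in% known)
    stopf("unknown strain preset '%s' (known: %s)", name,
          paste(known, collapse = ", "), class = "pgsperm_config_error")
  if (name == "fat-1") {
    ab[series == "F3"] <- 0
    ab["CePGF2"] <- 4
    ab["CePGF2b"] <- 2
  } else if (name == "fat-4") {
    ab[series == "F3"] <- 0
    ab[c("CePGF2", "CePGF2b")] <- 0
  } else if (name == "fat-1 fat-4") {
    ab[series == "F3"] <- 0
    ab[c("CePGF2", "CePGF2b")] <- 0
    ab[series == "F1"] <- 3
  } else if (name == "fat-3") {
    ab[] <- 0
  } else if (name == "glp-4") {
    ab[series %in% c("F2", "F3")] <- 0.25
  } else if (name == "cyp-31A2") {
    ab[] <- 2
  }
  structure(list(name = name, compound_abundances = ab,
                 noise_cv = noise_cv, baseline_cps = baseline_cps),
            class = "pg_strain_preset")
}

#' @export
print.pg_strain_preset <- function(x, ...) {
  cat(sprintf("<pg_strain_preset> %s  noise_cv %g  baseline %g cps\n",
              x$name, x$noise_cv, x$baseline_cps))
  ab <- x$compound_abundances
  cat("  abundances:", paste(sprintf("%s=%g", names(ab), ab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Simulate an MRM chromatogram for a strain preset
#'
#' Places a Gaussian peak (width `sigma_rt` minutes) at the library
#' retention time of every compound that responds to the transition
#' (parent mass matches Q1 and ion list contains Q3), with area
#' proportional to the preset abundance: a compound at relative
#' abundance a has true concentration `a * base_conc` ng/ml and true
#' area `response * a * base_conc` cps.min.  Point-wise multiplicative
#' lognormal noise (the preset's `noise_cv`) and a Poisson baseline (the
#' preset's `baseline_cps`) are added.  The retained ground truth makes
#' detection/quantification round trips assertable.
#'
#' @param preset A [strain_preset()].
#' @param transition A [transition()].
#' @param lib Compound library (default the packaged worm compounds).
#' @param seed Integer seed for reproducibility (identical seeds give
#'   identical output), or `NULL`.
#' @param sigma_rt Gaussian peak width (min).
#' @param response Response factor (area per ng/ml).
#' @param base_conc Wild-type-equivalent concentration (ng/ml).  The
#'   default (100) places simulated analytes in the upper middle of the
#'   0.1-1000 ng/ml calibrated range, where inversion of the unweighted
#'   calibration line is insensitive to intercept noise.
#' @param t_start,t_end,dt Time grid (minutes).
#' @return A list with `chromatogram` (a [chromatogram()]) and
#'   `ground_truth` (data frame `compound`, `rt`, `area`,
#'   `concentration`, plus the seed as an attribute).
#' @export
simulate_mrm <- function(preset, transition, lib = table3_compounds(),
                         seed = NULL, sigma_rt = 0.05, response = 100,
                         base_conc = 100, t_start = 0, t_end = 16,
                         dt = 0.01) {
  stopifnot(inherits(preset, "pg_strain_preset"),
            inherits(transition, "pg_transition"))
  comps <- transition_compounds(lib, transition)
  if (length(comps) == 0L)
    validation_error("no library compound responds to transition %s",
                     transition$label)
  times <- seq(t_start, t_end, by = dt)
  with_seed(seed, {
    signal <- numeric(length(times))
    gt <- data.frame(compound = character(0), rt = numeric(0),
                     area = numeric(0), concentration = numeric(0),
                     stringsAsFactors = FALSE)
    for (e in comps) {
      a <- preset$compound_abundances[[e$name]] %||% 1
      conc <- a * base_conc
      area <- response * conc
      if (conc > 0 && !is.na(e$rt_min)) {
        amp <- area / (sigma_rt * sqrt(2 * pi))
        signal <- signal + amp * exp(-(times - e$rt_min)^2 / (2 * sigma_rt^2))
      }
      gt <- rbind(gt, data.frame(compound = e$name, rt = e$rt_min,
                                 area = area, concentration = conc,
                                 stringsAsFactors = FALSE))
    }
    if (preset$noise_cv > 0)
      signal <- signal * exp(stats::rnorm(length(signal), 0, preset$noise_cv))
    if (preset$baseline_cps > 0)
      signal <- signal + stats::rpois(length(signal), preset$baseline_cps)
    lab <- sprintf("%s %s", preset$name, transition$label)
    if (!is.null(seed)) lab <- sprintf("%s #%d", lab, as.integer(seed))
    ch <- chromatogram(transition, times, signal, run_label = lab,
                       batch_id = preset$name)
    attr(gt, "seed") <- seed
    list(chromatogram = ch, ground_truth = gt)
  })
}

#' Simulate a noisy CID spectrum from a library compound
#'
#' Emits the compound's tabulated ion list with lognormal intensities and,
#' with probability `contaminant_rate`, adds 1-3 contaminant ions below
#' the parent mass (kept > 1 Da away from the compound's own ions so
#' they never pair with them).
#'
#' @param compound A [pg_standard()].
#' @param seed Integer seed or `NULL`.
#' @param contaminant_rate Probability of adding contaminant ions.
#' @param n_contaminants Number of contaminants when added; `NULL`
#'   draws 1-3 at random.
#' @return A [spectrum_record()] labelled `"sim:<name>"`.
#' @export
simulate_cid <- function(compound, seed = NULL, contaminant_rate = 0,
                         n_contaminants = NULL) {
  stopifnot(inherits(compound, "pg_standard"))
  with_seed(seed, {
    ions <- compound$product_ions
    intensity <- stats::rlnorm(length(ions), meanlog = log(100), sdlog = 0.5)
    if (contaminant_rate > 0 && stats::runif(1) < contaminant_rate) {
      k <- if (is.null(n_contaminants)) sample(1:3, 1L) else n_contaminants
      extra <- numeric(0)
      while (length(extra) < k) {
        cand <- stats::runif(1, 100, compound$parent_mz - 2)
        if (all(abs(c(ions, extra) - cand) > 1.1)) extra <- c(extra, cand)
      }
      ions <- c(ions, extra)
      intensity <- c(intensity, stats::rlnorm(length(extra),
                                              meanlog = log(20), sdlog = 0.3))
    }
    spectrum_record(compound$parent_mz,
                    data.frame(mz = ions, intensity = intensity),
                    rt_min = compound$rt_min,
                    source_label = sprintf("sim:%s", compound$name))
  })
}

#' Simulate an external-standard calibration series
#'
#' Areas follow `response * concentration * exp(eps)` with
#' `eps ~ Normal(0, noise_cv)`; the default levels are the five-point
#' serial dilution 1000, 100, 10, 1, 0.1 ng/ml.
#'
#' @param concs Concentrations (ng/ml, positive).
#' @param response Response factor (area per ng/ml).
#' @param noise_cv Multiplicative noise sd on the log scale.
#' @param seed Integer seed or `NULL`.
#' @return A data frame with columns `concentration` and `area`.
#' @export
simulate_calibration <- function(concs = c(1000, 100, 10, 1, 0.1),
                                 response = 100, noise_cv = 0.05,
                                 seed = NULL) {
  concs <- as.numeric(concs)
  if (any(!is.finite(concs)) || any(concs <= 0))
    validation_error("concentrations must be positive")
  with_seed(seed, {
    data.frame(
      concentration = concs,
      area = response * concs * exp(stats::rnorm(length(concs), 0, noise_cv)))
  })
}

#' Motility presets for track simulation
#'
#' Parameter bundles for the biased persistent random walk, calibrated
#' against the reference motility table:
#' \describe{
#'   \item{wild_type}{guided: speed 8.6 um/min, strong spermatheca bias,
#'     1.8 reversals/hr.}
#'   \item{guidance_null}{no bias, 16.2 reversals/hr, speed 3.4 um/min
#'     (the germline-deficient phenotype).}
#'   \item{fat_intermediate}{partial guidance: speed 6.5 um/min, weak
#'     bias, 5.9 reversals/hr.}
#' }
#'
#' @param name Preset name, or `"custom"` with explicit parameters.
#' @param speed Path speed (um/min, > 0).
#' @param turn_sd Heading noise per frame (degrees).
#' @param bias Fraction of the angle to the spermatheca corrected per
#'   frame (0 = unguided, 1 = immediate lock-on).
#' @param spontaneous_reversal_rate Poisson rate of injected 180-degree
#'   flips (per hour).
#' @param frame_interval Seconds between frames.
#' @return An object of class `pg_motility_preset`.
#' @export
motility_preset <- function(name = c("wild_type", "guidance_null",
                                     "fat_intermediate", "custom"),
                            speed = NULL, turn_sd = NULL, bias = NULL,
                            spontaneous_reversal_rate = NULL,
                            frame_interval = 30) {
  name <- match.arg(name)
  defaults <- switch(name,
    wild_type = list(speed = 8.6, turn_sd = 30, bias = 0.5, rate = 1.8),
    guidance_null = list(speed = 3.4, turn_sd = 60, bias = 0, rate = 16.2),
    fat_intermediate = list(speed = 6.5, turn_sd = 45, bias = 0.15,
                            rate = 5.9),
    custom = list(speed = 8.6, turn_sd = 30, bias = 0.5, rate = 1.8))
  p <- list(name = name,
            speed = speed %||% defaults$speed,
            turn_sd = turn_sd %||% defaults$turn_sd,
            bias = bias %||% defaults$bias,
            spontaneous_reversal_rate =
              spontaneous_reversal_rate %||% defaults$rate,
            frame_interval = frame_interval)
  if (p$speed <= 0) validation_error("preset speed must be > 0")
  if (p$bias < 0) validation_error("preset bias must be >= 0")
  if (p$spontaneous_reversal_rate < 0)
    validation_error("spontaneous_reversal_rate must be >= 0")
  structure(p, class = "pg_motility_preset")
}

#' @export
print.pg_motility_preset <- function(x, ...) {
  cat(sprintf("<pg_motility_preset> %s  speed %g um/min  turn_sd %g deg  bias %g  reversals %g/hr\n",
              x$name, x$speed, x$turn_sd, x$bias,
              x$spontaneous_reversal_rate))
  invisible(x)
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Simulate sperm tracks as a biased persistent random walk
#'
#' Tracks start at the vulva.  Per frame the heading receives Gaussian
#' turning noise (`turn_sd`), a correction of `bias` times the signed
#' angle to the spermatheca centre, and -- as a Poisson process at the
#' preset's spontaneous reversal rate -- a 180 +/- 10 degree flip whose
#' time is recorded in the ground truth.  Steps have length
#' `speed * frame_interval`; positions reflect at a rectangular uterus
#' boundary spanning the guidance axis (length `s + margin`) with the
#' given width.
#'
#' @param preset A [motility_preset()].
#' @param geom A [uterus_geometry()].
#' @param n Number of tracks (>= 1).
#' @param duration Track duration in minutes (>= 2.5).
#' @param seed Integer seed or `NULL`.
#' @param width Uterus width (um) for the reflecting boundary.
#' @param margin Extra boundary length past the spermatheca centre (um).
#' @param initial_heading Optional fixed initial heading(s) in degrees
#'   (recycled over tracks); default random.
#' @param reflect Reflect at the uterus boundary (default).  `FALSE`
#'   simulates an open geometry, useful for parameter-recovery checks
#'   where wall reflections would masquerade as direction changes.
#' @return A list with `tracks` (list of [sperm_track()]) and
#'   `ground_truth` (per-track injected reversal times, the preset, the
#'   seed).
#' @export
simulate_tracks <- function(preset, geom = uterus_geometry(), n = 100,
                            duration = 60, seed = NULL, width = 40,
                            margin = 20, initial_heading = NULL,
                            reflect = TRUE) {
  stopifnot(inherits(preset, "pg_motility_preset"),
            inherits(geom, "pg_geometry"))
  if (n < 1) validation_error("n must be >= 1")
  if (duration < 2.5)
    validation_error("duration must be >= 2.5 minutes")
  dt_s <- preset$frame_interval
  nsteps <- round(duration * 60 / dt_s)
  step_len <- preset$speed * dt_s / 60
  p_flip <- preset$spontaneous_reversal_rate * dt_s / 3600
  xmax <- geom$s + margin
  ymax <- width / 2
  with_seed(seed, {
    tracks <- vector("list", n)
    reversal_times <- vector("list", n)
    for (k in seq_len(n)) {
      pos <- matrix(0, nrow = nsteps + 1L, ncol = 2L)
      h <- if (is.null(initial_heading)) stats::runif(1, -180, 180) else
        initial_heading[((k - 1L) %% length(initial_heading)) + 1L]
      x <- 0; y <- 0
      flips <- numeric(0)
      for (i in seq_len(nsteps)) {
        target <- atan2(0 - y, geom$s - x) * 180 / pi
        h <- h + preset$bias * wrap180(target - h)
        if (preset$turn_sd > 0) h <- h + stats::rnorm(1, 0, preset$turn_sd)
        if (p_flip > 0 && stats::runif(1) < p_flip) {
          h <- h + 180 + stats::rnorm(1, 0, 10)
          flips <- c(flips, i * dt_s)
        }
        x <- x + step_len * cos(h * pi / 180)
        y <- y + step_len * sin(h * pi / 180)
        if (reflect) {
          # reflect at the rectangular uterus boundary
          if (x < 0) { x <- -x; h <- 180 - h }
          if (x > xmax) { x <- 2 * xmax - x; h <- 180 - h }
          if (y < -ymax) { y <- -2 * ymax - y; h <- -h }
          if (y > ymax) { y <- 2 * ymax - y; h <- -h }
        }
        h <- wrap180(h)
        pos[i + 1L, ] <- c(x, y)
      }
      # axis coordinates -> laboratory frame
      perp <- c(-geom$axis[2L], geom$axis[1L])
      lab <- sweep(pos[, 1L, drop = FALSE] %*% rbind(geom$axis) +
                     pos[, 2L, drop = FALSE] %*% rbind(perp),
                   2L, geom$vulva, `+`)
      tracks[[k]] <- sperm_track(lab, frame_interval = dt_s,
                                 track_id = sprintf("t%03d", k),
                                 gonad_id = "sim")
      reversal_times[[k]] <- flips
    }
    list(tracks = tracks,
         ground_truth = list(reversal_times = reversal_times,
                             preset = preset, geometry = geom,
                             seed = seed))
  })
}
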