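#' Uterus geometry for sperm-guidance scoring
#'
#' The guidance axis runs from the vulva (where males deposit sperm) to
#' the centre of the spermatheca (the fertilization site).  Zone 3 spans
#' the spermatheca centre plus `zone3_depth` microns toward the vulva
#' (default 50 um); the remaining vulva-side region is halved into
#' zones 1 and 2.  Positions are 2-D but scored by their orthogonal
#' projection onto the axis, with the origin at the vulva and positive
#' direction toward the spermatheca.
#'
#' @param vulva,spermatheca_center Numeric length-2 positions (um).
#' @param zone3_depth Zone-3 depth in um, positive and smaller than the
#'   vulva-to-spermatheca distance.
#' @return An object of class `pg_geometry` with the derived unit
#'   `axis` vector and axial spermatheca coordinate `s`.
#' @export
uterus_geometry <- function(vulva = c(0, 0),
                            spermatheca_center = c(200, 0),
                            zone3_depth = 50) {
  vulva <- as.numeric(vulva); spermatheca_center <- as.numeric(spermatheca_center)
  if (length(vulva) != 2L || length(spermatheca_center) != 2L)
    validation_error("vulva and spermatheca_center must be 2-D positions")
  d <- spermatheca_center - vulva
  s <- sqrt(sum(d^2))
  if (s == 0) validation_error("vulva and spermatheca_center must differ")
  assert_number(zone3_depth, "zone3_depth", positive = TRUE)
  if (zone3_depth >= s)
    validation_error("zone3_depth (%g) must be smaller than the vulva-spermatheca distance (%g)",
                     zone3_depth, s)
  structure(
    list(vulva = vulva, spermatheca_center = spermatheca_center,
         axis = d / s, s = s, zone3_depth = zone3_depth),
    class = "pg_geometry")
}

#' @export
print.pg_geometry <- function(x, ...) {
  cat(sprintf("<pg_geometry> vulva (%g, %g) -> spermatheca (%g, %g), %g um axis, zone 3 depth %g um\n",
              x$vulva[1], x$vulva[2], x$spermatheca_center[1],
              x$spermatheca_center[2], x$s, x$zone3_depth))
  invisible(x)
}

#' A time-lapse sperm track
#'
#' Per-frame 2-D positions at a fixed frame interval (default 30 s,
#' matching DIC/fluorescence acquisition every 30 seconds).
#'
#' @param positions An n x 2 matrix (or data frame) of positions in um.
#' @param frame_interval Seconds between frames.
#' @param track_id,gonad_id Identifiers.
#' @param t Optional explicit frame times (seconds); defaults to
#'   `0, frame_interval, 2*frame_interval, ...` and must be uniform.
#' @return An object of class `pg_track`.
#' @export
sperm_track <- function(positions, frame_interval = 30, track_id = "track",
                        gonad_id = "gonad", t = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) < 2L)
    validation_error("positions must be an n x 2 matrix with n >= 2")
  storage.mode(positions) <- "double"
  if (is.null(t)) t <- (seq_len(nrow(positions)) - 1L) * frame_interval
  t <- as.numeric(t)
  if (length(t) != nrow(positions))
    validation_error("t must match the number of frames")
  dt <- diff(t)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9)
    validation_error("frame times must be strictly increasing and uniform")
  if (abs(dt[1] - frame_interval) > 1e-9) frame_interval <- dt[1]
  structure(
    list(t = t, positions = positions, frame_interval = frame_interval,
         track_id = track_id, gonad_id = gonad_id),
    class = "pg_track")
}

#' @export
print.pg_track <- function(x, ...) {
  cat(sprintf("<pg_track> %s/%s  %d frames @ %g s  duration %.1f min\n",
              x$gonad_id, x$track_id, nrow(x$positions), x$frame_interval,
              track_duration(x)))
  invisible(x)
}

#' @rdname sperm_track
#' @param track A `pg_track`.
#' @return `track_duration()` returns the track duration in minutes.
#' @export
track_duration <- function(track) {
  (track$t[length(track$t)] - track$t[1]) / 60
}

axial_coordinate <- function(positions, geom) {
  positions <- if (is.matrix(positions)) positions else
    matrix(positions, ncol = 2L)
  sweep(positions, 2L, geom$vulva) %*% geom$axis
}

#' Zone boundaries along the guidance axis
#'
#' With the origin at the vulva and `s` the axial coordinate of the
#' spermatheca centre: zone 3 is `[s - zone3_depth, Inf)` (positions at
#' or past the centre remain zone 3), and the remaining `[0,
#' s - zone3_depth)` region is halved into zone 1 (vulva side) and
#' zone 2.
#'
#' @param geom A [uterus_geometry()].
#' @return A 3 x 2 matrix of interval bounds (rows zone1..zone3); each
#'   interval is closed on the left, open on the right.
#' @export
zone_boundaries <- function(geom) {
  stopifnot(inherits(geom, "pg_geometry"))
  b <- geom$s - geom$zone3_depth
  m <- rbind(zone1 = c(0, b / 2), zone2 = c(b / 2, b), zone3 = c(b, Inf))
  colnames(m) <- c("from", "to")
  m
}

#' Assign positions to uterine zones
#'
#' Projects each position onto the guidance axis and returns its zone;
#' positions projecting behind the vulva (negative axial coordinate) are
#' zone 1.
#'
#' @param position A 2-D position or an n x 2 matrix of positions (um).
#' @param geom A [uterus_geometry()].
#' @return Integer zone(s) in 1..3.
#' @export
assign_zone <- function(position, geom) {
  stopifnot(inherits(geom, "pg_geometry"))
  ax <- drop(axial_coordinate(position, geom))
  b <- geom$s - geom$zone3_depth
  as.integer(ifelse(ax >= b, 3L, ifelse(ax >= b / 2, 2L, 1L)))
}

#' Sperm motility metrics
#'
#' `avg_velocity` is the summed step displacement (path length) divided
#' by the track duration, in um/min.  `directional_velocity` is the net
#' axial displacement from the first to the last frame divided by the
#' duration, positive toward the spermatheca; it is bounded in absolute
#' value by the average velocity.
#'
#' @param track A [sperm_track()].
#' @param geom A [uterus_geometry()].
#' @return Velocity in um/min.
#' @export
avg_velocity <- function(track) {
  stopifnot(inherits(track, "pg_track"))
  steps <- diff(track$positions)
  sum(sqrt(rowSums(steps^2))) / track_duration(track)
}

#' @rdname avg_velocity
#' @export
directional_velocity <- function(track, geom) {
  stopifnot(inherits(track, "pg_track"))
  ax <- axial_coordinate(track$positions[c(1L, nrow(track$positions)), ],
                         geom)
  (ax[2L] - ax[1L]) / track_duration(track)
}

#' Count migration reversals
#'
#' A reversal is a change in migration direction exceeding 90 degrees
#' within 3 consecutive frames.  Per-step headings are computed from
#' successive displacements (steps below `min_step` um carry the
#' previous heading so that pauses do not create undefined angles).
#' Under the default `"window"` rule a reversal is scored at step i when
#' the unsigned angle between heading i and heading j exceeds 90 degrees
#' for some j in \{i+1, i+2\}; scoring advances past j so one manoeuvre
#' is counted once.  The `"adjacent"` rule compares only consecutive
#' headings (j = i+1) with the same skip.
#'
#' @param track A [sperm_track()] with >= 3 frames.
#' @param min_step Minimum displacement (um) for a step to define a new
#'   heading.
#' @param rule `"window"` (default) or `"adjacent"`.
#' @return A list with `count`, `rate` (reversals/hour) and `duration`
#'   (minutes).
#' @export
count_reversals <- function(track, min_step = 0.5, rule = c("window",
                                                            "adjacent")) {
  stopifnot(inherits(track, "pg_track"))
  rule <- match.arg(rule)
  n <- nrow(track$positions)
  if (n < 3L)
    validation_error("reversal counting needs at least 3 frames")
  headings <- step_headings(track$positions, min_step)
  span <- if (rule == "window") 2L else 1L
  count <- 0L
  i <- 1L
  m <- length(headings)
  while (i < m) {
    jmax <- min(i + span, m)
    scored <- FALSE
    for (j in (i + 1L):jmax) {
      if (heading_angle(headings[i], headings[j]) > 90) {
        count <- count + 1L
        i <- j + 1L
        scored <- TRUE
        break
      }
    }
    if (!scored) i <- i + 1L
  }
  dur <- track_duration(track)
  list(count = count, rate = count / (dur / 60), duration = dur)
}

# headings (degrees) per step; sub-threshold steps inherit the previous
# heading (0 if the track starts with a pause)
step_headings <- function(positions, min_step) {
  steps <- diff(positions)
  len <- sqrt(rowSums(steps^2))
  h <- numeric(nrow(steps))
  prev <- 0
  for (k in seq_len(nrow(steps))) {
    if (len[k] >= min_step) prev <- atan2(steps[k, 2L], steps[k, 1L]) * 180 / pi
    h[k] <- prev
  }
  h
}

heading_angle <- function(a, b) {
  d <- abs(a - b) %% 360
  if (d > 180) d <- 360 - d
  d
}

#' Filter tracks by duration
#'
#' Retains tracks whose duration lies in `[min_duration, max_duration]`
#' (both bounds inclusive; the reference assay scores traces from 2.5 to
#' 21 minutes) and logs a reason for each rejection.
#'
#' @param tracks A list of [sperm_track()] objects.
#' @param min_duration,max_duration Bounds in minutes.
#' @return A list with `tracks` (retained) and `rejections` (data frame
#'   with `track_id`, `gonad_id`, `duration`, `reason`).
#' @export
filter_tracks <- function(tracks, min_duration = 2.5, max_duration = 21) {
  dur <- vapply(tracks, track_duration, numeric(1))
  keep <- dur >= min_duration & dur <= max_duration
  reasons <- ifelse(dur < min_duration, "too short",
                    ifelse(dur > max_duration, "too long", ""))
  rej <- data.frame(
    track_id = vapply(tracks, `[[`, character(1), "track_id")[!keep],
    gonad_id = vapply(tracks, `[[`, character(1), "gonad_id")[!keep],
    duration = dur[!keep],
    reason = reasons[!keep],
    stringsAsFactors = FALSE)
  list(tracks = tracks[keep], rejections = rej)
}

#' Per-track metric summary
#'
#' Computes all motility metrics for a set of tracks.
#'
#' @param tracks A list of [sperm_track()] objects.
#' @param geom A [uterus_geometry()] (or a named list of geometries
#'   keyed by gonad_id).
#' @param ... Passed to [count_reversals()].
#' @return A data frame with one row per track: `gonad_id`, `track_id`,
#'   `duration`, `avg_velocity`, `directional_velocity`,
#'   `reversal_count`, `reversal_rate`.
#' @export
track_metrics <- function(tracks, geom, ...) {
  get_geom <- function(tr) {
    if (inherits(geom, "pg_geometry")) return(geom)
    g <- geom[[tr$gonad_id]]
    if (is.null(g))
      validation_error("no geometry for gonad '%s'", tr$gonad_id)
    g
  }
  rows <- lapply(tracks, function(tr) {
    rv <- count_reversals(tr, ...)
    data.frame(gonad_id = tr$gonad_id, track_id = tr$track_id,
               duration = track_duration(tr),
               avg_velocity = avg_velocity(tr),
               directional_velocity = directional_velocity(tr, get_geom(tr)),
               reversal_count = rv$count, reversal_rate = rv$rate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Uterine zone distribution
#'
#' Computes per-gonad zone occupancy fractions (each gonad's positions
#' classified by [assign_zone()] and normalized to sum to 1) and the
#' unweighted group mean and sample SD across gonads, each gonad
#' counting as one observation.
#'
#' @param positions_by_gonad A named list mapping gonad id to an n x 2
#'   position matrix.
#' @param geom A [uterus_geometry()] or a named list of geometries keyed
#'   by gonad id.
#' @return An object of class `pg_zone_distribution`: a list with
#'   `per_gonad` (data frame of fractions), `mean`, `sd`, `n_gonads`,
#'   `excluded` (gonads with no positions).
#' @export
zone_distribution <- function(positions_by_gonad, geom) {
  stopifnot(is.list(positions_by_gonad))
  get_geom <- function(id) {
    if (inherits(geom, "pg_geometry")) return(geom)
    g <- geom[[id]]
    if (is.null(g)) validation_error("no geometry for gonad '%s'", id)
    g
  }
  ids <- names(positions_by_gonad) %||%
    as.character(seq_along(positions_by_gonad))
  empty <- vapply(positions_by_gonad, function(p) NROW(p) == 0L, logical(1))
  frac <- t(vapply(which(!empty), function(i) {
    z <- assign_zone(as.matrix(positions_by_gonad[[i]]), get_geom(ids[i]))
    tabulate(z, nbins = 3L) / length(z)
  }, numeric(3)))
  colnames(frac) <- c("zone1", "zone2", "zone3")
  per_gonad <- data.frame(gonad_id = ids[!empty], frac,
                          stringsAsFactors = FALSE)
  structure(
    list(per_gonad = per_gonad,
         mean = colMeans(frac),
         sd = apply(frac, 2L, function(x) if (length(x) > 1) stats::sd(x) else 0),
         n_gonads = nrow(per_gonad),
         excluded = ids[empty]),
    class = "pg_zone_distribution")
}

#' @export
print.pg_zone_distribution <- function(x, ...) {
  cat(sprintf("<pg_zone_distribution> %d gonads\n", x$n_gonads))
  for (z in 1:3)
    cat(sprintf("  zone %d: %.1f%% +/- %.1f%%\n", z, 100 * x$mean[z],
                100 * x$sd[z]))
  if (length(x$excluded))
    cat("  excluded (no positions):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Compare two groups of motility values
#'
#' Welch two-sample t-test on per-track (or per-gonad) values, reported
#' with group means and standard errors of the mean.
#'
#' @param metrics_A,metrics_B Numeric vectors, each with n >= 2.
#' @return A list with `mean_A`, `sem_A`, `mean_B`, `sem_B`,
#'   `difference` (B - A), `t`, `df`, `p_value`.
#' @export
compare_groups <- function(metrics_A, metrics_B) {
  metrics_A <- as.numeric(metrics_A); metrics_B <- as.numeric(metrics_B)
  if (length(metrics_A) < 2L || length(metrics_B) < 2L)
    validation_error("both groups need at least 2 values")
  if (stats::sd(metrics_A) == 0 && stats::sd(metrics_B) == 0) {
    # degenerate: no within-group variance; t.test() would error
    d <- mean(metrics_B) - mean(metrics_A)
    tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
               parameter = length(metrics_A) + length(metrics_B) - 2,
               p.value = if (d == 0) 1 else 0)
  } else {
    tt <- stats::t.test(metrics_B, metrics_A)
  }
  list(mean_A = mean(metrics_A),
       sem_A = stats::sd(metrics_A) / sqrt(length(metrics_A)),
       mean_B = mean(metrics_B),
       sem_B = stats::sd(metrics_B) / sqrt(length(metrics_B)),
       difference = mean(metrics_B) - mean(metrics_A),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
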