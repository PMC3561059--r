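test_that("generators are deterministic given a seed", {
  tr <- transition(353, 193)
  wt <- strain_preset("wild_type")
  a <- simulate_mrm(wt, tr, seed = 5)
  b <- simulate_mrm(wt, tr, seed = 5)
  expect_identical(a$chromatogram$intensities, b$chromatogram$intensities)
  c <- simulate_mrm(wt, tr, seed = 6)
  expect_false(identical(a$chromatogram$intensities,
                         c$chromatogram$intensities))

  expect_identical(simulate_calibration(seed = 2),
                   simulate_calibration(seed = 2))

  t2 <- table2_standards()
  pgf2a <- Filter(function(e) e$name == "PGF2a", t2$entries)[[1]]
  expect_identical(simulate_cid(pgf2a, seed = 3)$peaks,
                   simulate_cid(pgf2a, seed = 3)$peaks)

  p <- motility_preset("wild_type")
  g <- uterus_geometry()
  s1 <- simulate_tracks(p, g, n = 5, duration = 10, seed = 8)
  s2 <- simulate_tracks(p, g, n = 5, duration = 10, seed = 8)
  expect_identical(lapply(s1$tracks, `[[`, "positions"),
                   lapply(s2$tracks, `[[`, "positions"))
})

test_that("unknown strain presets are rejected and patterns encoded", {
  expect_error(strain_preset("fat-99"), class = "pgsperm_config_error")
  f1 <- strain_preset("fat-1")
  expect_equal(unname(f1$compound_abundances["CePGF2"]), 4)
  expect_true(all(f1$compound_abundances[
    grepl("Class 3", names(f1$compound_abundances))] == 0))
  glp <- strain_preset("glp-4")
  expect_equal(unname(glp$compound_abundances["CePGF2"]), 0.25)
})

test_that("noiseless chromatograms integrate to the ground-truth areas", {
  wt0 <- strain_preset("wild_type", noise_cv = 0, baseline_cps = 0)
  sim <- simulate_mrm(wt0, transition(353, 193), seed = 1)
  pk <- match_peaks(detect_peaks(sim$chromatogram), sim$chromatogram,
                    table3_compounds())
  gt <- sim$ground_truth
  expect_equal(nrow(pk), sum(gt$concentration > 0))
  for (i in which(gt$concentration > 0)) {
    j <- match(gt$compound[i], pk$matched_standard)
    expect_false(is.na(j))
    expect_equal(pk$area[j], gt$area[i], tolerance = 0.02)
  }
})

test_that("the wild-type F2 trace carries one peak per F2 compound", {
  sim <- simulate_mrm(strain_preset("wild_type"), transition(353, 193),
                      seed = 11)
  pk <- detect_peaks(sim$chromatogram)
  expect_equal(nrow(pk), sum(sim$ground_truth$concentration > 0))
})

test_that("fat-1 has no detectable F3 signal", {
  sim <- simulate_mrm(strain_preset("fat-1"), transition(351, 193),
                      seed = 12)
  expect_true(all(sim$ground_truth$concentration == 0))
  expect_equal(nrow(detect_peaks(sim$chromatogram)), 0L)
})

test_that("simulated CID spectra classify like their templates", {
  t2 <- table2_standards()
  by_name <- function(n) Filter(function(e) e$name == n, t2$entries)[[1]]

  clean <- simulate_cid(by_name("PGF2a"), seed = 1, contaminant_rate = 0)
  call <- classify_spectrum(clean, t2)
  expect_equal(call$series, "F2")
  expect_true(call$best_match %in% c("PGF2a", "ent-PGF2a"))

  expect_equal(classify_spectrum(simulate_cid(by_name("PGD2"), seed = 2),
                                 t2)$series, "DEH_candidate")

  dirty <- simulate_cid(by_name("PGF2a"), seed = 1, contaminant_rate = 1,
                        n_contaminants = 3)
  dirty_call <- classify_spectrum(dirty, t2)
  expect_lt(dirty_call$jaccard, call$jaccard)
  expect_equal(dirty_call$series, call$series)
})

test_that("calibration generator obeys its noise model", {
  exact <- simulate_calibration(noise_cv = 0)
  expect_equal(exact$area, 100 * exact$concentration)
  one <- simulate_calibration(concs = 10, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_error(fit_calibration(one), class = "pgsperm_validation_error")
  expect_error(simulate_calibration(concs = c(1, -1)),
               class = "pgsperm_validation_error")
})

test_that("the deterministic limit of the walk is a straight track", {
  p <- motility_preset("custom", speed = 8.6, turn_sd = 0, bias = 0,
                       spontaneous_reversal_rate = 0)
  g <- uterus_geometry(c(0, 0), c(5000, 0), 50)
  sim <- simulate_tracks(p, g, n = 2, duration = 10, seed = 1,
                         initial_heading = c(0, 180), reflect = FALSE)
  dv <- vapply(sim$tracks, directional_velocity, numeric(1), geom = g)
  expect_equal(dv, c(8.6, -8.6))
  for (tr in sim$tracks)
    expect_equal(avg_velocity(tr), 8.6)
  expect_error(simulate_tracks(motility_preset("custom", speed = 0), g,
                               n = 1, duration = 10),
               class = "pgsperm_validation_error")
})

test_that("injected reversal rates are recovered within sampling error", {
  p <- motility_preset("custom", speed = 8.6, turn_sd = 5, bias = 0,
                       spontaneous_reversal_rate = 9)
  g <- uterus_geometry(c(0, 0), c(5000, 0), 50)
  dur <- 20
  sim <- simulate_tracks(p, g, n = 500, duration = dur, seed = 31,
                         initial_heading = 0, reflect = FALSE)
  rates <- vapply(sim$tracks, function(tr) count_reversals(tr)$rate,
                  numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))

  # injected flip count agrees in aggregate with the requested rate
  injected <- sum(lengths(sim$ground_truth$reversal_times)) /
    (500 * dur / 60)
  expect_equal(injected, 9, tolerance = 0.15)

  # the scoring rule merges manoeuvres closer than its 3-frame window
  # and cannot see a flip on the very first step, so the sharp oracle is
  # the window-censored injected count
  censored <- vapply(sim$ground_truth$reversal_times, function(tt) {
    steps <- tt / p$frame_interval
    steps <- steps[steps > 1]
    n <- 0L; last <- -Inf
    for (s in steps) if (s > last + 2) { n <- n + 1L; last <- s }
    n / (dur / 60)
  }, numeric(1))
  expect_lt(abs(mean(rates) - mean(censored)), 3 * se)
  # and the censored rate stays close to the nominal rate
  expect_equal(mean(rates), 9, tolerance = 0.15)
})

test_that("directional velocity grows with the guidance bias", {
  g <- uterus_geometry()
  dv <- vapply(c(0, 0.1, 0.2, 0.4, 0.8), function(b) {
    p <- motility_preset("custom", speed = 8.6, turn_sd = 30, bias = b,
                         spontaneous_reversal_rate = 1.8)
    sim <- simulate_tracks(p, g, n = 150, duration = 20, seed = 41)
    mean(vapply(sim$tracks, directional_velocity, numeric(1), geom = g))
  }, numeric(1))
  expect_true(all(diff(dv) >= 0))
})

test_that("the wild-type preset reaches the fertilization site", {
  g <- uterus_geometry()
  sim <- simulate_tracks(motility_preset("wild_type"), g, n = 100,
                         duration = 60, seed = 51)
  ends <- t(vapply(sim$tracks, function(tr)
    tr$positions[nrow(tr$positions), ], numeric(2)))
  expect_gt(mean(assign_zone(ends, g) == 3L), 0.9)
})
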