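gaussian_chrom <- function(amp, mu, sigma, baseline = 0, t_end = 16,
                           dt = 0.01) {
  t <- seq(0, t_end, by = dt)
  chromatogram(transition(353, 193), t,
               baseline + amp * exp(-(t - mu)^2 / (2 * sigma^2)))
}

test_that("chromatograms reject malformed grids", {
  tr <- transition(353, 193)
  expect_error(chromatogram(tr, c(0, 0.01, 0.03), c(1, 2, 3)),
               class = "pgsperm_validation_error")
  expect_error(chromatogram(tr, c(0, 0.01), c(1, -2)),
               class = "pgsperm_validation_error")
  expect_error(transition(193, 353), class = "pgsperm_validation_error")
})

test_that("a flat trace yields no peaks", {
  t <- seq(0, 16, by = 0.01)
  ch <- chromatogram(transition(353, 193), t, rep(20, length(t)))
  expect_equal(nrow(detect_peaks(ch)), 0L)
})

test_that("a synthetic Gaussian is integrated to within 2% of closed form", {
  A <- 5000; sigma <- 0.05
  pk <- detect_peaks(gaussian_chrom(A, 8, sigma))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$rt_apex, 8, tolerance = 0.011)
  expect_equal(pk$area, A * sigma * sqrt(2 * pi), tolerance = 0.02)
})

test_that("two close Gaussians resolve with apexes on the grid", {
  t <- seq(0, 16, by = 0.01)
  y <- 4000 * exp(-(t - 10)^2 / (2 * 0.06^2)) +
       3000 * exp(-(t - 10.5)^2 / (2 * 0.06^2))
  pk <- detect_peaks(chromatogram(transition(353, 193), t, y))
  expect_equal(nrow(pk), 2L)
  expect_equal(sort(pk$rt_apex), c(10, 10.5), tolerance = 0.011)
})

test_that("peak area is invariant to a constant baseline offset", {
  base0 <- detect_peaks(gaussian_chrom(5000, 8, 0.05))
  base50 <- detect_peaks(gaussian_chrom(5000, 8, 0.05, baseline = 50))
  expect_equal(base50$area, base0$area, tolerance = 0.01)
})

test_that("calibration fits recover the line and its figure of merit", {
  concs <- c(1000, 100, 10, 1, 0.1)
  exact <- fit_calibration(data.frame(concentration = concs,
                                      area = 100 * concs))
  expect_equal(exact$r, 1)
  expect_equal(unname(coef(exact)), c(0, 100), tolerance = 1e-10)
  expect_equal(exact$range, c(0.1, 1000))

  noisy <- fit_calibration(simulate_calibration(concs, 100, 0.05, seed = 7))
  expect_gt(noisy$r, 0.99)

  expect_error(fit_calibration(data.frame(concentration = c(1, 10),
                                          area = c(1, 10))),
               class = "pgsperm_validation_error")
  expect_error(fit_calibration(data.frame(concentration = c(1, 1, 1),
                                          area = c(1, 2, 3))),
               class = "pgsperm_validation_error")
})

test_that("OLS recovers known calibration parameters within standard errors", {
  set.seed(3)
  concs <- rep(c(1000, 100, 10, 1, 0.1), 3)
  cal <- data.frame(concentration = concs,
                    area = 50 + 250 * concs + rnorm(length(concs), sd = 400))
  cv <- fit_calibration(cal)
  ses <- summary(cv$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(cv$slope - 250), 3 * ses["concentration"])
  expect_lt(abs(cv$intercept - 50), 3 * ses["(Intercept)"])
})

test_that("quantification inverts the curve with range and clamp flags", {
  concs <- c(1000, 100, 10, 1, 0.1)
  curve <- fit_calibration(data.frame(concentration = concs,
                                      area = 100 * concs))
  q <- quantify(predict(curve, 10), curve)
  expect_equal(q$concentration, 10)
  expect_true(q$in_range)

  expect_equal(quantify(curve$intercept, curve)$concentration, 0)

  high <- quantify(predict(curve, 5000), curve)
  expect_false(high$in_range)
  expect_equal(high$concentration, 5000)

  # round trip across the calibrated range
  for (c0 in c(0.1, 1, 50, 1000))
    expect_equal(quantify(predict(curve, c0), curve)$concentration, c0)

  flat <- curve; flat$slope <- 0
  expect_error(quantify(100, flat), class = "pgsperm_degenerate_curve")
})

test_that("replicate averaging follows the stated design", {
  expect_equal(average_replicates(c(5, 5, 5))[c("mean", "sd")],
               list(mean = 5, sd = 0))
  expect_equal(average_replicates(c(4, 5, 6))[c("mean", "sd")],
               list(mean = 5, sd = 1))
  one <- average_replicates(7)
  expect_equal(one$mean, 7)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)
  expect_error(average_replicates(numeric(0)),
               class = "pgsperm_validation_error")
})

test_that("RT alignment uses the median shift over shared standards", {
  mk <- function(rts, names) {
    p <- detect_peaks(gaussian_chrom(5000, 8, 0.05))[rep(1, length(rts)), ]
    p$rt_apex <- rts; p$matched_standard <- names
    p
  }
  ref <- mk(c(11.73, 11.26, 11.83), c("PGF2a", "PGF3a", "PGF1a"))
  expect_equal(align_rt(ref, ref), 0)
  tgt <- mk(c(11.83, 11.36, 11.93), c("PGF2a", "PGF3a", "PGF1a"))
  expect_equal(align_rt(ref, tgt), 0.10)
  expect_equal(align_rt(mk(11.73, "PGF2a"), mk(11.80, "PGF2a")), 0.07)
  expect_error(align_rt(mk(11.73, "PGF2a"), mk(11.26, "PGF3a")),
               class = "pgsperm_alignment_error")
})

test_that("comparing a strain against itself is a no-op", {
  t3 <- table3_compounds()
  runs <- lapply(1:2, function(s)
    simulate_mrm(strain_preset("wild_type", noise_cv = 0),
                 transition(353, 193), seed = s)$chromatogram)
  cmp <- compare_strains(runs, runs, t3)
  expect_true(all(cmp$call == "UNCHANGED"))
  expect_true(all(abs(cmp$fold_change - 1) < 1e-9))
})

test_that("strain comparisons recover the encoded mutant phenotypes", {
  t3 <- table3_compounds()
  sim <- function(name, tr, seeds) lapply(seeds, function(s)
    simulate_mrm(strain_preset(name), tr, seed = s)$chromatogram)
  tr_f2 <- transition(353, 193); tr_f3 <- transition(351, 193)

  cmp <- compare_strains(c(sim("wild_type", tr_f2, 1:3),
                           sim("wild_type", tr_f3, 4:6)),
                         c(sim("fat-1", tr_f2, 7:9),
                           sim("fat-1", tr_f3, 10:12)), t3)
  ce <- cmp[cmp$compound == "CePGF2" & cmp$transition == "353/193", ]
  expect_equal(ce$call, "ELEVATED")
  expect_gt(ce$fold_change, 3)
  f3 <- cmp[cmp$transition == "351/193", ]
  expect_true(all(f3$call == "ABSENT_IN_B"))

  cmp2 <- compare_strains(sim("wild_type", tr_f2, 21:23),
                          sim("glp-4", tr_f2, 24:26), t3)
  ce2 <- cmp2[cmp2$compound == "CePGF2", ]
  expect_equal(ce2$call, "REDUCED")
  expect_equal(ce2$fold_change, 0.25, tolerance = 0.15)

  expect_error(compare_strains(sim("wild_type", tr_f2, 1),
                               sim("wild_type", tr_f3, 2), t3),
               class = "pgsperm_validation_error")
})
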