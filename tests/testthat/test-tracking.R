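test_that("zone boundaries follow the fixed-depth construction", {
  g <- uterus_geometry(c(0, 0), c(200, 0), 50)
  b <- zone_boundaries(g)
  expect_equal(unname(b["zone1", ]), c(0, 75))
  expect_equal(unname(b["zone2", ]), c(75, 150))
  expect_equal(unname(b["zone3", ]), c(150, Inf))

  g2 <- uterus_geometry(c(0, 0), c(100, 0), 50)
  expect_equal(unname(zone_boundaries(g2)["zone1", ]), c(0, 25))

  expect_error(uterus_geometry(c(0, 0), c(100, 0), 100),
               class = "pgsperm_validation_error")
  expect_error(uterus_geometry(c(0, 0), c(0, 0), 10),
               class = "pgsperm_validation_error")
})

test_that("zone assignment projects onto the guidance axis", {
  g <- uterus_geometry(c(0, 0), c(200, 0), 50)
  expect_equal(assign_zone(c(160, 10), g), 3L)
  expect_equal(assign_zone(c(0, 0), g), 1L)
  expect_equal(assign_zone(c(-20, 5), g), 1L)    # behind the vulva
  expect_equal(assign_zone(c(250, 0), g), 3L)    # past the spermatheca

  # oracle: interval lookup on the boundary table
  set.seed(9)
  pos <- cbind(runif(300, -50, 300), runif(300, -30, 30))
  b <- zone_boundaries(g)
  ax <- pos[, 1]                                  # axis is +x here
  oracle <- ifelse(ax >= b["zone3", 1], 3L, ifelse(ax >= b["zone1", 2], 2L, 1L))
  expect_equal(as.integer(assign_zone(pos, g)), oracle)
})

test_that("velocities match hand-computed tracks", {
  g <- uterus_geometry()
  expect_equal(avg_velocity(straight_track()), 10)
  expect_equal(directional_velocity(straight_track(), g), 10)

  stationary <- make_track(matrix(0, nrow = 5, ncol = 2))
  expect_equal(avg_velocity(stationary), 0)

  zig <- make_track(cbind(c(0, 5, 0, 5, 0), 0))
  expect_equal(avg_velocity(zig), 10)             # path length, not net

  away <- make_track(cbind(seq(50, 0, by = -5), 0))
  expect_equal(directional_velocity(away, g), -10)

  loop <- make_track(rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5), c(0, 0)))
  expect_equal(directional_velocity(loop, g), 0)
  expect_gt(avg_velocity(loop), 0)
})

test_that("|directional velocity| never exceeds average velocity", {
  g <- uterus_geometry()
  set.seed(13)
  for (k in 1:50) {
    tr <- make_track(random_walk_positions(sample(6:40, 1)))
    expect_lte(abs(directional_velocity(tr, g)), avg_velocity(tr) + 1e-12)
  }
})

test_that("metrics are invariant under joint rigid motion", {
  set.seed(5)
  pos <- random_walk_positions(20)
  g <- uterus_geometry(c(0, 0), c(200, 0), 50)
  theta <- 0.7; shift <- c(31, -12)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  g2 <- uterus_geometry(c(0, 0) %*% R + shift, c(200, 0) %*% R + shift, 50)
  tr <- make_track(pos)
  tr2 <- make_track(sweep(pos %*% R, 2, shift, `+`))
  expect_equal(avg_velocity(tr2), avg_velocity(tr))
  expect_equal(directional_velocity(tr2, g2), directional_velocity(tr, g))
  expect_equal(count_reversals(tr2)$count, count_reversals(tr)$count)
})

test_that("reversal counting matches hand cases and honours the rules", {
  expect_equal(count_reversals(straight_track())$count, 0L)

  # out 5 frames and straight back: one manoeuvre, one reversal
  back <- make_track(cbind(c(0:5, 4:0) * 5, 0))
  rv <- count_reversals(back)
  expect_equal(rv$count, 1L)
  expect_equal(rv$rate, 1 / (rv$duration / 60))

  expect_error(count_reversals(make_track(cbind(c(0, 5), 0))),
               class = "pgsperm_validation_error")

  # sub-threshold steps carry the previous heading instead of turning
  pause <- make_track(rbind(c(0, 0), c(5, 0), c(5.1, 0), c(10, 0)))
  expect_equal(count_reversals(pause)$count, 0L)

  # the adjacent-step variant sees a two-step 120-degree turn differently
  two_step <- make_track(rbind(c(0, 0), c(5, 0),
                               c(5 + 5 * cos(pi / 3), 5 * sin(pi / 3)),
                               c(5 + 5 * cos(pi / 3) - 5 * cos(pi / 3) * 2,
                                 5 * sin(pi / 3) + 5 * sin(pi / 3) * 2)))
  expect_gte(count_reversals(two_step, rule = "window")$count,
             count_reversals(two_step, rule = "adjacent")$count)
})

test_that("reversal counts equal the exhaustive window oracle", {
  set.seed(17)
  for (k in 1:200) {
    pos <- random_walk_positions(sample(4:30, 1), step = runif(1, 0.1, 8))
    tr <- make_track(pos)
    expect_equal(count_reversals(tr)$count, oracle_reversals(pos))
  }
})

test_that("track duration filtering is inclusive on both bounds", {
  mk_dur <- function(minutes)
    make_track(cbind(seq_len(minutes * 2 + 1), 0))   # 30-s frames
  tracks <- list(mk_dur(2), mk_dur(10), mk_dur(21), mk_dur(22))
  flt <- filter_tracks(tracks)
  expect_length(flt$tracks, 2L)
  expect_equal(sort(vapply(flt$tracks, track_duration, numeric(1))),
               c(10, 21))
  expect_setequal(flt$rejections$reason, c("too short", "too long"))
})

test_that("zone distributions average per gonad", {
  g <- uterus_geometry(c(0, 0), c(200, 0), 50)
  all3 <- lapply(1:4, function(i) cbind(runif(10, 160, 200), 0))
  names(all3) <- paste0("g", 1:4)
  zd <- zone_distribution(all3, g)
  expect_equal(unname(zd$mean), c(0, 0, 1))
  expect_equal(unname(zd$sd), c(0, 0, 0))
  expect_true(all(abs(rowSums(zd$per_gonad[, c("zone1", "zone2", "zone3")]) -
                        1) < 1e-9))

  two <- list(a = cbind(10, 0), b = cbind(190, 0), c = matrix(0, 0, 2))
  zd2 <- zone_distribution(two, g)
  expect_equal(unname(zd2$mean), c(0.5, 0, 0.5))
  expect_equal(zd2$excluded, "c")
  expect_equal(zd2$n_gonads, 2L)
})

test_that("group comparison uses a Welch t-test with SEM reporting", {
  same <- c(1, 2, 3, 4)
  res <- compare_groups(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  ident <- compare_groups(c(5, 5), c(5, 5))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)

  set.seed(23)
  a <- rnorm(50); b <- rnorm(50, 5)
  res2 <- compare_groups(a, b)
  expect_lt(res2$p_value, 0.001)
  expect_equal(res2$mean_B - res2$mean_A, res2$difference)
  expect_equal(res2$sem_A, stats::sd(a) / sqrt(50))

  expect_error(compare_groups(1, c(1, 2)), class = "pgsperm_validation_error")
})
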