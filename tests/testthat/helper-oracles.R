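# independent reference implementations used to cross-check the package

# maximum bipartite matching (Kuhn's augmenting paths) between two ion
# lists under a pairing tolerance; returns the optimal number of pairs
oracle_max_shared <- function(q, r, tol = 0.5) {
  match_r <- integer(length(r))
  try_augment <- function(i, env) {
    for (j in seq_along(r)) {
      if (!env$visited[j] && abs(q[i] - r[j]) <= tol) {
        env$visited[j] <- TRUE
        if (match_r[j] == 0L || try_augment(match_r[j], env)) {
          match_r[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_along(q)) {
    env <- new.env(parent = emptyenv())
    env$visited <- logical(length(r))
    if (try_augment(i, env)) n <- n + 1L
  }
  n
}

# exhaustive window scan for the reversal rule: headings from successive
# displacements (sub-threshold steps carry the previous heading), a
# reversal whenever heading i vs heading j (j within the window) differ
# by more than 90 degrees, scanning forward and skipping past a scored j
oracle_reversals <- function(positions, min_step = 0.5, span = 2L) {
  d <- diff(positions)
  len <- sqrt(rowSums(d^2))
  ang <- atan2(d[, 2L], d[, 1L]) * 180 / pi
  h <- numeric(length(len))
  cur <- 0
  for (k in seq_along(len)) {
    if (len[k] >= min_step) cur <- ang[k]
    h[k] <- cur
  }
  count <- 0L
  i <- 1L
  while (i < length(h)) {
    hit <- 0L
    for (j in (i + 1L):min(i + span, length(h))) {
      dd <- abs(h[i] - h[j]) %% 360
      if (dd > 180) dd <- 360 - dd
      if (dd > 90) { hit <- j; break }
    }
    if (hit) { count <- count + 1L; i <- hit + 1L } else i <- i + 1L
  }
  count
}

# random 2-D walk with uniform headings, as a bare position matrix
random_walk_positions <- function(nframes, step = 5) {
  h <- runif(nframes - 1L, -pi, pi)
  steps <- cbind(step * cos(h), step * sin(h))
  apply(rbind(c(0, 0), steps), 2L, cumsum)
}

make_track <- function(positions, frame_interval = 30, ...) {
  sperm_track(positions, frame_interval = frame_interval, ...)
}

# a straight track along +x at `per_frame` um per frame
straight_track <- function(nframes = 11, per_frame = 5) {
  make_track(cbind(seq(0, by = per_frame, length.out = nframes), 0))
}
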