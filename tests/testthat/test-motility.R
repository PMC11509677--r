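straight_track <- function(n_steps = 10, step = 1, dt = 5) {
  data.frame(track_id = 1L, frame = seq_len(n_steps + 1),
             t_min = (0:n_steps) * dt, x_um = (0:n_steps) * step, y_um = 0)
}

test_that("origin normalisation translates tracks without touching steps", {
  tr <- straight_track()
  tr$x_um <- tr$x_um + 5; tr$y_um <- tr$y_um - 3
  out <- normalize_tracks_to_origin(tr)
  expect_equal(out$x_um[1], 0)
  expect_equal(out$y_um[1], 0)
  expect_identical(normalize_tracks_to_origin(out), out)  # idempotent
  # step vectors preserved on random tracks
  set.seed(1)
  for (i in 1:100) {
    n <- sample(3:15, 1)
    tr <- data.frame(track_id = 1L, frame = 1:n, t_min = (1:n) * 2,
                     x_um = cumsum(stats::rnorm(n)), y_um = cumsum(stats::rnorm(n)))
    out <- normalize_tracks_to_origin(tr)
    expect_equal(diff(out$x_um), diff(tr$x_um), tolerance = 1e-12)
    expect_equal(diff(out$y_um), diff(tr$y_um), tolerance = 1e-12)
  }
})

test_that("track statistics match hand-computed values", {
  st <- track_statistics(straight_track(n_steps = 10, step = 1, dt = 5))
  expect_equal(st$speed_um_min, 0.2)
  expect_equal(st$displacement_um, 10)
  expect_equal(st$path_length_um, 10)
  expect_equal(st$straightness, 1)
  expect_equal(st$duration_min, 50)

  # stationary track: zero speed, straightness flagged undefined
  still <- straight_track(); still$x_um <- 0
  st0 <- track_statistics(still)
  expect_equal(st0$speed_um_min, 0)
  expect_true(is.na(st0$straightness))

  # square wave: alternating +-y with net +x drift, enumerated by hand
  sq <- data.frame(track_id = 1L, frame = 1:6, t_min = (0:5) * 2,
                   x_um = c(0, 1, 2, 3, 4, 5),
                   y_um = c(0, 1, 0, 1, 0, 1))
  stq <- track_statistics(sq)
  expect_equal(stq$path_length_um, 5 * sqrt(2))
  expect_equal(stq$displacement_um, sqrt(25 + 1))
  expect_equal(stq$speed_um_min, 5 * sqrt(2) / 10)
  expect_lt(stq$straightness, 1)

  # instantaneous-speed mode equals mean step speed
  sti <- track_statistics(sq, speed_mode = "instantaneous")
  expect_equal(sti$speed_um_min, mean(rep(sqrt(2) / 2, 5)))
})

test_that("MSD estimator matches definition and analytic limits", {
  still <- straight_track(); still$x_um <- 0
  curve <- msd(rbind(still, transform(still, track_id = 2L)))
  expect_true(all(curve$msd_um2 == 0))

  # ballistic track: MSD(tau) = v^2 tau^2 exactly
  bal <- straight_track(n_steps = 20, step = 2, dt = 5)  # v = 0.4 um/min
  curve <- msd(bal, max_lag = 50)
  expect_equal(curve$msd_um2, 0.4^2 * curve$lag_min^2, tolerance = 1e-12)

  # brute-force all-pairs oracle on short random tracks
  set.seed(2)
  trs <- do.call(rbind, lapply(1:5, function(id) {
    n <- sample(4:10, 1)
    data.frame(track_id = id, frame = 1:n, t_min = (0:(n - 1)) * 3,
               x_um = cumsum(stats::rnorm(n)), y_um = cumsum(stats::rnorm(n)))
  }))
  curve <- msd(trs, max_lag = 12)
  expect_equal(curve$msd_um2[-1], oracle_msd(trs, 12, 3), tolerance = 1e-12)

  # non-uniform sampling is refused
  bad <- straight_track(); bad$t_min[3] <- 7.5
  expect_error(msd(bad), "non-uniform")
  # short tracks are excluded with a message
  two <- data.frame(track_id = 9L, frame = 1:2, t_min = c(0, 5),
                    x_um = c(0, 1), y_um = 0)
  expect_message(msd(rbind(bal, two)), "excluding 1")
})

test_that("statistics are invariant under rotation and translation", {
  set.seed(3)
  tr <- simulate_tracks(10, seed = 4)
  th <- 0.7
  rot <- tr
  rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 12
  rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 8
  expect_equal(track_statistics(rot)$speed_um_min,
               track_statistics(tr)$speed_um_min, tolerance = 1e-12)
  expect_equal(msd(rot, max_lag = 30)$msd_um2, msd(tr, max_lag = 30)$msd_um2,
               tolerance = 1e-9)
})

test_that("Fuerth fitting recovers parameters and flags the ballistic bound", {
  lag <- seq(5, 100, by = 5)
  curve <- data.frame(lag_min = lag, msd_um2 = furth_msd(lag, S = 0.4, P = 10))
  fit <- fit_furth(curve)
  expect_equal(fit$S, 0.4, tolerance = 1e-4)
  expect_equal(fit$P, 10, tolerance = 1e-3)
  expect_false(fit$at_bound)

  # pure ballistic curve: P runs to the documented cap and is flagged
  bal <- data.frame(lag_min = lag, msd_um2 = (0.4 * lag)^2)
  fitb <- fit_furth(bal)
  expect_true(fitb$at_bound)

  expect_error(fit_furth(curve[1:3, ]), ">= 5")
})

test_that("simulated PRW ensemble matches the Fuerth form", {
  tr <- simulate_tracks(200, speed = 0.4, persistence = 10,
                        frame_interval = 5, n_frames = 73, seed = 5)
  curve <- msd(tr, max_lag = 50)                      # lags <= 5 P
  theo <- furth_msd(curve$lag_min[-1], 0.4, 10)
  rel <- abs(curve$msd_um2[-1] - theo) / theo
  expect_lt(max(rel), 0.15)
  fit <- fit_furth(curve)
  expect_lt(abs(fit$S - 0.4) / 0.4, 0.2)
  expect_lt(abs(fit$P - 10) / 10, 0.2)
})

test_that("mean path speed converges towards the stationary speed scale as dt -> 0", {
  # finite sampling underestimates the OU path speed; the bias shrinks with dt
  sp <- vapply(c(5, 1, 0.2), function(dt) {
    tr <- simulate_tracks(40, speed = 0.4, persistence = 10,
                          frame_interval = dt, n_frames = 200, seed = 6)
    mean(track_statistics(tr)$speed_um_min)
  }, 1)
  expect_true(all(diff(sp) > 0))
  # E|v| for a 2-D Gaussian speed of scale S is S * sqrt(pi) / 2
  expect_lt(abs(sp[3] - 0.4 * sqrt(pi) / 2) / (0.4 * sqrt(pi) / 2), 0.1)
})

test_that("track tables round-trip through CSV", {
  tr <- simulate_tracks(3, seed = 7)
  path <- tempfile(fileext = ".csv")
  write_tracks(tr, path)
  back <- read_tracks(path)
  expect_equal(back$x_um, tr$x_um, tolerance = 1e-9)
  expect_error(read_tracks({p <- tempfile(); writeLines("a,b", p); p}),
               "missing column")
})
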