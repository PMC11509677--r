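#' Simulate persistent-random-walk migration tracks
#'
#' 2-D persistent random walk: each velocity component follows an
#' Ornstein-Uhlenbeck process with persistence time P and stationary speed
#' scale S (stationary mean squared speed S^2, i.e. per-component variance
#' S^2/2), initialised from its stationary distribution. Per frame the joint
#' (position increment, velocity) update is drawn from its exact Gaussian
#' transition, so the sampled positions are the continuous process observed
#' at the frame times and the ensemble MSD follows the Fuerth form
#' MSD(tau) = 2 S^2 P (tau - P (1 - exp(-tau / P))) in expectation.
#'
#' @param n_tracks number of tracks (>= 1).
#' @param speed stationary speed scale S, um/min (default 0.4, a typical
#'   epithelial translocation rate).
#' @param persistence persistence time P, min (default 10).
#' @param frame_interval sampling interval, min (default 5).
#' @param n_frames number of samples per track (default 73, i.e. 6 h at
#'   5-min frames).
#' @param seed integer RNG seed.
#' @return A data.frame of class \code{"tracks"}: \code{track_id},
#'   \code{frame}, \code{t_min}, \code{x_um}, \code{y_um}.
#' @export
simulate_tracks <- function(n_tracks, speed = 0.4, persistence = 10,
                            frame_interval = 5, n_frames = 73L, seed = 1L) {
  stopifnot(n_tracks >= 1, speed >= 0, persistence > 0, frame_interval > 0,
            n_frames >= 2)
  set.seed(seed)
  S <- speed; P <- persistence; dt <- frame_interval
  sig2 <- S^2 / 2                      # per-component stationary variance
  a <- exp(-dt / P)
  var_v <- sig2 * (1 - a^2)
  var_x <- sig2 * P^2 * (2 * dt / P - 3 + 4 * a - a^2)
  cov_xv <- sig2 * P * (1 - a)^2
  # conditional decomposition of the joint (dx, v') Gaussian noise
  sd_v <- sqrt(var_v)
  beta <- if (var_v > 0) cov_xv / var_v else 0
  sd_x_res <- if (var_v > 0) sqrt(max(var_x - cov_xv^2 / var_v, 0)) else 0

  out <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    v <- matrix(stats::rnorm(2, 0, sqrt(sig2)), 1)
    pos <- matrix(0, n_frames, 2)
    for (k in seq_len(n_frames - 1)) {
      ev <- stats::rnorm(2, 0, sd_v)
      ex <- beta * ev + stats::rnorm(2, 0, sd_x_res)
      pos[k + 1, ] <- pos[k, ] + v * P * (1 - a) + ex
      v <- v * a + ev
    }
    out[[i]] <- data.frame(track_id = i, frame = seq_len(n_frames),
                           t_min = (seq_len(n_frames) - 1) * dt,
                           x_um = pos[, 1], y_um = pos[, 2])
  }
  res <- do.call(rbind, out)
  class(res) <- c("tracks", "data.frame")
  res
}

#' Read / write track tables
#'
#' CSV with columns track_id, frame, t_min, x_um, y_um.
#'
#' @param path CSV path.
#' @return A \code{tracks} data.frame.
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "t_min", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("read_tracks: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[order(df$track_id, df$t_min), need]
  rownames(df) <- NULL
  class(df) <- c("tracks", "data.frame")
  df
}

#' @rdname read_tracks
#' @param tracks a \code{tracks} data.frame.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Overlay all track starting points at the origin
#'
#' Translates every track so its first sample sits at (0, 0); times and step
#' vectors are unchanged.
#'
#' @param tracks a \code{tracks} data.frame.
#' @return The normalised \code{tracks}.
#' @export
normalize_tracks_to_origin <- function(tracks) {
  sp <- split(seq_len(nrow(tracks)), tracks$track_id)
  for (idx in sp) {
    first <- idx[which.min(tracks$t_min[idx])]
    tracks$x_um[idx] <- tracks$x_um[idx] - tracks$x_um[first]
    tracks$y_um[idx] <- tracks$y_um[idx] - tracks$y_um[first]
  }
  tracks
}

#' Per-track migration statistics
#'
#' Duration, start-to-end displacement, path length (sum of frame-to-frame
#' steps), speed and straightness. Two speed definitions are exposed:
#' \code{"path"} (path length / duration, the default) and
#' \code{"instantaneous"} (mean of step length / step duration).
#' Straightness = displacement / path length is flagged NA for stationary
#' tracks.
#'
#' @param tracks a \code{tracks} data.frame.
#' @param speed_mode \code{"path"} or \code{"instantaneous"}.
#' @return data.frame, one row per track: \code{track_id}, \code{n_samples},
#'   \code{duration_min}, \code{displacement_um}, \code{path_length_um},
#'   \code{speed_um_min}, \code{straightness}.
#' @export
track_statistics <- function(tracks, speed_mode = c("path", "instantaneous")) {
  speed_mode <- match.arg(speed_mode)
  one <- function(df) {
    df <- df[order(df$t_min), ]
    if (nrow(df) < 2) stop("track_statistics: track ", df$track_id[1],
                           " has fewer than 2 samples")
    duration <- df$t_min[nrow(df)] - df$t_min[1]
    if (duration <= 0) stop("track_statistics: track ", df$track_id[1],
                            " has zero duration")
    steps <- sqrt(diff(df$x_um)^2 + diff(df$y_um)^2)
    path_length <- sum(steps)
    displacement <- sqrt((df$x_um[nrow(df)] - df$x_um[1])^2 +
                           (df$y_um[nrow(df)] - df$y_um[1])^2)
    speed <- if (speed_mode == "path") path_length / duration
             else mean(steps / diff(df$t_min))
    straightness <- if (path_length > 0) displacement / path_length else NA_real_
    data.frame(track_id = df$track_id[1], n_samples = nrow(df),
               duration_min = duration, displacement_um = displacement,
               path_length_um = path_length, speed_um_min = speed,
               straightness = straightness)
  }
  res <- do.call(rbind, lapply(split(as.data.frame(tracks),
                                     tracks$track_id), one))
  rownames(res) <- NULL
  res
}

#' Ensemble mean squared displacement
#'
#' MSD(tau) averaged over all tracks and all overlapping ordered pairs at
#' each lag (ensemble-time average), for lags that are multiples of the
#' common frame interval. Tracks shorter than 3 samples are excluded with a
#' message. Non-uniform sampling raises an error (resample first).
#'
#' @param tracks a \code{tracks} data.frame.
#' @param max_lag maximum lag in minutes (default: half the longest track
#'   duration).
#' @return data.frame of class \code{"msd_curve"}: \code{lag_min},
#'   \code{msd_um2}, \code{n_pairs}; includes the lag-0 row (MSD = 0).
#' @export
msd <- function(tracks, max_lag = NULL) {
  sp <- split(as.data.frame(tracks), tracks$track_id)
  lens <- vapply(sp, nrow, 1L)
  short <- sum(lens < 3)
  if (short > 0) {
    message("msd: excluding ", short, " track(s) shorter than 3 samples")
    sp <- sp[lens >= 3]
  }
  if (!length(sp)) stop("msd: no usable tracks")
  dts <- unlist(lapply(sp, function(df) diff(sort(df$t_min))))
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-8 * max(dt, 1)))
    stop("msd: non-uniform frame interval; resample tracks to a common ",
         "interval first")
  if (is.null(max_lag))
    max_lag <- max(vapply(sp, function(df) max(df$t_min) - min(df$t_min), 1)) / 2
  max_m <- floor(max_lag / dt + 1e-9)
  ss <- numeric(max_m); np <- numeric(max_m)
  for (df in sp) {
    df <- df[order(df$t_min), ]
    x <- df$x_um; y <- df$y_um; n <- length(x)
    for (m in seq_len(min(max_m, n - 1))) {
      dx <- x[(1 + m):n] - x[1:(n - m)]
      dy <- y[(1 + m):n] - y[1:(n - m)]
      ss[m] <- ss[m] + sum(dx^2 + dy^2)
      np[m] <- np[m] + (n - m)
    }
  }
  keep <- np > 0
  res <- data.frame(lag_min = c(0, (seq_len(max_m) * dt)[keep]),
                    msd_um2 = c(0, (ss / pmax(np, 1))[keep]),
                    n_pairs = c(sum(lens[lens >= 3]), np[keep]))
  class(res) <- c("msd_curve", "data.frame")
  res
}

#' Fuerth mean squared displacement of a persistent random walk
#'
#' MSD(tau) = 2 S^2 P (tau - P (1 - exp(-tau / P))).
#'
#' @param lag lag times, min.
#' @param S speed scale, um/min.
#' @param P persistence time, min.
#' @return MSD values, um^2.
#' @export
furth_msd <- function(lag, S, P) 2 * S^2 * P * (lag - P * (1 - exp(-lag / P)))

# cap representing the ballistic limit in fit_furth output
FURTH_P_CAP <- 1e4

#' Fit the Fuerth persistent-random-walk form to an MSD curve
#'
#' Nonlinear least squares of MSD(tau) = 2 S^2 P (tau - P(1 - exp(-tau/P)))
#' over lags > 0. A persistence estimate at the documented upper bound
#' (1e4 min) is flagged: the curve is in the ballistic regime and P is not
#' identifiable.
#'
#' @param msd_curve data.frame with \code{lag_min} and \code{msd_um2}
#'   (e.g. from \code{\link{msd}}).
#' @param start optional named list with starting values \code{S}, \code{P}.
#' @return List: \code{S}, \code{P} (um/min, min), \code{residual} (RMS of
#'   fit residuals), \code{at_bound} flag, \code{fit} (the nls object).
#' @export
fit_furth <- function(msd_curve, start = NULL) {
  df <- msd_curve[msd_curve$lag_min > 0, , drop = FALSE]
  if (nrow(df) < 5) stop("fit_furth: need >= 5 positive lags")
  if (all(df$msd_um2 <= 0)) stop("fit_furth: MSD is nonpositive at all lags")
  if (is.null(start)) {
    # short-lag ballistic approximation for S, mid-range guess for P
    S0 <- sqrt(max(df$msd_um2[1], 1e-12)) / df$lag_min[1]
    start <- list(S = S0, P = max(df$lag_min) / 5)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(msd_um2 ~ 2 * S^2 * P * (lag_min - P * (1 - exp(-lag_min / P))),
                      data = df, start = start,
                      lower = c(S = 1e-9, P = 1e-3),
                      upper = c(S = Inf, P = FURTH_P_CAP),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit_furth: optimisation failed: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  list(S = unname(est["S"]), P = unname(est["P"]),
       residual = sqrt(mean(stats::resid(fit)^2)),
       at_bound = est["P"] >= 0.99 * FURTH_P_CAP, fit = fit)
}
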