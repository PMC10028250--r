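# --- stride segmentation: episodes, footfalls, cyclicality, filters -------

roll_mean <- function(x, k) {
  # centered rolling mean, shrinking window at the edges
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# per-frame lengths of every skeleton segment: matrix [frames x segments]
segment_length_frames <- function(traj) {
  seg <- skeleton_segments()
  out <- matrix(NA_real_, n_frames(traj), nrow(seg),
                dimnames = list(NULL, seg$segment))
  for (i in seq_len(nrow(seg))) {
    d <- traj$xy[, seg$from[i], , drop = FALSE] -
      traj$xy[, seg$to[i], , drop = FALSE]
    out[, i] <- sqrt(d[, 1, 1]^2 + d[, 1, 2]^2)
  }
  out
}

#' Find locomotion episodes
#'
#' Returns the maximal frame intervals in which (i) the rolling-mean
#' digitization likelihood of every landmark stays at or above
#' `likelihood_min`, (ii) no landmark jumps more than `noise_max` meters
#' between consecutive frames, and (iii) every skeleton-segment length
#' stays within a relative `bone_length_tolerance` of its episode median.
#' Frames failing any criterion split the surrounding episode.
#'
#' @param traj [landmark_trajectories()], calibrated.
#' @param likelihood_min rolling-mean likelihood threshold (default 0.9).
#' @param noise_max maximal frame-to-frame landmark displacement in meters
#'   (default 0.05, i.e. 2.5 m/s at 50 Hz).
#' @param bone_length_tolerance relative deviation of a segment length from
#'   its episode median before the frame is rejected (default 0.25).
#' @param likelihood_window rolling-mean window in frames (default 5).
#' @param min_frames shortest episode retained (default 10).
#' @return data.frame with columns `episode`, `start`, `end` (0-based,
#'   half-open `[start, end)`) and `mean_likelihood`.
#' @export
find_episodes <- function(traj, likelihood_min = 0.9, noise_max = 0.05,
                          bone_length_tolerance = 0.25,
                          likelihood_window = 5, min_frames = 10) {
  nfr <- n_frames(traj)
  lik_ok <- rep(TRUE, nfr)
  for (j in seq_len(dim(traj)[2])) {
    rm_ <- roll_mean(ifelse(is.na(traj$likelihood[, j]), 0,
                            traj$likelihood[, j]), likelihood_window)
    lik_ok <- lik_ok & rm_ >= likelihood_min
  }
  # frame-to-frame displacement: a frame is bad if the jump into it is large
  disp_ok <- rep(TRUE, nfr)
  if (nfr > 1) {
    d <- sqrt(apply((traj$xy[-1, , , drop = FALSE] -
                       traj$xy[-nfr, , , drop = FALSE])^2, c(1, 2), sum))
    jump <- apply(d, 1, max) > noise_max
    disp_ok[c(FALSE, jump)] <- FALSE      # arrival frame of a large jump
  }
  ok <- lik_ok & disp_ok
  runs <- ok_runs(ok, min_len = 2)
  # bone-length consistency within each candidate run, may split further
  seglen <- segment_length_frames(traj)
  out <- list()
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    med <- apply(seglen[idx, , drop = FALSE], 2, stats::median)
    dev <- sweep(abs(sweep(seglen[idx, , drop = FALSE], 2, med)), 2, med, "/")
    good <- apply(dev <= bone_length_tolerance, 1, all)
    sub <- ok_runs(good, min_len = min_frames)
    for (s in seq_len(nrow(sub)))
      out[[length(out) + 1]] <- c(idx[sub$start[s]], idx[sub$end[s]])
  }
  if (!length(out))
    return(data.frame(episode = integer(), start = integer(),
                      end = integer(), mean_likelihood = numeric()))
  m <- do.call(rbind, out)
  keep <- (m[, 2] - m[, 1] + 1) >= min_frames
  m <- m[keep, , drop = FALSE]
  ml <- vapply(seq_len(nrow(m)), function(i)
    mean(traj$likelihood[m[i, 1]:m[i, 2], ], na.rm = TRUE), numeric(1))
  data.frame(episode = seq_len(nrow(m)), start = m[, 1] - 1L,
             end = m[, 2], mean_likelihood = ml)  # 0-based half-open
}

# maximal runs of TRUE, 1-based inclusive indices
ok_runs <- function(ok, min_len = 1) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

hoof_speed <- function(traj, frames1, hoof) {
  # horizontal speed (m/s) from forward differences (displacement ahead
  # of each frame), so a stance onset is not blurred by the last swing
  # frame; backward difference at the final frame
  x <- traj$xy[frames1, hoof, 1]
  n <- length(x)
  v <- c(x[-1] - x[-n], x[n] - x[n - 1])
  abs(v) * traj$frame_rate
}

#' Detect footfalls of one hoof within an episode
#'
#' Kinematic ground-contact proxy: the hoof is in stance whenever its
#' horizontal speed drops below `v_stance_frac` times the episode-mean
#' withers speed for at least `min_stance` consecutive frames; the
#' touchdown is the first frame of each stance run, the liftoff the frame
#' after its last.
#'
#' @param traj [landmark_trajectories()].
#' @param episode one row of [find_episodes()] output (or a list with
#'   `start`, `end`).
#' @param hoof `"forehoof"` or `"hindhoof"`.
#' @param v_stance_frac stance threshold as a fraction of mean withers
#'   speed (default 0.1).
#' @param min_stance minimal stance duration in frames (default 3).
#' @return data.frame with 0-based columns `touchdown`, `liftoff`; zero
#'   rows when fewer than one stance phase is found.
#' @export
detect_footfalls <- function(traj, episode, hoof = "forehoof",
                             v_stance_frac = 0.1, min_stance = 3) {
  frames1 <- (episode$start + 1):episode$end   # 1-based
  v <- hoof_speed(traj, frames1, hoof)
  vref <- mean(hoof_speed(traj, frames1, "withers"))
  if (!is.finite(vref) || vref <= 0) vref <- mean(v)
  stance <- ok_runs(v < v_stance_frac * vref, min_len = min_stance)
  # a stance already in progress at the episode start has no observable
  # touchdown; drop it
  if (nrow(stance) && stance$start[1] == 1)
    stance <- stance[-1, , drop = FALSE]
  if (!nrow(stance))
    return(data.frame(touchdown = integer(), liftoff = integer()))
  data.frame(touchdown = frames1[stance$start] - 1L,
             liftoff = frames1[stance$end] - 1L + 1L)
}

#' Procrustes cyclicality of a stride
#'
#' Shape distance between the 17-landmark configurations at the first and
#' last frame of a stride after similarity (translation, rotation, scale)
#' superimposition; 0 means the posture at the end of the stride exactly
#' repeats the starting posture.
#'
#' @param traj [landmark_trajectories()].
#' @param start,end 0-based frames delimiting the stride (half-open: `end`
#'   is the touchdown frame beginning the next cycle).
#' @return non-negative Procrustes distance (square root of the symmetric
#'   Procrustes sum of squares).
#' @export
cyclicality <- function(traj, start, end) {
  a <- traj$xy[start + 1, , ]
  b <- traj$xy[end + 1, , ]
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite landmark configuration")
  css <- function(m) sqrt(sum(scale(m, scale = FALSE)^2))
  if (css(a) < 1e-12 || css(b) < 1e-12)
    stop("degenerate configuration: all landmarks coincident")
  pr <- vegan::procrustes(a, b, symmetric = TRUE)
  # residual-based distance: equals sqrt(pr$ss) but avoids the
  # catastrophic cancellation of the 1 - (sum sigma)^2 form near zero
  sqrt(sum((pr$X - pr$Yrot)^2))
}

#' Cut stride-cycle candidates from an episode
#'
#' A stride spans one full forelimb cycle: forehoof touchdown to the next
#' forehoof touchdown. The hindhoof touchdown falling inside the cycle is
#' attached for inter-limb timing.
#'
#' @param traj [landmark_trajectories()].
#' @param episode one row of [find_episodes()] output.
#' @param ... thresholds passed to [detect_footfalls()].
#' @return data.frame, one row per candidate, with 0-based frame columns
#'   `start`, `end`, `fore_touchdown`, `fore_liftoff`, `hind_touchdown`,
#'   `hind_liftoff` and `cyclicality`.
#' @export
cut_strides <- function(traj, episode, ...) {
  fore <- detect_footfalls(traj, episode, "forehoof", ...)
  hind <- detect_footfalls(traj, episode, "hindhoof", ...)
  if (nrow(fore) < 2)
    return(data.frame(start = integer(), end = integer(),
                      fore_touchdown = integer(), fore_liftoff = integer(),
                      hind_touchdown = integer(), hind_liftoff = integer(),
                      cyclicality = numeric()))
  out <- lapply(seq_len(nrow(fore) - 1), function(i) {
    t0 <- fore$touchdown[i]; t1 <- fore$touchdown[i + 1]
    hi <- which(hind$touchdown >= t0 & hind$touchdown < t1)
    data.frame(start = t0, end = t1,
               fore_touchdown = t0, fore_liftoff = fore$liftoff[i],
               hind_touchdown = if (length(hi)) hind$touchdown[hi[1]] else NA,
               hind_liftoff = if (length(hi)) hind$liftoff[hi[1]] else NA,
               cyclicality = cyclicality(traj, t0, t1))
  })
  do.call(rbind, out)
}

#' Default plausibility bounds for gait variables
#'
#' Half-open intervals outside which a stride is considered implausible
#' (digitization artifact rather than walking): dimensionless speed,
#' distance and frequency, fractional duty factors, clearances and
#' hindlimb phase. All bounds are configurable.
#'
#' @return named list of `c(lo, hi)` bounds.
#' @export
gait_variable_bounds <- function() {
  list(stride_distance = c(0, 4), stride_frequency = c(0.02, 3),
       speed = c(0, 3),
       duty_factor_fore = c(0, 1), duty_factor_hind = c(0, 1),
       clearance_fore = c(0, 1), clearance_hind = c(0, 1),
       hindlimb_phase = c(0, 1), head_angle = c(-pi, pi))
}

#' Apply plausibility filters to stride candidates
#'
#' Retains candidates whose gait variables all lie inside their configured
#' plausibility interval and whose Procrustes cyclicality is at most
#' `cyclicality_max`; the names of failed filters are recorded per stride.
#'
#' @param candidates data.frame from [cut_strides()] (any extra columns
#'   are kept).
#' @param gait data.frame of gait variables, same row order.
#' @param bounds named list of `c(lo, hi)` intervals, see
#'   [gait_variable_bounds()].
#' @param cyclicality_max maximal accepted cyclicality (default 0.1).
#' @return `candidates` with `gait` columns bound, plus `passed_filters`
#'   (logical) and `failed_filters` (comma-separated names, "" if none).
#' @export
filter_strides <- function(candidates, gait,
                           bounds = gait_variable_bounds(),
                           cyclicality_max = 0.1) {
  stopifnot(nrow(candidates) == nrow(gait))
  failed <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    f <- character()
    for (v in intersect(names(bounds), names(gait))) {
      val <- gait[[v]][i]
      if (!is.finite(val) || val < bounds[[v]][1] || val >= bounds[[v]][2])
        f <- c(f, v)
    }
    if (!is.finite(candidates$cyclicality[i]) ||
        candidates$cyclicality[i] > cyclicality_max)
      f <- c(f, "cyclicality")
    failed[i] <- paste(f, collapse = ",")
  }
  out <- cbind(candidates, gait[setdiff(names(gait), names(candidates))])
  out$passed_filters <- failed == ""
  out$failed_filters <- failed
  out
}

#' Segment a trajectory into quality-filtered strides
#'
#' Full segmentation stage: episode extraction, footfall detection, stride
#' cutting with cyclicality, gait-variable computation with dimensionless
#' conversion, and plausibility filtering.
#'
#' @param traj [landmark_trajectories()].
#' @param subject_id identifier copied into the output.
#' @param likelihood_min,noise_max,bone_length_tolerance see
#'   [find_episodes()].
#' @param v_stance_frac,min_stance see [detect_footfalls()].
#' @param bounds,cyclicality_max see [filter_strides()].
#' @return data.frame, one row per stride candidate, with episode and
#'   frame bookkeeping, gait variables (dimensionless where applicable)
#'   and filter verdicts.
#' @export
segment_strides <- function(traj, subject_id = "subj",
                            likelihood_min = 0.9, noise_max = 0.05,
                            bone_length_tolerance = 0.25,
                            v_stance_frac = 0.1, min_stance = 3,
                            bounds = gait_variable_bounds(),
                            cyclicality_max = 0.1) {
  eps <- find_episodes(traj, likelihood_min, noise_max,
                       bone_length_tolerance)
  out <- list()
  for (e in seq_len(nrow(eps))) {
    cand <- cut_strides(traj, eps[e, ], v_stance_frac = v_stance_frac,
                        min_stance = min_stance)
    if (!nrow(cand)) next
    gv <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      g <- gait_variables(traj, cand[i, ])
      dimensionless(g, stride_reference_length(traj, cand$start[i],
                                               cand$end[i]))
    }))
    res <- filter_strides(cand, gv, bounds, cyclicality_max)
    res <- cbind(episode = eps$episode[e], res)
    out[[length(out) + 1]] <- res
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  cbind(subject_id = subject_id, stride_id = paste0(subject_id, "_s",
                                                    seq_len(nrow(res))), res)
}
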