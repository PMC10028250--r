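# --- joint-angle profiles and spatiotemporal gait variables ---------------

#' Signed joint angle from three points
#'
#' Angle between the extension of the proximal->center segment and the
#' center->distal segment, in a right-handed frame: a straight joint
#' (collinear continuation) is 0, counter-clockwise angles are positive,
#' range `(-pi, pi]`.
#'
#' @param p_proximal,p_center,p_distal 2-vectors or `[n, 2]` matrices.
#' @return numeric angle(s) in radians.
#' @export
joint_angle <- function(p_proximal, p_center, p_distal) {
  as2 <- function(p) if (is.null(dim(p))) matrix(p, ncol = 2) else p
  a <- as2(p_proximal); b <- as2(p_center); c <- as2(p_distal)
  u <- b - a; v <- c - b
  if (any(rowSums(u^2) < 1e-20) || any(rowSums(v^2) < 1e-20))
    stop("coincident points: joint angle undefined")
  atan2(u[, 1] * v[, 2] - u[, 2] * v[, 1],
        u[, 1] * v[, 1] + u[, 2] * v[, 2])
}

# angle series for one joint definition row over 1-based frames
joint_angle_series <- function(traj, frames1, def_row) {
  joint_angle(traj$xy[frames1, def_row$proximal, ],
              traj$xy[frames1, def_row$center, ],
              traj$xy[frames1, def_row$distal, ])
}

unwrap <- function(a) {
  # remove +-2*pi discontinuities
  d <- diff(a)
  a + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Stride-average body reference length
#'
#' Cumulated distance of the landmarks along the snout-to-tailbase chain
#' (snout-eye-ear-withers-croup-tailbase), averaged over the stride; used
#' as the length scale for dimensionless conversion.
#'
#' @param traj [landmark_trajectories()].
#' @param start,end 0-based stride frames (half-open).
#' @return scalar length in meters.
#' @export
stride_reference_length <- function(traj, start, end) {
  frames1 <- (start + 1):end
  chain <- reference_chain()
  tot <- 0
  for (i in seq_len(length(chain) - 1)) {
    d <- traj$xy[frames1, chain[i + 1], , drop = FALSE] -
      traj$xy[frames1, chain[i], , drop = FALSE]
    tot <- tot + sqrt(d[, 1, 1]^2 + d[, 1, 2]^2)
  }
  mean(tot)
}

#' Extract joint-angle profiles of one stride
#'
#' Computes the six analysis joint angles plus the total-forelimb
#' reference angle per frame, unwraps them, and resamples each onto
#' `n_samples` uniform points of the cycle (phase 0 at the opening
#' forehoof touchdown, linear interpolation). Strides whose landmarks are
#' poorly digitized for more than `max_bad_fraction` of frames are
#' rejected.
#'
#' @param traj [landmark_trajectories()].
#' @param stride one row of [cut_strides()] / [segment_strides()] output
#'   (needs `start`, `end`; `stride_id`/`subject_id` copied if present).
#' @param n_samples samples per cycle (default 100).
#' @param likelihood_min frames with any relevant landmark below this are
#'   counted as badly digitized (default 0.9).
#' @param max_bad_fraction maximal tolerated fraction of bad frames
#'   (default 0.2).
#' @return object of class `stride_kinematics`: list with `angles`
#'   (matrix `n_samples x 7`, columns the analysis joints +
#'   `forelimb_total`, radians), `n_samples`, `reference_length` (m),
#'   `duration` (s), `stride_id`, `subject_id`.
#' @export
extract_profiles <- function(traj, stride, n_samples = 100,
                             likelihood_min = 0.9, max_bad_fraction = 0.2) {
  frames1 <- (stride$start + 1):stride$end
  defs <- joint_definitions()
  used <- unique(unlist(defs[, c("proximal", "center", "distal")]))
  lik <- traj$likelihood[frames1, used, drop = FALSE]
  if (mean(apply(lik < likelihood_min, 1, any)) > max_bad_fraction)
    stop("insufficient digitization: more than ",
         round(100 * max_bad_fraction), "% low-likelihood frames in stride")
  m <- length(frames1)                    # frames of the cycle (end open)
  phase_in <- (seq_len(m) - 1) / m
  phase_out <- (seq_len(n_samples) - 1) / n_samples
  ang <- matrix(NA_real_, n_samples, nrow(defs),
                dimnames = list(NULL, defs$joint))
  for (j in seq_len(nrow(defs))) {
    a <- unwrap(joint_angle_series(traj, frames1, defs[j, ]))
    # periodic linear interpolation: close the cycle with the first sample,
    # lifted to the branch the unwrapped series ended on
    wrap <- a[1] + 2 * pi * round((a[m] - a[1]) / (2 * pi))
    ang[, j] <- stats::approx(c(phase_in, 1), c(a, wrap),
                              xout = phase_out, method = "linear",
                              ties = "ordered")$y
  }
  structure(list(
    angles = ang, n_samples = n_samples,
    reference_length = stride_reference_length(traj, stride$start,
                                               stride$end),
    duration = m / traj$frame_rate,
    frame_rate = traj$frame_rate,
    stride_id = if (!is.null(stride$stride_id)) stride$stride_id else NA,
    subject_id = if (!is.null(stride$subject_id)) stride$subject_id else NA),
    class = "stride_kinematics")
}

#' @export
print.stride_kinematics <- function(x, ...) {
  cat(sprintf("<stride_kinematics: %d samples, ref length %.3f m>\n",
              x$n_samples, x$reference_length))
  invisible(x)
}

#' Spatiotemporal gait variables of one stride
#'
#' Stride distance (forehoof touchdown-to-touchdown advance), frequency
#' and speed; fore/hind duty factor (stance fraction of cycle time);
#' fore/hind clearance (1 - min/max of the trunk-to-hoof distance, a limb
#' flexion proxy; withers->forehoof and hip->hindhoof); stride-average
#' head (snout-ear) and torso (withers-croup) angles vs horizontal; and
#' hindlimb phase (fore-to-hind touchdown delay as cycle fraction).
#'
#' @param traj [landmark_trajectories()].
#' @param stride one row of [cut_strides()] output.
#' @return one-row data.frame of raw-unit gait variables.
#' @export
gait_variables <- function(traj, stride) {
  fr <- traj$frame_rate
  t0 <- stride$fore_touchdown; t1 <- stride$end
  if (t1 <= t0) stop("zero or negative stride duration")
  T_s <- (t1 - t0) / fr
  frames1 <- (t0 + 1):t1
  dist_m <- traj$xy[t1 + 1, "forehoof", 1] - traj$xy[t0 + 1, "forehoof", 1]
  lim_dist <- function(prox, hoof) {
    d <- traj$xy[frames1, hoof, , drop = FALSE] -
      traj$xy[frames1, prox, , drop = FALSE]
    sqrt(d[, 1, 1]^2 + d[, 1, 2]^2)
  }
  clearance <- function(d) 1 - min(d) / max(d)
  line_angle <- function(from, to) {
    v <- traj$xy[frames1, to, , drop = FALSE] -
      traj$xy[frames1, from, , drop = FALSE]
    mean(unwrap(atan2(v[, 1, 2], v[, 1, 1])))
  }
  df_fore <- (stride$fore_liftoff - t0) / (t1 - t0)
  df_hind <- if (is.finite(stride$hind_touchdown) &&
                 is.finite(stride$hind_liftoff))
    (stride$hind_liftoff - stride$hind_touchdown) / (t1 - t0) else NA_real_
  phase <- if (is.finite(stride$hind_touchdown))
    ((stride$hind_touchdown - t0) / (t1 - t0)) %% 1 else NA_real_
  data.frame(
    stride_distance = dist_m, stride_frequency = 1 / T_s,
    speed = dist_m / T_s,
    duty_factor_fore = df_fore, duty_factor_hind = df_hind,
    clearance_fore = clearance(lim_dist("withers", "forehoof")),
    clearance_hind = clearance(lim_dist("hip", "hindhoof")),
    head_angle = line_angle("ear", "snout"),
    torso_angle = line_angle("croup", "withers"),
    hindlimb_phase = phase)
}

#' Dimensionless conversion of gait variables
#'
#' Dynamic-similarity scaling with the body reference length `h`:
#' distance / h, frequency * sqrt(h / g), speed / sqrt(g * h). Fractions
#' and angles are unchanged. The identity speed = distance x frequency is
#' preserved by construction.
#'
#' @param gv one-row data.frame from [gait_variables()] (raw units).
#' @param reference_length body reference length h in meters, see
#'   [stride_reference_length()].
#' @param g gravitational acceleration (default 9.81 m/s^2).
#' @return `gv` with `stride_distance`, `stride_frequency` and `speed`
#'   replaced by their dimensionless values; raw values are kept in
#'   `*_raw` columns and `reference_length` is recorded.
#' @export
dimensionless <- function(gv, reference_length, g = 9.81) {
  h <- reference_length
  if (!is.finite(h) || h <= 0) stop("reference length must be positive")
  gv$stride_distance_raw <- gv$stride_distance
  gv$stride_frequency_raw <- gv$stride_frequency
  gv$speed_raw <- gv$speed
  gv$stride_distance <- gv$stride_distance / h
  gv$stride_frequency <- gv$stride_frequency * sqrt(h / g)
  gv$speed <- gv$speed / sqrt(g * h)
  gv$reference_length <- h
  gv
}

#' Names of the gait variables entering the subject models
#'
#' @return character vector of the 9 model gait variables.
#' @export
gait_variable_names <- function() {
  c("stride_distance", "stride_frequency", "speed",
    "duty_factor_fore", "duty_factor_hind",
    "clearance_fore", "clearance_hind", "head_angle", "hindlimb_phase")
}
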