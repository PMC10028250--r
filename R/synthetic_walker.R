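# --- planar walker: forward-kinematic landmark fixture --------------------
#
# A trunk translating at constant speed carries rigid head/back landmarks;
# each limb is a four-segment chain posed by two-link inverse kinematics
# between its trunk anchor and a prescribed hoof path (stance: fixed foot,
# swing: smoothstep advance). All segment lengths are exactly constant,
# every quantity is a function of the stride phase only, so strides are
# exactly cyclic and the touchdown frames are known by construction.

smoothstep <- function(u) 3 * u^2 - 2 * u^3

# default geometry, meters, scaled uniformly by `size`
walker_params <- function(size = 1, stride_frames = 25, n_strides = 6,
                          frame_rate = 50, duty = 0.6,
                          stride_length = 0.18, hind_phase = 0.52,
                          swing_height = 0.02) {
  list(size = size, stride_frames = stride_frames, n_strides = n_strides,
       frame_rate = frame_rate, duty = duty,
       stride_length = stride_length * size,
       hind_phase = hind_phase, swing_height = swing_height * size,
       withers_y = 0.205 * size, trunk_len = 0.17 * size,
       # rigid offsets from withers (head, scapula) and croup (tail, hip)
       off = lapply(list(
         ear = c(0.040, 0.050), eye = c(0.095, 0.060),
         snout = c(0.150, 0.045), scapula = c(0.010, -0.030),
         shoulder = c(0.035, -0.065),
         tailbase = c(-0.045, 0.005), hip = c(0.005, -0.030)),
         function(v) v * size),
       fore_links = c(0.060, 0.055, 0.045, 0.028) * size,
       hind_links = c(0.065, 0.060, 0.050, 0.030) * size,
       # prescribed joint bends (rad): mean + amplitude * sin(2*pi*s + psi)
       bend_elbow = c(0.35, 0.20, 0.8), bend_forefetlock = c(0.30, 0.15, 2.0),
       bend_stifle = c(0.40, 0.20, 1.2), bend_hindfetlock = c(0.35, 0.15, 2.6),
       hoof_y = 0.004 * size)
}

# hoof path as a function of global stride phase s (touchdowns at integers)
walker_hoof <- function(s, p, phase_offset = 0) {
  sp <- s - phase_offset
  k <- floor(sp)
  u <- sp - k
  swing <- u >= p$duty
  us <- (u - p$duty) / (1 - p$duty)
  x <- p$stride_length * (k + ifelse(swing, smoothstep(us), 0))
  y <- p$hoof_y + ifelse(swing, p$swing_height * sin(pi * us), 0)
  cbind(x = x, y = y)
}

bend_at <- function(spec, s) spec[1] + spec[2] * sin(2 * pi * s + spec[3])

# effective length of two links folded by bend angle b (b = 0: straight)
eff_len <- function(l1, l2, b) sqrt(l1^2 + l2^2 + 2 * l1 * l2 * cos(b))

# two-link IK: mid-joint position between anchors a and b with effective
# link lengths la, lb; `side` +1 bows the joint to the left of a->b
ik_mid <- function(a, b, la, lb, side = 1) {
  d <- b - a
  D <- sqrt(rowSums(d^2))
  reach <- pmin(D, la + lb - 1e-6)
  ax <- (la^2 - lb^2 + reach^2) / (2 * reach)
  h <- sqrt(pmax(la^2 - ax^2, 0))
  u <- d / D
  perp <- cbind(-u[, 2], u[, 1]) * side
  a + u * ax + perp * h
}

# insert the fold joint of a two-segment virtual link from a to b
fold_joint <- function(a, b, l1, l2, side = 1) {
  ik_mid(a, b, l1, l2, side)
}

# positions of all 17 landmarks at global stride phases s (vectorized)
walker_positions <- function(p, s) {
  n <- length(s)
  wx <- p$stride_length * s + 0.05   # withers advances one stride per cycle
  withers <- cbind(wx, rep(p$withers_y, n))
  croup <- cbind(wx - p$trunk_len, rep(p$withers_y - 0.01 * p$size, n))
  at <- function(base, off) sweep(base, 2, off, `+`)
  pos <- list(
    withers = withers, croup = croup,
    ear = at(withers, p$off$ear), eye = at(withers, p$off$eye),
    snout = at(withers, p$off$snout),
    scapula = at(withers, p$off$scapula),
    shoulder = at(withers, p$off$shoulder),
    tailbase = at(croup, p$off$tailbase), hip = at(croup, p$off$hip))
  # forelimb: shoulder -> elbow -> carpal -> forefetlock -> forehoof
  # feet are planted half a stance-advance ahead of the anchor so the
  # foot-to-anchor offset stays centered (reachable) through the cycle
  fh <- walker_hoof(s, p)
  fh[, 1] <- fh[, 1] + 0.05 + p$off$shoulder[1] +
    p$stride_length * p$duty / 2
  be <- bend_at(p$bend_elbow, s); bf <- bend_at(p$bend_forefetlock, s)
  la <- eff_len(p$fore_links[1], p$fore_links[2], be)
  lb <- eff_len(p$fore_links[3], p$fore_links[4], bf)
  carpal <- ik_mid(pos$shoulder, fh, la, lb, side = -1)
  elbow <- fold_joint(pos$shoulder, carpal, p$fore_links[1],
                      p$fore_links[2], side = 1)
  forefetlock <- fold_joint(carpal, fh, p$fore_links[3],
                            p$fore_links[4], side = 1)
  # hindlimb: hip -> stifle -> tarsal -> hindfetlock -> hindhoof
  hh <- walker_hoof(s, p, p$hind_phase)
  hh[, 1] <- hh[, 1] + 0.05 - p$trunk_len + p$off$hip[1] +
    p$stride_length * (p$hind_phase + p$duty / 2)
  bs <- bend_at(p$bend_stifle, s); bh <- bend_at(p$bend_hindfetlock, s)
  la2 <- eff_len(p$hind_links[1], p$hind_links[2], bs)
  lb2 <- eff_len(p$hind_links[3], p$hind_links[4], bh)
  tarsal <- ik_mid(pos$hip, hh, la2, lb2, side = 1)
  stifle <- fold_joint(pos$hip, tarsal, p$hind_links[1],
                       p$hind_links[2], side = -1)
  hindfetlock <- fold_joint(tarsal, hh, p$hind_links[3],
                            p$hind_links[4], side = -1)
  c(pos, list(elbow = elbow, carpal = carpal, forefetlock = forefetlock,
              forehoof = fh, stifle = stifle, tarsal = tarsal,
              hindfetlock = hindfetlock, hindhoof = hh))
}

# internal signed angle (generator-side ground truth, kept separate from
# the analysis implementation)
walker_angle <- function(a, b, c) {
  u <- b - a; v <- c - b
  atan2(u[, 1] * v[, 2] - u[, 2] * v[, 1],
        u[, 1] * v[, 1] + u[, 2] * v[, 2])
}

#' True joint-angle profiles of the walker at arbitrary phases
#'
#' @param walker [generate_walker()] output (or its `params`).
#' @param s numeric vector of global stride phases (1 = one full cycle).
#' @return matrix `length(s) x 7` of angles (analysis joints +
#'   `forelimb_total`), radians.
#' @export
walker_angles <- function(walker, s) {
  p <- if (!is.null(walker$params)) walker$params else walker
  pos <- walker_positions(p, s)
  defs <- joint_definitions()
  out <- sapply(seq_len(nrow(defs)), function(j)
    walker_angle(pos[[defs$proximal[j]]], pos[[defs$center[j]]],
                 pos[[defs$distal[j]]]))
  colnames(out) <- defs$joint
  out
}

#' Generate a synthetic planar walker
#'
#' Forward-kinematic fixture for the landmark-to-kinematics pipeline: a
#' walking quadruped with exactly constant bone lengths, exactly cyclic
#' strides and construction-known touchdown frames. Digitization
#' likelihood is 1.0 unless degraded.
#'
#' @param size uniform geometric scale factor (default 1).
#' @param n_strides full stride cycles (default 6).
#' @param stride_frames frames per stride cycle (default 25, i.e. 2 Hz at
#'   50 fps).
#' @param frame_rate Hz (default 50).
#' @param duty stance fraction of the cycle (default 0.6).
#' @param noise_sd Gaussian position noise added to every landmark, in
#'   meters (default 0: noiseless).
#' @param seed RNG seed, used only when `noise_sd > 0`.
#' @param ... further arguments to the internal geometry (stride_length,
#'   hind_phase, swing_height, ...).
#' @return list of class `synthetic_walker`: `traj`
#'   ([landmark_trajectories()]), `touchdowns_fore`, `touchdowns_hind`
#'   (0-based frames), `params`.
#' @export
generate_walker <- function(size = 1, n_strides = 6, stride_frames = 25,
                            frame_rate = 50, duty = 0.6, noise_sd = 0,
                            seed = 1, ...) {
  p <- walker_params(size = size, stride_frames = stride_frames,
                     n_strides = n_strides, frame_rate = frame_rate,
                     duty = duty, ...)
  # lead-in (part of the first swing) so that no touchdown coincides with
  # the episode start, plus a stance tail after the last touchdown
  lead_in <- round(0.2 * stride_frames)
  n_extra <- ceiling(duty * stride_frames) - 1
  nfr <- n_strides * stride_frames + lead_in + n_extra + 1
  s <- (seq_len(nfr) - 1 - lead_in) / stride_frames
  pos <- walker_positions(p, s)
  nms <- landmark_names()
  xy <- array(NA_real_, c(nfr, length(nms), 2),
              dimnames = list(NULL, nms, c("x", "y")))
  for (nm in nms) xy[, nm, ] <- pos[[nm]]
  if (noise_sd > 0)
    xy <- xy + with_seed(seed, array(stats::rnorm(length(xy), 0, noise_sd),
                                     dim(xy)))
  traj <- landmark_trajectories(xy, matrix(1, nfr, length(nms)),
                                frame_rate)
  td_f <- lead_in + (0:n_strides) * stride_frames
  td_h <- lead_in + round(p$hind_phase * stride_frames) +
    (0:(n_strides - 1)) * stride_frames
  structure(list(traj = traj, touchdowns_fore = td_f,
                 touchdowns_hind = td_h[td_h < nfr - 1],
                 lead_in = lead_in, params = p),
            class = "synthetic_walker")
}

#' @export
print.synthetic_walker <- function(x, ...) {
  cat(sprintf("<synthetic_walker: %d strides of %d frames, size %.2f>\n",
              x$params$n_strides, x$params$stride_frames, x$params$size))
  invisible(x)
}

#' Write landmark tables for a cohort of walkers
#'
#' Generates one planar walker per subject (geometry scaled with the
#' subject's size score) and writes each trajectory in the tracker CSV
#' dialect, so the full pipeline can be exercised from files.
#'
#' @param cohort [generate_cohort()] output.
#' @param dir output directory (created if needed); NULL returns walkers
#'   without writing.
#' @param subjects optional subset of subject ids.
#' @param n_strides strides per trajectory (default 6).
#' @return named list of `synthetic_walker` objects (invisibly if `dir`
#'   given).
#' @export
generate_landmarks <- function(cohort, dir = NULL, subjects = NULL,
                               n_strides = 6) {
  sub <- cohort$subjects
  if (!is.null(subjects)) sub <- sub[sub$subject_id %in% subjects, ]
  walkers <- lapply(seq_len(nrow(sub)), function(i) {
    generate_walker(size = exp(0.1 * sub$size[i]), n_strides = n_strides)
  })
  names(walkers) <- sub$subject_id
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(walkers))
      write_landmark_table(walkers[[id]]$traj,
                           file.path(dir, paste0(id, ".csv")))
    return(invisible(walkers))
  }
  walkers
}
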