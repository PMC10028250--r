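#' Landmark trajectory container
#'
#' Holds calibrated 2-D trajectories of the 17 canonical landmarks in a
#' right-handed frame (x rightward along the runway, y up), together with
#' the per-frame digitization likelihood reported by the tracking network.
#'
#' @param xy numeric array `[n_frames, n_landmarks, 2]`; third dimension
#'   is `c("x", "y")`, units meters (or pixels if uncalibrated).
#' @param likelihood numeric matrix `[n_frames, n_landmarks]` in `[0, 1]`.
#' @param frame_rate sampling rate in Hz.
#' @return object of class `landmark_trajectories` with elements `xy`,
#'   `likelihood`, `frame_rate`, `time` (seconds, 0-based frames / rate).
#' @export
landmark_trajectories <- function(xy, likelihood, frame_rate) {
  stopifnot(length(dim(xy)) == 3, dim(xy)[3] == 2)
  nms <- dimnames(xy)[[2]]
  if (is.null(nms)) stop("landmark dimension must be named")
  if (is.null(dim(likelihood)))
    likelihood <- matrix(likelihood, nrow = dim(xy)[1], ncol = dim(xy)[2])
  stopifnot(all(dim(likelihood) == dim(xy)[1:2]))
  bad <- likelihood[is.finite(likelihood)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 1))
    stop("likelihood values must lie in [0, 1]")
  dimnames(xy)[[3]] <- c("x", "y")
  colnames(likelihood) <- nms
  structure(list(
    xy = xy, likelihood = likelihood, frame_rate = frame_rate,
    time = (seq_len(dim(xy)[1]) - 1) / frame_rate,
    landmark_names = nms), class = "landmark_trajectories")
}

#' @export
print.landmark_trajectories <- function(x, ...) {
  cat(sprintf("<landmark_trajectories: %d frames, %d landmarks, %g Hz>\n",
              dim(x$xy)[1], dim(x$xy)[2], x$frame_rate))
  invisible(x)
}

#' @export
dim.landmark_trajectories <- function(x) dim(x$xy)[1:2]

n_frames <- function(traj) dim(traj$xy)[1]

#' Read a pose-estimation landmark table
#'
#' Parses the three-header-row CSV dialect written by DeepLabCut-style
#' trackers (rows: scorer / bodyparts / coords, with coords x, y,
#' likelihood per bodypart; first data column is the frame index).
#' Pixel coordinates are multiplied by `scale`; the image y axis (which
#' grows downward) is flipped so that up is positive and counter-clockwise
#' angles are positive downstream.
#'
#' @param path CSV file path.
#' @param frame_rate recording rate in Hz (default 50).
#' @param scale calibration factor in meters per pixel (default 1 leaves
#'   pixel units).
#' @param flip_y flip the image y axis (default TRUE).
#' @return [landmark_trajectories()] with all 17 canonical landmarks.
#' @export
read_landmark_table <- function(path, frame_rate = 50, scale = 1,
                                flip_y = TRUE) {
  head3 <- utils::read.csv(path, header = FALSE, nrows = 3,
                           colClasses = "character")
  if (tolower(head3[1, 1]) != "scorer" || tolower(head3[2, 1]) != "bodyparts" ||
      tolower(head3[3, 1]) != "coords")
    stop("malformed header: expected scorer / bodyparts / coords rows")
  parts <- as.character(unlist(head3[2, -1]))
  coords <- tolower(as.character(unlist(head3[3, -1])))
  if (!all(coords %in% c("x", "y", "likelihood")))
    stop("malformed header: coords must be x, y or likelihood")
  canon <- landmark_names()
  missing <- setdiff(canon, unique(parts))
  if (length(missing))
    stop("missing required landmark(s): ", paste(missing, collapse = ", "))
  dat <- utils::read.csv(path, header = FALSE, skip = 3)
  nfr <- nrow(dat)
  xy <- array(NA_real_, c(nfr, length(canon), 2),
              dimnames = list(NULL, canon, c("x", "y")))
  lik <- matrix(NA_real_, nfr, length(canon), dimnames = list(NULL, canon))
  for (j in seq_along(canon)) {
    ix <- which(parts == canon[j] & coords == "x")[1] + 1
    iy <- which(parts == canon[j] & coords == "y")[1] + 1
    il <- which(parts == canon[j] & coords == "likelihood")[1] + 1
    xy[, j, 1] <- dat[[ix]] * scale
    xy[, j, 2] <- (if (flip_y) -dat[[iy]] else dat[[iy]]) * scale
    lik[, j] <- if (is.na(il)) 1 else dat[[il]]
  }
  landmark_trajectories(xy, lik, frame_rate)
}

#' Write landmark trajectories in the tracker CSV dialect
#'
#' Inverse of [read_landmark_table()]: emits the three-header-row format
#' (image convention, y growing downward) so generated fixtures are read
#' back through the same code path as real tracker output.
#'
#' @param traj [landmark_trajectories()].
#' @param path output CSV path.
#' @param scorer value for the scorer header row.
#' @param scale meters per pixel used on read; coordinates are divided by
#'   it on write.
#' @export
write_landmark_table <- function(traj, path, scorer = "synthetic",
                                 scale = 1) {
  nms <- traj$landmark_names
  cols <- list(frame = seq_len(n_frames(traj)) - 1L)
  hdr_parts <- "bodyparts"; hdr_coords <- "coords"; hdr_scorer <- "scorer"
  for (j in seq_along(nms)) {
    cols[[paste0(nms[j], "_x")]] <- traj$xy[, j, 1] / scale
    cols[[paste0(nms[j], "_y")]] <- -traj$xy[, j, 2] / scale
    cols[[paste0(nms[j], "_l")]] <- traj$likelihood[, j]
    hdr_parts <- c(hdr_parts, rep(nms[j], 3))
    hdr_coords <- c(hdr_coords, "x", "y", "likelihood")
    hdr_scorer <- c(hdr_scorer, rep(scorer, 3))
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(hdr_scorer, collapse = ","), con)
  writeLines(paste(hdr_parts, collapse = ","), con)
  writeLines(paste(hdr_coords, collapse = ","), con)
  utils::write.table(as.data.frame(cols), con, sep = ",", col.names = FALSE,
                     row.names = FALSE)
}

#' Tidy long-format export of landmark trajectories
#'
#' @param traj [landmark_trajectories()].
#' @return data.frame with columns frame, time, landmark, x, y, likelihood.
#' @export
landmark_long <- function(traj) {
  nms <- traj$landmark_names
  nfr <- n_frames(traj)
  data.frame(
    frame = rep(seq_len(nfr) - 1L, times = length(nms)),
    time = rep(traj$time, times = length(nms)),
    landmark = rep(nms, each = nfr),
    x = as.vector(traj$xy[, , 1]),
    y = as.vector(traj$xy[, , 2]),
    likelihood = as.vector(traj$likelihood))
}

#' Mirror trajectories horizontally
#'
#' Reflects all x coordinates about the midrange of the observed x values,
#' so that leftward locomotion can be analyzed as if it were rightward
#' (the convention all angle definitions assume). Applying the operation
#' twice restores the input exactly, and all inter-landmark distances are
#' preserved.
#'
#' @param traj [landmark_trajectories()].
#' @return mirrored [landmark_trajectories()].
#' @export
mirror_horizontal <- function(traj) {
  xs <- traj$xy[, , 1]
  m <- max(xs, na.rm = TRUE) + min(xs, na.rm = TRUE)
  out <- traj
  out$xy[, , 1] <- m - xs
  out
}
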