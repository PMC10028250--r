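test_that("a noiseless walker yields one episode covering all frames", {
  w <- fixture_walker()
  ep <- find_episodes(w$traj)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, 0)
  expect_equal(ep$end, dim(w$traj)[1])
  expect_equal(ep$mean_likelihood, 1)
})

test_that("low-likelihood windows are excluded from episodes", {
  w <- generate_walker(n_strides = 6)
  tr <- w$traj
  tr$likelihood[41:60, "elbow"] <- 0       # frames 40..59 (0-based)
  ep <- find_episodes(tr)
  expect_true(nrow(ep) >= 2)
  for (i in seq_len(nrow(ep)))
    expect_true(ep$end[i] <= 40 || ep$start[i] >= 60)
})

test_that("a bone-length spike splits the episode at that frame", {
  w <- generate_walker(n_strides = 6)
  tr <- w$traj
  k <- 80                                   # 0-based spike frame
  tr$xy[k + 1, "elbow", ] <- tr$xy[k + 1, "elbow", ] * 10
  ep <- find_episodes(tr)
  expect_true(nrow(ep) >= 2)
  for (i in seq_len(nrow(ep)))
    expect_false(ep$start[i] <= k && k < ep$end[i])
})

test_that("footfalls are read off stance plateaus of the hoof speed", {
  # square-wave-velocity hoof: stance (v = 0) and swing (v > 0) phases
  nfr <- 120
  xy <- array(0, c(nfr, 17, 2), dimnames = list(NULL, landmark_names(),
                                                c("x", "y")))
  stance <- rep(c(rep(TRUE, 15), rep(FALSE, 15)), 4)
  x <- cumsum(ifelse(stance, 0, 0.02))
  for (nm in landmark_names()) xy[, nm, 1] <- x
  xy[, "withers", 1] <- seq(0, by = 0.01, length.out = nfr)
  xy[, "withers", 2] <- 0.2
  traj <- landmark_trajectories(xy, matrix(1, nfr, 17), 50)
  ep <- data.frame(start = 0, end = nfr)
  ff <- detect_footfalls(traj, ep, "forehoof")
  # first plateau is truncated at the episode start and dropped; the
  # position plateau of each later stance begins one sample before the
  # stance flag (the last swing displacement lands on its first frame)
  expect_equal(ff$touchdown, c(29, 59, 89))
})

test_that("a hoof that never stops yields no touchdowns", {
  nfr <- 100
  xy <- array(0, c(nfr, 17, 2), dimnames = list(NULL, landmark_names(),
                                                c("x", "y")))
  for (nm in landmark_names()) xy[, nm, 1] <- seq_len(nfr) * 0.01
  traj <- landmark_trajectories(xy, matrix(1, nfr, 17), 50)
  ff <- detect_footfalls(traj, data.frame(start = 0, end = nfr),
                         "forehoof")
  expect_equal(nrow(ff), 0)
})

test_that("stance plateaus shorter than min_stance are rejected", {
  nfr <- 60
  xy <- array(0, c(nfr, 17, 2), dimnames = list(NULL, landmark_names(),
                                                c("x", "y")))
  v <- rep(0.02, nfr); v[c(20, 21)] <- 0   # 2-frame pause only
  for (nm in landmark_names()) xy[, nm, 1] <- cumsum(v)
  xy[, "withers", 1] <- seq_len(nfr) * 0.01
  traj <- landmark_trajectories(xy, matrix(1, nfr, 17), 50)
  ff <- detect_footfalls(traj, data.frame(start = 0, end = nfr),
                         "forehoof", min_stance = 3)
  expect_equal(nrow(ff), 0)
})

test_that("cyclicality vanishes under similarity transforms of the end pose", {
  w <- fixture_walker()
  tr <- w$traj
  a <- tr$xy[11, , ]
  # end = start translated
  tr2 <- tr; tr2$xy[51, , ] <- sweep(a, 2, c(0.5, 0.1), `+`)
  expect_lt(cyclicality(tr2, 10, 50), 1e-10)
  # end = start rotated 10 deg and scaled x1.1
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  tr3 <- tr; tr3$xy[51, , ] <- 1.1 * a %*% R
  expect_lt(cyclicality(tr3, 10, 50), 1e-10)
})

test_that("cyclicality grows monotonically with a landmark displacement", {
  w <- fixture_walker()
  tr <- w$traj
  a <- tr$xy[11, , ]
  d <- vapply(c(0.005, 0.02, 0.05), function(shift) {
    tr2 <- tr
    tr2$xy[51, , ] <- a
    tr2$xy[51, "snout", 1] <- a["snout", 1] + shift
    cyclicality(tr2, 10, 50)
  }, numeric(1))
  expect_true(all(d > 0))
  expect_true(all(diff(d) > 0))
})

test_that("cyclicality is invariant to random similarity transforms", {
  w <- fixture_walker()
  tr <- w$traj
  base <- cyclicality(tr, 10, 60)
  set.seed(7)
  for (i in 1:5) {
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.3, 3)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr2 <- tr
    tr2$xy[61, , ] <- sweep(s * tr$xy[61, , ] %*% R, 2,
                            runif(2, -1, 1), `+`)
    expect_equal(cyclicality(tr2, 10, 60), base, tolerance = 1e-8)
  }
})

test_that("degenerate configurations are rejected", {
  w <- fixture_walker()
  tr <- w$traj
  tr$xy[11, , 1] <- 0.3; tr$xy[11, , 2] <- 0.1   # all coincident
  expect_error(cyclicality(tr, 10, 50), "degenerate")
})

test_that("plausibility filters name the violated variable", {
  cand <- data.frame(start = c(0, 0, 0), end = c(25, 25, 25),
                     cyclicality = c(0, 0, 0.5))
  gait <- data.frame(duty_factor_fore = c(0.6, 1.2, 0.6),
                     speed = c(0.5, 0.5, 0.5))
  out <- filter_strides(cand, gait)
  expect_equal(out$passed_filters, c(TRUE, FALSE, FALSE))
  expect_match(out$failed_filters[2], "duty_factor_fore")
  expect_match(out$failed_filters[3], "cyclicality")
})

test_that("out-of-bound strides are counted out, the rest retained", {
  n <- 10
  cand <- data.frame(start = seq_len(n), end = seq_len(n) + 25,
                     cyclicality = rep(0, n))
  gait <- data.frame(speed = rep(0.5, n))
  gait$speed[c(2, 5, 9)] <- 4.2            # outside (0, 3)
  out <- filter_strides(cand, gait)
  expect_equal(sum(out$passed_filters), 7)
  expect_true(all(grepl("speed", out$failed_filters[c(2, 5, 9)])))
})

test_that("segmentation recovers the generator's touchdowns within one frame", {
  w <- fixture_walker()
  ep <- find_episodes(w$traj)
  ff <- detect_footfalls(w$traj, ep[1, ], "forehoof")
  fh <- detect_footfalls(w$traj, ep[1, ], "hindhoof")
  expect_equal(length(ff$touchdown), length(w$touchdowns_fore))
  expect_true(all(abs(ff$touchdown - w$touchdowns_fore) <= 1))
  expect_true(all(abs(fh$touchdown - w$touchdowns_hind) <= 1))
})

test_that("retained strides are cyclic, full forelimb cycles", {
  st <- fixture_strides()
  expect_true(all(st$passed_filters))
  expect_true(all(st$cyclicality <= 0.1))
  expect_true(all(st$end - st$start > 0))
  expect_equal(st$start, st$fore_touchdown)
})
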