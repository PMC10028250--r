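test_that("decomposition matches the direct numerical-integration oracle", {
  t <- phase_grid(100)
  x <- 0.7 + 0.5 * cos(2 * pi * (t - 0.31)) - 0.2 * sin(2 * pi * 3 * t)
  co <- fourier_decompose(x)
  for (n in 0:8)
    expect_equal(unclass(co)[n + 1], oracle_coef(x, n), tolerance = 1e-12)
  # worked cases forced by the convention
  expect_equal(unclass(fourier_decompose(rep(0.4, 64)))[1], 0.4 + 0i)
  expect_lt(max(Mod(fourier_decompose(rep(0.4, 64))[-1])), 1e-14)
  c1 <- unclass(fourier_decompose(cos(2 * pi * t)))[2]
  expect_equal(c1, 0.5 + 0i, tolerance = 1e-12)
})

test_that("too few samples for the harmonic count is an error", {
  expect_error(fourier_decompose(rnorm(16), n_harmonics = 8), "samples")
})

test_that("band-limited signals round-trip exactly; Parseval holds", {
  set.seed(5)
  for (i in 1:10) {
    cre <- complex(real = rnorm(8, 0, 0.3), imaginary = rnorm(8, 0, 0.3))
    co <- structure(c(rnorm(1) + 0i, cre), class = "fourier_coef")
    x <- fourier_reconstruct(co, 100)
    rt <- fourier_reconstruct(fourier_decompose(x), 100)
    expect_lt(max(abs(rt - x)), 1e-10)
    expect_equal(mean((x - mean(x))^2), 2 * sum(Mod(cre)^2),
                 tolerance = 1e-10)
  }
})

test_that("reconstruction basics: zero and constant coefficients", {
  z <- structure(rep(0 + 0i, 9), class = "fourier_coef")
  expect_equal(fourier_reconstruct(z, 50), rep(0, 50))
  z[1] <- 1 + 0i
  expect_equal(fourier_reconstruct(z, 50), rep(1, 50))
})

test_that("affine components of a + b*cos(2*pi*(t - phi)) are (a, b/2, phi)", {
  t <- phase_grid(100)
  a <- 0.9; b <- 0.6; phi <- 0.23
  joints <- c(analysis_joints(), "forelimb_total")
  prof <- matrix(a + b * cos(2 * pi * (t - phi)), 100, 7,
                 dimnames = list(NULL, joints))
  ea <- extract_affine(stride_fourier(prof))
  expect_equal(ea$affine$mean, rep(a, 7), tolerance = 1e-10)
  expect_equal(ea$affine$amplitude, rep(b / 2, 7), tolerance = 1e-10)
  expect_equal(ea$affine$phase, rep(phi, 7), tolerance = 1e-10)
})

test_that("extract_affine on an already-normalized stride is the identity", {
  coh <- generate_cohort(generator_config(n_subjects = 4), seed = 3,
                         include_profiles = TRUE)
  co <- coh$profiles[[1]]
  norm1 <- extract_affine(co)$coef
  norm2 <- extract_affine(norm1)$coef
  expect_equal(norm2, norm1, tolerance = 1e-10)
})

test_that("a time-shifted stride has identical normalized rep, shifted phase", {
  coh <- generate_cohort(generator_config(n_subjects = 4), seed = 3,
                         include_profiles = TRUE)
  co <- coh$profiles[[1]]
  co_shift <- co
  for (j in seq_len(ncol(co)))
    co_shift[, j] <- co[, j] * exp(-2i * pi * (0:8) * 0.3)
  ea <- extract_affine(co); eas <- extract_affine(co_shift)
  expect_equal(eas$coef, ea$coef, tolerance = 1e-10)
  expect_equal((eas$reference_phase - ea$reference_phase) %% 1, 0.3,
               tolerance = 1e-10)
})

test_that("degenerate reference amplitude is a hard error", {
  joints <- c(analysis_joints(), "forelimb_total")
  prof <- matrix(sin(2 * pi * phase_grid(60)), 60, 7,
                 dimnames = list(NULL, joints))
  prof[, "forelimb_total"] <- 0.5            # flat reference
  expect_error(extract_affine(stride_fourier(prof)), "phase undefined")
})

test_that("alignment repairs destructive interference of antiphase cycles", {
  t <- phase_grid(100)
  joints <- c(analysis_joints(), "forelimb_total")
  mk <- function(shift) {
    prof <- matrix(sin(2 * pi * (t - shift)), 100, 7,
                   dimnames = list(NULL, joints))
    stride_fourier(prof)
  }
  s1 <- mk(0); s2 <- mk(0.5)
  naive <- (fourier_reconstruct(s1[, "stifle"], 100) +
              fourier_reconstruct(s2[, "stifle"], 100)) / 2
  expect_lt(peak_amplitude(naive), 1e-10)
  al <- align_cycles(list(s1, s2))
  aligned_mean <- (fourier_reconstruct(al$coefs[[1]][, "stifle"], 100) +
                     fourier_reconstruct(al$coefs[[2]][, "stifle"], 100)) / 2
  expect_equal(peak_amplitude(aligned_mean), 1, tolerance = 1e-6)
})

test_that("alignment preserves amplitude spectra and is idempotent", {
  coh <- generate_cohort(generator_config(n_subjects = 6), seed = 4,
                         include_profiles = TRUE)
  cos_ <- coh$profiles[1:5]
  al <- align_cycles(cos_)
  for (i in seq_along(al$coefs))
    expect_equal(Mod(al$coefs[[i]]), Mod(cos_[[i]]), tolerance = 1e-10)
  al2 <- align_cycles(al$coefs)
  for (i in seq_along(al$coefs))
    expect_equal(al2$coefs[[i]], al$coefs[[i]], tolerance = 1e-10)
  # single stride: alignment to its own phase is the identity
  al1 <- align_cycles(cos_[1])
  expect_equal(al1$coefs[[1]], cos_[[1]], tolerance = 1e-10)
})

test_that("coordination vector has 96 entries, invariant to affine maps", {
  coh <- generate_cohort(generator_config(n_subjects = 4), seed = 5,
                         include_profiles = TRUE)
  set.seed(17)
  for (co in coh$profiles[1:4]) {
    v0 <- coordination_residual(co)
    expect_length(v0, 96)
    co2 <- co
    for (j in seq_len(ncol(co2))) {          # per-joint offset and scale
      co2[1, j] <- co2[1, j] + runif(1, -1, 1)
      co2[, j] <- co2[, j] * runif(1, 0.3, 3)
    }
    dt <- runif(1)                           # whole-stride time shift
    for (j in seq_len(ncol(co2)))
      co2[, j] <- co2[, j] * exp(-2i * pi * (0:8) * dt)
    expect_lt(max(abs(coordination_residual(co2) - v0)), 1e-8)
  }
})

test_that("pure first harmonics in phase with the reference have zero Im", {
  t <- phase_grid(100)
  joints <- c(analysis_joints(), "forelimb_total")
  prof <- sapply(seq_len(7), function(j)
    j * 0.1 + j * 0.05 * cos(2 * pi * (t - 0.4)))
  colnames(prof) <- joints
  v <- coordination_residual(stride_fourier(prof))
  expect_lt(max(abs(v[grep("_im$", names(v))])), 1e-10)
  expect_equal(unname(v[grep("_h1_re$", names(v))]), rep(1, 6),
               tolerance = 1e-10)
})

test_that("degenerate joints contribute zeros and are flagged", {
  t <- phase_grid(100)
  joints <- c(analysis_joints(), "forelimb_total")
  prof <- matrix(0.3 + 0.2 * sin(2 * pi * t), 100, 7,
                 dimnames = list(NULL, joints))
  prof[, "elbow"] <- 0.5                     # frozen joint
  v <- coordination_residual(stride_fourier(prof))
  expect_true(all(v[grep("^elbow_", names(v))] == 0))
  expect_equal(attr(v, "degenerate"), "elbow")
})

test_that("phase-preserving averaging conserves the shared waveform", {
  t <- phase_grid(100)
  # two antiphase unit sines: naive mean cancels, aligned mean does not
  avg <- phase_preserving_average(list(sin(2 * pi * t),
                                       sin(2 * pi * (t - 0.5))))
  expect_equal(peak_amplitude(avg), 1, tolerance = 1e-6)
  # identical profiles average to themselves
  p <- 0.2 + 0.3 * cos(2 * pi * t) + 0.1 * sin(2 * pi * 2 * t)
  expect_equal(phase_preserving_average(list(p, p, p)), p,
               tolerance = 1e-10)
  # random-phase copies of one band-limited shape keep its amplitude
  set.seed(23)
  shape <- function(ph) 0.4 * cos(2 * pi * (t - ph)) +
    0.15 * cos(2 * pi * 2 * (t - ph))
  copies <- lapply(runif(8), shape)
  avg2 <- phase_preserving_average(copies)
  # grid peaks of the shifted copies differ at the sampling resolution
  expect_equal(peak_amplitude(avg2), peak_amplitude(shape(0)),
               tolerance = 1e-3)
  # mean angle is the arithmetic mean of the means
  copies3 <- list(1 + sin(2 * pi * t), 3 + sin(2 * pi * (t - 0.2)))
  expect_equal(mean(phase_preserving_average(copies3)), 2,
               tolerance = 1e-10)
})

test_that("degenerate amplitudes fall back to the arithmetic mean", {
  t <- phase_grid(60)
  expect_warning(
    avg <- phase_preserving_average(list(rep(0.5, 60), sin(2 * pi * t))),
    "degenerate")
  expect_equal(avg, (0.5 + sin(2 * pi * t)) / 2, tolerance = 1e-10)
})
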