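# --- Fourier Coefficient Affine Superimposition (FCAS) --------------------
#
# Convention (one-sided, used throughout and by all test oracles):
#   x(t) = c_0 + sum_{n=1..N} 2 * Re( c_n * exp(i * 2*pi * n * t) ),
# t in [0, 1).  c_0 is real and equals the temporal mean; a pure cosine
# a*cos(2*pi*(t - phi)) has c_1 = (a/2) * exp(-i*2*pi*phi).
#
# Affine components of a profile:
#   mean      = c_0
#   amplitude = sqrt( sum_{n>=1} |c_n|^2 )   (harmonic energy norm; equals
#               a/2 for a single harmonic of peak amplitude a)
#   phase     = -Arg(c_1) / (2*pi) mod 1 of the designated reference joint
# A whole-profile time shift t -> t - dt maps c_n -> c_n * exp(-i*2*pi*n*dt).

#' Fourier Series decomposition of a cyclic profile
#'
#' @param x numeric vector: one cycle, uniformly sampled (sample m+1 would
#'   wrap to sample 1).
#' @param n_harmonics number of harmonics N (default 8).
#' @return complex vector `c_0 .. c_N` (class `fourier_coef`).
#' @export
fourier_decompose <- function(x, n_harmonics = 8) {
  m <- length(x)
  if (m <= 2 * n_harmonics)
    stop("need more than ", 2 * n_harmonics, " samples for ",
         n_harmonics, " harmonics")
  f <- stats::fft(x) / m
  co <- f[seq_len(n_harmonics + 1)]
  co[1] <- complex(real = Re(co[1]), imaginary = 0)
  structure(co, class = "fourier_coef")
}

#' Evaluate a Fourier representation on a uniform grid
#'
#' @param coef complex vector `c_0 .. c_N` (or one column of a stride
#'   coefficient matrix).
#' @param n_samples samples of the reconstructed cycle.
#' @return numeric vector of length `n_samples`.
#' @export
fourier_reconstruct <- function(coef, n_samples = 100) {
  n <- length(coef) - 1
  t <- (seq_len(n_samples) - 1) / n_samples
  out <- rep(Re(coef[1]), n_samples)
  for (k in seq_len(n))
    out <- out + 2 * Re(coef[k + 1] * exp(2i * pi * k * t))
  out
}

coef_mean <- function(coef) Re(coef[1])
coef_amplitude <- function(coef) sqrt(sum(Mod(coef[-1])^2))
coef_phase <- function(coef) (-Arg(coef[2]) / (2 * pi)) %% 1

# rotate a coefficient vector by a time advance of `phi` cycles
# (c_n -> c_n * exp(+i*2*pi*n*phi) shifts the profile so that features at
# phase `phi` move to phase 0)
coef_rotate <- function(coef, phi) {
  n <- length(coef) - 1
  coef * exp(2i * pi * (0:n) * phi)
}

#' Decompose all joint-angle profiles of a stride
#'
#' @param kin [extract_profiles()] output, or a numeric matrix
#'   `samples x joints` with named columns.
#' @param n_harmonics harmonics per joint (default 8).
#' @return complex matrix `(n_harmonics + 1) x joints` of coefficients
#'   (class `stride_fourier`).
#' @export
stride_fourier <- function(kin, n_harmonics = 8) {
  ang <- if (inherits(kin, "stride_kinematics")) kin$angles else kin
  out <- vapply(seq_len(ncol(ang)),
                function(j) unclass(fourier_decompose(ang[, j],
                                                      n_harmonics)),
                complex(n_harmonics + 1))
  colnames(out) <- colnames(ang)
  structure(out, class = c("stride_fourier", "matrix"))
}

#' Extract affine components and the normalized representation
#'
#' Isolates per joint the mean angle (`c_0`), the amplitude (harmonic
#' energy norm) and the phase, and returns the coefficient matrix after
#' mean removal, per-joint amplitude normalization and a whole-stride
#' rotation that zeroes the phase of `reference_joint` (a single time
#' shift applied to every joint, preserving inter-joint phase relations).
#'
#' @param coefs `stride_fourier` coefficient matrix.
#' @param reference_joint column providing the stride phase (default
#'   `"forelimb_total"`).
#' @param eps amplitudes at or below this are treated as degenerate:
#'   such joints keep zero coefficients and are flagged (default 1e-6).
#' @return list with `affine` (data.frame joint / mean / amplitude /
#'   phase), `coef` (normalized complex matrix), `reference_phase`, and
#'   `degenerate` (character vector of flagged joints).
#' @export
extract_affine <- function(coefs, reference_joint = "forelimb_total",
                           eps = 1e-6) {
  stopifnot(reference_joint %in% colnames(coefs))
  amps <- apply(coefs, 2, coef_amplitude)
  if (amps[reference_joint] <= eps)
    stop("phase undefined: reference joint amplitude below eps")
  phi_ref <- coef_phase(coefs[, reference_joint])
  aff <- data.frame(joint = colnames(coefs),
                    mean = apply(coefs, 2, coef_mean),
                    amplitude = amps,
                    phase = apply(coefs, 2, function(co)
                      if (coef_amplitude(co) <= eps) NA_real_
                      else coef_phase(co)),
                    row.names = NULL)
  norm <- coefs
  degen <- character()
  for (j in seq_len(ncol(coefs))) {
    co <- coefs[, j]
    co[1] <- 0
    if (amps[j] <= eps) {
      norm[, j] <- 0
      degen <- c(degen, colnames(coefs)[j])
      next
    }
    co <- coef_rotate(co, phi_ref) / amps[j]
    norm[, j] <- co
  }
  list(affine = aff, coef = norm, reference_phase = phi_ref,
       degenerate = degen)
}

#' Temporally align a set of strides
#'
#' Rotates every stride (all joints by one common time shift) so that its
#' reference-joint phase equals the circular mean phase of the set;
#' amplitude spectra are untouched. Strides with a degenerate reference
#' are excluded with a warning.
#'
#' @param coef_list list of `stride_fourier` matrices.
#' @param reference_joint phase reference column (default
#'   `"forelimb_total"`).
#' @param eps degenerate-amplitude threshold.
#' @return list with `coefs` (aligned list), `phases` (original reference
#'   phases), `mean_phase`, and `excluded` (indices dropped).
#' @export
align_cycles <- function(coef_list, reference_joint = "forelimb_total",
                         eps = 1e-6) {
  phases <- vapply(coef_list, function(co) {
    if (coef_amplitude(co[, reference_joint]) <= eps) NA_real_
    else coef_phase(co[, reference_joint])
  }, numeric(1))
  excluded <- which(is.na(phases))
  if (length(excluded))
    warning("excluding ", length(excluded),
            " stride(s) with degenerate reference amplitude")
  ok <- setdiff(seq_along(coef_list), excluded)
  if (!length(ok)) stop("no stride with usable reference phase")
  mean_phase <- (Arg(sum(exp(2i * pi * phases[ok]))) / (2 * pi)) %% 1
  aligned <- lapply(ok, function(i) {
    shift <- phases[i] - mean_phase
    out <- coef_list[[i]]
    for (j in seq_len(ncol(out))) out[, j] <- coef_rotate(out[, j], shift)
    out
  })
  list(coefs = aligned, phases = phases, mean_phase = mean_phase,
       excluded = excluded)
}

#' Coordination vector of one stride
#'
#' The non-affine residual: real and imaginary parts of harmonics 1..N of
#' the six analysis joints after mean removal, per-joint amplitude
#' normalization and reference-phase alignment - 96 values for N = 8.
#' This vector is invariant under any per-joint offset, per-joint positive
#' scaling and whole-stride time shift of the input profiles.
#'
#' @param coefs `stride_fourier` matrix (must contain the six analysis
#'   joints and the reference joint).
#' @param reference_joint phase reference (default `"forelimb_total"`).
#' @param eps degenerate-amplitude threshold; degenerate joints contribute
#'   zeros.
#' @return named numeric vector of length `6 * N * 2` (attribute
#'   `degenerate` lists flagged joints).
#' @export
coordination_residual <- function(coefs, reference_joint = "forelimb_total",
                                  eps = 1e-6) {
  ea <- extract_affine(coefs, reference_joint, eps)
  joints <- analysis_joints()
  n <- nrow(coefs) - 1
  out <- numeric(0)
  nms <- character(0)
  for (j in joints) {
    co <- ea$coef[-1, j]
    pair <- as.vector(rbind(Re(co), Im(co)))
    out <- c(out, pair)
    nms <- c(nms, as.vector(rbind(paste0(j, "_h", 1:n, "_re"),
                                  paste0(j, "_h", 1:n, "_im"))))
  }
  names(out) <- nms
  attr(out, "degenerate") <- ea$degenerate
  out
}

#' Phase-preserving average of joint-angle profiles
#'
#' Averages a set of cyclic profiles of one joint in the frequency domain
#' after aligning their phases to the set's circular mean, then transforms
#' back to the time domain. Unlike the naive pointwise mean - which
#' attenuates or even cancels out-of-phase oscillations ("destructive
#' interference") - the result keeps the amplitude of the shared waveform
#' while mean angle and phase are averaged.
#'
#' @param profiles list of numeric vectors, or a matrix with one profile
#'   per column.
#' @param n_harmonics harmonics used (default 8).
#' @param n_samples samples of the returned average cycle (default length
#'   of the first profile).
#' @param eps profiles with amplitude at or below this cannot be aligned;
#'   if any occur the function falls back to the arithmetic mean with a
#'   warning.
#' @return numeric vector: the average profile.
#' @export
phase_preserving_average <- function(profiles, n_harmonics = 8,
                                     n_samples = NULL, eps = 1e-6) {
  if (is.matrix(profiles))
    profiles <- lapply(seq_len(ncol(profiles)), function(j) profiles[, j])
  stopifnot(length(profiles) >= 1)
  if (is.null(n_samples)) n_samples <- length(profiles[[1]])
  coefs <- lapply(profiles, fourier_decompose, n_harmonics = n_harmonics)
  amps <- vapply(coefs, coef_amplitude, numeric(1))
  if (any(amps <= eps)) {
    warning("degenerate amplitude(s): falling back to arithmetic mean")
    return(rowMeans(vapply(profiles, function(p)
      stats::approx(seq(0, 1, length.out = length(p) + 1)[-(length(p) + 1)],
                    p, xout = (seq_len(n_samples) - 1) / n_samples,
                    rule = 2)$y, numeric(n_samples))))
  }
  phases <- vapply(coefs, coef_phase, numeric(1))
  mean_phase <- (Arg(sum(exp(2i * pi * phases))) / (2 * pi)) %% 1
  aligned <- mapply(function(co, ph) coef_rotate(co, ph - mean_phase),
                    coefs, phases, SIMPLIFY = FALSE)
  avg <- Reduce(`+`, aligned) / length(aligned)
  fourier_reconstruct(avg, n_samples)
}
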