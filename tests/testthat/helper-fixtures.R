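# shared fixtures: all built in code at test time

phase_grid <- function(n) (seq_len(n) - 1) / n

with_seed_local <- function(seed, code) gaitscreen:::with_seed(seed, code)

peak_amplitude <- function(x) (max(x) - min(x)) / 2

# independent Fourier-coefficient oracle: direct numerical integration of
# the analysis convention, c_n = (1/m) * sum_j x_j exp(-i 2 pi n j / m)
oracle_coef <- function(x, n) {
  m <- length(x)
  j <- 0:(m - 1)
  sum(x * exp(-2i * pi * n * j / m)) / m
}

# a small default walker shared by segmentation/kinematics tests
fixture_walker <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- generate_walker()
    w
  }
})

# stride table of the fixture walker (segmented by the pipeline)
fixture_strides <- local({
  s <- NULL
  function() {
    if (is.null(s)) s <<- segment_strides(fixture_walker()$traj, "w")
    s
  }
})

# hand-made predictive-inference table: `shift` is the true offset of the
# predictive distribution (mean delta), `sd` its spread; per-stride
# summaries computed by brute force from explicit sample draws
fake_inferences <- function(subject_id, n_strides, shift, sd = 2,
                            actual = 5, n_samples = 2000, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    do.call(rbind, lapply(seq_len(n_strides), function(s) {
      draws <- actual + shift + rnorm(n_samples, 0, sd)
      data.frame(stride_id = paste0(subject_id, "_s", s),
                 subject_id = subject_id, outcome = "age",
                 actual = actual, pred_mean = mean(draws),
                 pred_sd = sd(draws),
                 delta_mean = mean(draws) - actual,
                 delta_sd = sd(draws),
                 frac_below = mean(draws < actual))
    }))
  })
}
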