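# --- probabilistic inverse model: subject characteristics ~ kinematics ----

#' Names of the dynamic-posture variables
#'
#' Mean joint angle and eROM amplitude for each of the six analysis
#' joints: 12 values.
#'
#' @return character vector of 12 names.
#' @export
posture_variable_names <- function() {
  c(paste0("mean_", analysis_joints()), paste0("erom_", analysis_joints()))
}

coordination_component_names <- function(k = 12) paste0("CC", seq_len(k))

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split a stride table into training, validation and test sets
#'
#' All low-birth-weight (LBW) strides form the out-of-sample test set; a
#' seeded random subset of NBW strides of (approximately) the same size
#' forms the validation set; the remaining NBW strides are the training
#' reference. The split is by stride, not by subject.
#'
#' @param rows stride feature table with a `birth_weight_category` column
#'   (`"LBW"` / `"NBW"`).
#' @param validation_fraction used only when no LBW rows exist: the NBW
#'   fraction assigned to validation (default 0.1).
#' @param seed RNG seed for the validation draw.
#' @return list with data.frames `train`, `validation`, `test`.
#' @export
split_dataset <- function(rows, validation_fraction = 0.1, seed = 1) {
  is_lbw <- rows$birth_weight_category == "LBW"
  test <- rows[is_lbw, , drop = FALSE]
  nbw_idx <- which(!is_lbw)
  n_val <- if (nrow(test) > 0) min(nrow(test), length(nbw_idx) - 1)
  else round(validation_fraction * length(nbw_idx))
  val_idx <- with_seed(seed, sample(nbw_idx, n_val))
  list(train = rows[setdiff(nbw_idx, val_idx), , drop = FALSE],
       validation = rows[sort(val_idx), , drop = FALSE],
       test = test)
}

#' Design of one subject-characteristic model
#'
#' The linear predictor comprises an intercept, the sex indicator
#' (male = 1), 9 gait variables, 12 dynamic-posture values and 12
#' coordination components - 34 slopes, which with intercept and residual
#' scale gives 36 free parameters. The outcome is modeled on a log scale
#' for mass (strictly positive, right-skewed) and untransformed for age
#' and size (size scores can be negative).
#'
#' @param outcome `"mass"`, `"size"` or `"age"` (or any column name).
#' @param transform `"identity"` or `"log"`; default `"log"` for mass,
#'   `"identity"` otherwise.
#' @param n_coordination number of coordination components (default 12).
#' @return object of class `model_design`.
#' @export
model_design <- function(outcome = c("mass", "size", "age"),
                         transform = NULL, n_coordination = 12) {
  outcome <- outcome[1]
  if (is.null(transform))
    transform <- if (outcome == "mass") "log" else "identity"
  transform <- match.arg(transform, c("identity", "log"))
  structure(list(
    outcome = outcome, transform = transform,
    predictors = c("sex_male", gait_variable_names(),
                   posture_variable_names(),
                   coordination_component_names(n_coordination))),
    class = "model_design")
}

#' @export
print.model_design <- function(x, ...) {
  cat(sprintf("<model_design: %s (%s), %d predictors>\n", x$outcome,
              x$transform, length(x$predictors)))
  invisible(x)
}

transform_outcome <- function(y, transform) {
  if (transform == "log") {
    if (any(y <= 0)) stop("log-transformed outcome must be positive")
    log(y)
  } else y
}

inv_transform_outcome <- function(y, transform)
  if (transform == "log") exp(y) else y

#' Assemble the probabilistic subject model
#'
#' Builds the robust linear regression of one subject characteristic on
#' sex, gait variables, dynamic posture and coordination. Predictors are
#' centered and scaled by the training mean and standard deviation; the
#' (possibly log-transformed) outcome likewise. On that scale the slope
#' priors are Normal(0, 2) - i.e. two observed standard deviations - the
#' intercept prior Normal(0, 2), the residual scale Half-Cauchy(1), and
#' the observation model a Student-t with Gamma(2, 0.1)-distributed
#' degrees of freedom.
#'
#' @param design [model_design()].
#' @param train training stride table containing all predictors and the
#'   outcome column.
#' @return object of class `subject_model` with the scaled design matrix,
#'   scalers and `n_parameters` (36 for the full design: intercept + 34
#'   slopes + residual scale).
#' @export
build_model <- function(design, train) {
  missing <- setdiff(c(design$predictors, design$outcome), names(train))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(train) < length(design$predictors) + 2)
    warning("fewer training rows (", nrow(train),
            ") than recommended for ", length(design$predictors) + 2,
            " free parameters")
  X <- as.matrix(train[, design$predictors, drop = FALSE])
  storage.mode(X) <- "double"
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("degenerate predictor(s) with zero variance: ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  x_center <- colMeans(X); x_scale <- sds
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)
  y <- transform_outcome(train[[design$outcome]], design$transform)
  y_center <- mean(y); y_scale <- stats::sd(y)
  if (y_scale == 0) stop("outcome has zero variance")
  structure(list(
    design = design, X = Xs, y = (y - y_center) / y_scale,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    n_train = nrow(Xs),
    n_parameters = ncol(Xs) + 2), class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model: %s, %d training strides, %d free parameters>\n",
              x$design$outcome, x$n_train, x$n_parameters))
  invisible(x)
}

# Student-t likelihood written as its exact scale-mixture-of-normals form
# so the conjugate block sampler can update all coefficients jointly
jags_model_code <- function() {
  "model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[i], tau * lam[i])
    lam[i] ~ dgamma(nu_half, nu_half)
    mu[i] <- alpha + inprod(X[i, ], beta)
  }
  alpha ~ dnorm(0, 0.25)
  for (k in 1:P) { beta[k] ~ dnorm(0, 0.25) }
  eps ~ dt(0, 1, 1) T(0,)
  tau <- 1 / (eps * eps)
  nu_half <- nu / 2
  nu ~ dgamma(2, 0.1)
}"
}

#' Sample the model posterior by MCMC
#'
#' Gradient-free Gibbs-type MCMC via JAGS (with the `glm` block-update
#' module). The default desk-scale profile is 4 chains of 1,000 tuning
#' and 1,000 retained steps; `profile = "full"` switches to 32 chains of
#' 2^14 + 2^14 steps. Convergence diagnostics (split R-hat, effective
#' sample size) are always computed; a run with any R-hat above 1.01 is
#' marked failed but its draws are still returned.
#'
#' @param model [build_model()] output.
#' @param chains,tune,draws MCMC profile (defaults 4 / 1000 / 1000).
#' @param seed integer; fully determines the draws.
#' @param profile `"desk"` (use the explicit arguments) or `"full"`
#'   (the large-scale study profile).
#' @param quiet suppress JAGS progress output (default TRUE).
#' @return object of class `posterior_bundle`: `draws` (matrix, one
#'   column per parameter: intercept, named slopes, eps, nu),
#'   `diagnostics` (data.frame parameter / rhat / ess), `failed`,
#'   `model`, and the run metadata.
#' @export
sample_posterior <- function(model, chains = 4, tune = 1000, draws = 1000,
                             seed = 1, profile = c("desk", "full"),
                             quiet = TRUE) {
  profile <- match.arg(profile)
  if (profile == "full") { chains <- 32; tune <- 2^14; draws <- 2^14 }
  rjags::load.module("glm", quiet = TRUE)
  data <- list(y = as.numeric(model$y), X = model$X,
               N = nrow(model$X), P = ncol(model$X))
  inits <- lapply(seq_len(chains), function(i)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + i) %% .Machine$integer.max))
  n_adapt <- min(tune, 1000)
  jm <- rjags::jags.model(textConnection(jags_model_code()), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = quiet)
  if (tune > n_adapt)
    stats::update(jm, n.iter = tune - n_adapt, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("alpha", "beta", "eps", "nu"),
                              n.iter = draws, progress.bar = "none")
  rhat <- if (chains >= 2)
    coda::gelman.diag(samp, multivariate = FALSE,
                      autoburnin = FALSE)$psrf[, 1]
  else rep(NA_real_, coda::nvar(samp))
  ess <- coda::effectiveSize(samp)
  mat <- as.matrix(samp)
  nm <- colnames(mat)
  nm[nm == "alpha"] <- "intercept"
  for (k in seq_along(model$design$predictors))
    nm[nm == sprintf("beta[%d]", k)] <- model$design$predictors[k]
  colnames(mat) <- nm
  diag_df <- data.frame(parameter = nm, rhat = unname(rhat),
                        ess = unname(ess[colnames(as.matrix(samp))]))
  structure(list(
    draws = mat, chains = chains, tune = tune, n_draws = draws,
    seed = seed, diagnostics = diag_df,
    failed = any(diag_df$rhat > 1.01, na.rm = TRUE),
    model = model), class = "posterior_bundle")
}

#' @export
print.posterior_bundle <- function(x, ...) {
  cat(sprintf(
    "<posterior_bundle: %s, %d chains x %d draws, max R-hat %.3f%s>\n",
    x$model$design$outcome, x$chains, x$n_draws,
    suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    if (x$failed) ", FAILED" else ""))
  invisible(x)
}

#' Coefficient draws on the natural predictor scale
#'
#' Undoes the training-set standardization: slopes are per unit of the
#' raw predictor, the intercept at raw predictor zero. Values refer to
#' the (possibly log-) transformed outcome scale of the design.
#'
#' @param bundle [sample_posterior()] output.
#' @return matrix of draws with columns intercept + predictor names.
#' @export
coef_draws <- function(bundle) {
  m <- bundle$model
  p <- m$design$predictors
  b_s <- bundle$draws[, p, drop = FALSE]
  b_nat <- sweep(b_s, 2, m$y_scale / m$x_scale, `*`)
  a_nat <- m$y_center + m$y_scale * bundle$draws[, "intercept"] -
    as.numeric(b_nat %*% m$x_center)
  cbind(intercept = a_nat, b_nat)
}

#' Posterior-predictive inference per stride
#'
#' For every stride, draws one predictive outcome per posterior draw from
#' the Student-t observation model at the stride's predictor values, so
#' that all posterior information enters the prediction distribution, and
#' summarizes the difference Delta = predicted - actual (negative Delta =
#' underestimation).
#'
#' @param bundle [sample_posterior()] output.
#' @param rows stride table with all predictors (and, if available, the
#'   actual outcome for Delta summaries).
#' @param seed RNG seed for the predictive noise draws.
#' @param keep_samples attach the full draws-by-strides sample matrix as
#'   attribute `"samples"` (default FALSE).
#' @return data.frame, one row per stride: `stride_id`, `subject_id`,
#'   `actual`, `pred_mean`, `pred_sd`, `delta_mean`, `delta_sd`,
#'   `frac_below` (fraction of predictive samples below actual).
#' @export
predict_strides <- function(bundle, rows, seed = 1, keep_samples = FALSE) {
  m <- bundle$model
  p <- m$design$predictors
  missing <- setdiff(p, names(rows))
  if (length(missing))
    stop("missing predictor(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(rows[, p, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing predictor values")
  Xs <- sweep(sweep(X, 2, m$x_center), 2, m$x_scale, `/`)
  alpha <- bundle$draws[, "intercept"]
  beta <- bundle$draws[, p, drop = FALSE]
  eps <- bundle$draws[, "eps"]
  nu <- bundle$draws[, "nu"]
  nd <- length(alpha)
  mu <- tcrossprod(beta, Xs) + alpha          # draws x strides
  noise <- with_seed(seed,
    matrix(stats::rt(nd * nrow(Xs), df = nu), nd, nrow(Xs)) * eps)
  pred <- inv_transform_outcome(m$y_center + m$y_scale * (mu + noise),
                                m$design$transform)
  actual <- if (m$design$outcome %in% names(rows))
    rows[[m$design$outcome]] else rep(NA_real_, nrow(Xs))
  delta <- sweep(pred, 2, actual)
  out <- data.frame(
    stride_id = if ("stride_id" %in% names(rows)) rows$stride_id
                else seq_len(nrow(Xs)),
    subject_id = if ("subject_id" %in% names(rows)) rows$subject_id
                 else NA,
    outcome = m$design$outcome,
    actual = actual,
    pred_mean = colMeans(pred),
    pred_sd = apply(pred, 2, stats::sd),
    delta_mean = colMeans(delta),
    delta_sd = apply(delta, 2, stats::sd),
    frac_below = colMeans(sweep(pred, 2, actual, `<`)))
  if (keep_samples) attr(out, "samples") <- pred
  out
}
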