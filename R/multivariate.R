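# --- PCA utilities: coordination components and body-size score -----------

#' Fit a centered PCA with a deterministic sign convention
#'
#' Thin wrapper around [stats::prcomp()] (no column scaling): each loading
#' vector is flipped, if necessary, so that its largest-magnitude entry is
#' positive, making scores reproducible across platforms.
#'
#' @param x numeric matrix, observations in rows.
#' @param n_components components to retain (default: all).
#' @return object of class `pca_model`: list with `center`, `rotation`
#'   (loadings, columns orthonormal), `sdev`, `explained` (variance
#'   fractions over all components), `n_components`.
#' @export
fit_pca <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 observations")
  if (all(apply(x, 2, stats::var) < 1e-300))
    stop("zero-variance matrix: PCA undefined")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(p$rotation, 2, flip, `*`)
  k <- if (is.null(n_components)) ncol(rot) else min(n_components, ncol(rot))
  structure(list(center = p$center, rotation = rot, sdev = p$sdev,
                 explained = p$sdev^2 / sum(p$sdev^2),
                 n_components = k), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d vars, %d retained, %.1f%% variance>\n",
              nrow(x$rotation), x$n_components,
              100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}

#' Project observations onto PCA components
#'
#' @param object `pca_model`.
#' @param newdata matrix of observations.
#' @param n_components overrides the model's retained count.
#' @param ... ignored.
#' @return score matrix (observations x components).
#' @export
predict.pca_model <- function(object, newdata, n_components = NULL, ...) {
  k <- if (is.null(n_components)) object$n_components else n_components
  sc <- sweep(as.matrix(newdata), 2, object$center) %*%
    object$rotation[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(k))
  sc
}

#' Reconstruct observations from PCA scores
#'
#' @param model `pca_model`.
#' @param scores score matrix (columns = leading components).
#' @return matrix in the original variable space.
#' @export
pca_inverse <- function(model, scores) {
  k <- ncol(scores)
  sweep(scores %*% t(model$rotation[, seq_len(k), drop = FALSE]), 2,
        model$center, `+`)
}

#' Serialize / restore a PCA model as JSON
#'
#' Text serialization (center, loadings, sdev, retained count) so a model
#' fitted at training time can be reused exactly at prediction time.
#'
#' @param model `pca_model`.
#' @param path JSON file path.
#' @export
pca_to_json <- function(model, path) {
  jsonlite::write_json(list(center = model$center,
                            rotation = model$rotation,
                            sdev = model$sdev,
                            n_components = model$n_components),
                       path, digits = NA, auto_unbox = TRUE)
}

#' @rdname pca_to_json
#' @export
pca_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = o$center, rotation = as.matrix(o$rotation),
                 sdev = o$sdev,
                 explained = o$sdev^2 / sum(o$sdev^2),
                 n_components = o$n_components), class = "pca_model")
}

#' Coordination components
#'
#' PCA of the stride-by-96 coordination matrix; the first `n_components`
#' (default 12) scores per stride enter the subject models. No column
#' standardization is applied: the inputs are already amplitude-normalized
#' and dimensionless, and raw covariance preserves the relative harmonic
#' weighting.
#'
#' @param coordination matrix with 96 columns (strides in rows).
#' @param n_components retained coordination components (default 12).
#' @return list with `model` (`pca_model`), `scores` (strides x
#'   `n_components`, columns CC1..), and `explained` (variance fraction
#'   captured by the retained components).
#' @export
coordination_pca <- function(coordination, n_components = 12) {
  coordination <- as.matrix(coordination)
  if (ncol(coordination) != 96)
    stop("coordination matrix must have 96 columns, got ",
         ncol(coordination))
  model <- fit_pca(coordination, n_components)
  if (sum(model$sdev > 1e-10) < n_components)
    stop("fewer than ", n_components, " non-degenerate components")
  scores <- predict(model, coordination)
  colnames(scores) <- paste0("CC", seq_len(n_components))
  list(model = model, scores = scores,
       explained = sum(model$explained[seq_len(n_components)]))
}

#' Stride-mean skeleton segment lengths
#'
#' @param traj [landmark_trajectories()].
#' @param start,end optional 0-based frame window (default: all frames).
#' @return named numeric vector, one mean length (m) per skeleton segment.
#' @export
mean_segment_lengths <- function(traj, start = 0, end = n_frames(traj)) {
  colMeans(segment_length_frames(traj)[(start + 1):end, , drop = FALSE])
}

#' Body-size score from skeleton segment lengths
#'
#' First principal component of the per-recording mean segment-length
#' matrix, sign-fixed so that larger animals score higher (positive
#' correlation with overall mean segment length).
#'
#' @param lengths matrix: one row per subject-recording, one column per
#'   skeleton segment (see [mean_segment_lengths()]).
#' @return list with `scores` (named numeric vector) and `model`
#'   (`pca_model`); `explained` gives PC1's variance fraction.
#' @export
size_score <- function(lengths) {
  lengths <- as.matrix(lengths)
  if (anyNA(lengths)) stop("missing segment lengths")
  if (!is.null(colnames(lengths))) {
    missing <- setdiff(skeleton_segments()$segment, colnames(lengths))
    if (length(missing))
      stop("missing segments: ", paste(missing, collapse = ", "))
  }
  model <- fit_pca(lengths, 1)
  sc <- drop(predict(model, lengths, 1))
  if (stats::cor(sc, rowMeans(lengths)) < 0) {
    model$rotation[, 1] <- -model$rotation[, 1]
    sc <- -sc
  }
  list(scores = sc, model = model, explained = model$explained[1])
}
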