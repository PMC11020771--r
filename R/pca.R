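#' Principal component analysis of Procrustes shape coordinates
#'
#' Computes components of the covariance of the aligned coordinates about
#' the consensus (centred, unstandardized) via singular value
#' decomposition, operating directly on the Procrustes-aligned coordinates
#' (no tangent-space projection by default — the standard small-variation
#' practice). Component signs follow a deterministic convention: the
#' largest-magnitude loading entry of each component is positive, so
#' scores are reproducible across runs and platforms.
#'
#' @param fit A [gpa()] fit (>= 3 specimens).
#' @param tangent If `TRUE`, orthogonally project the flattened coordinates
#'   onto the tangent space at the consensus before the SVD.
#' @return A `shape_pca` object with `scores` (tibble, specimen x PC),
#'   `loadings` (orthonormal columns in flattened (x1, y1, x2, y2, ...)
#'   shape space), `eigenvalues`, `variance_fraction`, and the consensus.
#' @export
pca_shapes <- function(fit, tangent = FALSE) {
  stopifnot(inherits(fit, "gpa_fit"))
  n <- dim(fit$aligned)[3]
  if (n < 3) abort("shape PCA needs at least 3 specimens")
  p <- dim(fit$aligned)[1]
  X <- t(apply(fit$aligned, 3, function(m) as.vector(t(m))))  # n x 2p
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (tangent) {
    cvec <- as.vector(t(fit$consensus))
    cvec <- cvec / sqrt(sum(cvec^2))
    Xc <- Xc - outer(drop(Xc %*% cvec), cvec)
  }
  s <- svd(Xc)
  k <- min(n - 1, ncol(Xc))
  d <- s$d[seq_len(k)]
  loadings <- s$v[, seq_len(k), drop = FALSE]
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(loadings[, j]))
    if (loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  eig <- d^2 / (n - 1)
  total <- sum(eig)
  vf <- if (total > 0) eig / total else rep(0, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  score_tbl <- dplyr::bind_cols(
    tibble(specimen_id = fit$specimen_ids), as_tibble(scores))
  structure(
    list(scores = score_tbl, loadings = loadings, eigenvalues = eig,
         variance_fraction = vf, center = mu, consensus = fit$consensus,
         n_landmarks = p),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(2, length(x$variance_fraction))
  cat(sprintf("<shape_pca>: %d specimens, %d components; PC1..PC%d explain %.1f%%\n",
              nrow(x$scores), length(x$eigenvalues), k,
              100 * sum(x$variance_fraction[seq_len(k)])))
  invisible(x)
}

#' @describeIn pca_shapes Tidy view: `matrix = "scores"` (default,
#'   long specimen/PC/score), `"loadings"`, or `"eigenvalues"`
#'   (per-component eigenvalue and variance fraction).
#' @param x A `shape_pca`.
#' @param matrix Which quantity to tidy.
#' @param ... Unused.
#' @exportS3Method
tidy.shape_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                           ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    return(tidyr::pivot_longer(x$scores, -"specimen_id",
                               names_to = "component", values_to = "score"))
  }
  if (matrix == "loadings") {
    ld <- as_tibble(x$loadings, .name_repair = ~paste0("PC", seq_along(.x)))
    ld$coordinate <- rep(c("x", "y"), x$n_landmarks)
    ld$point <- rep(seq_len(x$n_landmarks), each = 2)
    return(tidyr::pivot_longer(ld, dplyr::starts_with("PC"),
                               names_to = "component", values_to = "loading"))
  }
  tibble(component = paste0("PC", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         variance_fraction = x$variance_fraction,
         cumulative = cumsum(x$variance_fraction))
}

#' @describeIn pca_shapes One-row summary.
#' @exportS3Method
glance.shape_pca <- function(x, ...) {
  tibble(n_specimens = nrow(x$scores),
         n_components = length(x$eigenvalues),
         total_variance = sum(x$eigenvalues),
         pc1_fraction = x$variance_fraction[1] %||% NA_real_,
         pc12_fraction = sum(x$variance_fraction[seq_len(
           min(2, length(x$variance_fraction)))]))
}

#' @describeIn pca_shapes Morphospace scatter of two components.
#' @param object A `shape_pca`.
#' @param pcs Length-2 integer vector of components to plot.
#' @exportS3Method
autoplot.shape_pca <- function(object, pcs = c(1, 2), ...) {
  nm <- paste0("PC", pcs)
  vf <- 100 * object$variance_fraction[pcs]
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[nm[1]]], .data[[nm[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$specimen_id),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", nm[1], vf[1]),
                  y = sprintf("%s (%.1f%%)", nm[2], vf[2]),
                  title = "Shape morphospace") +
    ggplot2::theme_minimal()
}
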