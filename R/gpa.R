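#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: the square root of
#' the summed squared distances of all landmarks from their centroid.
#' Homogeneous of degree 1 in the coordinates (scaling a configuration by
#' k scales centroid size by k).
#'
#' @param points A two-column matrix / data frame of coordinates (mm), or
#'   a landmark tibble for a single specimen.
#' @return Positive centroid size (mm).
#' @export
#' @examples
#' centroid_size(cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5)))  # sqrt(2)
centroid_size <- function(points) {
  xy <- as_xy(points)
  if (nrow(xy) < 2) abort("centroid size needs at least 2 points")
  ctr <- colMeans(xy)
  cs <- sqrt(sum(sweep(xy, 2, ctr)^2))
  if (cs <= 0) abort("all points coincide: centroid size is zero")
  cs
}

#' Per-specimen centroid sizes
#'
#' @param data Landmark tibble.
#' @return Tibble with `specimen_id`, `taxon_id`, `centroid_size` (mm).
#' @export
centroid_sizes <- function(data) {
  validate_landmarks(data)
  dplyr::summarise(
    dplyr::group_by(data, .data$specimen_id, .data$taxon_id),
    centroid_size = centroid_size(cbind(.data$x, .data$y)),
    .groups = "drop")
}

as_xy <- function(points) {
  if (is.data.frame(points) && all(c("x", "y") %in% names(points))) {
    return(cbind(points$x, points$y))
  }
  m <- as.matrix(points)
  if (ncol(m) != 2) abort("expected two-column coordinates")
  storage.mode(m) <- "double"
  m
}

# optimal rotation (no reflection) aligning X onto target Y, both centered
procrustes_rotation <- function(X, Y) {
  H <- crossprod(X, Y)  # maximize tr(R' H) over rotations R, X R ~ Y
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

#' Generalized Procrustes superimposition
#'
#' Iteratively removes translation, scale and rotation from a set of
#' landmark configurations: each configuration is centred, scaled to unit
#' centroid size, and rotated onto the running consensus by the orthogonal
#' Procrustes solution (rotation only; reflections are excluded so left /
#' right anatomy is never silently mirrored). The consensus is updated and
#' the loop repeats until its displacement falls below `tol`.
#'
#' Semilandmarks are treated as fixed points: no sliding along curves is
#' performed (see the methods vignette for the rationale).
#'
#' @param data Landmark tibble (>= 2 configurations, equal point counts),
#'   or a p x 2 x n coordinate array.
#' @param tol Convergence tolerance on the consensus displacement
#'   (root-summed-squared coordinate change).
#' @param max_iter Maximum number of consensus updates; non-convergence is
#'   an error carrying the last residual.
#' @return A `gpa_fit` object: `aligned` (p x 2 x n array, unit centroid
#'   size, centred), `consensus` (p x 2 matrix), `centroid_sizes`
#'   (tibble, mm), `iterations`, `specimen_ids`.
#' @export
gpa <- function(data, tol = 1e-8, max_iter = 100) {
  if (is.array(data) && length(dim(data)) == 3) {
    arr <- data
    ids <- dimnames(arr)[[3]] %||% paste0("spec_", seq_len(dim(arr)[3]))
    dimnames(arr) <- list(dimnames(arr)[[1]], dimnames(arr)[[2]], ids)
    cs_tbl <- tibble(
      specimen_id = ids, taxon_id = ids,
      centroid_size = unname(apply(arr, 3, centroid_size)))
  } else {
    validate_landmarks(data)
    arr <- landmarks_to_array(data)
    cs_tbl <- centroid_sizes(data)
    cs_tbl <- cs_tbl[match(dimnames(arr)[[3]], cs_tbl$specimen_id), ]
  }
  n <- dim(arr)[3]
  if (n < 2) abort("GPA needs at least 2 configurations")

  # centre and scale each configuration to unit centroid size
  norm1 <- function(X) {
    X <- sweep(X, 2, colMeans(X))
    X / sqrt(sum(X^2))
  }
  aligned <- arr
  for (i in seq_len(n)) aligned[, , i] <- norm1(arr[, , i])

  consensus <- aligned[, , 1]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      aligned[, , i] <- aligned[, , i] %*% procrustes_rotation(
        aligned[, , i], consensus)
    }
    new_consensus <- norm1(apply(aligned, c(1, 2), mean))
    shift <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (shift < tol) break
    if (iter >= max_iter) {
      abort(sprintf(
        "GPA did not converge in %d iterations (last residual %.3e)",
        max_iter, shift))
    }
  }
  structure(
    list(aligned = aligned, consensus = consensus,
         centroid_sizes = cs_tbl, iterations = iter,
         specimen_ids = dimnames(arr)[[3]], tol = tol),
    class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat(sprintf("<gpa_fit>: %d configurations, %d landmarks, %d iterations\n",
              dim(x$aligned)[3], dim(x$aligned)[1], x$iterations))
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#'
#' @param a,b p x 2 coordinate matrices.
#' @return Root-summed-squared coordinate difference.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((as_xy(a) - as_xy(b))^2))

#' @describeIn gpa Tidy per-point aligned coordinates.
#' @param x A `gpa_fit`.
#' @param ... Unused.
#' @exportS3Method
tidy.gpa_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$specimen_ids), function(i) {
    tibble(specimen_id = x$specimen_ids[i],
           point = seq_len(dim(x$aligned)[1]),
           x = x$aligned[, 1, i], y = x$aligned[, 2, i])
  })
}

#' @describeIn gpa One-row summary (n, landmarks, iterations, mean squared
#'   Procrustes distance to the consensus).
#' @exportS3Method
glance.gpa_fit <- function(x, ...) {
  d2 <- apply(x$aligned, 3, function(m) sum((m - x$consensus)^2))
  tibble(n_specimens = dim(x$aligned)[3],
         n_landmarks = dim(x$aligned)[1],
         iterations = x$iterations,
         mean_sq_procrustes = mean(d2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
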