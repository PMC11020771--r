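# Planar polygon utilities shared by the meshing and FEA code.
# Polygons are m x 2 matrices of vertices, implicitly closed
# (the last vertex connects back to the first), counter-clockwise
# for outlines.

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param poly m x 2 vertex matrix (implicitly closed).
#' @param signed Return the signed area (positive for counter-clockwise)?
#' @return Area in the square of the coordinate unit.
#' @export
polygon_area <- function(poly, signed = FALSE) {
  p <- as_xy(poly)
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  a <- sum(x * yn - xn * y) / 2
  if (signed) a else abs(a)
}

#' Point-in-polygon test (even-odd ray casting)
#'
#' @param pts k x 2 matrix of query points.
#' @param poly m x 2 polygon vertex matrix (implicitly closed).
#' @return Logical vector: `TRUE` where the point is inside.
#' @export
point_in_polygon <- function(pts, poly) {
  pts <- as_xy(pts); poly <- as_xy(poly)
  px <- poly[, 1]; py <- poly[, 2]
  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
  inside <- rep(FALSE, nrow(pts))
  for (e in seq_along(px)) {
    x1 <- px[e]; y1 <- py[e]; x2 <- nx[e]; y2 <- ny[e]
    crosses <- ((y1 > pts[, 2]) != (y2 > pts[, 2]))
    if (any(crosses)) {
      xint <- x1 + (pts[crosses, 2] - y1) * (x2 - x1) / (y2 - y1)
      flip <- pts[crosses, 1] < xint
      inside[crosses] <- xor(inside[crosses], flip)
    }
  }
  inside
}

# resample a polyline/polygon boundary at roughly the target spacing,
# keeping original vertices, returning the densified vertex sequence
resample_boundary <- function(poly, spacing, closed = TRUE) {
  p <- as_xy(poly)
  if (closed) p <- rbind(p, p[1, , drop = FALSE])
  out <- list(p[1, , drop = FALSE])
  for (e in seq_len(nrow(p) - 1)) {
    a <- p[e, ]; b <- p[e + 1, ]
    len <- sqrt(sum((b - a)^2))
    nseg <- max(1L, ceiling(len / spacing))
    tfrac <- seq_len(nseg) / nseg
    seg <- cbind(a[1] + tfrac * (b[1] - a[1]), a[2] + tfrac * (b[2] - a[2]))
    out[[length(out) + 1]] <- seg
  }
  pts <- do.call(rbind, out)
  if (closed) pts <- pts[-nrow(pts), , drop = FALSE]  # drop repeated start
  pts
}

# n points spaced evenly by arc length along a (closed or open) polyline
sample_along <- function(poly, n, closed = TRUE) {
  p <- as_xy(poly)
  if (closed) p <- rbind(p, p[1, , drop = FALSE])
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  total <- s[length(s)]
  targets <- if (closed) total * (seq_len(n) - 1) / n
             else total * (seq_len(n) - 1) / (n - 1)
  idx <- findInterval(targets, s, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(p) - 1)
  frac <- (targets - s[idx]) / pmax(s[idx + 1] - s[idx], .Machine$double.eps)
  p[idx, , drop = FALSE] + (p[idx + 1, , drop = FALSE] -
                            p[idx, , drop = FALSE]) * frac
}

# TRUE if any two non-adjacent edges of the closed polygon intersect
polygon_self_intersects <- function(poly) {
  p <- as_xy(poly)
  m <- nrow(p)
  a1 <- p; a2 <- p[c(2:m, 1), , drop = FALSE]
  seg_int <- function(p1, p2, q1, q2) {
    d1 <- p2 - p1; d2 <- q2 - q1
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
    u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
    t > 1e-10 && t < 1 - 1e-10 && u > 1e-10 && u < 1 - 1e-10
  }
  for (i in seq_len(m - 2)) {
    jmax <- if (i == 1) m - 1 else m
    for (j in (i + 2):jmax) {
      if (seg_int(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(TRUE)
    }
  }
  FALSE
}
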