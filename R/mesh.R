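#' Planar triangulated mesh
#'
#' Container for a 2D triangulated solid domain: node coordinates (mm),
#' counter-clockwise triangle connectivity, per-element areas and region
#' labels, plus the polygon metadata (outline, labelled fenestra holes)
#' the mesh was generated from. Triangles cover the solid domain only —
#' fenestrae are unmeshed holes.
#'
#' @param nodes n x 2 numeric matrix of node coordinates (mm).
#' @param triangles m x 3 integer matrix of node indices; triangles given
#'   clockwise are reordered counter-clockwise.
#' @param region Per-triangle domain label (recycled).
#' @param outline Optional outline polygon (mm) for area bookkeeping.
#' @param fenestrae Optional named list of hole polygons (mm).
#' @return A `planar_mesh` object; element areas are computed and
#'   degenerate triangles (area <= 1e-12 mm^2) are an error.
#' @export
planar_mesh <- function(nodes, triangles, region = "solid",
                        outline = NULL, fenestrae = list()) {
  nodes <- as_xy(nodes)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  stopifnot(ncol(triangles) == 3)
  if (any(triangles < 1 | triangles > nrow(nodes))) {
    abort("triangle indices out of node range")
  }
  areas <- tri_signed_areas(nodes, triangles)
  flip <- areas < 0
  if (any(flip)) {
    triangles[flip, c(2, 3)] <- triangles[flip, c(3, 2)]
    areas <- abs(areas)
  }
  if (any(areas <= 1e-12)) abort("mesh contains degenerate triangles")
  fen_areas <- vapply(fenestrae, polygon_area, numeric(1))
  structure(
    list(nodes = nodes, triangles = triangles, element_areas = areas,
         region = rep_len(as.character(region), nrow(triangles)),
         outline = outline, fenestrae = fenestrae,
         fenestra_areas = fen_areas,
         outline_area = if (is.null(outline)) NA_real_
                        else polygon_area(outline)),
    class = "planar_mesh")
}

tri_signed_areas <- function(nodes, triangles) {
  x <- matrix(nodes[triangles, 1], ncol = 3)
  y <- matrix(nodes[triangles, 2], ncol = 3)
  ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
   (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])) / 2
}

tri_min_angles <- function(nodes, triangles) {
  x <- matrix(nodes[triangles, 1], ncol = 3)
  y <- matrix(nodes[triangles, 2], ncol = 3)
  a2 <- (x[, 2] - x[, 3])^2 + (y[, 2] - y[, 3])^2
  b2 <- (x[, 1] - x[, 3])^2 + (y[, 1] - y[, 3])^2
  c2 <- (x[, 1] - x[, 2])^2 + (y[, 1] - y[, 2])^2
  ang <- function(opp2, s1, s2) {
    acos(pmin(1, pmax(-1, (s1 + s2 - opp2) / (2 * sqrt(s1 * s2)))))
  }
  pmin(ang(a2, b2, c2), ang(b2, a2, c2), ang(c2, a2, b2)) * 180 / pi
}

#' @export
print.planar_mesh <- function(x, ...) {
  cat(sprintf(
    "<planar_mesh>: %d nodes, %d triangles, solid area %.4g mm^2, %d hole(s)\n",
    nrow(x$nodes), nrow(x$triangles), sum(x$element_areas),
    length(x$fenestrae)))
  invisible(x)
}

#' @describeIn planar_mesh Per-element tibble (node ids, centroid, area,
#'   region).
#' @param x A `planar_mesh`.
#' @param ... Unused.
#' @exportS3Method
tidy.planar_mesh <- function(x, ...) {
  cx <- rowMeans(matrix(x$nodes[x$triangles, 1], ncol = 3))
  cy <- rowMeans(matrix(x$nodes[x$triangles, 2], ncol = 3))
  tibble(element = seq_len(nrow(x$triangles)),
         n1 = x$triangles[, 1], n2 = x$triangles[, 2], n3 = x$triangles[, 3],
         cx = cx, cy = cy, area = x$element_areas, region = x$region)
}

#' Structured triangular mesh of a rectangle
#'
#' Regular grid of `nx` x `ny` cells, each split into two triangles.
#' Mainly used for patch tests and refinement studies where exact element
#' quality is wanted.
#'
#' @param width,height Rectangle dimensions (mm).
#' @param nx,ny Number of cells along x and y.
#' @param origin Lower-left corner.
#' @return A `planar_mesh`.
#' @export
mesh_rect <- function(width, height, nx = 8, ny = 8, origin = c(0, 0)) {
  stopifnot(width > 0, height > 0, nx >= 1, ny >= 1)
  xs <- origin[1] + seq(0, width, length.out = nx + 1)
  ys <- origin[2] + seq(0, height, length.out = ny + 1)
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  node_id <- function(i, j) (j - 1) * (nx + 1) + i
  tri <- matrix(NA_integer_, 2 * nx * ny, 3)
  k <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      n00 <- node_id(i, j); n10 <- node_id(i + 1, j)
      n01 <- node_id(i, j + 1); n11 <- node_id(i + 1, j + 1)
      tri[k + 1, ] <- c(n00, n10, n11)
      tri[k + 2, ] <- c(n00, n11, n01)
      k <- k + 2L
    }
  }
  rect <- rbind(c(origin[1], origin[2]), c(origin[1] + width, origin[2]),
                c(origin[1] + width, origin[2] + height),
                c(origin[1], origin[2] + height))
  planar_mesh(nodes, tri, outline = rect)
}

#' Triangulate a polygon with holes
#'
#' Quality mesh of the solid region between an outline polygon and a set
#' of hole polygons: the boundaries are resampled at the target edge
#' length, interior points are laid on a staggered (hexagonal) grid away
#' from the boundaries, the point set is Delaunay-triangulated (via
#' \pkg{deldir}), triangles whose centroid falls outside the solid region
#' are discarded, and one Laplacian smoothing pass of the interior nodes
#' (followed by re-triangulation) improves element quality. The summed
#' element area must match the polygon (shoelace) solid area to 0.1% and
#' the minimum element angle must reach `min_angle`, otherwise an error
#' suggests refining `target_edge`.
#'
#' @param outline Outline polygon (counter-clockwise, mm).
#' @param holes Named list of hole polygons strictly inside the outline.
#' @param target_edge Target element edge length (mm).
#' @param min_angle Minimum acceptable element angle (degrees).
#' @param smooth_iters Laplacian smoothing passes (interior nodes only).
#' @param .retries Automatic refinements (x 0.75 each) attempted before
#'   the quality error is raised.
#' @return A `planar_mesh` with the holes recorded as fenestrae.
#' @export
mesh_polygon <- function(outline, holes = list(), target_edge,
                         min_angle = 20, smooth_iters = 2, .retries = 3) {
  outline <- as_xy(outline)
  if (polygon_area(outline, signed = TRUE) < 0) outline <- outline[rev(seq_len(nrow(outline))), ]
  if (polygon_self_intersects(outline)) abort("outline polygon self-intersects")
  h <- target_edge
  # densify coarse boundaries; re-sample over-dense ones (e.g. finely
  # digitized hole ellipses) evenly so boundary spacing matches h
  boundary_at <- function(poly) {
    p <- as_xy(poly)
    closed <- rbind(p, p[1, , drop = FALSE])
    seg <- sqrt(rowSums(diff(closed)^2))
    if (stats::median(seg) < 0.7 * h) {
      q <- sample_along(p, max(8L, ceiling(sum(seg) / h)))
      # chords of a convex curve lose area; rescale about the centroid so
      # the coarsened polygon keeps the original enclosed area
      a0 <- polygon_area(p); a1 <- polygon_area(q)
      ctr <- colMeans(q)
      sweep(sweep(q, 2, ctr) * sqrt(a0 / a1), 2, ctr, `+`)
    } else {
      resample_boundary(p, h)
    }
  }
  bnd <- boundary_at(outline)
  hole_bnds <- lapply(holes, boundary_at)
  boundary_pts <- do.call(rbind, c(list(bnd), hole_bnds))
  # from here on the (re)sampled polygons ARE the meshed geometry, so
  # area bookkeeping and point filtering stay self-consistent
  outline <- bnd
  holes <- hole_bnds

  interior_grid <- function() {
    xr <- range(outline[, 1]); yr <- range(outline[, 2])
    dy <- h * sqrt(3) / 2
    ys <- seq(yr[1] + dy / 2, yr[2], by = dy)
    pts <- do.call(rbind, lapply(seq_along(ys), function(j) {
      off <- if (j %% 2 == 0) h / 2 else 0
      xs <- seq(xr[1] + h / 2 + off, xr[2], by = h)
      cbind(xs, ys[j])
    }))
    keep <- point_in_polygon(pts, outline)
    for (hp in holes) keep <- keep & !point_in_polygon(pts, as_xy(hp))
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) == 0) return(pts)
    # stay clear of the boundary so no sliver elements form
    dmin <- min_dist_to(pts, boundary_pts)
    pts[dmin > 0.62 * h, , drop = FALSE]
  }

  build <- function(all_pts) {
    tri <- delaunay_triangles(all_pts)
    cx <- rowMeans(matrix(all_pts[tri, 1], ncol = 3))
    cy <- rowMeans(matrix(all_pts[tri, 2], ncol = 3))
    ctr <- cbind(cx, cy)
    keep <- point_in_polygon(ctr, outline)
    for (hp in holes) keep <- keep & !point_in_polygon(ctr, as_xy(hp))
    list(pts = all_pts, tri = tri[keep, , drop = FALSE])
  }

  pts <- rbind(boundary_pts, interior_grid())
  mesh <- build(pts)
  n_fixed <- nrow(boundary_pts)
  for (it in seq_len(smooth_iters)) {
    if (nrow(mesh$pts) <= n_fixed) break
    mesh$pts <- smooth_interior(mesh$pts, mesh$tri, n_fixed)
    mesh <- build(mesh$pts)
  }

  out <- planar_mesh(mesh$pts, mesh$tri, outline = outline, fenestrae = holes)
  solid <- polygon_area(outline) - sum(out$fenestra_areas)
  rel_err <- abs(sum(out$element_areas) - solid) / solid
  quality <- min(tri_min_angles(out$nodes, out$triangles))
  if (rel_err > 1e-3 || quality < min_angle) {
    # narrow features (e.g. thin inter-fenestra struts) can defeat a
    # coarse target edge; retry refined before giving up
    if (.retries > 0) {
      return(mesh_polygon(outline, holes, 0.75 * target_edge,
                          min_angle = min_angle,
                          smooth_iters = smooth_iters,
                          .retries = .retries - 1))
    }
    if (rel_err > 1e-3) {
      abort(sprintf(
        "meshed area misses the polygon area by %.3g%%; refine target_edge",
        100 * rel_err))
    }
    abort(sprintf(
      "element quality below %g degrees at target_edge = %g; refine target_edge",
      min_angle, target_edge))
  }
  out
}

min_dist_to <- function(pts, ref) {
  # chunked to keep the distance matrix small
  apply_chunks <- function(p) {
    d2 <- outer(p[, 1], ref[, 1], "-")^2 + outer(p[, 2], ref[, 2], "-")^2
    sqrt(apply(d2, 1, min))
  }
  idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / 512))
  unlist(lapply(idx, function(i) apply_chunks(pts[i, , drop = FALSE])),
         use.names = FALSE)
}

delaunay_triangles <- function(pts) {
  # deldir occasionally narrates storage re-allocation on stdout
  utils::capture.output(
    dd <- deldir::deldir(pts[, 1], pts[, 2], round = FALSE,
                         suppressMsge = TRUE))
  tl <- deldir::triang.list(dd)
  tri <- t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
  tri
}

smooth_interior <- function(pts, tri, n_fixed) {
  n <- nrow(pts)
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  edges <- rbind(edges, edges[, c(2, 1)])
  sx <- tapply(pts[edges[, 2], 1], edges[, 1], mean)
  sy <- tapply(pts[edges[, 2], 2], edges[, 1], mean)
  ids <- as.integer(names(sx))
  new_pts <- pts
  movable <- ids[ids > n_fixed]
  new_pts[movable, 1] <- sx[as.character(movable)]
  new_pts[movable, 2] <- sy[as.character(movable)]
  new_pts
}

#' Uniformly refine a mesh
#'
#' Splits every triangle into four congruent children (edge midpoints),
#' used by convergence studies.
#'
#' @param mesh A `planar_mesh`.
#' @return The refined `planar_mesh`.
#' @export
refine_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "planar_mesh"))
  nodes <- mesh$nodes
  tri <- mesh$triangles
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_key <- c(key(tri[, 1], tri[, 2]), key(tri[, 2], tri[, 3]),
                key(tri[, 3], tri[, 1]))
  uk <- unique(edge_key)
  mid_id <- setNames(nrow(nodes) + seq_along(uk), uk)
  ab <- do.call(rbind, strsplit(uk, " "))
  mids <- (nodes[as.integer(ab[, 1]), , drop = FALSE] +
           nodes[as.integer(ab[, 2]), , drop = FALSE]) / 2
  nodes2 <- rbind(nodes, mids)
  m12 <- mid_id[key(tri[, 1], tri[, 2])]
  m23 <- mid_id[key(tri[, 2], tri[, 3])]
  m31 <- mid_id[key(tri[, 3], tri[, 1])]
  tri2 <- rbind(cbind(tri[, 1], m12, m31), cbind(m12, tri[, 2], m23),
                cbind(m31, m23, tri[, 3]), cbind(m12, m23, m31))
  planar_mesh(nodes2, tri2, region = rep(mesh$region, 4),
              outline = mesh$outline, fenestrae = mesh$fenestrae)
}

#' Write / read a mesh as a node/element CSV pair
#'
#' Nodes: `id, x_mm, y_mm`; elements: `id, n1, n2, n3, region`.
#'
#' @param mesh A `planar_mesh`.
#' @param nodes_path,elements_path CSV paths.
#' @return `write_mesh_csv`: invisibly, the paths; `read_mesh_csv`: a
#'   `planar_mesh` (without polygon metadata).
#' @export
write_mesh_csv <- function(mesh, nodes_path, elements_path) {
  stopifnot(inherits(mesh, "planar_mesh"))
  readr::write_csv(tibble(id = seq_len(nrow(mesh$nodes)),
                          x_mm = mesh$nodes[, 1], y_mm = mesh$nodes[, 2]),
                   nodes_path)
  readr::write_csv(tibble(id = seq_len(nrow(mesh$triangles)),
                          n1 = mesh$triangles[, 1], n2 = mesh$triangles[, 2],
                          n3 = mesh$triangles[, 3], region = mesh$region),
                   elements_path)
  invisible(c(nodes_path, elements_path))
}

#' @rdname write_mesh_csv
#' @export
read_mesh_csv <- function(nodes_path, elements_path) {
  nd <- readr::read_csv(nodes_path, show_col_types = FALSE)
  el <- readr::read_csv(elements_path, show_col_types = FALSE)
  planar_mesh(cbind(nd$x_mm, nd$y_mm),
              cbind(el$n1, el$n2, el$n3),
              region = if ("region" %in% names(el)) el$region else "solid")
}
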