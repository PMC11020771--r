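#' Linear-elastic material
#'
#' Isotropic material for the plane-strain models. Units follow the
#' consistent mm-N-MPa system used throughout: Young's modulus in MPa,
#' forces in N, lengths in mm, strains dimensionless (reported as
#' microstrain).
#'
#' @param young_modulus Young's modulus E (MPa), positive. Default
#'   20490 MPa (20.49 GPa cortical bone).
#' @param poisson_ratio Poisson's ratio in (0, 0.5). Default 0.4.
#' @return A `material` object.
#' @export
material <- function(young_modulus = 20490, poisson_ratio = 0.4) {
  if (young_modulus <= 0) abort("Young's modulus must be positive")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5) {
    abort("Poisson's ratio must be in (0, 0.5)")
  }
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio), class = "material")
}

# plane-strain constitutive matrix (3x3, engineering shear strain)
plane_strain_D <- function(mat) {
  E <- mat$young_modulus; nu <- mat$poisson_ratio
  E / ((1 + nu) * (1 - 2 * nu)) *
    matrix(c(1 - nu, nu, 0,
             nu, 1 - nu, 0,
             0, 0, (1 - 2 * nu) / 2), 3, 3, byrow = TRUE)
}

#' Constant-stress force scaling between models of different area
#'
#' Scales a reference force to a new model so both experience the same
#' stress state under plane-strain assumptions:
#' `F_new = F_ref * sqrt(area_new / area_ref)`. The reference model is,
#' by convention, the smallest model in a study, carrying the arbitrary
#' reference force (30 N by default in the pipeline).
#'
#' @param f_ref Reference force (N).
#' @param area_ref,area_new Model areas (mm^2), positive.
#' @return Scaled force (N).
#' @export
#' @examples
#' scale_force(30, 100, 400)  # 60
scale_force <- function(f_ref, area_ref, area_new) {
  if (any(area_ref <= 0) || any(area_new <= 0)) abort("areas must be positive")
  f_ref * sqrt(area_new / area_ref)
}

#' Load case for a planar model
#'
#' @param fixed Tibble of constraints: `node` (index) and `dir`
#'   (`"x"`, `"y"` or `"both"`).
#' @param loads Tibble of nodal forces: `node`, `fx`, `fy` (N).
#' @return A `load_case`.
#' @export
load_case <- function(fixed, loads) {
  fixed <- as_tibble(fixed); loads <- as_tibble(loads)
  stopifnot(all(c("node", "dir") %in% names(fixed)),
            all(c("node", "fx", "fy") %in% names(loads)))
  if (!all(fixed$dir %in% c("x", "y", "both"))) {
    abort("constraint dir must be 'x', 'y' or 'both'")
  }
  n_dof <- sum(ifelse(fixed$dir == "both", 2L, 1L))
  if (n_dof < 3) abort("at least 3 constrained DOFs needed (rigid-body modes)")
  structure(list(fixed = fixed, loads = loads), class = "load_case")
}

fixed_dof_indices <- function(case) {
  idx <- integer(0)
  for (i in seq_len(nrow(case$fixed))) {
    nd <- case$fixed$node[i]
    d <- case$fixed$dir[i]
    if (d %in% c("x", "both")) idx <- c(idx, 2L * nd - 1L)
    if (d %in% c("y", "both")) idx <- c(idx, 2L * nd)
  }
  sort(unique(idx))
}

# per-element strain-displacement matrices; returns list(B = 3x6 arrays)
element_B <- function(mesh) {
  tri <- mesh$triangles
  x <- matrix(mesh$nodes[tri, 1], ncol = 3)
  y <- matrix(mesh$nodes[tri, 2], ncol = 3)
  b1 <- y[, 2] - y[, 3]; b2 <- y[, 3] - y[, 1]; b3 <- y[, 1] - y[, 2]
  c1 <- x[, 3] - x[, 2]; c2 <- x[, 1] - x[, 3]; c3 <- x[, 2] - x[, 1]
  list(b = cbind(b1, b2, b3), c = cbind(c1, c2, c3),
       area = mesh$element_areas)
}

#' Assemble and solve a plane-strain CST model
#'
#' Assembles 3-node constant-strain-triangle stiffness under the
#' plane-strain constitutive law (unit thickness), applies the load case
#' constraints by reduction, and solves the reduced system with a sparse
#' symmetric (Cholesky) factorization. A reduced system that is not
#' positive definite — insufficient constraints leaving a rigid-body mode,
#' or a defective mesh — is an error, never silently regularized.
#'
#' @param mesh A [planar_mesh()].
#' @param mat A [material()].
#' @param case A [load_case()].
#' @return An `fea_result`: `displacements` (n x 2, mm), `reactions`
#'   (tibble at constrained DOFs, N), element strain table (microstrain),
#'   and the inputs. See [element_strains()] for the strain columns.
#' @export
solve_fea <- function(mesh, mat, case) {
  stopifnot(inherits(mesh, "planar_mesh"), inherits(mat, "material"),
            inherits(case, "load_case"))
  n <- nrow(mesh$nodes)
  ne <- nrow(mesh$triangles)
  D <- plane_strain_D(mat)
  eb <- element_B(mesh)
  trip_i <- vector("list", ne); trip_j <- vector("list", ne)
  trip_x <- vector("list", ne)
  for (e in seq_len(ne)) {
    A <- eb$area[e]
    B <- matrix(0, 3, 6)
    B[1, c(1, 3, 5)] <- eb$b[e, ]
    B[2, c(2, 4, 6)] <- eb$c[e, ]
    B[3, c(1, 3, 5)] <- eb$c[e, ]
    B[3, c(2, 4, 6)] <- eb$b[e, ]
    B <- B / (2 * A)
    Ke <- A * t(B) %*% D %*% B
    nd <- mesh$triangles[e, ]
    dofs <- c(rbind(2L * nd - 1L, 2L * nd))
    trip_i[[e]] <- rep(dofs, times = 6)
    trip_j[[e]] <- rep(dofs, each = 6)
    trip_x[[e]] <- as.vector(Ke)
  }
  K <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(2 * n, 2 * n))
  f <- numeric(2 * n)
  if (nrow(case$loads) > 0) {
    f[2 * case$loads$node - 1] <- f[2 * case$loads$node - 1] + case$loads$fx
    f[2 * case$loads$node] <- f[2 * case$loads$node] + case$loads$fy
  }
  fixed <- fixed_dof_indices(case)
  free <- setdiff(seq_len(2 * n), fixed)
  Kff <- K[free, free, drop = FALSE]
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(Kff), perm = TRUE),
    error = function(e) abort(paste0(
      "reduced stiffness is not positive definite (free rigid-body mode ",
      "or defective mesh): ", conditionMessage(e))))
  u <- numeric(2 * n)
  u[free] <- as.numeric(Matrix::solve(ch, f[free]))
  resid <- as.numeric(K %*% u) - f
  # CHOLMOD can factor a semi-definite system without complaint; a rigid
  # mode shows up as a non-finite or inconsistent solution
  scale_ref <- max(1, max(abs(f)))
  if (any(!is.finite(u)) || max(abs(resid[free])) > 1e-6 * scale_ref) {
    abort("reduced stiffness is singular (free rigid-body mode)")
  }
  reactions <- tibble(
    node = (fixed + 1L) %/% 2L,
    dof = ifelse(fixed %% 2L == 1L, "x", "y"),
    reaction = resid[fixed])
  displ <- cbind(u[seq(1, 2 * n, by = 2)], u[seq(2, 2 * n, by = 2)])
  res <- structure(
    list(mesh = mesh, material = mat, case = case,
         displacements = displ, reactions = reactions),
    class = "fea_result")
  res$strains <- element_strains(res)
  res
}

#' Element strain fields of a solved model
#'
#' Constant strain per triangle from the CST shape-function gradients.
#' Principal strains come from the 2x2 eigen-decomposition (`e1 >= e2`,
#' signed: positive tensile, negative compressive); the signed field for
#' contour maps is the principal strain of largest magnitude. The
#' equivalent strain is a von Mises-type non-negative scalar computed from
#' the deviatoric plane-strain tensor (out-of-plane strain zero),
#' `sqrt(2/3 * dev:dev)` — the scalar aggregated by [mwam()] and
#' [intervals_method()]. All strain columns are in microstrain.
#'
#' @param result An `fea_result` (or pass `displacements` and `mesh`).
#' @param displacements Optional n x 2 displacement matrix (mm) overriding
#'   the one in `result`.
#' @return Tibble: `element`, `area`, `eps_xx`, `eps_yy`, `gamma_xy`,
#'   `eps_1`, `eps_2`, `eps_signed`, `eps_eq` (all microstrain).
#' @export
element_strains <- function(result, displacements = NULL) {
  mesh <- if (inherits(result, "fea_result")) result$mesh else result
  u <- displacements %||%
    (if (inherits(result, "fea_result")) result$displacements else
       abort("displacements required"))
  if (nrow(u) != nrow(mesh$nodes)) abort("displacement/mesh size mismatch")
  eb <- element_B(mesh)
  tri <- mesh$triangles
  ux <- matrix(u[tri, 1], ncol = 3)
  uy <- matrix(u[tri, 2], ncol = 3)
  inv2A <- 1 / (2 * eb$area)
  eps_xx <- rowSums(eb$b * ux) * inv2A
  eps_yy <- rowSums(eb$c * uy) * inv2A
  gamma_xy <- (rowSums(eb$c * ux) + rowSums(eb$b * uy)) * inv2A
  # principal strains of the 2x2 tensor
  mid <- (eps_xx + eps_yy) / 2
  r <- sqrt(((eps_xx - eps_yy) / 2)^2 + (gamma_xy / 2)^2)
  e1 <- mid + r; e2 <- mid - r
  eps_signed <- ifelse(abs(e1) >= abs(e2), e1, e2)
  # von Mises-type equivalent from the deviatoric tensor, eps_zz = 0
  tr3 <- (eps_xx + eps_yy) / 3
  dev_sq <- (eps_xx - tr3)^2 + (eps_yy - tr3)^2 + tr3^2 +
    2 * (gamma_xy / 2)^2
  eps_eq <- sqrt(2 / 3 * dev_sq)
  tibble(element = seq_len(nrow(tri)), area = eb$area,
         eps_xx = eps_xx * 1e6, eps_yy = eps_yy * 1e6,
         gamma_xy = gamma_xy * 1e6, eps_1 = e1 * 1e6, eps_2 = e2 * 1e6,
         eps_signed = eps_signed * 1e6, eps_eq = eps_eq * 1e6)
}

#' Mesh-weighted arithmetic mean (MWAM) strain
#'
#' Area-weighted mean of a per-element scalar field,
#' `sum(eps_i * A_i) / sum(A_i)`, correcting model summaries for uneven
#' element sizes.
#'
#' @param strain Per-element non-negative scalar (microstrain).
#' @param areas Per-element areas (mm^2), positive.
#' @return MWAM (same unit as `strain`).
#' @export
mwam <- function(strain, areas) {
  if (length(strain) == 0) abort("empty strain field")
  if (length(strain) != length(areas)) abort("strain/area length mismatch")
  if (any(areas <= 0)) abort("element areas must be positive")
  sum(strain * areas) / sum(areas)
}

#' Intervals method: percent area per strain interval
#'
#' Summarises a model as the percentage of its area falling in successive
#' equal-width strain intervals `[0, u/n), [u/n, 2u/n), ...`; the final
#' interval is open-ended, capturing every value at or above its lower
#' edge, so the percentages always sum to 100.
#'
#' @param strain Per-element non-negative scalar (microstrain).
#' @param areas Per-element areas (mm^2).
#' @param n_intervals Number of intervals (>= 2). Default 4 (V1 lowest
#'   strain ... V4 highest).
#' @param upper_bound Upper edge (microstrain) of the closed part of the
#'   range; must be positive.
#' @return Tibble: `interval` ("V1"...), `lower`, `upper` (με; `Inf` for
#'   the last), `percent_area` summing to 100.
#' @export
intervals_method <- function(strain, areas, n_intervals = 4, upper_bound) {
  if (n_intervals < 2) abort("need at least 2 intervals")
  if (upper_bound <= 0) abort("upper_bound must be positive")
  if (length(strain) != length(areas)) abort("strain/area length mismatch")
  edges <- seq(0, upper_bound, length.out = n_intervals + 1)
  lower <- edges[-length(edges)]
  upper <- c(edges[2:n_intervals], Inf)
  bin <- pmin(findInterval(strain, edges), n_intervals)
  bin <- pmax(bin, 1L)  # strains are non-negative; guard exact zeros
  pct <- vapply(seq_len(n_intervals),
                function(k) sum(areas[bin == k]) / sum(areas) * 100,
                numeric(1))
  tibble(interval = paste0("V", seq_len(n_intervals)),
         lower = lower, upper = upper, percent_area = pct)
}

#' Fenestra to solid-area ratio of a mesh
#'
#' Ratio of the summed fenestra (hole) areas to the meshed solid area;
#' per-fenestra ratios are available for orbit / antorbital / lateral
#' temporal / naris analyses.
#'
#' @param mesh A [planar_mesh()] with fenestra polygons recorded.
#' @param per_fenestra Return one row per fenestra too?
#' @return With `per_fenestra = FALSE`, the total ratio (0 for a mesh with
#'   no holes); otherwise a tibble of `fenestra`, `area`, `ratio` with a
#'   `"total"` row.
#' @export
fenestra_ratio <- function(mesh, per_fenestra = FALSE) {
  stopifnot(inherits(mesh, "planar_mesh"))
  solid <- sum(mesh$element_areas)
  fen <- mesh$fenestra_areas
  if (length(fen) > 0 && is.finite(mesh$outline_area) &&
      sum(fen) >= mesh$outline_area) {
    abort("fenestra area is at least as large as the outline area")
  }
  total <- if (length(fen) == 0) 0 else sum(fen) / solid
  if (!per_fenestra) return(total)
  dplyr::bind_rows(
    tibble(fenestra = names(fen) %||% character(0),
           area = as.numeric(fen), ratio = as.numeric(fen) / solid),
    tibble(fenestra = "total", area = sum(fen), ratio = total))
}

#' @export
print.fea_result <- function(x, ...) {
  cat(sprintf(
    "<fea_result>: %d elements, MWAM equivalent strain %.1f microstrain\n",
    nrow(x$strains), mwam(x$strains$eps_eq, x$strains$area)))
  invisible(x)
}

#' @describeIn solve_fea Per-element strain tibble.
#' @param x An `fea_result`.
#' @param ... Unused.
#' @exportS3Method
tidy.fea_result <- function(x, ...) x$strains

#' @describeIn solve_fea One-row model summary: MWAM equivalent strain,
#'   totals, equilibrium residual.
#' @exportS3Method
glance.fea_result <- function(x, ...) {
  fx <- sum(x$case$loads$fx) + sum(x$reactions$reaction[x$reactions$dof == "x"])
  fy <- sum(x$case$loads$fy) + sum(x$reactions$reaction[x$reactions$dof == "y"])
  tibble(n_nodes = nrow(x$mesh$nodes),
         n_elements = nrow(x$strains),
         solid_area = sum(x$mesh$element_areas),
         mwam_eq = mwam(x$strains$eps_eq, x$strains$area),
         equilibrium_residual = max(abs(c(fx, fy))))
}
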