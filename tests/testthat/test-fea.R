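test_that("constant-stress force scaling follows the square-root law", {
  expect_equal(scale_force(30, 120, 120), 30)
  expect_equal(scale_force(30, 100, 400), 60)
  withr::with_seed(41, {
    for (i in 1:20) {
      f <- runif(1, 1, 100); a1 <- runif(1, 1, 1e4); a2 <- runif(1, 1, 1e4)
      oracle <- exp(log(f) + 0.5 * (log(a2) - log(a1)))  # log-domain
      expect_equal(scale_force(f, a1, a2), oracle, tolerance = 1e-12)
    }
  })
  expect_error(scale_force(30, -1, 10), "positive")
})

test_that("zero load gives zero displacement", {
  m <- mesh_rect(1, 1, 3, 3)
  case <- load_case(data.frame(node = c(1, 2), dir = c("both", "y")),
                    data.frame(node = 5, fx = 0, fy = 0))
  r <- solve_fea(m, material(), case)
  expect_lt(max(abs(r$displacements)), 1e-12)
})

test_that("the plane-strain patch test reproduces the closed form", {
  E <- 20490; nu <- 0.4; sigma <- 1
  exx <- sigma * (1 - nu^2) / E * 1e6
  eyy <- -sigma * nu * (1 + nu) / E * 1e6
  for (nx in c(2, 4, 8)) {
    r <- patch_test(nx, nx, sigma, E, nu)
    s <- r$strains
    expect_lt(max(abs(s$eps_xx - exx)) / exx, 1e-9)
    expect_lt(max(abs(s$eps_yy - eyy)) / abs(eyy), 1e-9)
    expect_lt(max(abs(s$gamma_xy)), 1e-9 * exx)
    # principal strains: e1 tensile along x, e2 compressive along y
    expect_equal(s$eps_1, rep(exx, nrow(s)), tolerance = 1e-9)
    expect_equal(s$eps_2, rep(eyy, nrow(s)), tolerance = 1e-9)
    # global equilibrium
    expect_lt(glance(r)$equilibrium_residual, 1e-6)
  }
})

test_that("reactions balance applied loads on a skull bite model", {
  study <- generate_study(n_taxa = 4, seed = 5, target_edge = 5)
  mesh <- study$meshes[[1]]
  tmpl <- study$templates[[1]]
  case <- bite_load_case(
    mesh, tmpl$levers["anterior_bite", ], tmpl$levers["jaw_joint", ],
    nodes_near(mesh, tmpl$attachments$temporal$center,
               tmpl$attachments$temporal$radius),
    tmpl$levers["temporal_insertion", ],
    nodes_near(mesh, tmpl$attachments$quadrate$center,
               tmpl$attachments$quadrate$radius),
    tmpl$levers["quadrate_insertion", ],
    total_force = 30)
  # nodal force magnitudes sum to the scaled total
  expect_equal(sum(sqrt(case$loads$fx^2 + case$loads$fy^2)), 30,
               tolerance = 1e-9)
  r <- solve_fea(mesh, material(), case)
  expect_lt(glance(r)$equilibrium_residual, 1e-6)
  expect_gte(min(r$strains$eps_eq), 0)
})

test_that("under-constrained models are rejected, not regularized", {
  m <- mesh_rect(1, 1, 2, 2)
  expect_error(load_case(data.frame(node = 1, dir = "x"),
                         data.frame(node = 9, fx = 1, fy = 0)),
               "3 constrained")
  # 3 DOFs that still leave x-translation free
  case <- load_case(data.frame(node = c(1, 3, 7), dir = c("y", "y", "y")),
                    data.frame(node = 9, fx = 1, fy = 0))
  expect_error(solve_fea(m, material(), case),
               "singular|not positive definite")
})

test_that("strains vanish for rigid displacement fields", {
  m <- mesh_rect(2, 1, 4, 3)
  u_trans <- cbind(rep(0.37, nrow(m$nodes)), rep(-1.2, nrow(m$nodes)))
  s <- element_strains(m, displacements = u_trans)
  expect_lt(max(abs(as.matrix(s[, c("eps_xx", "eps_yy", "gamma_xy")]))),
            1e-12)
  # small rotation: strains are O(theta^2)
  theta <- 1e-5
  u_rot <- cbind(-theta * m$nodes[, 2], theta * m$nodes[, 1])
  s2 <- element_strains(m, displacements = u_rot)
  expect_lt(max(abs(as.matrix(s2[, c("eps_xx", "eps_yy", "gamma_xy")]))),
            1e-9)
})

test_that("MWAM is the area-weighted mean", {
  expect_equal(mwam(c(4, 8), c(1, 3)), 7)
  m <- mesh_rect(1, 1, 3, 2)
  expect_equal(mwam(rep(5.5, nrow(m$triangles)), m$element_areas), 5.5)
  # refinement invariance: splitting elements in halves leaves MWAM fixed
  withr::with_seed(2, {
    eps <- runif(30, 0, 100); areas <- runif(30, 0.5, 2)
  })
  expect_equal(mwam(eps, areas),
               mwam(rep(eps, each = 2), rep(areas / 2, each = 2)),
               tolerance = 1e-12)
  expect_error(mwam(numeric(0), numeric(0)), "empty")
})

test_that("intervals percentages match a brute-force binning oracle", {
  iv <- intervals_method(c(5, 5, 5), c(1, 2, 3), 4, upper_bound = 100)
  expect_equal(iv$percent_area, c(100, 0, 0, 0))
  iv2 <- intervals_method(c(10, 90), c(1, 1), 2, upper_bound = 100)
  expect_equal(iv2$percent_area, c(50, 50))
  withr::with_seed(77, {
    for (i in 1:1000) {
      ne <- sample(3:40, 1)
      eps <- runif(ne, 0, 150)
      areas <- runif(ne, 0.1, 3)
      nb <- sample(2:6, 1)
      up <- runif(1, 50, 120)
      iv <- intervals_method(eps, areas, nb, up)
      expect_equal(iv$percent_area, intervals_oracle(eps, areas, nb, up),
                   tolerance = 1e-9)
      expect_equal(sum(iv$percent_area), 100, tolerance = 1e-6)
    }
  })
  expect_error(intervals_method(1, 1, 1, 10), "at least 2")
})

test_that("values at or beyond the last edge land in the top interval", {
  iv <- intervals_method(c(10, 60, 150, 9999), rep(1, 4), 4,
                         upper_bound = 100)
  expect_equal(iv$percent_area, c(25, 0, 25, 50))
})

test_that("fenestra ratios follow their definition", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  m0 <- mesh_polygon(sq, target_edge = 0.2)
  expect_identical(fenestra_ratio(m0), 0)
  hole <- rbind(c(.25, .25), c(.75, .25), c(.75, .75), c(.25, .75))
  m1 <- mesh_polygon(sq, list(h = hole), target_edge = 0.1)
  expect_equal(fenestra_ratio(m1), 1 / 3, tolerance = 2e-3)
  per <- fenestra_ratio(m1, per_fenestra = TRUE)
  expect_identical(per$fenestra, c("h", "total"))
})

test_that("geometry + force scaling leaves the strain field unchanged", {
  # the operational meaning of constant-stress scaling: scale the mesh by
  # s (area by s^2) and the load by s; strains agree to 1e-6 relative
  study <- generate_study(n_taxa = 4, seed = 6, target_edge = 5)
  mesh <- study$meshes[[2]]
  tmpl <- study$templates[[2]]
  s <- 2.5
  mesh_big <- planar_mesh(mesh$nodes * s, mesh$triangles,
                          region = mesh$region,
                          outline = mesh$outline * s,
                          fenestrae = lapply(mesh$fenestrae, `*`, s))
  build_case <- function(msh, scl, force) {
    bite_load_case(
      msh, tmpl$levers["anterior_bite", ] * scl,
      tmpl$levers["jaw_joint", ] * scl,
      nodes_near(msh, tmpl$attachments$temporal$center * scl,
                 tmpl$attachments$temporal$radius * scl),
      tmpl$levers["temporal_insertion", ] * scl,
      nodes_near(msh, tmpl$attachments$quadrate$center * scl,
                 tmpl$attachments$quadrate$radius * scl),
      tmpl$levers["quadrate_insertion", ] * scl,
      total_force = force)
  }
  a1 <- sum(mesh$element_areas)
  a2 <- sum(mesh_big$element_areas)
  expect_equal(a2 / a1, s^2, tolerance = 1e-9)
  f1 <- 30
  f2 <- scale_force(f1, a1, a2)
  expect_equal(f2, f1 * s, tolerance = 1e-9)
  r1 <- solve_fea(mesh, material(), build_case(mesh, 1, f1))
  r2 <- solve_fea(mesh_big, material(), build_case(mesh_big, s, f2))
  rel <- max(abs(r2$strains$eps_eq - r1$strains$eps_eq)) /
    max(r1$strains$eps_eq)
  expect_lt(rel, 1e-6)
  expect_equal(mwam(r2$strains$eps_eq, r2$strains$area),
               mwam(r1$strains$eps_eq, r1$strains$area),
               tolerance = 1e-6)
})
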