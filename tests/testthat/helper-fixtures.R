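# shared fixture builders: all data is generated in code, no files

# random landmark dataset as a tidy landmark table
random_landmarks <- function(n_spec = 4, p = 10, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_spec), function(i) {
      landmark_tbl(sprintf("s%02d", i), sprintf("t%02d", i),
                   cbind(runif(p, 0, 100), runif(p, 0, 40)))
    })
  })
}

# apply a random rotation + translation + positive scaling to one
# specimen's coordinates
rigid_motion <- function(xy, angle, shift = c(0, 0), s = 1) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(s * (as.matrix(xy) %*% t(R)), 2, shift, `+`)
}

# uniaxial plane-strain patch test on a rectangle: sigma_xx = sigma MPa,
# consistent edge lumping (half shares at corners), rollers on the left
# edge with one pinned corner
patch_test <- function(nx = 4, ny = 4, sigma = 1, E = 20490, nu = 0.4,
                       width = 1, height = 1) {
  m <- mesh_rect(width, height, nx, ny)
  nd <- m$nodes
  right <- which(abs(nd[, 1] - width) < 1e-12)
  left <- which(abs(nd[, 1]) < 1e-12)
  hseg <- height / ny
  corner <- abs(nd[right, 2]) < 1e-12 | abs(nd[right, 2] - height) < 1e-12
  w <- ifelse(corner, hseg / 2, hseg)
  fixed <- data.frame(node = left, dir = "x")
  fixed$dir[which.min(nd[left, 2])] <- "both"
  case <- load_case(fixed,
                    data.frame(node = right, fx = sigma * w, fy = 0))
  solve_fea(m, material(E, nu), case)
}

# balanced pure-birth tree rescaled to unit depth, deterministic
calib_tree <- function(n_tips, seed = 11) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
    tr
  })
}

star_tree <- function(n = 6, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, n)
  tr
}

# independent area-weighted binning oracle for the intervals method
intervals_oracle <- function(strain, areas, n_intervals, upper) {
  pct <- numeric(n_intervals)
  width <- upper / n_intervals
  for (i in seq_along(strain)) {
    k <- min(floor(strain[i] / width) + 1, n_intervals)
    pct[k] <- pct[k] + areas[i]
  }
  100 * pct / sum(areas)
}

# independent type-7 quantile (sort + linear interpolation between order
# statistics) for the outlier-test oracle
quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
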