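test_that("centroid size matches hand arithmetic and is homogeneous", {
  sq <- cbind(c(-.5, .5, .5, -.5), c(-.5, -.5, .5, .5))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(7.3 * sq), 7.3 * sqrt(2), tolerance = 1e-12)
  withr::with_seed(5, {
    pts <- cbind(rnorm(10), rnorm(10))
  })
  # direct per-point distance summation oracle
  ctr <- colMeans(pts)
  oracle <- sqrt(sum(apply(pts, 1, function(p) sum((p - ctr)^2))))
  expect_equal(centroid_size(pts), oracle, tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 3, 2)), "coincide")
})

test_that("gpa exactly superimposes similar shapes", {
  base <- cbind(c(0, 4, 2, 1), c(0, 0, 3, 5))
  rot <- rigid_motion(base, pi / 2, c(10, -2), 2)
  arr <- array(c(base, rot), dim = c(4, 2, 2),
               dimnames = list(NULL, NULL, c("a", "b")))
  fit <- gpa(arr)
  expect_lt(procrustes_distance(fit$aligned[, , 1], fit$aligned[, , 2]),
            1e-9)
  # unit centroid size and centred
  for (i in 1:2) {
    expect_equal(sqrt(sum(fit$aligned[, , i]^2)), 1, tolerance = 1e-9)
    expect_equal(colMeans(fit$aligned[, , i]), c(0, 0), tolerance = 1e-12)
  }
  expect_equal(fit$centroid_sizes$centroid_size[2],
               2 * fit$centroid_sizes$centroid_size[1], tolerance = 1e-9)
})

test_that("gpa output is invariant to per-specimen rigid motion + scaling", {
  lms <- random_landmarks(5, 12, seed = 3)
  moved <- lms
  withr::with_seed(8, {
    for (sid in unique(lms$specimen_id)) {
      sel <- moved$specimen_id == sid
      xy <- rigid_motion(cbind(moved$x[sel], moved$y[sel]),
                         runif(1, 0, 2 * pi), rnorm(2, 0, 50),
                         runif(1, 0.2, 5))
      moved$x[sel] <- xy[, 1]; moved$y[sel] <- xy[, 2]
    }
  })
  f1 <- gpa(lms); f2 <- gpa(moved)
  # aligned shapes agree after rotating one consensus onto the other
  R <- skullmech:::procrustes_rotation(f2$consensus, f1$consensus)
  for (i in seq_along(f1$specimen_ids)) {
    expect_lt(max(abs(f2$aligned[, , i] %*% R - f1$aligned[, , i])), 1e-7)
  }
  # pairwise Procrustes distances identical
  d <- function(f) {
    n <- dim(f$aligned)[3]
    outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      procrustes_distance(f$aligned[, , i], f$aligned[, , j])))
  }
  expect_equal(d(f1), d(f2), tolerance = 1e-7)
})

test_that("the optimal rotation matches an exhaustive grid search", {
  withr::with_seed(21, {
    X <- scale(cbind(rnorm(3), rnorm(3)), scale = FALSE)
    Y <- scale(cbind(rnorm(3), rnorm(3)), scale = FALSE)
  })
  R <- skullmech:::procrustes_rotation(X, Y)
  ang <- atan2(R[1, 2], R[1, 1])
  grid <- seq(-pi, pi, by = 0.001)
  ssd <- vapply(grid, function(a) {
    Ra <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    sum((X %*% Ra - Y)^2)
  }, numeric(1))
  best <- grid[which.min(ssd)]
  delta <- abs(atan2(sin(ang - best), cos(ang - best)))
  expect_lt(delta, 0.001)
  expect_equal(det(R), 1, tolerance = 1e-12)  # no reflection
})

test_that("gpa rejects non-converging or degenerate input", {
  lms <- random_landmarks(3, 6)
  expect_error(gpa(lms, max_iter = 0), "did not converge")
  one <- lms[lms$specimen_id == "s01", ]
  expect_error(gpa(one), "at least 2")
})

test_that("shape PCA handles degenerate and two-shape datasets", {
  base <- cbind(c(0, 4, 2, 1), c(0, 0, 3, 5))
  arr <- array(rep(base, 4), dim = c(4, 2, 4))
  fit <- gpa(arr)
  p <- pca_shapes(fit)
  expect_true(all(p$variance_fraction == 0))

  other <- base + cbind(c(.1, 0, -.1, 0), c(0, .1, 0, -.1))
  arr2 <- array(c(base, other, base, other), dim = c(4, 2, 4))
  p2 <- pca_shapes(gpa(arr2))
  expect_equal(p2$variance_fraction[1], 1, tolerance = 1e-9)
  expect_equal(sum(p2$variance_fraction), 1, tolerance = 1e-9)
  expect_error(pca_shapes(gpa(arr2[, , 1:2])), "at least 3")
})

test_that("PCA recovers a single generating deformation mode", {
  # 8 shapes from one mode plus tiny noise: PC1 dominates and its scores
  # are monotone in the generating weight
  base <- cbind(seq(0, 10, length.out = 12),
                rep(c(0, 4), 6))
  mode <- cbind(pmax(0, base[, 1] - 5), rep(0, 12))  # stretch one end
  w <- seq(-0.4, 0.4, length.out = 8)
  withr::with_seed(9, {
    arr <- array(NA_real_, c(12, 2, 8))
    for (i in 1:8) arr[, , i] <- base + w[i] * mode +
        matrix(rnorm(24, 0, 1e-4), 12, 2)
  })
  p <- pca_shapes(gpa(arr))
  expect_gt(p$variance_fraction[1], 0.95)
  s <- p$scores$PC1
  expect_true(all(diff(s) > 0) || all(diff(s) < 0))
})

test_that("variance fractions sum to 1 and match Procrustes dispersion", {
  lms <- random_landmarks(6, 10, seed = 13)
  fit <- gpa(lms)
  p <- pca_shapes(fit)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  # total variance equals mean squared distance to the column-mean shape
  X <- t(apply(fit$aligned, 3, function(m) as.vector(t(m))))
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(sum(p$eigenvalues), sum(Xc^2) / (nrow(X) - 1),
               tolerance = 1e-9)
})

test_that("k orthogonal modes give exactly k non-negligible eigenvalues", {
  base <- cbind(seq(0, 10, length.out = 10), rep(c(0, 3), 5))
  m1 <- cbind(pmax(0, base[, 1] - 5), rep(0, 10))
  m2 <- cbind(rep(0, 10), base[, 1] / 10)
  withr::with_seed(3, {
    w1 <- rnorm(8); w2 <- rnorm(8)
  })
  arr <- array(NA_real_, c(10, 2, 8))
  # amplitudes small enough that Procrustes alignment stays linear
  for (i in 1:8) arr[, , i] <- base + 1e-4 * (w1[i] * m1 + w2[i] * m2)
  p <- pca_shapes(gpa(arr))
  expect_true(all(p$eigenvalues[-(1:2)] < 1e-8 * sum(p$eigenvalues)))
  expect_gt(p$eigenvalues[2], 1e-4 * sum(p$eigenvalues))
})

test_that("Tukey-fence outliers match hand computation", {
  d <- data.frame(specimen_id = letters[1:5], v = c(1, 2, 3, 4, 100))
  rep <- boxplot_outliers(d, v)
  expect_identical(rep$outliers$specimen_id, "e")
  expect_identical(rep$outliers$side, "upper")
  q1 <- quantile7(d$v, .25); q3 <- quantile7(d$v, .75)
  expect_equal(rep$lower_fence, q1 - 1.5 * (q3 - q1))
  expect_equal(rep$upper_fence, q3 + 1.5 * (q3 - q1))

  const <- data.frame(specimen_id = letters[1:6], v = rep(2, 6))
  expect_identical(nrow(boxplot_outliers(const, v)$outliers), 0L)
  expect_error(boxplot_outliers(d[1:3, ], v), "at least 4")
})

test_that("negating values swaps lower/upper outlier flags", {
  withr::with_seed(4, {
    d <- data.frame(specimen_id = sprintf("s%d", 1:12),
                    v = c(rnorm(10), -30, 30))
  })
  up <- boxplot_outliers(d, v)
  d$v <- -d$v
  dn <- boxplot_outliers(d, v)
  expect_setequal(up$outliers$specimen_id, dn$outliers$specimen_id)
  flip <- c(lower = "upper", upper = "lower")
  m <- match(up$outliers$specimen_id, dn$outliers$specimen_id)
  expect_identical(unname(flip[up$outliers$side]), dn$outliers$side[m])
})

test_that("outlier fences agree with a sort-and-interpolate oracle", {
  withr::with_seed(99, {
    for (rep_i in 1:200) {
      n <- sample(4:40, 1)
      v <- rnorm(n, sd = sample(c(0.1, 1, 10), 1))
      d <- data.frame(specimen_id = as.character(seq_len(n)), v = v)
      r <- boxplot_outliers(d, v)
      q1 <- quantile7(v, .25); q3 <- quantile7(v, .75)
      expect_equal(r$lower_fence, q1 - 1.5 * (q3 - q1), tolerance = 1e-12)
      expect_equal(r$upper_fence, q3 + 1.5 * (q3 - q1), tolerance = 1e-12)
      flagged <- v < r$lower_fence | v > r$upper_fence
      expect_setequal(r$outliers$specimen_id, d$specimen_id[flagged])
    }
  })
})

test_that("allometry regression matches the normal equations", {
  d <- data.frame(x = 1:6, y = 2 * (1:6))
  f <- suppressWarnings(regress_allometry(d, y, x))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$adj_r_squared, 1, tolerance = 1e-12)

  d2 <- data.frame(x = c(-1, 0, 1), y = c(1, -2, 1))  # orthogonal
  f2 <- regress_allometry(d2, y, x)
  expect_lt(abs(f2$slope), 1e-9)

  withr::with_seed(2, {
    d3 <- data.frame(x = rnorm(20), y = rnorm(20))
  })
  f3 <- regress_allometry(d3, y, x)
  X <- cbind(1, d3$x)
  beta <- solve(t(X) %*% X, t(X) %*% d3$y)
  expect_equal(f3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(f3$slope, beta[2], tolerance = 1e-10)
  expect_error(regress_allometry(data.frame(x = rep(1, 5), y = rnorm(5)),
                                 y, x), "zero variance")
})
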