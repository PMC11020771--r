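test_that("Newick round trip preserves topology, lengths, labels", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)[seq_len(3)]
  expect_equal(depths, rep(2, 3))

  tr2 <- calib_tree(12, seed = 4)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr2, f2)
  back <- read_newick(f2)
  expect_setequal(back$tip.label, tr2$tip.label)
  # the whole metric structure round-trips (node order may be rewritten)
  D0 <- ape::cophenetic.phylo(tr2)
  D1 <- ape::cophenetic.phylo(back)[rownames(D0), colnames(D0)]
  expect_lt(max(abs(D1 - D0)), 1e-9)

  writeLines("((A:1,B:1:1,C:2);", f)
  expect_error(read_newick(f), "parse error")
  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_newick(f), "duplicate")
})

test_that("bm_covariance holds shared path lengths", {
  star <- star_tree(5, depth = 3)
  expect_equal(bm_covariance(star), 3 * diag(5), ignore_attr = TRUE)

  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  C <- bm_covariance(read_newick(f))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)
})

test_that("bm_covariance matches a brute-force MRCA path oracle", {
  for (seed in c(2, 9)) {
    tr <- calib_tree(10, seed = seed)
    C <- bm_covariance(tr)
    # oracle: shared path length = (d_i + d_j - d_ij) / 2 from cophenetic
    d_tip <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    names(d_tip) <- tr$tip.label
    D <- ape::cophenetic.phylo(tr)
    for (a in tr$tip.label) for (b in tr$tip.label) {
      expect_equal(C[a, b], (d_tip[[a]] + d_tip[[b]] - D[a, b]) / 2,
                   tolerance = 1e-10)
    }
    # PSD: Cholesky succeeds
    expect_silent(chol(C))
  }
})

test_that("simulate_bm is seeded, degenerate at rate ~ 0, BM-distributed", {
  tr <- calib_tree(8, seed = 3)
  x1 <- simulate_bm(tr, rate = 2, n_traits = 3, seed = 10)
  x2 <- simulate_bm(tr, rate = 2, n_traits = 3, seed = 10)
  expect_identical(x1, x2)
  x3 <- simulate_bm(tr, rate = 1e-30, seed = 1, root_state = 4)
  expect_lt(max(abs(x3 - 4)), 1e-10)
  # Monte-Carlo tip covariance ~ rate * C entrywise (within 10% on the
  # dominant entries)
  C <- bm_covariance(tr)
  sims <- simulate_bm(tr, rate = 1.5, n_traits = 2000, seed = 42)
  Cemp <- cov(t(sims))
  scale <- max(abs(1.5 * C))
  expect_lt(max(abs(Cemp - 1.5 * C)) / scale, 0.1)
})

test_that("K agrees with the independent picante implementation", {
  tr <- calib_tree(16, seed = 6)
  withr::with_seed(8, {
    x <- drop(simulate_bm(tr)) + rnorm(16, 0, 0.3)
  })
  k_pkg <- blomberg_k(tr, x, n_perm = 9, seed = 1)$statistic
  k_ref <- picante::Kcalc(x[tr$tip.label], tr)
  expect_equal(k_pkg, as.numeric(k_ref), tolerance = 1e-6)
})

test_that("kmult reduces to Blomberg's K for one variable", {
  tr <- calib_tree(10, seed = 5)
  withr::with_seed(2, x <- drop(simulate_bm(tr)))
  k1 <- blomberg_k(tr, x, n_perm = 99, seed = 3)
  k2 <- kmult(tr, matrix(x, ncol = 1, dimnames = list(names(x), "v")),
              n_perm = 99, seed = 3)
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-9)
  expect_equal(k1$p_value, k2$p_value)
})

test_that("permutation p-values are deterministic under a fixed seed", {
  tr <- calib_tree(10, seed = 5)
  withr::with_seed(2, x <- drop(simulate_bm(tr)))
  p1 <- blomberg_k(tr, x, n_perm = 99, seed = 7)$p_value
  p2 <- blomberg_k(tr, x, n_perm = 99, seed = 7)$p_value
  expect_identical(p1, p2)
  expect_true(p1 >= 1 / 100 && p1 <= 1)
  # admissible p grid
  expect_equal(p1 * 100, round(p1 * 100))
})

test_that("K and K_mult are invariant to affine trait rescaling", {
  tr <- calib_tree(12, seed = 9)
  withr::with_seed(4, {
    Y <- simulate_bm(tr, n_traits = 3)
  })
  k0 <- kmult(tr, Y, n_perm = 9, seed = 1)$statistic
  k1 <- kmult(tr, 5.5 * Y + 2, n_perm = 9, seed = 1)$statistic
  expect_equal(k0, k1, tolerance = 1e-9)
  # relabeling-consistent tip permutation
  perm <- sample(rownames(Y))
  k2 <- kmult(tr, Y[perm, , drop = FALSE][rownames(Y), , drop = FALSE],
              n_perm = 9, seed = 1)$statistic
  expect_equal(k0, k2, tolerance = 1e-12)
})

test_that("signal tests reject degenerate input", {
  tr <- calib_tree(8, seed = 1)
  const <- setNames(rep(1, 8), tr$tip.label)
  expect_error(blomberg_k(tr, const), "zero variance")
  wrong <- setNames(rnorm(8), paste0("x", 1:8))
  expect_error(blomberg_k(tr, wrong), "do not match")
})

test_that("PGLS equals OLS on a star phylogeny", {
  star <- star_tree(8)
  withr::with_seed(14, {
    d <- tibble::tibble(taxon_id = star$tip.label,
                        y = rnorm(8), x = rnorm(8))
  })
  f <- pgls(d, star, y, x)
  o <- summary(lm(y ~ x, d))
  expect_equal(f$slope, o$coefficients["x", "Estimate"], tolerance = 1e-9)
  expect_equal(f$intercept, o$coefficients["(Intercept)", "Estimate"],
               tolerance = 1e-9)
  expect_equal(f$slope_p, o$coefficients["x", "Pr(>|t|)"],
               tolerance = 1e-9)
  expect_equal(f$pseudo_r2_adj, o$adj.r.squared, tolerance = 1e-9)
})

test_that("PGLS agrees with nlme::gls under Brownian correlation", {
  tr <- calib_tree(12, seed = 13)
  withr::with_seed(3, {
    x <- drop(simulate_bm(tr))
    y <- 0.7 * x + drop(simulate_bm(tr)) * 0.5
  })
  d <- tibble::tibble(taxon_id = tr$tip.label, x = x[tr$tip.label],
                      y = y[tr$tip.label])
  f <- pgls(d, tr, y, x)
  g <- nlme::gls(y ~ x, data = as.data.frame(d),
                 correlation = ape::corBrownian(1, tr, form = ~taxon_id),
                 method = "ML")
  expect_equal(f$slope, unname(coef(g)["x"]), tolerance = 1e-6)
  expect_equal(f$intercept, unname(coef(g)["(Intercept)"]),
               tolerance = 1e-6)
})

test_that("PGLS recovers a perfect fit and rejects bad input", {
  tr <- calib_tree(6, seed = 2)
  withr::with_seed(5, x <- drop(simulate_bm(tr)))
  d <- tibble::tibble(taxon_id = tr$tip.label, x = x[tr$tip.label],
                      y = x[tr$tip.label])
  f <- suppressWarnings(pgls(d, tr, y, x))
  expect_equal(f$slope, 1, tolerance = 1e-9)
  expect_equal(f$pseudo_r2_adj, 1, tolerance = 1e-9)
  d$x <- 1
  expect_error(pgls(d, tr, y, x), "singular design")
  tiny <- star_tree(3)
  d3 <- tibble::tibble(taxon_id = tiny$tip.label, x = 1:3, y = 3:1)
  expect_error(pgls(d3, tiny, y, x), "at least 4")
})
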