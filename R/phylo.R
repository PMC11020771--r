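#' Read and write time-calibrated Newick trees
#'
#' Thin, validating wrappers around \pkg{ape}: trees must have unique tip
#' labels and finite, non-negative branch lengths (zero-length branches
#' are allowed but flagged with a warning). Polytomies are allowed.
#'
#' @param path Newick file path.
#' @return `read_newick`: an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort(paste0(
                     "Newick parse error in '", path, "': ",
                     conditionMessage(e))))
  if (is.null(tree)) abort(paste0("Newick parse error in '", path, "'"))
  validate_tree(tree)
}

#' @rdname read_newick
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return `write_newick`: `path`, invisibly. Branch lengths round-trip
#'   to 1e-9.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length))) abort("non-finite branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  if (any(tree$edge.length == 0)) {
    warn("tree contains zero-length branches")
  }
  tree
}

#' Brownian-motion covariance matrix of a tree
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j;
#' `C[i, i]` the root-to-tip depth. Symmetric positive semi-definite; the
#' expected tip covariance of a unit-rate Brownian motion.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Tip x tip matrix with tip-label dimnames.
#' @export
bm_covariance <- function(tree) {
  validate_tree(tree)
  ape::vcv.phylo(tree)
}

#' Simulate Brownian-motion traits on a tree
#'
#' Multivariate normal tip draws with covariance `rate * C` per trait,
#' where C is [bm_covariance()]. Reproducible under a fixed seed.
#'
#' @param tree An `ape::phylo`.
#' @param rate Brownian variance per unit branch length (> 0).
#' @param n_traits Number of independent traits.
#' @param seed Optional integer seed (applied locally).
#' @param root_state Trait value at the root.
#' @return Tip x trait matrix with tip-label rownames.
#' @export
simulate_bm <- function(tree, rate = 1, n_traits = 1, seed = NULL,
                        root_state = 0) {
  if (rate <= 0) abort("rate must be positive")
  C <- bm_covariance(tree)
  n <- nrow(C)
  L <- chol_psd(C)
  draw <- function() {
    root_state + drop(crossprod(L, rnorm(n)) * sqrt(rate))
  }
  sim <- function() {
    X <- vapply(seq_len(n_traits), function(j) draw(), numeric(n))
    dimnames(X) <- list(rownames(C), paste0("trait_", seq_len(n_traits)))
    X
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

# upper Cholesky factor tolerant of semi-definite C (zero-length branches)
chol_psd <- function(C) {
  tryCatch(chol(C), error = function(e) {
    eg <- eigen(C, symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    t(eg$vectors %*% diag(sqrt(vals), length(vals)))
  })
}

# core K statistic (Blomberg for 1 column; Adams multivariate otherwise):
# ratio of mean squared deviation from the phylogenetic mean to the
# phylogenetically whitened deviation, standardized by its BM expectation
k_statistic <- function(C, Y) {
  n <- nrow(C)
  one <- rep(1, n)
  Cinv1 <- solve(C, one)
  denom1 <- sum(Cinv1)
  a <- drop(crossprod(Cinv1, Y)) / denom1          # phylogenetic mean
  R <- sweep(Y, 2, a)
  num <- sum(R^2)
  den <- sum(R * solve(C, R))
  expected <- (sum(diag(C)) - n / denom1) / (n - 1)
  (num / den) / expected
}

signal_result <- function(statistic, p_value, n_permutations, seed, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, seed = seed,
                 method = method),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("<signal_test %s>: statistic %.4g, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

#' @describeIn blomberg_k One-row tibble of the test.
#' @param x A `signal_test`.
#' @param ... Unused.
#' @exportS3Method
tidy.signal_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_permutations = x$n_permutations)
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' K compares the observed ratio of trait variance about the phylogenetic
#' (GLS) mean to the phylogenetically corrected variance against its
#' expectation under Brownian motion on the given tree, so K has
#' expectation 1 under BM: K > 1 means close relatives are more similar
#' than BM predicts, K < 1 less similar. Significance comes from
#' permuting trait values across tips; the observed statistic is included
#' in the reference set, `p = (count >= observed + 1) / (B + 1)`.
#'
#' @param tree An `ape::phylo`.
#' @param trait Named numeric vector (names = tip labels) with positive
#'   variance.
#' @param n_perm Number of permutations B.
#' @param seed Optional integer seed for the permutations.
#' @return A `signal_test` (statistic, p_value, n_permutations, seed).
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  Y <- align_traits(tree, trait)
  if (ncol(Y) != 1) abort("blomberg_k takes a single trait; see kmult()")
  kmult_impl(tree, Y, n_perm, seed, method = "K")
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' The multivariate generalization of Blomberg's K for tip x variable
#' data (e.g. Procrustes shape coordinates): sums of squared deviations
#' from the phylogenetic mean across all variables, in the original and
#' phylogenetically whitened spaces, standardized by the Brownian-motion
#' expectation. Reduces exactly to Blomberg's K for one variable.
#'
#' @param tree An `ape::phylo`.
#' @param traits Tip x variable numeric matrix (rownames = tip labels) or
#'   a data frame with a `taxon_id` column.
#' @inheritParams blomberg_k
#' @return A `signal_test`.
#' @export
kmult <- function(tree, traits, n_perm = 999, seed = NULL) {
  Y <- align_traits(tree, traits)
  kmult_impl(tree, Y, n_perm, seed,
             method = if (ncol(Y) == 1) "K" else "K_mult")
}

kmult_impl <- function(tree, Y, n_perm, seed, method) {
  C <- bm_covariance(tree)
  Y <- Y[rownames(C), , drop = FALSE]
  if (all(apply(Y, 2, function(v) var(v) == 0))) {
    abort("traits have zero variance")
  }
  obs <- k_statistic(C, Y)
  run <- function() {
    perm <- vapply(seq_len(n_perm), function(b) {
      k_statistic(C, Y[sample(nrow(Y)), , drop = FALSE])
    }, numeric(1))
    (sum(perm >= obs) + 1) / (n_perm + 1)
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  signal_result(obs, p, n_perm, seed, method)
}

align_traits <- function(tree, traits) {
  validate_tree(tree)
  if (is.data.frame(traits)) {
    if (!"taxon_id" %in% names(traits)) {
      abort("trait data frame needs a taxon_id column")
    }
    m <- as.matrix(dplyr::select(traits, -"taxon_id"))
    rownames(m) <- traits$taxon_id
    traits <- m
  }
  if (is.null(dim(traits))) {
    if (is.null(names(traits))) abort("trait vector must be named by tip")
    traits <- matrix(traits, ncol = 1,
                     dimnames = list(names(traits), "trait"))
  }
  if (!setequal(rownames(traits), tree$tip.label) ||
      nrow(traits) != length(tree$tip.label)) {
    abort("trait labels do not match the tree's tips")
  }
  storage.mode(traits) <- "double"
  traits[tree$tip.label, , drop = FALSE]
}

#' Phylogenetic generalized least squares (PGLS) under Brownian motion
#'
#' GLS regression with residual covariance proportional to the shared
#' branch lengths, `beta = (X' C^-1 X)^-1 X' C^-1 y`, with a two-sided
#' t-test on the slope. The reported `pseudo_r2_adj` is
#' `1 - (RSS / TSS_GLS) * (n - 1) / (n - 2)` computed in the
#' phylogenetically whitened space (TSS about the GLS intercept-only
#' fit), approximating the adjusted R^2 of ordinary regression. With a
#' star phylogeny of equal depths PGLS coincides with OLS.
#'
#' @param data Data frame with a `taxon_id` column.
#' @param tree An `ape::phylo` whose tips match `data$taxon_id`.
#' @param response,predictor Columns (bare names or strings).
#' @return A `pgls_fit`: slope, intercept, `slope_p`, `pseudo_r2_adj`, n.
#' @export
pgls <- function(data, tree, response, predictor) {
  validate_tree(tree)
  if (!"taxon_id" %in% names(data)) abort("data needs a taxon_id column")
  ri <- tidyselect::eval_select(enquo(response), data)
  pi <- tidyselect::eval_select(enquo(predictor), data)
  if (length(ri) != 1 || length(pi) != 1) {
    abort("response and predictor must each select one column")
  }
  y <- data[[ri]]
  x <- data[[pi]]
  names(y) <- names(x) <- data$taxon_id
  if (!setequal(data$taxon_id, tree$tip.label)) {
    abort("data taxa do not match the tree's tips")
  }
  n <- length(y)
  if (n < 4) abort("PGLS needs at least 4 taxa")
  C <- bm_covariance(tree)
  ord <- rownames(C)
  y <- y[ord]; x <- x[ord]
  L <- tryCatch(chol(C), error = function(e) abort("singular BM covariance"))
  W <- function(v) backsolve(L, v, transpose = TRUE)  # whitening: L^-T v
  X <- cbind(intercept = 1, slope = x)
  Xw <- W(X); yw <- W(y)
  XtX <- crossprod(Xw)
  if (rcond(XtX) < 1e-12) abort("singular design (constant predictor?)")
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  names(beta) <- colnames(X)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  s2 <- rss / (n - 2)
  se <- setNames(sqrt(diag(solve(XtX)) * s2), colnames(X))
  t_slope <- beta[["slope"]] / se[["slope"]]
  p_slope <- 2 * pt(abs(t_slope), df = n - 2, lower.tail = FALSE)
  # GLS intercept-only fit for the total sum of squares
  ones_w <- Xw[, 1]
  mu <- sum(ones_w * yw) / sum(ones_w^2)
  tss <- sum((yw - mu * ones_w)^2)
  r2 <- if (tss > 0) 1 - (rss / tss) * (n - 1) / (n - 2) else 1
  structure(
    list(slope = beta[["slope"]], intercept = beta[["intercept"]],
         slope_se = se[["slope"]], slope_p = p_slope,
         pseudo_r2_adj = r2, n = n,
         response = names(ri),
         predictor = names(pi)),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "<pgls_fit %s ~ %s>: slope %.4g (p = %.4g), pseudo-R2_adj %.3f, n = %d\n",
    x$response, x$predictor, x$slope, x$slope_p, x$pseudo_r2_adj, x$n))
  invisible(x)
}

#' @describeIn pgls Coefficient-level tibble.
#' @param x A `pgls_fit`.
#' @param ... Unused.
#' @exportS3Method
tidy.pgls_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std_error = c(NA_real_, x$slope_se),
         p_value = c(NA_real_, x$slope_p))
}

#' @describeIn pgls One-row model summary.
#' @exportS3Method
glance.pgls_fit <- function(x, ...) {
  tibble(response = x$response, predictor = x$predictor, slope = x$slope,
         intercept = x$intercept, slope_p = x$slope_p,
         pseudo_r2_adj = x$pseudo_r2_adj, n = x$n)
}
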