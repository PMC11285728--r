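# Phylogenetic-signal tests for per-strain ARG effects: Pagel's lambda by
# maximum likelihood under a Brownian-motion model on the lambda-transformed
# tree covariance, and Blomberg's K with a tip-permutation p-value.

#' Lambda transform of a tree covariance matrix
#'
#' Scales the off-diagonal elements of the shared-path (Brownian) covariance
#' by `lambda`, leaving the diagonal unchanged. `lambda = 1` returns the
#' matrix unchanged; `lambda = 0` gives the diagonal (star-tree) covariance.
#'
#' @param V covariance matrix from [ape::vcv()].
#' @param lambda multiplier in `[0, 1]`.
#' @return Transformed covariance matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  out <- lambda * V
  diag(out) <- diag(V)
  out
}

# Align a named trait vector with the tips of a tree, pruning unmatched
# tips. Errors if traits are missing for remaining tips.
align_traits <- function(tree, traits) {
  if (is.null(names(traits))) {
    stop("traits must be named by tip label", call. = FALSE)
  }
  common <- intersect(tree$tip.label, names(traits))
  if (length(common) < 4) {
    stop("need at least 4 matched tips", call. = FALSE)
  }
  if (length(common) < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, common)
  }
  traits <- traits[tree$tip.label]
  if (anyNA(traits)) stop("missing trait values after alignment", call. = FALSE)
  list(tree = tree, traits = traits)
}

# Profile log-likelihood of the Brownian model at a given lambda: the
# ancestral mean and rate are profiled out analytically by GLS.
bm_loglik <- function(y, V, lambda) {
  n <- length(y)
  C <- lambda_transform(V, lambda)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdet <- 2 * sum(log(diag(R)))
  ones <- rep(1, n)
  Ci_y <- backsolve(R, forwardsolve(t(R), y))
  Ci_1 <- backsolve(R, forwardsolve(t(R), ones))
  a_hat <- sum(Ci_y) / sum(Ci_1)
  r <- y - a_hat
  Ci_r <- backsolve(R, forwardsolve(t(R), r))
  s2 <- sum(r * Ci_r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda for phylogenetic signal
#'
#' Maximizes the Brownian-motion likelihood over `lambda` in `[0, 1]`, where
#' the trait covariance is the lambda-transformed shared-path matrix (see
#' [lambda_transform()]); the ancestral mean and Brownian rate are profiled
#' out by generalized least squares. The search uses a grid pre-scan
#' followed by bounded scalar optimization, and the reported p-value is a
#' likelihood-ratio test against `lambda = 0` with the chi-square(1) tail
#' halved, because the null lies on the parameter boundary.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths (need not be
#'   ultrametric).
#' @param traits named numeric vector of tip values (e.g. per-strain effect
#'   of one ARG); tips absent from `traits` are pruned.
#' @param grid_points size of the pre-scan grid over `[0, 1]`.
#' @return A `phylo_signal` object: `statistic` (`"lambda"`), `estimate`,
#'   `log_likelihood`, `log_likelihood_null` (at lambda 0), `p_value`,
#'   `n_tips`.
#' @export
pagel_lambda <- function(tree, traits, grid_points = 21) {
  al <- align_traits(validate_tree(tree), traits)
  y <- as.numeric(al$traits)
  if (stats::sd(y) == 0) stop("zero trait variance", call. = FALSE)
  V <- ape::vcv(al$tree)
  ll <- function(lam) bm_loglik(y, V, lam)
  grid <- seq(0, 1, length.out = grid_points)
  ll_grid <- vapply(grid, ll, numeric(1))
  if (all(!is.finite(ll_grid))) stop("singular covariance", call. = FALSE)
  i <- which.max(ll_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8)
  # Keep whichever of the interior optimum and the boundaries wins.
  cand <- rbind(
    c(opt$maximum, opt$objective),
    c(0, ll_grid[1]),
    c(1, ll_grid[length(grid)])
  )
  best <- cand[which.max(cand[, 2]), ]
  lrt <- max(0, 2 * (best[2] - ll_grid[1]))
  p <- if (lrt == 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(
    statistic = "lambda",
    estimate = unname(best[1]),
    log_likelihood = unname(best[2]),
    log_likelihood_null = ll_grid[1],
    p_value = p,
    n_tips = length(y)
  ), class = "phylo_signal")
}

# Observed (MSE0 / MSE) ratio for Blomberg's K given precomputed V inverse.
k_ratio <- function(y, Vinv) {
  n <- length(y)
  a_hat <- sum(Vinv %*% y) / sum(Vinv)
  r <- y - a_hat
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(t(r) %*% Vinv %*% r) / (n - 1)
  mse0 / mse
}

#' Blomberg's K for phylogenetic signal
#'
#' K compares the observed partitioning of trait variance on the tree with
#' its Brownian-motion expectation:
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`, where `MSE0` is the mean squared
#' deviation of tips from the phylogenetically (GLS) corrected mean, `MSE`
#' the generalized mean squared error under the tree covariance `V`, and
#' `E[MSE0 / MSE] = (tr(V) - n / sum(V^-1)) / (n - 1)`. K near 1 indicates
#' Brownian-like signal, K much below 1 less signal than expected. The
#' p-value is the add-one-corrected fraction of tip-label permutations with
#' an `MSE0 / MSE` ratio at least as large as observed.
#'
#' @param tree rooted [ape::phylo] tree with branch lengths.
#' @param traits named numeric vector of tip values.
#' @param n_perm number of tip permutations.
#' @param seed integer seed for the permutations.
#' @return A `phylo_signal` object: `statistic` (`"K"`), `estimate`,
#'   `p_value`, `n_tips`.
#' @export
blomberg_k <- function(tree, traits, n_perm = 999, seed = 1) {
  al <- align_traits(validate_tree(tree), traits)
  y <- as.numeric(al$traits)
  if (stats::sd(y) == 0) {
    stop("zero trait variance; K undefined", call. = FALSE)
  }
  V <- ape::vcv(al$tree)
  n <- length(y)
  Vinv <- solve(V)
  expected <- (sum(diag(V)) - n / sum(Vinv)) / (n - 1)
  obs <- k_ratio(y, Vinv)
  K <- obs / expected
  perm <- with_seed(derive_seed(seed, "blomberg_perm"), {
    vapply(seq_len(n_perm), function(i) k_ratio(sample(y), Vinv), numeric(1))
  })
  p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  structure(list(
    statistic = "K",
    estimate = K,
    p_value = p,
    n_tips = n,
    n_perm = n_perm
  ), class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Phylogenetic signal (", x$statistic, ")\n", sep = "")
  cat("  estimate:", format(x$estimate, digits = 4),
      " tips:", x$n_tips, "\n")
  if (!is.null(x$log_likelihood)) {
    cat("  logLik:", format(x$log_likelihood, digits = 6),
        " logLik(lambda=0):", format(x$log_likelihood_null, digits = 6), "\n")
  }
  cat("  p-value:", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
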