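# V(lambda) = lambda * C off-diagonal, diagonal unchanged.
lambda_cov <- function(C, lambda) {
  d <- diag(C)
  V <- C * lambda
  diag(V) <- d
  V
}

#' Maximum-likelihood Pagel's lambda
#'
#' Profiles the Gaussian likelihood over `lambda` in `[0, 1]`, with the
#' phylogenetic mean and rate concentrated out analytically, and tests
#' `lambda = 0` by a likelihood-ratio test against a chi-square with one
#' degree of freedom. By default the p-value is not boundary-halved
#' (`boundary_mix = FALSE` gives the plain chi-square reference; `TRUE`
#' uses the 50:50 point-mass/chi-square mixture appropriate at the
#' boundary).
#'
#' @param tree a `phylo`.
#' @param trait named numeric vector over the tips.
#' @param boundary_mix halve the LRT p-value for the boundary null?
#' @return list: `lambda`, `loglik`, `loglik0` (at `lambda = 0`), `p`.
#' @export
pagel_lambda_ml <- function(tree, trait, boundary_mix = FALSE) {
  x <- align_trait(tree, trait)
  if (length(x) < 4) stop("need at least 4 tips")
  if (stats::var(x) == 0) stop("degenerate trait: zero variance")
  C <- phylo_cov(tree)[names(x), names(x)]
  X <- cbind(rep(1, length(x)))
  obj <- function(l) profile_loglik(x, X, lambda_cov(C, l))$loglik
  grid <- seq(0, 1, length.out = 21)
  gl <- vapply(grid, obj, numeric(1))
  i <- which.max(gl)
  opt <- stats::optimize(obj, lower = grid[max(1L, i - 1L)],
                         upper = grid[min(length(grid), i + 1L)],
                         maximum = TRUE, tol = 1e-10)
  lambda <- if (opt$objective >= gl[i]) opt$maximum else grid[i]
  ll <- max(opt$objective, gl[i])
  ll0 <- gl[1]
  lr <- max(0, 2 * (ll - ll0))
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  if (boundary_mix) p <- p / 2
  p <- min(1, max(p, .Machine$double.xmin))
  list(lambda = lambda, loglik = ll, loglik0 = ll0, p = p)
}

#' Blomberg's K with a permutation test
#'
#' Ratio of the observed to the Brownian-expected mean-square-error ratio:
#' with the GLS phylogenetic mean `a = (1' C^-1 1)^-1 1' C^-1 x`,
#' `K = [(x-a)'(x-a) / (x-a)' C^-1 (x-a)] /
#'      [(tr C - n / (1' C^-1 1)) / (n-1)]`.
#' Significance is assessed by permuting trait values across tips;
#' `p = (1 + #{K_perm >= K_obs}) / (1 + n_perm)`, so the smallest
#' attainable p is `1/(1 + n_perm)`.
#'
#' @param tree a `phylo`.
#' @param trait named numeric vector.
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for the permutations.
#' @return list: `K`, `p`, `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999L, seed = NULL) {
  x <- align_trait(tree, trait)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  C <- phylo_cov(tree)[names(x), names(x)]
  Ci <- solve(C)
  one <- rep(1, n)
  s1 <- sum(Ci)                       # 1' C^-1 1
  denom_exp <- (sum(diag(C)) - n / s1) / (n - 1)
  k_stat <- function(v) {
    a <- sum(Ci %*% v) / s1
    d <- v - a
    (sum(d^2) / drop(t(d) %*% Ci %*% d)) / denom_exp
  }
  K <- k_stat(x)
  perm <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- x[sample.int(n)]
  # vectorized: numerators and quadratic forms column-wise
  a_p <- colSums(Ci %*% perm) / s1
  D <- perm - matrix(a_p, n, n_perm, byrow = TRUE)
  num <- colSums(D^2)
  quad <- colSums(D * (Ci %*% D))
  Kp <- (num / quad) / denom_exp
  p <- (1 + sum(Kp >= K)) / (1 + n_perm)
  list(K = K, p = p, n_perm = n_perm)
}
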