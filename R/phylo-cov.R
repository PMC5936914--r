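#' Phylogenetic covariance matrix with optional Pagel's lambda transform
#'
#' Shared root-to-MRCA path lengths between every pair of tips; the
#' diagonal holds each tip's root-to-tip time. Non-ultrametric trees
#' (extinct tips) are supported. When `lambda` is supplied, off-diagonal
#' entries are multiplied by it and the diagonal is left unchanged (the
#' usual lambda transform; `lambda = 0` gives a star-like diagonal
#' structure, `lambda = 1` the identity transform).
#'
#' @param tree an [ape] `phylo` with nonnegative edge lengths in Myr.
#' @param lambda optional scalar in `[0, 1]`.
#' @return symmetric positive semidefinite matrix with tip-label dimnames.
#' @export
phylo_cov <- function(tree, lambda = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("negative edge length")
  C <- ape::vcv(tree)
  if (!is.null(lambda)) {
    stopifnot(length(lambda) == 1, lambda >= 0, lambda <= 1)
    d <- diag(C)
    C <- C * lambda
    diag(C) <- d
  }
  C
}

# Piecewise-constant reconstructed lineage-count function n(t), t measured
# forward from the root. Lineages increase by one at each internal-node
# time (the root split takes the count from 1 to 2 at t = 0) and decrease
# at each extinct tip's age. Tips within `tol` of the maximum root-to-tip
# time count as extant. Returns a list with change-point times, the count
# on each interval, and the cumulative integral of n(t).
lineage_count_steps <- function(tree, tol = 1e-8) {
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)     # time from root, all nodes
  tip_t <- depths[seq_len(n_tip)]
  node_t <- depths[-seq_len(n_tip)]
  t_max <- max(tip_t)
  extinct <- tip_t < t_max - tol
  ev_t <- c(node_t, tip_t[extinct])
  ev_d <- c(rep(1, length(node_t)), rep(-1, sum(extinct)))
  o <- order(ev_t, -ev_d)   # at ties, births before deaths (count stays >= 1)
  ev_t <- ev_t[o]; ev_d <- ev_d[o]
  times <- c(ev_t, t_max)                         # interval right endpoints
  counts <- 1 + cumsum(c(ev_d))                   # count after each event
  counts <- c(1, counts)[seq_along(times)]        # count on (t_{k-1}, t_k]
  # counts[k] applies on interval (times[k-1], times[k]] with times[0] = 0
  lefts <- c(0, times[-length(times)])
  widths <- times - lefts
  list(breaks = times, counts = counts,
       cum_int = cumsum(counts * widths), lefts = lefts)
}

# Integral of n(t) dt from 0 to each value in `s` (vectorized).
integrate_lineage_count <- function(steps, s) {
  idx <- findInterval(s, steps$breaks, left.open = TRUE) + 1L
  idx <- pmin(idx, length(steps$counts))
  base <- c(0, steps$cum_int)[idx]
  base + steps$counts[idx] * (s - steps$lefts[idx])
}

#' Model specification for trait-evolution models
#'
#' Six Gaussian models of continuous trait evolution on a time-calibrated
#' tree: `BM` (Brownian motion), `OU` (single stationary peak, root at the
#' optimum), `ACDC` (exponentially accelerating/decelerating rate),
#' `Trend` (rate varying linearly in time), `Drift` (BM plus a directional
#' trend in the mean) and `Div` (rate a linear function of reconstructed
#' lineage diversity).
#'
#' @param model one of `"BM"`, `"OU"`, `"ACDC"`, `"Trend"`, `"Drift"`,
#'   `"Div"`.
#' @param z0 root state (trait units).
#' @param sigma2 base rate, trait-units squared per Myr; must be positive.
#' @param alpha OU attraction strength (1/Myr, `>= 0`).
#' @param r ACDC exponential rate-change parameter (1/Myr; negative =
#'   early burst).
#' @param b_rate Trend linear rate slope (1/Myr); the rate
#'   `sigma2 * (1 + b_rate * t)` must stay nonnegative over the tree.
#' @param mu_drift Drift directional change in the mean (trait units/Myr).
#' @param psi Div diversity coefficient; the rate
#'   `sigma2 + psi * n(t)` must stay nonnegative over the tree.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model, z0 = 0, sigma2 = 1, alpha = NULL, r = NULL,
                       b_rate = NULL, mu_drift = NULL, psi = NULL) {
  model <- match.arg(model, c("BM", "OU", "ACDC", "Trend", "Drift", "Div"))
  stop_if_not_positive(sigma2, "sigma2")
  extra <- switch(model,
    BM = list(),
    OU = {
      if (is.null(alpha) || alpha < 0) stop("OU requires alpha >= 0")
      list(alpha = alpha)
    },
    ACDC = {
      if (is.null(r)) stop("ACDC requires r")
      list(r = r)
    },
    Trend = {
      if (is.null(b_rate)) stop("Trend requires b_rate")
      list(b_rate = b_rate)
    },
    Drift = {
      if (is.null(mu_drift)) stop("Drift requires mu_drift")
      list(mu_drift = mu_drift)
    },
    Div = {
      if (is.null(psi)) stop("Div requires psi")
      list(psi = psi)
    })
  structure(c(list(model = model, z0 = z0, sigma2 = sigma2), extra),
            class = "model_spec")
}

#' Mean vector and covariance matrix implied by a trait-evolution model
#'
#' Exact multivariate-normal law of the tip trait values under the given
#' model, for ultrametric or non-ultrametric trees. Writing `C` for the
#' shared-path-length matrix and `T_i = C_ii`:
#' * BM: mean `z0`, cov `sigma2 * C`.
#' * OU: mean `z0`, cov
#'   `sigma2/(2 alpha) * exp(-alpha (T_i + T_j - 2 C_ij)) * (1 - exp(-2 alpha C_ij))`.
#' * ACDC: rate `sigma2 * exp(r t)`; cov `sigma2 (exp(r C_ij) - 1)/r`.
#' * Trend: rate `sigma2 (1 + b_rate t)`;
#'   cov `sigma2 (C_ij + b_rate C_ij^2 / 2)`.
#' * Drift: cov as BM, mean `z0 + mu_drift * T_i`.
#' * Div: rate `sigma2 + psi * n(t)` with `n(t)` the reconstructed lineage
#'   count; cov integrates the piecewise-constant rate to the MRCA time.
#'
#' @param tree a `phylo`.
#' @param spec a [model_spec()].
#' @param C optional precomputed [phylo_cov()] matrix (performance).
#' @return list with `mean` (named vector) and `cov` (matrix).
#' @export
model_mean_cov <- function(tree, spec, C = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(C)) C <- phylo_cov(tree)
  Tv <- diag(C)
  n <- length(Tv)
  mu <- rep(spec$z0, n)
  names(mu) <- colnames(C)
  V <- switch(spec$model,
    BM = spec$sigma2 * C,
    OU = {
      a <- spec$alpha
      if (a < 1e-12) {
        spec$sigma2 * C
      } else {
        TT <- outer(Tv, Tv, "+")
        spec$sigma2 / (2 * a) * exp(-a * (TT - 2 * C)) * (1 - exp(-2 * a * C))
      }
    },
    ACDC = {
      r <- spec$r
      if (abs(r) < 1e-12) spec$sigma2 * C
      else spec$sigma2 * (exp(r * C) - 1) / r
    },
    Trend = {
      b <- spec$b_rate
      tmax <- max(Tv)
      if (b < 0 && 1 + b * tmax < -1e-10) {
        stop("Trend rate becomes negative on the tree's time span")
      }
      spec$sigma2 * (C + b * C^2 / 2)
    },
    Drift = spec$sigma2 * C,
    Div = {
      steps <- lineage_count_steps(tree)
      if (spec$sigma2 + spec$psi * max(steps$counts) < -1e-10 ||
          spec$sigma2 + spec$psi * min(steps$counts) < -1e-10) {
        stop("Div rate becomes negative on the tree's time span")
      }
      Nint <- integrate_lineage_count(steps, C)
      dim(Nint) <- dim(C)
      spec$sigma2 * C + spec$psi * Nint
    })
  if (spec$model == "Drift") mu <- mu + spec$mu_drift * Tv
  dimnames(V) <- dimnames(C)
  list(mean = mu, cov = V)
}

#' Simulate tip trait values under a trait-evolution model
#'
#' Draws one (or several) trait vectors from the exact multivariate normal
#' law given by [model_mean_cov()], via a Cholesky factor.
#'
#' @param tree a `phylo`.
#' @param spec a [model_spec()].
#' @param seed optional integer seed.
#' @param nsim number of replicate draws.
#' @return for `nsim = 1` a named numeric vector; otherwise an
#'   `nsim x n_tip` matrix with tip-label column names.
#' @export
simulate_trait <- function(tree, spec, seed = NULL, nsim = 1L) {
  if (!is.null(seed)) set.seed(seed)
  mc <- model_mean_cov(tree, spec)
  L <- chol(mc$cov + diag(1e-12 * max(diag(mc$cov)), nrow(mc$cov)))
  z <- matrix(stats::rnorm(nsim * length(mc$mean)), nrow = nsim)
  x <- z %*% L + matrix(mc$mean, nrow = nsim, ncol = length(mc$mean),
                        byrow = TRUE)
  colnames(x) <- names(mc$mean)
  if (nsim == 1L) x[1L, ] else x
}
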