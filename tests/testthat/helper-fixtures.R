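# Small fixed trees used across tests ---------------------------------

# cherry with stem lengths: ((a:2,b:4):3,c:5); shared path a-b = 3
cherry_tree <- function() {
  ape::read.tree(text = "((a:2,b:4):3,c:5);")
}

# two tips diverging at the root, both depth 5
two_tip_tree <- function(t1 = 5, t2 = 5) {
  ape::read.tree(text = sprintf("(a:%g,b:%g);", t1, t2))
}

# fixed 5-tip non-ultrametric tree
five_tip_tree <- function() {
  ape::read.tree(text = "(((a:1.5,b:2.5):1,c:4.2):0.8,(d:3.1,e:1.9):2.4);")
}

# star tree: n tips all attached to the root with equal depth
star_tree <- function(n = 8, depth = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

random_bd_tree <- function(n_tips, seed, birth = 0.3, death = 0.1) {
  simulate_tree(sim_config(seed = seed, n_tips = n_tips,
                           birth_rate = birth, death_rate = death))
}

# Independent oracles --------------------------------------------------

# dense MVN log density via explicit inverse and determinant (no Cholesky)
mvn_loglik_dense <- function(x, mu, V) {
  n <- length(x)
  -0.5 * (n * log(2 * pi) + log(det(V)) +
            drop(t(x - mu) %*% solve(V) %*% (x - mu)))
}

# brute-force quantile regression: enumerate every line through two data
# points and return the loss minimizer
qr_vertex_oracle <- function(x, y, tau) {
  best <- c(NA, NA, Inf)
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    u <- y - a - b * x
    l <- sum(u * (tau - (u < 0)))
    if (l < best[3]) best <- c(a, b, l)
  }
  names(best) <- c("intercept", "slope", "loss")
  best
}

# numeric posterior for a single species under fixed q and flat priors:
# TS on [fad, fad+pad], TE on [max(0, lad-pad), lad], density
# q^k exp(-q (ts - te)); marginals factorize, so medians come from 1-D
# grid integration.
duration_grid_oracle <- function(fad, lad, k, q, pad = 15,
                                 n_grid = 200000L) {
  ts <- seq(fad, fad + pad, length.out = n_grid)
  w_ts <- exp(-q * (ts - fad))
  cdf <- cumsum(w_ts) / sum(w_ts)
  ts_med <- ts[which.min(abs(cdf - 0.5))]
  lo <- max(0, lad - pad)
  te <- seq(lo, lad, length.out = n_grid)
  w_te <- exp(q * (te - lad))
  cdf_te <- cumsum(w_te) / sum(w_te)
  te_med <- te[which.min(abs(cdf_te - 0.5))]
  c(ts_median = ts_med, te_median = te_med)
}

# OLS via the normal equations (oracle for lambda = 0 PGLS)
ols_normal_equations <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}
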