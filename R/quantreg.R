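# Pinball (check) loss of residuals u at quantile tau.
pinball_loss <- function(u, tau) sum(u * (tau - (u < 0)))

# One exact simple quantile-regression fit. The objective
# sum rho_tau(y - a - b x) is piecewise-linear convex with a minimizing
# vertex on a line through two data points. We approach the optimum with
# asymmetric IRLS (smoothed check loss), then finish exactly by
# enumerating candidate lines through pairs of the lowest-|residual|
# points and keeping the loss minimizer.
qr_fit_one <- function(x, y, tau, irls_iter = 40L, polish_m = 20L) {
  n <- length(x)
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  eps <- 1e-6 * (stats::sd(y) + 1e-12)
  for (it in seq_len(irls_iter)) {
    r <- y - a - b * x
    w <- ifelse(r > 0, tau, 1 - tau) / pmax(abs(r), eps)
    sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
    swy <- sum(w * y); swxy <- sum(w * x * y)
    det <- sw * swxx - swx^2
    if (abs(det) < 1e-14) break
    a_new <- (swxx * swy - swx * swxy) / det
    b_new <- (sw * swxy - swx * swy) / det
    if (abs(a_new - a) + abs(b_new - b) < 1e-12) {
      a <- a_new; b <- b_new
      break
    }
    a <- a_new; b <- b_new
  }
  # exact finish: the support points of the optimal vertex have the
  # smallest residuals near the optimum
  r <- abs(y - a - b * x)
  cand <- order(r)[seq_len(min(polish_m, n))]
  best_a <- NA_real_; best_b <- NA_real_; best_loss <- Inf
  for (ii in seq_along(cand)) {
    for (jj in seq_len(ii - 1L)) {
      i <- cand[ii]; j <- cand[jj]
      if (x[i] == x[j]) next
      bb <- (y[j] - y[i]) / (x[j] - x[i])
      aa <- y[i] - bb * x[i]
      l <- pinball_loss(y - aa - bb * x, tau)
      if (l < best_loss) {
        best_loss <- l; best_a <- aa; best_b <- bb
      }
    }
  }
  # a minimizing vertex satisfies the quantile KKT conditions exactly;
  # fall back to the IRLS point only if it is strictly better (i.e. the
  # candidate set missed the optimum) or no vertex existed
  irls_loss <- pinball_loss(y - a - b * x, tau)
  if (irls_loss < best_loss - 1e-12 || !is.finite(best_loss)) {
    best_a <- a; best_b <- b; best_loss <- irls_loss
  }
  c(intercept = best_a, slope = best_b, loss = best_loss)
}

#' Simple linear quantile regression with bootstrap inference
#'
#' Fits `y = a + b x` at each requested quantile `tau` by minimizing the
#' check (pinball) loss `sum(rho_tau(y - a - b x))`, and obtains standard
#' errors as the standard deviation of the estimates over `n_bootstrap`
#' xy-pair resamples. Two-sided p-values use a normal reference on
#' `t = estimate / SE`; percentile intervals are also returned.
#'
#' @param y,x numeric vectors (`length >= 5`).
#' @param tau quantiles in (0, 1), e.g. `c(0.6, 0.7, 0.8, 0.9)`.
#' @param n_bootstrap bootstrap replications (the source analysis style
#'   uses 10000; reduce for quick looks).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per `tau`: intercept and slope, each
#'   with `se`, `t`, `p`, and 2.5/97.5% percentile bounds.
#' @export
quantile_regression <- function(y, x, tau = c(0.6, 0.7, 0.8, 0.9),
                                n_bootstrap = 1000L, seed = 1L) {
  if (length(x) < 5) stop("need n >= 5")
  if (any(tau <= 0 | tau >= 1)) stop("tau must be in (0, 1)")
  if (stats::var(x) == 0) stop("degenerate x: zero variance")
  set.seed(seed)
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_bootstrap, replace = TRUE),
                nrow = n_bootstrap)
  out <- lapply(tau, function(tt) {
    fit <- qr_fit_one(x, y, tt)
    boots <- matrix(NA_real_, n_bootstrap, 2)
    for (b in seq_len(n_bootstrap)) {
      ii <- idx[b, ]
      if (stats::var(x[ii]) == 0) next
      fb <- qr_fit_one(x[ii], y[ii], tt, irls_iter = 25L, polish_m = 12L)
      boots[b, ] <- fb[1:2]
    }
    boots <- boots[stats::complete.cases(boots), , drop = FALSE]
    se <- apply(boots, 2, stats::sd)
    est <- fit[1:2]
    tv <- est / se
    ci <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975))
    data.frame(tau = tt,
               intercept = est[1], intercept_se = se[1],
               intercept_t = tv[1],
               intercept_p = 2 * stats::pnorm(-abs(tv[1])),
               intercept_lo = ci[1, 1], intercept_hi = ci[2, 1],
               slope = est[2], slope_se = se[2], slope_t = tv[2],
               slope_p = 2 * stats::pnorm(-abs(tv[2])),
               slope_lo = ci[1, 2], slope_hi = ci[2, 2],
               loss = fit[3], n_bootstrap = nrow(boots),
               row.names = NULL)
  })
  do.call(rbind, out)
}
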