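# Relative covariance V(shape): model covariance with the base rate
# factored out (cov = sigma2 * V). For Div the shape is psi/sigma2 so the
# rate is sigma2 * (1 + shape * n(t)).
rel_cov <- function(model, C, shape = NULL, steps = NULL, Nint = NULL) {
  Tv <- diag(C)
  switch(model,
    BM = ,
    Drift = C,
    OU = {
      a <- shape
      if (a < 1e-12) C
      else {
        TT <- outer(Tv, Tv, "+")
        exp(-a * (TT - 2 * C)) * (1 - exp(-2 * a * C)) / (2 * a)
      }
    },
    ACDC = if (abs(shape) < 1e-12) C else (exp(shape * C) - 1) / shape,
    Trend = C + shape * C^2 / 2,
    Div = C + shape * Nint)
}

mean_design <- function(model, C) {
  n <- nrow(C)
  if (model == "Drift") cbind(z0 = rep(1, n), mu_drift = diag(C))
  else cbind(z0 = rep(1, n))
}

# Profiled Gaussian log-likelihood given a relative covariance V:
# GLS mean parameters and the ML scale sigma2 = Q/n are analytic.
profile_loglik <- function(x, X, V) {
  n <- length(x)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(list(loglik = -Inf))
  ldet <- 2 * sum(log(diag(L)))
  Xs <- backsolve(L, X, transpose = TRUE)
  xs <- backsolve(L, x, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- tryCatch(solve(XtX, crossprod(Xs, xs)), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf))
  res <- xs - Xs %*% beta
  Q <- sum(res^2)
  # clamp so an exact (zero-residual) fit stays finite; callers flag it
  s2 <- max(Q / n, 1e-290)
  ll <- -0.5 * (n * log(2 * pi * s2) + ldet + n)
  list(loglik = ll, beta = drop(beta), sigma2 = s2, XtX = XtX, Q = Q,
       ldet = ldet)
}

#' Log-likelihood of tip data under a fully specified trait-evolution model
#'
#' Multivariate-normal log density of the trait vector under the mean and
#' covariance of [model_mean_cov()], evaluated via a Cholesky factor.
#'
#' @param tree a `phylo`.
#' @param trait named numeric vector; names must match the tip labels.
#' @param spec a [model_spec()] with all parameters set.
#' @return scalar log-likelihood.
#' @export
trait_loglik <- function(tree, trait, spec) {
  x <- align_trait(tree, trait)
  mc <- model_mean_cov(tree, spec)
  L <- tryCatch(chol(mc$cov), error = function(e) {
    dup <- find_exchangeable_tips(mc$cov)
    stop("singular model covariance",
         if (length(dup)) paste0(" (exchangeable duplicate tips: ",
                                 paste(dup, collapse = ", "), ")") else "",
         call. = FALSE)
  })
  z <- backsolve(L, x - mc$mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

align_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label)) {
      stop("unnamed trait vector of wrong length")
    }
    names(trait) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss)) stop("trait values missing for tips: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  trait[tree$tip.label]
}

find_exchangeable_tips <- function(V) {
  n <- nrow(V)
  dup <- character(0)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (abs(V[i, i] - V[j, j]) < 1e-12 && abs(V[i, i] - V[i, j]) < 1e-12) {
      dup <- c(dup, rownames(V)[c(i, j)])
    }
  }
  unique(dup)
}

shape_bounds <- function(model, tmax, max_n) {
  switch(model,
    OU = c(0, 50 / tmax),
    ACDC = c(-15 / tmax, 15 / tmax),
    Trend = c(-1 / tmax + 1e-6, 20 / tmax),
    Div = c(-1 / max_n + 1e-6, 20 / max_n),
    c(NA, NA))
}

#' Fit one trait-evolution model by maximum likelihood
#'
#' The root state and base rate are profiled analytically (GLS mean and
#' `sigma2 = Q/n`), so only the single shape parameter of OU/ACDC/Trend/Div
#' needs numerical optimization; that is done by a coarse grid over the
#' feasible range followed by golden-section refinement, which is
#' deterministic and robust for these one-dimensional profiles. BM and
#' Drift are closed-form.
#'
#' Free-parameter counts (for AICc): BM 2 (`z0`, `sigma2`); OU, ACDC,
#' Trend, Div 3 (plus one shape); Drift 3 (`z0`, `sigma2`, `mu_drift`).
#'
#' @param tree a `phylo`.
#' @param trait named numeric vector over the tips.
#' @param model model name (see [model_spec()]).
#' @param C optional precomputed [phylo_cov()] matrix.
#' @param n_grid number of coarse-grid points for the shape profile.
#' @return object of class `trait_fit`: list with `model`, `params`,
#'   `loglik`, `k`, `n`, `aicc`, `convergence`.
#' @export
fit_trait_model <- function(tree, trait, model, C = NULL, n_grid = 16L) {
  model <- match.arg(model, c("BM", "OU", "ACDC", "Trend", "Drift", "Div"))
  x <- align_trait(tree, trait)
  if (is.null(C)) C <- phylo_cov(tree)
  C <- C[names(x), names(x)]
  X <- mean_design(model, C)
  tmax <- max(diag(C))
  steps <- NULL; Nint <- NULL; max_n <- 1
  if (model == "Div") {
    steps <- lineage_count_steps(tree)
    max_n <- max(steps$counts)
    Nint <- integrate_lineage_count(steps, C)
    dim(Nint) <- dim(C)
  }
  obj <- function(shape) {
    profile_loglik(x, X, rel_cov(model, C, shape, Nint = Nint))$loglik
  }
  if (model %in% c("BM", "Drift")) {
    shape_hat <- NULL
    pl <- profile_loglik(x, X, C)
    conv <- is.finite(pl$loglik)
  } else {
    b <- shape_bounds(model, tmax, max_n)
    grid <- seq(b[1], b[2], length.out = n_grid)
    if (model == "OU") {
      # concentrate points at weak attraction where curvature lives
      grid <- unique(c(0, exp(seq(log(1e-3 / tmax), log(b[2]),
                                  length.out = n_grid - 1L))))
    }
    gl <- vapply(grid, obj, numeric(1))
    i <- which.max(gl)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                           tol = 1e-10)
    shape_hat <- if (opt$objective >= gl[i]) opt$maximum else grid[i]
    pl <- profile_loglik(x, X, rel_cov(model, C, shape_hat, Nint = Nint))
    conv <- is.finite(pl$loglik)
  }
  params <- list(z0 = unname(pl$beta[1]), sigma2 = pl$sigma2)
  if (model == "Drift") params$mu_drift <- unname(pl$beta[2])
  if (model == "OU") params$alpha <- shape_hat
  if (model == "ACDC") params$r <- shape_hat
  if (model == "Trend") params$b_rate <- shape_hat
  if (model == "Div") params$psi <- shape_hat * pl$sigma2
  k <- if (model == "BM") 2L else 3L
  n <- length(x)
  structure(list(model = model, params = params, loglik = pl$loglik,
                 k = k, n = n,
                 aicc = aicc_from_loglik(pl$loglik, k, n),
                 convergence = conv),
            class = "trait_fit")
}

#' @export
print.trait_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik = %.4f, AICc = %.4f (k = %d, n = %d)\n",
              x$model, x$loglik, x$aicc, x$k, x$n))
  cat("  params:", paste(sprintf("%s = %.5g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

aicc_from_loglik <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Small-sample AIC and Akaike weights
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`; weights are
#' `exp(-delta/2)` normalized over the compared set, with
#' `delta_i = AICc_i - min(AICc)`. Supply either `aicc` directly or
#' `loglik`, `k` and `n`.
#'
#' @param loglik,k numeric vectors of log-likelihoods and free-parameter
#'   counts.
#' @param n sample size (number of tips/observations).
#' @param aicc optionally, precomputed AICc values.
#' @return data.frame with `aicc`, `delta`, `weight` (weights sum to 1).
#' @export
aicc_weights <- function(loglik = NULL, k = NULL, n = NULL, aicc = NULL) {
  if (is.null(aicc)) {
    if (is.null(loglik) || is.null(k) || is.null(n)) {
      stop("supply either 'aicc' or all of 'loglik', 'k', 'n'")
    }
    aicc <- mapply(aicc_from_loglik, loglik, k, MoreArgs = list(n = n))
  }
  if (!length(aicc)) stop("empty fit list")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  data.frame(aicc = aicc, delta = delta, weight = w / sum(w))
}

#' Fit and compare several trait-evolution models on one tree
#'
#' @param tree a `phylo`.
#' @param trait named numeric vector.
#' @param models character vector of model names.
#' @return data.frame (one row per model) with log-likelihood, k, AICc and
#'   Akaike weight; fits attached as attribute `"fits"`.
#' @export
compare_trait_models <- function(tree, trait,
                                 models = c("BM", "OU", "ACDC", "Trend",
                                            "Drift", "Div")) {
  C <- phylo_cov(tree)
  fits <- lapply(models, function(m) fit_trait_model(tree, trait, m, C = C))
  tab <- aicc_weights(loglik = vapply(fits, `[[`, 0, "loglik"),
                      k = vapply(fits, `[[`, 0L, "k"),
                      n = length(tree$tip.label))
  out <- cbind(data.frame(model = models,
                          loglik = vapply(fits, `[[`, 0, "loglik"),
                          k = vapply(fits, `[[`, 0L, "k")),
               tab)
  attr(out, "fits") <- fits
  out
}

#' Model selection across a posterior sample of trees
#'
#' Prunes each tree to the species present in the trait vector, fits the
#' requested models, computes per-tree Akaike weights and summarizes the
#' per-model weight distribution by its median across trees. Trees missing
#' more than half of the trait species are skipped with a warning. A
#' species list can be supplied to restrict the analysis to a subclade
#' (e.g. one subfamily).
#'
#' @param trees a `multiPhylo` (or list of `phylo`).
#' @param trait named numeric vector.
#' @param models model names.
#' @param n_trees number of trees to use (first `n_trees`).
#' @param species optional species subset.
#' @return list of class `posterior_model_summary`: `weights` (tree x
#'   model matrix), `median_weight` (named vector), `n_trees`, `skipped`.
#' @export
fit_over_posterior <- function(trees, trait,
                               models = c("BM", "OU", "ACDC", "Trend",
                                          "Drift", "Div"),
                               n_trees = length(trees), species = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- trees[seq_len(min(n_trees, length(trees)))]
  if (!is.null(species)) trait <- trait[names(trait) %in% species]
  W <- matrix(NA_real_, nrow = length(trees), ncol = length(models),
              dimnames = list(NULL, models))
  skipped <- integer(0)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    shared <- intersect(tr$tip.label, names(trait))
    if (length(shared) < max(4L, ceiling(length(trait) / 2))) {
      skipped <- c(skipped, i)
      next
    }
    tr <- ape::keep.tip(tr, shared)
    tab <- compare_trait_models(tr, trait[shared], models)
    W[i, ] <- tab$weight
  }
  if (length(skipped)) {
    warning(length(skipped), " tree(s) skipped: too few shared species")
  }
  W <- W[stats::complete.cases(W), , drop = FALSE]
  structure(list(weights = W,
                 median_weight = apply(W, 2, stats::median),
                 n_trees = nrow(W), skipped = skipped),
            class = "posterior_model_summary")
}

#' @export
print.posterior_model_summary <- function(x, ...) {
  cat("Model support over", x$n_trees, "trees (median Akaike weight):\n")
  print(round(x$median_weight, 4))
  invisible(x)
}
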