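#' Build the specialization-duration dataset
#'
#' Splits species at the median carnivory value: species at or below the
#' median form the "less carnivorous" side, species above it the "more
#' carnivorous" side (equality goes to "less" so the rule is
#' deterministic). Specialization is the absolute distance from the
#' median within each side. Configured outlier species are flagged:
#' they remain in the table but are excluded from every fitted
#' regression.
#'
#' @param scores data.frame `species`, `carnivory` (e.g. recentred PC1).
#' @param durations data.frame `species`, `duration` (Myr); other
#'   columns (e.g. `log10_mass`, `max_loc_cover`) are merged through.
#' @param exclusions character vector of outlier species.
#' @return data.frame `species`, `carnivory`, `side`, `specialization`,
#'   `duration`, `outlier`, plus merged extras.
#' @export
build_specialization_dataset <- function(scores, durations,
                                         exclusions = character(0)) {
  stopifnot(all(c("species", "carnivory") %in% names(scores)),
            all(c("species", "duration") %in% names(durations)))
  d <- merge(scores, durations, by = "species")
  if (!nrow(d)) stop("empty input: no shared species")
  if (anyNA(d$carnivory) || anyNA(d$duration)) {
    stop("carnivory and duration must be present for all species")
  }
  med <- stats::median(d$carnivory)
  d$side <- ifelse(d$carnivory <= med, "less", "more")
  d$specialization <- abs(d$carnivory - med)
  d$outlier <- d$species %in% exclusions
  attr(d, "carnivory_median") <- med
  d
}

#' Duration-on-specialization regressions per carnivory side
#'
#' For each side of the median split, fits duration ~ specialization.
#' Phylogenetic signal in the OLS residuals is measured with
#' [pagel_lambda_ml()]; when the ML lambda exceeds `lambda_threshold`
#' (and a tree is available) the slope is re-estimated by PGLS with ML
#' lambda, otherwise ordinary least squares is kept. Outlier-flagged
#' species never enter any fit. Quantile regressions at `tau` are run on
#' both sides.
#'
#' @param dataset output of [build_specialization_dataset()].
#' @param tree optional `phylo` (required if PGLS is selected).
#' @param lambda_threshold ML-lambda value above which PGLS is used
#'   (default 0.25).
#' @param tau quantiles for [quantile_regression()].
#' @param n_bootstrap bootstrap replications for the quantile fits.
#' @param seed integer seed.
#' @return list with one element per side: `method` ("OLS" or "PGLS"),
#'   `lambda`, `slope`, `se`, `p`, `n`, `fit`, `quantile` (per-tau
#'   table).
#' @export
fit_side_regressions <- function(dataset, tree = NULL,
                                 lambda_threshold = 0.25,
                                 tau = c(0.6, 0.7, 0.8, 0.9),
                                 n_bootstrap = 1000L, seed = 1L) {
  out <- list()
  for (s in c("less", "more")) {
    d <- dataset[dataset$side == s & !dataset$outlier, ]
    if (nrow(d) < 5) stop("side '", s, "' has fewer than 5 non-outlier ",
                          "species")
    ols <- stats::lm(duration ~ specialization, data = d)
    lambda <- NA_real_
    method <- "OLS"
    fit <- ols
    slope <- stats::coef(ols)[2]
    sm <- summary(ols)$coefficients
    se <- sm[2, 2]; pval <- sm[2, 4]
    if (!is.null(tree)) {
      shared <- intersect(tree$tip.label, d$species)
      if (length(shared) >= 5) {
        res <- stats::setNames(stats::resid(ols), d$species)[shared]
        sig <- pagel_lambda_ml(ape::keep.tip(tree, shared), res)
        lambda <- sig$lambda
        if (lambda > lambda_threshold) {
          method <- "PGLS"
          fit <- pgls_fit(duration ~ specialization, d, tree, "ml")
          slope <- fit$coefficients["specialization", "estimate"]
          se <- fit$coefficients["specialization", "se"]
          pval <- fit$coefficients["specialization", "p"]
        }
      }
    }
    qr <- quantile_regression(d$duration, d$specialization, tau,
                              n_bootstrap, seed = child_seed(seed, s))
    out[[s]] <- list(method = method, lambda = lambda,
                     slope = unname(slope), se = unname(se),
                     p = unname(pval), n = nrow(d), fit = fit,
                     quantile = qr)
  }
  out
}

#' Nested linear models of duration on mass, carnivory and coverage
#'
#' Five ordinary least-squares models: each single predictor, the
#' mass-by-carnivory full factorial, and the
#' mass-by-carnivory-by-coverage full factorial (all interaction terms).
#' Models are compared with AICc (k = number of mean parameters: 2, 2,
#' 2, 4, 8) and small-sample Akaike weights; adjusted R-squared and the
#' overall F-test p-value are reported per model.
#'
#' @param data data.frame with `duration`, `log10_mass`, `carnivory`,
#'   `max_loc_cover`; complete cases only are used.
#' @return data.frame (one row per model) with `model`, `loglik`, `k`,
#'   `aicc`, `weight`, `adj_r2`, `p`; fitted `lm` objects attached as
#'   attribute `"fits"`.
#' @export
nested_duration_models <- function(data) {
  vars <- c("duration", "log10_mass", "carnivory", "max_loc_cover")
  stopifnot(all(vars %in% names(data)))
  d <- data[stats::complete.cases(data[, vars]), vars]
  n <- nrow(d)
  if (n <= 9) stop("n <= 9: largest model unidentifiable with AICc")
  forms <- list(
    "body mass only" = duration ~ log10_mass,
    "carnivory only" = duration ~ carnivory,
    "maxLocCover only" = duration ~ max_loc_cover,
    "body mass and carnivory" = duration ~ log10_mass * carnivory,
    "body mass, carnivory and maxLocCover" =
      duration ~ log10_mass * carnivory * max_loc_cover)
  fits <- lapply(forms, stats::lm, data = d)
  ks <- vapply(fits, function(f) length(stats::coef(f)), 0L)
  lls <- vapply(fits, function(f) as.numeric(stats::logLik(f)), 0)
  tab <- aicc_weights(loglik = lls, k = ks, n = n)
  f_p <- vapply(fits, function(f) {
    fs <- summary(f)$fstatistic
    stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  }, 0)
  out <- data.frame(model = names(forms), loglik = lls, k = ks,
                    aicc = tab$aicc, weight = tab$weight,
                    adj_r2 = vapply(fits,
                                    function(f) summary(f)$adj.r.squared, 0),
                    p = f_p, row.names = NULL)
  attr(out, "fits") <- fits
  out
}
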