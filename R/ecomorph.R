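#' Estimate body mass from lower first molar length
#'
#' Log-log allometric regression `log10(mass_kg) = a + b * log10(m1_mm)`.
#' The coefficients are configuration: the default values follow the
#' widely used carnivoran m1-length regressions in the ecomorphology
#' literature but are NOT normative — supply the coefficients appropriate
#' for your clade.
#'
#' @param m1_length lower first molar length in mm (vectorized).
#' @param coeffs list with intercept `a` and slope `b` on the log10 scale.
#' @return data.frame with `log10_mass` and `mass_kg`.
#' @export
estimate_body_mass <- function(m1_length, coeffs = list(a = -2.58, b = 2.97)) {
  stop_if_not_positive(m1_length, "m1_length")
  lm10 <- coeffs$a + coeffs$b * log10(m1_length)
  data.frame(log10_mass = lm10, mass_kg = 10^lm10)
}

#' Compute the three dietary ratios
#'
#' * `RBL` relative blade length = trigonid blade length / m1 length;
#' * `RUGA` relative upper grinding area = sqrt(upper molar grinding
#'   area) / P4 length;
#' * `JD_DL` jaw depth / dentary length.
#'
#' Missing dentary lengths are imputed with a [fit_dentary_imputer()]
#' model when supplied; otherwise the ratio is left `NA` (flagged, never
#' fabricated).
#'
#' @param m data.frame with columns `species`, `m1_length`,
#'   `trigonid_blade_length`, `upper_grinding_area`, `p4_length`,
#'   `jaw_depth`, optionally `dentary_length` and `subfamily`.
#' @param imputer optional `dentary_imputer`.
#' @return data.frame `species`, `RBL`, `RUGA`, `JD_DL`,
#'   `dentary_imputed`.
#' @export
compute_dietary_ratios <- function(m, imputer = NULL) {
  req <- c("m1_length", "trigonid_blade_length", "upper_grinding_area",
           "p4_length", "jaw_depth")
  miss <- setdiff(req, names(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- !is.na(m$trigonid_blade_length) & !is.na(m$m1_length) &
    m$trigonid_blade_length > m$m1_length + 1e-9
  if (any(bad)) stop("trigonid blade longer than m1 for: ",
                     paste(m$species[bad], collapse = ", "))
  dl <- if ("dentary_length" %in% names(m)) m$dentary_length
        else rep(NA_real_, nrow(m))
  imputed <- rep(FALSE, nrow(m))
  if (!is.null(imputer)) {
    need <- is.na(dl) & !is.na(m$m1_length)
    if (any(need)) {
      dl[need] <- predict(imputer, m1_length = m$m1_length[need],
                          subfamily = m$subfamily[need])
      imputed <- need & !is.na(dl)
    }
  }
  data.frame(species = m$species,
             RBL = m$trigonid_blade_length / m$m1_length,
             RUGA = sqrt(m$upper_grinding_area) / m$p4_length,
             JD_DL = m$jaw_depth / dl,
             dentary_imputed = imputed)
}

#' Fit per-subfamily dentary-length imputation models
#'
#' Least-squares fit of `log10(dentary_length)` on `log10(m1_length)`,
#' one model per subfamily (allometric convention; no pooling across
#' subfamilies). Needs at least 3 complete training species per
#' subfamily.
#'
#' @param training data.frame with `m1_length`, `dentary_length`,
#'   `subfamily`.
#' @param pooled_fallback if `TRUE`, subfamilies with fewer than 3
#'   complete training species fall back to a model pooled over all
#'   subfamilies instead of raising an error.
#' @return object of class `dentary_imputer` (named list of coefficient
#'   pairs), usable via `predict()`.
#' @export
fit_dentary_imputer <- function(training, pooled_fallback = FALSE) {
  stopifnot(all(c("m1_length", "dentary_length", "subfamily") %in%
                names(training)))
  ok <- stats::complete.cases(training[c("m1_length", "dentary_length")])
  training <- training[ok, ]
  fit1 <- function(d) {
    stats::coef(stats::lm(log10(dentary_length) ~ log10(m1_length),
                          data = d))
  }
  models <- lapply(split(training, training$subfamily), function(d) {
    if (nrow(d) < 3) {
      if (!pooled_fallback) {
        stop("need >= 3 training species with m1 and dentary lengths in ",
             "subfamily '", d$subfamily[1], "'")
      }
      return(NULL)   # resolved through the pooled model
    }
    fit1(d)
  })
  if (pooled_fallback && any(vapply(models, is.null, TRUE))) {
    if (nrow(training) < 3) stop("need >= 3 training species overall")
    pooled <- fit1(training)
    models <- lapply(models, function(m) m %||% pooled)
  }
  structure(models, class = "dentary_imputer")
}

#' @param object a `dentary_imputer`.
#' @param m1_length m1 lengths (mm) to predict from.
#' @param subfamily subfamily of each species.
#' @param ... unused.
#' @rdname fit_dentary_imputer
#' @export
predict.dentary_imputer <- function(object, m1_length, subfamily, ...) {
  out <- rep(NA_real_, length(m1_length))
  for (sf in names(object)) {
    i <- which(subfamily == sf)
    cf <- object[[sf]]
    out[i] <- 10^(cf[1] + cf[2] * log10(m1_length[i]))
  }
  out
}

#' Fit the carnivory index (correlation-matrix PCA on extant species)
#'
#' Standardizes RBL, RUGA and JD_DL by their training means and standard
#' deviations (equivalent to a PCA on the correlation matrix, chosen
#' because the ratios differ in scale by an order of magnitude) and
#' eigendecomposes the correlation matrix. PC1 is the carnivory index;
#' its sign is fixed so that RBL loads positively (more carnivorous to
#' the right). PC2 approximates durophagy. Diet-category labels are not
#' used in the fit; they are carried along for visualization only.
#'
#' @param extant data.frame with `species`, `RBL`, `RUGA`, `JD_DL` and
#'   optionally `diet_category`.
#' @return object of class `carnivory_model`: `center`, `scale`,
#'   `loadings` (orthonormal 3x3), `sdev`, `var_share`, `scores`
#'   (training PC scores), `recenter` (fossil median, 0 until
#'   [project_carnivory()] is run with `store_recenter = TRUE`).
#' @export
fit_carnivory_index <- function(extant) {
  ratios <- c("RBL", "RUGA", "JD_DL")
  stopifnot(all(ratios %in% names(extant)))
  X <- as.matrix(extant[, ratios])
  if (nrow(X) < 4) stop("need >= 4 extant species with all three ratios")
  if (anyNA(X)) stop("extant training ratios must be complete")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance ratio: correlation undefined")
  Z <- scale(X, center = ctr, scale = scl)
  eig <- eigen(stats::cor(X), symmetric = TRUE)
  L <- eig$vectors
  # sign convention: carnivory (PC1) increases with RBL; PC2 sign fixed
  # the same way for reproducibility
  for (j in 1:3) if (L[1, j] < 0) L[, j] <- -L[, j]
  rownames(L) <- ratios
  colnames(L) <- paste0("PC", 1:3)
  scores <- Z %*% L
  structure(list(center = ctr, scale = scl, loadings = L,
                 sdev = sqrt(pmax(eig$values, 0)),
                 var_share = eig$values / sum(eig$values),
                 scores = data.frame(species = extant$species,
                                     pc1 = scores[, 1], pc2 = scores[, 2],
                                     diet_category =
                                       extant$diet_category %||% NA),
                 recenter = 0),
            class = "carnivory_model")
}

#' Project fossil species onto the carnivory index
#'
#' Standardizes fossil ratios with the extant training means/sds and
#' multiplies by the training loading matrix. PC1 is re-centred by
#' subtracting the median PC1 of the projected set, so the returned
#' median carnivory is exactly zero; the constant is stored on the
#' returned model so later projections stay comparable. Species with any
#' missing ratio are excluded and reported.
#'
#' @param model a `carnivory_model`.
#' @param fossil data.frame with `species`, `RBL`, `RUGA`, `JD_DL`.
#' @param recenter `"fit"` (default) computes and stores the median from
#'   this set; `"stored"` reuses `model$recenter`; `"none"` skips
#'   recentring.
#' @return list: `scores` (data.frame `species`, `pc1`, `pc2`),
#'   `excluded` (species with missing ratios), `model` (with updated
#'   `recenter`).
#' @export
project_carnivory <- function(model, fossil, recenter = c("fit", "stored",
                                                          "none")) {
  recenter <- match.arg(recenter)
  stopifnot(inherits(model, "carnivory_model"))
  ratios <- c("RBL", "RUGA", "JD_DL")
  X <- as.matrix(fossil[, ratios])
  ok <- stats::complete.cases(X)
  excluded <- fossil$species[!ok]
  Z <- sweep(sweep(X[ok, , drop = FALSE], 2, model$center), 2, model$scale,
             "/")
  S <- Z %*% model$loadings
  shift <- switch(recenter,
                  fit = stats::median(S[, 1]),
                  stored = model$recenter,
                  none = 0)
  if (recenter == "fit") model$recenter <- shift
  list(scores = data.frame(species = fossil$species[ok],
                           pc1 = S[, 1] - shift, pc2 = S[, 2]),
       excluded = excluded, model = model)
}

#' Serialize / restore a carnivory model as YAML
#'
#' @param model a `carnivory_model`.
#' @param path file path.
#' @return `read_carnivory_model` returns the restored model.
#' @export
write_carnivory_model <- function(model, path) {
  yaml::write_yaml(list(center = as.list(model$center),
                        scale = as.list(model$scale),
                        loadings = apply(model$loadings, 2, as.list),
                        sdev = model$sdev,
                        var_share = model$var_share,
                        recenter = model$recenter), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_carnivory_model
#' @export
read_carnivory_model <- function(path) {
  y <- yaml::read_yaml(path)
  L <- sapply(y$loadings, function(col) unlist(col))
  rownames(L) <- names(y$center)
  structure(list(center = unlist(y$center), scale = unlist(y$scale),
                 loadings = L, sdev = unlist(y$sdev),
                 var_share = unlist(y$var_share), scores = NULL,
                 recenter = y$recenter),
            class = "carnivory_model")
}

#' Classify diet from percentage of meat
#'
#' Hypocarnivore: less than 50% meat; mesocarnivore: 50-70% (inclusive);
#' hypercarnivore: more than 70%.
#'
#' @param percent_meat numeric in `[0, 100]` (vectorized).
#' @return character vector of categories.
#' @export
classify_diet <- function(percent_meat) {
  if (any(percent_meat < 0 | percent_meat > 100 | is.na(percent_meat))) {
    stop("percent_meat must be in [0, 100]")
  }
  ifelse(percent_meat < 50, "hypocarnivore",
         ifelse(percent_meat <= 70, "mesocarnivore", "hypercarnivore"))
}
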