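test_that("body-mass regression obeys the log-log form", {
  # inverse-transform consistency at the published summary value
  expect_equal(10^0.971, 9.354, tolerance = 1e-4)
  expect_equal(estimate_body_mass(7, list(a = 0, b = 0))$mass_kg, 1)
  expect_equal(estimate_body_mass(10, list(a = 0, b = 1))$mass_kg, 10)
  expect_error(estimate_body_mass(-1), "positive")
})

test_that("dietary ratios follow their definitions", {
  m <- data.frame(species = c("x", "y", "z"),
                  m1_length = c(20, 20, 10),
                  trigonid_blade_length = c(12, 20, 10),
                  upper_grinding_area = c(36, 144, 144),
                  p4_length = c(12, 12, 12),
                  jaw_depth = c(18, 18, 18),
                  dentary_length = c(120, 120, 120))
  r <- compute_dietary_ratios(m)
  expect_equal(r$RBL, c(0.6, 1, 1))          # fully trenchant molar -> 1
  expect_equal(r$RUGA, c(0.5, 1, 1))         # area = p4^2 -> 1
  expect_equal(r$JD_DL, rep(0.15, 3))
  expect_false(any(r$dentary_imputed))

  # missing dentary without imputer: flagged NA, never fabricated
  m$dentary_length[2] <- NA
  r2 <- compute_dietary_ratios(m)
  expect_true(is.na(r2$JD_DL[2]))
  expect_error(compute_dietary_ratios(transform(m,
    trigonid_blade_length = m1_length + 1)), "blade")
})

test_that("dentary imputer fits per-subfamily log-log models", {
  # exact log-linear data is reproduced to numerical precision
  tr <- data.frame(m1_length = rep(c(5, 10, 20, 30), 2),
                   subfamily = rep(c("A", "B"), each = 4))
  tr$dentary_length <- ifelse(tr$subfamily == "A",
                              10^(0.9 + 1.1 * log10(tr$m1_length)),
                              10^(0.5 + 0.8 * log10(tr$m1_length)))
  imp <- fit_dentary_imputer(tr)
  pred <- predict(imp, tr$m1_length, tr$subfamily)
  expect_equal(pred, tr$dentary_length, tolerance = 1e-10)
  # no pooling: each subfamily keeps its own slope
  expect_equal(unname(imp$A[2]), 1.1, tolerance = 1e-10)
  expect_equal(unname(imp$B[2]), 0.8, tolerance = 1e-10)
  expect_error(fit_dentary_imputer(tr[c(1, 5, 6, 7), ]), ">= 3")
})

test_that("dentary imputer recovers coefficients from noisy data", {
  set.seed(21)
  n <- 50
  m1 <- runif(n, 5, 30)
  dl <- 10^(0.9 + 1.1 * log10(m1) + rnorm(n, 0, 0.03))
  imp <- fit_dentary_imputer(data.frame(m1_length = m1, dentary_length = dl,
                                        subfamily = "A"))
  fit <- lm(log10(dl) ~ log10(m1))
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(imp$A[1] - 0.9), 3 * se[1])
  expect_lt(abs(imp$A[2] - 1.1), 3 * se[2])
})

test_that("carnivory index equals an independent PCA oracle up to sign", {
  ext <- simulate_extant_morphoset(seed = 31)
  model <- fit_carnivory_index(ext)
  # oracle: prcomp on the correlation-standardized ratios
  pr <- prcomp(ext[, c("RBL", "RUGA", "JD_DL")], center = TRUE,
               scale. = TRUE)
  for (j in 1:2) {
    s <- sign(sum(pr$rotation[, j] * model$loadings[, j]))
    expect_equal(unname(model$scores[[paste0("pc", j)]]),
                 unname(s * pr$x[, j]), tolerance = 1e-8)
  }
  expect_gt(model$loadings["RBL", 1], 0)   # sign convention
  # loadings orthonormal, variance shares sum to 1
  expect_equal(crossprod(model$loadings), diag(3), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(sum(model$var_share), 1)
})

test_that("duplicated ratio pair gives PC1 variance share 2/3", {
  set.seed(5)
  n <- 40
  r1 <- rnorm(n)
  r3 <- resid(lm(rnorm(n) ~ r1))   # exactly uncorrelated with r1 in-sample
  d <- data.frame(species = paste0("s", 1:n), RBL = r1, RUGA = r1,
                  JD_DL = r3)
  model <- fit_carnivory_index(d)
  expect_equal(model$var_share[1], 2 / 3, tolerance = 1e-8)
})

test_that("hyaenid-like morphologies score highest on the carnivory axis", {
  ext <- simulate_extant_morphoset(seed = 41)
  model <- fit_carnivory_index(ext)
  sc <- model$scores
  top <- sc$species[order(-sc$pc1)][1:3]
  expect_true(all(grepl("^hyae", top)))
  # centroid separation: hypercarnivore side positive
  expect_gt(mean(sc$pc1[sc$diet_category == "hypercarnivore"]),
            mean(sc$pc1[sc$diet_category == "hypocarnivore"]))
})

test_that("fossil projection is the training projection plus recentring", {
  ext <- simulate_extant_morphoset(seed = 51)
  model <- fit_carnivory_index(ext)
  # projecting the training set itself reproduces training scores
  proj <- project_carnivory(model, ext, recenter = "none")
  expect_equal(proj$scores$pc1, model$scores$pc1, tolerance = 1e-10)
  expect_equal(proj$scores$pc2, model$scores$pc2, tolerance = 1e-10)
  # recentred median is exactly zero
  proj2 <- project_carnivory(model, ext, recenter = "fit")
  expect_identical(median(proj2$scores$pc1), 0)
  # shifting along the PC1 loading in standardized space shifts all PC1
  # scores by delta before recentring (linearity)
  delta <- 0.7
  shifted <- ext
  shift_raw <- delta * model$loadings[, 1] * model$scale
  shifted$RBL <- ext$RBL + shift_raw["RBL"]
  shifted$RUGA <- ext$RUGA + shift_raw["RUGA"]
  shifted$JD_DL <- ext$JD_DL + shift_raw["JD_DL"]
  proj3 <- project_carnivory(model, shifted, recenter = "none")
  expect_equal(proj3$scores$pc1, model$scores$pc1 + delta,
               tolerance = 1e-10)
  # species with a missing ratio are excluded and reported
  holey <- ext; holey$RUGA[3] <- NA
  proj4 <- project_carnivory(model, holey, recenter = "fit")
  expect_identical(proj4$excluded, ext$species[3])
  expect_equal(nrow(proj4$scores), nrow(ext) - 1L)
})

test_that("carnivory model round-trips through YAML", {
  ext <- simulate_extant_morphoset(seed = 61)
  model <- fit_carnivory_index(ext)
  model <- project_carnivory(model, ext, recenter = "fit")$model
  path <- tempfile(fileext = ".yml")
  write_carnivory_model(model, path)
  back <- read_carnivory_model(path)
  expect_equal(back$center, model$center, tolerance = 1e-12)
  expect_equal(unname(back$loadings), unname(model$loadings),
               tolerance = 1e-12)
  expect_equal(back$recenter, model$recenter, tolerance = 1e-12)
})

test_that("diet categories follow the meat-percentage cutoffs", {
  expect_identical(classify_diet(c(45, 60, 80)),
                   c("hypocarnivore", "mesocarnivore", "hypercarnivore"))
  expect_identical(classify_diet(c(50, 70)),
                   c("mesocarnivore", "mesocarnivore"))
  expect_error(classify_diet(101), "0, 100")
})
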