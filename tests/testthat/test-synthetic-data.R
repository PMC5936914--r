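test_that("pure-birth trees are ultrametric with all tips extant", {
  res <- simulate_tree(sim_config(seed = 3, n_tips = 8, birth_rate = 0.3,
                                  death_rate = 0))
  expect_true(ape::is.ultrametric(res$tree, tol = 1e-8))
  expect_true(all(res$history$extant))
  expect_true(all(res$history$te == 0))
})

test_that("tree simulation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_tips = 15, birth_rate = 0.3,
                    death_rate = 0.15)
  a <- simulate_tree(cfg)
  b <- simulate_tree(cfg)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  expect_identical(a$history, b$history)
})

test_that("tree history is consistent with tip depths and tip count", {
  res <- random_bd_tree(25, seed = 7, birth = 0.3, death = 0.15)
  expect_equal(length(res$tree$tip.label), 25L)
  d <- ape::node.depth.edgelength(res$tree)[1:25]
  expect_equal(res$present - d, res$history$te, tolerance = 1e-9)
  expect_true(all(res$history$ts >= res$history$te))
  expect_true(all(res$history$te[!res$history$extant] > 0))
})

test_that("forward birth-death lineage count matches the closed form", {
  set.seed(11)
  birth <- 0.3; death <- 0.15; t_max <- 8
  n_rep <- 1000L
  counts <- replicate(n_rep, sim_bd_forward(birth, death, t_max))
  expect_equal(mean(counts), exp((birth - death) * t_max),
               tolerance = 3 * stats::sd(counts) / sqrt(n_rep) /
                 exp((birth - death) * t_max))
})

test_that("trait simulator matches the analytic law (BM, OU, Drift)", {
  # BM on a two-tip root divergence: tips iid Normal(z0, sigma2 * depth)
  tr <- two_tip_tree(1, 1)
  x <- simulate_trait(tr, model_spec("BM", z0 = 2, sigma2 = 1),
                      seed = 1, nsim = 20000)
  expect_equal(mean(x), 2, tolerance = 0.05)
  expect_equal(var(as.vector(x[, 1])), 1, tolerance = 0.05)
  expect_lt(abs(cor(x[, 1], x[, 2])), 0.05)

  # OU far past relaxation: tip variance ~ sigma2 / (2 alpha)
  tr2 <- two_tip_tree(10, 10)
  a <- 0.6   # alpha * depth = 6 >= 5
  xo <- simulate_trait(tr2, model_spec("OU", z0 = 0, sigma2 = 2,
                                       alpha = a), seed = 2, nsim = 5000)
  expect_equal(var(xo[, 1]), 2 / (2 * a), tolerance = 0.1 * 2 / (2 * a))

  # Drift: regression of tip value on root-to-tip time recovers mu
  res <- random_bd_tree(60, seed = 12, birth = 0.35, death = 0.2)
  mu <- 0.5
  xd <- simulate_trait(res$tree, model_spec("Drift", z0 = 0, sigma2 = 0.05,
                                            mu_drift = mu), seed = 3)
  Tt <- diag(phylo_cov(res$tree))[names(xd)]
  slope <- coef(lm(xd ~ Tt))[2]
  expect_equal(unname(slope), mu, tolerance = 0.25)
})

test_that("trait sample moments match model_mean_cov over replicates", {
  tr <- five_tip_tree()
  spec <- model_spec("ACDC", z0 = 1, sigma2 = 0.8, r = -0.3)
  mc <- model_mean_cov(tr, spec)
  x <- simulate_trait(tr, spec, seed = 9, nsim = 5000)
  expect_equal(unname(colMeans(x)), unname(mc$mean), tolerance = 0.08)
  expect_equal(unname(cov(x)), unname(mc$cov), tolerance = 0.12)
})

test_that("fossil record respects true ranges, extent, and Poisson law", {
  cfg <- sim_config(seed = 8, n_tips = 30, birth_rate = 0.3,
                    death_rate = 0.2, preservation_rate_q = 1.5)
  res <- simulate_tree(cfg)
  occ <- simulate_fossil_record(res$history, cfg)
  mid <- (occ$max_age + occ$min_age) / 2
  true_age <- mid  # reconstruct true age bounds from the history
  for (i in seq_len(nrow(occ))) {
    h <- res$history[res$history$species == occ$species[i], ]
    expect_lte(occ$min_age[i], h$ts)       # interval overlaps [te, ts]
    expect_gte(occ$max_age[i], h$te)
  }
  ext <- cfg$grid_extent
  expect_true(all(occ$lat >= ext[1] & occ$lat <= ext[2]))
  expect_true(all(occ$lon >= ext[3] & occ$lon <= ext[4]))

  # Poisson mean: duration 6, q = 1 -> mean count 6 over 10000 reps
  hist1 <- data.frame(species = "A", ts = 8, te = 2, extant = FALSE)
  counts <- vapply(1:10000, function(s) {
    cfg1 <- sim_config(seed = s, preservation_rate_q = 1)
    nrow(simulate_fossil_record(hist1, cfg1))
  }, 0)
  expect_equal(mean(counts), 6, tolerance = 3 * sd(counts) / sqrt(10000))

  # zero duration -> zero occurrences
  hist0 <- data.frame(species = "A", ts = 5, te = 5, extant = FALSE)
  expect_equal(nrow(simulate_fossil_record(hist0, cfg)), 0L)
})

test_that("dense preservation places the oldest occurrence near TS", {
  hist1 <- data.frame(species = "A", ts = 12, te = 2, extant = FALSE)
  hits <- vapply(1:200, function(s) {
    cfg <- sim_config(seed = s, preservation_rate_q = 100, dating_sd = 0)
    occ <- simulate_fossil_record(hist1, cfg)
    max(occ$max_age) >= 12 - 0.1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("extant morphoset honors centroids and category structure", {
  exact <- simulate_extant_morphoset(noise_sd = 0, seed = 1)
  ctr <- default_diet_centroids()
  for (cat in unique(exact$diet_category)) {
    rows <- exact[exact$diet_category == cat, ]
    expect_equal(unname(as.matrix(rows[, c("RBL", "RUGA", "JD_DL")])),
                 matrix(ctr[[cat]], nrow(rows), 3, byrow = TRUE),
                 tolerance = 1e-12)
  }
  # dropping a category leaves the others untouched
  full <- simulate_extant_morphoset(seed = 2)
  part <- simulate_extant_morphoset(n_per_category = c(hypocarnivore = 12,
                                                       mesocarnivore = 18,
                                                       hypercarnivore = 12,
                                                       hyaenid_like = 0),
                                    seed = 2)
  expect_false("hyaenid_like" %in% part$diet_category)
  expect_equal(part, full[full$diet_category != "hyaenid_like", ],
               ignore_attr = TRUE)
})
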