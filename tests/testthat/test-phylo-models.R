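test_that("phylogenetic covariance follows shared path lengths", {
  expect_equal(unname(phylo_cov(two_tip_tree(5, 5))),
               matrix(c(5, 0, 0, 5), 2))
  Ch <- phylo_cov(cherry_tree())[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(Ch),
               matrix(c(5, 3, 0, 3, 7, 0, 0, 0, 5), 3))
  # lambda transform: 0 -> diagonal of tip depths; 1 -> identity
  C0 <- phylo_cov(cherry_tree(), lambda = 0)
  expect_equal(unname(C0), diag(diag(Ch))[order(c(1, 2, 3)), ],
               ignore_attr = TRUE)
  expect_equal(phylo_cov(cherry_tree(), lambda = 1),
               phylo_cov(cherry_tree()))
  bad <- cherry_tree(); bad$edge.length[1] <- -1
  expect_error(phylo_cov(bad), "negative")
})

test_that("boundary parameters collapse every model to Brownian motion", {
  tr <- five_tip_tree()
  C <- phylo_cov(tr)
  bm <- model_mean_cov(tr, model_spec("BM", z0 = 1, sigma2 = 2))
  expect_equal(bm$cov, 2 * C)
  ou0 <- model_mean_cov(tr, model_spec("OU", z0 = 1, sigma2 = 2,
                                       alpha = 1e-10))
  expect_equal(ou0$cov, bm$cov, tolerance = 1e-6)
  ac0 <- model_mean_cov(tr, model_spec("ACDC", z0 = 1, sigma2 = 2, r = 0))
  expect_equal(ac0$cov, bm$cov, tolerance = 1e-8)
  tr0 <- model_mean_cov(tr, model_spec("Trend", z0 = 1, sigma2 = 2,
                                       b_rate = 0))
  expect_equal(tr0$cov, bm$cov, tolerance = 1e-10)
  dv0 <- model_mean_cov(tr, model_spec("Div", z0 = 1, sigma2 = 2, psi = 0))
  expect_equal(dv0$cov, bm$cov, tolerance = 1e-10)
  dr <- model_mean_cov(tr, model_spec("Drift", z0 = 1, sigma2 = 2,
                                      mu_drift = 0))
  expect_equal(dr$cov, bm$cov)
  expect_equal(dr$mean, bm$mean)
})

test_that("Div covariance matches a hand integral on a two-tip tree", {
  # (a:3,b:3); n(t) = 2 on (0, 3]; variance = int_0^3 (s2 + psi*2) dt
  tr <- two_tip_tree(3, 3)
  mc <- model_mean_cov(tr, model_spec("Div", z0 = 0, sigma2 = 1,
                                      psi = 0.25))
  expect_equal(diag(mc$cov), c(a = 3 * (1 + 0.25 * 2),
                               b = 3 * (1 + 0.25 * 2)))
  expect_equal(mc$cov[1, 2], 0)
  # cherry ((a:2,b:4):3,c:5): n = 2 on (0,3], 3 on (3, 7]
  trc <- cherry_tree()
  mcc <- model_mean_cov(trc, model_spec("Div", z0 = 0, sigma2 = 1,
                                        psi = 0.1))
  C <- phylo_cov(trc)
  # shared a-b time 3: integral n = 2*3 = 6
  expect_equal(mcc$cov["a", "b"], C["a", "b"] + 0.1 * 6)
  # tip a depth 5: integral n = 2*3 + 3*2 = 12
  expect_equal(mcc$cov["a", "a"], 5 + 0.1 * 12)
  # tip b depth 7: a and c are extinct at age 5, so n = 2 on (0,3],
  # 3 on (3,5], 1 on (5,7]: integral = 6 + 6 + 2 = 14
  expect_equal(mcc$cov["b", "b"], 7 + 0.1 * 14)
})

test_that("Drift and Trend mean/covariance structure is as specified", {
  tr <- cherry_tree()
  Tv <- diag(phylo_cov(tr))
  mc <- model_mean_cov(tr, model_spec("Drift", z0 = 1, sigma2 = 0.5,
                                      mu_drift = 0.3))
  expect_equal(mc$mean, 1 + 0.3 * Tv)
  mct <- model_mean_cov(tr, model_spec("Trend", z0 = 0, sigma2 = 1,
                                       b_rate = 0.2))
  C <- phylo_cov(tr)
  expect_equal(mct$cov, C + 0.2 * C^2 / 2)
  expect_error(model_mean_cov(tr, model_spec("Trend", z0 = 0, sigma2 = 1,
                                             b_rate = -1)), "negative")
})

test_that("all six likelihoods agree with a dense MVN oracle", {
  trees <- list(five_tip_tree(), cherry_tree())
  specs <- list(
    model_spec("BM", z0 = 0.5, sigma2 = 1.2),
    model_spec("OU", z0 = 0.5, sigma2 = 1.2, alpha = 0.4),
    model_spec("ACDC", z0 = 0.5, sigma2 = 1.2, r = -0.25),
    model_spec("Trend", z0 = 0.5, sigma2 = 1.2, b_rate = 0.3),
    model_spec("Drift", z0 = 0.5, sigma2 = 1.2, mu_drift = 0.4),
    model_spec("Div", z0 = 0.5, sigma2 = 1.2, psi = 0.2))
  for (tr in trees) {
    x <- simulate_trait(tr, specs[[1]], seed = 4)
    for (spec in specs) {
      mc <- model_mean_cov(tr, spec)
      expect_equal(trait_loglik(tr, x, spec),
                   mvn_loglik_dense(x[colnames(mc$cov)], mc$mean, mc$cov),
                   tolerance = 1e-9)
    }
  }
  # single tip: plain normal density
  one <- ape::read.tree(text = "(a:2);")
  x1 <- c(a = 1.3)
  expect_equal(trait_loglik(one, x1, model_spec("BM", z0 = 1, sigma2 = 2)),
               dnorm(1.3, 1, sqrt(2 * 2), log = TRUE))
})

test_that("boundary fits reproduce the BM log-likelihood", {
  tr <- five_tip_tree()
  x <- simulate_trait(tr, model_spec("BM", z0 = 0, sigma2 = 1), seed = 5)
  ll_bm <- trait_loglik(tr, x, model_spec("BM", z0 = 0.2, sigma2 = 0.9))
  for (spec in list(model_spec("OU", z0 = 0.2, sigma2 = 0.9, alpha = 0),
                    model_spec("ACDC", z0 = 0.2, sigma2 = 0.9, r = 0),
                    model_spec("Trend", z0 = 0.2, sigma2 = 0.9, b_rate = 0),
                    model_spec("Drift", z0 = 0.2, sigma2 = 0.9,
                               mu_drift = 0),
                    model_spec("Div", z0 = 0.2, sigma2 = 0.9, psi = 0))) {
    expect_equal(trait_loglik(tr, x, spec), ll_bm, tolerance = 1e-6)
  }
})

test_that("BM maximum-likelihood estimates match the closed form", {
  res <- random_bd_tree(30, seed = 33)
  x <- simulate_trait(res$tree, model_spec("BM", z0 = 2, sigma2 = 0.5),
                      seed = 6)
  fit <- fit_trait_model(res$tree, x, "BM")
  C <- phylo_cov(res$tree)[names(x), names(x)]
  Ci <- solve(C)
  one <- rep(1, length(x))
  z0 <- drop(t(one) %*% Ci %*% x) / drop(t(one) %*% Ci %*% one)
  s2 <- drop(t(x - z0) %*% Ci %*% (x - z0)) / length(x)
  expect_equal(fit$params$z0, z0, tolerance = 1e-6)
  expect_equal(fit$params$sigma2, s2, tolerance = 1e-6)
  expect_equal(fit$aicc, -2 * fit$loglik + 4 + 12 / (length(x) - 3),
               tolerance = 1e-10)
})

test_that("richer models never drop below BM at their MLEs (nesting)", {
  res <- random_bd_tree(40, seed = 44)
  x <- simulate_trait(res$tree, model_spec("BM", z0 = 0, sigma2 = 1),
                      seed = 7)
  tab <- compare_trait_models(res$tree, x)
  ll_bm <- tab$loglik[tab$model == "BM"]
  for (m in c("OU", "ACDC", "Trend", "Drift", "Div")) {
    expect_gte(tab$loglik[tab$model == m], ll_bm - 1e-6)
  }
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  # AICc difference decomposes into the LRT statistic minus the exact
  # small-sample penalty difference
  n <- 40
  pen <- function(k) 2 * k + 2 * k * (k + 1) / (n - k - 1)
  d_aicc <- tab$aicc[tab$model == "ACDC"] - tab$aicc[tab$model == "BM"]
  lrt <- 2 * (tab$loglik[tab$model == "ACDC"] - ll_bm)
  expect_equal(d_aicc, pen(3) - pen(2) - lrt, tolerance = 1e-10)
})

test_that("AICc weights match the published worked example", {
  aicc <- c(368.7387, 373.5720, 369.8013, 364.6341, 362.9215)
  w <- aicc_weights(aicc = aicc)$weight
  expect_equal(w, c(0.0360, 0.0032, 0.0212, 0.2801, 0.6595),
               tolerance = 5e-4)
  expect_equal(aicc_weights(loglik = -10, k = 2, n = 20)$aicc,
               20 + 4 + 12 / 17)
  expect_equal(aicc_weights(aicc = 100)$weight, 1)
  expect_error(aicc_weights(aicc = numeric(0)), "empty")
})

test_that("posterior-sample model selection is consistent under pruning", {
  res <- random_bd_tree(25, seed = 55)
  x <- simulate_trait(res$tree, model_spec("BM", z0 = 0, sigma2 = 1),
                      seed = 8)
  # identical trees: median weights equal the single-tree weights
  trees <- structure(list(res$tree, res$tree, res$tree),
                     class = "multiPhylo")
  fm <- fit_over_posterior(trees, x, models = c("BM", "OU", "Drift"))
  single <- compare_trait_models(res$tree, x, c("BM", "OU", "Drift"))
  expect_equal(unname(fm$median_weight), single$weight, tolerance = 1e-10)
  # pruning to a subset then fitting equals fitting the subset trait
  keep <- names(x)[1:12]
  fm_sub <- fit_over_posterior(trees[1], x[keep],
                               models = c("BM", "OU", "Drift"))
  sub_tree <- ape::keep.tip(res$tree, keep)
  direct <- compare_trait_models(sub_tree, x[keep], c("BM", "OU", "Drift"))
  expect_equal(unname(fm_sub$median_weight), direct$weight,
               tolerance = 1e-8)
})
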