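test_that("Gelman standardization halves the scale and round-trips", {
  d <- data.frame(x = rnorm(50, 10, 3), b = rbinom(50, 1, 0.4), k = 1)
  std <- standardize_predictors(d, c("x", "b"))
  expect_equal(mean(std$data$x), 0)
  expect_equal(sd(std$data$x), 0.5)
  expect_identical(std$data$b, d$b)   # binary indicators untouched
  expect_equal(unstandardize(std$scaling, "x", std$data$x), d$x)
  expect_error(standardize_predictors(d, "k"), "'k' is constant")
})

test_that("AICc follows the closed form and its guards", {
  expect_equal(aicc(logL = -100, k = 3, n = 50), 206.5217, tolerance = 1e-4)
  ## large-n limit is plain AIC
  expect_equal(aicc(logL = -100, k = 3, n = 1e8), 206, tolerance = 1e-5)
  expect_error(aicc(logL = -100, k = 3, n = 4), "AICc undefined")
})

test_that("sub-model enumeration respects marginality", {
  td <- mhcassoc:::divergence_terms(list(g = c("F", "M")))
  subsets <- enumerate_submodels(td$optional, td$deps)
  expect_length(subsets, 13)
  ## independent brute-force: explicit rule check over all 32 subsets
  all_sub <- unlist(lapply(0:31, function(m)
    list(td$optional[bitwAnd(m, 2^(0:4)) > 0])), recursive = FALSE)
  valid <- Filter(function(s) {
    q_ok <- (!"I(F^2)" %in% s || "F" %in% s) && (!"I(M^2)" %in% s || "M" %in% s)
    i_ok <- !"F:M" %in% s || all(c("F", "M") %in% s)
    q_ok && i_ok
  }, all_sub)
  expect_length(valid, 13)
  expect_setequal(vapply(subsets, paste, "", collapse = "+"),
                  vapply(valid, paste, "", collapse = "+"))
  ## no optional terms: exactly the null model
  expect_identical(enumerate_submodels(character(0)), list(character(0)))
  ## the two-parent-set (cross-fostered) enumeration gives 13^2 models
  td2 <- mhcassoc:::divergence_terms(list(g = c("gF", "gM"),
                                          s = c("sF", "sM")))
  expect_length(enumerate_submodels(td2$optional, td2$deps), 169)
})

test_that("model averaging reproduces the Akaike-weight algebra", {
  ## two models of equal k with delta-AICc (0, 2): weights exp(0), exp(-1)
  f1 <- fake_fit(-50, c(`(Intercept)` = 0.2, x = 1.0), c(0.1, 0.3))
  f2 <- fake_fit(-51, c(`(Intercept)` = 0.25), c(0.1), k = 2)
  avg <- model_average(list(m1 = f1, m2 = f2), delta_cutoff = 2)
  w <- avg$weights
  expect_equal(unname(w), c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(sum(w), 1)
  expect_equal(avg$model_selection$delta[1], 0)
  ## full averaging: x absent from m2 contributes 0
  cf <- avg$coefficients
  bx <- cf$estimate[cf$term == "x"]
  expect_equal(bx, unname(w["m1"]) * 1.0)
  ## Burnham-Anderson unconditional SE, hand-computed
  se_hand <- w["m1"] * sqrt(0.3^2 + (1.0 - bx)^2) +
    w["m2"] * sqrt(0 + (0 - bx)^2)
  expect_equal(cf$se_unc[cf$term == "x"], unname(se_hand))
  ## shrinkage: averaged magnitude never exceeds the largest per-model one
  expect_lte(abs(bx), 1.0)
  ## equal-support pair: beta = 1 in a weight-0.5 model, absent elsewhere
  g2 <- fake_fit(-50, c(`(Intercept)` = 0.25), c(0.1), k = 2)
  avg2 <- model_average(list(a = f1, b = g2))
  expect_equal(avg2$coefficients$estimate[avg2$coefficients$term == "x"], 0.5)
  ## single retained model: averaging is the identity
  avg3 <- model_average(list(only = f1))
  expect_equal(coef(avg3), f1$beta)
  expect_equal(avg3$coefficients$se_unc, unname(f1$se))
})

test_that("a mixed fit with null variance components equals the GLM", {
  set.seed(31)
  n <- 300
  d <- data.frame(x = rnorm(n, 0, 0.5), g = factor(sample(1:25, n, TRUE)),
                  clutch = rpois(n, 6) + 1L)
  d$fled <- rbinom(n, d$clutch, plogis(0.3 - 0.5 * d$x))   # no group effect
  fm <- fit_glmm(cbind(fled, clutch - fled) ~ x + (1 | g), d, "binomial")
  fg <- stats::glm(cbind(fled, clutch - fled) ~ x, binomial, d)
  expect_lt(max(abs(fm$beta - coef(fg))), 1e-4)
  ## a bar-free formula takes the GLM path exactly
  f0 <- fit_glmm(cbind(fled, clutch - fled) ~ x, d, "binomial")
  expect_equal(f0$beta, coef(fg))
  ## Poisson intercept recovers the log mean
  dp <- data.frame(y = rpois(2000, 6), g = factor(sample(1:10, 2000, TRUE)))
  fp <- fit_glmm(y ~ (1 | g), dp, "poisson")
  expect_equal(unname(fp$beta[1]), log(mean(dp$y)), tolerance = 0.05)
})

test_that("Benjamini-Hochberg adjustment matches the step-up construction", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(8)
  for (r in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- p.adjust(p, "BH")
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("variance inflation factors follow the closed form", {
  set.seed(12)
  n <- 500
  z1 <- rnorm(n); z2 <- rnorm(n)
  X <- cbind(a = z1, b = z2)   # independent
  v <- vif_check(X)
  expect_true(all(abs(v - 1) < 0.05))
  r <- 0.8
  X2 <- cbind(a = z1, b = r * z1 + sqrt(1 - r^2) * z2)
  v2 <- vif_check(X2)
  r_emp <- cor(X2[, 1], X2[, 2])
  expect_equal(unname(v2["a"]), 1 / (1 - r_emp^2), tolerance = 1e-8)
  expect_error(vif_check(cbind(a = z1, b = z1)), "collinearity")
})

test_that("EMM contrasts equal cell means and odds ratios on a 2x2 design", {
  set.seed(77)
  cells <- expand.grid(f = c("0", "1"), m = c("0", "1"))
  d <- cells[rep(1:4, each = 60), ]
  p <- c(0.5, 0.7, 0.4, 0.8)[rep(1:4, each = 60)]
  d$clutch <- 6L
  d$fled <- rbinom(nrow(d), d$clutch, p)
  d$f <- factor(d$f); d$m <- factor(d$m)
  fit <- fit_glmm(cbind(fled, clutch - fled) ~ f * m, d, "binomial")
  ct <- emm_contrasts(fit, c("f", "m"))
  ## saturated balanced model: EMMs are the observed cell logits
  obs <- vapply(1:4, function(i) {
    rows <- d$f == cells$f[i] & d$m == cells$m[i]
    qlogis(sum(d$fled[rows]) / sum(d$clutch[rows]))
  }, numeric(1))
  emm <- ct$emmeans
  got <- emm$emmean[order(emm$f, emm$m)]
  expect_equal(got, obs[order(cells$f, cells$m)], tolerance = 1e-6)
  ## the six pairwise contrasts are the six pairwise logit differences,
  ## and odds ratios exponentiate them
  diffs_hand <- sort(abs(as.vector(apply(utils::combn(4, 2), 2,
                                         function(p) obs[p[1]] - obs[p[2]]))))
  expect_equal(sort(abs(ct$contrasts$estimate)), diffs_hand,
               tolerance = 1e-6)
  expect_equal(ct$contrasts$odds_ratio, exp(ct$contrasts$estimate))
})

test_that("the divergence analysis guards small and aliased datasets", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 60, seed = 2)
  div <- divergence_table(geno, pool_alignment(pool))
  nests <- simulate_breeding(geno, div, effect_config(), n_nests = 20,
                             crossfoster_plan = "none", seed = 3)
  expect_error(run_divergence_analysis(nests, div, "DAB2", "fledging", "full"),
               "underpowered")
  ## cross-fostered mode with aliased parent sets drops the social terms
  nests2 <- simulate_breeding(geno, div, effect_config(), n_nests = 80,
                              crossfoster_plan = "none", seed = 4)
  nests2$crossfoster <- "full"   # labelled full but never swapped
  expect_message(
    avg <- run_divergence_analysis(nests2, div, "DAB2", "fledging",
                                   "crossfostered", include_quadratics = FALSE,
                                   include_interactions = FALSE, nAGQ = 0),
    "dropping social-parent terms")
  expect_false(any(grepl("social", avg$coefficients$term)))
})

test_that("an injected supertype interaction is detected and contrasted", {
  pool <- small_pool()
  geno <- simulate_population(list(DAB2 = pool), 300, seed = 2)
  div <- divergence_table(geno, pool_alignment(pool))
  dm <- build_descriptor_matrix(pool_alignment(pool)[["DAB2"]],
                                pool$spec$selected_sites)
  asg <- assign_supertypes(dm, 10, seed = 1)
  sf <- supertype_frequencies(asg, geno)
  st <- names(sort(sf$frequencies, decreasing = TRUE))[1]
  eff <- effect_config(supertype_effects =
                         setNames(list(c(0, 0, 1.8)), st))
  hits <- 0
  for (r in 1:5) {
    nests <- simulate_breeding(geno, div, eff, n_nests = 250,
                               crossfoster_plan = "none",
                               supertype_presence = sf$presence,
                               effect_locus = "DAB2", seed = 100 + r)
    tests <- run_supertype_analysis(nests, sf$presence,
                                    supertypes = filter_common_supertypes(
                                      sf$frequencies),
                                    response = "fledging", mode = "full",
                                    nAGQ = 0)
    row <- tests[tests$supertype == st & grepl(":", tests$term), ]
    if (nrow(row) && row$significant) {
      hits <- hits + 1
      expect_gt(row$beta, 0)
    }
  }
  expect_gte(hits, 3)
})
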