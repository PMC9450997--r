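test_that("effect sizes follow the pooled-SD mean-difference formulas", {
  e0 <- effect_size(5, 5, 1, 1, 3, 3)
  expect_equal(e0$es, 0)
  e1 <- effect_size(10, 8, sd_t = 2, sd_c = 4, n1 = 3, n2 = 3)
  expect_equal(e1$s_pooled, sqrt(10), tolerance = 1e-12) # ((2*4)+(2*16))/4
  e2 <- effect_size(1, 0, sd_t = sqrt(10), sd_c = sqrt(10), n1 = 4, n2 = 4)
  expect_equal(e2$v, 5) # (8/16) * 10
  expect_equal(e2$se_d, sqrt(5))
  expect_error(effect_size(1, 0, 1, 1, 1, 1), class = "nrimpact_domain_error")
  expect_error(effect_size(1, 0, 0, 0, 3, 3), class = "nrimpact_zero_variance")
})

test_that("DerSimonian-Laird tau2 matches hand computation and limits", {
  expect_equal(tau2_dl(rep(2.5, 6), rep(1, 6)), 0) # identical effects: Q <= df
  expect_equal(tau2_dl(c(-1, 1), c(1, 1)), 1) # Q = 2, C = 1
  set.seed(42)
  es <- rnorm(30, 0, 2)
  v <- runif(30, 0.5, 1.5)
  t_base <- tau2_dl(es, v)
  # pure-noise studies with enormous variance barely move the estimate
  t_noisy <- tau2_dl(c(es, rnorm(5, 0, 50)), c(v, rep(1e6, 5)))
  expect_equal(t_noisy, t_base, tolerance = 0.05)
  expect_error(tau2_dl(1, 1), class = "nrimpact_insufficient_studies")
})

test_that("pooling reproduces closed-form cases and reduces to fixed effect", {
  expect_equal(pool_effects(3.2, 0.5)$es_bar, 3.2) # k = 1
  p_eq <- pool_effects(c(1, 2, 6), rep(2, 3), tau2 = 0.7)
  expect_equal(p_eq$es_bar, 3) # equal weights -> arithmetic mean
  p <- pool_effects(c(1, 3), c(1, 1), tau2 = 0)
  expect_equal(p$es_bar, 2)
  expect_equal(p$se, sqrt(0.5), tolerance = 1e-12)
  expect_equal(p$ci_lb, 2 - 1.96 * sqrt(0.5))
  # tau2 = 0 equals the fixed-effect estimate exactly
  set.seed(7)
  es <- rnorm(8); v <- runif(8, 0.2, 2)
  expect_equal(pool_effects(es, v, tau2 = 0)$es_bar,
    sum(es / v) / sum(1 / v), tolerance = 1e-14)
  expect_error(pool_effects(numeric(0), numeric(0)), class = "nrimpact_empty_group")
})

test_that("pooled estimate is invariant to order and duplication", {
  set.seed(13)
  es <- rnorm(12, 1, 2); v <- runif(12, 0.3, 3)
  p <- pool_effects(es, v)
  idx <- sample(12)
  p_perm <- pool_effects(es[idx], v[idx])
  expect_equal(p_perm$es_bar, p$es_bar, tolerance = 1e-12)
  expect_equal(p_perm$tau2, p$tau2, tolerance = 1e-12)
  p_dup <- pool_effects(c(es, es), c(v, v), tau2 = p$tau2)
  expect_equal(p_dup$es_bar, pool_effects(es, v, tau2 = p$tau2)$es_bar,
    tolerance = 1e-12)
})

test_that("pooled estimate equals the grid-search weighted-least-squares minimizer", {
  set.seed(31)
  for (k in 2:5) {
    es <- rnorm(k, 2, 3)
    v <- runif(k, 0.2, 2)
    tau2 <- tau2_dl(es, v)
    expect_equal(pool_effects(es, v)$es_bar, grid_pool_oracle(es, v, tau2),
      tolerance = 1e-6)
  }
})

test_that("DL and REML pooling agree with the independent metafor oracle", {
  skip_if_not_installed("metafor")
  set.seed(88)
  es <- rnorm(25, 1.5, 1.2)
  v <- runif(25, 0.2, 1.5)
  p <- pool_effects(es, v, method = "DL")
  m <- metafor::rma(yi = es, vi = v, method = "DL")
  expect_equal(p$es_bar, as.numeric(m$beta), tolerance = 1e-10)
  expect_equal(p$se, m$se, tolerance = 1e-10)
  expect_equal(p$tau2, m$tau2, tolerance = 1e-10)
  expect_equal(p$Q, m$QE, tolerance = 1e-10)
  expect_equal(p$I2, m$I2, tolerance = 1e-6)
  p_reml <- pool_effects(es, v, method = "REML")
  m_reml <- metafor::rma(yi = es, vi = v, method = "REML")
  expect_equal(p_reml$tau2, m_reml$tau2, tolerance = 1e-4)
  expect_equal(p_reml$es_bar, as.numeric(m_reml$beta), tolerance = 1e-6)
})

test_that("fail-safe N follows the Rosenthal formula", {
  expect_equal(failsafe_n(1.96, 1), 0) # single study exactly at the boundary
  expect_equal(failsafe_n(rep(2, 10), rep(1, 10)), 94) # floor(400/3.8416 - 10)
  expect_equal(failsafe_n(rep(0, 5), rep(1, 5)), 0)
  skip_if_not_installed("metafor")
  set.seed(12)
  es <- rnorm(15, 0.8, 0.5)
  se <- runif(15, 0.3, 1)
  # metafor's Rosenthal target is one-tailed alpha; 0.025 matches the
  # two-sided 0.05 convention here up to its ceiling-vs-floor rounding
  fsn <- metafor::fsn(x = es, sei = se, type = "Rosenthal", alpha = 0.025)
  expect_lte(abs(failsafe_n(es, se) - fsn$fsnum), 1)
})

test_that("Egger diagnostics require k >= 3 and are calibrated on symmetric funnels", {
  expect_error(egger_funnel(c(1, 2), c(0.5, 0.5)),
    class = "nrimpact_insufficient_studies")
  set.seed(202)
  null_reject <- vapply(1:100, function(i) {
    se <- runif(200, 0.1, 1)
    es <- rnorm(200, 1, sqrt(se^2 + 0.1))
    egger_funnel(es, se)$egger_p < 0.05
  }, logical(1))
  expect_gte(mean(!null_reject), 0.90)
})

test_that("Egger test detects a shifted-small-se asymmetric funnel", {
  set.seed(303)
  hits <- vapply(1:50, function(i) {
    se <- runif(150, 0.1, 1)
    es <- rnorm(150, 1, se)
    delta <- 2 * median(se)
    es[se < median(se)] <- es[se < median(se)] + delta
    egger_funnel(es, se)$egger_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("group-wise pooling returns one row per group with diagnostics", {
  set.seed(5)
  df <- tibble::tibble(
    crop = rep(c("wheat", "rice"), each = 10),
    es = rnorm(20, rep(c(2, 5), each = 10), 1),
    v = runif(20, 0.2, 1)
  )
  pooled <- pool_groups(df, crop, min_k = 3)
  expect_equal(nrow(pooled), 2)
  expect_true(all(c("es_bar", "tau2", "I2", "failsafe_n", "rejected") %in%
    names(pooled)))
  expect_false(any(pooled$rejected))
  one <- pool_groups(df[1:2, ], crop, min_k = 3)
  expect_true(all(one$rejected))
})

test_that("tidy and glance summarize pooled objects", {
  p <- pool_effects(c(1, 3, 2), c(1, 1, 1))
  td <- tidy(p)
  expect_equal(td$estimate, p$es_bar)
  expect_equal(glance(p)$k, 3)
})
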