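make_metareg_data <- function(k, slopes = c(water_load = 0), tau = 1,
                              v_range = c(0.5, 1.5), mu = 10, seed = 1) {
  set.seed(seed)
  mods <- tibble::tibble(
    temperature = runif(k, 7, 24),
    water_load = runif(k, 20, 2000),
    soil_ph = runif(k, 5, 8.5),
    som = runif(k, 5, 40),
    stn = runif(k, 0.5, 2.5),
    clay = runif(k, 100, 500)
  )
  es <- rep(mu, k)
  for (nm in names(slopes)) {
    z <- as.numeric(scale(mods[[nm]]))
    es <- es + slopes[[nm]] * z
  }
  v <- runif(k, v_range[1], v_range[2])
  es <- es + rnorm(k, 0, sqrt(tau^2 + v))
  list(es = es, v = v, mods = mods)
}

test_that("intercept-only meta-regression matches the pooled estimate", {
  d <- make_metareg_data(60, seed = 3)
  fit <- fit_metareg(d$es, d$v, d$mods, character(0))
  p <- pool_effects(d$es, d$v, method = "DL")
  expect_equal(fit$coefficients$estimate[1], p$es_bar, tolerance = 1e-10)
  expect_equal(fit$tau2, p$tau2, tolerance = 1e-10)
})

test_that("zero residual heterogeneity reduces to plain weighted least squares", {
  set.seed(9)
  k <- 40
  mods <- tibble::tibble(water_load = runif(k, 0, 1000))
  z <- as.numeric(scale(mods$water_load))
  v <- runif(k, 5, 10) # large v so Q_E < df and tau2 hits 0
  es <- 5 + 0.4 * z + rnorm(k, 0, 0.05)
  fit <- fit_metareg(es, v, mods, "water_load")
  expect_equal(fit$tau2, 0)
  oracle <- lm(es ~ z, weights = 1 / v)
  expect_equal(unname(fit$coefficients$estimate), unname(coef(oracle)),
    tolerance = 1e-8)
})

test_that("meta-regression agrees with the independent metafor oracle", {
  skip_if_not_installed("metafor")
  d <- make_metareg_data(80, slopes = c(water_load = 2), seed = 11)
  z <- as.numeric(scale(d$mods$water_load))
  fit <- fit_metareg(d$es, d$v, d$mods, "water_load")
  m <- metafor::rma(yi = d$es, vi = d$v, mods = ~z, method = "DL")
  expect_equal(fit$tau2, m$tau2, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$estimate), unname(as.numeric(m$beta)),
    tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$std.error), unname(m$se), tolerance = 1e-8)
})

test_that("a planted moderator slope is recovered within 20%", {
  hits <- vapply(1:5, function(i) {
    d <- make_metareg_data(300, slopes = c(water_load = 5), tau = 1, seed = 100 + i)
    fit <- fit_metareg(d$es, d$v, d$mods, "water_load")
    est <- fit$coefficients$estimate[fit$coefficients$term == "water_load"]
    abs(est - 5) / 5 < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("collinear or degenerate designs raise named errors", {
  d <- make_metareg_data(50, seed = 5)
  mods <- d$mods
  mods$water_load2 <- 2 * mods$water_load + 3 # perfectly collinear
  expect_error(
    fit_metareg(d$es, d$v, mods, c("water_load", "water_load2")),
    class = "nrimpact_collinearity_error"
  )
  mods$flat <- 1
  expect_error(fit_metareg(d$es, d$v, mods, "flat"),
    class = "nrimpact_collinearity_error")
  expect_error(fit_metareg(d$es[1:4], d$v[1:4], d$mods[1:4, ], c("som", "stn")),
    class = "nrimpact_insufficient_studies")
})

test_that("model ranking is invariant to affine moderator rescaling", {
  d <- make_metareg_data(100, slopes = c(som = 2), seed = 21)
  mods2 <- d$mods
  mods2$som <- 100 * mods2$som + 55
  f1 <- fit_metareg(d$es, d$v, d$mods, "som")
  f2 <- fit_metareg(d$es, d$v, mods2, "som")
  expect_equal(f1$aicc, f2$aicc, tolerance = 1e-8)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
    tolerance = 1e-8) # standardized slopes unchanged
  raw1 <- f1$coefficients$estimate_raw[2]
  raw2 <- f2$coefficients$estimate_raw[2]
  expect_equal(raw2, raw1 / 100, tolerance = 1e-8) # raw slopes rescale inversely
})

test_that("Akaike weights are a proper distribution and importance sums them", {
  d <- make_metareg_data(120, slopes = c(water_load = 3), seed = 33)
  sel <- all_subsets_selection(d$es, d$v, d$mods,
    drivers = c("water_load", "som", "clay"))
  expect_equal(nrow(sel$models), 8)
  expect_equal(sum(sel$models$weight), 1, tolerance = 1e-12)
  # importance of each driver equals the weight mass of models containing it
  for (drv in c("water_load", "som", "clay")) {
    mass <- sum(sel$models$weight[grepl(drv, sel$models$drivers)])
    expect_equal(sel$importance$importance[sel$importance$driver == drv],
      mass, tolerance = 1e-12)
  }
  expect_true(all(sel$importance$importance >= 0 &
    sel$importance$importance <= 1))
})

test_that("pseudo-R2 is the clamped proportional tau2 reduction", {
  expect_equal(pseudo_r2(1, 1), 0)
  expect_equal(pseudo_r2(1, 0), 1)
  expect_equal(pseudo_r2(1.0, 0.65), 0.35)
  expect_equal(pseudo_r2(1, 2), 0) # clamped below
  expect_true(is.na(pseudo_r2(0, 0)))
  expect_error(pseudo_r2(1, -0.1), class = "nrimpact_domain_error")
})

test_that("small-sample subsets are skipped with a logged reason", {
  d <- make_metareg_data(5, seed = 44)
  sel <- all_subsets_selection(d$es, d$v, d$mods,
    drivers = c("temperature", "water_load", "som"))
  expect_equal(length(sel$skipped), 1) # the full 3-driver model needs k > 5
  expect_equal(nrow(sel$models), 7)
  expect_equal(sum(sel$models$weight), 1, tolerance = 1e-12)
  # too few rows for most subsets aborts the selection entirely
  d2 <- make_metareg_data(3, seed = 45)
  expect_error(
    all_subsets_selection(d2$es, d2$v, d2$mods,
      drivers = c("temperature", "water_load", "som")),
    class = "nrimpact_insufficient_studies"
  )
})
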