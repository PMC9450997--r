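test_that("SD recovery from SE, CV, CI, t and p follows the closed forms", {
  # SE
  expect_equal(sd_from_se(1, 4), 2)
  expect_equal(sd_from_se(0, 7), 0)
  expect_equal(sd_from_se(1.2, 3), 2.078461, tolerance = 1e-6)
  expect_error(sd_from_se(-1, 4), class = "nrimpact_domain_error")
  # CV
  expect_equal(sd_from_cv(20, 10), 2)
  expect_equal(sd_from_cv(0, 5), 0)
  expect_equal(sd_from_cv(12.5, 4.8), 0.6)
  expect_error(sd_from_cv(10, 0), class = "nrimpact_domain_error")
  # CI (t-based): frozen from t_{0.975,3} = 3.182446
  expect_equal(sd_from_ci(10, 10, 4, 0.95), 0)
  expect_equal(sd_from_ci(8, 12, 4, 0.95), 1.256899, tolerance = 1e-4)
  expect_equal(
    sd_from_ci(6, 14, 4, 0.95),
    2 * sd_from_ci(8, 12, 4, 0.95)
  )
  expect_error(sd_from_ci(8, 12, 1, 0.95), class = "nrimpact_domain_error")
  expect_error(sd_from_ci(12, 8, 4, 0.95), class = "nrimpact_domain_error")
  # a normal-based inversion implies a larger SD (1.96 < t quantile)
  expect_gt(sd_from_ci(8, 12, 4, 0.95, use_t = FALSE), sd_from_ci(8, 12, 4, 0.95))
  # t
  expect_equal(sd_from_t(2, 2, 2, 2), 1)
  expect_equal(sd_from_t(0, 3, 4, 4), 0)
  expect_equal(sd_from_t(6, 2, 3, 3), 3 * sd_from_t(2, 2, 3, 3))
  expect_error(sd_from_t(2, 0, 3, 3), class = "nrimpact_domain_error")
  # p inverts the two-sided t with n1+n2-2 df: round trip through the forward map
  md <- 2.5; n1 <- 4; n2 <- 3; sd_true <- 1.3
  se_d <- sd_true * sqrt((n1 + n2) / (n1 * n2))
  p <- 2 * pt(-abs(md / se_d), n1 + n2 - 2)
  expect_equal(sd_from_p(md, p, n1, n2), sd_true, tolerance = 1e-9)
})

test_that("formula imputation paths are scale-equivariant", {
  for (c_scale in c(0.1, 3, 100)) {
    expect_equal(sd_from_se(1.2 * c_scale, 5), c_scale * sd_from_se(1.2, 5))
    expect_equal(sd_from_cv(15, 4 * c_scale), c_scale * sd_from_cv(15, 4))
    expect_equal(
      sd_from_ci(8 * c_scale, 12 * c_scale, 4),
      c_scale * sd_from_ci(8, 12, 4)
    )
    expect_equal(sd_from_t(2 * c_scale, 2, 3, 3), c_scale * sd_from_t(2, 2, 3, 3))
  }
})

test_that("normality screen flags by p < 0.05 and rejects degenerate input", {
  set.seed(101)
  null_flags <- vapply(1:100, function(i) {
    normality_screen(rnorm(500))$flag
  }, logical(1))
  expect_gte(mean(!null_flags), 0.95) # calibration under the null
  exp_flags <- vapply(1:40, function(i) {
    normality_screen(rexp(200))$flag
  }, logical(1))
  expect_gte(mean(exp_flags), 0.95) # power against a skewed alternative
  expect_error(normality_screen(rep(1, 10)), class = "nrimpact_domain_error")
  expect_error(normality_screen(c(1, 2)), class = "nrimpact_domain_error")
})

test_that("imputation fills from formulas, never overwrites a reported SD", {
  obs <- make_obs(4, sd = 2)
  obs$disp_treat_kind <- c("SD", "SE", "CV", "CI")
  obs$disp_treat_value <- c(9, 1.2, 20, NA)
  obs$disp_treat_lower <- c(NA, NA, NA, 28)
  obs$disp_treat_upper <- c(NA, NA, NA, 32)
  obs$disp_treat_level <- c(NA, NA, NA, 0.95)
  out <- impute_dispersions(obs, seed = 1)
  expect_equal(out$sd_treat[1], 9) # reported SD kept verbatim
  expect_equal(out$sd_treat[2], 1.2 * sqrt(4))
  expect_equal(out$sd_treat[3], 20 / 100 * 30)
  expect_equal(out$sd_treat[4], sd_from_ci(28, 32, 4, 0.95))
  expect_equal(out$imputation_method_treat, c("SD", "SE", "CV", "CI"))
})

test_that("t and p dispersion kinds yield one pooled SD for both arms", {
  obs <- make_obs(1, sd = NA)
  obs$disp_treat_kind <- "t_value"
  obs$disp_treat_value <- 3
  obs$disp_ctrl_kind <- "missing"
  obs$disp_ctrl_value <- NA_real_
  out <- impute_dispersions(obs, seed = 1)
  expected <- sd_from_t(30 - 3, 3, 4, 4)
  expect_equal(out$sd_treat, expected)
  expect_equal(out$sd_ctrl, expected)
})

test_that("bootstrap route uses the stratum SD/mean ratio and a mandatory seed", {
  # degenerate bootstrap: every complete case has SD/mean = 0.2
  obs <- make_obs(8, loss_treat = 50, loss_ctrl = 10, sd = NA)
  obs$disp_treat_value <- 10 # 10/50 = 0.2
  obs$disp_ctrl_value <- 2 # 2/10 = 0.2
  obs$disp_treat_kind[7:8] <- "missing"
  obs$disp_ctrl_kind[7:8] <- "missing"
  out <- impute_dispersions(obs, seed = 99, n_boot = 50)
  expect_equal(out$sd_treat[7:8], c(10, 10)) # 0.2 * 50, any seed
  expect_equal(out$sd_ctrl[7:8], c(2, 2))
  expect_equal(out$imputation_method_treat[7], "bootstrap")
  expect_error(impute_dispersions(obs), class = "nrimpact_config_error")
})

test_that("bootstrap imputation is deterministic and converges to the stratum mean", {
  obs <- make_obs(12, loss_treat = 10, loss_ctrl = 1, sd = NA)
  # ratios alternate 0.1 / 0.3 across the 10 complete records
  obs$disp_treat_value <- rep(c(1, 3), 5)[seq_len(12)] # sd/mean = 0.1 or 0.3
  obs$disp_ctrl_value <- rep(c(0.1, 0.3), 5)[seq_len(12)]
  obs$disp_treat_kind[11:12] <- "missing"
  obs$disp_ctrl_kind[11:12] <- "missing"
  o1 <- impute_dispersions(obs, seed = 5, n_boot = 200)
  o2 <- impute_dispersions(obs, seed = 5, n_boot = 200)
  expect_identical(imputation_report(o1)$bootstrap_ratio,
    imputation_report(o2)$bootstrap_ratio)
  expect_identical(o1$sd_treat, o2$sd_treat)
  big <- impute_dispersions(obs, seed = 7, n_boot = 10000)
  expect_equal(unname(imputation_report(big)$bootstrap_ratio[["wheat:NH3"]]),
    0.2, tolerance = 0.01) # bootstrap mean -> sample mean of {0.1, 0.3}
})

test_that("records in strata without complete cases are refused, not guessed", {
  obs <- make_obs(3, sd = NA)
  obs$disp_treat_kind <- "missing"
  obs$disp_ctrl_kind <- "missing"
  out <- impute_dispersions(obs, seed = 1)
  rep <- imputation_report(out)
  expect_equal(rep$n_flagged, 3)
  expect_true(all(is.na(out$sd_treat)))
  expect_equal(rep$n_complete + rep$n_flagged, 3)
})

test_that("imputation counts partition the dataset", {
  sim <- simulate_observations(sim_config(seed = 21, n_total = 400))
  out <- impute_dispersions(sim$observations, seed = 21)
  rep <- imputation_report(out)
  expect_equal(rep$n_records, 400)
  # every record ends up complete, formula-imputed, bootstrap-imputed or flagged
  expect_equal(sum(!is.na(out$sd_treat) & !is.na(out$sd_ctrl)) + rep$n_flagged, 400)
})
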