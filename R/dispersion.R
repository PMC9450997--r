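#' Standard deviation from a standard error
#'
#' @param se Standard error(s), >= 0.
#' @param n Replicate count(s), >= 1.
#' @return `se * sqrt(n)`.
#' @export
sd_from_se <- function(se, n) {
  if (any(is.na(se)) || any(se < 0)) {
    abort("se must be >= 0", class = "nrimpact_domain_error")
  }
  if (any(is.na(n)) || any(n < 1)) {
    abort("n must be >= 1", class = "nrimpact_domain_error")
  }
  se * sqrt(n)
}

#' Standard deviation from a coefficient of variation
#'
#' @param cv_percent CV in percent.
#' @param mean Arm mean, > 0.
#' @return `cv_percent / 100 * mean`.
#' @export
sd_from_cv <- function(cv_percent, mean) {
  if (any(is.na(cv_percent)) || any(cv_percent < 0)) {
    abort("cv_percent must be >= 0", class = "nrimpact_domain_error")
  }
  if (any(is.na(mean)) || any(mean <= 0)) {
    abort("mean must be > 0 to invert a CV", class = "nrimpact_domain_error")
  }
  cv_percent / 100 * mean
}

#' Standard deviation from a confidence interval
#'
#' Inverts a symmetric two-sided confidence interval on an arm mean:
#' `SD = sqrt(n) * (upper - lower) / (2 * q)`. By default `q` is the
#' Student-t quantile with `n - 1` degrees of freedom (field reports are
#' typically t-based); the normal quantile is available via `use_t = FALSE`.
#'
#' @param lower,upper Interval bounds, `upper >= lower`.
#' @param n Replicate count, >= 2.
#' @param level Confidence level in (0, 1), default 0.95.
#' @param use_t Use the t quantile (default) or the normal quantile.
#' @return The implied standard deviation.
#' @export
sd_from_ci <- function(lower, upper, n, level = 0.95, use_t = TRUE) {
  if (any(is.na(lower)) || any(is.na(upper)) || any(upper < lower)) {
    abort("CI requires upper >= lower", class = "nrimpact_domain_error")
  }
  if (any(is.na(n)) || any(n < 2)) {
    abort("CI inversion needs n >= 2 (degrees of freedom)",
      class = "nrimpact_domain_error"
    )
  }
  if (any(is.na(level)) || any(level <= 0) || any(level >= 1)) {
    abort("level must lie in (0, 1)", class = "nrimpact_domain_error")
  }
  q <- if (use_t) qt(1 - (1 - level) / 2, df = n - 1) else qnorm(1 - (1 - level) / 2)
  sqrt(n) * (upper - lower) / (2 * q)
}

#' Pooled standard deviation from a t statistic
#'
#' Inverts `t = MD / SE_D` for the mean difference, then converts the
#' standard error of the difference to the pooled SD via
#' `SE_D = s_pooled * sqrt((n1 + n2) / (n1 * n2))`.
#'
#' @param mean_diff Treatment minus control mean difference.
#' @param t_value Reported t statistic, non-zero.
#' @param n1,n2 Replicate counts, >= 1.
#' @return The implied pooled standard deviation (applies to both arms).
#' @export
sd_from_t <- function(mean_diff, t_value, n1, n2) {
  if (any(is.na(t_value)) || any(t_value == 0)) {
    abort("t_value must be non-zero", class = "nrimpact_domain_error")
  }
  if (any(is.na(n1)) || any(is.na(n2)) || any(n1 < 1) || any(n2 < 1)) {
    abort("n1 and n2 must be >= 1", class = "nrimpact_domain_error")
  }
  se_d <- abs(mean_diff / t_value)
  se_d / sqrt((n1 + n2) / (n1 * n2))
}

#' Pooled standard deviation from a two-sided p value
#'
#' Converts a two-sided p value to `|t|` with `n1 + n2 - 2` degrees of
#' freedom, then routes through [sd_from_t()].
#'
#' @param mean_diff Treatment minus control mean difference.
#' @param p Two-sided p value in (0, 1).
#' @param n1,n2 Replicate counts with `n1 + n2 > 2`.
#' @return The implied pooled standard deviation.
#' @export
sd_from_p <- function(mean_diff, p, n1, n2) {
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    abort("p must lie strictly in (0, 1) to invert", class = "nrimpact_domain_error")
  }
  if (any(n1 + n2 <= 2)) {
    abort("p-to-t conversion needs n1 + n2 > 2", class = "nrimpact_domain_error")
  }
  t_abs <- qt(1 - p / 2, df = n1 + n2 - 2)
  sd_from_t(mean_diff, t_abs, n1, n2)
}

#' Shapiro-Wilk normality screen
#'
#' Quality-control screen used on raw and derived outcome vectors; flags a
#' vector as non-normal at p < 0.05.
#'
#' @param values Numeric vector, 3 <= length <= 5000, not constant.
#' @return List with `statistic`, `p_value` and logical `flag`
#'   (`TRUE` = non-normal at p < 0.05).
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("normality screen supports 3 <= n <= 5000",
      class = "nrimpact_domain_error"
    )
  }
  if (length(unique(values)) == 1) {
    abort("normality screen is undefined for a constant vector",
      class = "nrimpact_domain_error"
    )
  }
  sw <- shapiro.test(values)
  list(
    statistic = unname(sw$statistic),
    p_value = sw$p.value,
    flag = sw$p.value < 0.05
  )
}

# SD for one arm from its reported dispersion, or NA when it needs the
# bootstrap route. t/p kinds describe the difference and yield a pooled SD
# that is assigned to both arms.
arm_sd <- function(kind, value, lower, upper, level, n, mean,
                   mean_diff, n1, n2, use_t_ci = TRUE) {
  if (is.na(kind) || kind == "missing") return(NA_real_)
  switch(kind,
    SD = value,
    SE = sd_from_se(value, n),
    CV = sd_from_cv(value, mean),
    CI = sd_from_ci(lower, upper, n, level, use_t = use_t_ci),
    t_value = sd_from_t(mean_diff, value, n1, n2),
    p_value = sd_from_p(mean_diff, value, n1, n2),
    NA_real_
  )
}

#' Complete missing standard deviations
#'
#' Fills the `sd_treat` / `sd_ctrl` columns from each arm's reported
#' dispersion: SD is kept as reported; SE, CV, CI, t and p values are
#' inverted with the exact closed-form identities ([sd_from_se()],
#' [sd_from_cv()], [sd_from_ci()], [sd_from_t()], [sd_from_p()]); records
#' reporting nothing receive the bootstrap mean SD/mean ratio of complete
#' cases in their crop x pathway stratum, multiplied by the arm mean.
#' A reported SD is never overwritten.
#'
#' @param obs Observation tibble from [read_observations()] or
#'   [simulate_observations()].
#' @param n_boot Bootstrap resamples for the SD/mean ratio, default 2000.
#' @param seed Integer seed for the bootstrap (mandatory: the ratio is
#'   stochastic and runs must be reproducible).
#' @param min_complete Minimum complete cases a stratum needs before its
#'   ratio is used, default 5; sparser strata leave their records flagged.
#' @param use_t_ci Invert confidence intervals with the t quantile (default)
#'   or the normal quantile.
#' @return `obs` with columns `sd_treat`, `sd_ctrl`,
#'   `imputation_method_treat`, `imputation_method_ctrl` added. The
#'   [imputation_report()] is attached as attribute `"imputation_report"`.
#' @export
impute_dispersions <- function(obs, n_boot = 2000, seed, min_complete = 5,
                               use_t_ci = TRUE) {
  if (missing(seed)) {
    abort("seed is mandatory for bootstrap imputation", class = "nrimpact_config_error")
  }
  n <- nrow(obs)
  sd_treat <- rep(NA_real_, n)
  sd_ctrl <- rep(NA_real_, n)
  meth_treat <- rep(NA_character_, n)
  meth_ctrl <- rep(NA_character_, n)
  mean_diff <- obs$loss_treat_mean - obs$loss_ctrl_mean

  for (i in seq_len(n)) {
    kt <- obs$disp_treat_kind[i]
    kc <- obs$disp_ctrl_kind[i]
    sd_treat[i] <- arm_sd(kt, obs$disp_treat_value[i], obs$disp_treat_lower[i],
      obs$disp_treat_upper[i], obs$disp_treat_level[i], obs$n_treat[i],
      obs$loss_treat_mean[i], mean_diff[i], obs$n_treat[i], obs$n_ctrl[i],
      use_t_ci
    )
    sd_ctrl[i] <- arm_sd(kc, obs$disp_ctrl_value[i], obs$disp_ctrl_lower[i],
      obs$disp_ctrl_upper[i], obs$disp_ctrl_level[i], obs$n_ctrl[i],
      obs$loss_ctrl_mean[i], mean_diff[i], obs$n_treat[i], obs$n_ctrl[i],
      use_t_ci
    )
    meth_treat[i] <- if (is.na(sd_treat[i])) NA_character_ else kt
    meth_ctrl[i] <- if (is.na(sd_ctrl[i])) NA_character_ else kc
    # a t/p kind describes the comparison: its pooled SD covers both arms
    if (!is.na(kt) && kt %in% c("t_value", "p_value") && is.na(sd_ctrl[i])) {
      sd_ctrl[i] <- sd_treat[i]
      meth_ctrl[i] <- kt
    }
    if (!is.na(kc) && kc %in% c("t_value", "p_value") && is.na(sd_treat[i])) {
      sd_treat[i] <- sd_ctrl[i]
      meth_treat[i] <- kc
    }
  }

  # bootstrap SD/mean ratio per crop x pathway stratum over complete arms
  n_formula <- sum((!is.na(sd_treat) & meth_treat != "SD") |
    (!is.na(sd_ctrl) & meth_ctrl != "SD"))
  need_boot <- which(is.na(sd_treat) | is.na(sd_ctrl))
  strata <- paste(obs$crop, obs$pathway, sep = ":")
  ratio_obs <- c(
    ifelse(!is.na(sd_treat) & obs$loss_treat_mean > 0,
      sd_treat / obs$loss_treat_mean, NA_real_),
    ifelse(!is.na(sd_ctrl) & obs$loss_ctrl_mean > 0,
      sd_ctrl / obs$loss_ctrl_mean, NA_real_)
  )
  ratio_strata <- c(strata, strata)
  keep <- !is.na(ratio_obs)
  ratio_obs <- ratio_obs[keep]
  ratio_strata <- ratio_strata[keep]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  boot_ratios <- list()
  n_boot_imputed <- 0L
  flagged <- integer()
  for (i in need_boot) {
    st <- strata[i]
    if (is.null(boot_ratios[[st]])) {
      ratios <- ratio_obs[ratio_strata == st]
      if (length(ratios) < min_complete) {
        boot_ratios[[st]] <- list(mean = NA_real_, ci = c(NA_real_, NA_real_))
      } else {
        bm <- vapply(seq_len(n_boot), function(b) {
          mean(sample(ratios, length(ratios), replace = TRUE))
        }, numeric(1))
        boot_ratios[[st]] <- list(
          mean = mean(bm),
          ci = unname(stats::quantile(bm, c(0.025, 0.975)))
        )
      }
    }
    r <- boot_ratios[[st]]$mean
    if (is.na(r)) {
      flagged <- c(flagged, i)
      next
    }
    if (is.na(sd_treat[i])) {
      sd_treat[i] <- r * obs$loss_treat_mean[i]
      meth_treat[i] <- "bootstrap"
      n_boot_imputed <- n_boot_imputed + 1L
    }
    if (is.na(sd_ctrl[i])) {
      sd_ctrl[i] <- r * obs$loss_ctrl_mean[i]
      meth_ctrl[i] <- "bootstrap"
      n_boot_imputed <- n_boot_imputed + 1L
    }
  }

  out <- obs
  out$sd_treat <- sd_treat
  out$sd_ctrl <- sd_ctrl
  out$imputation_method_treat <- meth_treat
  out$imputation_method_ctrl <- meth_ctrl

  ratio_means <- vapply(boot_ratios, function(x) x$mean, numeric(1))
  report <- list(
    n_records = n,
    n_complete = sum(meth_treat == "SD" & meth_ctrl == "SD", na.rm = TRUE),
    n_imputed_by_formula = n_formula,
    n_imputed_by_bootstrap = n_boot_imputed,
    n_flagged = length(flagged),
    flagged_rows = flagged,
    bootstrap_ratio = if (length(ratio_means)) ratio_means else numeric(),
    bootstrap_ci = lapply(boot_ratios, function(x) x$ci),
    n_boot = n_boot,
    seed = seed
  )
  class(report) <- "nr_imputation_report"
  attr(out, "imputation_report") <- report
  out
}

#' Retrieve the imputation audit report
#'
#' @param obs Output of [impute_dispersions()].
#' @return The `nr_imputation_report` attached by [impute_dispersions()].
#' @export
imputation_report <- function(obs) {
  rep <- attr(obs, "imputation_report")
  if (is.null(rep)) {
    abort("no imputation report attached; run impute_dispersions() first",
      class = "nrimpact_domain_error"
    )
  }
  rep
}

#' @export
print.nr_imputation_report <- function(x, ...) {
  cat("Dispersion imputation report\n")
  cat("  records:            ", x$n_records, "\n")
  cat("  complete (SD both): ", x$n_complete, "\n")
  cat("  formula-imputed:    ", x$n_imputed_by_formula, "\n")
  cat("  bootstrap-imputed:  ", x$n_imputed_by_bootstrap,
    " (", x$n_boot, " resamples, seed ", x$seed, ")\n", sep = "")
  if (x$n_flagged > 0) cat("  flagged (no stratum ratio):", x$n_flagged, "\n")
  if (length(x$bootstrap_ratio)) {
    cat("  stratum SD/mean ratios:\n")
    for (nm in names(x$bootstrap_ratio)) {
      cat(sprintf("    %-14s %.4f\n", nm, x$bootstrap_ratio[[nm]]))
    }
  }
  invisible(x)
}
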