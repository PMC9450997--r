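#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimate
#' \eqn{\tau^2 = \max(0, (Q - (k-1))/C)} with fixed-effect weights
#' \eqn{W_i = 1/v_i}, Cochran's
#' \eqn{Q = \sum W_i (ES_i - \bar{ES}_{FE})^2} and
#' \eqn{C = \sum W_i - \sum W_i^2 / \sum W_i}.
#'
#' @param es Effect sizes.
#' @param v Within-comparison variances, > 0.
#' @return `tau2` (a single non-negative number).
#' @export
tau2_dl <- function(es, v) {
  k <- length(es)
  if (k < 2) {
    abort("tau-squared needs at least two effect sizes",
      class = "nrimpact_insufficient_studies"
    )
  }
  if (any(v <= 0)) abort("variances must be > 0", class = "nrimpact_domain_error")
  w <- 1 / v
  mu_fe <- sum(w * es) / sum(w)
  q <- sum(w * (es - mu_fe)^2)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (k - 1)) / c_dl)
}

# restricted maximum likelihood tau2 for the intercept-only model
tau2_reml <- function(es, v) {
  k <- length(es)
  if (k < 2) {
    abort("tau-squared needs at least two effect sizes",
      class = "nrimpact_insufficient_studies"
    )
  }
  nll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * es) / sum(w)
    0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (es - mu)^2))
  }
  upper <- max(tau2_dl(es, v) * 10, var(es) * 10, 1e-3)
  opt <- optimize(nll, c(0, upper))
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' Pool effect sizes under a random-effects model
#'
#' Inverse-variance weighting with \eqn{W_i = 1/(v_i + \tau^2)}:
#' \eqn{\bar{ES} = \sum W_i ES_i / \sum W_i}, standard error
#' \eqn{\sqrt{1/\sum W_i}}, 95% CI with the normal multiplier 1.96.
#' Heterogeneity (Cochran's Q, I-squared) uses fixed-effect weights.
#'
#' @param es Effect sizes (k >= 1).
#' @param v Within-comparison variances, > 0.
#' @param tau2 Between-study variance; `NULL` (default) estimates it with
#'   the chosen `method` (needs k >= 2; with k = 1 it is taken as 0).
#' @param method `"DL"` (DerSimonian-Laird, default) or `"REML"`.
#' @return An object of class `nr_pooled`: pooled mean `es_bar`, `se`,
#'   `ci_lb`/`ci_ub`, `tau2`, `Q`, `Q_p`, `I2` (percent), `k`. [tidy()] and
#'   [glance()] methods return one-row tibbles.
#' @examples
#' pool_effects(c(1, 3), c(1, 1), tau2 = 0)
#' @export
pool_effects <- function(es, v, tau2 = NULL, method = c("DL", "REML")) {
  method <- match.arg(method)
  k <- length(es)
  if (k == 0) abort("cannot pool an empty group", class = "nrimpact_empty_group")
  if (length(v) != k || any(is.na(v)) || any(v <= 0)) {
    abort("v must match es in length and be > 0", class = "nrimpact_domain_error")
  }
  if (is.null(tau2)) {
    tau2 <- if (k < 2) 0 else if (method == "DL") tau2_dl(es, v) else tau2_reml(es, v)
  }
  if (tau2 < 0) abort("tau2 must be >= 0", class = "nrimpact_domain_error")
  w <- 1 / (v + tau2)
  es_bar <- sum(w * es) / sum(w)
  se <- sqrt(1 / sum(w))
  if (k >= 2) {
    wf <- 1 / v
    mu_fe <- sum(wf * es) / sum(wf)
    q <- sum(wf * (es - mu_fe)^2)
    q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
    i2 <- max(0, (q - (k - 1)) / q) * 100
  } else {
    q <- NA_real_
    q_p <- NA_real_
    i2 <- NA_real_
  }
  structure(
    list(
      es_bar = es_bar, se = se,
      ci_lb = es_bar - 1.96 * se, ci_ub = es_bar + 1.96 * se,
      tau2 = tau2, Q = q, Q_p = q_p, I2 = i2, k = k,
      method = method, es = es, v = v
    ),
    class = "nr_pooled"
  )
}

#' @export
print.nr_pooled <- function(x, ...) {
  cat("Random-effects pooled estimate (", x$method, ")\n", sep = "")
  cat(sprintf("  es_bar = %.4g  se = %.4g  95%% CI [%.4g, %.4g]\n",
    x$es_bar, x$se, x$ci_lb, x$ci_ub))
  cat(sprintf("  k = %d  tau2 = %.4g  Q = %.4g (p = %.3g)  I2 = %.1f%%\n",
    x$k, x$tau2, x$Q, x$Q_p, x$I2))
  invisible(x)
}

#' @rdname pool_effects
#' @param x An `nr_pooled` object.
#' @param ... Unused.
#' @export
tidy.nr_pooled <- function(x, ...) {
  tibble(
    estimate = x$es_bar, std.error = x$se,
    conf.low = x$ci_lb, conf.high = x$ci_ub,
    tau2 = x$tau2, k = x$k
  )
}

#' @rdname pool_effects
#' @export
glance.nr_pooled <- function(x, ...) {
  tibble(
    k = x$k, tau2 = x$tau2, Q = x$Q, Q_p = x$Q_p, I2 = x$I2,
    method = x$method
  )
}

#' Pool effect sizes within groups of a table
#'
#' Grouped front end to [pool_effects()]: pools the `es` / `v` columns
#' within each combination of the grouping columns and returns one row per
#' group with the pooled estimate, heterogeneity statistics and the
#' Rosenthal fail-safe number.
#'
#' @param data Tibble with `es` and `v` columns
#'   (see [compute_effect_sizes()]).
#' @param ... Grouping columns (tidy-select, e.g. `crop, pathway`).
#' @param method Passed to [pool_effects()].
#' @param min_k Groups with fewer effect sizes are still returned but marked
#'   `rejected = TRUE` (insufficient comparisons); default 1 keeps all.
#' @return Tibble with one row per group: `k`, `es_bar`, `se`, `ci_lb`,
#'   `ci_ub`, `tau2`, `Q`, `Q_p`, `I2`, `failsafe_n`, `rejected`.
#' @export
pool_groups <- function(data, ..., method = "DL", min_k = 1) {
  data |>
    dplyr::group_by(...) |>
    dplyr::group_modify(function(df, key) {
      p <- pool_effects(df$es, df$v, method = method)
      tibble(
        k = p$k, es_bar = p$es_bar, se = p$se,
        ci_lb = p$ci_lb, ci_ub = p$ci_ub,
        tau2 = p$tau2, Q = p$Q, Q_p = p$Q_p, I2 = p$I2,
        failsafe_n = failsafe_n(df$es, sqrt(df$v)),
        rejected = p$k < min_k
      )
    }) |>
    dplyr::ungroup()
}
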