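#' Rosenthal fail-safe number
#'
#' Number of hypothetical null studies that would be needed to drag the
#' combined evidence below two-sided significance at alpha = 0.05:
#' \eqn{N_{fs} = \lfloor (\sum z_i)^2 / z_{0.975}^2 - k \rfloor},
#' floored at zero, with per-study \eqn{z_i = ES_i / SE_{D,i}}.
#'
#' @param es Effect sizes.
#' @param se_d Their standard errors, > 0.
#' @return Integer count >= 0.
#' @export
failsafe_n <- function(es, se_d) {
  if (length(es) < 1) abort("needs at least one study", class = "nrimpact_empty_group")
  if (any(se_d <= 0)) abort("se_d must be > 0", class = "nrimpact_domain_error")
  z <- es / se_d
  max(0L, as.integer(floor(sum(z)^2 / qnorm(0.975)^2 - length(z))))
}

#' Egger regression and funnel-plot coordinates
#'
#' Publication-bias diagnostics for a set of effect sizes: the Egger test
#' regresses the standardized effect `es / se` on precision `1 / se`; an
#' intercept far from zero signals funnel asymmetry. Funnel coordinates
#' `(es, se)` are returned for plotting.
#'
#' @param es Effect sizes (k >= 3).
#' @param se_d Their standard errors, > 0.
#' @return An object of class `nr_bias`: `egger_intercept`, `egger_se`,
#'   `egger_p` (two-sided), `failsafe_n`, `k` and a `funnel` tibble.
#'   [autoplot()] draws the funnel.
#' @export
egger_funnel <- function(es, se_d) {
  k <- length(es)
  if (k < 3) {
    abort("publication-bias diagnostics need at least 3 studies",
      class = "nrimpact_insufficient_studies"
    )
  }
  if (any(se_d <= 0)) abort("se_d must be > 0", class = "nrimpact_domain_error")
  fit <- lm(I(es / se_d) ~ I(1 / se_d))
  sm <- summary(fit)$coefficients
  structure(
    list(
      egger_intercept = unname(sm[1, 1]),
      egger_se = unname(sm[1, 2]),
      egger_p = unname(sm[1, 4]),
      failsafe_n = failsafe_n(es, se_d),
      k = k,
      funnel = tibble(es = es, se = se_d)
    ),
    class = "nr_bias"
  )
}

#' @export
print.nr_bias <- function(x, ...) {
  cat("Publication-bias diagnostics (k =", x$k, ")\n")
  cat(sprintf("  Egger intercept = %.4g (se %.4g, p = %.3g)\n",
    x$egger_intercept, x$egger_se, x$egger_p))
  cat("  fail-safe N =", x$failsafe_n, "\n")
  invisible(x)
}

#' @rdname egger_funnel
#' @param x An `nr_bias` object.
#' @param ... Unused.
#' @export
tidy.nr_bias <- function(x, ...) {
  tibble(
    egger_intercept = x$egger_intercept,
    egger_se = x$egger_se,
    egger_p = x$egger_p,
    failsafe_n = x$failsafe_n,
    k = x$k
  )
}

#' @rdname egger_funnel
#' @param object An `nr_bias` object.
#' @export
autoplot.nr_bias <- function(object, ...) {
  ggplot2::ggplot(object$funnel, ggplot2::aes(x = .data$es, y = .data$se)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "Effect size (mean difference)", y = "Standard error",
      title = "Funnel plot",
      subtitle = sprintf(
        "Egger intercept %.3g (p = %.3g), fail-safe N = %d",
        object$egger_intercept, object$egger_p, object$failsafe_n
      )
    ) +
    ggplot2::theme_minimal()
}
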