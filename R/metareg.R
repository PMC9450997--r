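#' Mixed-effects meta-regression on environmental moderators
#'
#' Weighted regression of effect sizes on a driver subset with residual
#' between-study variance estimated by the DerSimonian-Laird-type method of
#' moments on the regression residuals: with fixed-effect weights
#' \eqn{W = diag(1/v_i)} and hat-complement
#' \eqn{P = W - WX(X'WX)^{-1}X'W},
#' \eqn{\tau^2_{res} = \max(0, (Q_E - (k - p)) / tr(P))} where
#' \eqn{Q_E = y'Py}. Coefficients are then re-estimated with weights
#' \eqn{1/(v_i + \tau^2_{res})}. Moderators are z-standardized before
#' fitting so slopes are comparable across drivers with different units;
#' slopes on the original scale are reported alongside.
#'
#' @param es Effect sizes.
#' @param v Within-comparison variances, > 0.
#' @param moderators Data frame of candidate drivers (columns among
#'   temperature, water_load, soil_ph, som, stn, clay, or any numeric
#'   moderators). Rows with missing values in the selected drivers are
#'   dropped and counted.
#' @param drivers Character vector naming the columns of `moderators` to
#'   include; `character(0)` fits the intercept-only model.
#' @param method `"DL"` method-of-moments (default) or `"REML"`.
#' @return An object of class `nr_metareg` with `coefficients` (tibble:
#'   term, estimate, std.error, statistic, p.value, estimate_raw), `tau2`,
#'   `loglik`, `aicc`, `k`, `n_dropped`, `drivers`. [tidy()] and [glance()]
#'   methods are provided.
#' @export
fit_metareg <- function(es, v, moderators, drivers, method = c("DL", "REML")) {
  method <- match.arg(method)
  if (any(v <= 0)) abort("variances must be > 0", class = "nrimpact_domain_error")
  drivers <- as.character(drivers)
  bad <- setdiff(drivers, names(moderators))
  if (length(bad) > 0) {
    abort(paste0("unknown driver column(s): ", paste(bad, collapse = ", ")),
      class = "nrimpact_domain_error"
    )
  }
  keep <- if (length(drivers) == 0) {
    rep(TRUE, length(es))
  } else {
    complete.cases(moderators[drivers])
  }
  n_dropped <- sum(!keep)
  y <- es[keep]
  vv <- v[keep]
  k <- length(y)
  p_drv <- length(drivers)
  if (k <= p_drv + 2) {
    abort(paste0("too few effect sizes (k = ", k, ") for ", p_drv, " driver(s)"),
      class = "nrimpact_insufficient_studies"
    )
  }
  X <- matrix(1, nrow = k, ncol = 1, dimnames = list(NULL, "intercept"))
  scales <- numeric(0)
  centers <- numeric(0)
  if (p_drv > 0) {
    M <- as.matrix(moderators[keep, drivers, drop = FALSE])
    centers <- colMeans(M)
    scales <- apply(M, 2, sd)
    if (any(scales == 0)) {
      abort(
        paste0("constant moderator column(s): ",
          paste(drivers[scales == 0], collapse = ", ")),
        class = "nrimpact_collinearity_error"
      )
    }
    Z <- scale(M, center = centers, scale = scales)
    X <- cbind(X, Z)
  }
  if (qr(X)$rank < ncol(X)) {
    abort(
      paste0("collinear design among drivers: ", paste(drivers, collapse = ", ")),
      class = "nrimpact_collinearity_error"
    )
  }
  p_full <- ncol(X)

  wls <- function(w) {
    xtwx <- crossprod(X, w * X)
    beta <- solve(xtwx, crossprod(X, w * y))
    list(beta = beta, xtwx = xtwx, resid = y - drop(X %*% beta))
  }

  if (method == "DL") {
    w0 <- 1 / vv
    f0 <- wls(w0)
    q_e <- sum(w0 * f0$resid^2)
    # tr(P) with P = W - WX(X'WX)^{-1}X'W
    tr_p <- sum(w0) - sum(diag(solve(f0$xtwx, crossprod(X, w0^2 * X))))
    tau2 <- max(0, (q_e - (k - p_full)) / tr_p)
  } else {
    reml_nll <- function(tau2) {
      w <- 1 / (vv + tau2)
      f <- wls(w)
      0.5 * (sum(log(vv + tau2)) + determinant(f$xtwx, logarithm = TRUE)$modulus +
        sum(w * f$resid^2))
    }
    upper <- max(var(y) * 10, 1e-3)
    opt <- optimize(reml_nll, c(0, upper))
    tau2 <- if (reml_nll(0) <= opt$objective) 0 else opt$minimum
  }

  w <- 1 / (vv + tau2)
  fit <- wls(w)
  vc <- solve(fit$xtwx)
  se <- unname(sqrt(diag(vc)))
  est <- unname(drop(fit$beta))
  zstat <- est / se
  pval <- 2 * pnorm(-abs(zstat))
  loglik <- -0.5 * sum(log(2 * pi * (vv + tau2)) + w * fit$resid^2)
  q <- p_full + 1 # coefficients + tau2
  aicc <- if (k - q - 1 > 0) {
    -2 * loglik + 2 * q + 2 * q * (q + 1) / (k - q - 1)
  } else {
    Inf
  }
  est_raw <- est
  if (p_drv > 0) est_raw[-1] <- est[-1] / scales
  structure(
    list(
      coefficients = tibble(
        term = colnames(X), estimate = est, std.error = se,
        statistic = zstat, p.value = pval, estimate_raw = est_raw
      ),
      tau2 = tau2, loglik = loglik, aicc = aicc, k = k,
      n_dropped = n_dropped, drivers = drivers, method = method,
      centers = centers, scales = scales
    ),
    class = "nr_metareg"
  )
}

#' @export
print.nr_metareg <- function(x, ...) {
  cat("Mixed-effects meta-regression (", x$method, "), k = ", x$k,
    if (x$n_dropped > 0) paste0(" (", x$n_dropped, " rows dropped)"), "\n",
    sep = ""
  )
  cat(sprintf("  tau2_resid = %.4g  logLik = %.3f  AICc = %.3f\n",
    x$tau2, x$loglik, x$aicc))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_metareg
#' @param x,object An `nr_metareg` object.
#' @param ... Unused.
#' @export
tidy.nr_metareg <- function(x, ...) x$coefficients

#' @rdname fit_metareg
#' @export
glance.nr_metareg <- function(x, ...) {
  tibble(
    tau2 = x$tau2, logLik = x$loglik, AICc = x$aicc, k = x$k,
    n_dropped = x$n_dropped, p = length(x$drivers), method = x$method
  )
}

#' Proportional reduction in between-study variance
#'
#' Pseudo-R2 of a meta-regression: the share of the intercept-only residual
#' heterogeneity the moderators explain,
#' `max(0, (tau2_null - tau2_model) / tau2_null)`, clamped to `[0, 1]`.
#'
#' @param tau2_null Residual tau2 of the intercept-only model, > 0.
#' @param tau2_model Residual tau2 of the moderated model, >= 0.
#' @return A proportion in `[0, 1]`, or `NA` when `tau2_null` is 0 (the
#'   quantity is undefined without baseline heterogeneity).
#' @export
pseudo_r2 <- function(tau2_null, tau2_model) {
  if (is.na(tau2_null) || tau2_null == 0) {
    return(NA_real_)
  }
  if (tau2_null < 0 || tau2_model < 0) {
    abort("tau2 values must be >= 0", class = "nrimpact_domain_error")
  }
  min(1, max(0, (tau2_null - tau2_model) / tau2_null))
}

#' All-subsets AICc model selection and Akaike-weight driver importance
#'
#' Fits every subset of the candidate drivers (2^p models, capped at 12
#' drivers), ranks them by AICc with
#' \eqn{AICc = -2\ell + 2q + 2q(q+1)/(k-q-1)} (q = coefficients + 1 for the
#' residual variance), converts AICc differences into Akaike weights
#' \eqn{w_m = e^{-\Delta_m/2}/\sum e^{-\Delta/2}}, and scores each driver's
#' importance as the sum of weights over the models containing it. Drivers
#' at or above the `cutoff` (default 0.8) are flagged important. Subsets
#' whose complete-case sample is too small for their size are skipped with
#' a logged reason; if more than half the subsets are skipped the selection
#' aborts.
#'
#' @inheritParams fit_metareg
#' @param drivers Candidate driver columns; defaults to the six moderators
#'   present in `moderators`.
#' @param cutoff Importance cutoff separating unimportant from important
#'   predictors, default 0.8.
#' @return An object of class `nr_importance`: `models` (one row per fitted
#'   subset: drivers, k, tau2, loglik, aicc, delta, weight, pseudo_r2),
#'   `importance` (one row per driver: importance, important, slope sign and
#'   the best-model and model-averaged slopes), `skipped`, `cutoff`,
#'   `tau2_null`. [tidy()] returns the importance table; [autoplot()] draws
#'   the importance bars against the cutoff.
#' @export
all_subsets_selection <- function(es, v, moderators,
                                  drivers = intersect(.moderator_names, names(moderators)),
                                  cutoff = 0.8, method = "DL") {
  drivers <- as.character(drivers)
  p <- length(drivers)
  if (p < 1) abort("need at least one candidate driver", class = "nrimpact_domain_error")
  if (p > 12) {
    abort("all-subsets enumeration is capped at 12 drivers",
      class = "nrimpact_domain_error"
    )
  }
  subsets <- purrr::map(0:(2^p - 1), function(m) drivers[bitwAnd(m, 2^(seq_len(p) - 1)) > 0])
  fits <- vector("list", length(subsets))
  skipped <- character(0)
  for (i in seq_along(subsets)) {
    fits[i] <- list(tryCatch(
      fit_metareg(es, v, moderators, subsets[[i]], method = method),
      nrimpact_insufficient_studies = function(e) {
        skipped <<- c(skipped, paste0(
          "{", paste(subsets[[i]], collapse = ","), "}: ", conditionMessage(e)
        ))
        NULL
      }
    ))
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (sum(!ok) > length(subsets) / 2) {
    abort("more than half of the candidate subsets lack sufficient data; selection aborted",
      class = "nrimpact_insufficient_studies"
    )
  }
  fits <- fits[ok]
  subsets <- subsets[ok]
  tau2_null <- fit_metareg(es, v, moderators, character(0), method = method)$tau2

  models <- purrr::map2_dfr(fits, subsets, function(f, s) {
    tibble(
      drivers = paste(s, collapse = "+"),
      n_drivers = length(s), k = f$k, tau2 = f$tau2,
      loglik = f$loglik, aicc = f$aicc,
      pseudo_r2 = pseudo_r2(tau2_null, f$tau2)
    )
  })
  models$delta <- models$aicc - min(models$aicc)
  models$weight <- exp(-models$delta / 2) / sum(exp(-models$delta / 2))
  models <- dplyr::arrange(models, .data$aicc)

  contains <- vapply(drivers, function(d) {
    vapply(subsets, function(s) d %in% s, logical(1))
  }, logical(length(subsets)))
  contains <- matrix(contains, nrow = length(subsets), ncol = p,
    dimnames = list(NULL, drivers))
  weights_raw <- exp(-(vapply(fits, function(f) f$aicc, numeric(1)) -
    min(models$aicc)) / 2)
  weights_raw <- weights_raw / sum(weights_raw)

  best <- fits[[which.min(vapply(fits, function(f) f$aicc, numeric(1)))]]
  slope_of <- function(fit, d) {
    co <- fit$coefficients
    if (d %in% co$term) co$estimate[co$term == d] else NA_real_
  }
  importance <- purrr::map_dfr(drivers, function(d) {
    imp <- sum(weights_raw[contains[, d]])
    avg <- sum(vapply(seq_along(fits), function(i) {
      s <- slope_of(fits[[i]], d)
      if (is.na(s)) 0 else weights_raw[i] * s
    }, numeric(1)))
    bs <- slope_of(best, d)
    tibble(
      driver = d, importance = imp, important = imp >= cutoff,
      slope_best = bs, slope_averaged = avg,
      slope_sign = sign(if (is.na(bs)) avg else bs)
    )
  })
  structure(
    list(
      models = models, importance = importance, skipped = skipped,
      cutoff = cutoff, tau2_null = tau2_null, best = best
    ),
    class = "nr_importance"
  )
}

#' @export
print.nr_importance <- function(x, ...) {
  cat("All-subsets AICc selection over", nrow(x$models), "models",
    if (length(x$skipped) > 0) paste0("(", length(x$skipped), " skipped)"), "\n")
  cat("Driver importance (sum of Akaike weights, cutoff", x$cutoff, "):\n")
  print(x$importance)
  invisible(x)
}

#' @rdname all_subsets_selection
#' @param x,object An `nr_importance` object.
#' @param ... Unused.
#' @export
tidy.nr_importance <- function(x, ...) x$importance

#' @rdname all_subsets_selection
#' @export
glance.nr_importance <- function(x, ...) {
  tibble(
    n_models = nrow(x$models), n_skipped = length(x$skipped),
    tau2_null = x$tau2_null,
    best_drivers = x$models$drivers[1],
    best_pseudo_r2 = x$models$pseudo_r2[1]
  )
}

#' @rdname all_subsets_selection
#' @export
autoplot.nr_importance <- function(object, ...) {
  df <- object$importance
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$driver, .data$importance),
    y = .data$importance, fill = .data$important
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = "Sum of Akaike weights",
      title = "Model-averaged driver importance"
    ) +
    ggplot2::theme_minimal()
}
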