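#' Raw mean-difference effect size with its variance
#'
#' The effect size is the raw difference in means between treatment and
#' control. Its variance uses the pooled standard deviation of the two arms:
#' \deqn{s_{pooled} = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}},
#' \qquad V_D = \frac{n_1+n_2}{n_1 n_2}\, s_{pooled}^2, \qquad
#' SE_D = \sqrt{V_D}.}
#'
#' @param mean_t,mean_c Arm means (any consistent outcome unit).
#' @param sd_t,sd_c Arm standard deviations, >= 0, not both zero.
#' @param n1,n2 Replicate counts with `n1 + n2 > 2`.
#' @return Tibble with columns `es`, `s_pooled`, `v`, `se_d`.
#' @examples
#' effect_size(10, 8, sd_t = 2, sd_c = 4, n1 = 3, n2 = 3)
#' @export
effect_size <- function(mean_t, mean_c, sd_t, sd_c, n1, n2) {
  if (any(n1 + n2 <= 2)) {
    abort("effect size needs n1 + n2 > 2 (pooled-SD degrees of freedom)",
      class = "nrimpact_domain_error"
    )
  }
  if (any(is.na(sd_t)) || any(is.na(sd_c)) || any(sd_t < 0) || any(sd_c < 0)) {
    abort("arm SDs must be non-negative and non-missing",
      class = "nrimpact_domain_error"
    )
  }
  if (any(sd_t == 0 & sd_c == 0)) {
    abort("both arm SDs are zero: the comparison has no sampling variance",
      class = "nrimpact_zero_variance"
    )
  }
  s_pooled <- sqrt(((n1 - 1) * sd_t^2 + (n2 - 1) * sd_c^2) / (n1 + n2 - 2))
  v <- (n1 + n2) / (n1 * n2) * s_pooled^2
  tibble(
    es = mean_t - mean_c,
    s_pooled = s_pooled,
    v = v,
    se_d = sqrt(v)
  )
}

#' Per-record effect sizes for a grouped observation table
#'
#' Builds the effect-size columns downstream pooling consumes. Two modes
#' exist because group summaries can be read either as absolute means or as
#' treatment-control contrasts:
#' * `"single_group"` (default): the effect size is the treatment-arm value
#'   itself, with per-record variance `sd^2 / n` — used for the absolute
#'   per-Mg burden means.
#' * `"difference"`: the pairwise mean difference with the pooled-SD
#'   variance of [effect_size()].
#'
#' @param obs Imputed observation tibble (needs `sd_treat` / `sd_ctrl`,
#'   see [impute_dispersions()]) carrying the value columns named by
#'   `value_treat` / `value_ctrl`.
#' @param value_treat,value_ctrl Column names of the outcome in each arm.
#' @param sd_treat,sd_ctrl Column names of the outcome SDs.
#' @param mode `"single_group"` or `"difference"`.
#' @return `obs` with `es` and `v` columns appended; rows whose variance
#'   cannot be formed (missing or zero SD) are dropped with a warning.
#' @export
compute_effect_sizes <- function(obs,
                                 value_treat = "loss_treat_mean",
                                 value_ctrl = "loss_ctrl_mean",
                                 sd_treat = "sd_treat",
                                 sd_ctrl = "sd_ctrl",
                                 mode = c("single_group", "difference")) {
  mode <- match.arg(mode)
  yt <- obs[[value_treat]]
  st <- obs[[sd_treat]]
  if (mode == "single_group") {
    es <- yt
    v <- st^2 / obs$n_treat
  } else {
    yc <- obs[[value_ctrl]]
    sc <- obs[[sd_ctrl]]
    sp2 <- ((obs$n_treat - 1) * st^2 + (obs$n_ctrl - 1) * sc^2) /
      (obs$n_treat + obs$n_ctrl - 2)
    es <- yt - yc
    v <- (obs$n_treat + obs$n_ctrl) / (obs$n_treat * obs$n_ctrl) * sp2
  }
  bad <- is.na(v) | v <= 0
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " record(s) without a usable variance"))
  }
  out <- obs
  out$es <- es
  out$v <- v
  out[!bad, , drop = FALSE]
}
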