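# in-code fixtures: tiny schema-valid observation tables

blank_dispersion <- function(n, kind = "SD", value = 1) {
  tibble::tibble(
    disp_treat_kind = rep(kind, n), disp_treat_value = rep(value, n),
    disp_treat_lower = NA_real_, disp_treat_upper = NA_real_,
    disp_treat_level = NA_real_,
    disp_ctrl_kind = rep(kind, n), disp_ctrl_value = rep(value, n),
    disp_ctrl_lower = NA_real_, disp_ctrl_upper = NA_real_,
    disp_ctrl_level = NA_real_
  )
}

make_obs <- function(n = 3,
                     crop = "wheat", pathway = "NH3",
                     n_source = "urea", n_rate = 200,
                     placement = "surface", amendment = "none",
                     loss_treat = 30, loss_ctrl = 3,
                     yield_treat = 6, yield_ctrl = 4,
                     n_treat = 4L, n_ctrl = 4L,
                     sd = 2) {
  dplyr::bind_cols(
    tibble::tibble(
      study_id = sprintf("s%03d", seq_len(n)),
      site_id = sprintf("x%03d", seq_len(n)),
      province = "P01",
      crop = rep_len(crop, n), pathway = rep_len(pathway, n),
      n_source = rep_len(n_source, n), n_rate = rep_len(n_rate, n),
      placement = rep_len(placement, n), amendment = rep_len(amendment, n),
      loss_treat_mean = rep_len(loss_treat, n),
      loss_ctrl_mean = rep_len(loss_ctrl, n),
      yield_treat_mean = rep_len(yield_treat, n),
      yield_ctrl_mean = rep_len(yield_ctrl, n),
      n_treat = rep_len(n_treat, n), n_ctrl = rep_len(n_ctrl, n)
    ),
    blank_dispersion(n, value = sd),
    tibble::tibble(
      temperature = 15, water_load = 500, soil_ph = 6.5,
      som = 20, stn = 1.2, clay = 300
    )
  )
}

# independent grid-search minimizer of sum(W * (es - mu)^2), refined to tol
grid_pool_oracle <- function(es, v, tau2, tol = 1e-8) {
  w <- 1 / (v + tau2)
  lo <- min(es) - 1
  hi <- max(es) + 1
  for (iter in 1:60) {
    grid <- seq(lo, hi, length.out = 201)
    obj <- vapply(grid, function(mu) sum(w * (es - mu)^2), numeric(1))
    best <- grid[which.min(obj)]
    step <- (hi - lo) / 200
    lo <- best - step
    hi <- best + step
    if (step < tol / 10) break
  }
  best
}
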