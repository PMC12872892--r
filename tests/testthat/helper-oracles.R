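# Independent oracles and fixture builders used across the suite.

# Forward pour-through cycle: start at container capacity with the supply
# solution, let the plant absorb `uptake_conc` mg per litre of the `vt` litres
# it transpires, refill with DI to capacity. Returns the resulting leachate
# concentration. uptake_from_depletion() must invert this exactly.
forward_cycle_leachate <- function(supply, uptake_conc, capacity_l, vt_l) {
  residual_mass <- supply * capacity_l - uptake_conc * vt_l
  residual_mass / capacity_l
}

# Welch t statistic, Welch-Satterthwaite df and two-tailed p from the textbook
# formulas, written independently of stats::t.test.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Split-plot sums of squares by explicit design-matrix least squares: each
# stratum SS is an RSS drop along a nested model sequence.
rm_projection_oracle <- function(data, response, subject, between, within) {
  d <- data.frame(
    y = data[[response]], subject = factor(data[[subject]]),
    between = factor(data[[between]]), within = factor(data[[within]])
  )
  rss <- function(f) sum(stats::residuals(stats::lm(f, data = d))^2)
  ss_total <- sum((d$y - mean(d$y))^2)
  r_b <- rss(y ~ between)
  r_s <- rss(y ~ subject)
  r_w <- rss(y ~ subject + within)
  r_i <- rss(y ~ subject + within + between:within)
  g <- nlevels(d$between)
  n_sub <- nlevels(d$subject)
  d_occ <- nlevels(d$within)
  ss <- list(
    between = ss_total - r_b,
    subject_error = r_b - r_s,
    within = r_s - r_w,
    interaction = r_w - r_i,
    residual = r_i
  )
  df <- list(
    between = g - 1, subject_error = n_sub - g, within = d_occ - 1,
    interaction = (g - 1) * (d_occ - 1),
    residual = (n_sub - g) * (d_occ - 1)
  )
  f_of <- function(eff, err) (ss[[eff]] / df[[eff]]) / (ss[[err]] / df[[err]])
  list(
    ss = ss, df = df,
    f = list(between = f_of("between", "subject_error"),
             within = f_of("within", "residual"),
             interaction = f_of("interaction", "residual")),
    p = list(
      between = stats::pf(f_of("between", "subject_error"),
                          df$between, df$subject_error, lower.tail = FALSE),
      within = stats::pf(f_of("within", "residual"),
                         df$within, df$residual, lower.tail = FALSE),
      interaction = stats::pf(f_of("interaction", "residual"),
                              df$interaction, df$residual, lower.tail = FALSE)
    )
  )
}

# Cook's distance by leave-one-out refitting of the cell-means lm.
cooks_loo_oracle <- function(d) {
  fit <- stats::lm(y ~ between * within, data = d)
  p <- fit$rank
  s2 <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  vapply(seq_len(nrow(d)), function(i) {
    fit_i <- stats::lm(y ~ between * within, data = d[-i, , drop = FALSE])
    pred <- stats::predict(fit_i, newdata = d)
    sum((stats::fitted(fit) - pred)^2) / (p * s2)
  }, numeric(1))
}

# balanced split-plot fixture
make_rm_data <- function(seed = 1, g = 2, n = 4, d = 5, effect = 0,
                         effect_cell = NULL) {
  set.seed(seed)
  dat <- expand.grid(
    plant_id = paste0("p", seq_len(g * n)),
    date = paste0("d", seq_len(d)),
    stringsAsFactors = FALSE
  )
  grp <- rep(LETTERS[seq_len(g)], each = n)
  dat$cultivar <- grp[as.integer(sub("p", "", dat$plant_id))]
  dat$uptake_mg_per_l <- stats::rnorm(nrow(dat))
  if (!is.null(effect_cell)) {
    hit <- dat$cultivar == effect_cell[1] & dat$date == effect_cell[2]
    dat$uptake_mg_per_l[hit] <- dat$uptake_mg_per_l[hit] + effect
  }
  dat
}

zero_noise_config <- function(...) {
  trial_config(balance_noise_sd_g = 0, assay_noise_rel_sd = 0, ...)
}

# pipeline-equivalent uptake recovery from a trial dataset (gravimetric
# window volumes + depletion inversion), lighter than run_pipeline()
recover_uptake <- function(ds) {
  windows <- ds$mass_series |>
    dplyr::group_by(container_id) |>
    dplyr::group_modify(~ window_water_loss(.x)) |>
    dplyr::ungroup()
  ds$solution |>
    tidyr::pivot_wider(names_from = sample_type,
                       values_from = concentration_mg_per_l) |>
    dplyr::rename(supply_mg_per_l = supply, leachate_mg_per_l = leachate) |>
    dplyr::inner_join(windows, by = c(plant_id = "container_id", "date")) |>
    dplyr::mutate(capacity_l = ds$config$capacity_l) |>
    uptake_from_depletion()
}
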