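test_that("welch_t_test matches the closed-form recomputation", {
  a <- c(10, 12, 14, 16); b <- c(11, 13, 15, 17)
  got <- welch_t_test(a, b)
  want <- welch_oracle(a, b)
  expect_equal(got$statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p.value, want$p, tolerance = 1e-10)

  set.seed(10)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:9, 1), sd = stats::runif(1, 0.5, 3))
    y <- stats::rnorm(sample(3:9, 1), mean = stats::runif(1, -1, 1))
    got <- welch_t_test(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$statistic, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p.value, want$p, tolerance = 1e-10)
  }
})

test_that("welch_t_test symmetry, location invariance and degenerate handling", {
  x <- c(1, 2, 3, 4)
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  y <- c(2, 5, 4, 9)
  base <- welch_t_test(x, y)
  shifted <- welch_t_test(x + 100, y + 100)
  expect_equal(base$statistic, shifted$statistic)
  expect_equal(base$df, shifted$df)
  expect_equal(base$p.value, shifted$p.value)

  # equal sizes and equal variances reduce Welch df to n1 + n2 - 2
  expect_equal(welch_t_test(x, x + 5)$df, length(x) * 2 - 2)

  expect_error(welch_t_test(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("rm_anova matches the design-matrix projection oracle", {
  fixtures <- list(
    make_rm_data(seed = 21, g = 2, n = 4, d = 5, effect = 2, effect_cell = c("A", "d2")),
    make_rm_data(seed = 22, g = 2, n = 4, d = 10),
    make_rm_data(seed = 23, g = 3, n = 3, d = 4, effect = 1, effect_cell = c("B", "d1"))
  )
  for (dat in fixtures) {
    fit <- rm_anova(dat, "uptake_mg_per_l", subject = "plant_id")
    oracle <- rm_projection_oracle(dat, "uptake_mg_per_l", "plant_id",
                                   "cultivar", "date")
    tab <- tidy(fit)
    get <- function(eff, col) tab[[col]][tab$effect == eff]
    expect_equal(get("cultivar", "sumsq"), oracle$ss$between, tolerance = 1e-8)
    expect_equal(get("date", "sumsq"), oracle$ss$within, tolerance = 1e-8)
    expect_equal(get("cultivar:date", "sumsq"), oracle$ss$interaction, tolerance = 1e-8)
    expect_equal(get("cultivar", "statistic"), oracle$f$between, tolerance = 1e-8)
    expect_equal(get("date", "statistic"), oracle$f$within, tolerance = 1e-8)
    expect_equal(get("cultivar:date", "statistic"), oracle$f$interaction, tolerance = 1e-8)
    expect_equal(get("cultivar", "p.value"), oracle$p$between, tolerance = 1e-8)
    # df match the balanced closed forms
    g <- length(unique(dat$cultivar)); n <- length(unique(dat$plant_id)) / g
    d <- length(unique(dat$date))
    expect_equal(get("cultivar", "df"), g - 1)
    expect_equal(get("cultivar", "den_df"), g * n - g)
    expect_equal(get("date", "df"), d - 1)
    expect_equal(get("date", "den_df"), (g * n - g) * (d - 1))

    # stratum decomposition: total SS = between-subjects + within strata
    y <- dat$uptake_mg_per_l
    ss_total <- sum((y - mean(y))^2)
    parts <- sum(tab$sumsq) + fit$strata$ms_subject * fit$strata$df_subject +
      fit$strata$ms_residual * fit$strata$df_residual
    expect_equal(parts, ss_total, tolerance = 1e-9)
  }
})

test_that("rm_anova handles degenerate and structured responses as forced by construction", {
  dat <- make_rm_data(seed = 31)
  dat$uptake_mg_per_l <- 5
  fit <- rm_anova(dat, "uptake_mg_per_l", subject = "plant_id")
  expect_true(fit$degenerate)
  expect_true(all(is.nan(tidy(fit)$statistic)))

  # constant shift of one cultivar only: all variation in the between stratum
  dat2 <- make_rm_data(seed = 32)
  dat2$uptake_mg_per_l <- ifelse(dat2$cultivar == "A", 3, 0)
  fit2 <- rm_anova(dat2, "uptake_mg_per_l", subject = "plant_id")
  tab2 <- tidy(fit2)
  expect_equal(tab2$sumsq[tab2$effect == "date"], 0)
  expect_equal(tab2$sumsq[tab2$effect == "cultivar:date"], 0)
  expect_gt(tab2$sumsq[tab2$effect == "cultivar"], 0)

  expect_error(rm_anova(make_rm_data()[-1, ], "uptake_mg_per_l", subject = "plant_id"),
               "Unbalanced")
})

test_that("pairwise contrasts agree with emmeans on the same aov fit", {
  skip_if_not_installed("emmeans")
  dat <- make_rm_data(seed = 41, effect = 2, effect_cell = c("A", "d2"))
  fit <- rm_anova(dat, "uptake_mg_per_l", subject = "plant_id")
  got <- pairwise_contrasts(fit)

  d2 <- dat
  d2$plant_id <- factor(d2$plant_id); d2$cultivar <- factor(d2$cultivar)
  d2$date <- factor(d2$date)
  # embed the data in the call: emmeans re-evaluates aov() out of this scope
  af <- do.call(stats::aov,
                list(uptake_mg_per_l ~ cultivar * date + Error(plant_id),
                     data = d2))
  em <- summary(emmeans::contrast(emmeans::emmeans(af, ~ cultivar | date, data = d2),
                                  method = "pairwise", adjust = "none"))
  expect_equal(got$estimate, em$estimate, tolerance = 1e-8)
  expect_equal(got$se, em$SE, tolerance = 1e-8)
  expect_equal(got$df, em$df, tolerance = 1e-6)
  expect_equal(got$p.value, em$p.value, tolerance = 1e-8)
  # family-level Bonferroni: one family per element = all contrasts across dates
  expect_equal(got$p.adjusted, pmin(1, nrow(got) * got$p.value))

  within <- pairwise_contrasts(fit, family = "within_between")
  em2 <- summary(emmeans::contrast(emmeans::emmeans(af, ~ date | cultivar, data = d2),
                                   method = "pairwise", adjust = "none"))
  expect_equal(sort(abs(within$estimate)), sort(abs(em2$estimate)), tolerance = 1e-8)
  expect_equal(within$se[1], em2$SE[1], tolerance = 1e-8)
})

test_that("an injected cultivar-by-date difference carries the smallest adjusted p, permutation-confirmed", {
  dat <- make_rm_data(seed = 51, effect = 3, effect_cell = c("A", "d3"))
  fit <- rm_anova(dat, "uptake_mg_per_l", subject = "plant_id")
  got <- pairwise_contrasts(fit)
  expect_equal(got$level[which.min(got$p.adjusted)], "d3")

  # permutation oracle at rank level: permute cultivar labels over subjects,
  # largest |cell-mean difference| should sit at the injected date
  subjects <- unique(dat$plant_id)
  labels <- ifelse(as.integer(sub("p", "", subjects)) <= 4, "A", "B")
  cm <- tapply(dat$uptake_mg_per_l, list(dat$cultivar, dat$date), mean)
  obs_diff <- abs(cm["A", ] - cm["B", ])
  set.seed(99)
  perm_ge <- rep(0, length(obs_diff))
  for (b in 1:2000) {
    perm <- sample(labels)
    cv <- perm[match(dat$plant_id, subjects)]
    pd <- tapply(dat$uptake_mg_per_l, list(cv, dat$date), mean)
    perm_ge <- perm_ge + (abs(pd["A", ] - pd["B", ]) >= obs_diff)
  }
  perm_p <- (perm_ge + 1) / 2001
  expect_equal(names(which.min(perm_p)), "d3")
  expect_equal(which.min(perm_p), which.min(setNames(got$p.value, got$level)),
               ignore_attr = TRUE)
})

test_that("bonferroni_adjust is the capped product, monotone in family size", {
  expect_equal(bonferroni_adjust(0.01, 10), 0.1)
  expect_equal(bonferroni_adjust(0.2, 10), 1)
  p <- c(0.001, 0.04, 0.3)
  expect_equal(bonferroni_adjust(p), stats::p.adjust(p, "bonferroni"))
  for (m in 1:6) {
    expect_true(all(bonferroni_adjust(p, m) <= bonferroni_adjust(p, m + 1)))
  }
  expect_true(all(bonferroni_adjust(p, 1000) <= 1))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
})

test_that("influence diagnostics match hat-matrix identities and a leave-one-out oracle", {
  # balanced one-way layout: every leverage is 1/n and leverages sum to g
  oneway <- data.frame(
    uptake_mg_per_l = stats::rnorm(12), cultivar = rep(c("A", "B", "C"), each = 4),
    date = "d1"
  )
  d1 <- influence_diagnostics(oneway)
  expect_equal(d1$leverage, rep(1 / 4, 12))
  expect_equal(sum(d1$leverage), 3)

  dat <- make_rm_data(seed = 61, effect = 2, effect_cell = c("B", "d4"))
  diag <- influence_diagnostics(dat)
  expect_equal(sum(diag$leverage), 2 * 5)  # one parameter per cell

  d <- data.frame(y = dat$uptake_mg_per_l, between = factor(dat$cultivar),
                  within = factor(dat$date))
  expect_equal(diag$cooksd, cooks_loo_oracle(d), tolerance = 1e-8)

  # duplicating an observation strictly reduces its leverage
  dup <- rbind(d, d[1, ])
  h_before <- unname(stats::hatvalues(stats::lm(y ~ between * within, data = d)))[1]
  h_after <- unname(stats::hatvalues(stats::lm(y ~ between * within, data = dup)))[1]
  expect_lt(h_after, h_before)
})

test_that("null simulation keeps the cultivar-effect type-I rate near nominal", {
  set.seed(777)
  reps <- 400
  rej <- 0
  template <- make_rm_data(seed = 1, g = 2, n = 4, d = 10)
  for (i in seq_len(reps)) {
    template$uptake_mg_per_l <- stats::rnorm(nrow(template))
    fit <- rm_anova(template, "uptake_mg_per_l", subject = "plant_id")
    rej <- rej + (glance(fit)$p_between < 0.05)
  }
  rate <- rej / reps
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / reps)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})
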