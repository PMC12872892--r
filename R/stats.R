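#' Welch two-sample t-test
#'
#' Two-tailed Welch test (unpooled variances, Welch-Satterthwaite degrees of
#' freedom), the appropriate comparison for small replicate groups with
#' possibly unequal variances. A thin tidy wrapper around
#' [stats::t.test()] that validates degenerate inputs up front.
#'
#' @param x,y numeric samples, each of length >= 2; at least one must have
#'   nonzero variance.
#' @return a one-row tibble: `estimate` (mean difference x - y), `statistic`
#'   (t), `df`, `p.value`.
#' @examples
#' welch_t_test(c(10, 12, 14, 16), c(11, 13, 15, 17))
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each sample must contain at least 2 observations.")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Samples must be finite.")
  }
  if (var(x) == 0 && var(y) == 0) {
    abort("Degenerate input: both samples have zero variance.")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    estimate = mean(x) - mean(y),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p.value = max(unname(ht$p.value), 1e-16)
  )
}

#' @keywords internal
check_rm_design <- function(data, response, subject, between, within) {
  for (col in c(response, subject, between, within)) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found in `data`."))
  }
  if (any(!is.finite(data[[response]]))) abort("Response values must be finite.")
  # every subject x within-level cell present exactly once
  cells <- table(data[[subject]], data[[within]])
  if (any(cells != 1)) {
    abort(paste0(
      "Unbalanced repeated-measures layout: every subject x ", within,
      " cell must be observed exactly once. Handle missing observations ",
      "(e.g. listwise deletion) before calling rm_anova()."
    ))
  }
  # subjects nested in the between factor
  nest <- table(data[[subject]], data[[between]])
  if (any(rowSums(nest > 0) != 1)) {
    abort(paste0("Each subject must belong to exactly one ", between, " level."))
  }
  invisible(data)
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# subject x occasion matrix (reported informationally; F tests are uncorrected)
#' @keywords internal
gg_epsilon <- function(data, response, subject, between, within) {
  wide <- tapply(data[[response]], list(data[[subject]], data[[within]]), mean)
  grp <- tapply(as.character(data[[between]]), data[[subject]], function(x) x[1])
  grp <- grp[rownames(wide)]
  centered <- wide
  for (g in unique(grp)) {
    rows <- grp == g
    centered[rows, ] <- sweep(wide[rows, , drop = FALSE], 2,
                              colMeans(wide[rows, , drop = FALSE]))
  }
  n <- nrow(wide)
  S <- crossprod(centered) / (n - length(unique(grp)))
  d <- ncol(S)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  tr <- sum(diag(Sc))
  denom <- (d - 1) * sum(Sc^2)
  if (denom <= 0) return(NA_real_)
  min(1, tr^2 / denom)
}

#' Repeated-measures ANOVA (between x within split-plot)
#'
#' Univariate mixed-model analysis of variance for a balanced repeated-measures
#' layout: a grouping factor between subjects (cultivar), an occasion factor
#' within subjects (sampling date), and their interaction. The between effect
#' is tested against the subject-within-group stratum; the within effect and
#' the interaction against the subject x occasion residual stratum. F tests
#' are the uncorrected univariate tests; the Greenhouse-Geisser epsilon is
#' reported alongside for sphericity assessment but not applied.
#'
#' @param data a long-format data frame, one row per subject x occasion.
#' @param response,subject,between,within column names (strings) for the
#'   response value, subject identifier, between-subjects factor and
#'   within-subjects factor. Defaults match the package's uptake-record
#'   schema.
#' @return an object of class `rm_anova` with a `table` of effects (`effect`,
#'   `df`, `den_df`, `sumsq`, `meansq`, `statistic`, `p.value`), the error
#'   strata, `epsilon_gg`, and a `degenerate` flag set when the response has no
#'   variance at all (F is then NaN). Supports [tidy()] and [glance()].
#' @examples
#' dat <- expand.grid(plant = paste0("p", 1:8), date = paste0("d", 1:5))
#' dat$cultivar <- rep(c("A", "B"), each = 4)[match(dat$plant, paste0("p", 1:8))]
#' set.seed(1)
#' dat$uptake <- rnorm(nrow(dat))
#' fit <- rm_anova(dat, "uptake", subject = "plant")
#' tidy(fit)
#' @export
rm_anova <- function(data, response = "uptake_mg_per_l", subject = "plant_id",
                     between = "cultivar", within = "date") {
  check_rm_design(data, response, subject, between, within)
  d <- data.frame(
    y = data[[response]],
    subject = factor(data[[subject]]),
    between = factor(data[[between]]),
    within = factor(data[[within]])
  )
  if (nlevels(d$between) < 2) abort("Need at least 2 between-subject groups.")
  if (nlevels(d$within) < 2) abort("Need at least 2 within-subject occasions.")

  fit <- aov(y ~ between * within + Error(subject), data = d)
  s <- summary(fit)
  sub_tab <- s[["Error: subject"]][[1]]
  wit_tab <- s[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))

  ms_sub <- sub_tab[rn(sub_tab) == "Residuals", "Mean Sq"]
  df_sub <- sub_tab[rn(sub_tab) == "Residuals", "Df"]
  ms_res <- wit_tab[rn(wit_tab) == "Residuals", "Mean Sq"]
  df_res <- wit_tab[rn(wit_tab) == "Residuals", "Df"]

  pick <- function(tab, label, den_df) {
    row <- tab[rn(tab) == label, , drop = FALSE]
    tibble::tibble(
      df = row[["Df"]], den_df = den_df, sumsq = row[["Sum Sq"]],
      meansq = row[["Mean Sq"]], statistic = row[["F value"]],
      p.value = pmax(row[["Pr(>F)"]], 1e-16)
    )
  }
  table <- dplyr::bind_rows(
    dplyr::mutate(pick(sub_tab, "between", df_sub), effect = between),
    dplyr::mutate(pick(wit_tab, "within", df_res), effect = within),
    dplyr::mutate(pick(wit_tab, "between:within", df_res),
                  effect = paste0(between, ":", within))
  ) |>
    dplyr::relocate("effect")

  degenerate <- var(d$y) == 0 || isTRUE(all(table$sumsq < 1e-24 & ms_sub < 1e-24))
  if (degenerate) {
    table$statistic <- NaN
    table$p.value <- NaN
  }

  structure(
    list(
      table = table,
      strata = list(ms_subject = ms_sub, df_subject = df_sub,
                    ms_residual = ms_res, df_residual = df_res),
      epsilon_gg = gg_epsilon(d, "y", "subject", "between", "within"),
      degenerate = degenerate,
      dims = list(
        n_groups = nlevels(d$between),
        n_subjects_per_group = nrow(unique(d[c("subject", "between")])) / nlevels(d$between),
        n_occasions = nlevels(d$within)
      ),
      names = list(response = response, subject = subject,
                   between = between, within = within),
      cell_means = tapply(d$y, list(d$between, d$within), mean),
      data = d
    ),
    class = "rm_anova"
  )
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", x$names$between, " between x ",
      x$names$within, " within)\n", sep = "")
  print(x$table)
  cat(sprintf("Greenhouse-Geisser epsilon: %.3f (reported, not applied)\n",
              x$epsilon_gg))
  if (x$degenerate) cat("NOTE: degenerate (constant) response; F undefined.\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rm_anova
#' @param x an `rm_anova` object.
#' @param ... unused.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  p <- setNames(x$table$p.value, x$table$effect)
  tibble::tibble(
    n_groups = x$dims$n_groups,
    n_subjects_per_group = x$dims$n_subjects_per_group,
    n_occasions = x$dims$n_occasions,
    epsilon_gg = x$epsilon_gg,
    degenerate = x$degenerate,
    p_between = unname(p[x$names$between]),
    p_within = unname(p[x$names$within]),
    p_interaction = unname(p[paste0(x$names$between, ":", x$names$within)])
  )
}

#' Marginal-means pairwise contrasts with Bonferroni adjustment
#'
#' Pairwise comparisons of estimated marginal (cell) means from a fitted
#' [rm_anova()], with standard errors built from the appropriate error
#' strata of the balanced split-plot layout:
#'
#' * `"between_within"` (default family): group differences at each occasion.
#'   The variance combines the subject and residual strata,
#'   `2/n * (MS_subject + (d - 1) MS_residual) / d`, with Welch-Satterthwaite
#'   degrees of freedom.
#' * `"within_between"`: occasion pair differences within each group, using
#'   the residual stratum only, `2 MS_residual / n`.
#'
#' Adjusted p-values are Bonferroni: `min(1, m * p)` with `m` the family size.
#'
#' @param fit an `rm_anova` object.
#' @param family which contrast family to compute.
#' @return a tibble with `contrast`, the conditioning level, `estimate`,
#'   `se`, `df`, `statistic`, `p.value`, `p.adjusted`, and the family size
#'   `m`.
#' @export
pairwise_contrasts <- function(fit, family = c("between_within", "within_between")) {
  if (!inherits(fit, "rm_anova")) abort("`fit` must be an rm_anova object.")
  family <- match.arg(family)
  if (fit$degenerate) abort("Contrasts are undefined for a degenerate (constant) fit.")
  cm <- fit$cell_means
  n <- fit$dims$n_subjects_per_group
  d <- fit$dims$n_occasions
  ms_sub <- fit$strata$ms_subject
  df_sub <- fit$strata$df_subject
  ms_res <- fit$strata$ms_residual
  df_res <- fit$strata$df_residual
  groups <- rownames(cm)
  occasions <- colnames(cm)

  if (family == "between_within") {
    se <- sqrt((2 / n) * (ms_sub + (d - 1) * ms_res) / d)
    df_w <- (ms_sub + (d - 1) * ms_res)^2 /
      (ms_sub^2 / df_sub + ((d - 1) * ms_res)^2 / df_res)
    pairs_g <- utils::combn(groups, 2, simplify = FALSE)
    out <- tidyr::expand_grid(
      pair = pairs_g,
      level = occasions
    ) |>
      dplyr::mutate(
        contrast = purrr::map_chr(.data$pair, ~ paste(.x, collapse = " - ")),
        estimate = purrr::map2_dbl(.data$pair, .data$level,
                                   ~ cm[.x[1], .y] - cm[.x[2], .y]),
        se = se, df = df_w
      ) |>
      dplyr::select(-"pair")
  } else {
    se <- sqrt(2 * ms_res / n)
    df_w <- df_res
    pairs_o <- utils::combn(occasions, 2, simplify = FALSE)
    out <- tidyr::expand_grid(
      pair = pairs_o,
      level = groups
    ) |>
      dplyr::mutate(
        contrast = purrr::map_chr(.data$pair, ~ paste(.x, collapse = " - ")),
        estimate = purrr::map2_dbl(.data$pair, .data$level,
                                   ~ cm[.y, .x[1]] - cm[.y, .x[2]]),
        se = se, df = df_w
      ) |>
      dplyr::select(-"pair")
  }
  m <- nrow(out)
  out |>
    dplyr::mutate(
      statistic = .data$estimate / .data$se,
      p.value = pmax(2 * pt(-abs(.data$statistic), .data$df), 1e-16),
      p.adjusted = bonferroni_adjust(.data$p.value, m),
      m = m
    ) |>
    dplyr::relocate("contrast", "level")
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for a family of `m` tests; monotone in `m` and never above
#' 1.
#'
#' @param p raw p-values.
#' @param m family size; defaults to `length(p)`.
#' @return adjusted p-values.
#' @examples
#' bonferroni_adjust(c(0.01, 0.2), m = 10)
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) abort("Family size `m` must be >= 1.")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  pmin(1, m * p)
}

#' Leverage and Cook's distance for a cell-means model
#'
#' Fits the fixed-effects cell-means model implied by the group x occasion
#' layout with [stats::lm()] and returns per-observation influence
#' diagnostics: leverage (hat-matrix diagonal) and Cook's distance, the
#' assumption checks used alongside the repeated-measures analysis.
#'
#' @param data long-format data frame.
#' @param response,between,within column names, as in [rm_anova()].
#' @return the input rows with `.fitted`, `.resid`, `leverage` and `cooksd`
#'   columns appended.
#' @export
influence_diagnostics <- function(data, response = "uptake_mg_per_l",
                                  between = "cultivar", within = "date") {
  for (col in c(response, between, within)) {
    if (!col %in% names(data)) abort(paste0("Column `", col, "` not found."))
  }
  d <- data.frame(
    y = data[[response]],
    between = factor(data[[between]]),
    within = factor(data[[within]])
  )
  # drop single-level factors so one-way layouts reduce to the one-way fit
  terms <- c(
    if (nlevels(d$between) > 1) "between",
    if (nlevels(d$within) > 1) "within"
  )
  if (length(terms) == 0) abort("Need at least one factor with 2+ levels.")
  fit <- lm(stats::reformulate(paste(terms, collapse = "*"), "y"), data = d)
  if (fit$rank < ncol(model.matrix(fit))) {
    abort("Rank-deficient design: some group x occasion cells are empty.")
  }
  tibble::as_tibble(data) |>
    dplyr::mutate(
      .fitted = unname(fit$fitted.values),
      .resid = unname(fit$residuals),
      leverage = unname(hatvalues(fit)),
      cooksd = unname(cooks.distance(fit))
    )
}
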