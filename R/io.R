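#' Read trial input files
#'
#' Readers for the three CSV schemas the analysis consumes (UTF-8, comma
#' separated, ISO-8601 dates) and for YAML supply recipes keyed by element
#' symbol. Each reader validates its schema and element symbols up front and
#' fails with the offending file named.
#'
#' * solution samples: `date, plant_id, cultivar, element,
#'   concentration_mg_per_l, sample_type` (`supply` or `leachate`)
#' * tissue profiles: `plant_id, cultivar, organ, element,
#'   concentration_mg_per_g, organ_dry_mass_g`
#' * mass log: `timestamp, container_id, mass_g`
#'
#' @param path file path.
#' @return a tibble (readers) or named numeric vector (`read_recipe()`).
#' @name readers
NULL

#' @keywords internal
check_schema <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(basename(path), ": missing column(s) ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  invisible(df)
}

#' @rdname readers
#' @export
read_solution_samples <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("date", "plant_id", "cultivar", "element",
                     "concentration_mg_per_l", "sample_type"), path)
  if (!all(df$sample_type %in% c("supply", "leachate"))) {
    abort(paste0(basename(path), ": sample_type must be 'supply' or 'leachate'."))
  }
  check_elements(df$element)
  df$date <- as.Date(df$date)
  df
}

#' @rdname readers
#' @export
read_tissue_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("plant_id", "cultivar", "organ", "element",
                     "concentration_mg_per_g", "organ_dry_mass_g"), path)
  ok <- df$organ %in% c("leaf", "stem", "root", "flower")
  if (!all(ok)) {
    abort(paste0(basename(path), ": unknown organ(s): ",
                 paste(unique(df$organ[!ok]), collapse = ", "), "."))
  }
  check_elements(df$element)
  df
}

#' @rdname readers
#' @export
read_mass_log <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, c("timestamp", "container_id", "mass_g"), path)
  if (!inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC")
  }
  df
}

#' @rdname readers
#' @export
read_recipe <- function(path) {
  if (grepl("[.]ya?ml$", path)) {
    rec <- unlist(yaml::read_yaml(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    check_schema(df, c("element", "mg_per_l"), path)
    rec <- setNames(df$mg_per_l, df$element)
  }
  check_elements(names(rec))
  if (any(rec < 0)) abort(paste0(basename(path), ": recipe concentrations must be >= 0."))
  rec
}

#' Write a simulated trial to CSV files
#'
#' Emits the exact schemas the readers consume (plus the ground-truth ledger),
#' so a simulated dataset can round-trip through the file-based pipeline.
#'
#' @param dataset a `trial_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_trial_csvs <- function(dataset, dir) {
  if (!inherits(dataset, "trial_dataset")) abort("`dataset` must be a trial_dataset.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mass_log = file.path(dir, "mass_log.csv"),
    solution = file.path(dir, "solution_samples.csv"),
    tissue = file.path(dir, "tissue_profiles.csv"),
    recipe = file.path(dir, "recipe.csv"),
    ledger_events = file.path(dir, "ledger_events.csv")
  )
  readr::write_csv(dataset$mass_series, paths["mass_log"])
  readr::write_csv(dataset$solution, paths["solution"])
  readr::write_csv(dataset$tissue, paths["tissue"])
  readr::write_csv(
    tibble::tibble(element = names(dataset$recipe), mg_per_l = unname(dataset$recipe)),
    paths["recipe"]
  )
  readr::write_csv(dataset$ledger$events, paths["ledger_events"])
  invisible(paths)
}

#' @keywords internal
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

#' Run the full mass-balance pipeline
#'
#' Orchestrates every stage over a trial dataset: gravimetric water use
#' (daily transpiration, per-event 12-h window volumes, cumulative totals),
#' solution-depletion uptake, water-use efficiency, organ-explicit and
#' biomass-weighted input-concentration predictions, deviation scoring with
#' best-predictor selection, and the statistical layer (per-element
#' repeated-measures ANOVA with Bonferroni marginal-means contrasts, Welch
#' cultivar comparisons per tissue source).
#'
#' The run is deterministic given its inputs and options. Summary means carry
#' n and SEM (sample SD / sqrt(n), n = replicate plants).
#'
#' @param data a `trial_dataset` from [simulate_trial()], or a named list with
#'   tibbles `mass_series`, `solution`, `tissue` following the reader schemas.
#' @param capacity_l substrate solution capacity per container, L (defaults
#'   to the dataset's config where available).
#' @param threshold_g irrigation detection threshold, g.
#' @param smooth rolling-median smoothing of mass traces before differencing.
#' @param day_window the 12-h uptake window, `c(start, end)` in `"HH:MM"`.
#' @param contrast_family contrast family for [pairwise_contrasts()].
#' @return an object of class `report_bundle`: tibbles `wue`, `uptake_records`,
#'   `uptake_summary` (cultivar x element x source means +/- SEM),
#'   `deviations`, `best_predictors`, a named list `anova` of per-element
#'   [rm_anova()] fits, `contrasts`, `welch`, and a `provenance` list
#'   (option hash, package version, timestamp-free).
#' @export
run_pipeline <- function(data, capacity_l = NULL, threshold_g = 50,
                         smooth = FALSE, day_window = c("07:00", "19:00"),
                         contrast_family = "between_within") {
  if (inherits(data, "trial_dataset")) {
    capacity_l <- capacity_l %||% data$config$capacity_l
    inputs <- list(mass_series = data$mass_series, solution = data$solution,
                   tissue = data$tissue)
  } else {
    inputs <- data
  }
  for (nm in c("mass_series", "solution", "tissue")) {
    if (is.null(inputs[[nm]])) abort(paste0("`data` lacks component `", nm, "`."))
  }
  if (is.null(capacity_l)) abort("`capacity_l` must be supplied.")

  plants <- inputs$solution |>
    dplyr::distinct(.data$plant_id, .data$cultivar)

  # --- gravimetric stage ---------------------------------------------------
  by_container <- split(inputs$mass_series, inputs$mass_series$container_id)
  daily <- purrr::imap_dfr(by_container, function(s, id) {
    daily_water_loss(s, threshold_g = threshold_g, smooth = smooth) |>
      dplyr::mutate(container_id = id, .before = 1)
  })
  windows <- purrr::imap_dfr(by_container, function(s, id) {
    window_water_loss(s, window = day_window, smooth = smooth) |>
      dplyr::mutate(container_id = id, .before = 1)
  })
  totals <- cumulative_water_use(daily)

  # --- depletion uptake ----------------------------------------------------
  cycles <- inputs$solution |>
    tidyr::pivot_wider(names_from = "sample_type",
                       values_from = "concentration_mg_per_l") |>
    dplyr::rename(supply_mg_per_l = "supply", leachate_mg_per_l = "leachate") |>
    dplyr::inner_join(windows, by = c(plant_id = "container_id", date = "date")) |>
    dplyr::mutate(capacity_l = capacity_l)
  uptake_records <- uptake_from_depletion(cycles)

  # --- WUE -----------------------------------------------------------------
  harvest <- inputs$tissue |>
    dplyr::distinct(.data$plant_id, .data$cultivar, .data$organ, .data$organ_dry_mass_g) |>
    dplyr::group_by(.data$plant_id, .data$cultivar) |>
    dplyr::summarise(dry_mass_g = sum(.data$organ_dry_mass_g), .groups = "drop")
  wue_tbl <- harvest |>
    dplyr::inner_join(totals, by = c(plant_id = "container_id")) |>
    dplyr::mutate(wue_g_per_l = compute_wue(.data$dry_mass_g, .data$total_l,
                                            .data$plant_id))

  # --- predictions ---------------------------------------------------------
  weighted <- biomass_weighted_mean(
    inputs$tissue, by = c("plant_id", "cultivar")
  ) |>
    dplyr::transmute(.data$plant_id, .data$cultivar, .data$element,
                     source = "weighted",
                     concentration_mg_per_g = .data$weighted_mg_per_g)
  per_organ <- inputs$tissue |>
    dplyr::transmute(.data$plant_id, .data$cultivar, .data$element,
                     source = .data$organ, .data$concentration_mg_per_g)
  predictions_plant <- dplyr::bind_rows(per_organ, weighted) |>
    dplyr::inner_join(dplyr::select(wue_tbl, "plant_id", "wue_g_per_l"),
                      by = "plant_id") |>
    dplyr::mutate(predicted_mg_per_l = predict_input(.data$concentration_mg_per_g,
                                                     .data$wue_g_per_l))

  # --- summaries (mean of replicate plants; plants first averaged over events)
  uptake_plant <- uptake_records |>
    dplyr::group_by(.data$plant_id, .data$cultivar, .data$element) |>
    dplyr::summarise(value = mean(.data$uptake_mg_per_l), .groups = "drop") |>
    dplyr::mutate(source = "uptake")
  pred_plant <- predictions_plant |>
    dplyr::select("plant_id", "cultivar", "element", "source",
                  value = "predicted_mg_per_l")
  uptake_summary <- dplyr::bind_rows(uptake_plant, pred_plant) |>
    dplyr::group_by(.data$cultivar, .data$element, .data$source) |>
    dplyr::summarise(mean = mean(.data$value), sem = sem(.data$value),
                     n = dplyr::n(), .groups = "drop")

  # --- deviations ----------------------------------------------------------
  measured_means <- uptake_summary |>
    dplyr::filter(.data$source == "uptake") |>
    dplyr::select("cultivar", "element", uptake_mg_per_l = "mean")
  predicted_means <- uptake_summary |>
    dplyr::filter(.data$source != "uptake") |>
    dplyr::select("cultivar", "element", "source", predicted_mg_per_l = "mean")
  deviations <- compare_predictions(predicted_means, measured_means)
  best_predictors <- deviations |>
    dplyr::distinct(.data$cultivar, .data$element, .data$best_source, .data$tie_flag)

  # --- statistics ----------------------------------------------------------
  stats_in <- uptake_records |>
    dplyr::mutate(date = factor(.data$date))
  anova <- stats_in |>
    split(stats_in$element) |>
    purrr::map(~ rm_anova(.x, response = "uptake_mg_per_l",
                          subject = "plant_id", between = "cultivar",
                          within = "date"))
  contrasts <- purrr::imap_dfr(anova, function(fit, el) {
    dplyr::mutate(pairwise_contrasts(fit, family = contrast_family),
                  element = el, .before = 1)
  })
  welch <- predictions_plant |>
    dplyr::group_by(.data$element, .data$source) |>
    dplyr::group_modify(function(df, key) {
      cvs <- sort(unique(df$cultivar))
      if (length(cvs) != 2) return(tibble::tibble())
      a <- df$predicted_mg_per_l[df$cultivar == cvs[1]]
      b <- df$predicted_mg_per_l[df$cultivar == cvs[2]]
      if (length(a) < 2 || length(b) < 2 || (var(a) == 0 && var(b) == 0)) {
        return(tibble::tibble())
      }
      welch_t_test(a, b)
    }) |>
    dplyr::ungroup()

  opts <- list(capacity_l = capacity_l, threshold_g = threshold_g,
               smooth = smooth, day_window = day_window,
               contrast_family = contrast_family)
  structure(
    list(
      wue = wue_tbl,
      daily_transpiration = daily,
      uptake_records = uptake_records,
      uptake_summary = uptake_summary,
      deviations = deviations,
      best_predictors = best_predictors,
      anova = anova,
      contrasts = contrasts,
      welch = welch,
      provenance = list(
        options = opts,
        config_hash = rlang::hash(opts),
        package_version = as.character(utils::packageVersion("fertimass")),
        n_plants = nrow(plants)
      )
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Mass-balance report bundle:",
      x$provenance$n_plants, "plants,",
      length(unique(x$uptake_summary$element)), "elements;",
      "config hash", x$provenance$config_hash, "\n")
  invisible(x)
}

#' Render the uptake-vs-prediction summary table
#'
#' Formats the report bundle's cultivar x element summary in the layout used
#' for uptake comparison tables: one row per cultivar x element, columns
#' Uptake / Leaf / Stem / Root / Weighted, each cell "mean +/- SEM". Macro
#' elements print at 2 decimals; sub-1 mg/L trace values at `trace_digits`.
#' Missing cells render as explicit NA.
#'
#' @param bundle a `report_bundle`, or any tibble with columns `cultivar`,
#'   `element`, `source`, `mean`, `sem`.
#' @param digits decimals for macro-element values.
#' @param trace_digits decimals for values below 1 mg/L.
#' @return a tibble of formatted strings.
#' @export
render_uptake_table <- function(bundle, digits = 2, trace_digits = 2) {
  summary <- if (inherits(bundle, "report_bundle")) bundle$uptake_summary else bundle
  if (nrow(summary) == 0) {
    warn("Empty report: rendering header-only table.")
    return(tibble::tibble(cultivar = character(), element = character(),
                          Uptake = character(), Leaf = character(),
                          Stem = character(), Root = character(),
                          Weighted = character()))
  }
  fmt <- function(m, s) {
    d <- ifelse(abs(m) < 1, trace_digits, digits)
    ifelse(is.na(m), "NA",
           paste0(sprintf("%.*f", d, m), " ± ",
                  ifelse(is.na(s), "NA", sprintf("%.*f", d, s))))
  }
  summary |>
    dplyr::mutate(cell = fmt(.data$mean, .data$sem),
                  source = paste0(toupper(substr(.data$source, 1, 1)),
                                  substr(.data$source, 2, nchar(.data$source)))) |>
    dplyr::select("cultivar", "element", "source", "cell") |>
    tidyr::pivot_wider(names_from = "source", values_from = "cell",
                       values_fill = "NA") |>
    dplyr::arrange(.data$cultivar,
                   match(.data$element, measured_elements()))
}

#' Write a report bundle to CSV files
#'
#' Writes the summary, deviation, best-predictor, ANOVA, contrast and Welch
#' tables plus a provenance file. Output is written to a temporary directory
#' first and moved into place only on success, so a failed run never leaves
#' partial output.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "report_bundle")) abort("`bundle` must be a report_bundle.")
  staging <- tempfile("report_")
  dir.create(staging, recursive = TRUE)
  anova_tbl <- purrr::imap_dfr(bundle$anova, ~ dplyr::mutate(tidy(.x), element = .y,
                                                             .before = 1))
  tables <- list(
    uptake_summary = bundle$uptake_summary,
    uptake_table = render_uptake_table(bundle),
    deviations = bundle$deviations,
    best_predictors = bundle$best_predictors,
    anova = anova_tbl,
    contrasts = bundle$contrasts,
    welch = bundle$welch,
    wue = bundle$wue,
    daily_transpiration = bundle$daily_transpiration
  )
  paths <- file.path(staging, paste0(names(tables), ".csv"))
  purrr::walk2(tables, paths, readr::write_csv)
  writeLines(
    c(paste0("config_hash: ", bundle$provenance$config_hash),
      paste0("package_version: ", bundle$provenance$package_version)),
    file.path(staging, "provenance.txt")
  )
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  final <- file.path(dir, basename(list.files(staging, full.names = TRUE)))
  file.copy(list.files(staging, full.names = TRUE), dir, overwrite = TRUE)
  unlink(staging, recursive = TRUE)
  invisible(final)
}
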