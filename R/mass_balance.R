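#' Whole-plant water-use efficiency
#'
#' Water-use efficiency (WUE) is total plant dry biomass divided by the total
#' irrigation volume transpired over the monitored phase, in g dry biomass per
#' litre of water. It is the scaling factor that converts a tissue element
#' concentration (mg per g dry mass) into the element concentration the
#' irrigation solution must carry (mg per litre).
#'
#' @param dry_mass_g total plant dry biomass, g. Must be >= 0.
#' @param irrigation_volume_l total volume transpired, L. Must be > 0.
#' @param plant_id optional identifier(s) used in error messages.
#' @return numeric vector of WUE values, g L^-1.
#' @examples
#' compute_wue(188.4, 40) # 4.71 g/L
#' @export
compute_wue <- function(dry_mass_g, irrigation_volume_l, plant_id = NULL) {
  if (any(!is.finite(dry_mass_g)) || any(dry_mass_g < 0)) {
    abort("`dry_mass_g` must be finite and >= 0.")
  }
  bad <- !is.finite(irrigation_volume_l) | irrigation_volume_l <= 0
  if (any(bad)) {
    who <- if (!is.null(plant_id)) {
      paste0(" (plant ", paste(unique(plant_id[bad]), collapse = ", "), ")")
    } else {
      ""
    }
    abort(paste0("`irrigation_volume_l` must be > 0", who, "."))
  }
  dry_mass_g / irrigation_volume_l
}

#' Predicted fertigation input concentration
#'
#' The element concentration required in the irrigation solution is the
#' product of the tissue element concentration and whole-plant water-use
#' efficiency: `C_input = C_tissue * WUE`, giving mg L^-1. Applied element-wise
#' when the inputs are per-element vectors.
#'
#' @param tissue_mg_per_g tissue element concentration, mg per g dry mass (>= 0).
#' @param wue_g_per_l water-use efficiency, g dry biomass per L transpired (>= 0).
#' @return numeric vector, mg L^-1.
#' @examples
#' predict_input(10, 4.59) # 45.9 mg/L
#' @export
predict_input <- function(tissue_mg_per_g, wue_g_per_l) {
  if (any(!is.finite(tissue_mg_per_g)) || any(tissue_mg_per_g < 0)) {
    abort("`tissue_mg_per_g` must be finite and >= 0.")
  }
  if (any(!is.finite(wue_g_per_l)) || any(wue_g_per_l < 0)) {
    abort("`wue_g_per_l` must be finite and >= 0.")
  }
  tissue_mg_per_g * wue_g_per_l
}

#' Organ biomass-weighted mean tissue concentration
#'
#' Aggregates organ-level element concentrations into a whole-plant value by
#' weighting each organ's concentration by its fraction of total dry biomass:
#' `C_weighted = sum_organ C_organ * Biomass_organ / Biomass_total`. Organs
#' with greater biomass therefore exert more influence on the whole-plant
#' estimate than any single tissue would.
#'
#' @param tissue a data frame with columns `organ`, `element`,
#'   `concentration_mg_per_g` and `organ_dry_mass_g`, plus any grouping
#'   columns (e.g. `plant_id`, `cultivar`).
#' @param by character vector of grouping columns defining one plant (or one
#'   aggregation unit). Defaults to every column of `tissue` other than the
#'   four required ones.
#' @return a tibble with the grouping columns, `element`,
#'   `weighted_mg_per_g` and `total_dry_mass_g`.
#' @examples
#' tissue <- tibble::tibble(
#'   organ = c("leaf", "stem"), element = "N",
#'   concentration_mg_per_g = c(10, 20), organ_dry_mass_g = c(5, 5)
#' )
#' biomass_weighted_mean(tissue) # 15 mg/g
#' @export
biomass_weighted_mean <- function(tissue, by = NULL) {
  required <- c("organ", "element", "concentration_mg_per_g", "organ_dry_mass_g")
  missing_cols <- setdiff(required, names(tissue))
  if (length(missing_cols) > 0) {
    abort(paste0("`tissue` lacks column(s): ", paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(tissue) == 0) abort("`tissue` must contain at least one organ record.")
  if (any(tissue$concentration_mg_per_g < 0, na.rm = TRUE)) {
    abort("Tissue concentrations must be >= 0.")
  }
  if (any(tissue$organ_dry_mass_g < 0, na.rm = TRUE)) {
    abort("Organ dry masses must be >= 0.")
  }
  by <- by %||% setdiff(names(tissue), required)

  # organ dry masses must be consistent within a unit x organ; totals are
  # computed over distinct organs, not over element rows
  masses <- tissue |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(by, "organ", "organ_dry_mass_g"))))
  dup <- masses |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "organ")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Inconsistent `organ_dry_mass_g` within a plant x organ combination.")
  }
  totals <- masses |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(total_dry_mass_g = sum(.data$organ_dry_mass_g), .groups = "drop")
  if (any(totals$total_dry_mass_g <= 0)) {
    abort("Total dry mass must be > 0 for every aggregation unit.")
  }

  joined <- if (length(by)) {
    dplyr::left_join(tissue, totals, by = by)
  } else {
    dplyr::cross_join(tissue, totals)
  }
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "element", "total_dry_mass_g")))) |>
    dplyr::summarise(
      weighted_mg_per_g = sum(
        .data$concentration_mg_per_g * .data$organ_dry_mass_g / .data$total_dry_mass_g
      ),
      .groups = "drop"
    ) |>
    dplyr::relocate("total_dry_mass_g", .after = dplyr::last_col())
}

#' Nutrient uptake from pour-through solution depletion
#'
#' Inverts one 12-h pour-through depletion cycle into per-element uptake
#' concentrations, normalized per litre of water transpired. Under the
#' deionized-water refill protocol (absorbed element mass leaves the container
#' with transpired solution; the DI refill dilutes the residual back to
#' container capacity), element conservation gives
#' `uptake = (supply - leachate) * capacity / transpired`.
#'
#' Negative uptake (leachate more concentrated than supply, i.e. apparent
#' exclusion or accumulation in the root zone) is returned as-is with
#' `negative_flag = TRUE`; it is never clipped, since clipping would hide
#' conservation violations.
#'
#' @param cycles a data frame with one row per cycle x element: columns
#'   `element`, `supply_mg_per_l`, `leachate_mg_per_l`, `capacity_l`,
#'   `transpired_l`, plus any identifier columns (`plant_id`, `cultivar`,
#'   `date`, ...), which are carried through.
#' @param sanity_bound transpired volume must be strictly less than
#'   `capacity_l * sanity_bound` (a cycle cannot transpire more solution than
#'   the substrate holds). Default 1.
#' @return a tibble of uptake records: the identifier columns plus `element`,
#'   `uptake_mg_per_l` and `negative_flag`.
#' @examples
#' uptake_from_depletion(tibble::tibble(
#'   element = "N", supply_mg_per_l = 256.3, leachate_mg_per_l = 200,
#'   capacity_l = 3, transpired_l = 1.2
#' ))
#' @export
uptake_from_depletion <- function(cycles, sanity_bound = 1) {
  required <- c("element", "supply_mg_per_l", "leachate_mg_per_l",
                "capacity_l", "transpired_l")
  missing_cols <- setdiff(required, names(cycles))
  if (length(missing_cols) > 0) {
    abort(paste0("`cycles` lacks column(s): ", paste(missing_cols, collapse = ", "), "."))
  }
  if (any(!is.finite(cycles$transpired_l) | cycles$transpired_l <= 0)) {
    abort("`transpired_l` must be > 0 for every cycle.")
  }
  if (any(!is.finite(cycles$capacity_l) | cycles$capacity_l <= 0)) {
    abort("`capacity_l` must be > 0 for every cycle.")
  }
  if (any(cycles$transpired_l >= cycles$capacity_l * sanity_bound)) {
    abort("`transpired_l` must be < capacity_l * sanity_bound; check volumes.")
  }

  incomplete <- is.na(cycles$supply_mg_per_l) | is.na(cycles$leachate_mg_per_l)
  if (any(incomplete)) {
    warn(paste0(
      "Skipping ", sum(incomplete), " cycle-element record(s) with a missing ",
      "supply or leachate concentration (elements: ",
      paste(sort(unique(cycles$element[incomplete])), collapse = ", "), ")."
    ))
    cycles <- cycles[!incomplete, , drop = FALSE]
  }

  cycles |>
    tibble::as_tibble() |>
    dplyr::mutate(
      uptake_mg_per_l = (.data$supply_mg_per_l - .data$leachate_mg_per_l) *
        .data$capacity_l / .data$transpired_l,
      negative_flag = .data$uptake_mg_per_l < 0
    ) |>
    dplyr::select(-dplyr::all_of(c("supply_mg_per_l", "leachate_mg_per_l",
                                   "capacity_l", "transpired_l")))
}

#' Percent deviation of a predicted input from measured uptake
#'
#' `100 * (predicted - measured) / measured`; positive values are
#' overpredictions. `deviation_percent()` returns full-precision values;
#' reported tables round to one decimal with [round_deviation()] (half away
#' from zero).
#'
#' @param predicted predicted input concentration, mg L^-1.
#' @param measured measured uptake concentration, mg L^-1. Must be > 0.
#' @return numeric vector of percent deviations.
#' @examples
#' round_deviation(deviation_percent(125.08, 121.52)) # +2.9
#' @export
deviation_percent <- function(predicted, measured) {
  if (any(!is.finite(measured) | measured <= 0)) {
    abort("`measured` must be finite and > 0.")
  }
  if (any(!is.finite(predicted))) {
    abort("`predicted` must be finite.")
  }
  100 * (predicted - measured) / measured
}

#' @rdname deviation_percent
#' @param x numeric vector of deviations (percent).
#' @param digits decimal places for reporting (default 1).
#' @export
round_deviation <- function(x, digits = 1) {
  # round half away from zero, the convention used for reported percentages
  # (base round() rounds half to even)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# fixed tie-break priority among prediction sources
.source_priority <- c("weighted", "leaf", "root", "stem")

#' Best-predicting tissue source
#'
#' Given per-source deviations for one cultivar x element, returns the source
#' whose absolute deviation is smallest. Ties at reporting precision (one
#' decimal place of |deviation|) are broken by the fixed priority
#' weighted > leaf > root > stem and flagged.
#'
#' @param deviations named numeric vector of percent deviations; names are
#'   prediction sources (`weighted`, `leaf`, `stem`, `root`, ...).
#' @param digits reporting precision at which ties are assessed.
#' @return a list with elements `source` (character) and `tie_flag` (logical).
#' @examples
#' best_predictor(c(leaf = 34.2, stem = -36.2, root = 19.4, weighted = 2.9))
#' @export
best_predictor <- function(deviations, digits = 1) {
  if (length(deviations) == 0 || is.null(names(deviations)) ||
      any(!nzchar(names(deviations)))) {
    abort("`deviations` must be a nonempty named numeric vector.")
  }
  rounded <- round_deviation(abs(deviations), digits)
  best <- min(rounded)
  candidates <- names(deviations)[rounded == best]
  ord <- match(candidates, .source_priority)
  ord[is.na(ord)] <- length(.source_priority) + rank(candidates[is.na(ord)])
  list(
    source = candidates[which.min(ord)],
    tie_flag = length(candidates) > 1
  )
}

#' Compare predicted input concentrations with measured uptake
#'
#' Joins a table of per-source predicted input concentrations to measured
#' uptake means and scores each prediction as a signed percent deviation,
#' selecting the best source per cultivar x element.
#'
#' @param predictions data frame with columns `cultivar`, `element`, `source`,
#'   `predicted_mg_per_l`.
#' @param measured data frame with columns `cultivar`, `element`,
#'   `uptake_mg_per_l` (measured mean uptake).
#' @param digits reporting precision for `deviation_reported` and tie
#'   assessment.
#' @return a tibble with one row per cultivar x element x source:
#'   `deviation_percent` (full precision), `deviation_reported` (rounded),
#'   `best_source`, `tie_flag`.
#' @export
compare_predictions <- function(predictions, measured, digits = 1) {
  req_p <- c("cultivar", "element", "source", "predicted_mg_per_l")
  req_m <- c("cultivar", "element", "uptake_mg_per_l")
  if (length(setdiff(req_p, names(predictions))) > 0) {
    abort(paste0("`predictions` needs columns: ", paste(req_p, collapse = ", "), "."))
  }
  if (length(setdiff(req_m, names(measured))) > 0) {
    abort(paste0("`measured` needs columns: ", paste(req_m, collapse = ", "), "."))
  }
  joined <- dplyr::inner_join(
    tibble::as_tibble(predictions),
    dplyr::select(tibble::as_tibble(measured), dplyr::all_of(req_m)),
    by = c("cultivar", "element")
  )
  if (nrow(joined) == 0) {
    abort("No cultivar x element combinations shared between predictions and measured uptake.")
  }
  joined |>
    dplyr::mutate(
      deviation_percent = deviation_percent(.data$predicted_mg_per_l, .data$uptake_mg_per_l),
      deviation_reported = round_deviation(.data$deviation_percent, digits)
    ) |>
    dplyr::group_by(.data$cultivar, .data$element) |>
    dplyr::mutate(
      best_source = best_predictor(
        setNames(.data$deviation_percent, .data$source), digits
      )$source,
      tie_flag = best_predictor(
        setNames(.data$deviation_percent, .data$source), digits
      )$tie_flag
    ) |>
    dplyr::ungroup()
}

#' Daily nutrient replenishment estimate
#'
#' Converts uptake concentrations (mg per litre transpired) into the element
#' mass that must be replenished per day to hold the solution steady: mean
#' uptake concentration times the day's transpired volume.
#'
#' @param uptake_records data frame with columns `element` and
#'   `uptake_mg_per_l` (one or more records per element, e.g. one plant-day).
#' @param transpired_l the day's transpired volume, L (>= 0).
#' @return a tibble with `element`, `mean_uptake_mg_per_l` and
#'   `replenishment_mg_per_day`.
#' @examples
#' replenishment_estimate(
#'   tibble::tibble(element = "N", uptake_mg_per_l = 121.5), transpired_l = 2
#' )
#' @export
replenishment_estimate <- function(uptake_records, transpired_l) {
  if (!all(c("element", "uptake_mg_per_l") %in% names(uptake_records))) {
    abort("`uptake_records` needs columns `element` and `uptake_mg_per_l`.")
  }
  if (length(transpired_l) != 1 || !is.finite(transpired_l) || transpired_l < 0) {
    abort("`transpired_l` must be a single value >= 0.")
  }
  uptake_records |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(
      mean_uptake_mg_per_l = mean(.data$uptake_mg_per_l),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      replenishment_mg_per_day = .data$mean_uptake_mg_per_l * transpired_l
    )
}
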