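#' Default fertigation supply recipe
#'
#' The complete vegetative-phase supply solution, mg L^-1 per element, with
#' nitrogen given as total N (nitrate-N 250 + ammonium-N 6.3). Mo is a
#' supply-only element: accepted in recipes, excluded from uptake analysis.
#'
#' @return a named numeric vector keyed by element symbol.
#' @examples
#' default_recipe()[["K"]]
#' @export
default_recipe <- function() {
  c(N = 256.3, K = 350, P = 50, Mg = 61.7, Ca = 100, Fe = 2,
    Zn = 0.23, B = 0.09, Cu = 0.23, Mo = 0.07, Mn = 0.27)
}

# organ affinity multipliers (leaf, stem, root) used to partition absorbed
# element mass among organs on top of biomass allocation; loosely echoes the
# organ concentration contrasts typical of vegetative tissue panels
# (leaf-enriched N/Ca/Mg/B, root-enriched Fe/P/Cu). Weighted means are
# unaffected by these values (conservation fixes the whole-plant total).
.default_organ_affinity <- function() {
  tibble::tribble(
    ~element, ~leaf, ~stem, ~root,
    "N",  1.4, 0.60, 1.2,
    "P",  0.7, 0.50, 1.3,
    "K",  0.7, 1.20, 1.1,
    "Ca", 1.5, 0.50, 0.6,
    "Mg", 1.5, 0.40, 0.9,
    "Fe", 0.3, 0.15, 3.0,
    "Mn", 1.0, 1.10, 1.9,
    "B",  1.8, 0.70, 0.7,
    "Cu", 0.2, 0.50, 1.0,
    "Zn", 1.0, 0.50, 1.1
  )
}

#' Cultivar parameter set for the trial simulator
#'
#' Defines one cultivar's growth, water use and per-element uptake behaviour:
#' exponential biomass growth at a constant relative growth rate, daily
#' transpiration proportional to daily biomass gain (scaled so that final dry
#' mass / total transpiration equals the target WUE exactly), and linear
#' per-element uptake-concentration trajectories between a start and end
#' value over the phase.
#'
#' @param name cultivar label.
#' @param initial_dry_mass_g dry biomass at phase start, g.
#' @param rgr_per_day relative growth rate, d^-1.
#' @param allocation named numeric (leaf, stem, root) biomass fractions,
#'   summing to 1.
#' @param wue_g_per_l target water-use efficiency, g dry biomass per L.
#' @param trajectories tibble with columns `element`, `start_mg_per_l`,
#'   `end_mg_per_l`: uptake concentration (mg per L transpired) at phase start
#'   and end, interpolated linearly in between. A declining trajectory has
#'   start > end; rising the reverse.
#' @param organ_affinity tibble (`element`, `leaf`, `stem`, `root`) of
#'   positive multipliers biasing how absorbed element mass is partitioned
#'   among organs (on top of biomass allocation). Defaults to a built-in
#'   vegetative-tissue pattern.
#' @return an object of class `cultivar_params`.
#' @export
cultivar_params <- function(name, initial_dry_mass_g, rgr_per_day, allocation,
                            wue_g_per_l, trajectories,
                            organ_affinity = .default_organ_affinity()) {
  if (abs(sum(allocation) - 1) > 1e-12) {
    abort("Organ allocation fractions must sum to 1 (within 1e-12).")
  }
  if (!all(sort(names(allocation)) == c("leaf", "root", "stem"))) {
    abort("`allocation` must be named leaf, stem, root.")
  }
  if (any(allocation < 0)) abort("Allocation fractions must be >= 0.")
  if (wue_g_per_l <= 0) abort("`wue_g_per_l` must be > 0.")
  if (initial_dry_mass_g <= 0) abort("`initial_dry_mass_g` must be > 0.")
  req <- c("element", "start_mg_per_l", "end_mg_per_l")
  if (length(setdiff(req, names(trajectories))) > 0) {
    abort("`trajectories` needs columns element, start_mg_per_l, end_mg_per_l.")
  }
  if (any(trajectories$start_mg_per_l < 0 | trajectories$end_mg_per_l < 0)) {
    abort("Uptake trajectories must be non-negative.")
  }
  check_elements(trajectories$element, allow_supply_only = FALSE)
  structure(
    list(name = name, initial_dry_mass_g = initial_dry_mass_g,
         rgr_per_day = rgr_per_day, allocation = allocation,
         wue_g_per_l = wue_g_per_l,
         trajectories = tibble::as_tibble(trajectories),
         organ_affinity = tibble::as_tibble(organ_affinity)),
    class = "cultivar_params"
  )
}

#' Default cultivar presets
#'
#' Two contrasting cultivar parameter sets emulating a two-cultivar vegetative
#' fertigation trial: similar WUE (4.71 and 4.59 g L^-1), N and K uptake
#' concentrations peaking early and declining, Ca and Mg rising steadily, and
#' micronutrients rising mildly with biomass.
#'
#' @return a named list of two [cultivar_params()] objects.
#' @export
default_cultivars <- function() {
  phase <- 38
  m0 <- 15
  cj2_traj <- tibble::tribble(
    ~element, ~start_mg_per_l, ~end_mg_per_l,
    "N", 135, 75,
    "K", 205, 106,
    "P", 12, 47,
    "Ca", 37, 96,
    "Mg", 24, 51,
    "Fe", 1.2, 2.0,
    "Mn", 0.13, 0.25,
    "B", 0.05, 0.09,
    "Cu", 0.08, 0.14,
    "Zn", 0.07, 0.13
  )
  fl_traj <- tibble::tribble(
    ~element, ~start_mg_per_l, ~end_mg_per_l,
    "N", 144, 97,
    "K", 216, 112,
    "P", 14, 47,
    "Ca", 44, 97,
    "Mg", 31, 52,
    "Fe", 1.0, 1.8,
    "Mn", 0.12, 0.22,
    "B", 0.06, 0.10,
    "Cu", 0.05, 0.09,
    "Zn", 0.05, 0.09
  )
  list(
    `CJ2-like` = cultivar_params(
      name = "CJ2-like", initial_dry_mass_g = m0,
      rgr_per_day = log(188.4 / m0) / phase,
      allocation = c(leaf = 0.5, stem = 0.3, root = 0.2),
      wue_g_per_l = 4.71, trajectories = cj2_traj
    ),
    `FirstLight-like` = cultivar_params(
      name = "FirstLight-like", initial_dry_mass_g = m0,
      rgr_per_day = log(183.6 / m0) / phase,
      allocation = c(leaf = 0.48, stem = 0.32, root = 0.2),
      wue_g_per_l = 4.59, trajectories = fl_traj
    )
  )
}

#' Trial configuration for the simulator
#'
#' Study-design level settings for [simulate_trial()]: 2 cultivars x 4
#' replicate containers over a 38-day vegetative phase, ten 12-h pour-through
#' sampling events every second day across the active measurement window
#' (phase days 20-38, after root-zone establishment), two daily refill
#' irrigations (07:00 and 20:00), 10-minute gravimetric logging.
#'
#' @param cultivars named list of [cultivar_params()] objects.
#' @param replicates replicate plants per cultivar.
#' @param phase_days length of the vegetative phase, days.
#' @param start_date calendar date of phase day 1.
#' @param first_event_day,event_interval_days,n_events pour-through sampling
#'   schedule (phase-day of first event, spacing, count).
#' @param capacity_l solution volume held by the substrate at container
#'   capacity, L.
#' @param leachate_draw_ml leachate volume drawn per sampling event, mL
#'   (recorded in the dataset; the draw is assumed to sample the bulk
#'   solution perfectly).
#' @param balance_noise_sd_g additive Gaussian noise SD on each 10-min balance
#'   reading, g. 0 disables.
#' @param assay_noise_rel_sd multiplicative Gaussian noise SD (relative) on
#'   leachate assay concentrations. 0 disables.
#' @param day_fraction fraction of a day's transpiration occurring inside the
#'   07:00-19:00 day-course window.
#' @param base_mass_g container + dry substrate tare mass, g.
#' @param seed default RNG seed used by [simulate_trial()] when none is given.
#' @return an object of class `trial_config`.
#' @export
trial_config <- function(cultivars = default_cultivars(), replicates = 4,
                         phase_days = 38, start_date = as.Date("2024-07-07"),
                         first_event_day = 20, event_interval_days = 2,
                         n_events = 10, capacity_l = 3.0,
                         leachate_draw_ml = 230, balance_noise_sd_g = 2,
                         assay_noise_rel_sd = 0.01, day_fraction = 0.92,
                         base_mass_g = 2000, seed = 42) {
  if (!all(vapply(cultivars, inherits, logical(1), "cultivar_params"))) {
    abort("`cultivars` must be a list of cultivar_params objects.")
  }
  last_event <- first_event_day + (n_events - 1) * event_interval_days
  if (last_event > phase_days) {
    abort("Sampling events must fit within the phase.")
  }
  if (balance_noise_sd_g < 0 || assay_noise_rel_sd < 0) {
    abort("Noise SDs must be >= 0.")
  }
  if (capacity_l <= 0) abort("`capacity_l` must be > 0.")
  if (day_fraction <= 0 || day_fraction >= 1) {
    abort("`day_fraction` must lie in (0, 1).")
  }
  structure(
    list(cultivars = cultivars, replicates = replicates,
         phase_days = phase_days, start_date = start_date,
         event_days = seq(first_event_day, by = event_interval_days,
                          length.out = n_events),
         capacity_l = capacity_l, leachate_draw_ml = leachate_draw_ml,
         balance_noise_sd_g = balance_noise_sd_g,
         assay_noise_rel_sd = assay_noise_rel_sd,
         day_fraction = day_fraction, base_mass_g = base_mass_g, seed = seed),
    class = "trial_config"
  )
}

# linear uptake-concentration trajectory over phase days 1..phase
#' @keywords internal
trajectory_value <- function(start, end, day, phase_days) {
  start + (end - start) * (day - 1) / (phase_days - 1)
}

#' Simulate a mass-conserving fertigation trial
#'
#' Generates a complete synthetic trial dataset: per-container 10-minute
#' gravimetric mass logs with refill irrigation events, per-event supply and
#' leachate concentration panels produced by the forward depletion model,
#' harvest organ biomasses and tissue element concentrations, and a
#' ground-truth ledger (true transpiration, true per-event uptake
#' concentrations, cumulative absorbed element mass) for parameter-recovery
#' testing. Before measurement noise is added, every quantity satisfies
#' element and water conservation exactly.
#'
#' Within each day, transpiration is split 5% (00:00-06:50), `day_fraction`
#' (07:00-19:00, the pour-through uptake window), 1% (19:00-19:50) and the
#' remainder (20:00-24:00); the 10 minutes before each refill are the
#' irrigation dwell (no transpiration). Refills at 07:00 and 20:00 return the
#' substrate to capacity.
#'
#' @param config a [trial_config()].
#' @param seed integer RNG seed; defaults to `config$seed`. Identical
#'   config + seed give identical datasets.
#' @return an object of class `trial_dataset`: a list with tibbles
#'   `mass_series`, `solution`, `tissue`, ledger components (`plants`,
#'   `daily`, `events`, `absorbed`), the `recipe`, `config` and `seed`.
#' @export
simulate_trial <- function(config = trial_config(), seed = NULL) {
  if (!inherits(config, "trial_config")) abort("`config` must be a trial_config.")
  seed <- seed %||% config$seed
  set.seed(seed)
  recipe <- default_recipe()
  phase <- config$phase_days
  cap_g <- config$capacity_l * 1000
  f_day <- config$day_fraction
  f_n1 <- 0.05; f_n2 <- 0.01
  f_n3 <- 1 - f_day - f_n1 - f_n2
  if (f_n3 < 0) abort("`day_fraction` too large: night fractions become negative.")

  mass_series <- list(); solution <- list(); tissue <- list()
  led_plants <- list(); led_daily <- list(); led_events <- list()
  led_absorbed <- list()

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  times <- t0 + 600 * seq(0, phase * 144)
  t_min <- 600 * seq(0, phase * 144) / 60
  day_idx <- t_min %/% 1440 + 1
  tod <- t_min %% 1440

  for (cv in config$cultivars) {
    traj <- cv$trajectories
    elements <- traj$element
    m0 <- cv$initial_dry_mass_g
    mf <- m0 * exp(cv$rgr_per_day * phase)
    total_v <- mf / cv$wue_g_per_l
    m_day <- m0 * exp(cv$rgr_per_day * (0:phase))
    gain <- diff(m_day)
    v_day <- gain * total_v / (mf - m0)  # sums to total_v exactly up to fp
    # per-day true uptake concentrations (elements x days)
    conc_day <- vapply(seq_len(phase), function(d) {
      trajectory_value(traj$start_mg_per_l, traj$end_mg_per_l, d, phase)
    }, numeric(length(elements)))
    rownames(conc_day) <- elements
    absorbed_day <- sweep(conc_day, 2, v_day, `*`)  # mg, elements x days

    for (r in seq_len(config$replicates)) {
      plant <- paste0(cv$name, "-", r)

      # --- gravimetric trace -------------------------------------------------
      v_prev <- c(0, v_day)[pmin(day_idx, phase + 1)]
      v_cur <- c(v_day, 0)[pmin(day_idx, phase + 1)]
      deficit_l <- ifelse(
        tod < 420,
        f_n3 * v_prev + f_n1 * v_cur * pmin(tod, 410) / 410,
        ifelse(
          tod <= 1140,
          f_day * v_cur * (tod - 420) / 720,
          ifelse(
            tod < 1200,
            f_day * v_cur + f_n2 * v_cur * pmin(tod - 1140, 50) / 50,
            f_n3 * v_cur * (tod - 1200) / 240  # 20:00 refill resets the deficit
          )
        )
      )
      mass <- config$base_mass_g + cap_g - deficit_l * 1000
      if (config$balance_noise_sd_g > 0) {
        mass <- mass + rnorm(length(mass), 0, config$balance_noise_sd_g)
      }
      mass_series[[plant]] <- tibble::tibble(
        container_id = plant, timestamp = times, mass_g = mass
      )

      # --- pour-through events ----------------------------------------------
      ev <- tidyr::expand_grid(day = config$event_days, element = elements) |>
        dplyr::mutate(
          date = config$start_date + .data$day - 1,
          transpired_window_l = f_day * v_day[.data$day],
          true_uptake_mg_per_l = conc_day[cbind(match(.data$element, elements), .data$day)],
          supply_mg_per_l = unname(recipe[.data$element]),
          true_leachate_mg_per_l = .data$supply_mg_per_l -
            .data$true_uptake_mg_per_l * .data$transpired_window_l / config$capacity_l
        )
      if (any(ev$true_leachate_mg_per_l < 0)) {
        abort(paste0(
          "Configured uptake depletes the supply below zero for element(s): ",
          paste(unique(ev$element[ev$true_leachate_mg_per_l < 0]), collapse = ", "),
          ". Reduce trajectories or increase capacity/supply."
        ))
      }
      obs_leach <- ev$true_leachate_mg_per_l
      if (config$assay_noise_rel_sd > 0) {
        obs_leach <- pmax(0, obs_leach *
                            (1 + rnorm(length(obs_leach), 0, config$assay_noise_rel_sd)))
      }
      solution[[plant]] <- dplyr::bind_rows(
        tibble::tibble(
          date = ev$date, plant_id = plant, cultivar = cv$name,
          element = ev$element, concentration_mg_per_l = ev$supply_mg_per_l,
          sample_type = "supply"
        ),
        tibble::tibble(
          date = ev$date, plant_id = plant, cultivar = cv$name,
          element = ev$element, concentration_mg_per_l = obs_leach,
          sample_type = "leachate"
        )
      )
      led_events[[plant]] <- tibble::tibble(
        plant_id = plant, cultivar = cv$name, date = ev$date,
        element = ev$element,
        true_uptake_mg_per_l = ev$true_uptake_mg_per_l,
        true_leachate_mg_per_l = ev$true_leachate_mg_per_l,
        transpired_window_l = ev$transpired_window_l
      )

      # --- harvest tissue panel ---------------------------------------------
      absorbed <- rowSums(absorbed_day)  # mg per element
      aff <- cv$organ_affinity[match(elements, cv$organ_affinity$element), ]
      organs <- c("leaf", "stem", "root")
      w_raw <- sapply(organs, function(o) cv$allocation[[o]] * aff[[o]])
      w <- w_raw / rowSums(w_raw)  # elements x organs, rows sum to 1
      organ_mass <- cv$allocation[organs] * mf
      tissue[[plant]] <- purrr::map_dfr(organs, function(o) {
        tibble::tibble(
          plant_id = plant, cultivar = cv$name, organ = o,
          element = elements,
          concentration_mg_per_g = absorbed * w[, o] / organ_mass[[o]],
          organ_dry_mass_g = organ_mass[[o]]
        )
      })

      led_plants[[plant]] <- tibble::tibble(
        plant_id = plant, cultivar = cv$name,
        initial_dry_mass_g = m0, final_dry_mass_g = mf,
        total_transpired_l = sum(v_day), wue_true = mf / sum(v_day),
        wue_target = cv$wue_g_per_l
      )
      led_daily[[plant]] <- tibble::tibble(
        plant_id = plant, cultivar = cv$name,
        date = config$start_date + seq_len(phase) - 1,
        day = seq_len(phase), transpired_l = v_day
      )
      led_absorbed[[plant]] <- tibble::tibble(
        plant_id = plant, cultivar = cv$name, element = elements,
        absorbed_mg = absorbed
      )
    }
  }

  structure(
    list(
      mass_series = dplyr::bind_rows(mass_series),
      solution = dplyr::bind_rows(solution),
      tissue = dplyr::bind_rows(tissue),
      ledger = list(
        plants = dplyr::bind_rows(led_plants),
        daily = dplyr::bind_rows(led_daily),
        events = dplyr::bind_rows(led_events),
        absorbed = dplyr::bind_rows(led_absorbed)
      ),
      recipe = recipe,
      config = config,
      seed = seed
    ),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("Synthetic fertigation trial:",
      nrow(x$ledger$plants), "plants,",
      length(unique(x$ledger$events$date)), "sampling events,",
      x$config$phase_days, "days, seed", x$seed, "\n")
  invisible(x)
}

#' Audit element conservation in a trial dataset
#'
#' Checks the simulator's books: (i) per plant x element, the cumulative
#' absorbed mass in the ledger against the element mass recovered from the
#' harvest tissue panel (organ concentration x organ dry mass, summed); and
#' (ii) per pour-through event, the element-mass residual between the stored
#' (possibly noise-perturbed) leachate concentration and the true forward
#' model. Pre-noise, both are zero to numerical precision; under assay noise
#' only the event residuals grow, and a corrupted leachate record surfaces as
#' the largest residual.
#'
#' @param dataset a `trial_dataset`.
#' @return a list of class `ledger_audit`: `conservation` (plant, element,
#'   absorbed_mg, tissue_mg, discrepancy_mg), `event_residuals` (plant, date,
#'   element, residual_mg), and `max_discrepancy_mg`.
#' @export
ledger_audit <- function(dataset) {
  if (!inherits(dataset, "trial_dataset")) abort("`dataset` must be a trial_dataset.")
  tissue_mass <- dataset$tissue |>
    dplyr::group_by(.data$plant_id, .data$element) |>
    dplyr::summarise(
      tissue_mg = sum(.data$concentration_mg_per_g * .data$organ_dry_mass_g),
      .groups = "drop"
    )
  conservation <- dataset$ledger$absorbed |>
    dplyr::left_join(tissue_mass, by = c("plant_id", "element")) |>
    dplyr::mutate(discrepancy_mg = abs(.data$absorbed_mg - .data$tissue_mg))

  leach <- dataset$solution |>
    dplyr::filter(.data$sample_type == "leachate") |>
    dplyr::select("plant_id", "date", "element",
                  obs_leachate_mg_per_l = "concentration_mg_per_l")
  event_residuals <- dataset$ledger$events |>
    dplyr::left_join(leach, by = c("plant_id", "date", "element")) |>
    dplyr::mutate(
      residual_mg = abs(.data$obs_leachate_mg_per_l - .data$true_leachate_mg_per_l) *
        dataset$config$capacity_l
    ) |>
    dplyr::select("plant_id", "cultivar", "date", "element", "residual_mg")

  structure(
    list(conservation = conservation, event_residuals = event_residuals,
         max_discrepancy_mg = max(conservation$discrepancy_mg)),
    class = "ledger_audit"
  )
}

#' @export
print.ledger_audit <- function(x, ...) {
  cat("Ledger audit: max |absorbed - tissue| =",
      format(x$max_discrepancy_mg, digits = 3), "mg;",
      "max event residual =", format(max(x$event_residuals$residual_mg), digits = 3),
      "mg\n")
  invisible(x)
}
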