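test_that("compute_wue is the dry-mass / transpired-volume ratio with input validation", {
  expect_equal(compute_wue(188.4, 40), 4.71)
  expect_equal(compute_wue(0, 10), 0)
  expect_equal(compute_wue(c(10, 20), c(2, 4)), c(5, 5))
  expect_error(compute_wue(10, 0, plant_id = "CJ2-3"), "CJ2-3")
  expect_error(compute_wue(-1, 5), ">= 0")
})

test_that("predict_input multiplies tissue concentration by WUE element-wise", {
  expect_equal(predict_input(10, 4.59), 45.9)
  expect_equal(predict_input(0, 99), 0)
  expect_equal(predict_input(c(N = 26, K = 16), 4.7), c(N = 122.2, K = 75.2))
  expect_error(predict_input(-1, 4.7), ">= 0")
  expect_error(predict_input(10, -4.7), ">= 0")
})

test_that("biomass_weighted_mean weights organ concentrations by biomass fraction", {
  two <- tibble::tibble(
    organ = c("leaf", "stem"), element = "N",
    concentration_mg_per_g = c(10, 20), organ_dry_mass_g = c(5, 5)
  )
  expect_equal(biomass_weighted_mean(two)$weighted_mg_per_g, 15)

  one <- tibble::tibble(organ = "leaf", element = "K",
                        concentration_mg_per_g = 12.3, organ_dry_mass_g = 7)
  expect_equal(biomass_weighted_mean(one)$weighted_mg_per_g, 12.3)

  # hand-computed: 163.14*0.5 + 77.51*0.3 + 145.08*0.2 = 133.839
  three <- tibble::tibble(
    organ = c("leaf", "stem", "root"), element = "N",
    concentration_mg_per_g = c(163.14, 77.51, 145.08),
    organ_dry_mass_g = c(0.5, 0.3, 0.2) * 100
  )
  expect_equal(biomass_weighted_mean(three)$weighted_mg_per_g, 133.839)

  zero <- tibble::tibble(organ = "leaf", element = "N",
                         concentration_mg_per_g = 1, organ_dry_mass_g = 0)
  expect_error(biomass_weighted_mean(zero), "Total dry mass")
})

test_that("weighted mean stays within organ bounds and its weights sum to one", {
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    tissue <- tibble::tibble(
      organ = c("leaf", "stem", "root", "flower")[seq_len(k)],
      element = "N",
      concentration_mg_per_g = stats::runif(k, 0, 50),
      organ_dry_mass_g = stats::runif(k, 0.1, 100)
    )
    w <- tissue$organ_dry_mass_g / sum(tissue$organ_dry_mass_g)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    res <- biomass_weighted_mean(tissue)$weighted_mg_per_g
    expect_gte(res, min(tissue$concentration_mg_per_g) - 1e-12)
    expect_lte(res, max(tissue$concentration_mg_per_g) + 1e-12)
  }
})

test_that("weighting tissue then applying WUE commutes with weighting per-organ predictions", {
  set.seed(8)
  for (i in 1:20) {
    wue <- stats::runif(1, 3, 6)
    tissue <- tibble::tibble(
      organ = c("leaf", "stem", "root"), element = "Mg",
      concentration_mg_per_g = stats::runif(3, 0, 40),
      organ_dry_mass_g = stats::runif(3, 1, 120)
    )
    route_a <- predict_input(biomass_weighted_mean(tissue)$weighted_mg_per_g, wue)
    pred <- dplyr::mutate(tissue,
                          concentration_mg_per_g = predict_input(concentration_mg_per_g, wue))
    route_b <- biomass_weighted_mean(pred)$weighted_mg_per_g
    expect_equal(route_a, route_b, tolerance = 1e-9)
  }
})

test_that("uptake_from_depletion inverts the forward pour-through cycle", {
  # no depletion
  flat <- tibble::tibble(element = "K", supply_mg_per_l = 350,
                         leachate_mg_per_l = 350, capacity_l = 3, transpired_l = 1)
  expect_equal(uptake_from_depletion(flat)$uptake_mg_per_l, 0)

  # forward-simulated cycle: absorb 140.75 mg/L over 1.2 L from 3 L at 256.3
  leach <- forward_cycle_leachate(256.3, 140.75, 3, 1.2)
  expect_equal(leach, 200, tolerance = 1e-12)
  cyc <- tibble::tibble(element = "N", supply_mg_per_l = 256.3,
                        leachate_mg_per_l = 200, capacity_l = 3.0, transpired_l = 1.2)
  expect_equal(uptake_from_depletion(cyc)$uptake_mg_per_l, 140.75)

  # enrichment comes back negative and flagged, not clipped
  neg <- tibble::tibble(element = "Ca", supply_mg_per_l = 100,
                        leachate_mg_per_l = 110, capacity_l = 2, transpired_l = 0.5)
  out <- uptake_from_depletion(neg)
  expect_equal(out$uptake_mg_per_l, -40)
  expect_true(out$negative_flag)

  expect_error(uptake_from_depletion(dplyr::mutate(neg, transpired_l = 0)),
               "transpired_l")
  expect_error(uptake_from_depletion(dplyr::mutate(neg, transpired_l = 3)),
               "sanity")
  expect_warning(
    uptake_from_depletion(dplyr::mutate(neg, leachate_mg_per_l = NA)),
    "Skipping"
  )
})

test_that("depletion accounting conserves element mass over randomized cycles", {
  set.seed(42)
  n <- 1200
  supply <- stats::runif(n, 0.05, 400)
  capacity <- stats::runif(n, 1, 6)
  vt <- capacity * stats::runif(n, 0.05, 0.9)
  uptake_true <- supply * capacity / vt * stats::runif(n, -0.2, 0.9)
  leach <- forward_cycle_leachate(supply, uptake_true, capacity, vt)
  cycles <- tibble::tibble(
    element = "N", supply_mg_per_l = supply, leachate_mg_per_l = leach,
    capacity_l = capacity, transpired_l = vt
  )
  est <- uptake_from_depletion(cycles)$uptake_mg_per_l
  # inversion recovers the configured uptake
  expect_equal(est, uptake_true, tolerance = 1e-9)
  # mass balance: supply mass = residual mass + absorbed mass
  supply_mass <- supply * capacity
  closed <- leach * capacity + est * vt
  expect_lt(max(abs(closed - supply_mass) / pmax(supply_mass, 1e-12)), 1e-9)
  expect_equal(est < 0, uptake_true < 0)
})

test_that("deviation_percent is the signed relative error in percent", {
  expect_equal(round_deviation(deviation_percent(125.08, 121.52)), 2.9)
  expect_equal(round_deviation(deviation_percent(30.62, 38.40)), -20.3)
  expect_identical(deviation_percent(38.86, 38.86), 0)
  expect_error(deviation_percent(10, 0), "> 0")
  # rounding is half away from zero at one decimal
  expect_equal(round_deviation(c(2.25, -2.25, 2.24)), c(2.3, -2.3, 2.2))
})

test_that("best_predictor minimizes |deviation| with the fixed tie priority", {
  res <- best_predictor(c(leaf = 34.2, stem = -36.2, root = 19.4, weighted = 2.9))
  expect_equal(res$source, "weighted")
  expect_false(res$tie_flag)

  single <- best_predictor(c(root = -7.5))
  expect_equal(single$source, "root")
  expect_false(single$tie_flag)

  tie <- best_predictor(c(leaf = 5.0, root = -5.0))
  expect_equal(tie$source, "leaf")
  expect_true(tie$tie_flag)

  expect_error(best_predictor(numeric(0)), "nonempty")
  expect_error(best_predictor(c(1, 2)), "named")
})

test_that("compare_predictions reproduces the worked-example deviation table", {
  ref <- cannabis_vegetative_means()
  measured <- ref |>
    dplyr::filter(source == "uptake") |>
    dplyr::select(cultivar, element, uptake_mg_per_l = mean)
  predicted <- ref |>
    dplyr::filter(source != "uptake") |>
    dplyr::select(cultivar, element, source, predicted_mg_per_l = mean)
  dev <- compare_predictions(predicted, measured)

  pick <- function(cv, el, src) {
    dev$deviation_reported[dev$cultivar == cv & dev$element == el & dev$source == src]
  }
  expect_equal(pick("CJ2", "N", "weighted"), 2.9)
  expect_equal(pick("First Light", "N", "weighted"), -3.1)
  expect_equal(pick("CJ2", "P", "stem"), -65.8)
  # the organ-weighted mean is the best N predictor in both cultivars
  best_n <- unique(dev$best_source[dev$element == "N"])
  expect_equal(best_n, "weighted")
  # root is the best P predictor in both cultivars
  best_p <- unique(dev$best_source[dev$element == "P"])
  expect_equal(best_p, "root")
})

test_that("replenishment_estimate scales mean uptake by the day's transpiration", {
  one <- tibble::tibble(element = "N", uptake_mg_per_l = 121.5)
  expect_equal(replenishment_estimate(one, 2)$replenishment_mg_per_day, 243)
  expect_equal(replenishment_estimate(one, 0)$replenishment_mg_per_day, 0)
  expect_error(replenishment_estimate(one, -1), ">= 0")

  # zero-noise simulated day matches the simulator's absorbed-mass ledger
  ds <- simulate_trial(zero_noise_config(), seed = 5)
  plant <- ds$ledger$plants$plant_id[1]
  truth <- ds$ledger$daily |>
    dplyr::filter(plant_id == plant, day == 30)
  traj <- ds$config$cultivars[[1]]$trajectories
  true_conc <- traj$start_mg_per_l +
    (traj$end_mg_per_l - traj$start_mg_per_l) * (30 - 1) / (ds$config$phase_days - 1)
  recs <- tibble::tibble(element = traj$element, uptake_mg_per_l = true_conc)
  est <- replenishment_estimate(recs, truth$transpired_l)
  absorbed_day <- true_conc * truth$transpired_l
  expect_equal(est$replenishment_mg_per_day[match(traj$element, est$element)],
               absorbed_day, tolerance = 1e-6)
})
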