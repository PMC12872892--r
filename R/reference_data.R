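#' Bundled cultivar mean uptake and tissue-prediction summary
#'
#' A worked-example dataset: vegetative-phase means (+/- SEM, n = 4 replicate
#' plants, averaged over ten 12-h pour-through uptake cycles) of measured
#' solution uptake and of the input concentrations predicted from leaf, stem
#' and root tissue and from the organ biomass-weighted mean, for two
#' greenhouse cannabis cultivars (CJ2 and First Light), all in mg L^-1.
#'
#' Useful for exercising [compare_predictions()] and [render_uptake_table()]
#' on realistic numbers without running a trial.
#'
#' @return a tibble with columns `cultivar`, `element`, `source`
#'   (uptake/leaf/stem/root/weighted), `mean`, `sem`, `n`.
#' @examples
#' cannabis_vegetative_means() |> head()
#' @export
cannabis_vegetative_means <- function() {
  wide <- tibble::tribble(
    ~cultivar, ~element, ~uptake, ~uptake_sem, ~leaf, ~leaf_sem, ~stem, ~stem_sem,
    ~root, ~root_sem, ~weighted, ~weighted_sem,
    "CJ2", "N", 121.52, 5.56, 163.14, 10.34, 77.51, 16.28, 145.08, 5.50, 125.08, 11.99,
    "CJ2", "P", 38.86, 1.89, 19.84, 1.29, 13.28, 1.67, 35.94, 1.60, 19.00, 1.62,
    "CJ2", "K", 157.62, 10.40, 75.25, 4.00, 110.83, 12.14, 115.67, 11.14, 94.76, 7.19,
    "CJ2", "Ca", 66.27, 2.36, 84.04, 7.64, 30.04, 7.30, 35.99, 2.89, 55.78, 6.84,
    "CJ2", "Fe", 1.58, 0.12, 0.36, 0.03, 0.15, 0.03, 2.98, 0.24, 0.58, 0.07,
    "CJ2", "Mg", 39.86, 2.25, 37.98, 3.12, 10.20, 2.02, 22.83, 1.46, 24.60, 2.39,
    "CJ2", "Mn", 0.19, 0.01, 0.20, 0.02, 0.23, 0.03, 0.37, 0.03, 0.23, 0.02,
    "CJ2", "B", 0.07, 0.00, 0.13, 0.00, 0.05, 0.01, 0.05, 0.00, 0.08, 0.01,
    "CJ2", "Cu", 0.11, 0.02, 0.01, 0.00, 0.03, 0.02, 0.05, 0.00, 0.02, 0.01,
    "CJ2", "Zn", 0.10, 0.02, 0.10, 0.01, 0.04, 0.01, 0.10, 0.00, 0.08, 0.01,
    "First Light", "N", 131.77, 5.25, 165.60, 2.39, 82.58, 6.89, 139.53, 1.72, 127.70, 2.46,
    "First Light", "P", 38.40, 3.21, 21.70, 0.44, 15.69, 1.05, 30.62, 1.39, 20.56, 0.51,
    "First Light", "K", 169.41, 13.30, 77.74, 2.00, 135.90, 9.54, 105.29, 4.08, 105.70, 3.28,
    "First Light", "Ca", 69.89, 2.02, 66.76, 1.66, 40.54, 5.55, 29.83, 2.11, 50.50, 2.04,
    "First Light", "Fe", 1.37, 0.30, 0.27, 0.01, 0.17, 0.02, 2.85, 0.32, 0.61, 0.04,
    "First Light", "Mg", 41.03, 3.05, 28.23, 0.57, 11.36, 1.28, 23.35, 0.88, 20.58, 0.55,
    "First Light", "Mn", 0.17, 0.02, 0.27, 0.01, 0.17, 0.02, 0.34, 0.03, 0.24, 0.01,
    "First Light", "B", 0.08, 0.00, 0.09, 0.00, 0.06, 0.01, 0.05, 0.00, 0.07, 0.00,
    "First Light", "Cu", 0.07, 0.04, 0.01, 0.00, 0.01, 0.00, 0.04, 0.00, 0.01, 0.00,
    "First Light", "Zn", 0.07, 0.03, 0.09, 0.00, 0.04, 0.00, 0.10, 0.00, 0.07, 0.00
  )
  wide |>
    tidyr::pivot_longer(-c("cultivar", "element"),
                        names_to = "key", values_to = "value") |>
    dplyr::mutate(
      source = sub("_sem$", "", .data$key),
      stat = ifelse(grepl("_sem$", .data$key), "sem", "mean")
    ) |>
    dplyr::select(-"key") |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value") |>
    dplyr::mutate(n = 4L)
}
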