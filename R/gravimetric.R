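#' @keywords internal
check_mass_series <- function(series) {
  required <- c("timestamp", "mass_g")
  missing_cols <- setdiff(required, names(series))
  if (length(missing_cols) > 0) {
    abort(paste0("Mass series lacks column(s): ", paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(series) > 1 && any(diff(as.numeric(series$timestamp)) <= 0)) {
    abort("Mass series timestamps must be strictly increasing.")
  }
  if (any(series$mass_g < 0, na.rm = TRUE)) {
    abort("Masses must be >= 0.")
  }
  invisible(series)
}

#' @keywords internal
series_tz <- function(series) {
  attr(series$timestamp, "tzone") %||% "UTC"
}

# rolling-median smoothing (window 3) used to suppress single-sample balance
# jitter before differencing
#' @keywords internal
smooth_mass <- function(mass_g, window = 3) {
  if (length(mass_g) < window) return(mass_g)
  as.numeric(runmed(mass_g, window, endrule = "median"))
}

#' Detect irrigation events in a container mass log
#'
#' Scans a gravimetric mass series (nominally 10-minute cadence) for
#' consecutive-sample mass increases at or above a threshold; each such
#' increase is one irrigation (refill) event, timestamped at the sample where
#' the gain appears. Sub-threshold increases are treated as balance noise and
#' ignored (not subtracted).
#'
#' @param series data frame with columns `timestamp` (POSIXct, strictly
#'   increasing) and `mass_g`.
#' @param threshold_g minimum mass gain counted as irrigation, g. Default 50 g:
#'   dripper delivery is on the order of hundreds of grams per event, far above
#'   balance noise. Lower it for lightly-transpiring plants.
#' @param smooth apply rolling-median smoothing (window 3) before
#'   differencing.
#' @return a tibble of events: `timestamp`, `gain_g`.
#' @export
detect_irrigation_events <- function(series, threshold_g = 50, smooth = FALSE) {
  check_mass_series(series)
  if (length(threshold_g) != 1 || !is.finite(threshold_g) || threshold_g <= 0) {
    abort("`threshold_g` must be a single value > 0.")
  }
  if (nrow(series) < 2) {
    return(tibble::tibble(timestamp = series$timestamp[0], gain_g = numeric(0)))
  }
  mass <- if (smooth) smooth_mass(series$mass_g) else series$mass_g
  gains <- diff(mass)
  idx <- which(gains >= threshold_g) + 1L
  tibble::tibble(timestamp = series$timestamp[idx], gain_g = gains[idx - 1L])
}

#' Water loss per inter-irrigation segment
#'
#' Splits a mass series at irrigation events and reads each segment's water
#' loss as start mass minus end mass (clipped at zero), converted at
#' 1 g = 1 mL. The segment preceding an event ends at the last sample before
#' the event, so refill gains never contaminate the loss estimate.
#'
#' @inheritParams detect_irrigation_events
#' @param events a tibble of events as returned by
#'   [detect_irrigation_events()]; detected automatically when `NULL`.
#' @return a tibble with one row per segment: `start`, `end`, `loss_g`,
#'   `loss_l`. An empty or single-sample series yields zero segments.
#' @export
segment_water_loss <- function(series, events = NULL, threshold_g = 50,
                               smooth = FALSE) {
  check_mass_series(series)
  if (nrow(series) < 2) {
    return(tibble::tibble(start = series$timestamp[0], end = series$timestamp[0],
                          loss_g = numeric(0), loss_l = numeric(0)))
  }
  if (is.null(events)) {
    events <- detect_irrigation_events(series, threshold_g, smooth)
  }
  if (nrow(events) > 0) {
    if (is.unsorted(as.numeric(events$timestamp), strictly = TRUE)) {
      abort("`events` must be sorted by timestamp.")
    }
    ev_idx <- match(as.numeric(events$timestamp), as.numeric(series$timestamp))
    if (any(is.na(ev_idx))) {
      abort("Every event timestamp must correspond to a sample in `series`.")
    }
  } else {
    ev_idx <- integer(0)
  }
  mass <- if (smooth) smooth_mass(series$mass_g) else series$mass_g
  n <- nrow(series)
  # each segment runs from an event sample (or the series start) to the last
  # sample before the next event (or the series end)
  starts <- sort(unique(c(1L, ev_idx)))
  ends <- c(starts[-1] - 1L, n)
  keep <- ends >= starts
  tibble::tibble(
    start = series$timestamp[starts[keep]],
    end = series$timestamp[ends[keep]],
    loss_g = pmax(0, mass[starts[keep]] - mass[ends[keep]])
  ) |>
    dplyr::mutate(loss_l = .data$loss_g / 1000)
}

#' Daily transpiration from a container mass log
#'
#' Splits the series into calendar days (the sample at midnight closes the
#' previous day and opens the next), detects irrigation events within each
#' day, and sums segment water losses, giving litres transpired per day.
#'
#' @inheritParams segment_water_loss
#' @return a tibble with `date` and `loss_l` per calendar day.
#' @export
daily_water_loss <- function(series, threshold_g = 50, smooth = FALSE) {
  check_mass_series(series)
  if (nrow(series) < 2) {
    return(tibble::tibble(date = as.Date(character()), loss_l = numeric(0)))
  }
  tz <- series_tz(series)
  day <- as.Date(series$timestamp, tz = tz)
  days <- sort(unique(day))
  purrr::map_dfr(days, function(d) {
    idx <- which(day == d)
    # include the next day's first sample so the interval crossing midnight is
    # attributed to the day in which it starts
    nxt <- max(idx) + 1L
    if (nxt <= nrow(series)) idx <- c(idx, nxt)
    sub <- series[idx, , drop = FALSE]
    seg <- segment_water_loss(sub, threshold_g = threshold_g, smooth = smooth)
    tibble::tibble(date = d, loss_l = sum(seg$loss_l))
  })
}

#' Water loss across a fixed daily clock window
#'
#' Measures, for each calendar day, the mass decline between the first sample
#' at or after the window start and the last sample at or before the window
#' end (default 07:00-19:00, the 12-h day course over which pour-through
#' uptake cycles run). The window must not contain irrigation events; any mass
#' gain inside it makes the estimate a lower bound.
#'
#' @inheritParams segment_water_loss
#' @param window character vector `c(start, end)` in `"HH:MM"`, default
#'   `c("07:00", "19:00")`.
#' @return a tibble with `date` and `transpired_l`.
#' @export
window_water_loss <- function(series, window = c("07:00", "19:00"),
                              smooth = FALSE) {
  check_mass_series(series)
  tz <- series_tz(series)
  mins <- function(hhmm) {
    p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1]])
    p[1] * 60 + p[2]
  }
  w0 <- mins(window[1]); w1 <- mins(window[2])
  if (w1 <= w0) abort("`window` end must be after its start.")
  mass <- if (smooth) smooth_mass(series$mass_g) else series$mass_g
  tod <- as.integer(format(series$timestamp, "%H", tz = tz)) * 60 +
    as.integer(format(series$timestamp, "%M", tz = tz))
  day <- as.Date(series$timestamp, tz = tz)
  inside <- tod >= w0 & tod <= w1
  tibble::tibble(date = day[inside], mass_g = mass[inside]) |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(
      transpired_l = max(0, (dplyr::first(.data$mass_g) - dplyr::last(.data$mass_g)) / 1000),
      .groups = "drop"
    )
}

#' Cumulative water use over the monitored phase
#'
#' Sums daily transpiration into the total irrigation volume transpired per
#' plant, the denominator of water-use efficiency.
#'
#' @param daily a data frame with columns `date` and `loss_l`, optionally a
#'   `container_id` column (totals are then computed per container).
#' @return a tibble with `total_l` (and `container_id` when present).
#' @examples
#' cumulative_water_use(tibble::tibble(date = as.Date("2024-07-07") + 0:9, loss_l = 0.5))
#' @export
cumulative_water_use <- function(daily) {
  if (nrow(daily) == 0) {
    return(tibble::tibble(total_l = 0))
  }
  if (!all(c("date", "loss_l") %in% names(daily))) {
    abort("`daily` needs columns `date` and `loss_l`.")
  }
  by <- intersect("container_id", names(daily))
  dup <- daily |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "date")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Overlapping daily windows: duplicated date(s) within a container.")
  }
  if (length(by) == 0) {
    return(tibble::tibble(total_l = sum(daily$loss_l)))
  }
  daily |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(total_l = sum(.data$loss_l), .groups = "drop")
}
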