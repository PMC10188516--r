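#' Record-based ambient pesticide exposure assessment
#'
#' The exposure model turns agricultural application records into
#' participant-level ambient exposure estimates. For every address and year,
#' the pounds of each pesticide applied per treated acre on parcels
#' intersecting a 500 m buffer are summed, weighting each application by the
#' fraction of its parcel's area inside the buffer. Annual values are then
#' averaged over the exposure window (1974 up to ten years before the
#' participant's index year), using only years covered by address history,
#' and finally log1p-transformed and standardized within wave x location
#' strata so that association models estimate odds ratios per SD of
#' transformed exposure.
#'
#' @name exposure
NULL

# Buffer fractions for every (address point, parcel) pair with a positive
# intersection. Parcels are pre-filtered by bounding-box distance.
pair_fractions <- function(points, parcels, radius = 500, n_vertices = 64L) {
  stopifnot(all(c("address_id", "x", "y") %in% names(points)))
  out <- vector("list", nrow(points))
  px0 <- parcels$x0; px1 <- parcels$x1; py0 <- parcels$y0; py1 <- parcels$y1
  for (i in seq_len(nrow(points))) {
    ax <- points$x[i]; ay <- points$y[i]
    d2 <- pmax(px0 - ax, 0, ax - px1)^2 + pmax(py0 - ay, 0, ay - py1)^2
    near <- which(d2 < radius^2)
    if (length(near) == 0) next
    fr <- buffer_fraction(parcels[near, ], ax, ay, radius, n_vertices)
    keep <- fr > 0
    if (!any(keep)) next
    out[[i]] <- tibble(
      address_id = points$address_id[i],
      parcel_id = parcels$parcel_id[near][keep],
      fraction = fr[keep]
    )
  }
  bind_rows(out)
}

# Expand address spells into one row per (participant, location, year,
# address), with weights splitting a year equally across addresses occupied
# in that year (spell durations are recorded in whole calendar years, so
# equal weights are the documented tie-break).
spell_years <- function(addresses, years) {
  stopifnot(all(c(
    "participant_id", "location_type", "address_id",
    "start_year", "end_year"
  ) %in% names(addresses)))
  sy <- addresses %>%
    mutate(
      start_year = pmax(.data$start_year, min(years)),
      end_year = pmin(.data$end_year, max(years))
    ) %>%
    filter(.data$start_year <= .data$end_year) %>%
    rowwise() %>%
    mutate(year = list(seq(.data$start_year, .data$end_year))) %>%
    ungroup() %>%
    tidyr::unnest("year") %>%
    select("participant_id", "location_type", "address_id", "year")
  sy %>%
    group_by(.data$participant_id, .data$location_type, .data$year) %>%
    mutate(weight = 1 / dplyr::n()) %>%
    ungroup()
}

#' Years of address coverage per participant and location type
#'
#' @param addresses Address-history table with columns `participant_id`,
#'   `location_type`, `address_id`, `start_year`, `end_year`.
#' @param years Integer vector of calendar years with application data.
#' @return Tibble with one row per covered (participant, location, year).
#' @export
address_coverage <- function(addresses, years) {
  spell_years(addresses, years) %>%
    distinct(.data$participant_id, .data$location_type, .data$year)
}

#' Annual pounds-per-acre exposure within an address buffer
#'
#' For each participant, location type, pesticide and year, computes
#' \eqn{\sum_r (pounds_r / acres\_treated_r) \times fraction_r} over all
#' applications `r` on parcels intersecting the buffer, where `fraction` is
#' the share of the parcel's area inside the buffer. Years in which a
#' participant occupied several addresses of one location type contribute
#' the equal-weighted mean over those addresses. Only strictly positive
#' values are returned; covered years without nearby applications are
#' implicitly zero and are handled by [window_average()].
#'
#' @param applications Application records: `year`, `parcel_id`,
#'   `pesticide_id`, `pounds`, `acres_treated`.
#' @param addresses Address-history table (see [address_coverage()]) with
#'   point coordinates `x`, `y`.
#' @param parcels Parcel table with `parcel_id`, `x0`, `y0`, `x1`, `y1`.
#' @param radius Buffer radius in meters.
#' @param n_vertices Disc polygon resolution.
#' @return Tibble: `participant_id`, `location_type`, `pesticide_id`,
#'   `year`, `lbs_per_acre` (> 0 rows only).
#' @export
annual_exposure <- function(applications, addresses, parcels, radius = 500,
                            n_vertices = 64L) {
  bad <- which(applications$acres_treated <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "acres_treated <= 0 in application record(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  pts <- addresses %>% distinct(.data$address_id, .data$x, .data$y)
  fr <- pair_fractions(pts, parcels, radius, n_vertices)
  if (nrow(fr) == 0) {
    return(tibble(
      participant_id = character(), location_type = character(),
      pesticide_id = character(), year = integer(), lbs_per_acre = double()
    ))
  }
  addr_year <- fr %>%
    inner_join(
      applications %>%
        mutate(intensity = .data$pounds / .data$acres_treated),
      by = "parcel_id", relationship = "many-to-many"
    ) %>%
    group_by(.data$address_id, .data$pesticide_id, .data$year) %>%
    summarise(value = sum(.data$intensity * .data$fraction), .groups = "drop")
  spell_years(addresses, sort(unique(applications$year))) %>%
    inner_join(addr_year, by = c("address_id", "year"),
               relationship = "many-to-many") %>%
    group_by(
      .data$participant_id, .data$location_type,
      .data$pesticide_id, .data$year
    ) %>%
    summarise(lbs_per_acre = sum(.data$weight * .data$value),
              .groups = "drop")
}

#' Exposure-window average of annual estimates
#'
#' Averages annual lbs/acre values over calendar years in
#' `[window_start, index_year - window_offset]` intersected with the years
#' covered by address history for that location type. Covered years with no
#' nearby applications count as zeros. Participants with no covered year in
#' the window receive a missing (not zero) summary for that location type.
#'
#' @param annual Output of [annual_exposure()].
#' @param coverage Output of [address_coverage()].
#' @param participants Participant table with `participant_id`,
#'   `index_year`.
#' @param pesticide_ids Character vector: the full pesticide universe (so
#'   never-applied-nearby pesticides get explicit zero summaries).
#' @param window_start First calendar year of the exposure window.
#' @param window_offset Years before the index date excluded as a prodromal
#'   lag (window end = index_year - window_offset).
#' @return Tibble: `participant_id`, `location_type`, `pesticide_id`,
#'   `raw` (mean lbs/acre, NA when no covered years), `exposed`
#'   (raw > 0), `n_covered_years`.
#' @export
window_average <- function(annual, coverage, participants, pesticide_ids,
                           window_start = 1974, window_offset = 10) {
  win <- participants %>%
    transmute(
      .data$participant_id,
      win_start = window_start,
      win_end = .data$index_year - window_offset
    )
  if (any(win$win_end < win$win_start)) {
    abort("exposure window empty: index_year - window_offset < window_start.")
  }
  cov_in <- coverage %>%
    inner_join(win, by = "participant_id") %>%
    filter(.data$year >= .data$win_start, .data$year <= .data$win_end) %>%
    count(.data$participant_id, .data$location_type, name = "n_covered_years")
  sums <- annual %>%
    inner_join(win, by = "participant_id") %>%
    filter(.data$year >= .data$win_start, .data$year <= .data$win_end) %>%
    semi_join(coverage, by = c("participant_id", "location_type", "year")) %>%
    group_by(.data$participant_id, .data$location_type, .data$pesticide_id) %>%
    summarise(total = sum(.data$lbs_per_acre), .groups = "drop")
  grid <- tidyr::crossing(cov_in, pesticide_id = pesticide_ids)
  grid %>%
    left_join(sums,
      by = c("participant_id", "location_type", "pesticide_id")
    ) %>%
    mutate(
      total = tidyr::replace_na(.data$total, 0),
      raw = .data$total / .data$n_covered_years,
      exposed = .data$raw > 0
    ) %>%
    select(
      "participant_id", "location_type", "pesticide_id",
      "raw", "exposed", "n_covered_years"
    )
}

#' Log-transform and standardize exposure summaries within strata
#'
#' Computes `z = (log1p(raw) - mean) / SD` per pesticide within each
#' standardization stratum (study wave x location type, pooled over cases
#' and controls). Missing summaries stay missing.
#'
#' @param exposure Output of [window_average()].
#' @param participants Participant table with `participant_id`, `wave`.
#' @param on_degenerate `"error"` aborts when a pesticide has fewer than two
#'   non-missing values or zero variance in a stratum (naming both);
#'   `"drop"` sets that stratum's z to NA and signals a message.
#' @return `exposure` with a `wave` and a `z` column added.
#' @export
transform_exposure <- function(exposure, participants,
                               on_degenerate = c("error", "drop")) {
  on_degenerate <- match.arg(on_degenerate)
  out <- exposure %>%
    inner_join(participants %>% select("participant_id", "wave"),
               by = "participant_id") %>%
    group_by(.data$wave, .data$location_type, .data$pesticide_id) %>%
    mutate(
      .l = log1p(.data$raw),
      .n_ok = sum(!is.na(.data$.l)),
      .sd = sd(.data$.l, na.rm = TRUE),
      z = (.data$.l - mean(.data$.l, na.rm = TRUE)) / .data$.sd
    ) %>%
    ungroup()
  degen <- out %>%
    filter(.data$.n_ok < 2 | is.na(.data$.sd) | .data$.sd == 0) %>%
    distinct(.data$wave, .data$location_type, .data$pesticide_id)
  if (nrow(degen) > 0) {
    msg <- paste0(
      degen$pesticide_id, " in ", degen$wave, "/", degen$location_type
    )
    if (on_degenerate == "error") {
      abort(c("zero-variance or underpopulated stratum:",
              utils::head(msg, 5)))
    }
    inform(sprintf(
      "dropping %d degenerate pesticide-stratum combination(s).", nrow(degen)
    ))
    out <- out %>%
      mutate(z = ifelse(
        .data$.n_ok < 2 | is.na(.data$.sd) | .data$.sd == 0, NA_real_, .data$z
      ))
  }
  out %>% select(-".l", -".n_ok", -".sd")
}

#' Exposed-participant counts and the PWAS inclusion mask
#'
#' A participant counts as exposed to a pesticide when the windowed average
#' is positive at either location type; a pesticide enters the association
#' screen when at least `threshold` participants are exposed.
#'
#' @param exposure Output of [window_average()] (or of
#'   [transform_exposure()]).
#' @param threshold Minimum exposed-participant count (inclusive).
#' @return Tibble: `pesticide_id`, `n_exposed`, `include`.
#' @export
exposed_counts <- function(exposure, threshold = 25) {
  exposure %>%
    group_by(.data$pesticide_id) %>%
    summarise(
      n_exposed = dplyr::n_distinct(
        .data$participant_id[!is.na(.data$raw) & .data$raw > 0]
      ),
      .groups = "drop"
    ) %>%
    mutate(include = .data$n_exposed >= threshold)
}

#' One-call exposure matrix construction
#'
#' Convenience wrapper running [annual_exposure()], [address_coverage()],
#' [window_average()] and [transform_exposure()].
#'
#' @inheritParams annual_exposure
#' @inheritParams window_average
#' @inheritParams transform_exposure
#' @param participants Participant table with `participant_id`, `wave`,
#'   `index_year`.
#' @return Long exposure tibble with `raw`, `exposed`, `z`.
#' @export
build_exposure_matrix <- function(applications, addresses, parcels,
                                  participants,
                                  radius = 500, window_start = 1974,
                                  window_offset = 10, n_vertices = 64L,
                                  on_degenerate = "drop") {
  annual <- annual_exposure(applications, addresses, parcels, radius,
                            n_vertices)
  coverage <- address_coverage(addresses, sort(unique(applications$year)))
  expo <- window_average(
    annual, coverage, participants,
    pesticide_ids = sort(unique(applications$pesticide_id)),
    window_start = window_start, window_offset = window_offset
  )
  transform_exposure(expo, participants, on_degenerate = on_degenerate)
}
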