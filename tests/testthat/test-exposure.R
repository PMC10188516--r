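# A hand-built micro-landscape: one participant living at the origin,
# parcels in known positions, applications with known intensities.
micro_parcels <- tibble::tibble(
  parcel_id = c("in", "out", "straddle"),
  x0 = c(-50, 2000, 400), y0 = c(-50, 2000, -100),
  x1 = c(50, 2100, 600), y1 = c(50, 2100, 100)
)
micro_addresses <- tibble::tibble(
  participant_id = "sub1", location_type = "residential",
  address_id = "a1", x = 0, y = 0, start_year = 1970, end_year = 2000
)
micro_participants <- tibble::tibble(
  participant_id = "sub1", wave = "wave1", index_year = 2000
)

test_that("annual exposure is intensity times buffer fraction, summed", {
  apps <- tibble::tibble(
    year = 1990, parcel_id = "in", pesticide_id = "P01",
    pounds = 100, acres_treated = 10
  )
  ann <- annual_exposure(apps, micro_addresses, micro_parcels)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$lbs_per_acre, 10) # parcel fully inside the buffer
  # half-inside parcel scales by the (raster-checked) fraction
  apps2 <- apps %>% dplyr::mutate(parcel_id = "straddle")
  ann2 <- annual_exposure(apps2, micro_addresses, micro_parcels)
  fr <- pwastox:::raster_buffer_fraction(
    micro_parcels[micro_parcels$parcel_id == "straddle", ], 0, 0, 500
  )
  expect_lt(abs(ann2$lbs_per_acre - 10 * fr), 10 * 0.01)
  # out-of-buffer applications contribute nothing
  apps3 <- apps %>% dplyr::mutate(parcel_id = "out")
  expect_equal(nrow(annual_exposure(apps3, micro_addresses, micro_parcels)),
               0)
  expect_error(
    annual_exposure(apps %>% dplyr::mutate(acres_treated = 0),
                    micro_addresses, micro_parcels),
    "acres_treated"
  )
})

test_that("annual exposure is linear in pounds and split-invariant", {
  apps <- tibble::tibble(
    year = 1990, parcel_id = "in", pesticide_id = "P01",
    pounds = 80, acres_treated = 8
  )
  one <- annual_exposure(apps, micro_addresses, micro_parcels)
  doubled <- annual_exposure(apps %>% dplyr::mutate(pounds = 160),
                             micro_addresses, micro_parcels)
  expect_equal(doubled$lbs_per_acre, 2 * one$lbs_per_acre)
  # splitting one application into two with the same total pounds and the
  # same treated acreage per split leaves the estimate unchanged
  split <- tibble::tibble(
    year = 1990, parcel_id = "in", pesticide_id = "P01",
    pounds = c(30, 50), acres_treated = c(8, 8)
  )
  s <- annual_exposure(split, micro_addresses, micro_parcels)
  expect_equal(s$lbs_per_acre, one$lbs_per_acre)
})

test_that("window averaging uses covered years only and flags empty windows", {
  years <- 1974:1995
  coverage <- tidyr::crossing(
    participant_id = "sub1", location_type = "residential",
    year = c(1980, 1981, 1982)
  )
  annual <- tibble::tibble(
    participant_id = "sub1", location_type = "residential",
    pesticide_id = "P01", year = c(1980, 1982), lbs_per_acre = c(2, 4)
  )
  out <- window_average(annual, coverage, micro_participants,
                        pesticide_ids = c("P01", "P02"))
  # (2 + 0 + 4) / 3 covered years; uncovered years never enter
  expect_equal(out$raw[out$pesticide_id == "P01"], 2)
  expect_equal(out$raw[out$pesticide_id == "P02"], 0)
  expect_false(out$exposed[out$pesticide_id == "P02"])
  # constant series over a fully covered window averages to the constant
  cov_full <- tidyr::crossing(
    participant_id = "sub1", location_type = "residential",
    year = 1974:1990
  )
  ann_const <- cov_full %>%
    dplyr::mutate(pesticide_id = "P01", lbs_per_acre = 4)
  out2 <- window_average(ann_const, cov_full, micro_participants, "P01")
  expect_equal(out2$raw, 4)
  expect_equal(out2$n_covered_years, 17L) # 1974..1990 within index-10
  # no covered years in the window -> participant/location absent
  cov_late <- tidyr::crossing(
    participant_id = "sub1", location_type = "workplace", year = 1995:1999
  )
  out3 <- window_average(annual, dplyr::bind_rows(coverage, cov_late),
                         micro_participants, "P01")
  expect_false("workplace" %in% out3$location_type)
})

test_that("a 22-year covered window equals the direct mean over those years", {
  set.seed(9)
  yrs <- sort(sample(1974:1990, 17)) # covered years within the window
  yrs <- c(yrs, 1966:1970) # covered years before the window start
  vals <- round(runif(length(yrs), 0, 5), 3)
  coverage <- tibble::tibble(participant_id = "sub1",
                             location_type = "residential", year = yrs)
  annual <- coverage %>%
    dplyr::mutate(pesticide_id = "P01", lbs_per_acre = vals)
  out <- window_average(annual, coverage, micro_participants, "P01")
  in_win <- yrs >= 1974 & yrs <= 1990
  expect_equal(out$raw, mean(vals[in_win]))
  expect_equal(out$n_covered_years, sum(in_win))
})

test_that("transformation is a within-stratum z-score of log1p", {
  set.seed(3)
  expo <- tidyr::crossing(
    participant_id = sprintf("s%02d", 1:40),
    location_type = "residential", pesticide_id = c("P01", "P02")
  ) %>%
    dplyr::mutate(raw = rlnorm(dplyr::n()) *
                    rbinom(dplyr::n(), 1, 0.8),
                  exposed = .data$raw > 0, n_covered_years = 20L)
  parts <- tibble::tibble(
    participant_id = sprintf("s%02d", 1:40),
    wave = rep(c("wave1", "wave2"), 20), index_year = 2005
  )
  z <- transform_exposure(expo, parts)
  byg <- z %>%
    dplyr::group_by(.data$wave, .data$pesticide_id) %>%
    dplyr::summarise(m = mean(.data$z), s = sd(.data$z), .groups = "drop")
  expect_true(all(abs(byg$m) < 1e-9))
  expect_true(all(abs(byg$s - 1) < 1e-9))
  # x = 0 maps to log1p(0) = 0 before standardization; monotone after
  g <- z %>% dplyr::filter(.data$wave == "wave1",
                           .data$pesticide_id == "P01")
  expect_equal(order(g$raw), order(g$z))
  # degenerate stratum errors with names, or drops on request
  expo0 <- expo %>% dplyr::mutate(raw = 0)
  expect_error(transform_exposure(expo0, parts), "P01")
  expect_message(
    z0 <- transform_exposure(expo0, parts, on_degenerate = "drop"),
    "degenerate"
  )
  expect_true(all(is.na(z0$z)))
})

test_that("exposed counts honor the inclusive threshold of 25", {
  ids <- sprintf("s%03d", 1:60)
  expo <- dplyr::bind_rows(
    tibble::tibble(participant_id = ids, pesticide_id = "P01", raw = 0),
    tibble::tibble(participant_id = ids, pesticide_id = "P02",
                   raw = as.numeric(seq_along(ids) <= 25)),
    tibble::tibble(participant_id = ids, pesticide_id = "P03", raw = 1)
  ) %>%
    dplyr::mutate(location_type = "residential")
  counts <- exposed_counts(expo)
  c01 <- counts[counts$pesticide_id == "P01", ]
  c02 <- counts[counts$pesticide_id == "P02", ]
  c03 <- counts[counts$pesticide_id == "P03", ]
  expect_equal(c01$n_exposed, 0); expect_false(c01$include)
  expect_equal(c02$n_exposed, 25); expect_true(c02$include) # boundary
  expect_equal(c03$n_exposed, 60); expect_true(c03$include)
})

test_that("same-year multiple addresses are equally weighted", {
  adds <- tibble::tibble(
    participant_id = "sub1", location_type = "residential",
    address_id = c("a1", "a2"),
    x = c(0, 5000), y = c(0, 0),
    start_year = 1985, end_year = 1990
  )
  parcels <- tibble::tibble(
    parcel_id = c("near1", "near2"),
    x0 = c(-50, 4950), y0 = -50, x1 = c(50, 5050), y1 = 50
  )
  apps <- tibble::tibble(
    year = 1988, parcel_id = c("near1", "near2"), pesticide_id = "P01",
    pounds = c(100, 300), acres_treated = c(10, 10)
  )
  ann <- annual_exposure(apps, adds, parcels)
  expect_equal(ann$lbs_per_acre, 0.5 * 10 + 0.5 * 30)
})
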