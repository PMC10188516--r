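#' Simulate an agricultural landscape of rectangular parcels
#'
#' Parcels are axis-aligned rectangles placed on a jittered grid (one parcel
#' per grid cell, with a margin), so they never overlap and areas are exact.
#' Crops are assigned by nearest crop-zone seed, producing spatially
#' contiguous crop zones the way real growing regions cluster; this spatial
#' structure is what makes some participants unexposed to crop-specific
#' chemistries.
#'
#' @param config A [sim_config()].
#' @return Tibble: `parcel_id`, `x0`, `y0`, `x1`, `y1`, `crop`, `area_m2`,
#'   `acres`.
#' @export
sim_landscape <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 11L)
  n <- config$n_parcels
  nx <- ceiling(sqrt(n * config$region[1] / config$region[2]))
  ny <- ceiling(n / nx)
  cw <- config$region[1] / nx
  ch <- config$region[2] / ny
  if (min(cw, ch) < 60) {
    abort("region extent too small for n_parcels (cells under 60 m).")
  }
  cells <- tidyr::crossing(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L) %>%
    slice_head(n = n)
  w <- runif(n, 0.45, 0.85) * cw
  h <- runif(n, 0.45, 0.85) * ch
  ox <- runif(n, 0, 1) * (cw - w)
  oy <- runif(n, 0, 1) * (ch - h)
  crops <- c("cotton", "grape", "citrus", "almond", "alfalfa")
  seeds_x <- runif(length(crops), 0, config$region[1])
  seeds_y <- runif(length(crops), 0, config$region[2])
  parcels <- cells %>%
    mutate(
      parcel_id = sprintf("parcel%04d", dplyr::row_number()),
      x0 = .data$ix * cw + ox,
      y0 = .data$iy * ch + oy,
      x1 = .data$x0 + w,
      y1 = .data$y0 + h
    )
  cx <- (parcels$x0 + parcels$x1) / 2
  cy <- (parcels$y0 + parcels$y1) / 2
  nearest <- apply(
    outer(cx, seeds_x, "-")^2 + outer(cy, seeds_y, "-")^2, 1, which.min
  )
  parcels %>%
    mutate(
      crop = crops[nearest],
      area_m2 = (.data$x1 - .data$x0) * (.data$y1 - .data$y0),
      acres = .data$area_m2 / ACRE_M2
    ) %>%
    select("parcel_id", "x0", "y0", "x1", "y1", "crop", "area_m2", "acres")
}

#' Simulate pesticide application records
#'
#' Emulates mandated use-report records: one row per application event with
#' year, parcel, pounds of active ingredient and treated acreage.
#' Co-application structure: each cluster draws parcel-year "events" on its
#' anchor crop's parcels, and each member follows a given event with
#' probability `rho_within` (otherwise applying independently at the same
#' base rate), so `rho_within = 1` yields identical parcel-year application
#' sets within a cluster. Crop-exclusive pesticides (defoliants) appear only
#' on their crop; other pesticides favor their crop affinity but spill over
#' (85/15). Application intensity (lbs/acre) is log-normal with a shared
#' parcel-year factor, giving the right-skewed distributions seen in real
#' use reports.
#'
#' @param parcels Output of [sim_landscape()].
#' @param config A [sim_config()].
#' @param base_rate Per parcel-year probability of a cluster event on
#'   eligible parcels.
#' @return Tibble: `year`, `parcel_id`, `pesticide_id`, `pounds`,
#'   `acres_treated`, `crop`.
#' @export
sim_applications <- function(parcels, config, base_rate = 0.10) {
  validate_sim_config(config)
  set.seed(config$seed + 22L)
  pest <- config$pesticides
  ids <- pest$pesticide_id
  grouped <- unlist(config$clusters)
  all_clusters <- c(config$clusters, as.list(setdiff(ids, grouped)))
  out <- vector("list", length(all_clusters))
  for (ci in seq_along(all_clusters)) {
    members <- all_clusters[[ci]]
    ann <- pest[match(members, pest$pesticide_id), ]
    anchor_crop <- names(sort(table(ann$crop_affinity), decreasing = TRUE))[1]
    elig <- parcels %>% filter(.data$crop == anchor_crop)
    spill <- parcels %>% filter(.data$crop != anchor_crop)
    if (nrow(elig) == 0) next
    grid <- tidyr::crossing(parcel_id = elig$parcel_id, year = config$years)
    grid$event <- rbinom(nrow(grid), 1, base_rate) == 1
    # shared parcel-year magnitude factor for co-applied members
    grid$eta <- rnorm(nrow(grid), 0, 0.5)
    ev <- grid[grid$event, ]
    rows <- vector("list", length(members))
    for (mi in seq_along(members)) {
      m <- members[mi]
      excl <- ann$crop_exclusive[mi]
      if (excl && ann$crop_affinity[mi] != anchor_crop) {
        # crop-restricted member anchored elsewhere: apply independently on
        # its own crop only
        own_elig <- parcels %>%
          filter(.data$crop == ann$crop_affinity[mi])
        if (nrow(own_elig) == 0) next
        g2 <- tidyr::crossing(parcel_id = own_elig$parcel_id,
                              year = config$years)
        g2 <- g2[rbinom(nrow(g2), 1, base_rate) == 1, ]
        if (nrow(g2) == 0) next
        g2$eta <- rnorm(nrow(g2), 0, 0.5)
        g2$pesticide_id <- m
        rows[[mi]] <- g2
        next
      }
      follow <- runif(nrow(ev)) < config$rho_within
      own <- grid[!grid$event & rbinom(nrow(grid), 1,
                                       base_rate * (1 - config$rho_within)
      ) == 1, ]
      app <- bind_rows(ev[follow, c("parcel_id", "year", "eta")],
                       own[, c("parcel_id", "year", "eta")])
      if (!excl && nrow(spill) > 0 && config$rho_within < 1) {
        sp <- tidyr::crossing(parcel_id = spill$parcel_id,
                              year = config$years)
        keep <- rbinom(nrow(sp), 1,
                       base_rate * 0.15 * (1 - config$rho_within)) == 1
        sp <- sp[keep, ]
        sp$eta <- rnorm(nrow(sp), 0, 0.5)
        app <- bind_rows(app, sp)
      }
      if (nrow(app) == 0) next
      app$pesticide_id <- m
      rows[[mi]] <- app
    }
    out[[ci]] <- bind_rows(rows)
  }
  apps <- bind_rows(out)
  if (nrow(apps) == 0) abort("no applications generated; raise base_rate.")
  apps <- apps %>%
    inner_join(parcels %>% select("parcel_id", "acres", "crop"),
               by = "parcel_id")
  apps$acres_treated <- apps$acres * runif(nrow(apps), 0.4, 1)
  intensity <- exp(log(1.5) + apps$eta + rnorm(nrow(apps), 0, 0.8))
  apps$pounds <- intensity * apps$acres_treated
  apps %>%
    arrange(.data$year, .data$parcel_id, .data$pesticide_id) %>%
    select("year", "parcel_id", "pesticide_id", "pounds", "acres_treated",
           "crop")
}
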