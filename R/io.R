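#' Write parcels as GeoJSON
#'
#' Planar coordinates in meters (not longitude/latitude); each parcel is a
#' closed rectangular ring with `parcel_id`, `crop` and `acres` properties.
#'
#' @param parcels Parcel table from [sim_landscape()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcels_geojson <- function(parcels, path) {
  features <- purrr::map(seq_len(nrow(parcels)), function(i) {
    p <- parcels[i, ]
    ring <- list(
      c(p$x0, p$y0), c(p$x1, p$y0), c(p$x1, p$y1), c(p$x0, p$y1),
      c(p$x0, p$y0)
    )
    list(
      type = "Feature",
      properties = list(parcel_id = p$parcel_id, crop = p$crop,
                        acres = p$acres),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = "planar-meters")),
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read parcels from GeoJSON
#'
#' Inverse of [write_parcels_geojson()] for axis-aligned rectangular
#' parcels: reconstructs the bounding-box columns and areas.
#'
#' @param path GeoJSON path.
#' @return Parcel tibble.
#' @export
read_parcels_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  purrr::map_dfr(obj$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    tibble(
      parcel_id = f$properties$parcel_id,
      x0 = min(xy[, 1]), y0 = min(xy[, 2]),
      x1 = max(xy[, 1]), y1 = max(xy[, 2]),
      crop = f$properties$crop
    )
  }) %>%
    mutate(area_m2 = (.data$x1 - .data$x0) * (.data$y1 - .data$y0),
           acres = .data$area_m2 / ACRE_M2)
}

write_stage_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_stage_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
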