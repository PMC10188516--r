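#' Run the full simulate-to-screen pipeline
#'
#' Orchestrates all stages in dependency order, exchanging data only
#' through documented CSV/GeoJSON files in `outdir` (so any stage can be
#' rerun in isolation): `simulate` writes parcels.geojson,
#' applications.csv, participants.csv, addresses.csv, annotations.csv,
#' wells.csv, objects.csv, combo_counts.csv, ocr.csv and
#' ground_truth.json; `exposure` writes exposure.csv and
#' inclusion_mask.csv; `pwas` writes pwas_results.csv and
#' pwas_strata.csv; `ora` writes ora_results.csv; `screen` writes
#' well_counts.csv, toxicity_calls.csv, zprime.txt and dose_summary.csv;
#' `network` writes corr_matrix.csv and edges.csv; `cluster` writes
#' clusters.csv and crop_share.csv; `combos` writes combos.csv; `mito`
#' writes mito_params.csv. A manifest.json records the configuration hash,
#' seed, package version and per-file row counts. Deterministic stages are
#' byte-identical across reruns with the same configuration.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param stages Stage names to run, in pipeline order; `"all"` for every
#'   stage. Later stages read earlier stages' files from `outdir`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = demo_config(), outdir,
                         stages = "all") {
  all_stages <- c("simulate", "exposure", "pwas", "ora", "screen",
                  "network", "cluster", "combos", "mito")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) abort(sprintf("unknown stage(s): %s",
                                     paste(bad, collapse = ", ")))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pwastox")),
    stages = stages,
    rows = list()
  )
  for (st in stages) {
    inform(sprintf("[pwastox] stage %s", st))
    rows <- tryCatch(
      run_stage(st, config, outdir),
      error = function(e) {
        abort(sprintf("stage '%s' failed: %s", st, conditionMessage(e)))
      }
    )
    manifest$rows <- c(manifest$rows, rows)
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run a single pipeline stage
#'
#' @inheritParams run_pipeline
#' @param stage One stage name (see [run_pipeline()]).
#' @return Named list of row counts of the files written.
#' @export
run_stage <- function(stage, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(outdir, name)
  switch(stage,
    simulate = {
      parcels <- sim_landscape(config)
      apps <- sim_applications(parcels, config)
      cohort <- sim_cohort(parcels, apps, config)
      plate <- sim_plate(config)
      combo <- sim_combo_counts(config)
      ocr <- sim_ocr(config, conditions = tibble(
        condition = c("DMSO", "treated_30uM"),
        basal_mult = c(1, 0.95), atp_mult = c(1, 0.9),
        maximal_mult = c(1, 0.6)
      ))
      write_parcels_geojson(parcels, f("parcels.geojson"))
      write_stage_csv(apps, f("applications.csv"))
      write_stage_csv(cohort$participants, f("participants.csv"))
      write_stage_csv(cohort$addresses, f("addresses.csv"))
      write_stage_csv(config$pesticides, f("annotations.csv"))
      write_stage_csv(plate$wells, f("wells.csv"))
      write_stage_csv(plate$objects, f("objects.csv"))
      write_stage_csv(combo, f("combo_counts.csv"))
      write_stage_csv(ocr, f("ocr.csv"))
      write_stage_csv(cohort$truth$exposure, f("true_exposure.csv"))
      write_ground_truth(cohort$truth, f("ground_truth.json"))
      list(parcels = nrow(parcels), applications = nrow(apps),
           participants = nrow(cohort$participants),
           objects = nrow(plate$objects))
    },
    exposure = {
      parcels <- read_parcels_geojson(f("parcels.geojson"))
      apps <- read_stage_csv(f("applications.csv"))
      addresses <- read_stage_csv(f("addresses.csv"))
      participants <- read_stage_csv(f("participants.csv"))
      expo <- build_exposure_matrix(
        apps, addresses, parcels, participants,
        radius = config$buffer_radius, on_degenerate = "drop"
      )
      mask <- exposed_counts(expo)
      write_stage_csv(expo, f("exposure.csv"))
      write_stage_csv(mask, f("inclusion_mask.csv"))
      list(exposure = nrow(expo))
    },
    pwas = {
      expo <- read_stage_csv(f("exposure.csv"))
      participants <- read_stage_csv(f("participants.csv"))
      fit <- run_pwas(expo, participants)
      write_stage_csv(fit$results, f("pwas_results.csv"))
      write_stage_csv(fit$strata, f("pwas_strata.csv"))
      list(pwas_results = nrow(fit$results))
    },
    ora = {
      res <- read_stage_csv(f("pwas_results.csv"))
      ann <- read_stage_csv(f("annotations.csv"))
      assoc <- res$pesticide_id[res$associated]
      long <- ann %>%
        select("pesticide_id", "use_type", "chemical_class") %>%
        tidyr::pivot_longer(-"pesticide_id", values_to = "group") %>%
        select("pesticide_id", "group") %>%
        bind_rows(
          ann %>% filter(.data$cholinesterase_inhibitor) %>%
            transmute(.data$pesticide_id,
                      group = "cholinesterase inhibitor"),
          ann %>% filter(.data$carcinogen) %>%
            transmute(.data$pesticide_id, group = "carcinogen"),
          ann %>% filter(.data$bad_actor) %>%
            transmute(.data$pesticide_id, group = "bad actor")
        )
      ora <- run_ora(assoc, long, universe = res$pesticide_id)
      write_stage_csv(ora, f("ora_results.csv"))
      list(ora_results = nrow(ora))
    },
    screen = {
      wells <- read_stage_csv(f("wells.csv"))
      objects <- read_stage_csv(f("objects.csv"))
      wc <- count_positives(objects, wells)
      calls <- toxicity_call(wc, dose = max(config$doses))
      zp <- zprime(wc$count[wc$role == "DMSO"],
                   wc$count[wc$role == "positive"])
      ds <- dose_summary(wc)
      write_stage_csv(wc, f("well_counts.csv"))
      write_stage_csv(calls, f("toxicity_calls.csv"))
      writeLines(format(zp, digits = 15), f("zprime.txt"))
      write_stage_csv(ds$doses, f("dose_summary.csv"))
      write_stage_csv(ds$compounds, f("dose_compounds.csv"))
      list(well_counts = nrow(wc), toxic = sum(calls$toxic))
    },
    network = {
      expo <- read_stage_csv(f("exposure.csv"))
      res <- read_stage_csv(f("pwas_results.csv"))
      calls <- read_stage_csv(f("toxicity_calls.csv"))
      implicated <- res$pesticide_id[res$implicated]
      if (length(implicated) < 2) {
        inform("fewer than 2 implicated pesticides; using all tested.")
        implicated <- res$pesticide_id
      }
      r <- exposure_corr(expo, implicated)
      toxic <- intersect(calls$compound[calls$toxic], rownames(r))
      if (length(toxic) == 0) toxic <- rownames(r)[1]
      net <- build_network(r, toxic)
      rr <- as_tibble(r, rownames = "pesticide_id")
      write_stage_csv(rr, f("corr_matrix.csv"))
      write_stage_csv(net$edges, f("edges.csv"))
      write_stage_csv(net$nodes, f("network_nodes.csv"))
      list(edges = nrow(net$edges))
    },
    cluster = {
      rr <- read_stage_csv(f("corr_matrix.csv"))
      r <- as.matrix(rr[, -1])
      rownames(r) <- rr$pesticide_id
      keep <- !apply(is.na(r), 1, any)
      cl <- cluster_exposures(r[keep, keep, drop = FALSE])
      apps <- read_stage_csv(f("applications.csv"))
      cs <- share_on_crop(apps, "cotton")
      write_stage_csv(cl, f("clusters.csv"))
      write_stage_csv(cs, f("crop_share.csv"))
      list(clusters = max(cl$cluster))
    },
    combos = {
      combo <- read_stage_csv(f("combo_counts.csv"))
      ca <- combo_analysis(combo)
      write_stage_csv(ca$conditions, f("combos.csv"))
      write_stage_csv(ca$comparisons, f("combo_tests.csv"))
      write_stage_csv(ca$pairs, f("combo_pairs.csv"))
      list(combos = nrow(ca$conditions))
    },
    mito = {
      ocr <- read_stage_csv(f("ocr.csv"))
      mp <- mito_stress(ocr)
      write_stage_csv(mp, f("mito_params.csv"))
      list(mito_params = nrow(mp))
    },
    abort(sprintf("unknown stage '%s'", stage))
  )
}
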