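#' Default pesticide annotation table
#'
#' Builds a deterministic annotation table for `n` synthetic pesticide
#' active ingredients: use type, chemical class, toxicity flags and an
#' (optional) crop affinity. The first six pesticides form a "cotton
#' cluster" whose defoliants are applied exclusively on cotton, mirroring
#' the structure of real co-application groups; the remaining annotations
#' cycle through common categories so every overrepresentation group is
#' populated.
#'
#' @param n Number of pesticides (>= 10).
#' @return Tibble: `pesticide_id`, `use_type`, `chemical_class`,
#'   `cholinesterase_inhibitor`, `carcinogen`, `bad_actor`, `crop_affinity`,
#'   `crop_exclusive`.
#' @export
default_pesticides <- function(n = 40) {
  if (n < 10) abort("need at least 10 pesticides.")
  id <- sprintf("P%02d", seq_len(n))
  use_type <- rep(
    c("insecticide", "herbicide", "fungicide", "defoliant", "fumigant"),
    length.out = n
  )
  # first cluster: cotton chemistry (two defoliants applied only on cotton)
  use_type[1:6] <- c("defoliant", "defoliant", "herbicide", "herbicide",
                     "insecticide", "insecticide")
  chemical_class <- rep(
    c("organophosphorus", "organochlorine", "carbamate", "triazine",
      "dinitroaniline", "other"),
    length.out = n
  )
  crops <- c("cotton", "grape", "citrus", "almond", "alfalfa")
  crop_affinity <- rep(crops, length.out = n)
  crop_affinity[1:6] <- "cotton"
  crop_affinity[use_type == "defoliant"] <- "cotton"
  tibble(
    pesticide_id = id,
    use_type = use_type,
    chemical_class = chemical_class,
    cholinesterase_inhibitor = chemical_class %in%
      c("organophosphorus", "carbamate"),
    carcinogen = seq_len(n) %% 4 == 0,
    bad_actor = chemical_class %in% c("organophosphorus", "carbamate") |
      seq_len(n) %% 4 == 0,
    crop_affinity = crop_affinity,
    crop_exclusive = use_type == "defoliant"
  )
}

#' Default dose-response truth for the neurotoxicity screen
#'
#' Hill survival parameters for `n_compounds` screened compounds (relative
#' to solvent control): `n_toxic` compounds have low survival plateaus and
#' midpoints in the screened dose range; the rest are inert (flat at 1).
#' Positive controls mirror a strong mitochondrial toxicant.
#'
#' @param compounds Character vector of compound ids.
#' @param n_toxic Number of truly toxic compounds (taken from the front).
#' @return Tibble: `compound`, `top`, `bottom`, `ec50`, `hill`, `toxic`.
#' @export
default_plate_truth <- function(compounds, n_toxic = 10) {
  n <- length(compounds)
  if (n_toxic > n) abort("n_toxic exceeds number of compounds.")
  toxic <- seq_len(n) <= n_toxic
  tibble(
    compound = compounds,
    top = 1,
    bottom = ifelse(toxic, 0.05 + 0.01 * (seq_len(n) %% 10), 1),
    ec50 = ifelse(toxic, 3 + 0.5 * (seq_len(n) %% 7), 30),
    hill = ifelse(toxic, 1.8 + 0.1 * (seq_len(n) %% 6), 1),
    toxic = toxic
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: landscape, application
#' records, case-control cohort, screening plates, and respirometry traces.
#' Defaults emulate the structure of a two-wave agricultural case-control
#' study: a ~144 km^2 planar region dense with rectangular parcels, 26
#' years of application records, wave sizes 357/400 and 472/424
#' (cases/controls), co-application clusters with within-cluster
#' application correlation 0.8, and a handful of causal pesticides at
#' odds ratio 1.5 per SD of transformed exposure.
#'
#' @param n_pesticides Number of synthetic active ingredients.
#' @param n_parcels Number of parcels.
#' @param region Width and height of the region in meters.
#' @param years Calendar years with application records.
#' @param clusters List of character vectors partitioning (a subset of)
#'   pesticide ids into co-application clusters; pesticides not listed are
#'   applied independently.
#' @param rho_within Probability that a cluster member follows the
#'   cluster's parcel-year application events (1 = identical application
#'   sets, 0 = independent).
#' @param waves Tibble with `wave`, `n_cases`, `n_controls`,
#'   `enroll_start`, `enroll_end`.
#' @param causal_effects Named numeric: true log-odds ratio per SD of
#'   transformed residential exposure. Defaults to log(1.5) for three
#'   pesticides.
#' @param covariate_effects Named numeric log-OR for `age` (per year,
#'   centered at 65), `male` and `smoker`.
#' @param p_workplace Probability a participant has workplace address
#'   history.
#' @param buffer_radius Exposure buffer radius in meters.
#' @param doses Screening concentrations in micromolar.
#' @param pesticides Annotation table; defaults to
#'   [default_pesticides()].
#' @param plate_truth Dose-response truth table; defaults to
#'   [default_plate_truth()] over the first `min(39, n_pesticides)`
#'   pesticides.
#' @param combo_interactions Named numeric survival multipliers for
#'   compound pairs (names like `"P01+P02"`), applied on top of
#'   multiplicative independence; values < 1 are synergistic.
#' @param ocr_truth List with true respirometry parameters `non_mito`,
#'   `basal`, `atp`, `maximal` (protein-normalized OCR units) and
#'   `noise_sd`.
#' @param seed Master seed; each generated artifact uses its own stream
#'   derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pesticides = 40,
                       n_parcels = 600,
                       region = c(12000, 12000),
                       years = 1974:1999,
                       clusters = NULL,
                       rho_within = 0.8,
                       waves = tibble(
                         wave = c("wave1", "wave2"),
                         n_cases = c(357, 472),
                         n_controls = c(400, 424),
                         enroll_start = c(2000, 2009),
                         enroll_end = c(2007, 2015)
                       ),
                       causal_effects = NULL,
                       covariate_effects = c(age = 0.02, male = 0.3,
                                             smoker = -0.2),
                       p_workplace = 0.65,
                       buffer_radius = 500,
                       doses = c(1.1, 3.3, 10, 30),
                       pesticides = default_pesticides(n_pesticides),
                       plate_truth = NULL,
                       combo_interactions = c("P01+P02" = 0.5),
                       ocr_truth = list(non_mito = 10, basal = 90, atp = 60,
                                        maximal = 140, noise_sd = 2),
                       seed = 1L) {
  ids <- pesticides$pesticide_id
  if (is.null(clusters)) {
    clusters <- list(ids[1:6], ids[7:10], ids[11:13])
    clusters <- lapply(clusters, function(x) x[!is.na(x)])
  }
  if (is.null(causal_effects)) {
    causal_effects <- setNames(rep(log(1.5), 3), ids[c(1, 3, 7)])
  }
  if (is.null(plate_truth)) {
    plate_truth <- default_plate_truth(ids[seq_len(min(39, length(ids)))])
  }
  cfg <- structure(list(
    n_parcels = n_parcels, region = region, years = years,
    pesticides = pesticides, clusters = clusters, rho_within = rho_within,
    waves = waves, causal_effects = causal_effects,
    covariate_effects = covariate_effects, p_workplace = p_workplace,
    buffer_radius = buffer_radius, doses = doses, plate_truth = plate_truth,
    combo_interactions = combo_interactions, ocr_truth = ocr_truth,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_parcels <= 0) abort("n_parcels must be positive.")
  if (any(cfg$region <= 0)) abort("region extent must be positive.")
  if (length(cfg$years) == 0) abort("year range must be non-empty.")
  if (cfg$rho_within < 0 || cfg$rho_within > 1) {
    abort("rho_within must lie in [0, 1].")
  }
  if (any(cfg$waves$n_cases + cfg$waves$n_controls <= 0)) {
    abort("each wave needs n_cases + n_controls > 0.")
  }
  ids <- cfg$pesticides$pesticide_id
  extra <- setdiff(unlist(cfg$clusters), ids)
  if (length(extra) > 0) {
    abort(sprintf("cluster pesticide id(s) not in config: %s",
                  paste(extra, collapse = ", ")))
  }
  extra <- setdiff(names(cfg$causal_effects), ids)
  if (length(extra) > 0) {
    abort(sprintf("causal-effect pesticide id(s) not in config: %s",
                  paste(extra, collapse = ", ")))
  }
  if (any(cfg$plate_truth$ec50 <= 0)) abort("EC50 must be positive.")
  if (any(cfg$doses < 0)) abort("doses must be non-negative.")
  invisible(cfg)
}

#' Small demonstration configuration
#'
#' A scaled-down configuration (20 pesticides, 100 cases and 100 controls
#' per wave, 300 parcels on a 8 x 8 km region) used by the package
#' examples, the pipeline smoke test, and the vignette.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
demo_config <- function(seed = 1L, ...) {
  args <- list(
    n_pesticides = 20,
    n_parcels = 300,
    region = c(8000, 8000),
    waves = tibble(
      wave = c("wave1", "wave2"),
      n_cases = c(100, 100),
      n_controls = c(100, 100),
      enroll_start = c(2000, 2009),
      enroll_end = c(2007, 2015)
    ),
    plate_truth = default_plate_truth(sprintf("P%02d", 1:20), n_toxic = 5),
    seed = seed
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}
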