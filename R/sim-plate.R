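#' Hill survival function
#'
#' Fraction of control-level cell survival at dose `d` for a compound with
#' parameters `top`, `bottom`, `ec50` (same unit as `d`) and `hill` slope.
#'
#' @param d Dose (micromolar), non-negative.
#' @param top,bottom Survival plateaus (relative to control).
#' @param ec50 Dose of half-maximal effect; must be positive.
#' @param hill Slope.
#' @return Survival fraction(s).
#' @export
hill_survival <- function(d, top, bottom, ec50, hill) {
  if (any(d < 0)) abort("dose must be non-negative.")
  if (any(ec50 <= 0)) abort("EC50 must be positive.")
  bottom + (top - bottom) / (1 + (d / ec50)^hill)
}

#' Simulate a high-content screening plate at the object level
#'
#' Produces a well-metadata table and an object-level detection table
#' emulating the output of a commercial nuclei detector on a
#' reporter-purified dopaminergic-neuron survival assay. Detected objects
#' are a two-population mixture: a dominant dim population (debris, dead
#' cells, out-of-focus material, ~95% of filter-passing detections in
#' control wells) and a bright reporter-positive population whose expected
#' count follows the compound's Hill survival at the well's dose times a
#' log-normal well effect. A further 25% of rows deliberately fail the
#' size/roundness/brightness filters so the filtering step is exercised.
#'
#' @param config A [sim_config()] (uses `plate_truth`, `doses`, `seed`).
#' @param doses Doses to plate (micromolar); defaults to `config$doses`.
#' @param n_replicates Treated wells per compound and dose.
#' @param n_dmso,n_positive Numbers of DMSO and positive-control
#'   (rotenone-like) wells.
#' @param base_cells Expected bright (reporter-positive) cells per control
#'   well.
#' @param dim_per_bright Expected dim detections per expected control
#'   bright cell.
#' @param well_cv Log-normal coefficient of variation of the well effect.
#' @param timepoint Assay timepoint label stamped on the wells.
#' @param seed Seed; defaults to `config$seed + 44`.
#' @return List with `wells` and `objects` tibbles.
#' @export
sim_plate <- function(config, doses = config$doses, n_replicates = 3,
                      n_dmso = 24, n_positive = 8, base_cells = 80,
                      dim_per_bright = 19, well_cv = 0.10,
                      timepoint = "day11", seed = config$seed + 44L) {
  validate_sim_config(config)
  set.seed(seed)
  pt <- config$plate_truth
  treated <- tidyr::crossing(
    compound = pt$compound, dose = doses,
    replicate = seq_len(n_replicates)
  ) %>% mutate(role = "treated")
  controls <- bind_rows(
    tibble(compound = "DMSO", dose = 0, replicate = seq_len(n_dmso),
           role = "DMSO"),
    tibble(compound = "rotenone", dose = 10, replicate = seq_len(n_positive),
           role = "positive")
  )
  wells <- bind_rows(controls, treated) %>%
    mutate(
      well_id = sprintf("W%04d", dplyr::row_number()),
      plate = "plate1",
      timepoint = timepoint
    )
  surv <- rep(1, nrow(wells))
  surv[wells$role == "positive"] <- 0.08
  tr <- which(wells$role == "treated")
  mi <- match(wells$compound[tr], pt$compound)
  surv[tr] <- hill_survival(wells$dose[tr], pt$top[mi], pt$bottom[mi],
                            pt$ec50[mi], pt$hill[mi])
  well_factor <- rlnorm(nrow(wells), -well_cv^2 / 2, well_cv)
  n_bright <- rpois(nrow(wells), base_cells * surv * well_factor)
  n_dim <- rpois(nrow(wells), base_cells * dim_per_bright *
                   rlnorm(nrow(wells), 0, 0.05))
  objects <- purrr::map_dfr(seq_len(nrow(wells)), function(i) {
    nb <- n_bright[i]; nd <- n_dim[i]
    nj <- rpois(1, 0.25 * (nb + nd)) # filter-failing junk detections
    k <- nb + nd + nj
    if (k == 0) return(tibble())
    kind <- rep(c("bright", "dim", "junk"), c(nb, nd, nj))
    area <- c(runif(nb, 60, 350), runif(nd, 45, 380),
              ifelse(runif(nj) < 0.5, runif(nj, 5, 40),
                     runif(nj, 400, 900)))
    roundness <- c(runif(nb, 0.75, 1), runif(nd, 0.72, 1),
                   runif(nj, 0.2, 1))
    intensity <- c(rnorm(nb, 4500, 500),
                   550 + 150 * abs(rnorm(nd)),
                   runif(nj, 100, 5000))
    tibble(
      well_id = wells$well_id[i],
      field = sample.int(4L, k, replace = TRUE),
      area = area, roundness = roundness, intensity = intensity
    )
  })
  list(wells = wells, objects = objects)
}

#' Simulate well counts for a full combinatorial co-exposure plate
#'
#' All `2^k` subsets of `compounds` (including the empty DMSO condition) at
#' a single dose, `n_replicates` biological replicates each. Expected
#' survival of a subset is the product of its members' single-compound Hill
#' survivals (Bliss/multiplicative independence) times any configured
#' pairwise interaction multipliers; counts are Poisson around
#' `base_cells * survival` with a log-normal replicate effect.
#'
#' @param config A [sim_config()].
#' @param compounds Compound ids (default: first six of `plate_truth`).
#' @param dose Dose applied to every member of a combination (micromolar).
#' @param n_replicates Biological replicates per condition.
#' @param base_cells Expected control-well cell count.
#' @param well_cv Log-normal replicate CV.
#' @param null_model If TRUE every compound is inert and all interaction
#'   multipliers are 1 (the no-effect null used for calibration).
#' @param seed Seed; defaults to `config$seed + 55`.
#' @return Tibble: `condition` (canonical "+"-joined sorted compound ids,
#'   `"DMSO"` for the empty set), `well_id`, `replicate`, `count`.
#' @export
sim_combo_counts <- function(config,
                             compounds = utils::head(
                               config$plate_truth$compound, 6
                             ),
                             dose = 10, n_replicates = 4, base_cells = 400,
                             well_cv = 0.10, null_model = FALSE,
                             seed = config$seed + 55L) {
  validate_sim_config(config)
  set.seed(seed)
  pt <- config$plate_truth
  k <- length(compounds)
  s1 <- if (null_model) {
    setNames(rep(1, k), compounds)
  } else {
    setNames(hill_survival(
      dose,
      pt$top[match(compounds, pt$compound)],
      pt$bottom[match(compounds, pt$compound)],
      pt$ec50[match(compounds, pt$compound)],
      pt$hill[match(compounds, pt$compound)]
    ), compounds)
  }
  inter <- if (null_model) c() else config$combo_interactions
  subsets <- purrr::map(0:(2^k - 1), function(m) {
    compounds[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
  })
  cond_name <- purrr::map_chr(subsets, function(s) {
    if (length(s) == 0) "DMSO" else paste(sort(s), collapse = "+")
  })
  surv <- purrr::map_dbl(subsets, function(s) {
    v <- prod(s1[s])
    if (length(s) >= 2 && length(inter) > 0) {
      prs <- utils::combn(sort(s), 2, paste, collapse = "+")
      v <- v * prod(inter[prs], na.rm = TRUE)
    }
    v
  })
  grid <- tibble(condition = cond_name, survival = surv) %>%
    tidyr::crossing(replicate = seq_len(n_replicates))
  grid %>%
    mutate(
      count = rpois(dplyr::n(), base_cells * .data$survival *
                      rlnorm(dplyr::n(), -well_cv^2 / 2, well_cv)),
      well_id = sprintf("C%04d", dplyr::row_number())
    ) %>%
    select("condition", "well_id", "replicate", "count")
}

#' Simulate mito-stress respirometry traces
#'
#' Oxygen consumption traces with three measurement cycles per segment and
#' injections (oligomycin, then FCCP, then rotenone/antimycin-A) between
#' segments. Segment levels derive from the configured true parameters so
#' that noiseless traces invert exactly: pre-injection level =
#' `non_mito + basal`, post-oligomycin = `non_mito + basal - atp`,
#' post-FCCP = `non_mito + maximal`, post-rotenone/antimycin =
#' `non_mito`.
#'
#' @param config A [sim_config()] (uses `ocr_truth`).
#' @param conditions Tibble with `condition` and multipliers `basal_mult`,
#'   `atp_mult`, `maximal_mult` (default: DMSO only, all 1).
#' @param n_wells Wells per condition.
#' @param noise_sd Gaussian measurement noise SD; defaults to
#'   `config$ocr_truth$noise_sd` (set 0 for noiseless traces).
#' @param seed Seed; defaults to `config$seed + 66`.
#' @return Tibble: `well_id`, `condition`, `cycle`, `segment`, `ocr`.
#' @export
sim_ocr <- function(config,
                    conditions = tibble(condition = "DMSO", basal_mult = 1,
                                        atp_mult = 1, maximal_mult = 1),
                    n_wells = 6,
                    noise_sd = config$ocr_truth$noise_sd,
                    seed = config$seed + 66L) {
  validate_sim_config(config)
  set.seed(seed)
  tr <- config$ocr_truth
  segs <- c("basal", "oligomycin", "fccp", "rot_aa")
  grid <- conditions %>%
    tidyr::crossing(well = seq_len(n_wells),
                    segment = factor(segs, levels = segs),
                    rep_in_seg = 1:3) %>%
    arrange(.data$condition, .data$well, .data$segment, .data$rep_in_seg)
  level <- with(grid, dplyr::case_when(
    segment == "basal" ~ tr$non_mito + tr$basal * basal_mult,
    segment == "oligomycin" ~ tr$non_mito + tr$basal * basal_mult -
      tr$atp * atp_mult,
    segment == "fccp" ~ tr$non_mito + tr$maximal * maximal_mult,
    TRUE ~ tr$non_mito
  ))
  grid %>%
    group_by(.data$condition, .data$well) %>%
    mutate(cycle = dplyr::row_number()) %>%
    ungroup() %>%
    mutate(
      well_id = sprintf("%s_w%02d", .data$condition, .data$well),
      ocr = level + rnorm(dplyr::n(), 0, noise_sd)
    ) %>%
    select("well_id", "condition", "cycle", "segment", "ocr")
}
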