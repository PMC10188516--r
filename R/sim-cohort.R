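#' Simulate a two-wave case-control cohort with address histories
#'
#' Participants receive residential (and, for a fraction, workplace)
#' address spells in whole calendar years, covariates, a wave and an index
#' year inside the wave's enrollment window. Disease status is drawn from a
#' logistic model whose linear predictor uses the participant's true
#' standardized residential exposures (computed from the generated records
#' with a high-resolution 256-vertex buffer) and the configured covariate
#' effects; case/control quotas per wave are then filled by rejection
#' sampling from a candidate pool.
#'
#' @param parcels Output of [sim_landscape()].
#' @param applications Output of [sim_applications()].
#' @param config A [sim_config()].
#' @param pool_mult Candidate pool size as a multiple of the total quota.
#' @param truth_vertices Disc resolution used for the ground-truth exposure
#'   computation.
#' @return List with `participants`, `addresses` and `truth` (a
#'   `sim_truth` list holding the pre-noise exposure matrix and the
#'   generative parameters).
#' @export
sim_cohort <- function(parcels, applications, config, pool_mult = 2.4,
                       truth_vertices = 256L) {
  validate_sim_config(config)
  set.seed(config$seed + 33L)
  quotas <- config$waves
  n_quota <- sum(quotas$n_cases + quotas$n_controls)
  n_pool <- ceiling(pool_mult * n_quota)
  wave_of <- rep(quotas$wave,
                 ceiling(n_pool * (quotas$n_cases + quotas$n_controls) /
                           n_quota))[seq_len(n_pool)]
  pool <- tibble(
    participant_id = sprintf("sub%05d", seq_len(n_pool)),
    wave = wave_of,
    age = round(rnorm(n_pool, 65, 9)),
    male = rbinom(n_pool, 1, 0.55) == 1,
    smoker = rbinom(n_pool, 1, 0.4) == 1
  ) %>%
    inner_join(quotas, by = "wave") %>%
    mutate(index_year = .data$enroll_start +
             floor(runif(n_pool) *
                     (.data$enroll_end - .data$enroll_start + 1))) %>%
    select("participant_id", "wave", "age", "male", "smoker", "index_year")

  addresses <- sim_addresses(pool, config)
  truth_expo <- true_exposure(applications, addresses, parcels, pool, config,
                              truth_vertices)

  beta <- config$causal_effects
  zw <- truth_expo %>%
    filter(.data$location_type == "residential",
           .data$pesticide_id %in% names(beta)) %>%
    mutate(z0 = tidyr::replace_na(.data$z, 0),
           effect = beta[.data$pesticide_id] * .data$z0) %>%
    group_by(.data$participant_id) %>%
    summarise(lp_expo = sum(.data$effect), .groups = "drop")
  ce <- config$covariate_effects
  pool <- pool %>%
    left_join(zw, by = "participant_id") %>%
    mutate(
      lp = tidyr::replace_na(.data$lp_expo, 0) +
        ce[["age"]] * (.data$age - 65) + ce[["male"]] * .data$male +
        ce[["smoker"]] * .data$smoker,
      case = rbinom(dplyr::n(), 1, plogis(.data$lp)) == 1
    )

  take <- function(df, k) {
    if (nrow(df) < k) {
      abort("candidate pool exhausted before quotas met; raise pool_mult.")
    }
    df %>% slice_head(n = k)
  }
  selected <- purrr::map_dfr(seq_len(nrow(quotas)), function(i) {
    w <- quotas$wave[i]
    bind_rows(
      take(pool %>% filter(.data$wave == w, .data$case), quotas$n_cases[i]),
      take(pool %>% filter(.data$wave == w, !.data$case),
           quotas$n_controls[i])
    )
  })
  participants <- selected %>%
    select("participant_id", "wave", "case", "index_year", "age", "male",
           "smoker") %>%
    arrange(.data$participant_id)
  keep <- participants$participant_id
  truth <- structure(list(
    causal_effects = beta,
    covariate_effects = ce,
    exposure = truth_expo %>% filter(.data$participant_id %in% keep),
    toxic_compounds =
      config$plate_truth$compound[config$plate_truth$toxic],
    combo_interactions = config$combo_interactions,
    ocr = config$ocr_truth,
    seed = config$seed
  ), class = "sim_truth")
  list(
    participants = participants,
    addresses = addresses %>% filter(.data$participant_id %in% keep),
    truth = truth
  )
}

# Address spells in whole years. Residential history: 1-3 spells reaching
# back to early adulthood (a 15% minority only provides history from the
# mid-window on, exercising partial coverage). Workplace history (for a
# p_workplace fraction): 1-2 spells over working ages, shorter than the
# residential record, located within commuting range of home.
sim_addresses <- function(pool, config) {
  n <- nrow(pool)
  w <- config$region[1]; h <- config$region[2]
  res <- purrr::map_dfr(seq_len(n), function(i) {
    hist_start <- if (runif(1) < 0.15) {
      sample(1980:1990, 1)
    } else {
      pool$index_year[i] - pool$age[i] + sample(18:25, 1)
    }
    hist_start <- min(hist_start, pool$index_year[i] - 12L)
    n_sp <- sample(1:3, 1, prob = c(0.5, 0.35, 0.15))
    cuts <- sort(sample(seq(hist_start + 1L, pool$index_year[i] - 1L),
                        n_sp - 1L))
    starts <- c(hist_start, cuts)
    ends <- c(cuts - 1L, pool$index_year[i])
    x <- runif(1, 0, w); y <- runif(1, 0, h)
    tibble(
      participant_id = pool$participant_id[i],
      location_type = "residential",
      spell = seq_len(n_sp),
      x = pmin(pmax(x + c(0, cumsum(rnorm(n_sp - 1L, 0, 1500))), 0), w),
      y = pmin(pmax(y + c(0, cumsum(rnorm(n_sp - 1L, 0, 1500))), 0), h),
      start_year = starts,
      end_year = ends
    )
  })
  has_wp <- runif(n) < config$p_workplace
  wp <- purrr::map_dfr(which(has_wp), function(i) {
    home <- res %>%
      filter(.data$participant_id == pool$participant_id[i]) %>%
      slice_head(n = 1)
    start <- pool$index_year[i] - pool$age[i] + sample(20:30, 1)
    end <- min(pool$index_year[i], start + sample(15:35, 1))
    if (end < start) return(tibble())
    tibble(
      participant_id = pool$participant_id[i],
      location_type = "workplace",
      spell = 1L,
      x = pmin(pmax(home$x + rnorm(1, 0, 3000), 0), w),
      y = pmin(pmax(home$y + rnorm(1, 0, 3000), 0), h),
      start_year = start,
      end_year = end
    )
  })
  bind_rows(res, wp) %>%
    mutate(address_id = sprintf("addr%06d", dplyr::row_number())) %>%
    select("participant_id", "location_type", "address_id", "x", "y",
           "start_year", "end_year")
}

# Ground-truth exposure: the windowed, transformed exposure matrix computed
# at high disc resolution, recorded pre-noise alongside the cohort.
true_exposure <- function(applications, addresses, parcels, pool, config,
                          n_vertices) {
  build_exposure_matrix(
    applications, addresses, parcels, pool,
    radius = config$buffer_radius, n_vertices = n_vertices,
    on_degenerate = "drop"
  )
}

#' Direct cohort-level PWAS simulator
#'
#' Generates participant exposures and case-control outcomes at the summary
#' level (no landscape or geometry), for statistical calibration studies
#' where hundreds of replicate cohorts are needed: false-discovery control
#' under the null, confidence-interval coverage, and co-exposure cluster
#' recovery. Exposure occurrence and magnitude share a cluster-level latent
#' factor with loading `rho`, producing right-skewed, zero-inflated,
#' cluster-correlated lbs/acre summaries; `z` is the log1p-standardized
#' value within wave. Outcomes follow a logistic model in `z` with the
#' given true log-ORs; quotas are filled from a candidate pool.
#'
#' @param n_cases,n_controls Per-wave quotas (recycled over `waves`).
#' @param waves Character vector of wave labels.
#' @param pesticide_ids Character vector of pesticide ids.
#' @param clusters List of character vectors (subsets of `pesticide_ids`).
#' @param rho Within-cluster correlation of the latent application factor.
#' @param effects Named numeric true log-OR per SD of transformed exposure.
#' @param prevalence Exposure prevalence per pesticide (recycled).
#' @param seed Seed.
#' @return List with `participants`, `exposure` (long tibble with `raw`,
#'   `exposed`, `z`, `location_type = "residential"`) and `truth`.
#' @export
sim_pwas_data <- function(n_cases = 500, n_controls = 500,
                          waves = c("wave1", "wave2"),
                          pesticide_ids = sprintf("P%02d", 1:20),
                          clusters = list(),
                          rho = 0.8,
                          effects = c(),
                          prevalence = 0.35,
                          seed = 1L) {
  set.seed(seed)
  p <- length(pesticide_ids)
  prev <- rep_len(prevalence, p)
  cluster_of <- rep(NA_integer_, p)
  for (ci in seq_along(clusters)) {
    cluster_of[match(clusters[[ci]], pesticide_ids)] <- ci
  }
  n_cases <- rep_len(n_cases, length(waves))
  n_controls <- rep_len(n_controls, length(waves))
  out_p <- list(); out_e <- list()
  for (wi in seq_along(waves)) {
    quota_case <- n_cases[wi]; quota_ctrl <- n_controls[wi]
    n <- ceiling(2.6 * (quota_case + quota_ctrl))
    f_occ <- matrix(rnorm(n * length(clusters)), n)
    f_mag <- matrix(rnorm(n * length(clusters)), n)
    raw <- matrix(0, n, p)
    for (j in seq_len(p)) {
      ci <- cluster_of[j]
      if (is.na(ci)) {
        g <- rnorm(n); m <- rnorm(n)
      } else {
        g <- sqrt(rho) * f_occ[, ci] + sqrt(1 - rho) * rnorm(n)
        m <- sqrt(rho) * f_mag[, ci] + sqrt(1 - rho) * rnorm(n)
      }
      exposed <- g > qnorm(1 - prev[j])
      raw[, j] <- ifelse(exposed, exp(log(2) + 1.0 * m), 0)
    }
    z <- scale(log1p(raw))
    # a pesticide nobody (or everybody equally) touches has no scale
    z[, attr(z, "scaled:scale") == 0 | is.na(attr(z, "scaled:scale"))] <- NA
    beta <- setNames(rep(0, p), pesticide_ids)
    beta[names(effects)] <- effects
    lp <- as.vector(ifelse(is.na(z), 0, z) %*% beta)
    case <- rbinom(n, 1, plogis(lp)) == 1
    idx_case <- which(case)[seq_len(quota_case)]
    idx_ctrl <- which(!case)[seq_len(quota_ctrl)]
    if (anyNA(c(idx_case, idx_ctrl))) {
      abort("candidate pool exhausted; effects too extreme for quotas.")
    }
    keep <- sort(c(idx_case, idx_ctrl))
    pid <- sprintf("%s_sub%05d", waves[wi], keep)
    out_p[[wi]] <- tibble(
      participant_id = pid, wave = waves[wi],
      case = case[keep],
      index_year = 2005L, age = 65, male = FALSE, smoker = FALSE
    )
    rk <- raw[keep, , drop = FALSE]
    out_e[[wi]] <- tibble(
      participant_id = rep(pid, p),
      location_type = "residential",
      pesticide_id = rep(pesticide_ids, each = length(keep)),
      raw = as.vector(rk),
      exposed = as.vector(rk > 0),
      n_covered_years = 22L
    )
  }
  participants <- bind_rows(out_p)
  exposure <- transform_exposure(bind_rows(out_e), participants,
                                 on_degenerate = "drop")
  list(
    participants = participants,
    exposure = exposure,
    truth = structure(list(
      causal_effects = effects, clusters = clusters, rho = rho, seed = seed
    ), class = "sim_truth")
  )
}

#' Persist ground truth alongside simulated data
#'
#' @param truth A `sim_truth` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  obj <- truth
  class(obj) <- NULL
  # keep names of scalar maps in the JSON output
  obj <- lapply(obj, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  if (is.data.frame(obj$exposure)) {
    obj$exposure_rows <- nrow(obj$exposure)
    obj$exposure <- NULL # full matrix is written as CSV by the pipeline
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
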