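#' Unconditional logistic regression for one pesticide-stratum
#'
#' Maximum-likelihood logistic fit of case status on a standardized
#' exposure, optionally adjusted for covariates (the default is univariate,
#' matching the primary screen; sensitivity analyses pass e.g. an
#' occupational-pesticide-use indicator). The reported standard error comes
#' from the observed information. Separation or non-convergence is flagged
#' so callers can exclude the stratum from pooling with a logged reason.
#'
#' @param data Data frame holding the variables.
#' @param outcome Name of the binary outcome column.
#' @param exposure Name of the (standardized) exposure column.
#' @param covariates Character vector of adjustment covariates (default
#'   none).
#' @return One-row tibble: `beta`, `se`, `n`, `converged`, `flagged`,
#'   `reason`.
#' @export
fit_logistic <- function(data, outcome = "case", exposure = "z",
                         covariates = NULL) {
  df <- data[stats::complete.cases(data[c(outcome, exposure, covariates)]), ]
  y <- df[[outcome]]
  if (length(unique(y)) < 2) {
    return(tibble(beta = NA_real_, se = NA_real_, n = nrow(df),
                  converged = FALSE, flagged = TRUE,
                  reason = "needs at least one case and one control"))
  }
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  beta <- unname(coef(fit)[exposure])
  se <- sqrt(diag(vcov(fit)))[exposure]
  flagged <- !fit$converged || !is.finite(beta) || !is.finite(se) ||
    abs(beta) > 10 || se > 10
  tibble(
    beta = beta, se = unname(se), n = nrow(df),
    converged = fit$converged, flagged = flagged,
    reason = if (flagged) "separation or non-convergence" else NA_character_
  )
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-stratum log-OR estimates with weights `w_i = 1 / SE_i^2`:
#' pooled beta is the weighted mean, pooled SE is `(sum w_i)^(-1/2)`, and
#' the two-sided p-value comes from the z statistic `beta / SE`.
#'
#' @param fits Data frame with columns `beta` and `se` (and optionally
#'   `flagged`, which excludes rows).
#' @return One-row tibble: `k` (strata pooled), `beta`, `se`, `z`, `p`,
#'   `or`, `ci_low`, `ci_high` (normal-theory 95% CI, exponentiated).
#' @export
meta_fixed <- function(fits) {
  use <- fits
  if ("flagged" %in% names(use)) use <- use[!is.na(use$flagged) &
                                              !use$flagged, ]
  use <- use[is.finite(use$beta) & is.finite(use$se) & use$se > 0, ]
  if (nrow(use) == 0) {
    return(tibble(k = 0L, beta = NA_real_, se = NA_real_, z = NA_real_,
                  p = NA_real_, or = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_))
  }
  w <- 1 / use$se^2
  beta <- sum(w * use$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  tibble(
    k = nrow(use), beta = beta, se = se, z = z,
    p = 2 * pnorm(-abs(z)),
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se)
  )
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH adjustment; a thin, validating wrapper around
#' [stats::p.adjust()] so every module corrects for multiplicity the same
#' way.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Pesticide-wide association study
#'
#' For every pesticide passing the exposed-count inclusion mask, fits an
#' unconditional logistic regression of case status on the standardized
#' exposure within each stratum (study wave x location type), pools the
#' per-stratum log-ORs by fixed-effects inverse-variance meta-analysis,
#' converts the pooled z statistic to a two-sided p-value, adjusts across
#' pesticides by Benjamini-Hochberg FDR, and assigns reporting tiers at the
#' configured FDR cut-offs. A stratum is used only if the pesticide has at
#' least one exposed case and one exposed control there and the exposure
#' has positive variance.
#'
#' @param exposure Long exposure tibble from [build_exposure_matrix()] or
#'   [sim_pwas_data()] (`participant_id`, `location_type`, `pesticide_id`,
#'   `raw`, `z`).
#' @param participants Participant table (`participant_id`, `wave`,
#'   `case`, covariate columns).
#' @param min_exposed Inclusion threshold on the exposed-participant count.
#' @param fdr_tiers Three increasing FDR cut-offs; the defaults label
#'   `FDR <= 0.01`, `0.01 < FDR <= 0.05` and `0.05 < FDR < 0.10`, with the
#'   implicated set defined by `FDR < 0.10` and the associated set (used by
#'   overrepresentation analysis) by `FDR <= 0.05`.
#' @param covariates Optional adjustment covariates for sensitivity runs.
#' @return A `pwas_result`: list with `results` (one row per included
#'   pesticide), `strata` (per-stratum fits), and `settings`.
#' @export
run_pwas <- function(exposure, participants, min_exposed = 25,
                     fdr_tiers = c(0.01, 0.05, 0.10), covariates = NULL) {
  stopifnot(length(fdr_tiers) == 3, !is.unsorted(fdr_tiers))
  mask <- exposed_counts(exposure, threshold = min_exposed)
  included <- mask$pesticide_id[mask$include]
  dat <- exposure %>%
    filter(.data$pesticide_id %in% included, !is.na(.data$z)) %>%
    select(-dplyr::any_of(c("wave", "case"))) %>%
    inner_join(participants, by = "participant_id")
  strata <- dat %>%
    group_by(.data$pesticide_id, .data$wave, .data$location_type) %>%
    filter(
      sum(.data$raw > 0 & .data$case) >= 1,
      sum(.data$raw > 0 & !.data$case) >= 1,
      sd(.data$z) > 0
    ) %>%
    group_modify(~ fit_logistic(.x, covariates = covariates)) %>%
    ungroup()
  meta <- strata %>%
    group_by(.data$pesticide_id) %>%
    group_modify(~ meta_fixed(.x)) %>%
    ungroup() %>%
    filter(.data$k > 0)
  meta$q <- bh_fdr(meta$p)
  t1 <- fdr_tiers[1]; t2 <- fdr_tiers[2]; t3 <- fdr_tiers[3]
  results <- meta %>%
    mutate(
      tier = dplyr::case_when(
        .data$q <= t1 ~ sprintf("FDR<=%.2g", t1),
        .data$q <= t2 ~ sprintf("%.2g<FDR<=%.2g", t1, t2),
        .data$q < t3 ~ sprintf("%.2g<FDR<%.2g", t2, t3),
        TRUE ~ "not implicated"
      ),
      implicated = .data$q < t3,
      associated = .data$q <= t2
    ) %>%
    left_join(mask, by = "pesticide_id") %>%
    arrange(.data$q, .data$p)
  structure(list(
    results = results,
    strata = strata,
    settings = list(min_exposed = min_exposed, fdr_tiers = fdr_tiers,
                    covariates = covariates,
                    n_tested = length(included))
  ), class = "pwas_result")
}

#' @export
print.pwas_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "<pwas_result> %d pesticides tested (>=%d exposed); %d implicated (FDR<%.2g), %d associated (FDR<=%.2g)\n",
    s$n_tested, s$min_exposed, sum(x$results$implicated),
    s$fdr_tiers[3], sum(x$results$associated), s$fdr_tiers[2]
  ))
  print(x$results, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_pwas
#' @param x A `pwas_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pwas_result <- function(x, ...) x$results

#' @rdname run_pwas
#' @exportS3Method generics::glance
glance.pwas_result <- function(x, ...) {
  t <- x$settings$fdr_tiers
  tibble(
    n_tested = x$settings$n_tested,
    n_tier1 = sum(x$results$q <= t[1]),
    n_tier2 = sum(x$results$q > t[1] & x$results$q <= t[2]),
    n_tier3 = sum(x$results$q > t[2] & x$results$q < t[3]),
    n_implicated = sum(x$results$implicated),
    n_associated = sum(x$results$associated)
  )
}

#' Gender-interaction sensitivity test
#'
#' Adds an exposure x gender product term to each stratum model and pools
#' the interaction coefficient across strata by fixed-effects
#' inverse-variance meta-analysis, giving one Wald interaction p-value per
#' pesticide. Strata with a single gender, or no exposure variance within a
#' gender, are flagged and excluded from pooling.
#'
#' @inheritParams run_pwas
#' @param pesticide_ids Pesticides to test (default: all in `exposure`).
#' @return Tibble: `pesticide_id`, `k`, `beta_int`, `se_int`, `p_int`,
#'   `n_flagged`.
#' @export
interaction_test <- function(exposure, participants,
                             pesticide_ids = NULL) {
  if (is.null(pesticide_ids)) {
    pesticide_ids <- sort(unique(exposure$pesticide_id))
  }
  dat <- exposure %>%
    filter(.data$pesticide_id %in% pesticide_ids, !is.na(.data$z)) %>%
    select(-dplyr::any_of(c("wave", "case"))) %>%
    inner_join(participants, by = "participant_id")
  fits <- dat %>%
    group_by(.data$pesticide_id, .data$wave, .data$location_type) %>%
    group_modify(function(d, key) {
      degenerate <- length(unique(d$male)) < 2 ||
        any(tapply(d$z, d$male, sd) == 0, na.rm = TRUE) ||
        length(unique(d$case)) < 2
      if (degenerate) {
        return(tibble(beta = NA_real_, se = NA_real_, flagged = TRUE))
      }
      fit <- suppressWarnings(
        glm(case ~ z * male, family = binomial(), data = d)
      )
      cn <- "z:maleTRUE"
      if (!cn %in% names(coef(fit))) cn <- grep("^z:", names(coef(fit)),
                                                value = TRUE)[1]
      b <- unname(coef(fit)[cn]); s <- sqrt(diag(vcov(fit)))[cn]
      tibble(beta = b, se = unname(s),
             flagged = !fit$converged || !is.finite(b) || !is.finite(s) ||
               abs(b) > 10 || s > 10)
    }) %>%
    ungroup()
  fits %>%
    group_by(.data$pesticide_id) %>%
    group_modify(function(d, key) {
      m <- meta_fixed(d)
      tibble(k = m$k, beta_int = m$beta, se_int = m$se, p_int = m$p,
             n_flagged = sum(d$flagged))
    }) %>%
    ungroup()
}
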