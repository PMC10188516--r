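#' Filter detected objects to candidate cell bodies
#'
#' Keeps detections with area strictly between 40 and 400 square
#' micrometers, roundness above 0.7 and mean intensity above 500 — the
#' size/shape/brightness gates that remove debris, doublets and dead cells
#' from the nuclei-detector output before counting.
#'
#' @param objects Object-level detection table with numeric columns `area`,
#'   `roundness`, `intensity`.
#' @return The filtered table.
#' @export
filter_objects <- function(objects) {
  need <- c("area", "roundness", "intensity")
  missing <- setdiff(need, names(objects))
  if (length(missing) > 0) {
    abort(sprintf("object table lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  objects %>%
    filter(.data$area > 40, .data$area < 400, .data$roundness > 0.7,
           .data$intensity > 500)
}

#' Control-referenced intensity cutoff
#'
#' Second step of the two-step image analysis: the cutoff is the mean plus
#' `sd_mult` standard deviations of the candidate-object intensities in the
#' control wells; objects strictly brighter than the cutoff count as
#' reporter-positive cells.
#'
#' @param objects Object table (filtered or raw; raw tables are filtered
#'   first).
#' @param wells Well metadata with `well_id` and `role`.
#' @param control_role Role label of the control wells.
#' @param sd_mult Multiplier on the control SD.
#' @return The intensity cutoff (single number).
#' @export
control_threshold <- function(objects, wells, control_role = "DMSO",
                              sd_mult = 3) {
  ctrl_wells <- wells$well_id[wells$role == control_role]
  if (length(ctrl_wells) == 0) abort("no control wells found.")
  cand <- filter_objects(objects) %>%
    filter(.data$well_id %in% ctrl_wells)
  if (nrow(cand) < 2) abort("need at least 2 control candidate objects.")
  mean(cand$intensity) + sd_mult * sd(cand$intensity)
}

#' Count reporter-positive cells per well
#'
#' Applies the object filters and the control-referenced intensity cutoff,
#' then counts qualifying objects per well, summed over imaging fields.
#' Wells without qualifying objects get a zero count.
#'
#' @param objects Object-level detection table with `well_id`.
#' @param wells Well metadata.
#' @param cutoff Intensity cutoff; computed by [control_threshold()] when
#'   NULL.
#' @inheritParams control_threshold
#' @return `wells` with a `count` column appended.
#' @export
count_positives <- function(objects, wells, cutoff = NULL,
                            control_role = "DMSO", sd_mult = 3) {
  if (is.null(cutoff)) {
    cutoff <- control_threshold(objects, wells, control_role, sd_mult)
  }
  counts <- filter_objects(objects) %>%
    filter(.data$intensity > cutoff) %>%
    count(.data$well_id, name = "count")
  wells %>%
    left_join(counts, by = "well_id") %>%
    mutate(count = as.integer(tidyr::replace_na(.data$count, 0L)))
}

#' Toxicity calls at the screening dose
#'
#' A condition is called toxic when its mean reporter-positive cell count
#' falls strictly below the control mean minus `sd_mult` control standard
#' deviations (computed over control well-level counts at the matching
#' timepoint, per plate by default).
#'
#' @param well_counts Output of [count_positives()] (columns `compound`,
#'   `dose`, `role`, `timepoint`, `count`, optionally `plate`).
#' @param dose Screening dose at which calls are made.
#' @param timepoint Assay timepoint of the call.
#' @param sd_mult SD multiplier below the control mean.
#' @param control_role Negative-control role label.
#' @param by_plate Compute the control mean/SD per plate (default) or
#'   pooled.
#' @return Tibble: `compound` (plus `plate` when per-plate), `n_wells`,
#'   `mean_count`, `threshold`, `toxic`.
#' @export
toxicity_call <- function(well_counts, dose = 30, timepoint = "day11",
                          sd_mult = 3, control_role = "DMSO",
                          by_plate = TRUE) {
  wc <- well_counts %>% filter(.data$timepoint == .env$timepoint)
  grp <- if (by_plate && "plate" %in% names(wc)) "plate" else character(0)
  ctrl <- wc %>%
    filter(.data$role == control_role) %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(ctrl_mean = mean(.data$count), ctrl_sd = sd(.data$count),
              n_ctrl = dplyr::n(), .groups = "drop")
  if (nrow(ctrl) == 0 || any(ctrl$n_ctrl < 2)) {
    abort("need at least 2 control wells at the call timepoint.")
  }
  treated <- wc %>%
    filter(.data$role == "treated", .data$dose == .env$dose) %>%
    group_by(dplyr::across(dplyr::all_of(c(grp, "compound")))) %>%
    summarise(n_wells = dplyr::n(), mean_count = mean(.data$count),
              .groups = "drop")
  joined <- if (length(grp) > 0) {
    treated %>% inner_join(ctrl, by = grp)
  } else {
    treated %>% tidyr::crossing(ctrl)
  }
  joined %>%
    mutate(
      threshold = .data$ctrl_mean - sd_mult * .data$ctrl_sd,
      toxic = .data$mean_count < .data$threshold
    ) %>%
    select(dplyr::all_of(grp), "compound", "n_wells", "mean_count",
           "threshold", "toxic")
}

#' Z-prime assay quality statistic
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, computed over
#' well-level counts of the negative and positive control arms. Values
#' approach 1 for perfectly separated controls; equal means make the
#' statistic undefined.
#'
#' @param negative,positive Numeric vectors of well counts (>= 2 each).
#' @return Z-prime (single number, always <= 1).
#' @export
zprime <- function(negative, positive) {
  if (length(negative) < 2 || length(positive) < 2) {
    abort("need at least 2 wells per control arm.")
  }
  mu_n <- mean(negative); mu_p <- mean(positive)
  if (mu_n == mu_p) abort("Z-prime undefined: control means are equal.")
  1 - 3 * (sd(positive) + sd(negative)) / abs(mu_p - mu_n)
}

#' Per-dose summaries and interpolated LD50
#'
#' Mean counts per compound and dose, percent decrease relative to the
#' control mean, a monotonicity flag, and an LD50 interpolated log-linearly
#' between the doses bracketing 50% of the control mean (NA when the
#' response never crosses it).
#'
#' @param well_counts Output of [count_positives()].
#' @param timepoint Assay timepoint.
#' @param control_role Negative-control role label.
#' @return List with `doses` (compound, dose, n, mean_count, pct_decrease)
#'   and `compounds` (compound, monotone, ld50).
#' @export
dose_summary <- function(well_counts, timepoint = "day11",
                         control_role = "DMSO") {
  wc <- well_counts %>% filter(.data$timepoint == .env$timepoint)
  mu_ctrl <- mean(wc$count[wc$role == control_role])
  if (!is.finite(mu_ctrl) || mu_ctrl <= 0) {
    abort("control mean count must be positive.")
  }
  per_dose <- wc %>%
    filter(.data$role == "treated") %>%
    group_by(.data$compound, .data$dose) %>%
    summarise(n = dplyr::n(), mean_count = mean(.data$count),
              .groups = "drop") %>%
    mutate(pct_decrease = 100 * (mu_ctrl - .data$mean_count) / mu_ctrl) %>%
    arrange(.data$compound, .data$dose)
  if (any(table(per_dose$compound) < 2)) {
    abort("need at least 2 doses per compound.")
  }
  per_compound <- per_dose %>%
    group_by(.data$compound) %>%
    group_modify(function(d, key) {
      half <- mu_ctrl / 2
      m <- d$mean_count; dd <- d$dose
      ld50 <- NA_real_
      for (i in seq_len(nrow(d) - 1)) {
        lo <- m[i] >= half && m[i + 1] < half
        if (lo) {
          t <- (m[i] - half) / (m[i] - m[i + 1])
          ld50 <- exp(log(dd[i]) + t * (log(dd[i + 1]) - log(dd[i])))
          break
        }
      }
      if (is.na(ld50) && m[1] < half && dd[1] > 0) ld50 <- dd[1]
      tibble(monotone = !is.unsorted(rev(m)), ld50 = ld50)
    }) %>%
    ungroup()
  list(doses = per_dose, compounds = per_compound,
       control_mean = mu_ctrl)
}

#' Combinatorial co-exposure analysis
#'
#' Analyzes an all-combinations design: every subset of the compound panel
#' at a fixed dose (the empty subset being the solvent control). Reports
#' per-condition mean counts and percent change versus control, ordered for
#' upset-style display (descending mean count, lexical tie-break);
#' two-sample Student's t-tests comparing each multi-compound condition
#' with each of its constituent singletons and with the control,
#' Benjamini-Hochberg adjusted over all comparisons; a Bliss
#' (multiplicative-independence) expectation for pairs; and an
#' enhanced-toxicity flag for pairs whose counts are significantly lower
#' than both constituent singletons.
#'
#' @param counts Tibble with `condition` (compound ids sorted and joined by
#'   `"+"`, `"DMSO"` for the control), `replicate`, `count` (e.g. from
#'   [sim_combo_counts()]).
#' @param alpha FDR level for the enhanced-toxicity flag.
#' @param var_equal Use the classical equal-variance Student's t-test
#'   (default); FALSE gives Welch.
#' @param control Label of the control condition.
#' @return A `combo_result`: list with `conditions`, `comparisons`,
#'   `pairs`.
#' @export
combo_analysis <- function(counts, alpha = 0.05, var_equal = TRUE,
                           control = "DMSO") {
  conds <- unique(counts$condition)
  compounds <- sort(unique(unlist(strsplit(setdiff(conds, control), "+",
                                           fixed = TRUE))))
  k <- length(compounds)
  expected <- purrr::map_chr(0:(2^k - 1), function(m) {
    s <- compounds[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    if (length(s) == 0) control else paste(sort(s), collapse = "+")
  })
  absent <- setdiff(expected, conds)
  if (length(absent) > 0) {
    abort(c("missing condition(s) in the combination design:",
            utils::head(absent, 10)))
  }
  reps <- counts %>% count(.data$condition)
  if (any(reps$n < 2)) abort("need >= 2 replicates per condition.")
  mu_ctrl <- mean(counts$count[counts$condition == control])
  cond_tab <- counts %>%
    group_by(.data$condition) %>%
    summarise(n = dplyr::n(), mean_count = mean(.data$count),
              .groups = "drop") %>%
    mutate(
      n_compounds = ifelse(.data$condition == control, 0L,
                           lengths(strsplit(.data$condition, "+",
                                            fixed = TRUE))),
      pct_change = 100 * (.data$mean_count - mu_ctrl) / mu_ctrl
    ) %>%
    arrange(dplyr::desc(.data$mean_count), .data$condition)
  by_cond <- split(counts$count, counts$condition)
  multis <- cond_tab$condition[cond_tab$n_compounds >= 2]
  comparisons <- purrr::map_dfr(multis, function(cd) {
    members <- strsplit(cd, "+", fixed = TRUE)[[1]]
    refs <- c(members, control)
    purrr::map_dfr(refs, function(rf) {
      x <- by_cond[[cd]]; y <- by_cond[[rf]]
      p <- if (sd(x) == 0 && sd(y) == 0) {
        # degenerate: constant arms carry no evidence unless means differ
        if (mean(x) == mean(y)) 1 else 0
      } else {
        t.test(x, y, var.equal = var_equal)$p.value
      }
      tibble(condition = cd, reference = rf,
             diff = mean(x) - mean(y), p = p)
    })
  })
  comparisons$q <- bh_fdr(comparisons$p)
  pairs <- cond_tab %>%
    filter(.data$n_compounds == 2) %>%
    select("condition", "mean_count") %>%
    rowwise() %>%
    mutate(members = list(strsplit(.data$condition, "+",
                                   fixed = TRUE)[[1]])) %>%
    ungroup()
  pairs <- pairs %>%
    mutate(
      bliss_expected = purrr::map_dbl(.data$members, function(m) {
        mu_ctrl * prod(vapply(m, function(x) mean(by_cond[[x]]) / mu_ctrl,
                              numeric(1)))
      }),
      bliss_excess = .data$bliss_expected - .data$mean_count,
      enhanced = purrr::map2_lgl(.data$condition, .data$members,
        function(cd, m) {
          cmp <- comparisons %>%
            filter(.data$condition == cd, .data$reference %in% m)
          all(cmp$q < alpha & cmp$diff < 0)
        })
    ) %>%
    select(-"members")
  structure(list(conditions = cond_tab, comparisons = comparisons,
                 pairs = pairs, control = control, alpha = alpha),
            class = "combo_result")
}

#' @export
print.combo_result <- function(x, ...) {
  cat(sprintf(
    "<combo_result> %d conditions, %d comparisons, %d/%d pairs flagged enhanced-toxicity (q < %.2g)\n",
    nrow(x$conditions), nrow(x$comparisons), sum(x$pairs$enhanced),
    nrow(x$pairs), x$alpha
  ))
  print(x$conditions, ...)
  invisible(x)
}

#' @rdname combo_analysis
#' @param x A `combo_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.combo_result <- function(x, ...) x$conditions

#' @rdname combo_analysis
#' @exportS3Method generics::glance
glance.combo_result <- function(x, ...) {
  tibble(
    n_conditions = nrow(x$conditions),
    n_comparisons = nrow(x$comparisons),
    n_pairs = nrow(x$pairs),
    n_enhanced = sum(x$pairs$enhanced)
  )
}

#' Mito-stress parameters from an oxygen-consumption trace
#'
#' Extracts the canonical respirometry parameters from a mito-stress run
#' (three measurement cycles per segment, injections of oligomycin, FCCP
#' and rotenone/antimycin-A between segments), following the standard
#' cycle-selection rules: non-mitochondrial OCR is the minimum after
#' rotenone/antimycin-A, basal respiration the last pre-oligomycin cycle
#' minus non-mitochondrial, ATP-linked respiration the last pre-oligomycin
#' cycle minus the post-oligomycin minimum, maximal respiration the
#' post-FCCP maximum minus non-mitochondrial, spare capacity maximal minus
#' basal, and spare percent `100 * maximal / basal`.
#'
#' @param trace Tibble with `well_id`, `cycle`, `segment` (one of
#'   `"basal"`, `"oligomycin"`, `"fccp"`, `"rot_aa"`) and `ocr`
#'   (protein-normalized).
#' @return Tibble with one row per well: `non_mito`, `basal`, `atp_linked`,
#'   `maximal`, `spare`, `spare_pct`, `flagged` (TRUE when basal <= 0).
#' @export
mito_stress <- function(trace) {
  segs <- c("basal", "oligomycin", "fccp", "rot_aa")
  extra <- c("condition")[c("condition") %in% names(trace)]
  trace %>%
    group_by(dplyr::across(dplyr::all_of(c("well_id", extra)))) %>%
    group_modify(function(d, key) {
      missing <- setdiff(segs, as.character(unique(d$segment)))
      if (length(missing) > 0) {
        abort(sprintf("well %s missing segment(s): %s", key$well_id,
                      paste(missing, collapse = ", ")))
      }
      if (any(table(d$segment)[segs] < 3)) {
        abort(sprintf("well %s has fewer than 3 cycles in a segment.",
                      key$well_id))
      }
      base <- d[d$segment == "basal", ]
      last_basal <- base$ocr[which.max(base$cycle)]
      non_mito <- min(d$ocr[d$segment == "rot_aa"])
      basal <- last_basal - non_mito
      atp <- last_basal - min(d$ocr[d$segment == "oligomycin"])
      maximal <- max(d$ocr[d$segment == "fccp"]) - non_mito
      tibble(
        non_mito = non_mito, basal = basal, atp_linked = atp,
        maximal = maximal, spare = maximal - basal,
        spare_pct = 100 * maximal / basal,
        flagged = basal <= 0
      )
    }) %>%
    ungroup()
}
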