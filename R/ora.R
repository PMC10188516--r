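#' Conditional maximum-likelihood odds ratio of a 2x2 table
#'
#' The odds ratio paired with Fisher's exact framework: the noncentral
#' hypergeometric parameter whose conditional expectation (given all table
#' margins) equals the observed top-left count. Solved by root-finding on
#' the exact enumerated conditional mean to near machine precision; tables
#' whose observed count sits on the support boundary return 0 or Inf.
#'
#' @param a,b,c,d Cell counts: `a` successes in the group, `b` successes
#'   outside it, `c` group failures, `d` remaining failures.
#' @return The conditional MLE of the odds ratio.
#' @examples
#' cmle_or(19, 34, 31, 202)
#' @export
cmle_or <- function(a, b, c, d) {
  m1 <- a + c; m2 <- b + d; k <- a + b
  lo <- max(0L, k - m2); hi <- min(k, m1)
  if (a == lo && a == hi) return(NaN)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  support <- lo:hi
  lw <- lchoose(m1, support) + lchoose(m2, k - support)
  cond_mean <- function(log_psi) {
    lp <- lw + support * log_psi
    lp <- lp - max(lp)
    w <- exp(lp)
    sum(support * w) / sum(w) - a
  }
  root <- stats::uniroot(cond_mean, lower = -80, upper = 80, tol = 1e-12)
  exp(root$root)
}

#' Overrepresentation analysis of pesticide groups
#'
#' For each annotation group (toxicity class, chemical class, use type),
#' forms the 2x2 table of membership in the disease-associated pesticide
#' set versus the tested universe, and reports the Fisher-exact framework's
#' conditional maximum-likelihood odds ratio with its exact 95% confidence
#' interval and two-sided p-value (probability summation convention),
#' Benjamini-Hochberg adjusted across groups. Universe members lacking any
#' annotation are dropped before testing; empty groups are skipped with a
#' message. The conditional MLE, not the sample cross-product ratio, is
#' reported because it is the estimate the exact framework pairs with its
#' interval (the two can differ in the second decimal).
#'
#' @param associated Character vector of associated pesticide ids (must be
#'   a subset of the universe).
#' @param annotations Either a long tibble (`pesticide_id`, `group`) or a
#'   wide tibble with `pesticide_id` plus logical group columns.
#' @param universe Character vector of all tested pesticide ids; defaults
#'   to all annotated pesticides.
#' @return An `ora_result` tibble: `group`, counts `a` (associated in
#'   group), `b` (associated not in group), `c` (group not associated),
#'   `d` (rest), `or` (conditional MLE), `ci_low`, `ci_high`, `p`, `q`,
#'   `pct_of_group_associated`, `pct_of_universe`.
#' @examples
#' ann <- tibble::tibble(
#'   pesticide_id = sprintf("P%02d", 1:20),
#'   group = rep(c("organophosphorus", "other"), each = 10)
#' )
#' run_ora(sprintf("P%02d", 1:6), ann)
#' @export
run_ora <- function(associated, annotations, universe = NULL) {
  if (!"group" %in% names(annotations)) {
    flag_cols <- names(annotations)[vapply(annotations, is.logical,
                                           logical(1))]
    annotations <- annotations %>%
      select("pesticide_id", dplyr::all_of(flag_cols)) %>%
      tidyr::pivot_longer(-"pesticide_id", names_to = "group",
                          values_to = ".in") %>%
      filter(.data$.in) %>%
      select(-".in")
  }
  annotated <- unique(annotations$pesticide_id)
  if (is.null(universe)) universe <- annotated
  dropped <- setdiff(universe, annotated)
  if (length(dropped) > 0) {
    inform(sprintf("dropping %d universe member(s) lacking annotations.",
                   length(dropped)))
    universe <- intersect(universe, annotated)
    associated <- intersect(associated, universe)
  }
  if (!all(associated %in% universe)) {
    abort("`associated` must be a subset of the universe.")
  }
  associated <- unique(associated)
  m <- length(universe)
  groups <- annotations %>%
    filter(.data$pesticide_id %in% universe) %>%
    distinct(.data$group, .data$pesticide_id)
  res <- groups %>%
    group_by(.data$group) %>%
    group_modify(function(d, key) {
      members <- d$pesticide_id
      if (length(members) == 0) return(tibble())
      a <- length(intersect(associated, members))
      b <- length(associated) - a
      cc <- length(members) - a
      dd <- m - a - b - cc
      ft <- fisher.test(matrix(c(a, cc, b, dd), nrow = 2))
      tibble(
        a = a, b = b, c = cc, d = dd,
        or = cmle_or(a, b, cc, dd),
        ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
        p = ft$p.value,
        pct_of_group_associated = 100 * a / (a + cc),
        pct_of_universe = 100 * (a + cc) / m
      )
    }) %>%
    ungroup()
  empty <- setdiff(unique(annotations$group), res$group)
  if (length(empty) > 0) {
    inform(sprintf("skipped empty group(s): %s",
                   paste(empty, collapse = ", ")))
  }
  res$q <- bh_fdr(res$p)
  res <- res %>% arrange(.data$p)
  class(res) <- c("ora_result", class(res))
  res
}
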