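# Independent oracles used across the suite. Each reimplements a quantity
# from first principles (enumeration, brute force, closed form) without
# touching the code path it checks.

# Conditional MLE of the odds ratio for a 2x2 table (a, b, c, d) by direct
# maximization of the exact noncentral-hypergeometric conditional
# log-likelihood over log(psi). Margins: m1 = a + c (group), m2 = b + d,
# k = a + b (associated). Independent of the package's mean-matching root
# finder.
oracle_cmle_or <- function(a, b, c, d) {
  m1 <- a + c; m2 <- b + d; k <- a + b
  lo <- max(0L, k - m2); hi <- min(k, m1)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  support <- lo:hi
  lw <- lchoose(m1, support) + lchoose(m2, k - support)
  loglik <- function(log_psi) {
    lp <- lw + support * log_psi
    mx <- max(lp)
    (lchoose(m1, a) + lchoose(m2, k - a) + a * log_psi) -
      (mx + log(sum(exp(lp - mx))))
  }
  opt <- stats::optimize(loglik, interval = c(-60, 60), maximum = TRUE,
                         tol = 1e-12)
  exp(opt$maximum)
}

# Naive agglomerative clustering with complete linkage on distance matrix d
# (as a matrix), cutting at height h: merge the closest pair while the
# minimum complete-linkage distance is <= h.
oracle_complete_cut <- function(d, h) {
  n <- nrow(d)
  groups <- as.list(seq_len(n))
  repeat {
    k <- length(groups)
    if (k == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        dd <- max(d[groups[[i]], groups[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    if (best_d > h) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (g in seq_along(groups)) memb[groups[[g]]] <- g
  memb
}

# Adjusted Rand index between two labelings (standard contingency formula).
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# A tiny deterministic combination-counts fixture built from printed-style
# percent decreases: singletons at 32% and 8% decrease, the pair at 65%,
# around a control mean of 1000 with tight replicate noise.
combo_fixture <- function() {
  base <- c(-6, -2, 2, 6) # small spread across 4 replicates
  tibble::tibble(
    condition = rep(c("DMSO", "triA", "triB", "triA+triB"), each = 4),
    replicate = rep(1:4, times = 4),
    count = c(1000 + base, 680 + base, 920 + base, 350 + base)
  ) %>%
    dplyr::mutate(well_id = sprintf("F%02d", dplyr::row_number()))
}
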