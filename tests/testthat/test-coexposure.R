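test_that("correlation matrix is symmetric, unit-diagonal and permutation-invariant", {
  sim <- sim_pwas_data(n_cases = 300, n_controls = 300,
                       clusters = list(c("P01", "P02", "P03")),
                       rho = 0.9, seed = 51)
  r <- exposure_corr(sim$exposure)
  expect_equal(r, t(r), tolerance = 1e-12)
  expect_equal(unname(diag(r)), rep(1, nrow(r)))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  # permuting participant order leaves R unchanged
  perm <- sim$exposure %>% dplyr::arrange(dplyr::desc(.data$participant_id))
  expect_equal(exposure_corr(perm), r, tolerance = 1e-12)
  # co-applied pesticides correlate far above independent ones
  expect_gt(r["P01", "P02"], 0.5)
  expect_lt(abs(r["P10", "P15"]), 0.2)
})

test_that("perfect noiseless co-application yields near-unit correlation", {
  cfg <- demo_config(seed = 52)
  parcels <- sim_landscape(cfg)
  apps <- sim_applications(parcels, cfg)
  # duplicate one pesticide's records verbatim under a new id: identical
  # parcel-year sets AND identical amounts
  twin <- apps %>% dplyr::filter(.data$pesticide_id == "P11") %>%
    dplyr::mutate(pesticide_id = "P11twin")
  cohort <- sim_cohort(parcels, apps, cfg)
  expo <- build_exposure_matrix(
    dplyr::bind_rows(apps, twin), cohort$addresses, parcels,
    cohort$participants, on_degenerate = "drop"
  )
  r <- exposure_corr(expo, pesticide_ids = c("P11", "P11twin"),
                     value = "raw")
  expect_gte(r["P11", "P11twin"], 0.99)
})

test_that("zero-variance pesticides get missing rows with a message", {
  sim <- sim_pwas_data(n_cases = 100, n_controls = 100, seed = 53,
                       prevalence = c(0, rep(0.4, 19)))
  expect_message(r <- exposure_corr(sim$exposure, value = "raw"), "P01")
  expect_true(all(is.na(r["P01", setdiff(rownames(r), "P01")])))
})

test_that("network construction matches a hand-checkable star design", {
  ids <- c("hub", paste0("n", 1:5), "far")
  r <- diag(7); rownames(r) <- colnames(r) <- ids
  r["hub", paste0("n", 1:5)] <- 0.6
  r[paste0("n", 1:5), "hub"] <- 0.6
  net <- build_network(r, toxic = "hub", threshold = 0.45)
  hub <- net$nodes[net$nodes$pesticide_id == "hub", ]
  expect_equal(hub$degree, 5)
  expect_equal(net$nodes$pesticide_id[1], "hub") # ordered by degree
  expect_equal(max(net$nodes$closeness, na.rm = TRUE), hub$closeness)
  expect_equal(nrow(net$edges), 5)
  # summary: 5 of 6 non-toxic pesticides link to the toxic layer
  expect_equal(net$linked_fraction, 5 / 6)
  # edges only between layers: none among n1..n5 even if correlated
  r2 <- r; r2["n1", "n2"] <- r2["n2", "n1"] <- 0.9
  net2 <- build_network(r2, toxic = "hub")
  expect_equal(nrow(net2$edges), 5)
  expect_error(build_network(r, toxic = character(0)), "non-empty")
})

test_that("raising the edge threshold never adds edges", {
  sim <- sim_pwas_data(n_cases = 200, n_controls = 200,
                       clusters = list(sprintf("P%02d", 1:6)),
                       rho = 0.7, seed = 54)
  r <- exposure_corr(sim$exposure)
  toxic <- c("P01", "P02")
  e1 <- nrow(build_network(r, toxic, threshold = 0.3)$edges)
  e2 <- nrow(build_network(r, toxic, threshold = 0.45)$edges)
  e3 <- nrow(build_network(r, toxic, threshold = 0.8)$edges)
  expect_gte(e1, e2); expect_gte(e2, e3)
  expect_equal(nrow(build_network(r, toxic, threshold = 1)$edges), 0)
})

test_that("clustering matches block structure, brute force, and refinement", {
  # two blocks with within-R 0.9, cross-R 0 -> exactly 2 clusters at 0.55
  ids <- sprintf("V%02d", 1:6)
  r <- matrix(0, 6, 6, dimnames = list(ids, ids))
  r[1:3, 1:3] <- 0.9; r[4:6, 4:6] <- 0.9; diag(r) <- 1
  cl <- cluster_exposures(r, height = 0.55)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(cl$cluster[cl$pesticide_id %in% ids[1:3]], rep(1, 3))
  # all-zero correlations -> singletons
  r0 <- diag(6); dimnames(r0) <- list(ids, ids)
  cl0 <- cluster_exposures(r0, height = 0.55)
  expect_equal(dplyr::n_distinct(cl0$cluster), 6)
  # random 8-variable instances agree with the naive agglomeration oracle
  set.seed(55)
  for (i in 1:10) {
    x <- matrix(rnorm(50 * 8), 50, 8,
                dimnames = list(NULL, sprintf("W%d", 1:8)))
    x[, 2] <- x[, 1] + rnorm(50, 0, 0.3)
    x[, 3] <- x[, 1] + rnorm(50, 0, 0.5)
    rr <- cor(x)
    ours <- cluster_exposures(rr, height = 0.55)
    oracle <- oracle_complete_cut(1 - rr, 0.55)
    expect_equal(oracle_ari(ours$cluster[match(colnames(rr),
                                               ours$pesticide_id)],
                            oracle), 1)
    # partitions at lower heights refine partitions at higher heights
    fine <- cluster_exposures(rr, height = 0.3)
    coarse <- cluster_exposures(rr, height = 0.7)
    tab <- table(fine$cluster[match(colnames(rr), fine$pesticide_id)],
                 coarse$cluster[match(colnames(rr), coarse$pesticide_id)])
    expect_true(all(rowSums(tab > 0) == 1))
  }
  # missing entries are refused with guidance
  rna <- r; rna[1, 2] <- NA
  expect_error(cluster_exposures(rna), "pairwise-complete")
})

test_that("configured co-application clusters are recovered from exposures", {
  truth_clusters <- list(sprintf("P%02d", 1:5), sprintf("P%02d", 6:9),
                         sprintf("P%02d", 10:12))
  sim <- sim_pwas_data(n_cases = 500, n_controls = 500,
                       clusters = truth_clusters, rho = 0.8, seed = 56)
  r <- exposure_corr(sim$exposure)
  cl <- cluster_exposures(r, height = 0.55)
  truth_lab <- rep(0L, nrow(cl))
  for (ci in seq_along(truth_clusters)) {
    truth_lab[cl$pesticide_id %in% truth_clusters[[ci]]] <- ci
  }
  truth_lab[truth_lab == 0] <- 100 + seq_len(sum(truth_lab == 0))
  expect_gte(oracle_ari(cl$cluster, truth_lab), 0.9)
})

test_that("crop shares are proportions that sum to one across crops", {
  apps <- tibble::tibble(
    pesticide_id = rep(c("tribufos_like", "mixed"), c(10000, 200)),
    crop = c(rep("cotton", 9996), rep("grape", 4),
             rep(c("cotton", "grape"), 100))
  )
  cs <- share_on_crop(apps, "cotton")
  expect_equal(cs$share[cs$pesticide_id == "tribufos_like"], 0.9996)
  expect_equal(cs$share[cs$pesticide_id == "mixed"], 0.5)
  # proportions over crops sum to 1 per pesticide
  crops <- unique(apps$crop)
  total <- Reduce(`+`, lapply(crops, function(cr) {
    share_on_crop(apps, cr) %>% dplyr::arrange(.data$pesticide_id) %>%
      dplyr::pull(.data$share)
  }))
  expect_equal(total, rep(1, 2))
  expect_message(share_on_crop(apps, "cotton", pesticide_ids = "absent"),
                 "no application records")
})
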