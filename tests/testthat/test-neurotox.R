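test_that("object filters use the stated strict boundaries", {
  obj <- tibble::tibble(
    well_id = "w1", field = 1,
    area = c(40, 40.1, 100, 399.9, 400, 100, 100),
    roundness = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.7, 0.71),
    intensity = c(800, 800, 800, 800, 800, 800, 500)
  )
  kept <- filter_objects(obj)
  # area 40 and 400 excluded; roundness 0.7 excluded; intensity 500 excluded
  expect_equal(nrow(kept), 3)
  expect_true(all(kept$area > 40 & kept$area < 400))
  expect_error(filter_objects(obj[, c("well_id", "area")]), "lacks column")
  # filtering is idempotent
  expect_identical(filter_objects(kept), kept)
})

test_that("control threshold is mean + 3 SD of control candidates", {
  wells <- tibble::tibble(well_id = c("c1", "c2", "t1"),
                          role = c("DMSO", "DMSO", "treated"))
  obj <- tibble::tibble(
    well_id = c("c1", "c2", "c1", "t1"),
    area = 100, roundness = 0.9,
    intensity = c(900, 1000, 1100, 5000)
  )
  cut <- control_threshold(obj, wells)
  expect_equal(cut, 1000 + 3 * sd(c(900, 1000, 1100)))
  # degenerate: all control intensities equal -> cutoff = mean
  obj2 <- obj %>% dplyr::mutate(intensity = c(1000, 1000, 1000, 5000))
  expect_equal(control_threshold(obj2, wells), 1000)
  expect_error(
    control_threshold(obj, wells %>% dplyr::mutate(role = "treated")),
    "no control wells"
  )
})

test_that("counting recovers a known bright fraction", {
  set.seed(61)
  wells <- tibble::tibble(
    well_id = c(sprintf("c%d", 1:4), "t1"),
    role = c(rep("DMSO", 4), "treated")
  )
  n <- 4000; f <- 0.05
  objs <- purrr::map_dfr(wells$well_id, function(w) {
    bright <- rbinom(1, n, f)
    tibble::tibble(
      well_id = w, area = 100, roundness = 0.9,
      intensity = c(rnorm(n - bright, 700, 80), rnorm(bright, 4500, 400))
    )
  })
  wc <- count_positives(objs, wells)
  expect_true(all(abs(wc$count - n * f) < 4 * sqrt(n * f * (1 - f))))
})

test_that("toxicity calls use a strict 3-SD-below-control rule", {
  wells <- tibble::tibble(
    well_id = sprintf("w%02d", 1:8),
    role = rep(c("DMSO", "treated"), each = 4),
    compound = rep(c("DMSO", "X"), each = 4),
    dose = rep(c(0, 30), each = 4),
    timepoint = "day11",
    count = c(950, 1000, 1000, 1050, 840, 840, 840, 840)
  )
  # control mean 1000, SD ~ 40.8 -> threshold ~ 877.5; treated mean 840
  calls <- toxicity_call(wells)
  expect_true(calls$toxic)
  expect_equal(calls$threshold,
               1000 - 3 * sd(c(950, 1000, 1000, 1050)))
  # exactly at the threshold is NOT toxic (strict <)
  wells2 <- wells %>%
    dplyr::mutate(count = ifelse(.data$role == "treated",
                                 1000 - 3 * sd(c(950, 1000, 1000, 1050)),
                                 .data$count))
  expect_false(toxicity_call(wells2)$toxic)
  expect_error(toxicity_call(wells[c(1, 5:8), ]), "at least 2 control")
})

test_that("toxicity calls are invariant to well order and SD-monotone", {
  set.seed(62)
  wells <- tibble::tibble(
    well_id = sprintf("w%02d", 1:12),
    role = rep(c("DMSO", "treated"), c(8, 4)),
    compound = rep(c("DMSO", "X"), c(8, 4)),
    dose = rep(c(0, 30), c(8, 4)),
    timepoint = "day11",
    count = c(rnorm(8, 1000, 50), rnorm(4, 700, 30))
  )
  c1 <- toxicity_call(wells)
  c2 <- toxicity_call(wells %>% dplyr::slice_sample(prop = 1))
  expect_equal(c1, c2)
  # inflating control SD can only turn toxic into non-toxic, never back
  wider <- wells %>%
    dplyr::mutate(count = ifelse(.data$role == "DMSO",
                                 1000 + (.data$count - 1000) * 6,
                                 .data$count))
  expect_true(c1$toxic >= toxicity_call(wider)$toxic)
})

test_that("Z-prime matches closed forms and direct evaluation", {
  neg <- c(95, 100, 100, 105); pos <- c(15, 20, 20, 25)
  # means 100 and 20, SDs equal: hand value from the definition
  expect_equal(zprime(neg, pos),
               1 - 3 * (sd(pos) + sd(neg)) / 80, tolerance = 1e-12)
  expect_equal(zprime(c(100, 100), c(20, 20)), 1) # zero-variance arms
  set.seed(63)
  for (i in 1:20) {
    a <- rnorm(8, 1000, 60); b <- rnorm(8, 150, 40)
    expect_equal(zprime(a, b),
                 1 - 3 * (sd(b) + sd(a)) / abs(mean(b) - mean(a)),
                 tolerance = 1e-12)
    expect_lte(zprime(a, b), 1)
  }
  expect_error(zprime(c(10, 10), c(10, 10)), "undefined")
})

test_that("dose summaries interpolate the LD50 between bracketing doses", {
  wells <- tibble::tibble(
    well_id = sprintf("w%02d", 1:12),
    role = rep(c("DMSO", "treated"), c(4, 8)),
    compound = rep(c("DMSO", "X"), c(4, 8)),
    dose = c(rep(0, 4), rep(c(1.1, 3.3, 10, 30), each = 2)),
    timepoint = "day11",
    count = c(rep(1000, 4), 1000, 1000, 900, 900, 480, 480, 100, 100)
  )
  ds <- dose_summary(wells)
  x <- ds$compounds[ds$compounds$compound == "X", ]
  expect_gt(x$ld50, 3.3); expect_lt(x$ld50, 10)
  # hand interpolation on the log-dose scale, crossing half = 500 between
  # the 3.3 (mean 900) and 10 (mean 480) doses
  expect_equal(x$ld50, exp(log(3.3) + (900 - 500) / (900 - 480) *
                             (log(10) - log(3.3))))
  expect_true(x$monotone)
  # identical treated and control -> 0% decrease everywhere
  flat <- wells %>% dplyr::mutate(count = 1000)
  expect_true(all(dose_summary(flat)$doses$pct_decrease == 0))
  expect_error(dose_summary(wells %>% dplyr::mutate(count = 0)),
               "positive")
})

test_that("Hill-generated compounds yield LD50 within twofold of the true EC50", {
  cfg <- demo_config(seed = 64)
  cfg$plate_truth <- tibble::tibble(
    compound = "H1", top = 1, bottom = 0, ec50 = 10, hill = 1.5,
    toxic = TRUE
  )
  pl <- sim_plate(cfg, n_replicates = 6, base_cells = 300)
  wc <- count_positives(pl$objects, pl$wells)
  ld <- dose_summary(wc)$compounds$ld50
  expect_gt(ld, 5); expect_lt(ld, 20)
})

test_that("combination analysis flags the printed-style synergy fixture", {
  ca <- combo_analysis(combo_fixture())
  conds <- ca$conditions
  expect_equal(nrow(conds), 4) # 2^2 subsets
  expect_equal(conds$condition[1], "DMSO") # descending mean count
  expect_equal(
    conds$pct_change[conds$condition == "triA"], -32, tolerance = 0.01
  )
  expect_equal(
    conds$pct_change[conds$condition == "triB"], -8, tolerance = 0.01
  )
  expect_equal(
    conds$pct_change[conds$condition == "triA+triB"], -65, tolerance = 0.01
  )
  expect_true(ca$pairs$enhanced)
  expect_gt(ca$pairs$bliss_excess, 0)
})

test_that("combination analysis covers the full 2^6 design with ordered ties", {
  cfg <- demo_config(seed = 65)
  cb <- sim_combo_counts(cfg)
  ca <- combo_analysis(cb)
  expect_equal(nrow(ca$conditions), 64)
  expect_true("DMSO" %in% ca$conditions$condition)
  expect_equal(nrow(ca$pairs), choose(6, 2))
  # missing subsets are reported by name
  expect_error(combo_analysis(cb[cb$condition != "P01+P02", ]), "P01\\+P02")
  # all-identical conditions: nothing significant; ordering ties lexical
  flat <- cb %>% dplyr::mutate(count = 500)
  ca0 <- combo_analysis(flat)
  expect_true(all(ca0$comparisons$q == 1))
  expect_false(any(ca0$pairs$enhanced))
  expect_equal(ca0$conditions$condition,
               sort(ca0$conditions$condition))
})

test_that("mito-stress parameters follow their closed-form definitions", {
  # hand-built trace: pre-oligo last 100, post-oligo min 40, post-FCCP max
  # 150, post-rot/AA min 10
  tr <- tibble::tibble(
    well_id = "w1",
    cycle = 1:12,
    segment = rep(c("basal", "oligomycin", "fccp", "rot_aa"), each = 3),
    ocr = c(102, 101, 100, 42, 40, 41, 150, 149, 148, 11, 10, 12)
  )
  mp <- mito_stress(tr)
  expect_equal(mp$non_mito, 10)
  expect_equal(mp$basal, 90)
  expect_equal(mp$atp_linked, 60)
  expect_equal(mp$maximal, 140)
  expect_equal(mp$spare, 50)
  expect_equal(mp$spare_pct, 100 * 140 / 90, tolerance = 1e-10)
  expect_false(mp$flagged)
  # spare = maximal - basal identically; shift invariance
  shifted <- tr %>% dplyr::mutate(ocr = .data$ocr + 25)
  mps <- mito_stress(shifted)
  expect_equal(mps$basal, mp$basal)
  expect_equal(mps$atp_linked, mp$atp_linked)
  expect_equal(mps$maximal, mp$maximal)
  expect_equal(mps$spare, mp$spare)
  expect_equal(mps$non_mito, mp$non_mito + 25)
  # missing segment errors
  expect_error(mito_stress(tr[tr$segment != "fccp", ]), "fccp")
})

test_that("noiseless simulated traces invert exactly to the configured truth", {
  cfg <- demo_config(seed = 66)
  tr <- sim_ocr(cfg, noise_sd = 0)
  mp <- mito_stress(tr)
  expect_true(all(mp$non_mito == cfg$ocr_truth$non_mito))
  expect_true(all(mp$basal == cfg$ocr_truth$basal))
  expect_true(all(mp$atp_linked == cfg$ocr_truth$atp))
  expect_true(all(mp$maximal == cfg$ocr_truth$maximal))
  expect_true(all(mp$spare == cfg$ocr_truth$maximal - cfg$ocr_truth$basal))
})
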