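test_that("simulated truth lattices honour the lesion spec", {
  s0 <- simulate_truth(10, 10, seed = 1)
  expect_identical(s0$slide_label, "non-cancer")
  expect_identical(sum(s0$truth == "cancer", na.rm = TRUE), 0L)

  s1 <- simulate_truth(10, 10, lesions = lesion_rect(2, 2, 3, 3), seed = 1)
  expect_identical(s1$slide_label, "cancer")
  expect_identical(sum(s1$truth == "cancer", na.rm = TRUE), 9L)

  expect_error(simulate_truth(5, 5, lesions = lesion_rect(4, 4, 3, 3)),
               "outside the grid")

  # determinism
  a <- simulate_truth(15, 15, lesions = lesion_blob(10),
                      tissue_fraction = 0.7, seed = 42)
  b <- simulate_truth(15, 15, lesions = lesion_blob(10),
                      tissue_fraction = 0.7, seed = 42)
  expect_identical(a$truth, b$truth)
})

test_that("blob lesions are connected and have the requested size", {
  sim <- simulate_truth(20, 20, lesions = lesion_blob(25), seed = 31)
  cancer <- !is.na(sim$truth) & sim$truth == "cancer"
  expect_identical(sum(cancer), 25L)
  cl <- find_clusters(cancer, 4)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$size, 25L)
})

test_that("rendered slides round-trip through tiling and filtering", {
  # all non-tissue: nothing retained
  sim0 <- simulate_truth(4, 4, tissue_fraction = 0.5, seed = 2)
  sim0$tissue_mask[] <- FALSE
  sim0$truth[] <- NA_character_
  slide0 <- render_slide(sim0, patch_size_px = 8, seed = 2)
  g0 <- filter_background(tile_slide(slide0, 8), slide0)
  expect_false(any(g0$tissue_mask))

  # checkerboard tissue: recovered mask equals the planted mask
  simc <- simulate_truth(6, 6, tissue_fraction = 1, seed = 3)
  simc$tissue_mask <- outer(1:6, 1:6, function(i, j) (i + j) %% 2 == 0)
  simc$truth[!simc$tissue_mask] <- NA
  slidec <- render_slide(simc, patch_size_px = 8, seed = 3)
  gc_ <- filter_background(tile_slide(slidec, 8), slidec)
  expect_identical(gc_$tissue_mask, simc$tissue_mask)
})

test_that("rendered patches satisfy the background clauses by construction", {
  sim <- simulate_truth(3, 3, lesions = lesion_rect(1, 1, 1, 1),
                        tissue_fraction = 0.6, seed = 13)
  slide <- render_slide(sim, patch_size_px = 10, seed = 13)
  grid <- tile_slide(slide, 10)
  crit <- background_criteria()
  for (i in 1:3) for (j in 1:3)
    expect_identical(is_background(get_patch(slide, grid, i, j), crit),
                     !sim$tissue_mask[i, j])
})

test_that("operating characteristics recover the k = 1 closed form", {
  # all-negative slides with N patches: slide FPR = 1 - spec^N
  cfg <- simulated_classifier_config(sensitivity = 0.95, specificity = 0.99)
  oc <- estimate_operating_characteristics(
    n_rows = 10, n_cols = 10,
    lesion_sampler = function() lesion_rect(1, 1, 3, 3),
    classifier_cfg = cfg, cluster_sizes = 1, n_reps = 500, seed = 77)
  p0 <- 1 - 0.99^100
  se <- sqrt(p0 * (1 - p0) / 500)
  expect_lt(abs(oc$slide_FPR - p0), 3 * se)
})

test_that("slide error rates are monotone in cluster size", {
  cfg <- simulated_classifier_config()
  oc <- estimate_operating_characteristics(
    n_rows = 20, n_cols = 20, classifier_cfg = cfg,
    cluster_sizes = c(1, 2, 4, 8), n_reps = 100, seed = 5)
  expect_true(all(diff(oc$slide_sensitivity) <= 0))
  expect_true(all(diff(oc$slide_FPR) <= 0))
})

test_that("perfect classifier and k-sized lesions give perfect slides", {
  cfg <- simulated_classifier_config(sensitivity = 1, specificity = 1)
  oc <- estimate_operating_characteristics(
    n_rows = 12, n_cols = 12,
    lesion_sampler = function() lesion_rect(3, 3, 3, 3),
    classifier_cfg = cfg, cluster_sizes = c(1, 2, 4, 8),
    n_reps = 50, seed = 9)
  expect_true(all(oc$slide_sensitivity == 1))
  expect_true(all(oc$slide_FPR == 0))
})

test_that("patient-level error follows the union closed form", {
  # m = 1: patient metrics equal slide metrics
  cfg <- simulated_classifier_config(specificity = 0.99)
  pe1 <- patient_level_error(1, n_rows = 10, n_cols = 10,
                             lesion_sampler = function() lesion_rect(1, 1, 3, 3),
                             classifier_cfg = cfg, cluster_size = 1,
                             n_reps = 300, seed = 11)
  expect_identical(pe1$patient_sensitivity, pe1$slide_sensitivity)
  expect_identical(pe1$patient_FPR, pe1$slide_FPR)

  # m = 3 at a calibrated slide FPR: patient FPR ~ 1 - (1 - fpr)^3.
  # k = 2 on a 10x10 grid with patch FPR 0.035 gives a slide FPR far from
  # 0 and 1, so the check is informative.
  cfg2 <- simulated_classifier_config(specificity = 0.965)
  pe3 <- patient_level_error(3, n_rows = 10, n_cols = 10,
                             lesion_sampler = function() lesion_rect(1, 1, 4, 4),
                             classifier_cfg = cfg2, cluster_size = 2,
                             n_reps = 400, seed = 12)
  expect_gte(pe3$patient_FPR, pe3$slide_FPR)
  want <- 1 - (1 - pe3$slide_FPR)^3
  se_slide <- sqrt(pe3$slide_FPR * (1 - pe3$slide_FPR) / (400 * 3))
  se_prop <- 3 * (1 - pe3$slide_FPR)^2 * se_slide
  se_pat <- sqrt(want * (1 - want) / 400)
  expect_lt(abs(pe3$patient_FPR - want),
            3 * sqrt(se_pat^2 + se_prop^2) + 1e-9)

  # sensitivity is non-decreasing in m when every slide carries the lesion
  pe1s <- patient_level_error(1, n_rows = 10, n_cols = 10,
                              lesion_sampler = function() lesion_rect(1, 1, 2, 2),
                              classifier_cfg = simulated_classifier_config(sensitivity = 0.8),
                              cluster_size = 4, n_reps = 300, seed = 13)
  pe3s <- patient_level_error(3, n_rows = 10, n_cols = 10,
                              lesion_sampler = function() lesion_rect(1, 1, 2, 2),
                              classifier_cfg = simulated_classifier_config(sensitivity = 0.8),
                              cluster_size = 4, n_reps = 300, seed = 13)
  se_pair <- sqrt(0.25 / 300)
  expect_gte(pe3s$patient_sensitivity,
             pe1s$patient_sensitivity - 3 * se_pair)
})

test_that("simulations are fully deterministic under a fixed seed", {
  args <- list(n_rows = 12, n_cols = 12, cluster_sizes = c(1, 4),
               n_reps = 30, seed = 99)
  a <- do.call(estimate_operating_characteristics, args)
  b <- do.call(estimate_operating_characteristics, args)
  expect_identical(a, b)
})
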