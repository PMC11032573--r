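test_that("the synthetic atlas renders the layout with merged labels and a usable WM map", {
  cfg <- sim_config(n_subjects = 5, roi_layout = small_layout(), seed = 7)
  synth <- make_synthetic_atlas(cfg)
  tab <- synth$atlas$label_table
  expect_equal(nrow(tab), 3)          # 1 pair + 1 midline = 3 raw labels
  expect_equal(n_rois(synth$atlas), 2)
  wm <- synth$wm$probabilities
  expect_true(all(wm >= 0 & wm <= 1))
  expect_true(all(wm[synth$atlas$labels > 0] >= 0.5))
  dims <- dim(wm)
  rim <- c(wm[1, , ], wm[dims[1], , ], wm[, 1, ], wm[, , dims[3]])
  expect_true(all(rim < 0.3))
})

test_that("degenerate layouts are rejected with informative errors", {
  expect_error(sim_config(roi_layout = small_layout()[0, ],
                          grid_shape = c(18, 16, 10)), "non-empty")
  overlap <- small_layout()
  # move the midline block onto 'pair A left' in all three axes
  overlap$x0[3] <- 3; overlap$x1[3] <- 6
  overlap$y0[3] <- 3; overlap$y1[3] <- 6
  expect_error(sim_config(roi_layout = overlap),
               "overlapping ROI blocks: 'pair A left' and 'mid B midline'")
  off <- small_layout()
  off$x1[3] <- 99
  expect_error(sim_config(roi_layout = off), "outside")
  asym <- small_layout()
  asym$y1[2] <- 7
  expect_error(sim_config(roi_layout = asym), "mirror")
})

test_that("simulated demographics follow the configured cohort profile", {
  cfg <- sim_config(n_subjects = 1000, n_sites = 4, seed = 11)
  subj <- simulate_subjects(cfg)
  expect_lt(abs(mean(subj$age) - 71.5), 1.0)
  expect_true(all(subj$age >= 40 & subj$age <= 100))
  expect_true(all(subj$sex %in% 0:1))
  counts <- table(subj$site)
  expect_lte(diff(range(counts)), 1)  # balanced site assignment
  expect_identical(simulate_subjects(cfg), subj)  # determinism
  # amyloid values land on the correct side of the registered cutoff
  status <- dichotomize_amyloid(subj$amyloid_value, subj$amyloid_rule_id,
                                subj$amyloid_modality)
  expect_equal(as.integer(status == "positive"), subj$true_abeta)
})

test_that("indicator missingness drives VRCS availability", {
  cfg0 <- sim_config(n_subjects = 200, missingness_rates = rep(0, 6), seed = 2)
  subj0 <- simulate_subjects(cfg0)
  expect_false(anyNA(subj0[, risk_factor_names()]))
  expect_false(anyNA(compute_vrcs(subj0[, risk_factor_names()])))
  # four always-missing indicators leave only two available: all undefined
  cfg1 <- sim_config(n_subjects = 200,
                     missingness_rates = c(1, 1, 1, 1, 0, 0), seed = 2)
  subj1 <- simulate_subjects(cfg1)
  expect_true(all(is.na(compute_vrcs(subj1[, risk_factor_names()]))))
})

test_that("a flat generative model produces empty masks", {
  cfg <- sim_config(n_subjects = 10, baseline = 0, beta_age = 0, beta_sex = 0,
                    noise_sd = 1e-9, site_sd = 0, seed = 4)
  synth <- make_synthetic_atlas(cfg)
  les <- simulate_lesions(simulate_subjects(cfg), synth$atlas, cfg)
  expect_true(all(vapply(les$masks, function(m) sum(m$mask), 0) == 0))
  expect_true(all(les$ground_truth$total_wmh == 0))
})

test_that("lesion masks are deterministic, in-ROI, and volumetrically faithful", {
  cfg <- sim_config(n_subjects = 20, n_sites = 3, seed = 31)
  synth <- make_synthetic_atlas(cfg)
  subj <- simulate_subjects(cfg)
  les <- simulate_lesions(subj, synth$atlas, cfg)
  les2 <- simulate_lesions(subj, synth$atlas, cfg)
  expect_identical(lapply(les2$masks, `[[`, "mask"),
                   lapply(les$masks, `[[`, "mask"))
  expect_identical(les2$ground_truth, les$ground_truth)
  for (m in les$masks)
    expect_true(all(synth$atlas$labels[m$mask == 1L] > 0L))

  vt <- regional_volume_table(lapply(les$masks, apply_wm_mask, wm = synth$wm),
                              synth$atlas)
  rois <- roi_names(synth$atlas)
  vox_ml <- prod(cfg$voxel_size_mm^c(1, 1, 1)) / 1000
  # placed volumes match volumetry exactly, continuous targets within 1 voxel
  expect_equal(as.matrix(vt[rois]),
               as.matrix(les$ground_truth[rois]), ignore_attr = TRUE)
  expect_lte(max(abs(as.matrix(vt[rois]) - as.matrix(les$target[rois]))),
             vox_ml)
})

test_that("volumes exceeding ROI capacity are capped with one aggregated warning", {
  cfg <- sim_config(n_subjects = 5, baseline = 3, seed = 8)
  synth <- make_synthetic_atlas(cfg)
  expect_warning(
    les <- simulate_lesions(simulate_subjects(cfg), synth$atlas, cfg),
    "capped")
  caps <- table(factor(synth$atlas$label_table$merged_id[
    synth$atlas$labels[synth$atlas$labels > 0]],
    levels = seq_len(n_rois(synth$atlas))))
  vox_ml <- prod(rep(cfg$voxel_size_mm, 3)) / 1000
  for (r in seq_along(roi_names(synth$atlas)))
    expect_true(all(les$ground_truth[[roi_names(synth$atlas)[r]]] <=
                      caps[r] * vox_ml + 1e-12))
})

test_that("null-effect simulations yield uniform downstream p-values", {
  # determinant effects zero, no site heterogeneity; nuisance age/sex effects
  # stay on so the adjustment set is exercised
  pvals <- numeric(0)
  for (rep in 1:200) {
    cfg <- sim_config(n_subjects = 500, n_sites = 5, site_sd = 0,
                      seed = 5000 + rep)
    subj <- simulate_subjects(cfg)
    vols <- simulate_roi_volumes(subj, cfg)
    res <- run_association_suite(vols, sim_covariates(subj),
                                 determinants = "vrcs_z", adjust = FALSE)
    pvals <- c(pvals, res$p)
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})
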