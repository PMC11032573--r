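make_model_data <- function(n = 200, n_sites = 4, B = 0.3, tau = 0.2,
                            sigma = 1, seed = 1) {
  set.seed(seed)
  site <- factor(rep_len(paste0("s", seq_len(n_sites)), n))
  u <- rnorm(n_sites, 0, tau)
  det <- rnorm(n)
  age <- rnorm(n, 70, 9)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.5 + B * det + 0.01 * age + 0.05 * sex + u[as.integer(site)] +
    rnorm(n, 0, sigma)
  data.frame(y = y, det = det, age = age, sex = sex, site = site)
}

test_that("a noiseless single-site fit recovers the coefficient exactly", {
  set.seed(2)
  det <- rnorm(40)
  d <- data.frame(y = 0.5 * det, det = det, age = rnorm(40), sex = rbinom(40, 1, 0.5),
                  site = "only")
  fit <- fit_roi_model(d)
  expect_equal(fit$B, 0.5, tolerance = 1e-10)
  expect_lt(fit$SE, 1e-10)
  expect_identical(fit$method, "ols")
})

test_that("with one site the mixed model reduces to ordinary least squares", {
  for (seed in 1:5) {
    d <- make_model_data(n = 60, n_sites = 1, seed = seed)
    fit <- fit_roi_model(d)
    ols <- summary(lm(y ~ det + age + sex, data = d))$coefficients
    expect_equal(fit$B, ols["det", "Estimate"], tolerance = 1e-8)
    expect_equal(fit$SE, ols["det", "Std. Error"], tolerance = 1e-8)
  }
})

test_that("fixed variance components reproduce the closed-form GLS oracle", {
  d <- make_model_data(n = 24, n_sites = 3, B = 0.4, tau = 0.5, sigma = 0.8,
                       seed = 13)
  tau2 <- 0.25; sigma2 <- 0.64
  fit <- fit_roi_model(d, varcomp = c(tau2, sigma2))
  X <- model.matrix(y ~ det + age + sex, d)
  beta_oracle <- gls_oracle(X, d$y, as.character(d$site), tau2, sigma2)
  expect_equal(fit$B, unname(beta_oracle[2]), tolerance = 1e-6)
  expect_identical(fit$method, "gls_fixed")
})

test_that("Wald intervals achieve nominal coverage across replicate fits", {
  hits <- 0L
  for (seed in 1:100) {
    d <- make_model_data(n = 500, n_sites = 5, B = 0.30, tau = 0.2,
                         sigma = 1, seed = seed)
    fit <- fit_roi_model(d)
    if (abs(fit$B - 0.30) <= 1.96 * fit$SE) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("flipping the determinant sign flips the coefficient", {
  d <- make_model_data(n = 120, n_sites = 1, seed = 3)
  flip <- d; flip$det <- -flip$det
  expect_equal(fit_roi_model(flip)$B, -fit_roi_model(d)$B, tolerance = 1e-12)
  d2 <- make_model_data(n = 300, n_sites = 5, tau = 0.4, seed = 4)
  flip2 <- d2; flip2$det <- -flip2$det
  f <- fit_roi_model(d2); g <- fit_roi_model(flip2)
  expect_equal(g$B, -f$B, tolerance = 1e-6)
  expect_equal(g$SE, f$SE, tolerance = 1e-6)
})

test_that("degenerate outcomes and collinear designs are rejected by name", {
  d <- make_model_data(n = 50, seed = 6)
  d$y <- 1
  expect_error(fit_roi_model(d), class = "wmh_degenerate")
  d2 <- make_model_data(n = 50, seed = 7)
  d2$age <- d2$det   # perfectly collinear with the determinant
  expect_error(fit_roi_model(d2), "collinear.*age")
})

test_that("the Bonferroni threshold divides the family alpha", {
  thr <- bonferroni_threshold(0.05, 28)
  expect_equal(thr, 0.05 / 28)
  expect_equal(round(thr, 3), 0.002)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
})

test_that("Bonferroni keeps the family-wise error under alpha for independent nulls", {
  set.seed(17)
  thr <- bonferroni_threshold(0.05, 28)
  fw <- replicate(5000, any(runif(28) < thr))
  mc_se <- sqrt(0.05 * 0.95 / 5000)
  expect_lte(mean(fw), 0.05 + 2 * mc_se)
})

test_that("the suite emits one ordered row per determinant, ROI and adjustment", {
  cfg <- sim_config(n_subjects = 80, n_sites = 4,
                    roi_layout = icbm_like_layout(), seed = 21)
  subj <- simulate_subjects(cfg)
  vols <- simulate_roi_volumes(subj, cfg)
  res <- run_association_suite(vols[, setdiff(names(vols), "site")],
                               sim_covariates(subj))
  expect_equal(nrow(res), 28 * 2 * 2)
  expect_equal(unique(res$determinant), c("vrcs_z", "abeta_status"))
  rois <- names(cfg$baseline)
  expect_equal(res$roi[res$determinant == "vrcs_z" & !res$adjusted_for_total],
               rois)
  expect_equal(res$adjusted_for_total[1:2], c(FALSE, TRUE))
  expect_equal(attr(res, "n_tests"), 28L)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$SE > 0))
})

test_that("a zero-variance ROI is skipped with a warning but keeps its rows", {
  cfg <- sim_config(n_subjects = 60, n_sites = 3, seed = 22)
  subj <- simulate_subjects(cfg)
  vols <- simulate_roi_volumes(subj, cfg)
  vols[["external capsule"]] <- 0
  warns <- capture_warnings(
    res <- run_association_suite(vols[, setdiff(names(vols), "site")],
                                 sim_covariates(subj),
                                 determinants = "vrcs_z"))
  expect_length(warns, 2)  # one per adjustment setting
  expect_true(all(grepl("skipped", warns)))
  expect_equal(nrow(res), 6 * 2)
  bad <- res[res$roi == "external capsule", ]
  expect_true(all(is.na(bad$B)))
  expect_true(all(!bad$significant))
  expect_false(anyNA(res$B[res$roi != "external capsule"]))
})

test_that("cohort exclusion validates the cohort and reruns the complement", {
  cfg <- sim_config(n_subjects = 90, n_sites = 3, seed = 23)
  subj <- simulate_subjects(cfg)
  vols <- simulate_roi_volumes(subj, cfg)[, -2]
  cov <- sim_covariates(subj)
  main <- run_association_suite(vols, cov, determinants = "vrcs_z")
  expect_error(sensitivity_exclude_cohort(vols, cov, "siteXX"),
               "unknown cohort")
  # a declared-but-empty cohort changes nothing
  ghost <- sensitivity_exclude_cohort(vols, cov, "ghost",
                                      cohorts = c(unique(cov$site), "ghost"),
                                      determinants = "vrcs_z")
  expect_identical(as.data.frame(ghost), as.data.frame(main))
  sub <- sensitivity_exclude_cohort(vols, cov, "site01",
                                    determinants = "vrcs_z")
  expect_true(all(sub$n < main$n))
  # excluding the only cohort leaves nobody
  one <- cov; one$site <- "site01"
  expect_error(sensitivity_exclude_cohort(vols, one, "site01"),
               "no subjects")
})

test_that("complete-case restriction equals the main analysis when nothing is missing", {
  cfg <- sim_config(n_subjects = 80, n_sites = 4, missingness_rates = rep(0, 6),
                    amyloid_missing_rate = 0, seed = 24)
  subj <- simulate_subjects(cfg)
  vols <- simulate_roi_volumes(subj, cfg)[, -2]
  cov <- sim_covariates(subj)
  main <- run_association_suite(vols, cov)
  cc <- sensitivity_complete_cases(vols, cov)
  expect_identical(as.data.frame(cc), as.data.frame(main))
  # disjoint availability leaves an empty intersection
  cov2 <- cov
  cov2$vrcs[seq(1, nrow(cov2), 2)] <- NA
  cov2$abeta[seq(2, nrow(cov2), 2)] <- NA
  expect_error(sensitivity_complete_cases(vols, cov2), "both VRCS and amyloid")
})
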