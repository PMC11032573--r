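#' Bonferroni per-test significance threshold
#'
#' Family-wise error control over the per-ROI models: with 28 merged ROIs and
#' a family-wise alpha of 0.05 the per-test threshold is 0.05/28 = 0.00179,
#' i.e. p < 0.002 at the precision usually quoted. Significance uses a strict
#' `<` comparison against this threshold.
#'
#' @param alpha_family family-wise alpha, default 0.05.
#' @param n_tests number of tests in the family (number of merged ROIs).
#' @return per-test alpha.
#' @examples bonferroni_threshold(0.05, 28)
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_tests) {
  n_tests <- assert_positive_int(n_tests, "n_tests")
  if (alpha_family <= 0 || alpha_family >= 1)
    stop("alpha_family must be in (0, 1)", call. = FALSE)
  alpha_family / n_tests
}

#' Fit the per-ROI linear mixed model
#'
#' Fits `y ~ det + age + sex (+ total) + (1 | site)` by restricted maximum
#' likelihood and reports the unstandardized determinant coefficient B, its
#' standard error, and a Wald z p-value (normal reference). With a single
#' site, or when the REML fit lands on the tau^2 = 0 boundary (singular fit),
#' the model collapses to ordinary least squares, which is then used
#' directly with a note in the result.
#'
#' @param data data.frame with columns `y` (outcome), `det` (determinant),
#'   `age`, `sex` (female = 1, male = 0), `site`, and `total` when
#'   `adjust_total = TRUE`. Rows with missing values in the used columns are
#'   dropped (complete-case analysis per model).
#' @param adjust_total add the (transformed) total WMH volume as a fixed
#'   covariate.
#' @param varcomp optional `c(tau2, sigma2)`: hold the variance components
#'   fixed at these values and compute the generalized-least-squares fixed
#'   effects in closed form instead of estimating by REML (used for oracle
#'   checks and simulation studies with known variances).
#' @return one-row data.frame: `B`, `SE`, `p`, `n`, `method`
#'   (`"reml"`, `"ols"`, `"ols_boundary"` or `"gls_fixed"`).
#' @export
fit_roi_model <- function(data, adjust_total = FALSE, varcomp = NULL) {
  cols <- c("y", "det", "age", "sex", "site", if (adjust_total) "total")
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(d)
  if (n < length(cols))
    stop("too few complete cases to fit the model", call. = FALSE)
  d$site <- droplevels(factor(d$site))
  if (stats::sd(d$y) == 0)
    degenerate_error("outcome has zero variance")

  fixed <- if (adjust_total) y ~ det + age + sex + total else y ~ det + age + sex
  X <- stats::model.matrix(fixed, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  if (!is.null(varcomp)) {
    est <- gls_known_varcomp(X, d$y, d$site, varcomp[1], varcomp[2])
    method <- "gls_fixed"
  } else if (nlevels(d$site) < 2L) {
    est <- ols_fit(fixed, d)
    method <- "ols"
  } else {
    mixed <- stats::update(fixed, . ~ . + (1 | site))
    fit <- suppressMessages(lme4::lmer(
      mixed, data = d, REML = TRUE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    if (lme4::isSingular(fit, tol = 1e-6)) {
      # tau^2 floored at 0: the GLS solution is OLS, refit there
      est <- ols_fit(fixed, d)
      method <- "ols_boundary"
    } else {
      cf <- summary(fit)$coefficients
      est <- c(B = cf["det", "Estimate"], SE = cf["det", "Std. Error"])
      method <- "reml"
    }
  }
  B <- unname(est["B"]); SE <- unname(est["SE"])
  z <- if (SE > 0) B / SE else sign(B) * Inf
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  data.frame(B = B, SE = SE, p = p, n = n, method = method,
             stringsAsFactors = FALSE)
}

ols_fit <- function(fixed, d) {
  cf <- summary(stats::lm(fixed, data = d))$coefficients
  c(B = cf["det", "Estimate"], SE = cf["det", "Std. Error"])
}

# closed-form GLS with known variance components: V = sigma2 I + tau2 Z Z'
gls_known_varcomp <- function(X, y, site, tau2, sigma2) {
  stopifnot(tau2 >= 0, sigma2 > 0)
  Z <- stats::model.matrix(~ 0 + site)
  V <- diag(sigma2, nrow(X)) + tau2 * tcrossprod(Z)
  Vi <- chol2inv(chol(V))
  XtVi <- crossprod(X, Vi)
  cov_b <- solve(XtVi %*% X)
  beta <- drop(cov_b %*% (XtVi %*% y))
  names(beta) <- colnames(X)
  se <- sqrt(diag(cov_b))
  c(B = beta[["det"]], SE = se[[which(colnames(X) == "det")]])
}

#' Run the full per-ROI association suite
#'
#' For each determinant (z-scored VRCS; dichotomous amyloid status), each
#' merged ROI, and each adjustment set (without / with total WMH volume),
#' fits a separate linear mixed model of the transformed regional WMH volume
#' with fixed age and sex effects and a random site intercept, and flags
#' Bonferroni-significant associations.
#'
#' Outcomes are cube-root transformed and, by default, z-scored over the
#' complete-case subject set of the model at hand; the total-WMH covariate
#' enters on the same scale. ROIs whose outcome is degenerate (zero variance
#' in the analysis sample) are skipped with a warning and reported as NA
#' rows, so the result keeps one row per determinant x ROI x adjustment.
#'
#' @param volumes data.frame from [regional_volume_table()]: `subject_id`,
#'   one mL column per merged ROI, `total_wmh`.
#' @param covariates data.frame with `subject_id`, `site`, `age`, `sex`
#'   (`"female"`/`"male"` or 1/0 with female = 1), `vrcs` (raw score in
#'   \[0, 1\], NA where undefined), `abeta` (`"positive"`/`"negative"` or
#'   1/0, NA where unavailable).
#' @param determinants subset of `c("vrcs_z", "abeta_status")`.
#' @param adjust logical vector of adjustment settings to run
#'   (default `c(FALSE, TRUE)`: before and after total-WMH correction).
#' @param alpha_family family-wise alpha (default 0.05).
#' @param n_tests number of tests for the Bonferroni correction; defaults to
#'   the number of ROI columns and is kept fixed even if some ROIs are
#'   skipped.
#' @param standardize_outcome z-score the transformed outcome (and total)
#'   over the per-model analysis sample (default TRUE). With FALSE the
#'   outcome stays on the cube-root mL scale, which is convenient for
#'   parameter-recovery studies against a generative model.
#' @return data.frame with one row per determinant x ROI x adjustment,
#'   ordered by (determinant, merged ROI, adjustment): `determinant`, `roi`,
#'   `adjusted_for_total`, `B`, `SE`, `p`, `n`, `significant`, `sign`,
#'   `method`. Attributes `alpha_family`, `n_tests`, `p_threshold`.
#' @export
run_association_suite <- function(volumes, covariates,
                                  determinants = c("vrcs_z", "abeta_status"),
                                  adjust = c(FALSE, TRUE),
                                  alpha_family = 0.05, n_tests = NULL,
                                  standardize_outcome = TRUE) {
  determinants <- match.arg(determinants, several.ok = TRUE)
  volumes <- volumes[, setdiff(names(volumes), "site"), drop = FALSE]
  rois <- setdiff(names(volumes), c("subject_id", "total_wmh"))
  if (!length(rois)) stop("no ROI columns in volume table", call. = FALSE)
  if (!("total_wmh" %in% names(volumes)) && any(adjust))
    stop("volume table lacks 'total_wmh', needed for adjusted models",
         call. = FALSE)
  n_tests <- if (is.null(n_tests)) length(rois) else
    assert_positive_int(n_tests, "n_tests")
  thr <- bonferroni_threshold(alpha_family, n_tests)

  dat <- merge(covariates, volumes, by = "subject_id")
  if (!nrow(dat)) stop("no subjects shared between volumes and covariates",
                       call. = FALSE)
  dat$sex_num <- code_sex(dat$sex)
  dat$abeta_num <- if ("abeta" %in% names(dat)) code_abeta(dat$abeta) else NA_real_

  out <- list()
  for (det in determinants) {
    raw_det <- switch(det, vrcs_z = dat$vrcs, abeta_status = dat$abeta_num)
    cc <- !is.na(raw_det) & !is.na(dat$age) & !is.na(dat$sex_num) &
      !is.na(dat$site)
    if (!any(cc))
      stop("no subjects with a defined determinant '", det, "'", call. = FALSE)
    d0 <- dat[cc, , drop = FALSE]
    det_val <- if (det == "vrcs_z") standardize_vrcs(d0$vrcs) else d0$abeta_num
    total_t <- cube_root_transform(d0$total_wmh)
    if (standardize_outcome)
      total_t <- tryCatch(zscore(total_t), wmh_degenerate = function(e) total_t)
    for (roi in rois) {
      y <- cube_root_transform(d0[[roi]])
      for (adj in adjust) {
        row <- tryCatch({
          y_t <- if (standardize_outcome) zscore(y) else y
          md <- data.frame(y = y_t, det = det_val, age = d0$age,
                           sex = d0$sex_num, site = d0$site, total = total_t)
          fit_roi_model(md, adjust_total = adj)
        }, wmh_degenerate = function(e) {
          warning(sprintf("ROI '%s' skipped (%s): %s", roi, det,
                          conditionMessage(e)), call. = FALSE)
          data.frame(B = NA_real_, SE = NA_real_, p = NA_real_,
                     n = sum(cc), method = "skipped",
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          warning(sprintf("ROI '%s' skipped (%s): %s", roi, det,
                          conditionMessage(e)), call. = FALSE)
          data.frame(B = NA_real_, SE = NA_real_, p = NA_real_,
                     n = sum(cc), method = "error",
                     stringsAsFactors = FALSE)
        })
        row <- cbind(data.frame(determinant = det, roi = roi,
                                adjusted_for_total = adj,
                                stringsAsFactors = FALSE), row)
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  res$significant <- !is.na(res$p) & res$p < thr
  res$sign <- ifelse(is.na(res$B), NA_character_,
                     ifelse(res$B >= 0, "positive", "negative"))
  rownames(res) <- NULL
  structure(res, alpha_family = alpha_family, n_tests = n_tests,
            p_threshold = thr)
}

code_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1, NA))) stop("numeric sex must be 0/1 (female = 1)",
                                         call. = FALSE)
    return(as.numeric(sex))
  }
  sx <- tolower(as.character(sex))
  bad <- setdiff(unique(sx[!is.na(sx)]), c("female", "male", "f", "m"))
  if (length(bad)) stop("unrecognised sex coding: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ifelse(is.na(sx), NA_real_, as.numeric(sx %in% c("female", "f")))
}

code_abeta <- function(abeta) {
  if (is.numeric(abeta)) {
    if (!all(abeta %in% c(0, 1, NA)))
      stop("numeric abeta must be 0/1 (positive = 1)", call. = FALSE)
    return(as.numeric(abeta))
  }
  ab <- tolower(as.character(abeta))
  bad <- setdiff(unique(ab[!is.na(ab)]), c("positive", "negative"))
  if (length(bad)) stop("unrecognised amyloid status coding: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ifelse(is.na(ab), NA_real_, as.numeric(ab == "positive"))
}

#' Sensitivity analysis: exclude one cohort
#'
#' Reruns the association suite on all subjects outside the named cohort
#' (study site), e.g. to replicate a finding independently of the cohort in
#' which it was first described.
#'
#' @inheritParams run_association_suite
#' @param cohort site/cohort identifier to exclude.
#' @param cohorts declared cohort identifiers; defaults to the sites present
#'   in `covariates`. An excluded cohort must be declared (excluding an
#'   unknown cohort is an error; excluding a declared-but-empty cohort is a
#'   no-op).
#' @param ... passed to [run_association_suite()].
#' @return result table as from [run_association_suite()].
#' @export
sensitivity_exclude_cohort <- function(volumes, covariates, cohort,
                                       cohorts = unique(covariates$site),
                                       ...) {
  if (!(cohort %in% cohorts))
    stop("unknown cohort: '", cohort, "'", call. = FALSE)
  keep <- covariates$site != cohort
  if (!any(keep))
    stop("excluding cohort '", cohort, "' leaves no subjects", call. = FALSE)
  run_association_suite(volumes, covariates[keep, , drop = FALSE], ...)
}

#' Sensitivity analysis: restrict to complete cases on both determinants
#'
#' Reruns both determinants on the subjects that have a defined VRCS *and* a
#' known amyloid status, so differences between the two main analyses cannot
#' be attributed to differences in sample composition.
#'
#' @inheritParams run_association_suite
#' @param ... passed to [run_association_suite()].
#' @return result table as from [run_association_suite()].
#' @export
sensitivity_complete_cases <- function(volumes, covariates, ...) {
  if (!all(c("vrcs", "abeta") %in% names(covariates)))
    stop("covariates need 'vrcs' and 'abeta' columns", call. = FALSE)
  keep <- !is.na(covariates$vrcs) & !is.na(covariates$abeta)
  if (!any(keep))
    stop("no subjects have both VRCS and amyloid status", call. = FALSE)
  run_association_suite(volumes, covariates[keep, , drop = FALSE], ...)
}

#' Plain-text summary of significant ROIs
#'
#' Lists, per determinant and adjustment set, the Bonferroni-significant
#' ROIs sorted by p-value, with the direction of association.
#'
#' @param results result table from [run_association_suite()].
#' @return character vector of report lines.
#' @export
significance_report <- function(results) {
  thr <- attr(results, "p_threshold")
  lines <- c("Significant ROI associations",
             sprintf("per-test threshold: p < %.6g (alpha %.3g over %d tests)",
                     thr, attr(results, "alpha_family"),
                     attr(results, "n_tests")))
  for (det in unique(results$determinant)) {
    for (adj in unique(results$adjusted_for_total)) {
      sub <- results[results$determinant == det &
                       results$adjusted_for_total == adj, , drop = FALSE]
      sub <- sub[order(sub$p), , drop = FALSE]
      lines <- c(lines, "",
                 sprintf("%s, %s total-WMH adjustment (n = %d):", det,
                         if (adj) "with" else "without", max(sub$n)))
      sig <- sub[!is.na(sub$significant) & sub$significant, , drop = FALSE]
      if (!nrow(sig)) {
        lines <- c(lines, "  (none)")
      } else {
        lines <- c(lines, sprintf("  %s: B = %.3f, SE = %.3f, p = %.3g (%s)",
                                  sig$roi, sig$B, sig$SE, sig$p, sig$sign))
      }
    }
  }
  lines
}
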