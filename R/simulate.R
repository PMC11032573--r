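#' Simulation configuration
#'
#' Describes a synthetic multi-site memory-clinic cohort and its generative
#' lesion model. For each merged ROI r the cube-root regional volume of
#' subject s follows
#' \deqn{y_{sr} = baseline_r + \beta^{age}_r age_s + \beta^{sex}_r sex_s +
#'   \beta^{vrcs}_r z(VRCS)_s + \beta^{a\beta}_r A\beta_s +
#'   loading_r (\gamma_{vrcs} z(VRCS)_s + \gamma_{a\beta} A\beta_s) +
#'   u_{site(s)} + \epsilon_{sr}}
#' with \eqn{u \sim N(0, site\_sd^2)}, \eqn{\epsilon \sim N(0, noise\_sd^2)},
#' y clamped at 0, and regional volume \eqn{y^3} mL realised as a voxel set
#' inside the ROI's block. The `gamma` terms act through a shared global
#' lesion-load factor (every ROI with nonzero `loading` receives them),
#' mimicking determinants whose regional effect is mediated by total lesion
#' burden; the `beta_vrcs`/`beta_abeta` terms are ROI-specific direct
#' effects.
#'
#' Demographics default to the multicenter memory-clinic profile the
#' simulator emulates: age ~ Normal(71.5, 9) truncated to \[40, 100\], 50%
#' female, six vascular risk indicators with literature-typical prevalences
#' and missingness, and 59% amyloid-positivity emitted as a continuous
#' CSF-like value on the correct side of the registered cutoff.
#'
#' @param n_subjects,n_sites cohort size and number of study sites.
#' @param roi_layout ROI block layout, see [default_roi_layout()]; its
#'   `grid_shape` attribute (or `grid_shape` argument) sets the grid.
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param voxel_size_mm isotropic voxel edge length in mm (default 2).
#' @param baseline,beta_age,beta_sex,beta_vrcs,beta_abeta,loading per-ROI
#'   coefficients on the cube-root-volume scale: scalar (recycled), full
#'   vector, or named vector overriding the scalar default per merged ROI.
#' @param gamma_vrcs,gamma_abeta scalar effects acting through the shared
#'   lesion-load factor.
#' @param site_sd SD of the site random intercept (>= 0).
#' @param noise_sd residual SD (> 0).
#' @param age_mean,age_sd,age_range age distribution (truncated normal).
#' @param sex_female_rate probability of female sex (coded 1).
#' @param risk_prevalence length-6 prevalences of the risk indicators.
#' @param missingness_rates length-6 per-indicator missingness probabilities.
#' @param abeta_positive_rate probability of true amyloid positivity.
#' @param amyloid_missing_rate probability that the amyloid measurement is
#'   unavailable (default 0: everyone measured).
#' @param amyloid_rule_id dichotomization rule used to emit the continuous
#'   amyloid value, see [amyloid_rules()].
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return object of class `wmh_sim_config`.
#' @export
sim_config <- function(n_subjects = 500, n_sites = 5,
                       roi_layout = default_roi_layout(),
                       grid_shape = attr(roi_layout, "grid_shape"),
                       voxel_size_mm = 2,
                       baseline = 0.1, beta_age = 0.008, beta_sex = 0.01,
                       beta_vrcs = 0, beta_abeta = 0, loading = 1,
                       gamma_vrcs = 0, gamma_abeta = 0,
                       site_sd = 0.1, noise_sd = 0.2,
                       age_mean = 71.5, age_sd = 9, age_range = c(40, 100),
                       sex_female_rate = 0.5,
                       risk_prevalence = c(0.216, 0.513, 0.490,
                                           0.204, 0.112, 0.289),
                       missingness_rates = c(0.26, 0.03, 0.29,
                                             0.24, 0.78, 0.21),
                       abeta_positive_rate = 0.59,
                       amyloid_missing_rate = 0,
                       amyloid_rule_id = "csf_elisa_640",
                       seed = 1L) {
  n_subjects <- assert_positive_int(n_subjects, "n_subjects")
  n_sites <- assert_positive_int(n_sites, "n_sites")
  if (is.null(grid_shape))
    stop("grid_shape must be given (or carried by the layout)", call. = FALSE)
  grid_shape <- vapply(grid_shape, assert_positive_int, 1L, name = "grid_shape")
  if (length(grid_shape) != 3L) stop("grid_shape must have 3 entries",
                                     call. = FALSE)
  if (length(voxel_size_mm) != 1L || voxel_size_mm <= 0)
    stop("voxel_size_mm must be a single positive value", call. = FALSE)
  validate_roi_layout(roi_layout, grid_shape)
  if (site_sd < 0) stop("site_sd must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (length(missingness_rates) != 6L ||
      any(missingness_rates < 0 | missingness_rates > 1))
    stop("missingness_rates must be six probabilities", call. = FALSE)
  if (length(risk_prevalence) != 6L ||
      any(risk_prevalence < 0 | risk_prevalence > 1))
    stop("risk_prevalence must be six probabilities", call. = FALSE)

  tab <- merge_bilateral(roi_layout[, c("name", "laterality")] |>
                           transform(raw_id = seq_len(nrow(roi_layout))))
  rois <- roi_names(tab)
  cfg <- list(
    n_subjects = n_subjects, n_sites = n_sites,
    roi_layout = roi_layout, grid_shape = grid_shape,
    voxel_size_mm = as.numeric(voxel_size_mm),
    baseline = resolve_roi_param(baseline, rois, "baseline"),
    beta_age = resolve_roi_param(beta_age, rois, "beta_age"),
    beta_sex = resolve_roi_param(beta_sex, rois, "beta_sex"),
    beta_vrcs = resolve_roi_param(beta_vrcs, rois, "beta_vrcs"),
    beta_abeta = resolve_roi_param(beta_abeta, rois, "beta_abeta"),
    loading = resolve_roi_param(loading, rois, "loading"),
    gamma_vrcs = as.numeric(gamma_vrcs), gamma_abeta = as.numeric(gamma_abeta),
    site_sd = as.numeric(site_sd), noise_sd = as.numeric(noise_sd),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    sex_female_rate = sex_female_rate,
    risk_prevalence = stats::setNames(risk_prevalence, risk_factor_names()),
    missingness_rates = stats::setNames(missingness_rates, risk_factor_names()),
    abeta_positive_rate = abeta_positive_rate,
    amyloid_missing_rate = amyloid_missing_rate,
    amyloid_rule_id = amyloid_rule_id,
    seed = as.integer(seed))
  structure(cfg, class = "wmh_sim_config")
}

resolve_roi_param <- function(value, rois, what) {
  k <- length(rois)
  if (is.null(names(value))) {
    if (!(length(value) %in% c(1L, k)))
      stop(sprintf("'%s' must be scalar or length %d", what, k), call. = FALSE)
    return(stats::setNames(rep_len(as.numeric(value), k), rois))
  }
  unknown <- setdiff(names(value), rois)
  if (length(unknown))
    stop(sprintf("'%s' names not in layout: %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  out <- stats::setNames(rep(0, k), rois)
  out[names(value)] <- as.numeric(value)
  out
}

#' @exportS3Method base::print
print.wmh_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<wmh_sim_config> n = %d subjects, %d sites, grid %s @ ",
                     "%g mm, %d raw labels -> %d merged ROIs, seed %d\n"),
              x$n_subjects, x$n_sites, paste(x$grid_shape, collapse = "x"),
              x$voxel_size_mm, nrow(x$roi_layout), length(x$baseline), x$seed))
  invisible(x)
}

#' Outcome SD implied by the nuisance terms of a simulation config
#'
#' The cube-root-scale outcome SD a null ROI would show: residual noise,
#' site heterogeneity, and the age and sex contributions,
#' `sqrt(noise_sd^2 + site_sd^2 + (beta_age * age_sd)^2 + (beta_sex/2)^2)`.
#' Useful for expressing simulated determinant effects in SD units (e.g. a
#' "0.3 SD" effect is `0.3 * baseline_outcome_sd(cfg)` on the raw scale).
#'
#' @param config a [sim_config()].
#' @return named numeric vector, one value per merged ROI.
#' @export
baseline_outcome_sd <- function(config) {
  sqrt(config$noise_sd^2 + config$site_sd^2 +
         (config$beta_age * config$age_sd)^2 + (config$beta_sex / 2)^2)
}

# deterministic substream seeds fanned out from the global seed, so each
# generator stage is reproducible independently of call order
substream_seeds <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  sample.int(2147483646L, 4L)
}

#' Build the synthetic atlas and white-matter probability map
#'
#' Renders the config's ROI layout as an integer label grid (one raw label
#' per layout row, in row order) with a merged label table, and a
#' deterministic WM probability map: high probability (0.95) inside all ROI
#' blocks, moderate (0.6) elsewhere, and below-threshold (0.1) in a
#' one-voxel rim at the grid boundary (layouts keep blocks off the boundary),
#' so WM-mask filtering has bite.
#'
#' @param config a [sim_config()].
#' @return list with `atlas` ([label_atlas()]) and `wm`
#'   ([wm_probability_map()]).
#' @export
make_synthetic_atlas <- function(config) {
  stopifnot(inherits(config, "wmh_sim_config"))
  layout <- config$roi_layout
  dims <- config$grid_shape
  labels <- array(0L, dims)
  for (i in seq_len(nrow(layout))) {
    b <- layout[i, ]
    labels[b$x0:b$x1, b$y0:b$y1, b$z0:b$z1] <- i
  }
  tab <- data.frame(raw_id = seq_len(nrow(layout)), name = layout$name,
                    laterality = layout$laterality, zone = layout$zone,
                    stringsAsFactors = FALSE)
  tab <- merge_bilateral(tab)
  atlas <- label_atlas(labels, config$voxel_size_mm, tab)

  wm <- array(0.6, dims)
  wm[c(1L, dims[1]), , ] <- 0.1
  wm[, c(1L, dims[2]), ] <- 0.1
  wm[, , c(1L, dims[3])] <- 0.1
  wm[labels > 0L] <- 0.95
  list(atlas = atlas,
       wm = wm_probability_map(wm, config$voxel_size_mm))
}

#' Simulate subject covariates for a multi-site cohort
#'
#' Draws demographics, the six tri-state vascular risk indicators, and an
#' amyloid measurement per subject. Risk indicators are generated as true
#' present/absent states and then masked to missing at the configured
#' per-indicator rates; the emitted amyloid value is a continuous CSF-like
#' (or SUVR-like) measurement lying on the correct side of the registered
#' cutoff for the subject's true status. Latent truth columns (`true_vrcs`,
#' computed from all six unmasked indicators, and `true_abeta`) are carried
#' along for ground-truth evaluation; real cohort data would not have them.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per subject: `subject_id`, `site`, `age`,
#'   `sex` (female = 1), the six indicator columns (1/0/NA), `amyloid_value`,
#'   `amyloid_modality`, `amyloid_rule_id`, `true_vrcs`, `true_abeta`.
#' @export
simulate_subjects <- function(config) {
  stopifnot(inherits(config, "wmh_sim_config"))
  s <- substream_seeds(config)
  set.seed(s[1])
  n <- config$n_subjects
  ids <- sprintf("S%05d", seq_len(n))
  site <- factor(sprintf("site%02d", rep_len(seq_len(config$n_sites), n)))
  # inverse-CDF truncated normal
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1, config$sex_female_rate)

  true_ind <- vapply(config$risk_prevalence,
                     function(p) stats::rbinom(n, 1, p), integer(n))
  if (n == 1L) true_ind <- matrix(true_ind, nrow = 1L,
                                  dimnames = list(NULL, risk_factor_names()))
  obs_ind <- true_ind
  for (j in seq_len(6L)) {
    hide <- stats::runif(n) < config$missingness_rates[j]
    obs_ind[hide, j] <- NA_integer_
  }
  true_vrcs <- compute_vrcs(true_ind)

  true_abeta <- stats::rbinom(n, 1, config$abeta_positive_rate)
  rule <- amyloid_rules()
  rule <- rule[rule$rule_id == config$amyloid_rule_id, , drop = FALSE]
  if (!nrow(rule))
    stop("unknown amyloid_rule_id: ", config$amyloid_rule_id, call. = FALSE)
  # continuous value on the correct side of the cutoff
  off_mean <- if (rule$modality == "CSF") 30 else 0.3
  off_sd <- if (rule$modality == "CSF") 10 else 0.1
  offset <- abs(stats::rnorm(n, off_mean, off_sd))
  toward_pos <- if (rule$direction == "below_is_positive") -1 else 1
  value <- rule$cutoff + ifelse(true_abeta == 1, toward_pos, -toward_pos) * offset
  # strict-< CSF rules: a negative draw landing exactly on the cutoff stays
  # negative, and values are kept positive
  value <- pmax(value, rule$cutoff * 0.01)
  hide_amy <- stats::runif(n) < config$amyloid_missing_rate
  value[hide_amy] <- NA_real_

  out <- data.frame(subject_id = ids, site = site, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(obs_ind))
  out$amyloid_value <- value
  out$amyloid_modality <- ifelse(hide_amy, NA_character_, rule$modality)
  out$amyloid_rule_id <- ifelse(hide_amy, NA_character_, rule$rule_id)
  out$true_vrcs <- true_vrcs
  out$true_abeta <- true_abeta
  out
}

#' Ground-truth regional volumes from the generative model
#'
#' Evaluates the linear model of [sim_config()] on the cube-root scale for
#' every subject and merged ROI, using the latent (unmasked) covariates,
#' clamps at zero, and cubes to millilitres. This is the continuous truth
#' that [simulate_lesions()] discretises into voxel masks; it can also be
#' analysed directly (its `total_wmh` column is the ROI sum) when voxel
#' placement is irrelevant, e.g. in estimator calibration studies.
#'
#' @param subjects table from [simulate_subjects()].
#' @param config the same [sim_config()].
#' @return data.frame: `subject_id`, `site`, one mL column per merged ROI,
#'   `total_wmh`; attribute `y` holds the cube-root-scale matrix before
#'   clamping.
#' @export
simulate_roi_volumes <- function(subjects, config) {
  stopifnot(inherits(config, "wmh_sim_config"))
  s <- substream_seeds(config)
  n <- nrow(subjects)
  rois <- names(config$baseline)
  k <- length(rois)

  set.seed(s[2])
  u_site <- stats::rnorm(config$n_sites, 0, config$site_sd)
  names(u_site) <- sprintf("site%02d", seq_len(config$n_sites))
  set.seed(s[3])
  eps <- matrix(stats::rnorm(n * k, 0, config$noise_sd), n, k)

  zv <- if (stats::sd(subjects$true_vrcs, na.rm = TRUE) %in% c(0, NA)) {
    rep(0, n)
  } else {
    z <- standardize_vrcs(subjects$true_vrcs)
    ifelse(is.na(z), 0, z)   # undefined scores contribute at the mean
  }
  ab <- subjects$true_abeta
  usub <- u_site[as.character(subjects$site)]
  usub[is.na(usub)] <- 0

  y <- matrix(0, n, k, dimnames = list(NULL, rois))
  for (j in seq_len(k)) {
    y[, j] <- config$baseline[j] + config$beta_age[j] * subjects$age +
      config$beta_sex[j] * subjects$sex + config$beta_vrcs[j] * zv +
      config$beta_abeta[j] * ab +
      config$loading[j] * (config$gamma_vrcs * zv + config$gamma_abeta * ab) +
      usub + eps[, j]
  }
  vol <- pmax(y, 0)^3
  out <- data.frame(subject_id = subjects$subject_id, site = subjects$site,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vol, check.names = FALSE))
  out$total_wmh <- rowSums(vol)
  attr(out, "y") <- y
  out
}

#' Simulate 3D lesion masks with known ground truth
#'
#' Converts the generative regional volumes into per-subject binary masks:
#' for each merged ROI the implied voxel count (volume / voxel volume,
#' rounded) is placed as a compact-ish random voxel set grown from a random
#' seed voxel inside the ROI's blocks (nearest-to-seed voxels first, ties
#' random; connectivity is not guaranteed, which is irrelevant for
#' count-based volumetry). A count exceeding the ROI's capacity is capped at
#' the ROI size; capping events are reported in one aggregated warning.
#'
#' @param subjects table from [simulate_subjects()].
#' @param atlas the atlas from [make_synthetic_atlas()] on the same config.
#' @param config the same [sim_config()].
#' @return list with `masks` (list of [lesion_mask()]), `ground_truth`
#'   (data.frame of placed volumes in mL per merged ROI + `total_wmh` —
#'   exactly the voxel counts times the voxel volume), and `target` (the
#'   continuous volumes from [simulate_roi_volumes()]).
#' @export
simulate_lesions <- function(subjects, atlas, config) {
  stopifnot(inherits(config, "wmh_sim_config"), inherits(atlas, "label_atlas"))
  target <- simulate_roi_volumes(subjects, config)
  rois <- names(config$baseline)
  vox_ml <- prod(rep_len(config$voxel_size_mm, 3)) / 1000
  dims <- dim(atlas$labels)

  tab <- atlas$label_table
  lut <- integer(max(tab$raw_id)); lut[tab$raw_id] <- tab$merged_id
  merged_grid <- array(0L, dims)
  pos <- atlas$labels > 0L
  merged_grid[pos] <- lut[atlas$labels[pos]]
  roi_vox <- lapply(seq_along(rois), function(m) which(merged_grid == m))
  roi_xyz <- lapply(roi_vox, function(ix) arrayInd(ix, dims))

  s <- substream_seeds(config)
  set.seed(s[4])
  subj_seeds <- sample.int(2147483646L, nrow(subjects))

  n_capped <- 0L
  masks <- vector("list", nrow(subjects))
  placed <- matrix(0, nrow(subjects), length(rois),
                   dimnames = list(NULL, rois))
  for (i in seq_len(nrow(subjects))) {
    set.seed(subj_seeds[i])
    mask <- array(0L, dims)
    for (m in seq_along(rois)) {
      kv <- round(target[i, rois[m]] / vox_ml)
      if (kv <= 0) next
      cap <- length(roi_vox[[m]])
      if (kv > cap) { kv <- cap; n_capped <- n_capped + 1L }
      seed_ix <- sample.int(cap, 1L)
      d2 <- rowSums(sweep(roi_xyz[[m]], 2L,
                          roi_xyz[[m]][seed_ix, ], "-")^2)
      pick <- order(d2, stats::runif(cap))[seq_len(kv)]
      mask[roi_vox[[m]][pick]] <- 1L
      placed[i, m] <- kv * vox_ml
    }
    masks[[i]] <- lesion_mask(mask, config$voxel_size_mm,
                              subjects$subject_id[i])
  }
  if (n_capped > 0L)
    warning(sprintf("%d ROI draw(s) exceeded ROI capacity and were capped",
                    n_capped), call. = FALSE)
  gt <- data.frame(subject_id = subjects$subject_id, site = subjects$site,
                   stringsAsFactors = FALSE)
  gt <- cbind(gt, as.data.frame(placed, check.names = FALSE))
  gt$total_wmh <- rowSums(placed)
  list(masks = masks, ground_truth = gt, target = target)
}
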