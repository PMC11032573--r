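#' Read and resolve an analysis configuration
#'
#' Configurations are YAML (or an equivalent named list) with the entries
#' used by the three pipeline stages:
#'
#' * `output_dir`, `seed`, `wm_threshold` (default 0.30), `alpha_family`
#'   (default 0.05)
#' * `paths`: `atlas`, `atlas_table`, `wm_map`, `mask_dir`, `covariates`,
#'   `volumes`
#' * `simulate`: arguments for [sim_config()], plus `layout`
#'   (`"default"` or `"icbm"`)
#' * `amyloid_rules`: optional list of extra dichotomization rules
#' * `sensitivity`: `exclude_cohort` (cohort id or null), `complete_cases`
#'   (flag)
#'
#' @param config path to a YAML file, or a named list.
#' @param seed optional seed overriding the configured one.
#' @return resolved config list (class `wmh_analysis_config`) with defaults
#'   filled in and a `config_hash` computed over the canonical YAML text.
#' @export
read_analysis_config <- function(config, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- list(
    output_dir = config$output_dir,
    seed = as.integer(config$seed %||% 1L),
    wm_threshold = as.numeric(config$wm_threshold %||% 0.30),
    alpha_family = as.numeric(config$alpha_family %||% 0.05),
    paths = config$paths %||% list(),
    simulate = config$simulate %||% list(),
    amyloid_rules = config$amyloid_rules,
    sensitivity = list(
      exclude_cohort = config$sensitivity$exclude_cohort,
      complete_cases = isTRUE(config$sensitivity$complete_cases)))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (cfg$wm_threshold <= 0 || cfg$wm_threshold >= 1)
    stop("wm_threshold must be in (0, 1)", call. = FALSE)
  cfg$config_hash <- md5_of_text(yaml::as.yaml(
    cfg[c("seed", "wm_threshold", "alpha_family", "paths", "simulate",
          "amyloid_rules", "sensitivity")]))
  structure(cfg, class = "wmh_analysis_config")
}

require_config_keys <- function(cfg, keys, where = "paths") {
  holder <- if (where == "paths") cfg$paths else cfg
  miss <- keys[vapply(keys, function(k) is.null(holder[[k]]), TRUE)]
  if (length(miss))
    stop("config is missing required key(s): ",
         paste(if (where == "paths") paste0("paths.", miss) else miss,
               collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

pipeline_log <- function(cfg, fmt, ...) {
  line <- sprintf(fmt, ...)
  message("[wmhregions] ", line)
  if (!is.null(cfg$output_dir)) {
    logf <- file.path(cfg$output_dir, "pipeline.log")
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line, "\n",
        sep = "", file = logf, append = TRUE)
  }
  invisible(line)
}

registered_rules <- function(cfg) {
  extra <- cfg$amyloid_rules
  if (is.null(extra) || !length(extra)) return(amyloid_rules())
  amyloid_rules(extra = do.call(rbind, lapply(extra, as.data.frame)))
}

#' Pipeline stage 1: write a synthetic dataset to disk
#'
#' Generates the synthetic atlas, WM probability map, subject covariates and
#' per-subject lesion masks defined by the config's `simulate` section, and
#' writes them in the on-disk layout the later stages consume (NIfTI grids,
#' covariate CSV, ground-truth CSV, resolved-config YAML, and a manifest
#' with a reproducibility hash).
#'
#' @param config config path or list, see [read_analysis_config()].
#' @param seed optional seed override.
#' @return invisibly, the manifest list.
#' @export
run_simulate <- function(config, seed = NULL) {
  cfg <- read_analysis_config(config, seed)
  require_config_keys(cfg, "output_dir", where = "top")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(cfg$output_dir))
    stop("cannot create output directory: ", cfg$output_dir, call. = FALSE)

  sim_args <- cfg$simulate
  layout_name <- sim_args$layout %||% "default"
  sim_args$layout <- NULL
  sim_args$roi_layout <- switch(layout_name,
    default = default_roi_layout(),
    icbm = icbm_like_layout(),
    stop("unknown layout: ", layout_name, call. = FALSE))
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)

  pipeline_log(cfg, "simulate: %d subjects, %d sites, layout '%s', seed %d",
               scfg$n_subjects, scfg$n_sites, layout_name, cfg$seed)
  synth <- make_synthetic_atlas(scfg)
  subjects <- simulate_subjects(scfg)
  les <- simulate_lesions(subjects, synth$atlas, scfg)

  out <- cfg$output_dir
  write_label_atlas(synth$atlas, file.path(out, "atlas.nii.gz"),
                    file.path(out, "atlas_labels.tsv"))
  write_wm_map(synth$wm, file.path(out, "wm_map.nii.gz"))
  mask_dir <- file.path(out, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  for (m in les$masks)
    write_lesion_mask(m, file.path(mask_dir, paste0(m$subject_id, ".nii.gz")))

  cov <- subjects
  cov$sex <- ifelse(cov$sex == 1, "female", "male")
  cov_out <- cov[, c("subject_id", "site", "age", "sex", risk_factor_names(),
                     "amyloid_value", "amyloid_modality", "amyloid_rule_id")]
  cov_path <- file.path(out, "covariates.csv")
  utils::write.csv(cov_out, cov_path, row.names = FALSE, na = "")

  gt <- les$ground_truth
  gt$true_vrcs <- subjects$true_vrcs
  gt$true_abeta <- subjects$true_abeta
  gt_path <- file.path(out, "ground_truth.csv")
  utils::write.csv(gt, gt_path, row.names = FALSE)

  resolved <- file.path(out, "resolved_config.yaml")
  yaml::write_yaml(list(seed = cfg$seed, wm_threshold = cfg$wm_threshold,
                        alpha_family = cfg$alpha_family,
                        simulate = c(cfg$simulate, list(layout = layout_name))),
                   resolved)
  manifest <- list(
    config_hash = unname(md5_of_text(c(readLines(resolved),
                                       readLines(cov_path),
                                       readLines(gt_path)))),
    seed = cfg$seed, n_subjects = scfg$n_subjects,
    n_masks = length(les$masks), layout = layout_name)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  pipeline_log(cfg, "simulate: wrote %d masks, manifest hash %s",
               manifest$n_masks, manifest$config_hash)
  invisible(manifest)
}

#' Pipeline stage 2: regional volumetry of a mask directory
#'
#' Reads the atlas, WM probability map and every lesion mask in the mask
#' directory; removes out-of-WM voxels at the configured threshold; and
#' writes the per-subject regional volume table (mL per merged ROI plus
#' total). Masks that cannot be read, are not binary, or sit on a different
#' grid are excluded and accounted for, one row per subject with a reason
#' code, in `exclusions_volumetry.csv`.
#'
#' @param config config path or list; uses `paths.atlas`,
#'   `paths.atlas_table`, `paths.wm_map`, `paths.mask_dir`, `output_dir`,
#'   `wm_threshold`.
#' @return invisibly, the volume table.
#' @export
run_volumetrize <- function(config) {
  cfg <- read_analysis_config(config)
  require_config_keys(cfg, "output_dir", where = "top")
  require_config_keys(cfg, c("atlas", "atlas_table", "wm_map", "mask_dir"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  atlas <- read_label_atlas(cfg$paths$atlas, cfg$paths$atlas_table)
  wm <- read_wm_map(cfg$paths$wm_map)
  files <- sort(list.files(cfg$paths$mask_dir, pattern = "\\.nii(\\.gz)?$",
                           full.names = TRUE))
  if (!length(files))
    stop("no NIfTI masks found in ", cfg$paths$mask_dir, call. = FALSE)

  rows <- list(); excl <- list()
  for (f in files) {
    sid <- sub("\\.nii(\\.gz)?$", "", basename(f))
    res <- tryCatch({
      m <- read_lesion_mask(f, subject_id = sid)
      m <- apply_wm_mask(m, wm, threshold = cfg$wm_threshold)
      rv <- regional_volumes(m, atlas)
      c(rv$volumes_ml, total_wmh = rv$total_ml)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reason <- if (grepl("mismatch", conditionMessage(res)))
        "grid_mismatch" else "unreadable_mask"
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = sid, stage = "volumetry", reason = reason,
        detail = conditionMessage(res), stringsAsFactors = FALSE)
      pipeline_log(cfg, "volumetrize: excluded %s (%s)", sid, reason)
    } else {
      rows[[sid]] <- res
    }
  }
  if (!length(rows))
    stop("no readable masks on the atlas grid", call. = FALSE)

  vols <- data.frame(subject_id = names(rows),
                     do.call(rbind, unname(rows)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(vols, file.path(cfg$output_dir, "volumes.csv"),
                   row.names = FALSE)
  excl_df <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(), stage = character(),
               reason = character(), detail = character())
  utils::write.csv(excl_df,
                   file.path(cfg$output_dir, "exclusions_volumetry.csv"),
                   row.names = FALSE)
  pipeline_log(cfg, "volumetrize: %d subjects volumetrized, %d excluded (hash %s)",
               nrow(vols), nrow(excl_df), cfg$config_hash)
  invisible(vols)
}

#' Pipeline stage 3: scores and per-ROI mixed-model associations
#'
#' Computes the vascular risk compound score and harmonized amyloid status
#' from the covariate CSV, joins the regional volume table, runs the full
#' association suite (both determinants, before and after total-WMH
#' adjustment, Bonferroni-controlled), and writes the results table, a
#' plain-text report (ROIs sorted by p within determinant), an exclusion
#' accounting CSV, and any requested sensitivity analyses.
#'
#' @param config config path or list; uses `paths.covariates`,
#'   `paths.volumes` (defaults to `<output_dir>/volumes.csv`), `output_dir`,
#'   `alpha_family`, `amyloid_rules`, `sensitivity`.
#' @return invisibly, the main result table.
#' @export
run_associate <- function(config) {
  cfg <- read_analysis_config(config)
  require_config_keys(cfg, "output_dir", where = "top")
  require_config_keys(cfg, "covariates")
  vol_path <- cfg$paths$volumes %||% file.path(cfg$output_dir, "volumes.csv")
  if (!file.exists(vol_path))
    stop("volume table not found: ", vol_path, call. = FALSE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  volumes <- utils::read.csv(vol_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  raw_cov <- utils::read.csv(cfg$paths$covariates, check.names = FALSE,
                             stringsAsFactors = FALSE)
  covariates <- prepare_covariates(raw_cov, rules = registered_rules(cfg))

  excl <- exclusion_accounting(covariates)
  utils::write.csv(excl,
                   file.path(cfg$output_dir, "exclusions_association.csv"),
                   row.names = FALSE)

  res <- run_association_suite(volumes, covariates,
                               alpha_family = cfg$alpha_family)
  utils::write.csv(res, file.path(cfg$output_dir, "results_main.csv"),
                   row.names = FALSE)
  report <- c(sprintf("config hash: %s", cfg$config_hash),
              significance_report(res), "",
              "subjects per model:",
              sprintf("  %s: n = %d", unique(res$determinant),
                      vapply(unique(res$determinant), function(d)
                        max(res$n[res$determinant == d]), 1L)))
  writeLines(report, file.path(cfg$output_dir, "report.txt"))
  for (d in unique(res$determinant))
    pipeline_log(cfg, "associate: %s fitted on n = %d subjects", d,
                 max(res$n[res$determinant == d]))

  if (!is.null(cfg$sensitivity$exclude_cohort)) {
    co <- cfg$sensitivity$exclude_cohort
    res_ex <- sensitivity_exclude_cohort(volumes, covariates, co,
                                         alpha_family = cfg$alpha_family)
    utils::write.csv(res_ex,
                     file.path(cfg$output_dir,
                               paste0("results_exclude_", co, ".csv")),
                     row.names = FALSE)
    pipeline_log(cfg, "associate: sensitivity run without cohort '%s'", co)
  }
  if (isTRUE(cfg$sensitivity$complete_cases)) {
    res_cc <- sensitivity_complete_cases(volumes, covariates,
                                         alpha_family = cfg$alpha_family)
    utils::write.csv(res_cc,
                     file.path(cfg$output_dir, "results_complete_cases.csv"),
                     row.names = FALSE)
    pipeline_log(cfg, "associate: complete-case sensitivity run on n = %d",
                 max(res_cc$n))
  }
  invisible(res)
}

#' Derive analysis covariates from the raw covariate table
#'
#' Computes the VRCS from the six indicator columns and the dichotomous
#' amyloid status from the (value, modality, rule_id) triplet, keeping
#' `subject_id`, `site`, `age`, `sex`.
#'
#' @param raw data.frame in the covariate CSV dialect (indicators coded
#'   1/0/empty; amyloid columns `amyloid_value`, `amyloid_modality`,
#'   `amyloid_rule_id`).
#' @param rules amyloid rule registry.
#' @return data.frame ready for [run_association_suite()].
#' @export
prepare_covariates <- function(raw, rules = amyloid_rules()) {
  req <- c("subject_id", "site", "age", "sex", risk_factor_names())
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("covariate table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- raw[, c("subject_id", "site", "age", "sex")]
  out$vrcs <- compute_vrcs(raw[, risk_factor_names()])
  if (all(c("amyloid_value", "amyloid_modality", "amyloid_rule_id") %in%
          names(raw))) {
    out$abeta <- dichotomize_amyloid(raw$amyloid_value, raw$amyloid_rule_id,
                                     raw$amyloid_modality, rules = rules)
  } else {
    out$abeta <- NA_character_
  }
  out
}

exclusion_accounting <- function(covariates) {
  rows <- list()
  add <- function(keep, analysis, reason) {
    if (any(!keep))
      rows[[length(rows) + 1L]] <<- data.frame(
        subject_id = covariates$subject_id[!keep], analysis = analysis,
        reason = reason, stringsAsFactors = FALSE)
  }
  base_ok <- !is.na(covariates$age) & !is.na(covariates$sex) &
    !is.na(covariates$site)
  add(base_ok, "both", "missing_demographics")
  add(!base_ok | !is.na(covariates$vrcs), "vrcs_z", "vrcs_undefined")
  add(!base_ok | !is.na(covariates$abeta), "abeta_status", "abeta_unavailable")
  if (!length(rows))
    return(data.frame(subject_id = character(), analysis = character(),
                      reason = character()))
  do.call(rbind, rows)
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `volumetrize` and `associate` subcommands; a
#' ready-to-run wrapper script ships at
#' `system.file("cli", "wmh-pipeline", package = "wmhregions")`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`:
#'   `<subcommand> --config <yaml> [--seed <int>] [--exclude-cohort <id>]
#'   [--complete-cases]`.
#' @return exit status, invisibly (0 on success).
#' @export
wmh_pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: wmh-pipeline {simulate|volumetrize|associate} --config <yaml> [--seed <int>] [--exclude-cohort <id>] [--complete-cases]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--exclude-cohort", type = "character",
                          dest = "exclude_cohort", default = NULL),
    optparse::make_option("--complete-cases", action = "store_true",
                          dest = "complete_cases", default = FALSE)))
  opt <- optparse::parse_args(parser, args = args[-1])
  if (is.null(opt$config)) stop(usage, call. = FALSE)
  cfg <- yaml::read_yaml(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  if (!is.null(opt$exclude_cohort))
    cfg$sensitivity$exclude_cohort <- opt$exclude_cohort
  if (isTRUE(opt$complete_cases)) cfg$sensitivity$complete_cases <- TRUE
  switch(cmd,
         simulate = run_simulate(cfg),
         volumetrize = run_volumetrize(cfg),
         associate = run_associate(cfg),
         stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
  invisible(0L)
}
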