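#' The six vascular risk indicators
#'
#' Canonical column names for the six predefined risk factors entering the
#' vascular risk compound score: current smoking, hypertension,
#' hypercholesterolemia, diabetes mellitus, obesity (BMI >= 30), and history
#' of a vascular event other than stroke.
#'
#' @return character vector of length 6.
#' @export
risk_factor_names <- function() {
  c("smoking", "hypertension", "hypercholesterolemia",
    "diabetes", "obesity", "vascular_event")
}

#' Vascular risk compound score (VRCS)
#'
#' The VRCS is the proportion of *present* risk factors among the *available*
#' ones, over the six predefined indicators, each given equal weight. To
#' guard against sparse data, the score is only defined when at least
#' `min_available` (default 3) indicators are non-missing; otherwise it is
#' `NA` and the subject is excluded from VRCS analyses.
#'
#' @param indicators either a length-6 vector or an n x 6 matrix/data.frame
#'   with values 1 (present), 0 (absent), NA (missing).
#' @param min_available minimum number of non-missing indicators (default 3).
#' @return numeric scalar (or vector of length n) in \[0, 1\], NA where
#'   undefined.
#' @examples
#' compute_vrcs(c(1, 1, 1, 0, 0, 0))        # 0.5
#' compute_vrcs(c(1, 1, 0, 0, NA, NA))      # 2/4
#' compute_vrcs(c(1, 0, NA, NA, NA, NA))    # NA: only 2 available
#' @export
compute_vrcs <- function(indicators, min_available = 3L) {
  if (is.data.frame(indicators)) indicators <- as.matrix(indicators)
  if (is.null(dim(indicators))) {
    if (length(indicators) != 6L)
      stop("expected exactly six risk indicators", call. = FALSE)
    indicators <- matrix(indicators, nrow = 1L)
  }
  if (ncol(indicators) != 6L)
    stop("expected exactly six risk indicator columns", call. = FALSE)
  vals <- indicators[!is.na(indicators)]
  if (!all(vals %in% c(0, 1)))
    stop("indicators must be 0 (absent), 1 (present) or NA (missing)",
         call. = FALSE)
  avail <- rowSums(!is.na(indicators))
  present <- rowSums(indicators == 1, na.rm = TRUE)
  out <- ifelse(avail >= min_available, present / avail, NA_real_)
  as.numeric(out)
}

#' Amyloid-beta 42 dichotomization rules
#'
#' Each cohort measures cerebral amyloid with its own assay, and positivity
#' is defined against the locally validated cutoff; harmonization to a single
#' dichotomous status is done through a registry of rules. CSF rules call a
#' value *below* the cutoff positive (strict `<`); PET rules call an SUVR
#' *at or above* the cutoff positive (`>=`).
#'
#' The default registry ships the four commonly used rules: Fujirebio
#' sandwich ELISA CSF < 640 ng/L, INNOTEST CSF < 694 pg/mL (mixture-model
#' derived), CRM-anchored mass-spectrometry CSF < 1096 pg/mL, and amyloid
#' PET SUVR >= 1.5.
#'
#' @param extra optional data.frame of additional rules with the same
#'   columns, appended to the defaults (cohorts with local norms must
#'   register a rule explicitly).
#' @return data.frame with columns `rule_id`, `modality` (`"CSF"`/`"PET"`),
#'   `cutoff`, `units`, `direction` (`"below_is_positive"` /
#'   `"at_or_above_is_positive"`).
#' @export
amyloid_rules <- function(extra = NULL) {
  rules <- data.frame(
    rule_id = c("csf_elisa_640", "csf_innotest_694", "csf_crm_1096",
                "pet_suvr_1.5"),
    modality = c("CSF", "CSF", "CSF", "PET"),
    cutoff = c(640, 694, 1096, 1.5),
    units = c("ng/L", "pg/mL", "pg/mL", "SUVR"),
    direction = c("below_is_positive", "below_is_positive",
                  "below_is_positive", "at_or_above_is_positive"),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    req <- c("rule_id", "modality", "cutoff", "direction")
    if (!all(req %in% names(extra)))
      stop("extra rules need columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    if (!("units" %in% names(extra))) extra$units <- NA_character_
    rules <- rbind(rules, extra[, names(rules)])
  }
  if (anyDuplicated(rules$rule_id))
    stop("duplicated rule_id in amyloid rule registry", call. = FALSE)
  if (any(rules$cutoff <= 0)) stop("cutoffs must be positive", call. = FALSE)
  rules
}

#' Dichotomize an amyloid measurement
#'
#' @param value measured value(s): CSF concentration or PET SUVR.
#' @param rule_id registry key(s) of the rule to apply (recycled).
#' @param modality measurement modality, `"CSF"` or `"PET"` (recycled); must
#'   match the rule's modality.
#' @param rules rule registry, see [amyloid_rules()].
#' @return character vector, `"positive"`/`"negative"` (NA in, NA out).
#' @examples
#' dichotomize_amyloid(c(639, 640), "csf_elisa_640", "CSF")
#' dichotomize_amyloid(1.5, "pet_suvr_1.5", "PET")
#' @export
dichotomize_amyloid <- function(value, rule_id, modality,
                                rules = amyloid_rules()) {
  n <- length(value)
  rule_id <- rep_len(as.character(rule_id), n)
  modality <- rep_len(as.character(modality), n)
  out <- rep(NA_character_, n)
  todo <- which(!is.na(value))
  if (!length(todo)) return(out)
  idx <- match(rule_id[todo], rules$rule_id)
  if (anyNA(idx))
    stop("unknown amyloid rule_id: ",
         paste(unique(rule_id[todo][is.na(idx)]), collapse = ", "),
         call. = FALSE)
  bad <- modality[todo] != rules$modality[idx]
  if (any(bad))
    stop(sprintf("measurement modality '%s' does not match rule '%s' (%s)",
                 modality[todo][bad][1], rule_id[todo][bad][1],
                 rules$modality[idx][bad][1]), call. = FALSE)
  cut <- rules$cutoff[idx]
  dir <- rules$direction[idx]
  pos <- ifelse(dir == "below_is_positive", value[todo] < cut,
                value[todo] >= cut)
  out[todo] <- ifelse(pos, "positive", "negative")
  out
}

#' Standardize VRCS values across cohorts
#'
#' Pooled (not per-site) z-transform of the VRCS over the analysis sample,
#' so that a one-unit effect corresponds to one pooled standard deviation of
#' vascular risk burden. Undefined scores stay NA.
#'
#' @param vrcs numeric vector of VRCS values in \[0, 1\], NA where undefined.
#' @return z-scored values (mean 0, SD 1 over the defined entries).
#' @export
standardize_vrcs <- function(vrcs) {
  def <- !is.na(vrcs)
  if (sum(def) < 2L)
    stop("need at least two defined VRCS values to standardize", call. = FALSE)
  s <- stats::sd(vrcs[def])
  if (s == 0)
    stop("VRCS has zero variance in the analysis sample", call. = FALSE)
  (vrcs - mean(vrcs[def])) / s
}
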