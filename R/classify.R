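# The two claims-based algorithms and the EHR reference standard.

#' Algorithm configuration
#'
#' Options for the claims-based severe-obesity classification and BMI
#' categorization algorithms and their sensitivity-analysis variants.
#'
#' @param severe_threshold severe-obesity cutoff: 35 (base) or 40
#'   kg/m^2.
#' @param scheme categorization scheme: "ten_level" (base),
#'   "five_level" or "four_level".
#' @param include_nonspecific expand the algorithms with nonspecific
#'   weight codes (278.xx/E66.xx)?
#' @param windows a [window_spec()].
#' @return list of class `algorithm_config`.
#' @export
algorithm_config <- function(severe_threshold = 35,
                             scheme = c("ten_level", "five_level",
                                        "four_level"),
                             include_nonspecific = FALSE,
                             windows = window_spec()) {
  if (!severe_threshold %in% c(35, 40))
    stop("`severe_threshold` must be 35 or 40")
  scheme <- match.arg(scheme)
  stopifnot(is.logical(include_nonspecific), inherits(windows, "window_spec"))
  structure(list(severe_threshold = severe_threshold, scheme = scheme,
                 include_nonspecific = include_nonspecific,
                 windows = windows),
            class = "algorithm_config")
}

#' Claims-based severe obesity classification
#'
#' TRUE iff the patient has at least one weight-related diagnosis code
#' indicating BMI at or above the threshold any time within the window
#' ("any time" semantics, not last-available). Nonspecific codes never
#' qualify under the base algorithm; with `include_nonspecific` the
#' morbid-obesity codes (278.01/E66.01) also count as indicating BMI
#' >= 35.
#'
#' @param diagnoses the patient's diagnosis records (`date`, `code`,
#'   optional `system`).
#' @param start,end window bounds (inclusive).
#' @param config an [algorithm_config()].
#' @param dictionary weight-code dictionary.
#' @return logical scalar.
#' @export
severe_obesity_claims <- function(diagnoses, start, end,
                                  config = algorithm_config(),
                                  dictionary = weight_code_table()) {
  d <- diagnoses[diagnoses$date >= start & diagnoses$date <= end, ,
                 drop = FALSE]
  if (nrow(d) == 0) return(FALSE)
  if (!all(c("class", "level") %in% names(d)))
    d <- annotate_weight_codes(d, dictionary)
  lower <- bmi_levels("ten_level")$lower
  hit <- d$class == "granular" & !is.na(d$level) &
    lower[ifelse(is.na(d$level), 1L, d$level)] >= config$severe_threshold
  if (config$include_nonspecific && config$severe_threshold == 35)
    hit <- hit | d$code %in% c("278.01", "E66.01")
  any(hit)
}

#' EHR-based severe obesity reference standard
#'
#' TRUE iff any BMI measurement in the window is at or above the
#' threshold. Returns NA (flagged: no reference data) when the patient
#' has no measurements in the window; such patients are excluded from
#' validation denominators, never counted as negatives.
#'
#' @param bmi the patient's BMI measurements (`date`, `value`).
#' @param start,end window bounds (inclusive).
#' @param threshold cutoff in kg/m^2 (35 or 40).
#' @return logical scalar, NA if no measurements in window.
#' @export
severe_obesity_ehr <- function(bmi, start, end, threshold = 35) {
  v <- bmi$value[bmi$date >= start & bmi$date <= end]
  if (length(v) == 0) return(NA)
  any(v >= threshold)
}

#' Claims-based BMI categorization
#'
#' Maps the last available weight-related diagnosis code in the window
#' to a BMI category under the configured scheme. With the base
#' (granular-only) algorithm, nonspecific codes are ignored when
#' selecting the last code. With `include_nonspecific`, nonspecific
#' codes can be the last code: under the four-level scheme they map to
#' the "obese >= 30.0" bucket; under the ten- and five-level schemes no
#' principled level assignment exists, so a nonspecific last code yields
#' NA with the `nonspecific_last` flag (keeping denominators auditable).
#'
#' @inheritParams severe_obesity_claims
#' @return one-row data.frame: `level` (coarse scheme index or NA),
#'   `code`, `code_date`, `nonspecific_last` flag; or NULL when no
#'   qualifying code exists.
#' @export
bmi_category_claims <- function(diagnoses, start, end,
                                config = algorithm_config(),
                                dictionary = weight_code_table()) {
  filter <- if (config$include_nonspecific) "any_weight_code" else
    "granular_only"
  lac <- last_available_code(diagnoses, start, end, filter, dictionary)
  if (is.null(lac)) return(NULL)
  if (lac$class == "nonspecific") {
    lvl <- if (config$scheme == "four_level") 4L else NA_integer_
    return(data.frame(level = lvl, code = lac$code, code_date = lac$date,
                      nonspecific_last = TRUE, stringsAsFactors = FALSE))
  }
  data.frame(level = coarsen_level(lac$level, config$scheme),
             code = lac$code, code_date = lac$date,
             nonspecific_last = FALSE, stringsAsFactors = FALSE)
}

#' EHR-based BMI categorization
#'
#' Bins a measured BMI value into the configured scheme. Values outside
#' the physiologic range 10-120 kg/m^2 are flagged as data-quality
#' failures and return NA (they are excluded from comparisons).
#'
#' @param value numeric BMI values (kg/m^2).
#' @param scheme category scheme.
#' @return integer level indices, NA where non-physiologic.
#' @export
bmi_category_ehr <- function(value, scheme = "ten_level") {
  lvl <- categorize_bmi(value, scheme)
  lvl[!is.na(value) & (value < 10 | value > 120)] <- NA_integer_
  lvl
}

#' Per-patient classification table
#'
#' The single input to the metrics module: one row per validated patient
#' and window with the claims-derived and reference labels. The
#' reference-standard asymmetry of the validation design is preserved:
#' preoperative comparisons (Cohort 2) use the EHR measurement most
#' proximate to the last claims code, postoperative comparisons
#' (Cohort 3) use the last available EHR measurement in the
#' postoperative window.
#'
#' @param cohorts list from [build_cohorts()] (or with elements
#'   `cohort2`, `cohort3`).
#' @param world the `claims_world`.
#' @param config an [algorithm_config()].
#' @param dictionary weight-code dictionary.
#' @return data.frame with columns `patient_id`, `window`,
#'   `claims_level`, `ref_level`, `claims_severe`, `ref_severe`,
#'   `anchor_code`, `anchor_code_date`, `ref_bmi`, `ref_bmi_date`,
#'   `nonspecific_last`, `flag`.
#' @export
classification_table <- function(cohorts, world,
                                 config = algorithm_config(),
                                 dictionary = weight_code_table()) {
  windows <- config$windows
  dx_by <- split(annotate_weight_codes(world$diagnoses, dictionary),
                 world$diagnoses$patient_id)
  bmi_by <- split(world$bmi, world$bmi$patient_id)

  run_window <- function(cohort, window) {
    n <- nrow(cohort)
    patient_id <- cohort$patient_id
    claims_level <- integer(n); ref_level <- integer(n)
    claims_severe <- rep(NA, n); ref_severe <- rep(NA, n)
    anchor_code <- character(n); anchor_code_date <- rep(as.Date(NA), n)
    ref_bmi <- numeric(n); ref_bmi_date <- rep(as.Date(NA), n)
    nonspecific_last <- logical(n); flag <- character(n)
    keep <- logical(n)
    for (i in seq_len(n)) {
      pid <- as.character(cohort$patient_id[i])
      w <- resolve_window(cohort$index_date[i], window, windows)
      dxp <- dx_by[[pid]]
      bmip <- bmi_by[[pid]]
      if (is.null(dxp) || is.null(bmip)) next
      cat_claims <- bmi_category_claims(dxp, w$start, w$end, config,
                                        dictionary)
      if (is.null(cat_claims)) next
      if (window == "preop") {
        ref <- find_proximate_bmi(bmip, cat_claims$code_date,
                                  windows$proximity_days)
        sev_c <- severe_obesity_claims(dxp, w$start, w$end, config,
                                       dictionary)
        sev_r <- severe_obesity_ehr(bmip, w$start, w$end,
                                    config$severe_threshold)
      } else {
        inwin <- bmip[bmip$date >= w$start & bmip$date <= w$end, ,
                      drop = FALSE]
        ref <- if (nrow(inwin)) {
          j <- which.max(as.integer(inwin$date))
          list(date = inwin$date[j], value = inwin$value[j])
        } else NULL
        sev_c <- NA
        sev_r <- NA
      }
      if (is.null(ref)) next
      keep[i] <- TRUE
      claims_level[i] <- cat_claims$level
      ref_level[i] <- bmi_category_ehr(ref$value, config$scheme)
      claims_severe[i] <- sev_c
      ref_severe[i] <- sev_r
      anchor_code[i] <- cat_claims$code
      anchor_code_date[i] <- cat_claims$code_date
      ref_bmi[i] <- ref$value
      ref_bmi_date[i] <- ref$date
      nonspecific_last[i] <- cat_claims$nonspecific_last
      flag[i] <- if (is.na(ref_level[i])) "nonphysiologic_reference" else
        if (cat_claims$nonspecific_last) "nonspecific_last" else ""
    }
    data.frame(
      patient_id = patient_id[keep], window = rep(window, sum(keep)),
      claims_level = claims_level[keep], ref_level = ref_level[keep],
      claims_severe = claims_severe[keep], ref_severe = ref_severe[keep],
      anchor_code = anchor_code[keep],
      anchor_code_date = anchor_code_date[keep],
      ref_bmi = ref_bmi[keep], ref_bmi_date = ref_bmi_date[keep],
      nonspecific_last = nonspecific_last[keep], flag = flag[keep],
      stringsAsFactors = FALSE
    )
  }

  out <- rbind(run_window(cohorts$cohort2, "preop"),
               run_window(cohorts$cohort3, "postop"))
  rownames(out) <- NULL
  out
}

#' Validation metrics from a classification table
#'
#' Computes, for each window present, the severe-obesity 2x2 accuracy
#' (preoperative only), the k x k agreement table, the weighted kappa
#' with confidence interval, and the per-level one-vs-rest metrics.
#'
#' @param classification output of [classification_table()].
#' @param config the [algorithm_config()] used.
#' @param weight kappa weight scheme.
#' @param ci_method "asymptotic" or "bootstrap".
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list with elements `severe` (a `confusion_2x2` or NULL) and,
#'   per window, `preop` / `postop`: list(table, kappa, per_level).
#' @export
validation_metrics <- function(classification, config = algorithm_config(),
                               weight = "linear",
                               ci_method = "asymptotic", B = 2000,
                               seed = 1) {
  k <- nrow(bmi_levels(config$scheme))
  labels <- bmi_levels(config$scheme)$label
  out <- list(severe = NULL)
  pre <- classification[classification$window == "preop", ]
  sev <- pre[!is.na(pre$claims_severe) & !is.na(pre$ref_severe), ]
  if (nrow(sev)) out$severe <- confusion_2x2(sev$claims_severe,
                                             sev$ref_severe)
  for (win in c("preop", "postop")) {
    cl <- classification[classification$window == win &
                           !is.na(classification$claims_level) &
                           !is.na(classification$ref_level), ]
    if (!nrow(cl)) next
    tab <- agreement_table(cl$claims_level, cl$ref_level, k, labels)
    out[[win]] <- list(
      table = tab,
      kappa = if (tab$n >= 2)
        kappa_ci(tab, weight = weight, method = ci_method, B = B,
                 seed = seed)
      else weighted_kappa(tab, weight),
      per_level = per_level_metrics(tab)
    )
  }
  out
}
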