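# Descriptive availability of weight-related diagnosis codes.

# per-patient mutually exclusive presence class within a window
presence_class <- function(diagnoses, start, end,
                           dictionary = weight_code_table()) {
  d <- diagnoses[diagnoses$date >= start & diagnoses$date <= end, ,
                 drop = FALSE]
  if (nrow(d) == 0) return("none")
  if (!"class" %in% names(d)) d <- annotate_weight_codes(d, dictionary)
  if (any(d$class == "granular")) return("granular")
  if (any(d$class == "nonspecific")) return("nonspecific")
  "none"
}

#' Per-patient presence class of weight-related codes
#'
#' For each cohort member, the mutually exclusive presence class within
#' the window: "granular" (>= 1 granular code, regardless of nonspecific
#' codes), "nonspecific" (nonspecific codes only) or "none".
#'
#' @inheritParams code_presence
#' @return character vector, one class per cohort row.
#' @export
presence_classes <- function(cohort, world, window = c("preop", "postop"),
                             windows = window_spec(),
                             dictionary = weight_code_table()) {
  window <- match.arg(window)
  dx_by <- split(annotate_weight_codes(world$diagnoses, dictionary),
                 world$diagnoses$patient_id)
  vapply(seq_len(nrow(cohort)), function(i) {
    w <- resolve_window(cohort$index_date[i], window, windows)
    dxp <- dx_by[[as.character(cohort$patient_id[i])]]
    if (is.null(dxp)) return("none")
    presence_class(dxp, w$start, w$end, dictionary)
  }, character(1))
}

#' Presence of weight-related codes in a cohort
#'
#' Assigns every cohort member to exactly one mutually exclusive class
#' within the window: `granular` if they have at least one granular code,
#' else `nonspecific` if they have at least one nonspecific code, else
#' `none` (precedence granular > nonspecific > none, so the three
#' percentages sum to 100). Percentages are printed to one decimal,
#' half-up.
#'
#' @param cohort a cohort membership table (needs `patient_id`,
#'   `index_date`).
#' @param world the `claims_world` (for diagnosis records).
#' @param window "preop" or "postop".
#' @param windows a [window_spec()].
#' @param dictionary weight-code dictionary.
#' @param stratum optional label describing the stratum.
#' @return one-row data.frame: stratum, window, denominator `n`, counts
#'   `n_granular`, `n_nonspecific`, `n_none`, `n_any`, and the matching
#'   `pct_*` columns (one-decimal half-up).
#' @export
code_presence <- function(cohort, world, window = c("preop", "postop"),
                          windows = window_spec(),
                          dictionary = weight_code_table(),
                          stratum = "overall") {
  window <- match.arg(window)
  cls <- presence_classes(cohort, world, window, windows, dictionary)
  n <- length(cls)
  counts <- c(granular = sum(cls == "granular"),
              nonspecific = sum(cls == "nonspecific"),
              none = sum(cls == "none"))
  pct <- if (n > 0) format_pct(counts / n) else rep(NA_real_, 3)
  data.frame(
    stratum = stratum, window = window, n = n,
    n_granular = counts[["granular"]],
    n_nonspecific = counts[["nonspecific"]],
    n_none = counts[["none"]],
    n_any = n - counts[["none"]],
    pct_granular = pct[[1]], pct_nonspecific = pct[[2]],
    pct_none = pct[[3]],
    pct_any = if (n > 0) format_pct((n - counts[["none"]]) / n) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Stratified presence of weight-related codes
#'
#' One presence summary per stratum level; stratum denominators
#' partition the cohort. Available strata: operation type (`operation`),
#' calendar year of the index operation (`year`), and coding era of the
#' index operation (`era`, boundary 2015-10-01).
#'
#' @inheritParams code_presence
#' @param strata character subset of c("operation", "year", "era").
#' @return data.frame of presence summaries, one row per stratum level,
#'   with a leading overall row.
#' @export
stratified_presence <- function(cohort, world,
                                window = c("preop", "postop"),
                                strata = c("operation", "year", "era"),
                                windows = window_spec(),
                                dictionary = weight_code_table()) {
  window <- match.arg(window)
  if (!all(strata %in% c("operation", "year", "era")))
    stop("strata must be a subset of operation/year/era")
  world$diagnoses <- annotate_weight_codes(world$diagnoses, dictionary)
  out <- list(code_presence(cohort, world, window, windows, dictionary))
  stratum_col <- c(operation = "op_type", year = "year", era = "era")
  for (s in strata) {
    col <- stratum_col[[s]]
    for (v in sort(unique(cohort[[col]]))) {
      sub <- cohort[cohort[[col]] == v, , drop = FALSE]
      out[[length(out) + 1]] <- code_presence(
        sub, world, window, windows, dictionary,
        stratum = paste0(s, "=", v))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
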