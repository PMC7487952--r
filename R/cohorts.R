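# Nested study cohorts: eligibility, exclusions, temporal anchors.

#' Temporal window specification
#'
#' Fixed-day windows anchored on the index operation date: the
#' preoperative window is `[index - preop_days, index]` (the index day
#' included), the postoperative window is `(index, index + postop_days]`
#' (index day excluded, last day included). The proximity rule requires
#' the reference BMI measurement within `proximity_days` of the
#' anchoring claims code (inclusive, both directions).
#'
#' @param preop_days look-back length in days ("6 months" = 182).
#' @param postop_days follow-up length in days ("1 year" = 365; 183 and
#'   730 are the 6-month and 2-year variants).
#' @param proximity_days proximity bound in days (default 30).
#' @return a list of class `window_spec`.
#' @export
window_spec <- function(preop_days = 182, postop_days = 365,
                        proximity_days = 30) {
  if (preop_days <= 0 || postop_days <= 0 || proximity_days < 0)
    stop("window lengths must be positive; proximity_days >= 0")
  structure(list(preop_days = as.integer(preop_days),
                 postop_days = as.integer(postop_days),
                 proximity_days = as.integer(proximity_days)),
            class = "window_spec")
}

# resolve a window to [start, end] dates for an index date
resolve_window <- function(index_date, window = c("preop", "postop"),
                           windows = window_spec()) {
  window <- match.arg(window)
  if (window == "preop") {
    list(start = index_date - windows$preop_days, end = index_date)
  } else {
    list(start = index_date + 1L, end = index_date + windows$postop_days)
  }
}

.bariatric_ops <- c("AGB", "RYGB", "SG")
# disqualifying procedure types in the preoperative period
.preop_excl_ops <- c("AGB", "RYGB", "SG", "REVISION", "OTHER_BARIATRIC")
# small built-in screening code sets (prefix match on normalized codes)
.gi_malignancy_prefixes <- c("151", "230.2", "C16")
.gi_ulcer_prefixes <- c("531", "532", "533", "534",
                        "K25", "K26", "K27", "K28")

code_has_prefix <- function(code, prefixes) {
  bare <- gsub(".", "", code, fixed = TRUE)
  pref <- gsub(".", "", prefixes, fixed = TRUE)
  Reduce(`|`, lapply(pref, function(p) startsWith(bare, p)))
}

#' Build Cohort 1 (availability cohort)
#'
#' Adults (>= 18 years at index) with a first qualifying bariatric
#' operation (AGB, RYGB or SG) in the accrual window and continuous
#' enrollment through the full preoperative window. Exclusions, applied
#' in order with a logged reason per patient: (1) no qualifying index
#' operation; (2) age < 18; (3) enrollment gap in the preoperative
#' window; (4) multiple conflicting bariatric procedure types on the
#' index day; (5) any major bariatric or revisional procedure in the
#' preoperative period before the index day; (6) gastrointestinal
#' malignancy diagnosis in the preoperative window; (7) emergency
#' department encounter on the index day; (8) gastrointestinal ulcer
#' diagnosis on the index day.
#'
#' @param world a `claims_world` (or any list with `patients`,
#'   `enrollment`, `procedures`, `diagnoses` tables of the documented
#'   schema).
#' @param windows a [window_spec()].
#' @param accrual_start,accrual_end accrual window for index operations.
#' @param enrollment_gap_days administrative enrollment gap tolerated
#'   when merging spans (default 0, strict).
#' @param malignancy_prefixes,ulcer_prefixes diagnosis-code prefixes used
#'   for the two diagnosis-based exclusions (pluggable for real data).
#' @return data.frame, one row per member: `patient_id`, `op_type`,
#'   `index_date`, `setting`, `age`, plus `year` and `era` of the index
#'   operation. The exclusion log (patient, reason) is attached as
#'   attribute `"exclusions"` and the per-rule attrition counts as
#'   attribute `"attrition"`.
#' @export
build_cohort1 <- function(world, windows = window_spec(),
                          accrual_start = as.Date("2011-01-01"),
                          accrual_end = as.Date("2018-06-30"),
                          enrollment_gap_days = 0,
                          malignancy_prefixes = .gi_malignancy_prefixes,
                          ulcer_prefixes = .gi_ulcer_prefixes) {
  check_world_schema(world)
  pr <- world$procedures
  dx <- world$diagnoses
  en <- world$enrollment
  pats <- world$patients
  pr_by <- split(pr, pr$patient_id)
  dx_by <- split(dx, dx$patient_id)
  en_by <- split(en, en$patient_id)

  excl <- list()
  note <- function(ids, reason) {
    if (length(ids))
      excl[[length(excl) + 1]] <<- data.frame(patient_id = ids,
                                              reason = reason)
  }

  # index operation: first qualifying procedure in the accrual window
  qual <- pr[pr$type %in% .bariatric_ops &
               pr$date >= accrual_start & pr$date <= accrual_end, ]
  qual <- qual[order(qual$patient_id, qual$date), ]
  first_idx <- qual[!duplicated(qual$patient_id), ]
  note(setdiff(pats$patient_id, first_idx$patient_id),
       "no_qualifying_operation")

  m <- merge(first_idx, pats, by = "patient_id")
  names(m)[names(m) == "date"] <- "index_date"

  ok_age <- m$age >= 18
  note(m$patient_id[!ok_age], "age")
  m <- m[ok_age, ]

  # continuous enrollment over the whole preoperative window
  covered <- vapply(seq_len(nrow(m)), function(i) {
    w <- resolve_window(m$index_date[i], "preop", windows)
    sp <- en_by[[as.character(m$patient_id[i])]]
    if (is.null(sp)) return(FALSE)
    spans_cover(sp, w$start, w$end, enrollment_gap_days)
  }, logical(1))
  note(m$patient_id[!covered], "enrollment")
  m <- m[covered, ]

  # conflicting bariatric procedure types on the index day
  conflict <- vapply(seq_len(nrow(m)), function(i) {
    p <- pr_by[[as.character(m$patient_id[i])]]
    sameday <- p$type[p$date == m$index_date[i] &
                        p$type %in% .bariatric_ops]
    length(unique(sameday)) > 1
  }, logical(1))
  note(m$patient_id[conflict], "conflicting_procedures")
  m <- m[!conflict, ]

  # prior bariatric / revisional procedure in the preop period
  prior <- vapply(seq_len(nrow(m)), function(i) {
    w <- resolve_window(m$index_date[i], "preop", windows)
    p <- pr_by[[as.character(m$patient_id[i])]]
    any(p$type %in% .preop_excl_ops &
          p$date >= w$start & p$date < m$index_date[i])
  }, logical(1))
  note(m$patient_id[prior], "preop_bariatric")
  m <- m[!prior, ]

  dx_flag <- function(i, prefixes, from, to) {
    d <- dx_by[[as.character(m$patient_id[i])]]
    if (is.null(d)) return(FALSE)
    d <- d[d$date >= from & d$date <= to, , drop = FALSE]
    nrow(d) > 0 && any(code_has_prefix(normalize_icd(d$code), prefixes))
  }
  malig <- vapply(seq_len(nrow(m)), function(i) {
    w <- resolve_window(m$index_date[i], "preop", windows)
    dx_flag(i, malignancy_prefixes, w$start, w$end)
  }, logical(1))
  note(m$patient_id[malig], "gi_malignancy")
  m <- m[!malig, ]

  ed <- vapply(seq_len(nrow(m)), function(i) {
    p <- pr_by[[as.character(m$patient_id[i])]]
    any(p$date == m$index_date[i] & p$setting == "emergency")
  }, logical(1))
  note(m$patient_id[ed], "ed_index_day")
  m <- m[!ed, ]

  ulcer <- vapply(seq_len(nrow(m)), function(i) {
    dx_flag(i, ulcer_prefixes, m$index_date[i], m$index_date[i])
  }, logical(1))
  note(m$patient_id[ulcer], "ulcer_index_day")
  m <- m[!ulcer, ]

  out <- data.frame(
    patient_id = m$patient_id,
    op_type = m$type,
    index_date = m$index_date,
    setting = m$setting,
    age = m$age,
    stringsAsFactors = FALSE
  )
  out$year <- as.integer(format(out$index_date, "%Y"))
  out$era <- ifelse(out$index_date >= icd10_switch_date(),
                    "ICD10CM", "ICD9CM")
  rownames(out) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(patient_id = integer(0), reason = character(0))
  attr(out, "exclusions") <- exclusions
  attr(out, "attrition") <- as.data.frame(table(reason = exclusions$reason),
                                          stringsAsFactors = FALSE)
  out
}

check_world_schema <- function(world) {
  need <- list(patients = c("patient_id", "age"),
               enrollment = c("patient_id", "start", "end"),
               procedures = c("patient_id", "date", "type", "setting"),
               diagnoses = c("patient_id", "date", "code"))
  for (nm in names(need)) {
    if (is.null(world[[nm]]))
      stop("world is missing the `", nm, "` table")
    missing_cols <- setdiff(need[[nm]], names(world[[nm]]))
    if (length(missing_cols))
      stop("table `", nm, "` lacks columns: ",
           paste(missing_cols, collapse = ", "))
  }
  en <- world$enrollment
  if (nrow(en) > 1) {
    en <- en[order(en$patient_id, en$start), ]
    same <- en$patient_id[-1] == en$patient_id[-nrow(en)]
    overlap <- en$start[-1] <= en$end[-nrow(en)]
    if (any(same & overlap))
      stop("overlapping enrollment spans")
  }
  invisible(TRUE)
}

# does the patient's span set cover [start, end] allowing gaps <= gap days?
spans_cover <- function(spans, start, end, gap = 0) {
  if (nrow(spans) == 0) return(FALSE)
  spans <- spans[order(spans$start), ]
  cur_start <- spans$start[1]
  cur_end <- spans$end[1]
  merged <- list()
  if (nrow(spans) > 1) {
    for (i in 2:nrow(spans)) {
      if (as.integer(spans$start[i] - cur_end) - 1L <= gap) {
        cur_end <- max(cur_end, spans$end[i])
      } else {
        merged[[length(merged) + 1]] <- c(cur_start, cur_end)
        cur_start <- spans$start[i]
        cur_end <- spans$end[i]
      }
    }
  }
  merged[[length(merged) + 1]] <- c(cur_start, cur_end)
  any(vapply(merged, function(sp) sp[1] <= start && sp[2] >= end,
             logical(1)))
}

#' Last available weight-related diagnosis code in a window
#'
#' Returns the weight-related diagnosis record with maximal service date
#' within the window, under a granularity filter. Same-day ties at the
#' last date are resolved deterministically: a granular code beats a
#' nonspecific one, and among granular codes the highest BMI category
#' wins (near-threshold up-coding makes the higher code the one that
#' drives authorization); ties are flagged in the `tie` column.
#'
#' @param diagnoses diagnosis records for one patient (columns
#'   `date`, `code`; `system` inferred from date if absent).
#' @param start,end window bounds (Dates, inclusive).
#' @param filter "granular_only", "any_weight_code" or
#'   "with_nonspecific" (the latter two are equivalent: all weight codes
#'   qualify).
#' @param dictionary weight-code dictionary.
#' @return a one-row data.frame (`date`, `code`, `system`, `class`,
#'   `level`, `tie`) or NULL when no qualifying code exists.
#' @export
last_available_code <- function(diagnoses, start, end,
                                filter = c("granular_only",
                                           "any_weight_code",
                                           "with_nonspecific"),
                                dictionary = weight_code_table()) {
  filter <- match.arg(filter)
  d <- diagnoses[diagnoses$date >= start & diagnoses$date <= end, ,
                 drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  if (!all(c("class", "level") %in% names(d)))
    d <- annotate_weight_codes(d, dictionary)
  keep <- if (filter == "granular_only") d$class == "granular" else
    d$class %in% c("granular", "nonspecific")
  if (!any(keep)) return(NULL)
  d <- d[keep, , drop = FALSE]
  last <- d$date == max(d$date)
  d <- d[last, , drop = FALSE]
  tie <- nrow(d) > 1 && length(unique(d$code)) > 1
  # granular beats nonspecific; among granular, highest category wins
  rank <- ifelse(d$class == "granular",
                 1000 + ifelse(is.na(d$level), 0, d$level), 0)
  j <- which.max(rank)
  data.frame(date = d$date[j], code = d$code[j], system = d$system[j],
             class = d$class[j], level = d$level[j], tie = tie,
             stringsAsFactors = FALSE)
}

#' Most proximate BMI measurement to an anchoring code
#'
#' Returns the EHR BMI measurement minimizing the absolute distance to
#' the anchor date, within `proximity_days` (inclusive). Equidistant
#' before/after ties choose the earlier measurement (in clinical
#' workflow the measurement precedes the coding).
#'
#' @param bmi BMI measurements for one patient (columns `date`,
#'   `value`).
#' @param anchor_date the anchoring diagnosis date.
#' @param proximity_days proximity bound (inclusive).
#' @param within optional list(start, end): additionally require the
#'   measurement itself to fall inside this window.
#' @return one-row data.frame (`date`, `value`, `distance`) or NULL.
#' @export
find_proximate_bmi <- function(bmi, anchor_date, proximity_days = 30,
                               within = NULL) {
  d <- bmi
  if (!is.null(within))
    d <- d[d$date >= within$start & d$date <= within$end, , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  dist <- as.integer(d$date - anchor_date)
  ok <- abs(dist) <= proximity_days
  if (!any(ok)) return(NULL)
  d <- d[ok, , drop = FALSE]
  dist <- dist[ok]
  best <- abs(dist) == min(abs(dist))
  # equidistant tie: earlier measurement
  j <- which(best)[which.min(dist[best])]
  data.frame(date = d$date[j], value = d$value[j], distance = dist[j])
}

#' Build Cohort 2 (preoperative validation cohort)
#'
#' Cohort 1 members whose last available preoperative weight-related
#' diagnosis code is granular and who have an EHR BMI measurement within
#' the proximity bound of that code. The anchoring code and measurement
#' are stored on the membership row.
#'
#' @param cohort1 output of [build_cohort1()].
#' @param world the `claims_world` (for `diagnoses` and `bmi`).
#' @param windows a [window_spec()].
#' @param dictionary weight-code dictionary.
#' @return data.frame of tier-2 memberships with anchor columns
#'   `last_preop_code`, `last_preop_code_date`, `last_preop_level`,
#'   `anchor_preop_bmi`, `anchor_preop_bmi_date`.
#' @export
build_cohort2 <- function(cohort1, world, windows = window_spec(),
                          dictionary = weight_code_table()) {
  anchors <- window_anchors(cohort1, world, "preop", windows, dictionary,
                            bmi_within_window = FALSE)
  out <- cbind(cohort1[anchors$keep, , drop = FALSE],
               data.frame(last_preop_code = anchors$code,
                          last_preop_code_date = anchors$code_date,
                          last_preop_level = anchors$level,
                          anchor_preop_bmi = anchors$bmi,
                          anchor_preop_bmi_date = anchors$bmi_date,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# shared anchor-selection engine for cohorts 2 and 3: last weight code
# must be granular and a proximate BMI measurement must exist
window_anchors <- function(cohort, world, window, windows, dictionary,
                           bmi_within_window) {
  n <- nrow(cohort)
  dx_by <- split(annotate_weight_codes(world$diagnoses, dictionary),
                 world$diagnoses$patient_id)
  bmi_by <- split(world$bmi, world$bmi$patient_id)
  keep <- logical(n)
  code <- character(n); code_date <- rep(as.Date(NA), n)
  level <- integer(n); bmi <- numeric(n); bmi_date <- rep(as.Date(NA), n)
  for (i in seq_len(n)) {
    pid <- as.character(cohort$patient_id[i])
    w <- resolve_window(cohort$index_date[i], window, windows)
    dxp <- dx_by[[pid]]
    if (is.null(dxp)) next
    lac <- last_available_code(dxp, w$start, w$end, "any_weight_code",
                               dictionary)
    if (is.null(lac) || lac$class != "granular") next
    bmip <- bmi_by[[pid]]
    if (is.null(bmip)) next
    pb <- find_proximate_bmi(bmip, lac$date, windows$proximity_days,
                             within = if (bmi_within_window) w else NULL)
    if (is.null(pb)) next
    keep[i] <- TRUE
    code[i] <- lac$code; code_date[i] <- lac$date; level[i] <- lac$level
    bmi[i] <- pb$value; bmi_date[i] <- pb$date
  }
  list(keep = keep, code = code[keep], code_date = code_date[keep],
       level = level[keep], bmi = bmi[keep], bmi_date = bmi_date[keep])
}

#' Build Cohort 3 (postoperative validation cohort)
#'
#' Cohort 2 members whose last available postoperative weight-related
#' diagnosis code is granular, with an EHR BMI measurement that is both
#' within the proximity bound of that code and inside the postoperative
#' window.
#'
#' @param cohort2 output of [build_cohort2()].
#' @param world the `claims_world`.
#' @param windows a [window_spec()].
#' @param dictionary weight-code dictionary.
#' @return data.frame of tier-3 memberships with additional anchor
#'   columns `last_postop_code`, `last_postop_code_date`,
#'   `last_postop_level`, `anchor_postop_bmi`, `anchor_postop_bmi_date`.
#' @export
build_cohort3 <- function(cohort2, world, windows = window_spec(),
                          dictionary = weight_code_table()) {
  anchors <- window_anchors(cohort2, world, "postop", windows, dictionary,
                            bmi_within_window = TRUE)
  out <- cbind(cohort2[anchors$keep, , drop = FALSE],
               data.frame(last_postop_code = anchors$code,
                          last_postop_code_date = anchors$code_date,
                          last_postop_level = anchors$level,
                          anchor_postop_bmi = anchors$bmi,
                          anchor_postop_bmi_date = anchors$bmi_date,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Build all three nested cohorts
#'
#' @param world a `claims_world`.
#' @param windows a [window_spec()].
#' @param ... passed to [build_cohort1()].
#' @return list with elements `cohort1`, `cohort2`, `cohort3`.
#' @export
build_cohorts <- function(world, windows = window_spec(), ...) {
  c1 <- build_cohort1(world, windows, ...)
  c2 <- build_cohort2(c1, world, windows)
  c3 <- build_cohort3(c2, world, windows)
  list(cohort1 = c1, cohort2 = c2, cohort3 = c3)
}
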