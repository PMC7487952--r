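# Weight-related diagnosis code dictionaries and BMI category schemes.

# package-local cache for the loaded dictionary
.bariclaims_env <- new.env(parent = emptyenv())

#' BMI category schemes
#'
#' The ordered BMI bins used by the categorization algorithm. The full
#' ten-level scheme bins BMI (kg/m^2) into <20.0, \[20,25), \[25,30),
#' \[30,35), \[35,40), \[40,45), \[45,50), \[50,60), \[60,70) and >=70.
#' The five-level and four-level schemes are order-preserving coarsenings
#' of the ten-level scheme (the four-level scheme is the classical
#' underweight / normal / overweight / obese split).
#'
#' Intervals are half-open \code{[lower, upper)}: a printed label such as
#' "30.0-34.9" means 30.0 <= BMI < 35.0, so a measured 34.95 falls in
#' that bin and there are no gaps between labels.
#'
#' @param scheme one of "ten_level", "five_level", "four_level".
#' @return a data.frame with columns \code{level} (1-based ordinal index),
#'   \code{lower} (inclusive bound, kg/m^2), \code{upper} (exclusive bound,
#'   \code{Inf} for the top bin) and \code{label}.
#' @export
#' @examples
#' bmi_levels("ten_level")
bmi_levels <- function(scheme = c("ten_level", "five_level", "four_level")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    ten_level = data.frame(
      level = 1:10,
      lower = c(-Inf, 20, 25, 30, 35, 40, 45, 50, 60, 70),
      upper = c(20, 25, 30, 35, 40, 45, 50, 60, 70, Inf),
      label = c("<=19.9", "20.0-24.9", "25.0-29.9", "30.0-34.9",
                "35.0-39.9", "40.0-44.9", "45.0-49.9", "50.0-59.9",
                "60.0-69.9", ">=70.0")
    ),
    five_level = data.frame(
      level = 1:5,
      lower = c(-Inf, 30, 40, 50, 60),
      upper = c(30, 40, 50, 60, Inf),
      label = c("<=29.9", "30.0-39.9", "40.0-49.9", "50.0-59.9", ">=60.0")
    ),
    four_level = data.frame(
      level = 1:4,
      lower = c(-Inf, 20, 25, 30),
      upper = c(20, 25, 30, Inf),
      label = c("underweight <=19.9", "normal 20.0-24.9",
                "overweight 25.0-29.9", "obese >=30.0")
    )
  )
}

# fine-to-coarse level maps; positions are ten-level indices 1..10
.coarse_map <- list(
  five_level = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 5L, 5L),
  four_level = c(1L, 2L, 3L, 4L, 4L, 4L, 4L, 4L, 4L, 4L)
)

#' Coarsen ten-level BMI categories
#'
#' Maps ten-level category indices onto the five-level or four-level
#' scheme. The merge is surjective and order preserving; each coarse
#' bin's bounds equal the min/max of the merged fine bins.
#'
#' @param level integer vector of ten-level indices (1..10); NA passes
#'   through.
#' @param scheme "ten_level" (identity), "five_level" or "four_level".
#' @return integer vector of coarse level indices.
#' @export
coarsen_level <- function(level,
                          scheme = c("ten_level", "five_level", "four_level")) {
  scheme <- match.arg(scheme)
  if (!is.numeric(level)) stop("`level` must be numeric (ten-level indices)")
  lev <- as.integer(level)
  bad <- !is.na(lev) & (lev < 1L | lev > 10L)
  if (any(bad)) stop("ten-level indices must lie in 1..10")
  if (scheme == "ten_level") return(lev)
  .coarse_map[[scheme]][lev]
}

#' Bin a BMI value into a category scheme
#'
#' @param value numeric BMI values (kg/m^2).
#' @param scheme category scheme (see [bmi_levels()]).
#' @return integer level indices (NA for NA input).
#' @export
#' @examples
#' categorize_bmi(c(19.99, 35, 44.8))  # 1, 5, 6
categorize_bmi <- function(value,
                           scheme = c("ten_level", "five_level", "four_level")) {
  scheme <- match.arg(scheme)
  lv <- bmi_levels(scheme)
  # half-open [lower, upper): findInterval on lower bounds does exactly this
  idx <- findInterval(value, lv$lower[-1]) + 1L
  idx[is.na(value)] <- NA_integer_
  as.integer(idx)
}

#' Normalize an ICD diagnosis code string
#'
#' Accepts dotted and undotted forms ("Z6841" and "Z68.41" are
#' equivalent), case-insensitively, and normalizes to dotted uppercase
#' (decimal point after the third character, the ICD convention for both
#' ICD-9-CM and ICD-10-CM).
#'
#' @param code character vector of code strings.
#' @return normalized character vector.
#' @export
normalize_icd <- function(code) {
  if (!is.character(code)) stop("`code` must be a character vector")
  x <- toupper(trimws(code))
  if (any(is.na(x) | x == "")) stop("empty or missing diagnosis code")
  if (any(!grepl("^[A-Z0-9]{1,3}(\\.?[A-Z0-9]{0,4})$", x)))
    stop("malformed diagnosis code: ",
         paste(utils::head(x[!grepl("^[A-Z0-9]{1,3}(\\.?[A-Z0-9]{0,4})$", x)], 3),
               collapse = ", "))
  bare <- gsub(".", "", x, fixed = TRUE)
  ifelse(nchar(bare) > 3L,
         paste0(substr(bare, 1L, 3L), ".", substring(bare, 4L)),
         bare)
}

#' Load the weight-related code dictionary
#'
#' The dictionary ships as a plain-text table (one row per code: code,
#' coding system, granularity class, BMI level label) so that users can
#' audit it, and can be extended with additional rows (e.g. local
#' nonspecific codes) via `extra`.
#'
#' @param path optional path to a dictionary TSV; defaults to the table
#'   shipped with the package.
#' @param extra optional data.frame of additional rows with the same
#'   columns (`code`, `system`, `granularity`, `level_label`).
#' @return data.frame with columns code, system, granularity, level
#'   (ten-level index; NA for nonspecific codes) and level_label.
#' @export
weight_code_table <- function(path = NULL, extra = NULL) {
  if (is.null(path) && is.null(extra) &&
      !is.null(.bariclaims_env$dict)) {
    return(.bariclaims_env$dict)
  }
  if (is.null(path)) {
    path <- system.file("extdata", "weight_codes.tsv", package = "bariclaims")
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(extra)) d <- rbind(d, extra[names(d)])
  need <- c("code", "system", "granularity", "level_label")
  if (!all(need %in% names(d))) stop("dictionary must have columns: ",
                                     paste(need, collapse = ", "))
  if (!all(d$system %in% c("ICD9CM", "ICD10CM")))
    stop("dictionary `system` must be ICD9CM or ICD10CM")
  if (!all(d$granularity %in% c("granular", "nonspecific")))
    stop("dictionary `granularity` must be granular or nonspecific")
  d$code <- normalize_icd(d$code)
  if (anyDuplicated(d[c("code", "system")]))
    stop("duplicate code/system rows in dictionary")
  lv <- bmi_levels("ten_level")
  d$level <- lv$level[match(d$level_label, lv$label)]
  if (any(d$granularity == "granular" & is.na(d$level)))
    stop("every granular code needs a valid ten-level label")
  if (is.null(path) || path == system.file("extdata", "weight_codes.tsv",
                                           package = "bariclaims")) {
    if (is.null(extra)) .bariclaims_env$dict <- d
  }
  d
}

#' Classify a diagnosis code against the weight-code dictionary
#'
#' Deterministically classifies each code as `granular` (with its
#' ten-level BMI category), `nonspecific` (obesity status without a
#' narrow BMI range), or `not_weight_related`. Unknown codes are never an
#' error: they are simply not weight related.
#'
#' @param code character vector of ICD codes (dotted or undotted).
#' @param system "ICD9CM" or "ICD10CM" (scalar or vector matching `code`).
#' @param dictionary dictionary table, defaults to [weight_code_table()].
#' @return data.frame with columns `code` (normalized), `system`,
#'   `class` (granular / nonspecific / not_weight_related) and `level`
#'   (ten-level index, NA unless granular).
#' @export
#' @examples
#' map_weight_code("Z68.41", "ICD10CM")   # granular, level 6 (40.0-44.9)
#' map_weight_code("E66.9", "ICD10CM")    # nonspecific
#' map_weight_code("I10", "ICD10CM")      # not weight related
map_weight_code <- function(code, system, dictionary = weight_code_table()) {
  code <- normalize_icd(code)
  system <- match_system(system, length(code))
  key <- paste(code, system)
  dkey <- paste(dictionary$code, dictionary$system)
  i <- match(key, dkey)
  data.frame(
    code = code,
    system = system,
    class = ifelse(is.na(i), "not_weight_related", dictionary$granularity[i]),
    level = ifelse(is.na(i), NA_integer_, dictionary$level[i]),
    stringsAsFactors = FALSE
  )
}

# annotate a diagnosis table once with normalized code, system, class and
# ten-level category; downstream per-patient operations then skip mapping
annotate_weight_codes <- function(diagnoses,
                                  dictionary = weight_code_table()) {
  if (all(c("system", "class", "level") %in% names(diagnoses)))
    return(diagnoses)
  if (nrow(diagnoses) == 0) {
    diagnoses$system <- character(0)
    diagnoses$class <- character(0)
    diagnoses$level <- integer(0)
    return(diagnoses)
  }
  sys <- if ("system" %in% names(diagnoses)) diagnoses$system else
    icd_system_for_date(diagnoses$date)
  m <- map_weight_code(diagnoses$code, sys, dictionary)
  diagnoses$code <- m$code
  diagnoses$system <- m$system
  diagnoses$class <- m$class
  diagnoses$level <- m$level
  diagnoses
}

match_system <- function(system, n) {
  if (!all(system %in% c("ICD9CM", "ICD10CM")))
    stop("`system` must be ICD9CM or ICD10CM")
  rep_len(as.character(system), n)
}

#' Does a code indicate BMI at or above a threshold?
#'
#' TRUE iff the code is granular and the lower bound of its BMI category
#' is at or above the threshold. Nonspecific codes (e.g. 278.01/E66.01
#' "morbid obesity") never qualify under the base algorithm.
#'
#' @param code,system as in [map_weight_code()].
#' @param threshold severe-obesity cutoff, 35 (default) or 40 kg/m^2.
#' @param dictionary dictionary table.
#' @return logical vector.
#' @export
#' @examples
#' indicates_bmi_at_least("V85.35", "ICD9CM", 35)   # TRUE
#' indicates_bmi_at_least("Z68.34", "ICD10CM", 35)  # FALSE
indicates_bmi_at_least <- function(code, system, threshold = 35,
                                   dictionary = weight_code_table()) {
  if (!threshold %in% c(35, 40)) stop("`threshold` must be 35 or 40")
  m <- map_weight_code(code, system, dictionary)
  lv <- bmi_levels("ten_level")
  !is.na(m$level) & lv$lower[m$level] >= threshold
}

#' Coding system in effect on a service date
#'
#' ICD-9-CM before 2015-10-01, ICD-10-CM on or after.
#'
#' @param date a Date vector.
#' @return character vector "ICD9CM"/"ICD10CM".
#' @export
icd_system_for_date <- function(date) {
  date <- as.Date(date)
  ifelse(date >= icd10_switch_date(), "ICD10CM", "ICD9CM")
}

#' @rdname icd_system_for_date
#' @export
icd10_switch_date <- function() as.Date("2015-10-01")

#' Label for a category level
#'
#' @param level integer level indices.
#' @param scheme category scheme.
#' @return character labels (NA preserved).
#' @export
level_label <- function(level, scheme = "ten_level") {
  bmi_levels(scheme)$label[level]
}
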