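# Shared fixture builders: hand-built mini worlds and generator configs.

# assemble a claims_world-shaped list from compact per-table specs
mk_world <- function(patients, procedures, diagnoses = NULL, bmi = NULL,
                     enrollment = NULL) {
  if (is.null(enrollment)) {
    # default: full coverage around each patient's first procedure
    first <- procedures[!duplicated(procedures$patient_id), ]
    enrollment <- data.frame(patient_id = first$patient_id,
                             start = first$date - 240,
                             end = first$date + 730)
  }
  if (is.null(diagnoses))
    diagnoses <- data.frame(patient_id = integer(0),
                            date = as.Date(character(0)),
                            code = character(0))
  if (is.null(bmi))
    bmi <- data.frame(patient_id = integer(0),
                      date = as.Date(character(0)),
                      value = numeric(0))
  structure(list(patients = patients, enrollment = enrollment,
                 procedures = procedures, diagnoses = diagnoses,
                 bmi = bmi, truth = NULL),
            class = "claims_world")
}

pat <- function(id, age = 45) data.frame(patient_id = id, age = age,
                                         sex = "F", ehr_linked = TRUE)

proc <- function(id, date, type = "SG", setting = "inpatient")
  data.frame(patient_id = id, date = as.Date(date), type = type,
             setting = setting, stringsAsFactors = FALSE)

dx <- function(id, date, code)
  data.frame(patient_id = id, date = as.Date(date), code = code,
             stringsAsFactors = FALSE)

vital <- function(id, date, value)
  data.frame(patient_id = id, date = as.Date(date), value = value)

# a zero-noise, identity-kernel, fully coded and fully linked generator
perfect_config <- function(n, seed = 1, ...) {
  generator_config(
    n_patients = n, seed = seed,
    fidelity_kernel = diag(10),
    upcode_at_35 = 0,
    ehr_noise_sd = 0,
    p_any_code_preop = 1, p_granular_given_code_preop = 1,
    p_any_code_postop = 1, p_granular_given_code_postop = 1,
    p_ehr_linked = 1, p_bmi_at_encounter = 1,
    ...
  )
}

# ten-patient fixture exercising every Cohort-1 exclusion rule and the
# Cohort-2/3 anchor rules; hand-enumerated expectation:
#   cohort1 = {1, 9, 10}; cohort2 = {1, 10}; cohort3 = {1}
cohort_rule_fixture <- function() {
  d0 <- as.Date("2014-06-01")  # ICD-9-CM era: V85.x / 278.xx / 531.x codes
  patients <- do.call(rbind, list(
    pat(1), pat(2, age = 17), pat(3), pat(4), pat(5), pat(6), pat(7),
    pat(8), pat(9), pat(10)))
  procedures <- do.call(rbind, list(
    proc(1, d0),
    proc(2, d0),
    proc(3, d0),
    proc(4, d0, "SG"), proc(4, d0, "RYGB"),      # conflicting same-day ops
    proc(5, d0), proc(5, d0 - 50, "REVISION"),   # revision in preop period
    proc(6, d0),
    proc(7, d0), proc(7, d0, "OTHER", setting = "emergency"),  # ED visit
    proc(8, d0),
    proc(9, d0),
    proc(10, d0)))
  enrollment <- data.frame(
    patient_id = 1:10,
    start = c(rep(d0 - 240, 2), d0 - 100, rep(d0 - 240, 7)),  # 3: gap
    end = rep(d0 + 730, 10))
  diagnoses <- do.call(rbind, list(
    dx(1, d0 - 10, "V85.41"),      # last preop code, granular
    dx(1, d0 + 100, "V85.42"),     # last postop code, granular
    dx(6, d0 - 30, "151.0"),       # gastric malignancy in preop window
    dx(8, d0, "531.30"),           # gastric ulcer on index day
    dx(9, d0 - 20, "V85.41"),
    dx(9, d0 - 5, "278.00"),       # last preop code nonspecific
    dx(10, d0 - 10, "V85.43"),
    dx(10, d0 + 360, "V85.42")))   # postop code near end of window
  bmi <- do.call(rbind, list(
    vital(1, d0 - 15, 43.0),       # 5 d from preop anchor code
    vital(1, d0 + 110, 46.2),      # 10 d from postop anchor code
    vital(9, d0 - 20, 41.0),
    vital(10, d0 - 12, 51.0),      # 2 d from preop anchor code
    vital(10, d0 + 400, 40.0)))    # 40 d from postop code, outside window
  mk_world(patients, procedures, diagnoses, bmi, enrollment)
}

# independent naive double-loop weighted kappa (test oracle)
kappa_naive <- function(O, weight = "linear") {
  k <- nrow(O)
  n <- sum(O)
  W <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k) {
    d <- abs(i - j) / (k - 1)
    W[i, j] <- if (weight == "linear") 1 - d else 1 - d^2
  }
  po <- 0
  pe <- 0
  for (i in 1:k) for (j in 1:k) {
    po <- po + W[i, j] * O[i, j] / n
    pe <- pe + W[i, j] * sum(O[i, ]) * sum(O[, j]) / n^2
  }
  (po - pe) / (1 - pe)
}

# random k x k count table with at least two occupied marginal levels
random_table <- function(k, n) {
  p <- stats::runif(k * k)
  O <- matrix(stats::rmultinom(1, n, p / sum(p)), k, k)
  if (sum(O > 0) < 2) O[1, min(2, k)] <- O[1, min(2, k)] + 1
  O
}

as_agreement <- function(O) {
  k <- nrow(O)
  pairs <- which(O > 0, arr.ind = TRUE)
  claims <- rep(pairs[, 1], O[pairs])
  ref <- rep(pairs[, 2], O[pairs])
  agreement_table(claims, ref, k)
}
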