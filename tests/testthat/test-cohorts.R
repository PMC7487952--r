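# Cohort construction: eligibility, exclusions, temporal anchors.

test_that("the hand-built fixture yields the enumerated memberships", {
  w <- cohort_rule_fixture()
  c1 <- build_cohort1(w)
  expect_setequal(c1$patient_id, c(1, 9, 10))
  ex <- attr(c1, "exclusions")
  reason_of <- function(id) ex$reason[ex$patient_id == id]
  expect_equal(reason_of(2), "age")
  expect_equal(reason_of(3), "enrollment")
  expect_equal(reason_of(4), "conflicting_procedures")
  expect_equal(reason_of(5), "preop_bariatric")
  expect_equal(reason_of(6), "gi_malignancy")
  expect_equal(reason_of(7), "ed_index_day")
  expect_equal(reason_of(8), "ulcer_index_day")
  c2 <- build_cohort2(c1, w)
  expect_setequal(c2$patient_id, c(1, 10))
  expect_equal(c2$last_preop_code[c2$patient_id == 1], "V85.41")
  expect_equal(c2$anchor_preop_bmi[c2$patient_id == 1], 43.0)
  c3 <- build_cohort3(c2, w)
  expect_equal(c3$patient_id, 1)
  expect_equal(c3$last_postop_code, "V85.42")
})

test_that("schema violations and overlapping enrollment are input errors", {
  w <- cohort_rule_fixture()
  w_bad <- w
  w_bad$procedures$type <- NULL
  expect_error(build_cohort1(w_bad), "lacks columns")
  w_ov <- w
  w_ov$enrollment <- rbind(
    w_ov$enrollment,
    data.frame(patient_id = 1,
               start = w$enrollment$start[1] + 5,
               end = w$enrollment$end[1]))
  expect_error(build_cohort1(w_ov), "overlapping")
})

test_that("last_available_code selects max date with deterministic ties", {
  d0 <- as.Date("2016-05-01")
  codes <- dx(1, c(d0 - 90, d0 - 10), c("Z68.41", "Z68.42"))
  lac <- last_available_code(codes, d0 - 182, d0)
  expect_equal(lac$code, "Z68.42")
  # a single nonspecific code is invisible under granular_only
  ns <- dx(1, d0 - 5, "E66.9")
  expect_null(last_available_code(ns, d0 - 182, d0, "granular_only"))
  expect_equal(last_available_code(ns, d0 - 182, d0,
                                   "any_weight_code")$class,
               "nonspecific")
  # same-day granular tie: higher category wins, tie flagged
  tie <- dx(1, c(d0 - 3, d0 - 3), c("Z68.41", "Z68.42"))
  lac <- last_available_code(tie, d0 - 182, d0)
  expect_equal(lac$code, "Z68.42")
  expect_true(lac$tie)
  # same-day granular vs nonspecific: granular wins
  gvn <- dx(1, c(d0 - 3, d0 - 3), c("E66.01", "Z68.34"))
  expect_equal(last_available_code(gvn, d0 - 182, d0,
                                   "any_weight_code")$code, "Z68.34")
  # non-weight codes never qualify
  expect_null(last_available_code(dx(1, d0 - 2, "I10"), d0 - 182, d0,
                                  "any_weight_code"))
})

test_that("find_proximate_bmi minimizes distance within the bound", {
  a <- as.Date("2016-03-01")
  b <- vital(1, a + c(-29, 5), c(40, 41))
  expect_equal(find_proximate_bmi(b, a, 30)$value, 41)
  expect_null(find_proximate_bmi(vital(1, a + 31, 40), a, 30))
  expect_equal(find_proximate_bmi(vital(1, a + 31, 40), a, 31)$value, 40)
  # equidistant tie: earlier measurement
  tie <- vital(1, a + c(-7, 7), c(39, 44))
  expect_equal(find_proximate_bmi(tie, a, 30)$value, 39)
  # window restriction applies on top of proximity
  expect_null(find_proximate_bmi(vital(1, a + 5, 40), a, 30,
                                 within = list(start = a + 10,
                                               end = a + 20)))
})

test_that("cohorts nest and are idempotent under restriction", {
  w <- generate_world(generator_config(n_patients = 800, seed = 17,
                                       p_ehr_linked = 0.5))
  ch <- build_cohorts(w)
  expect_true(all(ch$cohort2$patient_id %in% ch$cohort1$patient_id))
  expect_true(all(ch$cohort3$patient_id %in% ch$cohort2$patient_id))
  # restricting the world to cohort-1 members reproduces cohorts 2 and 3
  keep <- ch$cohort1$patient_id
  w2 <- w
  for (nm in c("patients", "enrollment", "procedures", "diagnoses", "bmi"))
    w2[[nm]] <- w[[nm]][w[[nm]]$patient_id %in% keep, ]
  ch2 <- build_cohorts(w2)
  expect_equal(ch2$cohort2$patient_id, ch$cohort2$patient_id)
  expect_equal(ch2$cohort3$patient_id, ch$cohort3$patient_id)
})

test_that("widening the proximity bound never removes members", {
  w <- generate_world(generator_config(n_patients = 600, seed = 23,
                                       p_ehr_linked = 0.6,
                                       p_bmi_at_encounter = 0.3))
  sizes2 <- integer(0)
  sizes3 <- integer(0)
  members2 <- list()
  for (px in c(5, 15, 30, 60)) {
    ch <- build_cohorts(w, window_spec(proximity_days = px))
    sizes2 <- c(sizes2, nrow(ch$cohort2))
    sizes3 <- c(sizes3, nrow(ch$cohort3))
    members2[[length(members2) + 1]] <- ch$cohort2$patient_id
  }
  expect_false(is.unsorted(sizes2))
  expect_false(is.unsorted(sizes3))
  for (i in seq_len(length(members2) - 1))
    expect_true(all(members2[[i]] %in% members2[[i + 1]]))
})

test_that("perfect-coder worlds make cohort 2 the coded-and-linked subset", {
  w <- generate_world(perfect_config(400, seed = 19))
  ch <- build_cohorts(w)
  # everyone with >= 1 preop code qualifies: codes at every encounter,
  # vitals at every encounter, so proximity always holds
  cls <- presence_classes(ch$cohort1, w, "preop")
  expect_setequal(ch$cohort2$patient_id,
                  ch$cohort1$patient_id[cls == "granular"])
  pc3 <- presence_classes(ch$cohort2, w, "postop")
  expect_setequal(ch$cohort3$patient_id,
                  ch$cohort2$patient_id[pc3 == "granular"])
})

test_that("enrollment gaps are tolerated only up to the allowance", {
  d0 <- as.Date("2014-06-01")
  w <- mk_world(
    pat(1), proc(1, d0),
    diagnoses = dx(1, d0 - 10, "V85.41"),
    enrollment = data.frame(patient_id = c(1, 1),
                            start = c(d0 - 240, d0 - 99),
                            end = c(d0 - 105, d0 + 365)))
  # 5-day administrative gap between spans
  expect_equal(nrow(build_cohort1(w)), 0)
  expect_equal(nrow(build_cohort1(w, enrollment_gap_days = 5)), 1)
})
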