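# Synthetic world generator and its analytic oracle.

test_that("generation is reproducible and patient substreams are stable", {
  cfg <- generator_config(n_patients = 150, seed = 9)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  for (nm in c("patients", "enrollment", "procedures", "diagnoses",
               "bmi", "truth"))
    expect_identical(w1[[nm]], w2[[nm]])
  # growing the population leaves earlier patients untouched
  w3 <- generate_world(generator_config(n_patients = 300, seed = 9))
  expect_identical(w1$truth, w3$truth[w3$truth$patient_id <= 150, ])
  # different seeds differ
  w4 <- generate_world(generator_config(n_patients = 150, seed = 10))
  expect_false(identical(w1$diagnoses, w4$diagnoses))
})

test_that("an empty world has valid empty tables", {
  w <- generate_world(generator_config(n_patients = 0))
  expect_s3_class(w$patients, "data.frame")
  expect_equal(nrow(w$patients), 0)
  expect_equal(nrow(w$diagnoses), 0)
  expect_equal(nrow(w$bmi), 0)
  expect_true(all(c("patient_id", "date", "code") %in% names(w$diagnoses)))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(p_ehr_linked = 1.2), "probability")
  expect_error(generator_config(preop_bmi_sd = 0), "preop_bmi_sd")
  expect_error(generator_config(op_mix = c(AGB = 0.5, RYGB = 0.6, SG = 0.1)),
               "op_mix")
  K <- default_fidelity_kernel()
  K[1, 1] <- K[1, 1] + 0.1
  expect_error(generator_config(fidelity_kernel = K), "row-stochastic")
})

test_that("coding-system era follows the service date in emitted claims", {
  w <- generate_world(generator_config(n_patients = 400, seed = 3))
  d <- w$diagnoses
  pre10 <- d$date < as.Date("2015-10-01")
  expect_true(all(grepl("^(V85|278)", d$code[pre10])))
  expect_true(all(grepl("^(Z68|E66)", d$code[!pre10])))
  expect_true(all(d$system[pre10] == "ICD9CM"))
  expect_true(all(d$system[!pre10] == "ICD10CM"))
})

test_that("all records lie within enrollment; truth covers every record", {
  w <- generate_world(generator_config(n_patients = 200, seed = 5))
  en <- w$enrollment
  for (tbl in list(w$diagnoses, w$bmi)) {
    m <- merge(tbl, en, by = "patient_id")
    expect_true(all(m$date >= m$start & m$date <= m$end))
  }
  expect_equal(nrow(w$diagnoses), sum(w$truth$has_code))
  expect_equal(nrow(w$bmi), sum(w$truth$has_bmi))
})

test_that("a perfect coder reproduces the contemporaneous true category", {
  w <- generate_world(perfect_config(250, seed = 21))
  t <- w$truth
  emitted <- t[t$has_code & t$code_class == "granular", ]
  expect_gt(nrow(emitted), 0)
  expect_equal(emitted$coded_level, emitted$true_level)
  expect_equal(t$measured_bmi[t$has_bmi], t$true_bmi[t$has_bmi])
  # nonspecific codes are chosen by the morbid-obesity threshold
  w2 <- generate_world(generator_config(n_patients = 200, seed = 2,
                                        p_granular_given_code_preop = 0,
                                        p_granular_given_code_postop = 0))
  t2 <- w2$truth[w2$truth$has_code, ]
  morbid <- t2$true_bmi >= 35
  expect_true(all(t2$code[morbid] %in% c("278.01", "E66.01")))
  expect_true(all(t2$code[!morbid] %in% c("278.00", "E66.9")))
})

test_that("operation mix converges to the configured probabilities", {
  w <- generate_world(generator_config(n_patients = 4000, seed = 13))
  frac <- as.numeric(table(w$procedures$type)[c("AGB", "RYGB", "SG")]) / 4000
  expect_equal(frac, c(0.100, 0.322, 0.578),
               tolerance = 0.05)
})

test_that("the expected agreement matrix is a normalized joint distribution", {
  cfg <- generator_config()
  for (win in c("preop", "postop")) {
    J <- expected_agreement_matrix(cfg, win)
    expect_equal(sum(J), 1, tolerance = 1e-12)
    expect_true(all(J >= 0))
  }
})

test_that("identity kernel and zero noise give a diagonal matrix equal to the true marginal", {
  cfg <- perfect_config(10)
  J <- expected_agreement_matrix(cfg, "preop", n_grid = 200000)
  expect_true(all(J[row(J) != col(J)] == 0))
  # independent marginal: log-normal bin masses
  m <- 46.1; s <- 9.0
  sdlog <- sqrt(log(1 + (s / m)^2)); meanlog <- log(m) - sdlog^2 / 2
  lv <- bmi_levels("ten_level")
  mass <- plnorm(lv$upper, meanlog, sdlog) - plnorm(pmax(lv$lower, 0),
                                                    meanlog, sdlog)
  expect_equal(unname(diag(J)), mass, tolerance = 1e-4)
})

test_that("the oracle matches independent per-cell numerical integration", {
  cfg <- generator_config(ehr_noise_sd = 1.5, upcode_at_35 = 0.4)
  J <- expected_agreement_matrix(cfg, "preop", n_grid = 100000)
  m <- 46.1; s <- 9.0
  sdlog <- sqrt(log(1 + (s / m)^2)); meanlog <- log(m) - sdlog^2 / 2
  lv <- bmi_levels("ten_level")
  K <- cfg$fidelity_kernel
  cell <- function(i, j) {
    integrand <- function(b) {
      lev <- categorize_bmi(b)
      crow <- K[lev, i]
      u4 <- lev == 4L
      crow[u4] <- (1 - 0.4) * K[4, i] + 0.4 * (i == 5)
      ref <- pnorm(lv$upper[j], b, 1.5) - pnorm(lv$lower[j], b, 1.5)
      dlnorm(b, meanlog, sdlog) * crow * ref
    }
    integrate(integrand, 5, 200, subdivisions = 500,
              rel.tol = 1e-9)$value
  }
  # quantile-grid quadrature is least dense in the upper tail; 1e-3
  # relative still detects any substantive kernel/up-coding error
  for (ij in list(c(5, 5), c(5, 6), c(4, 4), c(6, 4), c(10, 10))) {
    expect_equal(J[ij[1], ij[2]], cell(ij[1], ij[2]), tolerance = 1e-3)
  }
})

test_that("empirical joint frequencies converge to the oracle (moderate n)", {
  cfg <- generator_config(n_patients = 6000, seed = 31,
                          p_ehr_linked = 1, p_bmi_at_encounter = 1)
  w <- generate_world(cfg)
  for (win in c("preop", "postop")) {
    pairs <- encounter_pairs(w, win)
    emp <- table(factor(pairs$claims_level, 1:10),
                 factor(pairs$ref_level, 1:10)) / nrow(pairs)
    J <- expected_agreement_matrix(cfg, win)
    tv <- 0.5 * sum(abs(emp - J))
    expect_lt(tv, 0.05)
  }
})

test_that("worlds round-trip through CSV", {
  w <- generate_world(generator_config(n_patients = 40, seed = 8))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  expect_true(file.exists(file.path(dir, "diagnoses.csv")))
  w2 <- read_world(dir)
  expect_equal(w2$diagnoses$code, w$diagnoses$code)
  expect_equal(w2$bmi$value, w$bmi$value, tolerance = 1e-9)
  expect_equal(w2$enrollment$start, w$enrollment$start)
  cfg2 <- attr(w2, "config")
  expect_equal(cfg2$fidelity_kernel, attr(w, "config")$fidelity_kernel)
  # a rebuilt cohort pipeline runs identically on the round-tripped world
  c1a <- build_cohort1(w)
  c1b <- build_cohort1(w2)
  expect_equal(c1a$patient_id, c1b$patient_id)
})
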