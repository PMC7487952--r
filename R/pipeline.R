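# End-to-end orchestration: config, pipeline execution, report.

#' Pipeline run configuration
#'
#' Either simulate a synthetic world (`generator` given) or read one
#' from CSV tables (`input_dir` given, schema of [write_world()]). All
#' defaults mirror the base analysis: 35 kg/m^2 severe-obesity cutoff,
#' ten-level categorization, granular codes only, +/-30-day proximity,
#' 182-day preoperative and 365-day postoperative windows, linear kappa
#' weights with an asymptotic confidence interval.
#'
#' @param generator a [generator_config()] (simulate mode), or NULL.
#' @param input_dir directory of input CSV tables (non-simulate mode).
#' @param windows a [window_spec()].
#' @param algorithm an [algorithm_config()] (its `windows` field is kept
#'   in sync with `windows`).
#' @param kappa_weight "linear" or "quadratic".
#' @param ci_method "asymptotic" or "bootstrap".
#' @param bootstrap_B bootstrap replicates.
#' @param suppression_threshold small-cell suppression threshold.
#' @param seed seed for stochastic steps (bootstrap; and the generator
#'   unless its config carries its own).
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       input_dir = NULL,
                       windows = window_spec(),
                       algorithm = algorithm_config(windows = windows),
                       kappa_weight = "linear",
                       ci_method = "asymptotic",
                       bootstrap_B = 2000,
                       suppression_threshold = 10,
                       seed = 1) {
  if (is.null(generator) && is.null(input_dir))
    stop("either a generator config (simulate mode) or `input_dir` is required")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input directory does not exist: ", input_dir)
  algorithm$windows <- windows
  structure(list(generator = generator, input_dir = input_dir,
                 windows = windows, algorithm = algorithm,
                 kappa_weight = kappa_weight, ci_method = ci_method,
                 bootstrap_B = bootstrap_B,
                 suppression_threshold = suppression_threshold,
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with (optional) blocks `generator`, `windows`,
#'   `algorithm` and top-level metric options; omitted fields take the
#'   package defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  y <- yaml::read_yaml(path)
  gen <- if (!is.null(y$input_dir)) NULL else {
    ga <- y$generator %||% list()
    if (!is.null(ga$fidelity_kernel))
      ga$fidelity_kernel <- matrix(unlist(ga$fidelity_kernel), 10, 10)
    for (f in c("op_mix", "postop_loss_fraction_by_op", "year_range"))
      if (!is.null(ga[[f]])) ga[[f]] <- unlist(ga[[f]])
    do.call(generator_config, ga)
  }
  win <- do.call(window_spec, y$windows %||% list())
  alg_args <- y$algorithm %||% list()
  alg_args$windows <- win
  top <- y[intersect(names(y), c("kappa_weight", "ci_method",
                                 "bootstrap_B", "suppression_threshold",
                                 "seed"))]
  do.call(run_config, c(list(generator = gen, input_dir = y$input_dir,
                             windows = win,
                             algorithm = do.call(algorithm_config,
                                                 alg_args)),
                        top))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full validation pipeline
#'
#' Sequences generate (or load) -> cohorts -> classification ->
#' availability -> metrics -> report. When `out_dir` is given, every
#' artifact is written as CSV (plus a markdown report and a JSON
#' manifest recording the config hash, seed and row counts); a rerun
#' with the same config and seed reproduces the artifacts byte for
#' byte.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return (invisibly when writing) a list with `world`, `cohorts`,
#'   `classification`, `availability_preop`, `availability_postop`,
#'   `metrics`, `report` (character lines), `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  world <- stage("generate", {
    if (!is.null(config$input_dir)) read_world(config$input_dir)
    else {
      gc <- config$generator
      if (is.null(gc$seed)) gc$seed <- config$seed
      generate_world(gc)
    }
  })
  cohorts <- stage("cohorts", build_cohorts(world, config$windows))
  classification <- stage("classify",
                          classification_table(cohorts, world,
                                               config$algorithm))
  avail_pre <- stage("availability",
                     stratified_presence(cohorts$cohort1, world, "preop",
                                         windows = config$windows))
  avail_post <- stage("availability",
                      stratified_presence(cohorts$cohort1, world, "postop",
                                          windows = config$windows))
  metrics <- stage("metrics",
                   validation_metrics(classification, config$algorithm,
                                      weight = config$kappa_weight,
                                      ci_method = config$ci_method,
                                      B = config$bootstrap_B,
                                      seed = config$seed))
  report <- stage("report",
                  render_validation_report(cohorts, avail_pre, avail_post,
                                           metrics,
                                           config$suppression_threshold))
  res <- list(world = world, cohorts = cohorts,
              classification = classification,
              availability_preop = avail_pre,
              availability_postop = avail_post,
              metrics = metrics, report = report)
  res$manifest <- build_manifest(config, res)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(d, nm) utils::write.csv(d, file.path(out_dir, nm),
                                           row.names = FALSE)
    wr(cohorts$cohort1, "cohort1.csv")
    wr(cohorts$cohort2, "cohort2.csv")
    wr(cohorts$cohort3, "cohort3.csv")
    wr(attr(cohorts$cohort1, "attrition"), "attrition.csv")
    wr(classification, "classification.csv")
    wr(avail_pre, "availability_preop.csv")
    wr(avail_post, "availability_postop.csv")
    wr(metrics_long(metrics, config$suppression_threshold), "metrics.csv")
    writeLines(report, file.path(out_dir, "report.md"))
    jsonlite::write_json(res$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(res)
}

# stable FNV-1a hash of the serialized config (hex string)
config_hash <- function(config) {
  s <- utils::capture.output(utils::str(config, digits.d = 15,
                                        vec.len = 1e6))
  bytes <- utf8ToInt(paste(s, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

build_manifest <- function(config, res) {
  list(
    config_hash = config_hash(config),
    seed = config$seed,
    rows = list(
      patients = nrow(res$world$patients),
      diagnoses = nrow(res$world$diagnoses),
      bmi = nrow(res$world$bmi),
      cohort1 = nrow(res$cohorts$cohort1),
      cohort2 = nrow(res$cohorts$cohort2),
      cohort3 = nrow(res$cohorts$cohort3),
      classification = nrow(res$classification)
    )
  )
}

# flatten the metrics list to one row per window x level for CSV export
metrics_long <- function(metrics, suppression_threshold = 10) {
  rows <- list()
  if (!is.null(metrics$severe)) {
    cc <- metrics$severe
    rows[[1]] <- data.frame(
      window = "preop", analysis = "severe_obesity", level = NA,
      label = "BMI >= threshold",
      TP = cc$counts[["TP"]], FP = cc$counts[["FP"]],
      TN = cc$counts[["TN"]], FN = cc$counts[["FN"]],
      sensitivity = cc$estimates[["sensitivity"]],
      specificity = cc$estimates[["specificity"]],
      ppv = cc$estimates[["ppv"]], npv = cc$estimates[["npv"]],
      kappa = NA, kappa_lower = NA, kappa_upper = NA,
      stringsAsFactors = FALSE)
  }
  for (win in c("preop", "postop")) {
    mw <- metrics[[win]]
    if (is.null(mw)) next
    pl <- mw$per_level
    kap <- mw$kappa
    rows[[length(rows) + 1]] <- data.frame(
      window = win, analysis = "bmi_categorization", level = pl$level,
      label = pl$label,
      TP = pl$TP, FP = pl$FP, TN = pl$TN, FN = pl$FN,
      sensitivity = pl$sensitivity, specificity = pl$specificity,
      ppv = pl$ppv, npv = pl$npv,
      kappa = kap$kappa,
      kappa_lower = if (!is.null(kap$ci)) kap$ci$lower else NA,
      kappa_upper = if (!is.null(kap$ci)) kap$ci$upper else NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a human-readable validation report
#'
#' Markdown report with the attrition log, availability summaries, the
#' severe-obesity accuracy and the per-level validation tables for both
#' windows, with small-cell suppression applied to every reported count
#' (masking applies at reporting only).
#'
#' @param cohorts,availability_preop,availability_postop,metrics pipeline
#'   artifacts.
#' @param suppression_threshold counts at or below this are masked.
#' @return character vector of markdown lines.
#' @export
render_validation_report <- function(cohorts, availability_preop,
                                     availability_postop, metrics,
                                     suppression_threshold = 10) {
  mask_n <- function(x) ifelse(x <= suppression_threshold & x > 0, "--",
                               format(x, trim = TRUE))
  L <- c("# Claims-based BMI algorithm validation report", "")
  att <- attr(cohorts$cohort1, "attrition")
  L <- c(L, "## Cohort attrition", "",
         sprintf("- Cohort 1 (availability): %d patients",
                 nrow(cohorts$cohort1)),
         sprintf("- Cohort 2 (preoperative validation): %d patients",
                 nrow(cohorts$cohort2)),
         sprintf("- Cohort 3 (postoperative validation): %d patients",
                 nrow(cohorts$cohort3)), "")
  if (nrow(att)) {
    L <- c(L, "Exclusions (patients, by first failing rule):", "",
           sprintf("- %s: %s", att$reason, mask_n(att$Freq)), "")
  }
  avail_block <- function(av, title) {
    c(sprintf("## %s", title), "",
      "| stratum | N | granular %% | nonspecific %% | none %% |",
      "|---|---|---|---|---|",
      sprintf("| %s | %s | %.1f | %.1f | %.1f |",
              av$stratum, mask_n(av$n), av$pct_granular,
              av$pct_nonspecific, av$pct_none), "")
  }
  L <- c(L, avail_block(availability_preop,
                        "Code availability, preoperative window"),
         avail_block(availability_postop,
                     "Code availability, postoperative window"))
  if (!is.null(metrics$severe)) {
    cc <- suppress_small_cells(
      per_level_like(metrics$severe), suppression_threshold)
    L <- c(L, "## Severe obesity classification (preoperative)", "",
           "| Se | Sp | PPV | NPV | TP | FP | TN | FN |",
           "|---|---|---|---|---|---|---|---|",
           sprintf("| %s | %s | %s | %s | %s | %s | %s | %s |",
                   cc$sensitivity_display, cc$specificity_display,
                   cc$ppv_display, cc$npv_display, cc$TP_display,
                   cc$FP_display, cc$TN_display, cc$FN_display), "")
  }
  for (win in c("preop", "postop")) {
    mw <- metrics[[win]]
    if (is.null(mw)) next
    pl <- suppress_small_cells(mw$per_level, suppression_threshold)
    kap <- mw$kappa
    kline <- if (isTRUE(kap$undefined)) "kappa: undefined" else
      if (!is.null(kap$ci))
        sprintf("weighted kappa %.2f (%d%% CI %.2f, %.2f)", kap$kappa,
                round(100 * kap$ci$level), kap$ci$lower, kap$ci$upper)
      else sprintf("weighted kappa %.2f", kap$kappa)
    L <- c(L,
           sprintf("## BMI categorization, %s window", win), "",
           kline, "",
           "| BMI level | Sensitivity | Specificity | PPV | NPV |",
           "|---|---|---|---|---|",
           sprintf("| %s | %s | %s | %s | %s |", pl$label,
                   pl$sensitivity_display, pl$specificity_display,
                   pl$ppv_display, pl$npv_display), "")
  }
  L <- c(L, sprintf(
    "Cells with %d or fewer patients are masked ('--'); rates derived from a masked cell are reported as one-sided bounds.",
    suppression_threshold))
  L
}

# shape a confusion_2x2 like a per_level_metrics row for suppression
per_level_like <- function(cc) {
  data.frame(level = 1, label = "severe obesity",
             TP = cc$counts[["TP"]], FP = cc$counts[["FP"]],
             TN = cc$counts[["TN"]], FN = cc$counts[["FN"]],
             sensitivity = cc$estimates[["sensitivity"]],
             specificity = cc$estimates[["specificity"]],
             ppv = cc$estimates[["ppv"]], npv = cc$estimates[["npv"]],
             sensitivity_undefined = cc$undefined[["sensitivity"]],
             specificity_undefined = cc$undefined[["specificity"]],
             ppv_undefined = cc$undefined[["ppv"]],
             npv_undefined = cc$undefined[["npv"]],
             stringsAsFactors = FALSE)
}

#' Sensitivity-analysis sweep
#'
#' Runs one full validation per value of the swept axis and tabulates
#' the validation sample sizes and kappas, mirroring the published
#' sensitivity analyses (proximity relaxation, alternative postoperative
#' windows, the BMI >= 40 cutoff, coarser categorizations, nonspecific
#' code expansion).
#'
#' @param config a [run_config()].
#' @param axis one of "proximity_days", "postop_window",
#'   "severe_threshold", "scheme", "include_nonspecific".
#' @param values vector of values for the axis.
#' @return data.frame, one row per value: cohort sizes, preop/postop
#'   kappa and CI bounds.
#' @export
sensitivity_sweep <- function(config,
                              axis = c("proximity_days", "postop_window",
                                       "severe_threshold", "scheme",
                                       "include_nonspecific"),
                              values) {
  axis <- match.arg(axis)
  if (length(values) < 1) stop("no sweep values given")
  rows <- lapply(values, function(v) {
    cfg <- config
    if (axis == "proximity_days") cfg$windows$proximity_days <- as.integer(v)
    if (axis == "postop_window") cfg$windows$postop_days <- as.integer(v)
    if (axis == "severe_threshold") cfg$algorithm$severe_threshold <- v
    if (axis == "scheme") cfg$algorithm$scheme <- v
    if (axis == "include_nonspecific")
      cfg$algorithm$include_nonspecific <- as.logical(v)
    cfg$algorithm$windows <- cfg$windows
    res <- run_pipeline(cfg)
    kp <- res$metrics$preop$kappa
    ko <- res$metrics$postop$kappa
    getk <- function(k, f) if (is.null(k)) NA_real_ else
      if (f == "kappa") k$kappa else if (!is.null(k$ci)) k$ci[[f]] else
        NA_real_
    data.frame(axis = axis, value = as.character(v),
               cohort1_n = nrow(res$cohorts$cohort1),
               cohort2_n = nrow(res$cohorts$cohort2),
               cohort3_n = nrow(res$cohorts$cohort3),
               kappa_preop = getk(kp, "kappa"),
               kappa_preop_lower = getk(kp, "lower"),
               kappa_preop_upper = getk(kp, "upper"),
               kappa_postop = getk(ko, "kappa"),
               kappa_postop_lower = getk(ko, "lower"),
               kappa_postop_upper = getk(ko, "upper"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
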