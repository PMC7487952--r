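# Validation statistics: 2x2 and per-level diagnostic accuracy, weighted
# Cohen's kappa with confidence intervals, small-cell suppression.

#' Agreement weights for weighted kappa
#'
#' Linear (Cicchetti-Allison) weights `1 - |i-j|/(k-1)` or quadratic
#' (Fleiss-Cohen) weights `1 - ((i-j)/(k-1))^2`. For k = 2 both reduce to
#' the identity weights of the unweighted Cohen's kappa.
#'
#' @param k number of categories.
#' @param weight "linear" or "quadratic".
#' @return a k x k symmetric matrix with unit diagonal.
#' @export
kappa_weights <- function(k, weight = c("linear", "quadratic")) {
  weight <- match.arg(weight)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  if (weight == "linear") 1 - d else 1 - d^2
}

#' Two-by-two diagnostic accuracy
#'
#' Sensitivity, specificity, positive and negative predictive value for
#' paired boolean claims/reference labels (or explicit counts).
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). A metric whose denominator is zero is returned as
#' NA and flagged undefined, never as 0 or 1.
#'
#' @param claims,reference logical vectors (algorithm and reference
#'   labels); or leave NULL and pass `counts`.
#' @param counts optional named vector c(TP=, FP=, TN=, FN=).
#' @return an object of class `confusion_2x2`: list with `counts`,
#'   `estimates` (proportions), `undefined` (logical flags) and `n`.
#' @export
#' @examples
#' confusion_2x2(counts = c(TP = 90, FP = 10, TN = 60, FN = 40))
confusion_2x2 <- function(claims = NULL, reference = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (length(claims) != length(reference) || length(claims) < 1)
      stop("need >= 1 claims/reference label pair")
    if (anyNA(claims) || anyNA(reference))
      stop("missing labels must be filtered (and flagged) upstream")
    counts <- c(TP = sum(claims & reference),
                FP = sum(claims & !reference),
                TN = sum(!claims & !reference),
                FN = sum(!claims & reference))
  }
  counts <- counts[c("TP", "FP", "TN", "FN")]
  if (anyNA(counts) || any(counts < 0)) stop("invalid counts")
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  est <- c(
    sensitivity = rate(counts["TP"], counts["TP"] + counts["FN"]),
    specificity = rate(counts["TN"], counts["TN"] + counts["FP"]),
    ppv = rate(counts["TP"], counts["TP"] + counts["FP"]),
    npv = rate(counts["TN"], counts["TN"] + counts["FN"])
  )
  names(est) <- c("sensitivity", "specificity", "ppv", "npv")
  structure(list(counts = counts, estimates = est,
                 undefined = is.na(est), n = sum(counts)),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat("2x2 diagnostic accuracy (N =", x$n, ")\n")
  print(x$counts)
  e <- ifelse(x$undefined, "undefined",
              sprintf("%.1f%%", 100 * x$estimates))
  cat(paste(names(x$estimates), e, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Cross-classification of claims vs reference categories
#'
#' Builds the k x k observed table (rows = claims-derived category,
#' columns = reference category), its marginals and the expected counts
#' under marginal independence E_ij = row_i * col_j / N. Categories with
#' zero marginal are retained so k stays fixed by the scheme.
#'
#' @param claims,reference integer level indices from the same scheme.
#' @param k number of categories in the scheme.
#' @param labels optional category labels.
#' @return an object of class `agreement_table`: list with `O`, `E`,
#'   `n`, `k`.
#' @export
agreement_table <- function(claims, reference, k, labels = NULL) {
  if (length(claims) != length(reference))
    stop("claims and reference must be paired")
  ok <- !is.na(claims) & !is.na(reference)
  claims <- claims[ok]; reference <- reference[ok]
  if (length(claims) == 0) stop("no comparable pairs")
  if (any(claims < 1 | claims > k) || any(reference < 1 | reference > k))
    stop("labels outside 1..k: are both sides from the same scheme?")
  if (is.null(labels)) labels <- as.character(seq_len(k))
  O <- table(factor(claims, levels = seq_len(k)),
             factor(reference, levels = seq_len(k)))
  O <- matrix(as.numeric(O), k, k, dimnames = list(claims = labels,
                                                   reference = labels))
  n <- sum(O)
  E <- outer(rowSums(O), colSums(O)) / n
  structure(list(O = O, E = E, n = n, k = k, labels = labels),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("agreement table: k =", x$k, ", N =", x$n, "\n")
  print(x$O)
  invisible(x)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal categories with partial credit
#' for near-miss disagreement:
#' `kappa_w = (sum(W * O)/N - sum(W * E)/N) / (1 - sum(W * E)/N)`
#' with linear or quadratic weights (see [kappa_weights()]). For a 2x2
#' table both weight schemes equal the unweighted Cohen's kappa.
#' Interpretation bands follow the conventional cutpoints: > 0.75
#' excellent, 0.40-0.75 fair to good, < 0.40 poor.
#'
#' @param table an [agreement_table()].
#' @param weight "linear" (default) or "quadratic".
#' @return an object of class `kappa_result` with elements `kappa`,
#'   `weight`, `po`, `pe`, `n`, `undefined`, `band`.
#' @export
weighted_kappa <- function(table, weight = c("linear", "quadratic")) {
  stopifnot(inherits(table, "agreement_table"))
  weight <- match.arg(weight)
  if (table$n < 1) stop("N must be >= 1")
  W <- kappa_weights(table$k, weight)
  po <- sum(W * table$O) / table$n
  pe <- sum(W * table$E) / table$n
  undefined <- abs(1 - pe) < 1e-12
  kap <- if (undefined) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kap, weight = weight, po = po, pe = pe,
                 n = table$n, undefined = undefined,
                 band = kappa_band(kap)),
            class = "kappa_result")
}

kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa > 0.75) "excellent" else if (kappa >= 0.40) "fair_to_good"
  else "poor"
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined) {
    cat("weighted kappa: undefined (all expected agreement)\n")
  } else {
    cat(sprintf("weighted kappa (%s weights): %.4f [%s]\n",
                x$weight, x$kappa, x$band))
    if (!is.null(x$ci))
      cat(sprintf("%d%% CI (%s): %.4f, %.4f\n", round(100 * x$ci$level),
                  x$ci$method, x$ci$lower, x$ci$upper))
  }
  invisible(x)
}

#' Confidence interval for weighted kappa
#'
#' Asymptotic method: the large-sample variance of the weighted kappa
#' (Fleiss-Cohen-Everitt form) with a normal interval truncated to
#' \[-1, 1\]. Bootstrap method: percentile interval from B multinomial
#' resamples of the pairs, reproducible for a fixed seed.
#'
#' @param table an [agreement_table()].
#' @param weight "linear" or "quadratic".
#' @param level confidence level (default 0.95).
#' @param method "asymptotic" (default) or "bootstrap".
#' @param B bootstrap replicates.
#' @param seed seed for the bootstrap resamples.
#' @return a `kappa_result` with `se` and `ci` elements; a warning flag
#'   `small_n` is set when N < 30 (asymptotic normality doubtful;
#'   bootstrap recommended).
#' @export
kappa_ci <- function(table, weight = c("linear", "quadratic"),
                     level = 0.95, method = c("asymptotic", "bootstrap"),
                     B = 2000, seed = 1) {
  stopifnot(inherits(table, "agreement_table"))
  weight <- match.arg(weight)
  method <- match.arg(method)
  if (table$n < 2) stop("N must be >= 2 for a confidence interval")
  res <- weighted_kappa(table, weight)
  res$small_n <- table$n < 30
  if (res$small_n && method == "asymptotic")
    warning("N < 30: asymptotic interval unreliable; consider bootstrap")
  if (res$undefined) {
    res$se <- NA_real_
    res$ci <- list(level = level, lower = NA_real_, upper = NA_real_,
                   method = method, degenerate = TRUE)
    return(res)
  }
  k <- table$k
  W <- kappa_weights(k, weight)
  n <- table$n
  p <- table$O / n
  pr <- rowSums(p); pc <- colSums(p)
  po <- res$po; pe <- res$pe
  if (method == "asymptotic") {
    # Fleiss, Cohen & Everitt large-sample variance
    wr <- as.vector(W %*% pc)        # row-wise expected weight
    wc <- as.vector(t(W) %*% pr)     # column-wise expected weight
    term <- (W * (1 - pe) -
               outer(wr, wc, function(a, b) a + b) * (1 - po))^2
    v <- (sum(p * term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
    se <- sqrt(max(v, 0))
    zc <- stats::qnorm(1 - (1 - level) / 2)
    lo <- max(-1, res$kappa - zc * se)
    hi <- min(1, res$kappa + zc * se)
    degen <- se == 0
  } else {
    cells <- as.vector(table$O)
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
    draws <- stats::rmultinom(B, n, cells / n)
    kaps <- apply(draws, 2, function(cnt) {
      Ob <- matrix(cnt, k, k)
      Eb <- outer(rowSums(Ob), colSums(Ob)) / n
      peb <- sum(W * Eb) / n
      if (abs(1 - peb) < 1e-12) return(NA_real_)
      (sum(W * Ob) / n - peb) / (1 - peb)
    })
    kaps <- kaps[!is.na(kaps)]
    se <- stats::sd(kaps)
    qs <- stats::quantile(kaps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE, type = 6)
    lo <- qs[1]; hi <- qs[2]
    degen <- length(unique(kaps)) == 1
  }
  res$se <- se
  res$ci <- list(level = level, lower = lo, upper = hi, method = method,
                 degenerate = degen)
  res
}

#' Per-level (one-vs-rest) diagnostic accuracy
#'
#' For each category level L, collapses the agreement table to a 2x2
#' table (claims = L vs not-L against reference = L vs not-L) and
#' computes sensitivity, specificity, PPV and NPV. A level with no
#' reference patients has its sensitivity flagged as not calculated
#' (NA), and likewise for the other metrics' denominators.
#'
#' @param table an [agreement_table()].
#' @return data.frame, one row per level, with counts, proportion
#'   estimates, and logical `*_undefined` flags.
#' @export
per_level_metrics <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  out <- lapply(seq_len(table$k), function(L) {
    TP <- table$O[L, L]
    FP <- sum(table$O[L, ]) - TP
    FN <- sum(table$O[, L]) - TP
    TN <- table$n - TP - FP - FN
    cc <- confusion_2x2(counts = c(TP = TP, FP = FP, TN = TN, FN = FN))
    data.frame(level = L, label = table$labels[L],
               TP = TP, FP = FP, TN = TN, FN = FN,
               sensitivity = cc$estimates[["sensitivity"]],
               specificity = cc$estimates[["specificity"]],
               ppv = cc$estimates[["ppv"]],
               npv = cc$estimates[["npv"]],
               sensitivity_undefined = cc$undefined[["sensitivity"]],
               specificity_undefined = cc$undefined[["specificity"]],
               ppv_undefined = cc$undefined[["ppv"]],
               npv_undefined = cc$undefined[["npv"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Small-cell suppression for de-identified reporting
#'
#' Masks any reported count at or below the threshold (default 10).
#' Percentages derived from one masked count with an unmasked complement
#' are reported as one-sided bounds: for a metric a/(a+b), a masked
#' complement b gives "> floor(a/(a + threshold))", a masked numerator a
#' gives "< ceiling(threshold/(threshold + b))". Masking applies only at
#' reporting; internal computation always uses the full counts.
#'
#' @param metrics a data.frame from [per_level_metrics()].
#' @param threshold suppression threshold; counts <= threshold are
#'   masked.
#' @param mask marker string for masked values.
#' @return the data.frame with added display columns `TP_display`, ...,
#'   `sensitivity_display`, ... containing masked markers and bounds.
#' @export
suppress_small_cells <- function(metrics, threshold = 10, mask = "--") {
  stopifnot(is.data.frame(metrics))
  cnt_cols <- c("TP", "FP", "TN", "FN")
  for (cc in cnt_cols) {
    metrics[[paste0(cc, "_display")]] <-
      ifelse(metrics[[cc]] <= threshold, mask,
             format(metrics[[cc]], trim = TRUE, scientific = FALSE))
  }
  disp <- function(num, den_other, undefined) {
    # metric = num / (num + den_other), as a percentage, masked per cell
    mapply(function(a, b, und) {
      if (und) return("NC")  # not calculated: zero denominator
      am <- a <= threshold; bm <- b <= threshold
      if (!am && !bm) return(sprintf("%.0f", round_half_up(100 * a / (a + b), 0)))
      if (am && bm) return(mask)
      if (bm) sprintf("> %.0f", round_half_up(100 * a / (a + threshold), 0))
      else sprintf("< %.0f", round_half_up(100 * threshold / (threshold + b), 0))
    }, num, den_other, undefined)
  }
  metrics$sensitivity_display <-
    disp(metrics$TP, metrics$FN, metrics$sensitivity_undefined)
  metrics$specificity_display <-
    disp(metrics$TN, metrics$FP, metrics$specificity_undefined)
  metrics$ppv_display <- disp(metrics$TP, metrics$FP, metrics$ppv_undefined)
  metrics$npv_display <- disp(metrics$TN, metrics$FN, metrics$npv_undefined)
  attr(metrics, "suppression_threshold") <- threshold
  metrics
}

#' Round half up
#'
#' Decimal rounding with ties away from zero (the convention used for
#' printed percentages), unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 93.35), c(0, 0, 1))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Format a proportion as a printed percentage
#'
#' @param x proportions in \[0, 1\].
#' @param digits decimal places (default 1, half-up).
#' @return numeric percentages rounded half-up.
#' @export
format_pct <- function(x, digits = 1) {
  round_half_up(100 * x, digits)
}
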