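#' 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer cell counts. In `"diagnostic"`
#'   orientation these are TP, FN, FP, TN (rows = truth, columns = test).
#'   In `"agreement"` orientation: both-positive, rater1-only, rater2-only,
#'   both-negative.
#' @param orientation `"diagnostic"` or `"agreement"`.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, orientation = c("diagnostic", "agreement")) {
  orientation <- match.arg(orientation)
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    eq_error("echoquant_validation", "cells must be non-negative integers")
  if (sum(cells) < 1) eq_error("echoquant_validation", "table total must be >= 1")
  structure(list(a = a, b = b, c = c, d = d, orientation = orientation),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  lab <- if (x$orientation == "diagnostic") c("TP", "FN", "FP", "TN")
         else c("+/+", "+/-", "-/+", "-/-")
  cat(sprintf("<contingency_table:%s> %s=%d %s=%d %s=%d %s=%d (n=%d)\n",
              x$orientation, lab[1], x$a, lab[2], x$b, lab[3], x$c, lab[4], x$d,
              x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Build a diagnostic 2x2 table from nodule records
#'
#' @param records data frame of nodule records with a `truth` column and the
#'   predictor column. Binary predictors must be 0/1 (or logical). For EI
#'   columns, supply `rule`: `"less_than_zero"` (strictly negative is test-
#'   positive) or `"less_than_median"` (strictly below the median over all
#'   supplied records; the median itself falls in the test-negative group).
#' @param predictor column name.
#' @param truth_positive label of the disease-positive class in `truth`.
#' @param rule `NULL` for a binary feature, else the EI cut-off rule.
#' @param negate if `TRUE`, the binary predictor is inverted (test-positive
#'   when the column is 0) -- e.g. risk factor "size < 2 cm" from a
#'   `size_ge_2cm` column.
#' @return A diagnostic-orientation [contingency_table].
#' @export
contingency_from_records <- function(records, predictor,
                                     truth_positive = "malignant",
                                     rule = NULL, negate = FALSE) {
  if (!predictor %in% names(records))
    eq_error("echoquant_validation", paste("no such column:", predictor))
  v <- records[[predictor]]
  if (anyNA(v) || anyNA(records$truth)) {
    ids <- if ("id" %in% names(records)) records$id[is.na(v) | is.na(records$truth)]
           else which(is.na(v) | is.na(records$truth))
    eq_error("echoquant_missing_values",
             paste("missing predictor/truth for records:", paste(ids, collapse = ", ")))
  }
  test_pos <- if (is.null(rule)) {
    p <- as.logical(v)
    if (negate) !p else p
  } else if (rule == "less_than_zero") {
    v < 0
  } else if (rule == "less_than_median") {
    v < stats::median(v)
  } else eq_error("echoquant_validation", paste("unknown rule:", rule))
  truth_pos <- records$truth == truth_positive
  contingency_table(
    a = sum(truth_pos & test_pos), b = sum(truth_pos & !test_pos),
    c = sum(!truth_pos & test_pos), d = sum(!truth_pos & !test_pos),
    orientation = "diagnostic"
  )
}

#' Diagnostic performance metrics of a 2x2 table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and negative
#' predictive values, and accuracy. A metric whose denominator is zero is
#' reported as `NA` (undefined).
#'
#' @param table a diagnostic-orientation [contingency_table].
#' @return An object of class `diagnostic_metrics` (a list of the five
#'   proportions).
#' @export
diagnostic_metrics <- function(table) {
  if (table$orientation != "diagnostic")
    eq_error("echoquant_validation", "table must be in diagnostic orientation")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  tp <- table$a; fn <- table$b; fp <- table$c; tn <- table$d
  structure(list(
    sensitivity = rat(tp, tp + fn), specificity = rat(tn, tn + fp),
    ppv = rat(tp, tp + fp), npv = rat(tn, tn + fn),
    accuracy = (tp + tn) / (tp + fn + fp + tn)
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("sens %.4f  spec %.4f  PPV %.4f  NPV %.4f  acc %.4f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy))
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad/bc`; `beta = ln OR`; CI by the Woolf (log) method,
#' `exp(beta +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param table a [contingency_table].
#' @param conf confidence level (default 0.95).
#' @param continuity `"none"` (default; a zero cell is an error) or
#'   `"haldane"` (add 0.5 to every cell when any cell is zero).
#' @return List with `or`, `beta`, `ci_low`, `ci_high`, `se`.
#' @export
odds_ratio <- function(table, conf = 0.95, continuity = c("none", "haldane")) {
  continuity <- match.arg(continuity)
  cells <- c(table$a, table$b, table$c, table$d)
  if (any(cells == 0)) {
    if (continuity == "none")
      eq_error("echoquant_undefined_or", "zero cell; use continuity = \"haldane\"")
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  beta <- log(or)
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, beta = beta, ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se), se = se)
}

#' Fisher's exact test (two-sided) for a 2x2 table
#'
#' The two-sided p-value is the sum of the hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (the standard small-sample definition).
#'
#' @param table a [contingency_table].
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Cohen's kappa for inter-observer agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (a + d)/n` and chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2`. The interpretation bin follows
#' the conventional scale: 0.00--0.20 slight, 0.21--0.40 fair, 0.41--0.60
#' moderate, 0.61--0.80 substantial, 0.81--1.00 almost perfect (negative
#' values: poor).
#'
#' @param table an agreement-orientation [contingency_table].
#' @return List with `kappa`, `p_observed`, `p_expected`, `interpretation`.
#' @export
cohen_kappa <- function(table) {
  if (table$orientation != "agreement")
    eq_error("echoquant_validation", "table must be in agreement orientation")
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  p_o <- (a + d) / n
  p_e <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (1 - p_e <= 0)
    eq_error("echoquant_undefined_kappa", "chance agreement is 1; kappa undefined")
  kap <- (p_o - p_e) / (1 - p_e)
  bin <- if (kap < 0) "poor" else if (kap <= 0.20) "slight" else
    if (kap <= 0.40) "fair" else if (kap <= 0.60) "moderate" else
    if (kap <= 0.80) "substantial" else "almost perfect"
  list(kappa = kap, p_observed = p_o, p_expected = p_e, interpretation = bin)
}

#' ROC curve and AUC
#'
#' The AUC is the Mann-Whitney pair statistic: the probability that a
#' randomly chosen positive scores on the positive side of a randomly
#' chosen negative, ties counted 1/2. For the echogenicity indices, lower
#' values indicate malignancy, so `direction = "lower_positive"` is used.
#'
#' @param scores numeric scores.
#' @param labels binary truth (logical or 0/1; 1 = positive class).
#' @param direction `"higher_positive"` or `"lower_positive"`.
#' @return List with `auc` and `curve` (data frame of `fpr`, `tpr` swept
#'   over all distinct thresholds).
#' @export
roc_auc <- function(scores, labels, direction = c("higher_positive", "lower_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    eq_error("echoquant_validation", "scores/labels must be equal-length and complete")
  if (all(labels) || !any(labels))
    eq_error("echoquant_undefined_auc", "both classes must be present")
  s <- if (direction == "lower_positive") -scores else scores
  npos <- sum(labels); nneg <- sum(!labels)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  th <- c(Inf, sort(unique(s), decreasing = TRUE))
  curve <- data.frame(
    tpr = vapply(th, function(t) sum(s[labels] >= t) / npos, 0),
    fpr = vapply(th, function(t) sum(s[!labels] >= t) / nneg, 0)
  )
  list(auc = auc, curve = curve)
}

#' Uni- and multivariate logistic regression for binary US predictors
#'
#' Maximum-likelihood logistic regression (fit by iteratively reweighted
#' least squares via [stats::glm]) of a binary outcome on binary predictors,
#' with Wald confidence intervals on the odds-ratio scale. In univariate
#' mode each predictor is fit alone (its beta then equals the log odds
#' ratio of the corresponding 2x2 table); in multivariate mode all
#' predictors enter one model.
#'
#' @param data data frame holding the predictors and outcome.
#' @param predictors character vector of predictor column names (binary).
#' @param outcome name of the binary outcome column (0/1 or logical).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param conf confidence level for the Wald intervals.
#' @return An object of class `logistic_fit`: a data frame with one row per
#'   predictor (`predictor`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `p`,
#'   `separation`).
#' @export
logistic_fit <- function(data, predictors, outcome = "truth_bin",
                         mode = c("univariate", "multivariate"), conf = 0.95) {
  mode <- match.arg(mode)
  y <- data[[outcome]]
  if (is.null(y)) eq_error("echoquant_validation", paste("no such column:", outcome))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  fit_one <- function(preds) {
    fm <- stats::as.formula(paste(outcome, "~", paste(preds, collapse = " + ")))
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fm, data = data, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!fit$converged)
      eq_error("echoquant_convergence", "logistic regression did not converge")
    cf <- summary(fit)$coefficients
    rows <- rownames(cf) != "(Intercept)"
    if (any(abs(cf[rows, 1]) > 15)) sep <- TRUE
    data.frame(
      predictor = sub("TRUE$", "", rownames(cf)[rows]),
      beta = cf[rows, 1], se = cf[rows, 2],
      or = exp(cf[rows, 1]),
      ci_low = exp(cf[rows, 1] - z * cf[rows, 2]),
      ci_high = exp(cf[rows, 1] + z * cf[rows, 2]),
      p = cf[rows, 4], separation = sep,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- if (mode == "univariate") {
    do.call(rbind, lapply(predictors, fit_one))
  } else {
    fit_one(predictors)
  }
  structure(out, class = c("logistic_fit", "data.frame"), mode = mode)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (%s)\n", attr(x, "mode")))
  df <- as.data.frame(x)
  df$beta <- round(df$beta, 4); df$or <- round(df$or, 2)
  df$ci <- sprintf("%.2f-%.2f", df$ci_low, df$ci_high)
  df$p <- format.pval(df$p, digits = 3)
  print(df[, c("predictor", "beta", "or", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Malignancy prevalence by quartile of an echogenicity index
#'
#' Splits the records at the first, second and third quartiles of the index
#' (type-7 quantiles by default; group boundaries are half-open with the
#' quantile itself in the upper group) and reports the malignant fraction in
#' each quarter, plus a chi-square test for linear trend in proportions
#' across the ordered groups.
#'
#' @param values numeric EI values (n >= 4).
#' @param labels binary truth (1/TRUE = malignant).
#' @param qtype quantile algorithm type passed to [stats::quantile].
#' @return An object of class `quartile_prevalence`: a data frame with one
#'   row per group (`group`, `lo`, `hi`, `n`, `n_positive`, `fraction`,
#'   `degenerate`), with the trend-test p-value in attribute `trend_p`.
#' @export
quartile_prevalence <- function(values, labels, qtype = 7) {
  labels <- as.logical(labels)
  if (length(values) < 4L) eq_error("echoquant_validation", "need at least 4 records")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
  grp <- 1L + (values >= q[1]) + (values >= q[2]) + (values >= q[3])
  rows <- lapply(1:4, function(g) {
    idx <- grp == g
    n <- sum(idx)
    data.frame(group = g,
               lo = if (n) min(values[idx]) else NA_real_,
               hi = if (n) max(values[idx]) else NA_real_,
               n = n, n_positive = sum(labels[idx]),
               fraction = if (n) sum(labels[idx]) / n else NA_real_,
               degenerate = n == 0L)
  })
  out <- do.call(rbind, rows)
  trend_p <- if (any(out$degenerate) || sum(out$n_positive) == 0 ||
                 sum(out$n_positive) == sum(out$n)) NA_real_ else
    suppressWarnings(stats::prop.trend.test(out$n_positive, out$n)$p.value)
  structure(out, class = c("quartile_prevalence", "data.frame"), trend_p = trend_p)
}

#' @export
print.quartile_prevalence <- function(x, ...) {
  df <- as.data.frame(x)
  df$range <- sprintf("[%.2f, %.2f]", df$lo, df$hi)
  df$fraction <- round(df$fraction, 3)
  print(df[, c("group", "range", "n", "n_positive", "fraction")], row.names = FALSE)
  cat(sprintf("chi-square trend p = %.4g\n", attr(x, "trend_p")))
  invisible(x)
}

#' Full diagnostic report over a cohort of nodule records
#'
#' For every available predictor -- the binary US features and the
#' echogenicity indices under their cut-off rules -- builds the 2x2 table
#' against histological truth and reports counts, diagnostic metrics, odds
#' ratio with Woolf CI, Fisher's exact p, and the univariate logistic beta.
#'
#' @param records data frame of nodule records (see [make_cohort] for the
#'   schema).
#' @return A data frame with one row per predictor, class
#'   `diagnostic_report`.
#' @export
diagnostic_report <- function(records) {
  specs <- list(
    list(name = "size_lt_2cm", col = "size_ge_2cm", rule = NULL, negate = TRUE),
    list(name = "us_e_hypo", col = "us_e_hypo", rule = NULL, negate = FALSE),
    list(name = "irregular_margin", col = "irregular_margin", rule = NULL, negate = FALSE),
    list(name = "microcalcification", col = "microcalcification", rule = NULL, negate = FALSE),
    list(name = "heterogeneous", col = "heterogeneous", rule = NULL, negate = FALSE),
    list(name = "ei_n_lt_median", col = "ei_n", rule = "less_than_median", negate = FALSE),
    list(name = "ei_nt_lt_median", col = "ei_nt", rule = "less_than_median", negate = FALSE),
    list(name = "ei_nm_lt_median", col = "ei_nm", rule = "less_than_median", negate = FALSE),
    list(name = "ei_auto_lt_median", col = "ei_auto", rule = "less_than_median", negate = FALSE),
    list(name = "ei_nt_lt_zero", col = "ei_nt", rule = "less_than_zero", negate = FALSE),
    list(name = "ei_nm_lt_zero", col = "ei_nm", rule = "less_than_zero", negate = FALSE)
  )
  rows <- lapply(specs, function(s) {
    if (!s$col %in% names(records) || anyNA(records[[s$col]])) return(NULL)
    tab <- contingency_from_records(records, s$col, rule = s$rule, negate = s$negate)
    met <- diagnostic_metrics(tab)
    orr <- tryCatch(odds_ratio(tab), echoquant_undefined_or = function(e)
      odds_ratio(tab, continuity = "haldane"))
    data.frame(predictor = s$name, tp = tab$a, fn = tab$b, fp = tab$c, tn = tab$d,
               sensitivity = met$sensitivity, specificity = met$specificity,
               ppv = met$ppv, npv = met$npv, accuracy = met$accuracy,
               beta = orr$beta, or = orr$or, ci_low = orr$ci_low,
               ci_high = orr$ci_high, fisher_p = fisher_exact(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("diagnostic_report", "data.frame"))
}
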