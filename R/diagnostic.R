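# Dichotomized diagnostic analysis: 2x2 confusion tables against the
# gold standard, Cohen's kappa, exact McNemar, and the metric battery with
# confidence intervals. Point estimates for accuracy / sensitivity /
# specificity carry Clopper-Pearson exact intervals; PPV and NPV carry
# standard-logit intervals (the combination used in clinical FFR
# validation tables). A small exhaustive-search oracle reconstructs the
# unique integer table behind printed percentages.

#' Confusion table
#'
#' @param tp,fp,fn,tn non-negative integer cell counts (positive =
#'   functional failure, i.e. FFR at or below the threshold)
#' @return object of class `confusion_table`
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_ffrct("cell counts must be non-negative integers", class = "ffrct_stats_error")
  if (sum(cells) < 1)
    stop_ffrct("confusion table must contain at least one observation",
               class = "ffrct_stats_error")
  structure(as.list(cells), n = sum(cells), class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("2x2 table (n = %d): tp %d, fp %d, fn %d, tn %d\n",
              attr(x, "n"), x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Dichotomize FFR values at a diagnostic threshold
#'
#' Positive (functional failure) means value at or below the threshold;
#' the default threshold 0.90 is the usual post-intervention cut-point.
#' The same inclusive rule applies to candidate and gold-standard values.
#'
#' @param values numeric vector of FFR values
#' @param threshold diagnostic threshold, default 0.90
#' @return logical vector, `TRUE` = positive
#' @export
dichotomize <- function(values, threshold = 0.90) {
  if (any(!is.finite(values)))
    stop_ffrct("non-finite FFR values", class = "ffrct_stats_error")
  values <= threshold
}

#' Build a confusion table from binary labels
#'
#' @param gold logical vector, gold-standard positives
#' @param pred logical vector, candidate-method positives
#' @return a [confusion_table()]
#' @export
confusion_from_labels <- function(gold, pred) {
  stopifnot(length(gold) == length(pred))
  confusion_table(tp = sum(gold & pred), fp = sum(!gold & pred),
                  fn = sum(gold & !pred), tn = sum(!gold & !pred))
}

clopper_pearson <- function(x, n, conf = 0.95) {
  a <- 1 - conf
  lo <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(lo, hi)
}

logit_ci_predictive <- function(value, var_logit, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lg <- stats::qlogis(value)
  stats::plogis(c(lg - z * sqrt(var_logit), lg + z * sqrt(var_logit)))
}

#' Diagnostic metrics with confidence intervals
#'
#' Accuracy `(tp+tn)/n`, sensitivity `tp/(tp+fn)`, specificity
#' `tn/(tn+fp)`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`. Accuracy,
#' sensitivity and specificity carry Clopper-Pearson exact intervals; PPV
#' and NPV carry standard-logit intervals with
#' `var(logit PPV) = ((1-se)/se)/n1 + (sp/(1-sp))/n0` and
#' `var(logit NPV) = (se/(1-se))/n1 + ((1-sp)/sp)/n0`, where n1/n0 are the
#' gold-standard positive/negative counts. A metric with a zero
#' denominator is reported as `NA` with a flag.
#'
#' @param table a [confusion_table()]
#' @param conf confidence level, default 0.95
#' @return object of class `diagnostic_report`: per metric a list with
#'   `estimate`, `ci` (both as proportions) plus `kappa` from
#'   [cohen_kappa()]
#' @export
diagnostic_metrics <- function(table, conf = 0.95) {
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- attr(table, "n")
  n1 <- tp + fn
  n0 <- tn + fp
  metric <- function(x, d, ci_fun) {
    if (d == 0) return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                            undefined = TRUE))
    list(estimate = x / d, ci = ci_fun(x / d), undefined = FALSE)
  }
  acc <- metric(tp + tn, n, function(p) clopper_pearson(tp + tn, n, conf))
  sens <- metric(tp, n1, function(p) clopper_pearson(tp, n1, conf))
  spec <- metric(tn, n0, function(p) clopper_pearson(tn, n0, conf))
  se_hat <- if (n1 > 0) tp / n1 else NA_real_
  sp_hat <- if (n0 > 0) tn / n0 else NA_real_
  ppv <- metric(tp, tp + fp, function(p) {
    v <- ((1 - se_hat) / se_hat) / n1 + (sp_hat / (1 - sp_hat)) / n0
    logit_ci_predictive(p, v, conf)
  })
  npv <- metric(tn, tn + fn, function(p) {
    v <- (se_hat / (1 - se_hat)) / n1 + ((1 - sp_hat) / sp_hat) / n0
    logit_ci_predictive(p, v, conf)
  })
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, kappa = cohen_kappa(table, conf),
                 n = n, conf = conf),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  fmt <- function(m, name) {
    if (isTRUE(m$undefined)) return(sprintf("  %-12s undefined\n", name))
    sprintf("  %-12s %.1f%% (%.0f%% CI %.1f-%.1f%%)\n", name,
            100 * m$estimate, 100 * x$conf, 100 * m$ci[1], 100 * m$ci[2])
  }
  cat(sprintf("Diagnostic report (n = %d):\n", x$n))
  cat(fmt(x$accuracy, "accuracy"), fmt(x$sensitivity, "sensitivity"),
      fmt(x$specificity, "specificity"), fmt(x$ppv, "PPV"),
      fmt(x$npv, "NPV"), sep = "")
  cat(sprintf("  kappa        %.2f (CI %.2f-%.2f, %s)\n", x$kappa$kappa,
              x$kappa$ci[1], x$kappa$ci[2], x$kappa$band))
  invisible(x)
}

#' Cohen's kappa for a 2x2 table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement from the
#' row/column marginals, the large-sample standard error
#' `sqrt(p_o (1-p_o) / (n (1-p_e)^2))`, and the qualitative band at the
#' conventional cut-points (< 0.40 poor, 0.40-0.60 moderate, 0.60-0.80
#' good, > 0.80 excellent).
#'
#' @param table a [confusion_table()]
#' @param conf confidence level, default 0.95
#' @return list with `kappa`, `se`, `ci`, `p_o`, `p_e`, `band`
#' @export
cohen_kappa <- function(table, conf = 0.95) {
  tp <- table$tp; fp <- table$fp; fn <- table$fn; tn <- table$tn
  n <- attr(table, "n")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (p_e >= 1)
    stop_ffrct("expected agreement is 1; kappa undefined", class = "ffrct_stats_error")
  kap <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  band <- if (kap < 0.40) "poor" else if (kap <= 0.60) "moderate"
          else if (kap <= 0.80) "good" else "excellent"
  list(kappa = kap, se = se, ci = c(kap - z * se, kap + z * se),
       p_o = p_o, p_e = p_e, band = band)
}

#' Exact McNemar test
#'
#' Exact two-sided binomial test on the discordant counts:
#' `p = min(1, 2 * P(X <= min(b, c)))` with `X ~ Binomial(b + c, 1/2)`.
#' `b = c = 0` returns p = 1 by convention.
#'
#' @param b,c discordant counts
#' @return p-value
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop_ffrct("discordant counts must be non-negative integers",
               class = "ffrct_stats_error")
  if (b + c == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
}

#' Reconstruct the unique 2x2 table behind printed percentages
#'
#' Exhaustively searches positive counts `P = 1..n-1` and integer cells
#' for tables whose sensitivity and specificity round (half-up, one
#' decimal) to the supplied percentages, optionally cross-checked against
#' printed PPV and NPV. Returns the table if it is unique; raises an
#' error listing the candidates otherwise.
#'
#' @param sens_pct printed sensitivity, percent to one decimal
#' @param spec_pct printed specificity, percent to one decimal
#' @param n total sample size
#' @param ppv_pct,npv_pct optional printed predictive values for
#'   disambiguation
#' @return a [confusion_table()]
#' @export
reconstruct_confusion <- function(sens_pct, spec_pct, n,
                                  ppv_pct = NULL, npv_pct = NULL) {
  match1 <- function(x, d, target) {
    d > 0 && round_half_up(100 * x / d, 1) == target
  }
  found <- list()
  for (P in 1:(n - 1)) {
    N <- n - P
    tps <- which(vapply(0:P, function(tp) match1(tp, P, sens_pct), TRUE)) - 1L
    tns <- which(vapply(0:N, function(tn) match1(tn, N, spec_pct), TRUE)) - 1L
    for (tp in tps) for (tn in tns) {
      fn <- P - tp
      fp <- N - tn
      if (!is.null(ppv_pct) && !match1(tp, tp + fp, ppv_pct)) next
      if (!is.null(npv_pct) && !match1(tn, tn + fn, npv_pct)) next
      found[[length(found) + 1L]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
    }
  }
  if (length(found) == 0L)
    stop_ffrct("no integer 2x2 table at n = %d matches the printed percentages",
               n, class = "ffrct_stats_error")
  if (length(found) > 1L) {
    desc <- paste(vapply(found, function(f)
      sprintf("(%d,%d,%d,%d)", f["tp"], f["fp"], f["fn"], f["tn"]), ""),
      collapse = " ")
    stop_ffrct("printed percentages are ambiguous at n = %d: candidates %s",
               n, desc, class = "ffrct_ambiguous_error")
  }
  f <- found[[1]]
  confusion_table(f[["tp"]], f[["fp"]], f[["fn"]], f[["tn"]])
}
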