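# End-to-end study pipeline: generate a synthetic cohort, compute pre- and
# post-intervention FFR-CT both ways, and run the complete agreement and
# diagnostic battery overall and stratified by discovery/validation
# cohort. Every number in the report is recomputable from the emitted
# cohort record table alone.

#' Run the full virtual-stenting replication study
#'
#' Executes [generate_cohort()] and then, on the record table, the
#' continuous agreement block (Bland-Altman, Spearman, ICC, Passing-Bablok,
#' RMSE) for the pre-PCI comparison and both post-PCI arms, overall and per
#' cohort, plus the diagnostic block at the post-PCI threshold 0.90
#' (metrics with CIs and kappa per arm, exact McNemar between arms, and
#' the discordance share). Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()]
#' @param threshold diagnostic FFR threshold, default 0.90
#' @return object of class `study_report`
#' @export
run_study <- function(config = cohort_config(), threshold = 0.90) {
  cohort <- generate_cohort(config)
  rep <- analyze_cohort(cohort$records, threshold = threshold)
  rep$config <- config
  rep$seed <- config$seed
  rep$cohort <- cohort
  rep
}

#' Recompute all study statistics from a cohort record table
#'
#' The statistical half of [run_study()], usable directly on a record
#' table read back from CSV; re-running it on the emitted table reproduces
#' the report bit for bit.
#'
#' @param records data frame of vessel records (see [generate_cohort()])
#' @param threshold diagnostic FFR threshold, default 0.90
#' @return object of class `study_report`
#' @export
analyze_cohort <- function(records, threshold = 0.90) {
  agree_block <- function(df, xcol, ycol) {
    x <- df[[xcol]]
    y <- df[[ycol]]
    list(n = length(x),
         median_x = stats::median(x), median_y = stats::median(y),
         p_median = wilcoxon_signed_rank(y, x)$p,
         bland_altman = bland_altman(x, y),
         spearman = spearman_cor(x, y),
         icc = icc_oneway(cbind(x, y)),
         passing_bablok = suppressWarnings(passing_bablok(x, y)),
         rmse = rmse(x, y))
  }
  arms <- list(
    pre = c("ffr_invasive_pre", "ffr_ct_pre"),
    post_blinded = c("ffr_invasive_post", "ffr_ct_post_blinded"),
    post_nonblinded = c("ffr_invasive_post", "ffr_ct_post_nonblinded"))
  strata <- list(overall = records,
                 discovery = records[records$cohort == "discovery", ],
                 validation = records[records$cohort == "validation", ])
  agreement <- lapply(strata, function(df)
    lapply(arms, function(cols) agree_block(df, cols[1], cols[2])))

  gold <- dichotomize(records$ffr_invasive_post, threshold)
  pred_b <- dichotomize(records$ffr_ct_post_blinded, threshold)
  pred_nb <- dichotomize(records$ffr_ct_post_nonblinded, threshold)
  disc <- sum(pred_b != pred_nb)
  diagnostic <- list(
    threshold = threshold,
    blinded = diagnostic_metrics(confusion_from_labels(gold, pred_b)),
    nonblinded = diagnostic_metrics(confusion_from_labels(gold, pred_nb)),
    mcnemar_between_arms = mcnemar_exact(sum(pred_b & !pred_nb),
                                         sum(!pred_b & pred_nb)),
    discordance_share = disc / nrow(records),
    discordant = c(b = sum(pred_b & !pred_nb), c = sum(!pred_b & pred_nb)))

  structure(list(agreement = agreement, diagnostic = diagnostic,
                 n = nrow(records),
                 n_discovery = sum(records$cohort == "discovery"),
                 n_validation = sum(records$cohort == "validation")),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Study report: %d vessels (%d discovery / %d validation)\n",
              x$n, x$n_discovery, x$n_validation))
  for (stratum in names(x$agreement)) {
    cat(sprintf("-- %s --\n", stratum))
    for (arm in names(x$agreement[[stratum]])) {
      b <- x$agreement[[stratum]][[arm]]
      cat(sprintf(paste0("  %-15s median %.2f vs %.2f (p = %.3f); bias %.4f, ",
                         "LOA %.3f to %.3f; rho %.3f; ICC %.3f; PB slope %.3f, ",
                         "intercept %.3f; RMSE %.4f\n"),
                  arm, b$median_x, b$median_y, b$p_median,
                  b$bland_altman$mean_diff, b$bland_altman$loa_low,
                  b$bland_altman$loa_high, b$spearman$rho, b$icc$icc,
                  b$passing_bablok$slope, b$passing_bablok$intercept, b$rmse))
    }
  }
  cat(sprintf("-- diagnostic at FFR <= %.2f --\n", x$diagnostic$threshold))
  cat("blinded arm:\n"); print(x$diagnostic$blinded)
  cat("non-blinded arm:\n"); print(x$diagnostic$nonblinded)
  cat(sprintf("McNemar between arms p = %.3f; discordance %d + %d of %d (%.1f%%)\n",
              x$diagnostic$mcnemar_between_arms, x$diagnostic$discordant["b"],
              x$diagnostic$discordant["c"], x$n,
              100 * x$diagnostic$discordance_share))
  invisible(x)
}

#' Write a study report as JSON
#'
#' Full-precision machine-readable dump of every statistic in the report
#' (the cohort table itself is written separately with
#' [write_cohort_csv()]).
#'
#' @param report a `study_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_study_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, c("bland_altman", "passing_bablok", "icc_result",
                      "diagnostic_report", "confusion_table")))
      x <- unclass(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- list(n = report$n, n_discovery = report$n_discovery,
              n_validation = report$n_validation, seed = report$seed,
              agreement = strip(report$agreement),
              diagnostic = strip(report$diagnostic))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
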