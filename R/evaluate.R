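# Figures of merit and the statistical comparison protocol against a
# reference method. Recovery is 100 * found / taken; RMSEC and RMSEP are
# the root mean square errors of calibration (training autoprediction) and
# of prediction (independent test set). Method comparison uses the
# pooled-variance two-sample t-test and the variance-ratio F-test on
# summary statistics, against two-tailed t and upper-tail F critical
# values at significance alpha.

#' Assay report: taken/found/recovery with summary figures of merit
#'
#' @param taken Reference concentrations (ug/mL), all > 0.
#' @param found Model-predicted concentrations, same length.
#' @param role `"calibration"` (training autoprediction; RMSE is labelled
#'   RMSEC) or `"prediction"` (independent test set; RMSEP).
#' @return Object of class `"assay_report"`: list with `samples` (data
#'   frame taken/found/recovery), `mean_recovery`, `sd_recovery` (percent),
#'   `rmse` (ug/mL), `role`.
#' @export
assay_report <- function(taken, found, role = c("calibration", "prediction")) {
  role <- match.arg(role)
  taken <- as.numeric(taken); found <- as.numeric(found)
  if (length(taken) < 1L || length(taken) != length(found))
    stop("taken and found must be non-empty and of equal length")
  if (any(taken == 0))
    stop("taken contains zero at row ", which(taken == 0)[1],
         "; recovery undefined")
  recovery <- 100 * found / taken
  structure(list(
    samples = data.frame(taken = taken, found = found, recovery = recovery),
    mean_recovery = mean(recovery),
    sd_recovery = if (length(recovery) > 1L) stats::sd(recovery) else 0,
    rmse = rmsep(taken, found),
    role = role),
    class = "assay_report")
}

#' @export
print.assay_report <- function(x, digits = 2, ...) {
  lab <- if (x$role == "calibration") "RMSEC" else "RMSEP"
  df <- x$samples
  df$found <- round(df$found, 3)
  df$recovery <- round(df$recovery, digits)
  names(df) <- c("Taken (ug/mL)", "Found (ug/mL)", "R%")
  print(df, row.names = FALSE)
  cat(sprintf("Mean (%%)  %.*f\nSD        %.*f\n%s     %.4f ug/mL\n",
              digits, x$mean_recovery, max(digits, 3), x$sd_recovery,
              lab, x$rmse))
  invisible(x)
}

#' Write an assay report as CSV
#'
#' Per-sample rows followed by `Mean`, `SD` and `RMSEC`/`RMSEP` summary
#' rows, mirroring the conventional assay-table layout.
#'
#' @param x An `"assay_report"`.
#' @param path Output file path.
#' @export
write_assay_csv <- function(x, path) {
  lab <- if (x$role == "calibration") "RMSEC" else "RMSEP"
  lines <- c("taken,found,recovery",
             sprintf("%s,%s,%s", format_num(x$samples$taken),
                     format_num(x$samples$found),
                     format_num(x$samples$recovery)),
             sprintf("Mean,,%s", format_num(x$mean_recovery)),
             sprintf("SD,,%s", format_num(x$sd_recovery)),
             sprintf("%s,%s,", lab, format_num(x$rmse)))
  writeLines(lines, path)
  invisible(NULL)
}

#' Variance-ratio F-test from summary statistics
#'
#' The statistic places the larger variance in the numerator, so it is
#' invariant to argument order and always >= 1; the critical value is the
#' upper-alpha quantile of the F distribution with degrees of freedom
#' ordered accordingly.
#'
#' @param var1,var2 Sample variances, > 0.
#' @param n1,n2 Sample sizes, >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List with `f_statistic`, `f_critical`, `significant`,
#'   `df` (numerator, denominator).
#' @export
f_test_summary <- function(var1, var2, n1, n2, alpha = 0.05) {
  if (var1 <= 0 || var2 <= 0) stop("variances must be positive")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (var1 >= var2) { vn <- var1; vd <- var2; dfn <- n1 - 1; dfd <- n2 - 1 }
  else { vn <- var2; vd <- var1; dfn <- n2 - 1; dfd <- n1 - 1 }
  fstat <- vn / vd
  fcrit <- stats::qf(1 - alpha, dfn, dfd)
  list(f_statistic = fstat, f_critical = fcrit,
       significant = fstat > fcrit, df = c(dfn, dfd))
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Classical method-comparison t-test on means, SDs and sizes, with the
#' two-tailed critical value at `n1 + n2 - 2` degrees of freedom.
#'
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations, >= 0.
#' @param n1,n2 Group sizes, >= 2.
#' @param alpha Significance level (default 0.05).
#' @return List with `t_statistic`, `t_critical`, `significant`, `df`.
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (sd1 == 0 && sd2 == 0 && mean1 != mean2)
    stop("zero variance in both groups with differing means: statistic infinite")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  list(t_statistic = tstat, t_critical = tcrit,
       significant = abs(tstat) > tcrit, df = df)
}

#' Tabulated critical values for the comparison protocol
#'
#' @param alpha Significance level.
#' @param df_t Degrees of freedom for the two-tailed t quantile.
#' @param df_f Length-2 vector (numerator, denominator) for the upper-tail
#'   F quantile.
#' @return List with `t_critical` and `f_critical`.
#' @export
critical_values <- function(alpha, df_t, df_f) {
  if (df_t <= 0 || any(df_f <= 0)) stop("degrees of freedom must be positive")
  list(t_critical = stats::qt(1 - alpha / 2, df_t),
       f_critical = stats::qf(1 - alpha, df_f[1], df_f[2]))
}

#' Compare a candidate assay against a reference method
#'
#' Runs the pooled t-test on means and the variance-ratio F-test on
#' variances from summary statistics of replicate recoveries.
#'
#' @param candidate,reference Lists (or named vectors) with `mean`, `sd`,
#'   `n`.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `"method_comparison"` combining both tests.
#' @export
method_comparison <- function(candidate, reference, alpha = 0.05) {
  cand <- as.list(candidate); ref <- as.list(reference)
  tt <- t_test_summary(cand$mean, cand$sd, cand$n,
                       ref$mean, ref$sd, ref$n, alpha)
  ft <- f_test_summary(cand$sd^2, ref$sd^2, cand$n, ref$n, alpha)
  structure(list(candidate = cand, reference = ref, alpha = alpha,
                 t = tt, f = ft),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Method comparison (alpha = ", x$alpha, ")\n", sep = "")
  cat(sprintf("  candidate: mean %.3f, SD %.3f, n %d\n",
              x$candidate$mean, x$candidate$sd, x$candidate$n))
  cat(sprintf("  reference: mean %.3f, SD %.3f, n %d\n",
              x$reference$mean, x$reference$sd, x$reference$n))
  cat(sprintf("  t = %.3f (critical %.3f, df %d) -> %s\n",
              x$t$t_statistic, x$t$t_critical, x$t$df,
              if (x$t$significant) "significant" else "not significant"))
  cat(sprintf("  F = %.3f (critical %.3f, df %d,%d) -> %s\n",
              x$f$f_statistic, x$f$f_critical, x$f$df[1], x$f$df[2],
              if (x$f$significant) "significant" else "not significant"))
  invisible(x)
}
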