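#' @include metrics.R
NULL

.bootCI <- function(stat, n, n_boot, seed, level = 0.95) {
  .withSeed(seed, {
    vals <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      stat(idx)
    }, numeric(1))
    a <- (1 - level) / 2
    stats::quantile(vals, c(a, 1 - a), names = FALSE, na.rm = TRUE)
  })
}

#' Pearson correlation with bootstrap CI and F-test p-value
#'
#' Product-moment correlation with a seeded percentile bootstrap over
#' paired resamples (default 5000 iterations) and a p-value from the
#' regression F-test (equivalent to the square of the t statistic for a
#' simple correlation).
#'
#' @param x,y paired numeric vectors (n >= 3, finite).
#' @param n_boot bootstrap iterations.
#' @param seed bootstrap seed.
#' @return list(r, ci = c(lo, hi), p, n).
#' @export
pearsonWithCI <- function(x, y, n_boot = 5000L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  n <- length(x)
  r <- stats::cor(x, y)
  Fstat <- r^2 * (n - 2) / (1 - r^2)
  p <- if (1 - r^2 < 1e-15) 0 else
    stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  ci <- .bootCI(function(idx) {
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
    else stats::cor(x[idx], y[idx])
  }, n, n_boot, seed)
  list(r = r, ci = ci, p = p, n = n)
}

# ICC(2,1): two-way random effects, absolute agreement, single rater,
# from the two-column table via ANOVA mean squares.
.icc21 <- function(x, y) {
  n <- length(x); k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  rowM <- rowMeans(m); colM <- colMeans(m)
  MSR <- k * sum((rowM - grand)^2) / (n - 1)
  MSC <- n * sum((colM - grand)^2) / (k - 1)
  SSE <- sum((m - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  list(icc = icc, MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Intraclass correlation ICC(2,1) with bootstrap CI and F-test p-value
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC
#' computed from the ANOVA mean squares of the n x 2 measurement table;
#' seeded percentile bootstrap over subjects; p-value from the F-test
#' F = MSR / MSE with (n - 1, (n - 1)(k - 1)) degrees of freedom.
#'
#' @inheritParams pearsonWithCI
#' @return list(icc, ci, p, n).
#' @export
iccWithCI <- function(x, y, n_boot = 5000L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("degenerate (constant) measurement columns")
  n <- length(x)
  fit <- .icc21(x, y)
  Fstat <- fit$MSR / fit$MSE
  p <- if (fit$MSE < 1e-30) 0 else
    stats::pf(Fstat, n - 1, (n - 1) * (2 - 1), lower.tail = FALSE)
  ci <- .bootCI(function(idx) .icc21(x[idx], y[idx])$icc, n, n_boot, seed)
  list(icc = fit$icc, ci = ci, p = p, n = n)
}

#' Mean absolute error with bootstrap CI
#'
#' @inheritParams pearsonWithCI
#' @return list(mae, ci, n).
#' @export
maeWithCI <- function(x, y, n_boot = 5000L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  d <- abs(x - y)
  ci <- .bootCI(function(idx) mean(d[idx]), n, n_boot, seed)
  list(mae = mean(d), ci = ci, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences against means, with bias = mean difference and limits of
#' agreement bias +/- 1.96 sd of the differences.
#'
#' @param x,y paired numeric vectors.
#' @return list(bias, loa_lower, loa_upper, means, differences).
#' @export
blandAltman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  bias <- mean(d)
  s <- if (length(d) > 1) stats::sd(d) else 0
  list(bias = bias, loa_lower = bias - 1.96 * s,
       loa_upper = bias + 1.96 * s, means = (x + y) / 2, differences = d)
}

#' Bland-Altman plot
#'
#' @param ba result of [blandAltman()].
#' @param main,xlab,ylab plot labels.
#' @return Invisibly, \code{ba}.
#' @export
plotBlandAltman <- function(ba, main = "Bland-Altman",
                            xlab = "mean of methods",
                            ylab = "difference") {
  graphics::plot(ba$means, ba$differences, pch = 19, col = "#00000080",
                 main = main, xlab = xlab, ylab = ylab)
  graphics::abline(h = ba$bias, col = "blue")
  graphics::abline(h = c(ba$loa_lower, ba$loa_upper), col = "red",
                   lty = 2)
  invisible(ba)
}

#' Per-metric agreement report for paired measurement tables
#'
#' Computes, for every shared metric column of two per-eye measurement
#' tables, Pearson r, ICC(2,1) and MAE with seeded bootstrap CIs and
#' p-values, plus Bland-Altman bias and limits of agreement.
#'
#' @param a,b data.frames with one row per eye and identical metric
#'   columns (e.g. from \code{as.data.frame} of [ChoroidMetrics-class]).
#' @param metrics character vector of column names to compare.
#' @param n_boot,seed bootstrap settings.
#' @return An [AgreementReport-class].
#' @export
agreementReport <- function(a, b,
                            metrics = c("rt_mm", "ct_mm", "ca_mm2",
                                        "cv_mm3", "cvi"),
                            n_boot = 5000L, seed = 1L) {
  stopifnot(nrow(a) == nrow(b))
  rows <- lapply(metrics, function(mt) {
    x <- a[[mt]]; y <- b[[mt]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3) {
      # too few finite pairs for any correlation statistic
      return(data.frame(metric = mt, n = length(x),
                        pearson_r = NA_real_, pearson_lo = NA_real_,
                        pearson_hi = NA_real_, pearson_p = NA_real_,
                        icc = NA_real_, icc_lo = NA_real_,
                        icc_hi = NA_real_, icc_p = NA_real_,
                        mae = if (length(x)) mean(abs(x - y)) else NA_real_,
                        mae_lo = NA_real_, mae_hi = NA_real_,
                        ba_bias = if (length(x)) mean(x - y) else NA_real_,
                        ba_lo = NA_real_, ba_hi = NA_real_,
                        stringsAsFactors = FALSE))
    }
    pe <- pearsonWithCI(x, y, n_boot, seed)
    ic <- iccWithCI(x, y, n_boot, seed)
    ma <- maeWithCI(x, y, n_boot, seed)
    ba <- blandAltman(x, y)
    data.frame(metric = mt, n = length(x),
               pearson_r = pe$r, pearson_lo = pe$ci[1],
               pearson_hi = pe$ci[2], pearson_p = pe$p,
               icc = ic$icc, icc_lo = ic$ci[1], icc_hi = ic$ci[2],
               icc_p = ic$p,
               mae = ma$mae, mae_lo = ma$ci[1], mae_hi = ma$ci[2],
               ba_bias = ba$bias, ba_lo = ba$loa_lower,
               ba_hi = ba$loa_upper, stringsAsFactors = FALSE)
  })
  new("AgreementReport", stats = do.call(rbind, rows),
      nBoot = as.integer(n_boot), seed = as.integer(seed))
}

#' Format a p-value the way agreement tables print it
#'
#' @param p numeric p-value.
#' @return \code{"***"} for p < 0.001, otherwise the rounded value.
#' @export
formatPValue <- function(p) {
  ifelse(p < 0.001, "***", sprintf("%.3f", p))
}

#' Reader-study scoring of real-versus-synthetic grading records
#'
#' Scores expert responses against ground truth: accuracy, sensitivity
#' (proportion of real items called real; "real" is the positive class)
#' and specificity (proportion of synthetic items called synthetic), per
#' expert and for the per-item expert majority, overall and within each
#' stratum and task. Paired-task records are expected to contribute one
#' row per image, like single-image records.
#'
#' @param records data.frame with columns \code{item}, \code{truth}
#'   (\code{"real"} or \code{"synthetic"}), optional \code{stratum} and
#'   \code{task}, and one response column per expert (values drawn from
#'   the same answer set as \code{truth}).
#' @param experts character vector naming the expert response columns;
#'   must be of odd length for the majority vote.
#' @return data.frame with one row per (grader, scope) combination and
#'   columns grader, scope, n, accuracy, sensitivity, specificity (in
#'   percent).
#' @export
gradingScores <- function(records, experts = grep("^expert",
                                                  names(records),
                                                  value = TRUE)) {
  stopifnot(nrow(records) >= 1, all(experts %in% names(records)))
  if (length(experts) %% 2 == 0)
    stop("majority voting needs an odd number of experts")
  if (!all(records$truth %in% c("real", "synthetic")))
    stop("truth must be 'real' or 'synthetic'")
  resp <- as.matrix(records[, experts, drop = FALSE])
  majority <- apply(resp, 1, function(r) {
    names(sort(table(r), decreasing = TRUE))[1]
  })
  graders <- c(stats::setNames(experts, experts),
               majority = "majority")
  scopes <- list(all = rep(TRUE, nrow(records)))
  if (!is.null(records$stratum))
    for (st in unique(records$stratum))
      scopes[[st]] <- records$stratum == st
  if (!is.null(records$task))
    for (tk in unique(records$task))
      scopes[[paste0("task_", tk)]] <- records$task == tk
  out <- list()
  for (g in names(graders)) {
    pred <- if (g == "majority") majority else records[[g]]
    for (sc in names(scopes)) {
      sel <- scopes[[sc]]
      tr <- records$truth[sel]; pr <- pred[sel]
      correct <- pr == tr
      isReal <- tr == "real"
      out[[length(out) + 1L]] <- data.frame(
        grader = g, scope = sc, n = sum(sel),
        accuracy = 100 * mean(correct),
        sensitivity = if (any(isReal)) 100 * mean(correct[isReal])
                      else NA_real_,
        specificity = if (any(!isReal)) 100 * mean(correct[!isReal])
                      else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write an agreement report to JSON and CSV
#'
#' @param report an [AgreementReport-class].
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Invisibly, the written file paths.
#' @export
writeAgreementReport <- function(report, dir, prefix = "agreement") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, ".csv"))
  js <- file.path(dir, paste0(prefix, ".json"))
  utils::write.csv(report@stats, csv, row.names = FALSE)
  jsonlite::write_json(list(n_boot = report@nBoot, seed = report@seed,
                            stats = report@stats),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
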