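# Test-retest reliability: ICC(2,1) — two-way random effects, absolute
# agreement, single measures — with subject-resampled bootstrap percentile
# confidence intervals, and a paired bootstrap for the between-condition
# ICC difference.

#' ICC(2,1): two-way random, absolute agreement, single measures
#'
#' From the two-way ANOVA decomposition of an n subjects x k raters table
#' (here raters are the runs of one condition):
#' `ICC = (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))`,
#' where MSR, MSC, MSE are the between-subject, between-rater and residual
#' mean squares. Absolute agreement: a constant added to one rater lowers
#' the ICC, a constant added to the whole table does not.
#'
#' @param table Numeric matrix, n subjects (rows) x k raters (columns),
#'   no missing cells, n >= 3, k >= 2.
#' @return ICC value in `[-1, 1]`.
#' @export
icc_2_1 <- function(table) {
  table <- as.matrix(table)
  if (any(!is.finite(table))) {
    stop("table must have no missing cells; drop incomplete subjects first",
      call. = FALSE
    )
  }
  n <- nrow(table)
  k <- ncol(table)
  if (n < 3L || k < 2L) {
    stop("need at least 3 subjects and 2 raters", call. = FALSE)
  }
  gm <- mean(table)
  rmeans <- rowMeans(table)
  cmeans <- colMeans(table)
  ssr <- k * sum((rmeans - gm)^2)
  ssc <- n * sum((cmeans - gm)^2)
  sst <- sum((table - gm)^2)
  sse <- sst - ssr - ssc
  if (sst == 0) {
    stop("zero total variance: ICC undefined", call. = FALSE)
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Interpretation band of an ICC value
#'
#' poor < 0.4, fair 0.4-0.59, good 0.6-0.74, excellent >= 0.75 (the
#' printed convention leaves 0.74-0.75 ambiguous; this package assigns
#' 0.75 to excellent).
#'
#' @param icc ICC value.
#' @return One of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
icc_interpret <- function(icc) {
  stop_if_not_scalar_number(icc, "icc")
  if (icc < 0.4) {
    "poor"
  } else if (icc < 0.6) {
    "fair"
  } else if (icc < 0.75) {
    "good"
  } else {
    "excellent"
  }
}

# One set of bootstrap row indices per replicate: n x n_boot matrix.
bootstrap_rows <- function(n, n_boot) {
  matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
}

safe_icc <- function(table) {
  tryCatch(icc_2_1(table), error = function(e) NA_real_)
}

#' Bootstrap percentile CI for ICC(2,1)
#'
#' Resamples subjects (rows) with replacement, recomputes the ICC per
#' replicate, and takes the 2.5th/97.5th percentiles. Replicates where the
#' ICC is degenerate (zero variance) are dropped and counted.
#'
#' @param table n x k rater table, as in [icc_2_1()].
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; same seed gives the identical CI.
#' @return An object of class `icc_estimate`: list with `icc`, `ci95`,
#'   `n_boot`, `n_dropped`, `interpretation`.
#' @export
icc_bootstrap_ci <- function(table, n_boot = 1000, seed = NULL) {
  table <- as.matrix(table)
  point <- icc_2_1(table)
  reps <- with_seed(seed, {
    idx <- bootstrap_rows(nrow(table), n_boot)
    vapply(
      seq_len(n_boot),
      function(b) safe_icc(table[idx[, b], , drop = FALSE]),
      numeric(1)
    )
  })
  dropped <- sum(is.na(reps))
  if (dropped > 0) {
    message(sprintf("icc_bootstrap_ci: %d degenerate replicate(s) dropped", dropped))
  }
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, type = 7))
  structure(
    list(
      icc = point, ci95 = ci, n_boot = n_boot, n_dropped = dropped,
      interpretation = icc_interpret(point)
    ),
    class = "icc_estimate"
  )
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf(
    "<icc_estimate> ICC(2,1) = %.3f, 95%% CI [%.3f, %.3f] (%d boot), %s\n",
    x$icc, x$ci95[1], x$ci95[2], x$n_boot, x$interpretation
  ))
  invisible(x)
}

#' Paired bootstrap CI of an ICC difference
#'
#' For two rater tables over the same subjects (e.g. movie vs rest), each
#' bootstrap replicate draws one subject resample and applies it to both
#' tables, preserving the within-subject pairing; the CI of
#' `ICC_a - ICC_b` is the percentile interval, and the difference is
#' flagged significant iff the CI excludes 0.
#'
#' @param table_a,table_b n x k rater tables over the same subjects in the
#'   same row order.
#' @param n_boot Number of replicates (default 1000).
#' @param seed Integer seed.
#' @return A list with `icc_a`, `icc_b`, `difference`, `ci95`,
#'   `significant`, `n_boot`, `n_dropped`.
#' @export
icc_difference_ci <- function(table_a, table_b, n_boot = 1000, seed = NULL) {
  table_a <- as.matrix(table_a)
  table_b <- as.matrix(table_b)
  if (nrow(table_a) != nrow(table_b)) {
    stop("tables must cover the same subjects (same number of rows)", call. = FALSE)
  }
  icc_a <- icc_2_1(table_a)
  icc_b <- icc_2_1(table_b)
  diffs <- with_seed(seed, {
    idx <- bootstrap_rows(nrow(table_a), n_boot)
    vapply(seq_len(n_boot), function(b) {
      rows <- idx[, b]
      safe_icc(table_a[rows, , drop = FALSE]) -
        safe_icc(table_b[rows, , drop = FALSE])
    }, numeric(1))
  })
  dropped <- sum(is.na(diffs))
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975), na.rm = TRUE, type = 7))
  list(
    icc_a = icc_a, icc_b = icc_b, difference = icc_a - icc_b,
    ci95 = ci, significant = ci[1] > 0 || ci[2] < 0,
    n_boot = n_boot, n_dropped = dropped
  )
}

#' Build per-condition rater tables from a per-run ROI table
#'
#' Pivots a long table of per-run region values into an n subjects x k
#' runs matrix for one condition and region, dropping (and counting)
#' subjects with any missing run.
#'
#' @param roi_tbl Tibble with columns `subject`, `condition`, `run`,
#'   `region`, `h`.
#' @param condition Condition to extract.
#' @param region Region to extract.
#' @return Numeric matrix, subjects x runs; attribute `n_dropped`.
#' @export
rater_table <- function(roi_tbl, condition, region) {
  sub <- roi_tbl[roi_tbl$condition == condition & roi_tbl$region == region, ]
  if (nrow(sub) == 0) {
    stop("no rows for that condition/region", call. = FALSE)
  }
  runs <- sort(unique(sub$run))
  subjects <- sort(unique(sub$subject))
  m <- matrix(NA_real_, length(subjects), length(runs),
    dimnames = list(subjects, runs)
  )
  m[cbind(match(sub$subject, subjects), match(sub$run, runs))] <- sub$h
  complete <- stats::complete.cases(m)
  out <- m[complete, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!complete)
  out
}
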