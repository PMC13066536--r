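#' Subjects x sessions matrix of one repeated metric
#'
#' Container for test-retest data: one row per subject, one column per
#' session (e.g. `A1`, `A2`, `B1`, `B2` for two repeated measurements in
#' each of two scan sessions). Missing cells are kept and flagged; the
#' ANOVA-based statistics exclude incomplete rows listwise and report the
#' count.
#'
#' @param values Numeric matrix (subjects x sessions) or data frame.
#' @param subject_ids Optional subject identifiers (rownames by default).
#' @param session_labels Optional session labels (colnames by default).
#' @return An object of class `repeat_matrix`.
#' @export
repeat_matrix <- function(values, subject_ids = NULL, session_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_pv("`values` must be numeric")
  if (nrow(values) < 2 || ncol(values) < 2) {
    stop_pv("need at least 2 subjects and 2 sessions")
  }
  if (is.null(subject_ids)) {
    subject_ids <- rownames(values)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(session_labels)) {
    session_labels <- colnames(values)
    if (is.null(session_labels)) session_labels <- paste0("T", seq_len(ncol(values)))
  }
  dimnames(values) <- list(subject_ids, session_labels)
  structure(list(values = values, subject_ids = subject_ids,
                 session_labels = session_labels,
                 n_missing = sum(!is.finite(values))),
            class = "repeat_matrix")
}

#' @export
print.repeat_matrix <- function(x, ...) {
  cat(sprintf("Repeat matrix: %d subjects x %d sessions (%s)",
              nrow(x$values), ncol(x$values),
              paste(x$session_labels, collapse = ", ")))
  if (x$n_missing > 0) cat(sprintf(", %d missing cells", x$n_missing))
  cat("\n")
  invisible(x)
}

# complete-case values with a report of how many rows were dropped
complete_rows <- function(m) {
  v <- m$values
  ok <- complete.cases(v) & apply(is.finite(v), 1, all)
  list(values = v[ok, , drop = FALSE], n_excluded = sum(!ok))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measurement ICC from the two-way ANOVA
#' decomposition. The default (`type = "agreement"`) is the
#' absolute-agreement form
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`; the consistency
#' form `(MSR - MSE) / (MSR + (k-1) MSE)` is exposed as an option. The
#' label follows the conventional interpretation bands, made total with
#' half-open intervals: poor < 0.50, moderate \[0.50, 0.75), good
#' \[0.75, 0.90), excellent >= 0.90.
#'
#' @param m A [repeat_matrix()]. Rows with missing cells are excluded
#'   (listwise) and counted.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return A list of class `icc_result`: `icc`, `label`, `n`, `k`,
#'   `n_excluded`, and the mean squares `ms`.
#' @export
icc_2_1 <- function(m, type = c("agreement", "consistency")) {
  stopifnot(inherits(m, "repeat_matrix"))
  type <- match.arg(type)
  cc <- complete_rows(m)
  v <- cc$values
  n <- nrow(v); k <- ncol(v)
  if (n < 2) stop_pv("need at least 2 complete subject rows")
  grand <- mean(v)
  if (sum((v - grand)^2) < 1e-300) stop_pv("zero total variance: ICC undefined")
  msr <- k * var(rowMeans(v))
  msc <- n * var(colMeans(v))
  sst <- sum((v - grand)^2)
  sse <- sst - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  structure(list(icc = icc, label = icc_label(icc), type = type,
                 n = n, k = k, n_excluded = cc$n_excluded,
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "icc_result")
}

#' @rdname icc_2_1
#' @param icc A numeric ICC value.
#' @export
icc_label <- function(icc) {
  if (!is_num1(icc)) stop_pv("`icc` must be a single number")
  if (icc < 0.50) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.90) "good"
  else "excellent"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) %s = %.3f (%s), %d subjects x %d sessions",
              x$type, x$icc, x$label, x$n, x$k))
  if (x$n_excluded > 0) cat(sprintf(" [%d incomplete rows excluded]", x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Standard error of measurement and minimal detectable change
#'
#' `SEM = SD * sqrt(1 - ICC)`, with SD the pooled standard deviation of all
#' measurements, and `MDC = 1.96 * sqrt(2) * SEM` (the 95% threshold for a
#' real change between two measurements). The MDC/SEM ratio is therefore
#' 2.77 for every metric.
#'
#' @param m A [repeat_matrix()].
#' @param icc ICC value in `(-Inf, 1]`, e.g. from [icc_2_1()].
#' @return A list with `sem` and `mdc` in the metric's units.
#' @export
sem_mdc <- function(m, icc) {
  stopifnot(inherits(m, "repeat_matrix"))
  if (!is_num1(icc) || icc > 1) stop_pv("`icc` must be a number <= 1")
  v <- complete_rows(m)$values
  sd_pooled <- sd(as.vector(v))
  sem <- sd_pooled * sqrt(1 - icc)
  list(sem = sem, mdc = mdc_from_sem(sem))
}

#' @rdname sem_mdc
#' @param sem A standard error of measurement.
#' @export
mdc_from_sem <- function(sem) {
  if (any(!is.finite(sem)) || any(sem < 0)) stop_pv("`sem` must be >= 0")
  1.96 * sqrt(2) * sem
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`: bias = mean(d), limits of agreement =
#' bias +/- 1.96 SD(d) (n-1 SD).
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @return A list of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `means`, `diffs`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_pv("`a` and `b` must have equal lengths")
  if (length(a) < 2) stop_pv("need at least 2 pairs")
  d <- a - b
  bias <- mean(d); s <- sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman: bias %.*f, limits of agreement [%.*f, %.*f] (n = %d)\n",
              digits, x$bias, digits, x$loa_low, digits, x$loa_high,
              length(x$diffs)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of pair",
                              ylab = "difference", ...) {
  plot(x$means, x$diffs, xlab = xlab, ylab = ylab,
       ylim = range(c(x$diffs, x$loa_low, x$loa_high)), ...)
  abline(h = x$bias, col = "red")
  abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Friedman test with Dunn-Sidak post hoc comparisons
#'
#' Tie-corrected Friedman rank test across sessions (repeated measures on
#' the same subjects), followed by all pairwise session comparisons based
#' on within-subject mean-rank differences with Sidak adjustment
#' `p_adj = 1 - (1 - p)^m`, `m = k(k-1)/2`. The pairwise z statistic uses
#' the pooled within-subject rank variance, which reduces to
#' `k(k+1)/(6n)` for untied data.
#'
#' @param m A [repeat_matrix()] with complete rows (incomplete rows are
#'   excluded listwise).
#' @return A list of class `friedman_posthoc`: `chi2`, `df`, `p`, and a
#'   data frame `pairwise` with raw and Sidak-adjusted p-values.
#' @export
friedman_dunnsidak <- function(m) {
  stopifnot(inherits(m, "repeat_matrix"))
  v <- complete_rows(m)$values
  n <- nrow(v); k <- ncol(v)
  if (k < 2) stop_pv("need at least 2 sessions")
  if (n < 2) stop_pv("need at least 2 complete subject rows")
  r <- t(apply(v, 1, rank))
  # pooled within-subject rank variance (k(k+1)/12 without ties)
  sigma2 <- (sum(r^2) - n * k * (k + 1)^2 / 4) / (n * (k - 1))
  if (sigma2 <= 0) {
    chi2 <- 0; p <- 1
  } else {
    fr <- friedman.test(v)
    chi2 <- unname(fr$statistic); p <- fr$p.value
    if (!is.finite(chi2)) { chi2 <- 0; p <- 1 }
  }
  pairs <- utils::combn(k, 2)
  mr <- colMeans(r)
  mtests <- ncol(pairs)
  pw <- data.frame(
    session_a = m$session_labels[pairs[1, ]],
    session_b = m$session_labels[pairs[2, ]],
    mean_rank_diff = mr[pairs[1, ]] - mr[pairs[2, ]])
  se <- sqrt(2 * sigma2 / n)
  pw$z <- if (se > 0) pw$mean_rank_diff / se else 0
  pw$p_raw <- 2 * pnorm(-abs(pw$z))
  pw$p_sidak <- sidak_adjust(pw$p_raw, mtests)
  structure(list(chi2 = chi2, df = k - 1, p = p, pairwise = pw,
                 n = n, k = k),
            class = "friedman_posthoc")
}

#' Sidak adjustment for multiple comparisons
#'
#' `p_adj = 1 - (1 - p)^m`.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param m Number of comparisons in the family.
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p, m) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_pv("p-values must lie in [0, 1]")
  if (!is_count(m) || m < 1) stop_pv("`m` must be a positive integer")
  1 - (1 - p)^m
}

#' @export
print.friedman_posthoc <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.3f, df = %d, p = %.4g (%d subjects x %d sessions)\n",
              x$chi2, x$df, x$p, x$n, x$k))
  cat("Pairwise Dunn-Sidak comparisons:\n")
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: z = %+.2f, p = %.4g (adj %.4g)\n",
                pw$session_a[i], pw$session_b[i], pw$z[i], pw$p_raw[i],
                pw$p_sidak[i]))
  }
  invisible(x)
}

#' Pool session pairs into a two-column repeat matrix
#'
#' Intra-session repeatability uses the within-session pairs (e.g.
#' `(A1, A2)` and `(B1, B2)`) stacked into one subjects*pairs x 2 matrix;
#' inter-session repeatability uses `(A1, B1)` and `(A2, B2)`. Each listed
#' pair contributes its subjects as additional rows.
#'
#' @param m A [repeat_matrix()].
#' @param pairs List of length-2 character vectors of session labels.
#' @return A [repeat_matrix()] with 2 columns.
#' @export
pool_sessions <- function(m, pairs) {
  stopifnot(inherits(m, "repeat_matrix"))
  blocks <- lapply(pairs, function(p) {
    if (!all(p %in% m$session_labels)) {
      stop_pv("unknown session label in pair: ", paste(p, collapse = ", "))
    }
    m$values[, p, drop = FALSE]
  })
  v <- do.call(rbind, lapply(blocks, unname))
  ids <- unlist(lapply(seq_along(pairs), function(i) {
    paste0(m$subject_ids, ".", paste(pairs[[i]], collapse = ""))
  }))
  repeat_matrix(v, subject_ids = ids, session_labels = c("first", "second"))
}

#' Test-retest repeatability table for a set of metrics
#'
#' For each metric column, computes intra- and inter-session ICC(2,1), SEM
#' and MDC from the pooled session pairs, mirroring the standard
#' repeatability-table layout (SEM Intra, SEM Inter, MDC Intra, MDC Inter,
#' ICC Intra, ICC Inter), plus the Friedman test across all sessions.
#'
#' @param data Long-format data frame with columns `subject`, `session`,
#'   `metric`, `value`.
#' @param intra_pairs,inter_pairs Lists of session-label pairs; defaults
#'   assume labels `A1`, `A2`, `B1`, `B2`.
#' @return A list of class `repeatability_table`: data frame `table` with
#'   one row per metric, and per-metric details in `details`.
#' @export
repeatability_table <- function(data,
                                intra_pairs = list(c("A1", "A2"), c("B1", "B2")),
                                inter_pairs = list(c("A1", "B1"), c("A2", "B2"))) {
  need <- c("subject", "session", "metric", "value")
  if (!all(need %in% names(data))) {
    stop_pv("`data` must have columns ", paste(need, collapse = ", "))
  }
  metrics <- unique(data$metric)
  rows <- list(); details <- list()
  for (met in metrics) {
    d <- data[data$metric == met, ]
    wide <- tapply(d$value, list(d$subject, d$session), mean)
    rm_all <- repeat_matrix(wide)
    intra <- pool_sessions(rm_all, intra_pairs)
    inter <- pool_sessions(rm_all, inter_pairs)
    icc_intra <- icc_2_1(intra); icc_inter <- icc_2_1(inter)
    sm_intra <- sem_mdc(intra, icc_intra$icc)
    sm_inter <- sem_mdc(inter, icc_inter$icc)
    fr <- friedman_dunnsidak(rm_all)
    rows[[met]] <- data.frame(
      metric = met,
      sem_intra = sm_intra$sem, sem_inter = sm_inter$sem,
      mdc_intra = sm_intra$mdc, mdc_inter = sm_inter$mdc,
      icc_intra = icc_intra$icc, icc_inter = icc_inter$icc,
      icc_intra_label = icc_intra$label, icc_inter_label = icc_inter$label,
      friedman_p = fr$p)
    details[[met]] <- list(icc_intra = icc_intra, icc_inter = icc_inter,
                           friedman = fr,
                           bland_altman_intra = bland_altman(
                             intra$values[, 1], intra$values[, 2]),
                           bland_altman_inter = bland_altman(
                             inter$values[, 1], inter$values[, 2]))
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 details = details),
            class = "repeatability_table")
}

#' @export
print.repeatability_table <- function(x, digits = 3, ...) {
  cat("Test-retest repeatability\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
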