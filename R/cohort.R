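#' Dubois body surface area
#'
#' `BSA = 0.007184 * height(cm)^0.725 * weight(kg)^0.425` in m^2.
#'
#' @param height_cm Height in cm (> 0), vectorised.
#' @param weight_kg Weight in kg (> 0), vectorised.
#' @return Body surface area in m^2.
#' @examples
#' bsa_dubois(180, 75)
#' @export
bsa_dubois <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0) ||
      any(!is.finite(weight_kg)) || any(weight_kg <= 0)) {
    stop_pv("height and weight must be positive")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}

#' Effect-size label for eta squared
#'
#' Cohen's bands, made total with half-open intervals: negligible < 0.01,
#' small \[0.01, 0.06), moderate \[0.06, 0.14\], large > 0.14.
#'
#' @param eta2 Eta-squared value (clamped at 0 for labelling).
#' @return One of `"negligible"`, `"small"`, `"moderate"`, `"large"`.
#' @export
eta_squared_label <- function(eta2) {
  if (!is_num1(eta2)) stop_pv("`eta2` must be a single number")
  e <- max(eta2, 0)
  if (e < 0.01) "negligible"
  else if (e < 0.06) "small"
  else if (e <= 0.14) "moderate"
  else "large"
}

#' Kruskal-Wallis test with eta squared and Dunn-Sidak post hoc
#'
#' Tie-corrected Kruskal-Wallis H across groups with the rank-based effect
#' size `eta^2_H = (H - k + 1) / (n - k)` (clamped at 0 for labelling), and
#' pairwise Dunn z-tests on mean ranks with tie-corrected pooled variance
#' and Sidak adjustment over `m = k(k-1)/2` comparisons.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels, each group n >= 2.
#' @return A list of class `group_test`: `h_statistic`, `df`, `p`,
#'   `eta_squared`, `effect_label`, and data frame `pairwise`.
#' @export
kruskal_eta <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (length(values) != length(groups)) stop_pv("length mismatch")
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop_pv("need at least 2 groups")
  ng <- table(groups)
  if (any(ng < 2)) {
    stop_pv("every group needs n >= 2 (violated by: ",
            paste(names(ng)[ng < 2], collapse = ", "), ")")
  }
  n <- length(values)
  if (length(unique(values)) == 1L) {
    # complete ties: no rank variation, H defined as 0
    kt <- list(statistic = 0, p.value = 1)
  } else {
    kt <- kruskal.test(values, groups)
  }
  h <- unname(kt$statistic)
  eta2 <- (h - k + 1) / (n - k)
  # Dunn pairwise z on mean ranks with tie correction
  rk <- rank(values)
  ties <- table(values)
  tiecorr <- sum(ties^3 - ties) / (12 * (n - 1))
  mr <- tapply(rk, groups, mean)
  pairs <- utils::combn(k, 2)
  mtests <- ncol(pairs)
  lev <- levels(groups)
  pw <- data.frame(group_a = lev[pairs[1, ]], group_b = lev[pairs[2, ]])
  se <- sqrt((n * (n + 1) / 12 - tiecorr) *
               (1 / ng[pairs[1, ]] + 1 / ng[pairs[2, ]]))
  pw$z <- as.numeric((mr[pairs[1, ]] - mr[pairs[2, ]]) / se)
  pw$z[!is.finite(pw$z)] <- 0
  pw$p_raw <- 2 * pnorm(-abs(pw$z))
  pw$p_sidak <- sidak_adjust(pw$p_raw, mtests)
  structure(list(h_statistic = h, df = k - 1, p = kt$p.value,
                 eta_squared = max(eta2, 0), eta_squared_raw = eta2,
                 effect_label = eta_squared_label(eta2),
                 pairwise = pw, n = n, k = k),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.4g; eta^2 = %.3f (%s)\n",
              x$h_statistic, x$df, x$p, x$eta_squared, x$effect_label))
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("  %s vs %s: z = %+.2f, p = %.4g (adj %.4g)\n",
                pw$group_a[i], pw$group_b[i], pw$z[i], pw$p_raw[i],
                pw$p_sidak[i]))
  }
  invisible(x)
}

#' Bonferroni correction
#'
#' `min(1, p * m)` elementwise.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param m Family size (default: number of p-values).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop_pv("p-values must lie in [0, 1]")
  }
  if (!is_count(m) || m < 1) stop_pv("`m` must be a positive integer")
  pmin(1, pvals * m)
}

#' Multivariable linear regression of a dynamic metric
#'
#' Ordinary least squares of `outcome ~ status + gender + age + bsa` with
#' dummy coding: status reference level Healthy (contrasts `Status [PH]`,
#' `Status [COPD]`), gender reference male (`Gender [F]`). BSA is computed
#' with [bsa_dubois()] when absent. Per-coefficient t and p values come
#' from the OLS fit; each term's F is the extra-sum-of-squares comparison
#' against the model without that term.
#'
#' @param records Data frame with columns `status` (levels among Healthy,
#'   COPD, PH), `gender` (M/F), `age`, either `bsa` or `height_cm` +
#'   `weight_kg`, and the outcome column.
#' @param outcome Name of the outcome column.
#' @param predictors Predictor columns to include; `status` and `gender`
#'   are coded as factors with the reference levels above, everything else
#'   is taken as numeric.
#' @return An object of class `cohort_lm`: `coefficients` (estimate, SE, t,
#'   p), `term_f` (per-term F and p), and the underlying `fit`.
#' @export
fit_linear_model <- function(records, outcome,
                             predictors = c("status", "gender", "age", "bsa")) {
  if (!outcome %in% names(records)) stop_pv("outcome `", outcome, "` not found")
  if ("bsa" %in% predictors && !"bsa" %in% names(records)) {
    if (!all(c("height_cm", "weight_kg") %in% names(records))) {
      stop_pv("`records` needs `bsa` or `height_cm` + `weight_kg`")
    }
    records$bsa <- bsa_dubois(records$height_cm, records$weight_kg)
  }
  missing_cols <- setdiff(predictors, names(records))
  if (length(missing_cols) > 0) {
    stop_pv("predictor column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  d <- data.frame(y = records[[outcome]])
  for (pr in predictors) {
    d[[pr]] <- if (pr == "status") {
      factor(records$status,
             levels = intersect(c("Healthy", "PH", "COPD"),
                                unique(as.character(records$status))))
    } else if (pr == "gender") {
      factor(records$gender, levels = c("M", "F"))
    } else {
      as.numeric(records[[pr]])
    }
  }
  d <- d[complete.cases(d), ]
  if (nrow(d) < 10) stop_pv("need at least 10 complete records")
  fit <- lm(stats::reformulate(predictors, response = "y"), data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_pv("rank-deficient design: collinear term(s) ",
            paste(bad, collapse = ", "))
  }
  ct <- summary(fit)$coefficients
  colnames(ct) <- c("estimate", "std_error", "t", "p")
  # extra-sum-of-squares F per term against the model dropping that term
  terms_all <- attr(fit$terms, "term.labels")
  rss_full <- sum(fit$residuals^2)
  df_res <- fit$df.residual
  tf <- lapply(terms_all, function(tm) {
    rest <- setdiff(terms_all, tm)
    form0 <- if (length(rest) == 0) y ~ 1 else stats::reformulate(rest, response = "y")
    fit0 <- lm(form0, data = d)
    rss0 <- sum(fit0$residuals^2)
    df_num <- fit0$df.residual - df_res
    f <- ((rss0 - rss_full) / df_num) / (rss_full / df_res)
    data.frame(term = tm, df = df_num, f = f,
               p = pf(f, df_num, df_res, lower.tail = FALSE))
  })
  structure(list(coefficients = ct,
                 term_f = do.call(rbind, c(tf, make.row.names = FALSE)),
                 fit = fit, n = nrow(d), outcome = outcome),
            class = "cohort_lm")
}

#' @export
print.cohort_lm <- function(x, digits = 4, ...) {
  cat(sprintf("Linear model for %s (n = %d)\n", x$outcome, x$n))
  printCoefmat(x$coefficients, digits = digits,
               cs.ind = 1:2, tst.ind = 3, P.values = TRUE, has.Pvalue = TRUE)
  cat("Per-term F (extra sum of squares):\n")
  tf <- x$term_f
  for (i in seq_len(nrow(tf))) {
    cat(sprintf("  %-8s F = %.2f, p = %.4g\n", tf$term[i], tf$f[i], tf$p[i]))
  }
  invisible(x)
}

#' @export
coef.cohort_lm <- function(object, ...) object$coefficients[, "estimate"]

#' @export
summary.cohort_lm <- function(object, ...) summary(object$fit, ...)

#' @export
residuals.cohort_lm <- function(object, ...) residuals(object$fit, ...)

#' @export
predict.cohort_lm <- function(object, ...) predict(object$fit, ...)

#' Group comparison table across cohorts
#'
#' Runs [kruskal_eta()] for each metric column against `status`, reporting
#' medians and interquartile ranges per group, the H statistic and p-value
#' (raw and Bonferroni-adjusted across the metric family), eta squared with
#' its label, and Sidak-adjusted pairwise comparisons.
#'
#' @param data Data frame with a `status` column and the metric columns.
#' @param metrics Character vector of metric column names.
#' @param family_size Bonferroni family size (default: number of metrics).
#' @return A list of class `cohort_comparison`: data frame `table` and
#'   per-metric `tests`.
#' @export
cohort_comparison <- function(data, metrics, family_size = length(metrics)) {
  if (!"status" %in% names(data)) stop_pv("`data` must have a `status` column")
  missing_cols <- setdiff(metrics, names(data))
  if (length(missing_cols) > 0) {
    stop_pv("metric column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  tests <- lapply(metrics, function(met) kruskal_eta(data[[met]], data$status))
  names(tests) <- metrics
  lev <- levels(as.factor(data$status))
  rows <- lapply(metrics, function(met) {
    gt <- tests[[met]]
    meds <- vapply(lev, function(g) {
      median(data[[met]][data$status == g], na.rm = TRUE)
    }, numeric(1))
    out <- data.frame(metric = met)
    for (g in lev) out[[paste0("median_", g)]] <- meds[[g]]
    out$h <- gt$h_statistic; out$p <- gt$p
    out$eta_squared <- gt$eta_squared; out$effect_label <- gt$effect_label
    out
  })
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  tab$p_bonferroni <- bonferroni(tab$p, m = family_size)
  structure(list(table = tab, tests = tests, family_size = family_size),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort comparison (Kruskal-Wallis; Bonferroni family m = %d)\n",
              x$family_size))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}

#' Simulate a synthetic cohort table
#'
#' Generates per-subject dynamic metrics and covariates for the three
#' cohorts with group-specific medians and spreads chosen to resemble a
#' healthy/COPD/pulmonary-hypertension comparison: increased vessel- and
#' lung-area variability in PH, prolonged SE-delay and reduced heart rate
#' in COPD, older patient groups, and a female-dominant PH cohort. Metrics
#' are drawn log-normally (they are positive and right-skewed); covariates
#' normally within physiologic ranges. This is a statistical stand-in for
#' cohort tables, not patient data.
#'
#' @param n Named integer vector of group sizes
#'   (`c(Healthy = , COPD = , PH = )`).
#' @param seed Integer seed.
#' @return Data frame with subject_id, status, gender, age, height_cm,
#'   weight_kg, bsa and the five metric columns.
#' @export
simulate_cohort <- function(n = c(Healthy = 25, COPD = 25, PH = 25),
                            seed = 1L) {
  stopifnot(all(c("Healthy", "COPD", "PH") %in% names(n)))
  # group medians for (cv_vessel_area, cv_lung_area, cv_vessel_signal,
  # se_delay, heart_rate) and log-scale SDs
  med <- list(
    Healthy = c(2.97, 8.41, 4.02, 62.97, 78),
    COPD    = c(2.67, 7.03, 3.64, 81.98, 65),
    PH      = c(4.58, 16.74, 3.68, 67.20, 85))
  lsd <- c(0.25, 0.45, 0.25, 0.15, 0.12)
  demo <- list( # mean age, female fraction
    Healthy = c(30, 0.35), COPD = c(65, 0.35), PH = c(68, 0.65))
  metrics <- c("cv_vessel_area", "cv_lung_area", "cv_vessel_signal",
               "se_delay", "heart_rate")
  with_seed(seed, {
    out <- lapply(c("Healthy", "COPD", "PH"), function(g) {
      ng <- n[[g]]
      vals <- vapply(seq_along(metrics), function(j) {
        exp(rnorm(ng, mean = log(med[[g]][j]), sd = lsd[j]))
      }, numeric(ng))
      colnames(vals) <- metrics
      gender <- ifelse(stats::runif(ng) < demo[[g]][2], "F", "M")
      height <- round(rnorm(ng, ifelse(gender == "F", 166, 179), 7))
      weight <- round(rnorm(ng, ifelse(gender == "F", 68, 82), 12))
      weight <- pmax(weight, 40)
      data.frame(subject_id = paste0(g, seq_len(ng)), status = g,
                 gender = gender,
                 age = round(pmin(pmax(rnorm(ng, demo[[g]][1], 8), 18), 90)),
                 height_cm = height, weight_kg = weight,
                 bsa = bsa_dubois(height, weight), vals)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
  })
}

#' @importFrom stats printCoefmat residuals predict
NULL
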