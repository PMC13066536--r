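# independent ICC(2,1) oracle from the two-way ANOVA via stats::aov
icc_oracle <- function(v) {
  n <- nrow(v); k <- ncol(v)
  d <- data.frame(y = as.vector(v),
                  subj = factor(rep(seq_len(n), k)),
                  sess = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("ICC(2,1) matches the explicit ANOVA decomposition", {
  v <- cbind(c(1, 2, 3, 4, 5), c(1.1, 2.0, 3.2, 3.9, 5.1))
  m <- repeat_matrix(v, session_labels = c("A1", "A2"))
  res <- icc_2_1(m)
  expect_equal(res$icc, icc_oracle(v), tolerance = 1e-10)
  # a larger unbalanced-looking fixture with a session shift
  set.seed(42)
  v2 <- matrix(rnorm(12 * 4, rep(rnorm(12, 20, 4), 4), 1.5), 12, 4)
  v2[, 3] <- v2[, 3] + 2
  res2 <- icc_2_1(repeat_matrix(v2))
  expect_equal(res2$icc, icc_oracle(v2), tolerance = 1e-10)
  # consistency form ignores the session shift more than agreement does
  expect_gt(icc_2_1(repeat_matrix(v2), type = "consistency")$icc, res2$icc)
})

test_that("perfect within-subject agreement gives ICC 1", {
  v <- cbind(1:6, 1:6, 1:6)
  res <- icc_2_1(repeat_matrix(v))
  expect_equal(res$icc, 1)
  expect_equal(res$label, "excellent")
  expect_error(icc_2_1(repeat_matrix(matrix(5, 4, 2))), "zero total variance")
})

test_that("ICC interpretation bands are total and half-open", {
  expect_equal(icc_label(0.3), "poor")
  expect_equal(icc_label(0.50), "moderate")
  expect_equal(icc_label(0.74999), "moderate")
  expect_equal(icc_label(0.75), "good")
  expect_equal(icc_label(0.80), "good")
  expect_equal(icc_label(0.90), "excellent")
  expect_equal(icc_label(-0.2), "poor")
})

test_that("ICC is invariant under shift and positive rescaling", {
  set.seed(7)
  v <- matrix(rnorm(10 * 3, rep(rnorm(10), 3), 0.4), 10, 3)
  base <- icc_2_1(repeat_matrix(v))$icc
  expect_equal(icc_2_1(repeat_matrix(v + 100))$icc, base, tolerance = 1e-10)
  expect_equal(icc_2_1(repeat_matrix(v * 3.5))$icc, base, tolerance = 1e-10)
})

test_that("ICC estimates the variance-ratio truth in simulation", {
  # subjects ~ N(mu, sb^2), session error ~ N(0, se^2): ICC -> sb^2/(sb^2+se^2)
  set.seed(101)
  n <- 500; sb <- 2; se <- 1
  subj <- rnorm(n, 10, sb)
  v <- cbind(subj + rnorm(n, 0, se), subj + rnorm(n, 0, se))
  expect_equal(icc_2_1(repeat_matrix(v))$icc, sb^2 / (sb^2 + se^2),
               tolerance = 0.05)
})

test_that("SEM and MDC follow their defining identities", {
  v <- cbind(c(1, 2, 3, 4, 5), c(1.1, 2.0, 3.2, 3.9, 5.1))
  m <- repeat_matrix(v)
  # no measurement error at ICC 1
  sm1 <- sem_mdc(m, 1)
  expect_equal(sm1$sem, 0); expect_equal(sm1$mdc, 0)
  sm <- sem_mdc(m, 0.8)
  expect_equal(sm$sem, sd(as.vector(v)) * sqrt(0.2))
  expect_equal(sm$mdc / sm$sem, 1.96 * sqrt(2))
  expect_equal(round(sm$mdc / sm$sem, 2), 2.77)
  expect_error(sem_mdc(m, 1.2), "<= 1")
})

test_that("Bland-Altman reduces to direct mean/SD arithmetic", {
  a <- c(1, 2, 3); b <- a
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0); expect_equal(ba$loa_high - ba$loa_low, 0)
  # constant offset: bias -2, zero-width limits
  ba2 <- bland_altman(a, a + 2)
  expect_equal(ba2$bias, -2); expect_equal(ba2$sd_diff, 0)
  set.seed(9)
  x <- rnorm(30, 5, 1); y <- x + rnorm(30, 0.3, 0.5)
  ba3 <- bland_altman(x, y)
  d <- x - y
  expect_equal(ba3$bias, mean(d))
  expect_equal(ba3$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba3$loa_high, mean(d) + 1.96 * sd(d))
  expect_true(ba3$loa_low <= ba3$bias && ba3$bias <= ba3$loa_high)
  expect_error(bland_altman(1:3, 1:4), "equal lengths")
})

test_that("Friedman statistic matches a brute-force rank computation", {
  set.seed(3)
  v <- matrix(rnorm(8 * 4, rep(rnorm(8, 10, 2), 4), 1), 8, 4)
  res <- friedman_dunnsidak(repeat_matrix(v))
  # brute force: within-subject ranks, tie-corrected statistic
  r <- t(apply(v, 1, rank))
  n <- nrow(v); k <- ncol(v)
  ties <- apply(r, 1, function(z) sum(table(z)^3 - table(z)))
  chi2 <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) /
    (n * k * (k + 1) - sum(ties) / (k - 1))
  expect_equal(res$chi2, chi2, tolerance = 1e-10)
  expect_equal(res$p, pchisq(chi2, k - 1, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("identical sessions give a null Friedman result", {
  v <- matrix(rep(c(3, 1, 4, 1, 5), 4), 5, 4)
  res <- friedman_dunnsidak(repeat_matrix(v))
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$p_sidak == 1))
})

test_that("a shifted session is detected with Sidak-adjusted post hocs", {
  set.seed(11)
  subj <- rnorm(20, 50, 5)
  v <- sapply(1:4, function(j) subj + rnorm(20, 0, 1))
  v[, 4] <- v[, 4] + 5 * 1   # one session shifted by 5 SDs of the error
  res <- friedman_dunnsidak(repeat_matrix(v, session_labels = c("A1", "A2", "B1", "B2")))
  expect_lt(res$p, 0.05)
  pw <- res$pairwise
  shifted <- pw$session_a == "B2" | pw$session_b == "B2"
  expect_true(all(pw$p_sidak[shifted] < 0.05))
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.01, 6), 1 - 0.99^6)
  expect_equal(sidak_adjust(0, 4), 0)
  expect_equal(sidak_adjust(1, 3), 1)
  expect_error(sidak_adjust(1.2, 3), "\\[0, 1\\]")
})

test_that("incomplete rows are excluded listwise and counted", {
  v <- cbind(c(1, 2, NA, 4, 5, 6), c(1.2, 2.1, 3.0, 4.2, 5.1, 5.8))
  m <- repeat_matrix(v)
  expect_equal(m$n_missing, 1L)
  res <- icc_2_1(m)
  expect_equal(res$n, 5L)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$icc, icc_oracle(v[-3, ]), tolerance = 1e-10)
})

test_that("session pooling builds the intra/inter pairs", {
  v <- matrix(1:20, 5, 4, dimnames = list(NULL, c("A1", "A2", "B1", "B2")))
  m <- repeat_matrix(v)
  intra <- pool_sessions(m, list(c("A1", "A2"), c("B1", "B2")))
  expect_equal(dim(intra$values), c(10L, 2L))
  expect_equal(intra$values[1, ], c(first = 1, second = 6))
  expect_equal(intra$values[6, ], c(first = 11, second = 16))
  expect_error(pool_sessions(m, list(c("A1", "C9"))), "unknown session")
})

test_that("the repeatability table carries the full metric panel", {
  set.seed(21)
  subj <- rep(sprintf("S%02d", 1:15), times = 4)
  sess <- rep(c("A1", "A2", "B1", "B2"), each = 15)
  base <- rep(rnorm(15, 3, 0.6), 4)
  long <- rbind(
    data.frame(subject = subj, session = sess, metric = "cv_vessel_area",
               value = base + rnorm(60, 0, 0.2)),
    data.frame(subject = subj, session = sess, metric = "heart_rate",
               value = rep(rnorm(15, 75, 8), 4) + rnorm(60, 0, 3)))
  rt <- repeatability_table(long)
  expect_equal(nrow(rt$table), 2L)
  expect_true(all(c("sem_intra", "sem_inter", "mdc_intra", "mdc_inter",
                    "icc_intra", "icc_inter") %in% names(rt$table)))
  expect_equal(rt$table$mdc_intra / rt$table$sem_intra,
               rep(1.96 * sqrt(2), 2))
  expect_true(all(rt$table$icc_intra > 0.5))  # generated with real subject variance
  ba <- rt$details$cv_vessel_area$bland_altman_intra
  expect_s3_class(ba, "bland_altman")
  expect_length(ba$diffs, 30)
})
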