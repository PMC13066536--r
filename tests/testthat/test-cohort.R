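test_that("Dubois BSA follows the power law", {
  expect_equal(round(bsa_dubois(180, 75), 2), 1.94)
  # doubling weight scales BSA by 2^0.425
  expect_equal(bsa_dubois(170, 140) / bsa_dubois(170, 70), 2^0.425)
  # monotone increasing in both arguments
  expect_gt(bsa_dubois(181, 75), bsa_dubois(180, 75))
  expect_gt(bsa_dubois(180, 76), bsa_dubois(180, 75))
  expect_error(bsa_dubois(0, 75), "positive")
  expect_error(bsa_dubois(180, -2), "positive")
})

test_that("Kruskal-Wallis H matches an exhaustive rank computation", {
  vals <- c(3.1, 2.8, 3.5, 2.9,   4.2, 4.8, 3.9, 4.1,   2.1, 2.5, 2.1, 2.7)
  grp <- rep(c("Healthy", "PH", "COPD"), each = 4)
  res <- kruskal_eta(vals, grp)
  # brute force with tie correction
  n <- length(vals); k <- 3
  r <- rank(vals)
  rs <- tapply(r, grp, sum); ng <- tapply(r, grp, length)
  h0 <- 12 / (n * (n + 1)) * sum(rs^2 / ng) - 3 * (n + 1)
  tie <- table(vals)
  h <- h0 / (1 - sum(tie^3 - tie) / (n^3 - n))
  expect_equal(res$h_statistic, h, tolerance = 1e-10)
  expect_equal(res$p, pchisq(h, k - 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(res$eta_squared, (h - k + 1) / (n - k), tolerance = 1e-10)
})

test_that("identical groups give a null group test", {
  vals <- rep(c(1, 2, 3, 4), 3)
  res <- kruskal_eta(vals, rep(c("A", "B", "C"), each = 4))
  expect_equal(res$h_statistic, 0, tolerance = 1e-10)
  expect_equal(res$eta_squared, 0)
  # completely tied data as the extreme degenerate case
  res2 <- kruskal_eta(rep(5, 9), rep(c("A", "B", "C"), each = 3))
  expect_equal(res2$h_statistic, 0)
  expect_equal(res2$p, 1)
  expect_error(kruskal_eta(1:5, c("A", "A", "A", "A", "B")), "n >= 2")
})

test_that("group test is invariant under monotone transforms", {
  set.seed(5)
  vals <- c(rnorm(8, 3), rnorm(8, 4), rnorm(8, 2.5))
  grp <- rep(c("Healthy", "COPD", "PH"), each = 8)
  r1 <- kruskal_eta(vals, grp)
  r2 <- kruskal_eta(exp(vals / 2), grp)
  expect_equal(r1$h_statistic, r2$h_statistic, tolerance = 1e-12)
  expect_equal(r1$pairwise$z, r2$pairwise$z, tolerance = 1e-12)
})

test_that("eta-squared labels cover the Cohen bands totally", {
  expect_equal(eta_squared_label(0.005), "negligible")
  expect_equal(eta_squared_label(0.01), "small")
  expect_equal(eta_squared_label(0.059), "small")
  expect_equal(eta_squared_label(0.06), "moderate")
  expect_equal(eta_squared_label(0.14), "moderate")
  expect_equal(eta_squared_label(0.141), "large")
  expect_equal(eta_squared_label(0.35), "large")
  expect_equal(eta_squared_label(-0.03), "negligible")  # clamped
})

test_that("Bonferroni correction is capped and order-preserving", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 4), 1)
  p <- c(0.001, 0.02, 0.04, 0.3)
  expect_equal(order(bonferroni(p, 5)), order(p))
  expect_error(bonferroni(c(0.1, 1.4), 2), "\\[0, 1\\]")
})

test_that("exact linear data is reproduced with zero residuals", {
  d <- simulate_cohort(n = c(Healthy = 10, COPD = 10, PH = 10), seed = 2)
  d$y <- 2 + 0.5 * d$age
  # lm warns about the numerically perfect fit; that is the point here
  fit <- suppressWarnings(fit_linear_model(d, "y"))
  expect_equal(unname(fit$coefficients["age", "estimate"]), 0.5,
               tolerance = 1e-8)
  expect_lt(sum(residuals(fit)^2), 1e-16)
})

test_that("a single binary predictor reproduces the two-group closed form", {
  d <- simulate_cohort(n = c(Healthy = 12, COPD = 12, PH = 2), seed = 4)
  d <- d[d$status != "PH", ]
  fit <- fit_linear_model(d, "heart_rate", predictors = "status")
  diff_means <- mean(d$heart_rate[d$status == "COPD"]) -
    mean(d$heart_rate[d$status == "Healthy"])
  expect_equal(unname(fit$coefficients["statusCOPD", "estimate"]), diff_means,
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)", "estimate"]),
               mean(d$heart_rate[d$status == "Healthy"]), tolerance = 1e-10)
})

test_that("duplicated predictors raise a collinearity error", {
  d <- simulate_cohort(n = c(Healthy = 10, COPD = 10, PH = 10), seed = 6)
  d$age2 <- d$age
  expect_error(
    fit_linear_model(d, "heart_rate",
                     predictors = c("status", "gender", "age", "age2", "bsa")),
    "collinear")
})

test_that("reference levels match the reported contrasts", {
  d <- simulate_cohort(seed = 8)
  fit <- fit_linear_model(d, "se_delay")
  rn <- rownames(fit$coefficients)
  expect_setequal(rn, c("(Intercept)", "statusPH", "statusCOPD", "genderF",
                        "age", "bsa"))
  expect_equal(fit$term_f$term, c("status", "gender", "age", "bsa"))
  expect_true(all(fit$term_f$f >= 0))
})

test_that("OLS estimates cover their truth at nominal CI rates", {
  truth <- c(b0 = 50, bPH = 6, bCOPD = -10, bF = -2, bage = 0.1, bbsa = -4)
  hits <- matrix(FALSE, 50, 6)
  for (s in 1:50) {
    set.seed(s)
    n <- 300
    status <- sample(c("Healthy", "COPD", "PH"), n, replace = TRUE)
    gender <- sample(c("M", "F"), n, replace = TRUE)
    age <- runif(n, 20, 80)
    bsa <- runif(n, 1.4, 2.3)
    y <- truth["b0"] + truth["bPH"] * (status == "PH") +
      truth["bCOPD"] * (status == "COPD") + truth["bF"] * (gender == "F") +
      truth["bage"] * age + truth["bbsa"] * bsa + rnorm(n, 0, 5)
    d <- data.frame(status = status, gender = gender, age = age, bsa = bsa,
                    y = y)
    fit <- fit_linear_model(d, "y")
    ct <- fit$coefficients[c("(Intercept)", "statusPH", "statusCOPD",
                             "genderF", "age", "bsa"), ]
    lo <- ct[, "estimate"] - 1.96 * ct[, "std_error"]
    hi <- ct[, "estimate"] + 1.96 * ct[, "std_error"]
    hits[s, ] <- truth >= lo & truth <= hi
  }
  # every coefficient's 95% CI covers its truth in at least 90% of runs
  expect_true(all(colMeans(hits) >= 0.9))
})

test_that("cohort comparison table mirrors the group-comparison layout", {
  d <- simulate_cohort(seed = 12)
  mets <- c("cv_vessel_area", "cv_lung_area", "cv_vessel_signal",
            "se_delay", "heart_rate")
  cc <- cohort_comparison(d, mets)
  expect_equal(nrow(cc$table), 5L)
  expect_true(all(c("median_Healthy", "median_COPD", "median_PH", "h", "p",
                    "eta_squared", "effect_label", "p_bonferroni")
                  %in% names(cc$table)))
  expect_true(all(cc$table$p_bonferroni >= cc$table$p))
  # the synthetic cohort carries its designed large effects
  pha <- cc$table[cc$table$metric == "cv_lung_area", ]
  expect_lt(pha$p, 0.05)
  expect_equal(pha$effect_label, "large")
  expect_error(cohort_comparison(d, "nonexistent"), "not found")
})
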