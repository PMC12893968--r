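# contingency tables printed with their group counts (HER2-positive vs
# HER2-negative columns as rows here; chi-square is transpose-invariant)
published_tables <- list(
  histologic_grade   = matrix(c(11, 12, 33, 16), 2),
  lymph_node_status  = matrix(c(14, 9, 24, 25), 2),
  orientation        = matrix(c(20, 3, 29, 20), 2),
  microcalcification = matrix(c(15, 8, 16, 33), 2),
  area_of_enhancement = matrix(c(5, 18, 47, 2), 2),
  mv_distribution    = matrix(c(1, 12, 10, 6, 35, 8), 3),
  mv_flow_direction  = matrix(c(5, 18, 33, 16), 2))
published_chisq <- c(2.510, 0.888, 5.554, 6.770, 42.933, 6.509, 13.064)

test_that("Pearson chi-square reproduces the published table statistics", {
  for (i in seq_along(published_tables)) {
    r <- pearson_chi_square(published_tables[[i]])
    expect_equal(round(r$statistic, 3), published_chisq[i],
                 info = names(published_tables)[i])
  }
})

test_that("chi-square matches the direct formula and the 2x2 z identity", {
  set.seed(51)
  for (rep in 1:10) {
    m <- matrix(rpois(6, 20) + 1, 3, 2)
    r <- pearson_chi_square(m)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(r$statistic, sum((m - E)^2 / E), tolerance = 1e-10)
    expect_equal(r$statistic,
                 unname(stats::chisq.test(m, correct = FALSE)$statistic),
                 tolerance = 1e-10)
    expect_equal(r$df, 2L)
  }
  ## identical proportions -> 0
  expect_equal(pearson_chi_square(matrix(c(10, 10, 20, 20), 2))$statistic, 0)
  ## 2x2 chi-square equals the squared two-proportion z statistic
  m <- matrix(c(15, 8, 16, 33), 2)
  n1 <- sum(m[, 1]); n2 <- sum(m[, 2])
  p1 <- m[1, 1] / n1; p2 <- m[1, 2] / n2
  pp <- (m[1, 1] + m[1, 2]) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(pearson_chi_square(m)$statistic, z^2, tolerance = 1e-10)
  expect_error(pearson_chi_square(matrix(c(0, 0, 5, 5), 2)), "margin")
})

# full enumeration oracle for the two-sided Fisher p-value
fisher_enum_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("Fisher exact p equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1,
               tolerance = 1e-12)
  set.seed(52)
  for (rep in 1:20) {
    m <- matrix(rpois(4, 6), 2, 2)
    if (sum(m[1, ]) == 0 || sum(m[2, ]) == 0 ||
        sum(m[, 1]) == 0 || sum(m[, 2]) == 0) next
    expect_equal(fisher_exact(m)$p_value, fisher_enum_p(m), tolerance = 1e-12)
  }
})

test_that("t statistics match hand computation and switch variants", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  r <- two_sample_t(x, y, variance_rule = "pooled")
  expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-9)  # -1.2247
  expect_equal(r$df, 4)

  same <- two_sample_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  ## forced Welch reports Welch df
  set.seed(53)
  a <- stats::rnorm(30); b <- stats::rnorm(30, sd = 6)
  rw <- two_sample_t(a, b, variance_rule = "welch")
  expect_equal(rw$method, "Welch t")
  expect_lt(rw$df, 58)
  ## automatic rule switches on strong variance inequality
  expect_equal(two_sample_t(a, b)$method, "Welch t")
  expect_lt(two_sample_t(a, b)$levene_p, 0.1)
})

test_that("Mann-Whitney U handles separation, identity and small samples", {
  sep <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 0)

  id <- mann_whitney_u(c(5, 6, 7), c(5, 6, 7))
  expect_equal(id$z, 0, tolerance = 1e-12)

  ## tie-corrected normal approximation agrees with wilcox.test
  set.seed(54)
  for (rep in 1:10) {
    x <- sample(1:8, 12, replace = TRUE)
    y <- sample(2:9, 10, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }

  ## normal approximation close to the exact permutation null on
  ## moderate untied samples
  set.seed(55)
  for (rep in 1:5) {
    x <- stats::rnorm(30); y <- stats::rnorm(28, mean = 0.4)
    ours <- mann_whitney_u(x, y)
    exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(ours$p_value - exact), 0.01)
  }
})

test_that("Cohen's kappa matches hand computation and simulation", {
  a <- rep(c("x", "y"), c(10, 10))
  expect_equal(cohens_kappa(a, a)$kappa, 1)

  ## confusion [[20, 5], [10, 15]]: p_o = 0.7, p_e = 0.5 -> kappa 0.4
  ra <- rep(c("p", "p", "n", "n"), c(20, 5, 10, 15))
  rb <- rep(c("p", "n", "p", "n"), c(20, 5, 10, 15))
  k <- cohens_kappa(ra, rb)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)
  expect_equal(k$agreement_pct, 70)
  expect_true(k$ci[1] < 0.4 && k$ci[2] > 0.4)

  ## independent raters -> kappa near zero
  set.seed(56)
  r1 <- sample(c("a", "b", "c"), 1e4, replace = TRUE)
  r2 <- sample(c("a", "b", "c"), 1e4, replace = TRUE)
  expect_lt(abs(cohens_kappa(r1, r2)$kappa), 0.05)

  ## degenerate: a single shared category
  kd <- cohens_kappa(rep("a", 5), rep("a", 5))
  expect_true(kd$degenerate)

  ## invariance under simultaneous relabeling
  relabel <- c(p = "P2", n = "N2")
  k2 <- cohens_kappa(relabel[ra], relabel[rb])
  expect_equal(k2$kappa, k$kappa, tolerance = 1e-12)
})

test_that("logistic fits recover odds ratios and flag separation", {
  ## balanced null predictor
  set.seed(57)
  d0 <- data.frame(y = factor(rep(c("neg", "pos"), 100)),
                   x = stats::rnorm(200))
  f0 <- logistic_fit(y ~ x, d0)
  expect_lt(abs(f0$coefficients$beta[2]), 0.3)
  expect_false(f0$separation)

  ## univariate OR equals the cross-product ratio of the published
  ## microcalcification counts: (15 x 33) / (8 x 16)
  d1 <- data.frame(
    her2 = factor(rep(c("positive", "negative"), c(23, 49)),
                  levels = c("negative", "positive")),
    microcalc = c(rep(c(1, 0), c(15, 8)), rep(c(1, 0), c(16, 33))))
  f1 <- logistic_fit(her2 ~ microcalc, d1)
  expect_equal(f1$coefficients$or[2], (15 * 33) / (8 * 16), tolerance = 1e-4)
  expect_equal(f1$coefficients$wald[2],
               (f1$coefficients$beta[2] / f1$coefficients$se[2])^2)

  ## separation detection
  ds <- data.frame(y = factor(rep(c("neg", "pos"), each = 20)),
                   x = c(stats::rnorm(20, -5), stats::rnorm(20, 5)))
  fs <- suppressWarnings(logistic_fit(y ~ x, ds))
  expect_true(fs$separation)
})

test_that("coefficients are recovered within 2 SE on a large cohort", {
  set.seed(58)
  n <- 5000
  x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
  beta_true <- c(-0.5, 0.8, -1.2)
  eta <- beta_true[1] + beta_true[2] * x1 + beta_true[3] * x2
  y <- stats::rbinom(n, 1, 1 / (1 + exp(-eta)))
  f <- logistic_fit(y ~ x1 + x2, data.frame(y, x1, x2))
  for (i in 1:3)
    expect_lt(abs(f$coefficients$beta[i] - beta_true[i]),
              2 * f$coefficients$se[i])
})

test_that("ROC analysis obeys the Mann-Whitney identity and Youden rule", {
  r1 <- roc_analysis(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_equal(r1$auc, 1.0)
  expect_equal(r1$sensitivity, 1.0)
  expect_equal(r1$specificity, 1.0)

  r2 <- roc_analysis(c(1, 3, 2, 4), c(1, 1, 0, 0))
  expect_equal(r2$auc, 0.25)      # 1 of 4 concordant pairs

  ## AUC equals the normalized U statistic on random scores
  set.seed(59)
  sc <- stats::rnorm(60); lb <- rep(c(0, 1), 30)
  r3 <- roc_analysis(sc, lb)
  U <- mann_whitney_u(sc[lb == 1], sc[lb == 0])$statistic
  expect_equal(r3$auc, U / (30 * 30), tolerance = 1e-12)
  ## complement symmetry
  expect_equal(roc_analysis(-sc, lb)$auc, 1 - r3$auc, tolerance = 1e-12)

  ## independent cross-check against pROC (AUC and DeLong interval)
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(r3$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(r3$auc_ci, ci[c(1, 3)], tolerance = 1e-6)

  ## degenerate scores
  rd <- roc_analysis(rep(1, 10), rep(c(0, 1), 5))
  expect_true(rd$degenerate)
  expect_equal(rd$auc, 0.5)
  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("modality combinations are evaluated in-sample over all subsets", {
  set.seed(60)
  coh <- simulate_cohort(default_cohort_spec(n_pos = 60L, n_neg = 120L,
                                             seed = 61L))
  sets <- list(CUS = c("max_diameter_cm", "orientation", "microcalcification"),
               CEUS = c("pi", "wash_in_rate", "area_of_enhancement"),
               SRUS = c("mean_tortuosity", "max_flow_velocity",
                        "mv_distribution", "mv_flow_direction"))
  res <- combine_modalities(coh, sets)
  expect_equal(nrow(res), 7L)
  expect_true(all(c("CUS", "CEUS+SRUS", "CUS+CEUS+SRUS") %in% res$combination))
  expect_true(all(res$auc >= 0 & res$auc <= 1, na.rm = TRUE))

  ## a perfectly separating synthetic feature gives AUC 1
  coh$oracle <- ifelse(coh$her2 == "positive", 1, 0) + stats::rnorm(180, 0, 1e-4)
  r1 <- suppressWarnings(
    combine_modalities(coh, list(X = "oracle"))$auc)
  expect_equal(r1, 1.0)

  ## nested informative subsets: in-sample AUC non-decreasing
  auc_of <- function(combo) res$auc[res$combination == combo]
  expect_gte(auc_of("CUS+CEUS") + 1e-9, auc_of("CUS"))
  expect_gte(auc_of("CUS+CEUS+SRUS") + 1e-9, auc_of("CUS+CEUS"))

  ## pure-noise features: mean in-sample AUC near 0.5 with a small
  ## optimism bias, over repeated cohorts
  set.seed(62)
  aucs <- vapply(1:30, function(i) {
    d <- data.frame(y = factor(rep(c("n", "p"), each = 100)),
                    z = stats::rnorm(200))
    combine_modalities(d, list(N = "z"), label = "y")$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
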