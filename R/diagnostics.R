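#' @title Diagnostic statistics layer
#' @description Group-comparison tests (chi-square, Fisher, t, Mann-Whitney),
#'   interobserver agreement (Cohen's kappa), logistic regression with Wald
#'   statistics and odds ratios, ROC analysis with DeLong confidence
#'   intervals, and multimodality model combinations.
#' @name diagnostics
NULL

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson statistic sum((O - E)^2 / E) with
#' df = (r - 1)(c - 1) and an upper-tail p-value. No continuity
#' correction is applied.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @return list of class `test_result`: `statistic`, `df`, `p_value`,
#'   `method`, `expected`.
#' @export
pearson_chi_square <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) stop("need an r x c table with r, c >= 2")
  if (any(m < 0) || sum(m) == 0) stop("counts must be non-negative, total > 0")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
  E <- outer(rs, cs) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "Pearson chi-square (uncorrected)", expected = E),
            class = "test_result")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing the hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return `test_result` with `p_value` and the conditional odds ratio
#'   estimate (sample cross-product ratio).
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  ft <- stats::fisher.test(m)
  structure(list(statistic = unname((m[1, 1] * m[2, 2]) /
                                      max(m[1, 2] * m[2, 1], .Machine$double.eps)),
                 df = NA_integer_, p_value = ft$p.value,
                 method = "Fisher exact (two-sided)"),
            class = "test_result")
}

#' Two-sample t test with a variance rule
#'
#' Pooled-variance t by default; when `variance_rule = "levene"` a
#' Brown-Forsythe/Levene test (deviations from the median) with p below
#' `levene_alpha` switches to the Welch statistic. Both variants are kept
#' in the result for inspection.
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param variance_rule `"pooled"`, `"welch"`, or `"levene"` (automatic).
#' @param levene_alpha switch threshold for the automatic rule.
#' @return `test_result` with `statistic`, `df`, `p_value`, `method`,
#'   `pooled`, `welch`, `levene_p`.
#' @export
two_sample_t <- function(x, y, variance_rule = c("levene", "pooled", "welch"),
                         levene_alpha = 0.1) {
  variance_rule <- match.arg(variance_rule)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  pooled <- stats::t.test(x, y, var.equal = TRUE)
  welch <- stats::t.test(x, y, var.equal = FALSE)
  ## Brown-Forsythe: one-way ANOVA on absolute deviations from group medians
  z <- c(abs(x - stats::median(x)), abs(y - stats::median(y)))
  g <- factor(rep(1:2, c(length(x), length(y))))
  lev_p <- if (stats::var(z) == 0) 1
           else summary(stats::aov(z ~ g))[[1]][["Pr(>F)"]][1]
  use_welch <- switch(variance_rule,
                      pooled = FALSE, welch = TRUE,
                      levene = !is.na(lev_p) && lev_p < levene_alpha)
  r <- if (use_welch) welch else pooled
  structure(list(statistic = unname(r$statistic), df = unname(r$parameter),
                 p_value = r$p.value,
                 method = if (use_welch) "Welch t" else "pooled t",
                 pooled = list(statistic = unname(pooled$statistic),
                               df = unname(pooled$parameter),
                               p_value = pooled$p.value),
                 welch = list(statistic = unname(welch$statistic),
                              df = unname(welch$parameter),
                              p_value = welch$p.value),
                 levene_p = lev_p),
            class = "test_result")
}

#' Mann-Whitney U test
#'
#' U statistic with the tie-corrected normal approximation
#' z = (U - n1 n2 / 2) / sd and a two-sided p-value.
#'
#' @param x,y numeric samples.
#' @return `test_result` with `statistic` (U for `x`), `z`, `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sig2 > 0) (U - mu) / sqrt(sig2) else 0
  structure(list(statistic = U, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 df = NA_integer_,
                 method = "Mann-Whitney U (normal approximation, tie-corrected)"),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g%s, p = %.4g\n",
              x$method, x$statistic,
              if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value))
  invisible(x)
}

#' Cohen's kappa for interobserver agreement
#'
#' kappa = (p_o - p_e) / (1 - p_e) with the large-sample standard error
#' sqrt(p_o (1 - p_o) / (n (1 - p_e)^2)) and a normal 95% confidence
#' interval. Percent agreement is reported alongside.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @param conf_level confidence level (default 0.95).
#' @return list of class `kappa_result`: `kappa`, `ci`, `agreement_pct`,
#'   `se`; kappa is NA (flagged) when both raters use a single shared
#'   category so chance agreement is 1.
#' @export
cohens_kappa <- function(ratings_a, ratings_b, conf_level = 0.95) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) > 0)
  lev <- sort(unique(c(as.character(ratings_a), as.character(ratings_b))))
  a <- factor(as.character(ratings_a), levels = lev)
  b <- factor(as.character(ratings_b), levels = lev)
  m <- table(a, b)
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (1 - pe < .Machine$double.eps)
    return(structure(list(kappa = NA_real_, ci = c(NA_real_, NA_real_),
                          agreement_pct = 100 * po, se = NA_real_,
                          degenerate = TRUE),
                     class = "kappa_result"))
  kap <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(kappa = kap, ci = c(kap - zq * se, kap + zq * se),
                 agreement_pct = 100 * po, se = se, degenerate = FALSE),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa = %.3f (95%% CI %.3f-%.3f), agreement %.1f%%\n",
              x$kappa, x$ci[1], x$ci[2], x$agreement_pct))
  invisible(x)
}

#' Logistic regression with Wald statistics and odds ratios
#'
#' Maximum-likelihood binomial fit; per predictor the coefficient, its
#' standard error, the Wald statistic (beta/SE)^2, p-value, odds ratio
#' exp(beta) and its exp(beta +/- 1.96 SE) interval. Quasi-complete
#' separation (diverging coefficients) is detected and reported, not
#' silently returned.
#'
#' @param formula model formula, e.g. `her2 ~ pi + microcalcification`.
#' @param data data.frame; the response must be a two-level factor or 0/1.
#' @param conf_level confidence level for the OR interval.
#' @return list of class `logistic_model`: `coefficients` data.frame
#'   (beta, se, wald, p, or, or_lo, or_hi), `fit` (the glm), `converged`,
#'   `separation`.
#' @export
logistic_fit <- function(formula, data, conf_level = 0.95) {
  fit <- stats::glm(formula, data = data, family = stats::binomial())
  sm <- summary(fit)$coefficients
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- sm[, 1]; se <- sm[, 2]
  co <- data.frame(term = rownames(sm), beta = beta, se = se,
                   wald = (beta / se)^2,
                   p = stats::pchisq((beta / se)^2, 1, lower.tail = FALSE),
                   or = exp(beta),
                   or_lo = exp(beta - zq * se), or_hi = exp(beta + zq * se),
                   row.names = NULL)
  separation <- any(abs(beta[-1]) > 15) ||
    any(fit$fitted.values > 1 - 1e-10) && any(fit$fitted.values < 1e-10)
  structure(list(coefficients = co, fit = fit,
                 converged = fit$converged, separation = separation),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model>", if (x$separation) "(separation detected)" else "", "\n")
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

## internal: DeLong variance of the empirical AUC
delong_auc_var <- function(scores, labels) {
  xs <- scores[labels == 1]; ys <- scores[labels == 0]
  m <- length(xs); n <- length(ys)
  ## placement values
  V10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n, numeric(1))
  V01 <- vapply(ys, function(y) (sum(xs > y) + 0.5 * sum(xs == y)) / m, numeric(1))
  stats::var(V10) / m + stats::var(V01) / n
}

#' ROC analysis
#'
#' Empirical ROC over all observed cutoffs; AUC by the Mann-Whitney
#' identity (probability a positive outscores a negative, ties counted
#' half); DeLong 95% confidence interval; sensitivity, specificity and
#' accuracy at the Youden-optimal cutoff (J = sens + spec - 1), ties
#' broken toward higher specificity.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels two-level factor or 0/1 vector (1 / second level = positive).
#' @param conf_level confidence level.
#' @return list of class `roc_result`: `auc`, `auc_ci`, `sensitivity`,
#'   `specificity`, `accuracy`, `cutoff`, `curve` (data.frame fpr, tpr,
#'   cutoff), `degenerate`.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L
       else as.integer(labels > 0)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  xs <- scores[y == 1]; ys <- scores[y == 0]
  m <- length(xs); n <- length(ys)
  ## Mann-Whitney identity
  auc <- (sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))) / (m * n)
  degenerate <- length(unique(scores)) == 1L
  v <- if (degenerate) NA_real_ else delong_auc_var(scores, y)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(v)) c(NA_real_, NA_real_)
        else pmin(pmax(auc + c(-1, 1) * zq * sqrt(v), 0), 1)
  ## empirical curve: cutoffs midway between consecutive distinct scores
  su <- sort(unique(scores))
  cuts <- c(-Inf, (su[-1] + su[-length(su)]) / 2, Inf)
  tpr <- vapply(cuts, function(c0) mean(xs > c0), numeric(1))
  fpr <- vapply(cuts, function(c0) mean(ys > c0), numeric(1))
  curve <- data.frame(cutoff = cuts, fpr = fpr, tpr = tpr)
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.max(1 - fpr[best])]      # ties -> higher specificity
  sens <- tpr[best]; spec <- 1 - fpr[best]
  acc <- (sens * m + spec * n) / (m + n)
  structure(list(auc = auc, auc_ci = ci, sensitivity = sens,
                 specificity = spec, accuracy = acc, cutoff = cuts[best],
                 curve = curve, degenerate = degenerate,
                 n_pos = m, n_neg = n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f); sens %.1f%%, spec %.1f%%, acc %.1f%% at cutoff %.3g\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], 100 * x$sensitivity,
              100 * x$specificity, 100 * x$accuracy, x$cutoff))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Diagnostic performance of modality combinations
#'
#' For every non-empty union of the named feature sets (e.g. CUS, CEUS,
#' SRUS - seven combinations for three modalities), a logistic score model
#' is fit in-sample on that feature subset and its fitted probabilities are
#' evaluated by [roc_analysis()]. Results are in-sample and labelled as
#' such; a singular or separated fit is reported per combination rather
#' than aborting the rest.
#'
#' @param data data.frame with the features and the label column.
#' @param modality_sets named list of character vectors of column names.
#' @param label name of the two-level label column (second level = positive).
#' @return data.frame of class `modality_roc`: one row per combination with
#'   sensitivity, specificity, accuracy (percent), AUC and its CI, plus a
#'   `note` column for fit warnings. ROC objects are attached as attribute
#'   `"roc"`.
#' @export
combine_modalities <- function(data, modality_sets, label = "her2") {
  stopifnot(length(modality_sets) >= 1L, !is.null(names(modality_sets)))
  nm <- names(modality_sets)
  combos <- list()
  for (k in seq_along(nm))
    combos <- c(combos, utils::combn(nm, k, simplify = FALSE))
  rows <- list(); rocs <- list()
  for (cb in combos) {
    cname <- paste(cb, collapse = "+")
    feats <- unique(unlist(modality_sets[cb]))
    fml <- stats::as.formula(paste(label, "~",
                                   paste(sprintf("`%s`", feats), collapse = " + ")))
    note <- ""
    fit <- tryCatch(logistic_fit(fml, data), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[cname]] <- data.frame(combination = cname, sensitivity_pct = NA,
                                  specificity_pct = NA, accuracy_pct = NA,
                                  auc = NA, auc_lo = NA, auc_hi = NA,
                                  note = conditionMessage(fit))
      next
    }
    if (fit$separation) note <- "separation"
    if (!fit$converged) note <- paste(note, "non-convergence")
    roc <- roc_analysis(stats::fitted(fit$fit), data[[label]])
    rocs[[cname]] <- roc
    rows[[cname]] <- data.frame(
      combination = cname,
      sensitivity_pct = 100 * roc$sensitivity,
      specificity_pct = 100 * roc$specificity,
      accuracy_pct = 100 * roc$accuracy,
      auc = roc$auc, auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
      note = trimws(note))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "roc") <- rocs
  class(out) <- c("modality_roc", class(out))
  out
}
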