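## Statistical stage: rank tests, ROC, cut-off diagnostics, outlier screen.
## The substantive tests are implemented directly (exact Mann-Whitney via a
## shift-algorithm convolution, rank AUC, Grubbs); ordinary fits and the
## normality gate delegate to base R.

#' Shapiro-Wilk normality gate
#'
#' Used to justify nonparametric group tests in small samples; the result is
#' logged, not branched on.
#'
#' @param values numeric sample, 3 <= n <= 50.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  assert_that(n >= 3 && n <= 50, "parameter",
              "Shapiro-Wilk gate requires 3 <= n <= 50")
  assert_that(stats::sd(values) > 0, "parameter",
              "sample is constant; normality test degenerate")
  s <- stats::shapiro.test(values)
  list(W = unname(s$statistic), p = s$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test with mid-ranks for ties. The reported statistic is
#' `U = min(U_a, U_b)`. When `n_a * n_b <= exact_limit` the two-tailed
#' p-value is exact, computed from the permutation distribution of the rank
#' sum (shift-algorithm convolution, valid under ties); otherwise the
#' tie-corrected normal approximation is used.
#'
#' @param a,b numeric samples.
#' @param exact_limit product threshold for the exact branch.
#' @return list of class `group_comparison`: `U`, `p`, `method`, and per-group
#'   `median` / `iqr` (named `a`, `b`).
#' @export
mann_whitney_u <- function(a, b, exact_limit = 400) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  assert_that(length(a) >= 1 && length(b) >= 1, "parameter",
              "both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  Ra <- sum(r[seq_len(n1)])
  Ua <- Ra - n1 * (n1 + 1) / 2
  Ub <- n1 * n2 - Ua
  mu <- n1 * n2 / 2
  if (n1 * n2 <= exact_limit) {
    p <- exact_rank_p(r, n1, Ua)
    method <- "exact"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    z <- if (sigma > 0) (Ua - mu) / sigma else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_tie_corrected"
  }
  structure(list(U = min(Ua, Ub), p = p, method = method,
                 median = c(a = stats::median(a), b = stats::median(b)),
                 iqr = c(a = unname(diff(stats::quantile(a, c(.25, .75)))),
                         b = unname(diff(stats::quantile(b, c(.25, .75))))),
                 n = c(a = n1, b = n2)),
            class = "group_comparison")
}

## Exact two-tailed p for the rank-sum of the first group: the fraction of
## equally-likely n1-subsets whose U deviates from n1*n2/2 by at least as
## much as the observed U. Doubled mid-ranks are integers, so the
## distribution of the subset score sum is built by convolution.
exact_rank_p <- function(r, n1, Ua_obs) {
  scores <- sort(round(2 * r))
  N <- length(scores)
  n2 <- N - n1
  maxsum <- sum(scores[(N - n1 + 1):N])
  ## counts[k+1, s+1] = number of k-subsets with score sum s
  counts <- matrix(0, nrow = n1 + 1, ncol = maxsum + 1)
  counts[1, 1] <- 1
  for (i in seq_along(scores)) {
    sc <- scores[i]
    for (k in seq(min(i, n1), 1L)) {
      shifted <- c(numeric(sc), counts[k, seq_len(maxsum + 1 - sc)])
      counts[k + 1, ] <- counts[k + 1, ] + shifted
    }
  }
  tot <- counts[n1 + 1, ]
  sums <- which(tot > 0) - 1
  U_all <- sums / 2 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev <- abs(U_all - mu)
  obs <- abs(Ua_obs - mu)
  sum(tot[sums + 1][dev >= obs - 1e-9]) / sum(tot)
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param tab 2x2 matrix of counts.
#' @return list with `chisq` and `p` (1 df, no continuity correction).
#' @export
chi_square_binary <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == 2) && all(tab >= 0), "parameter",
              "need a 2x2 table of non-negative counts")
  assert_that(all(rowSums(tab) > 0) && all(colSums(tab) > 0), "parameter",
              "table has a zero margin")
  s <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(s$statistic), p = s$p.value)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R-squared rescaled by its attainable maximum.
#'
#' @param loglik_null,loglik_model log-likelihoods of the intercept-only and
#'   fitted models.
#' @param n number of observations.
#' @return value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_model, n) {
  assert_that(n > 0, "parameter", "n must be positive")
  assert_that(loglik_model >= loglik_null - 1e-8, "parameter",
              "model log-likelihood below null log-likelihood")
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  r2_max <- 1 - exp(2 * loglik_null / n)
  if (r2_max <= 0) return(0)
  min(max(r2_cs / r2_max, 0), 1)
}

#' ROC curve and AUC for an SPA biomarker
#'
#' Nonparametric (rank) AUC with mid-rank tie handling. By default the
#' orientation is "lower SPA predicts the positive class", matching the
#' direction of spindle power asymmetry after unilateral injury. The
#' standard error uses the Hanley-McNeil variance formula and the 95%
#' interval is asymptotic, truncated to `[0, 1]`.
#'
#' @param scores numeric biomarker values (SPA).
#' @param labels logical or 0/1 vector, `TRUE` = positive class (UCP).
#' @param orientation `"lower_positive"` (default) or `"higher_positive"`.
#' @return list of class `roc_result`: `auc`, `se`, `ci95`, `orientation`,
#'   and `curve` (data frame of threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels, orientation = c("lower_positive",
                                                    "higher_positive")) {
  orientation <- match.arg(orientation)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  n1 <- sum(labels); n2 <- sum(!labels)
  assert_that(n1 > 0 && n2 > 0, "parameter", "both classes must be present")
  s <- if (orientation == "lower_positive") -scores else scores
  r <- rank(s)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n2 - 1) * (q2 - auc^2)) /
    (n1 * n2)
  se <- sqrt(max(v, 0))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  thr <- sort(unique(c(-Inf, s, Inf)))
  curve <- data.frame(
    threshold = if (orientation == "lower_positive") -thr else thr,
    sensitivity = vapply(thr, function(t) mean(s[labels] > t), numeric(1)),
    specificity = vapply(thr, function(t) mean(s[!labels] <= t), numeric(1)))
  structure(list(auc = auc, se = se, ci95 = ci, orientation = orientation,
                 n = c(positive = n1, negative = n2), curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (SE %.3f, 95%% CI %.3f-%.3f), orientation: %s\n",
              x$auc, x$se, x$ci95[1], x$ci95[2], x$orientation))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  o <- order(1 - x$curve$specificity, x$curve$sensitivity)
  graphics::plot(1 - x$curve$specificity[o], x$curve$sensitivity[o],
                 type = "s", xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Diagnostics at a fixed SPA cut-off
#'
#' Predicts the positive class (UCP) when SPA is strictly below the cut-off;
#' a value exactly at the cut-off is classified as typical.
#'
#' @param scores SPA values.
#' @param labels logical or 0/1, `TRUE` = UCP.
#' @param cutoff SPA cut-off (default 0.65).
#' @return list of class `diagnostic_metrics`: `cutoff`, the 2x2 counts
#'   (`tp`, `fp`, `tn`, `fn`) and `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
diagnostic_metrics <- function(scores, labels, cutoff = 0.65) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.logical(labels[keep])
  assert_that(any(labels) && any(!labels), "parameter",
              "both classes must be present")
  pred <- scores < cutoff
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
  structure(list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
            class = "diagnostic_metrics")
}

#' Grubbs test for a single outlier
#'
#' Compares the maximum studentized deviation `G = max|x - mean| / sd`
#' against the t-based critical value at two-sided significance `alpha`. At
#' most one outlier is reported per call; `iterate = TRUE` re-tests after
#' removal until no outlier remains.
#'
#' @param values numeric sample (n >= 3); names, if present, identify the
#'   outlier.
#' @param alpha two-sided significance level.
#' @param iterate re-test after removing each detected outlier.
#' @return list of class `grubbs_result`: `G`, `critical`, `outlier`
#'   (name/index or `NA`), and with `iterate`, `outliers` (all removed).
#' @export
grubbs_test <- function(values, alpha = 0.05, iterate = FALSE) {
  x <- values[!is.na(values)]
  assert_that(length(x) >= 3, "parameter", "Grubbs test requires n >= 3")
  assert_that(stats::sd(x) > 0, "domain", "zero variance; test degenerate")
  if (is.null(names(x))) names(x) <- as.character(seq_along(x))
  one_pass <- function(x) {
    n <- length(x)
    dev <- abs(x - mean(x)) / stats::sd(x)
    G <- max(dev)
    crit <- grubbs_critical(n, alpha)
    list(G = G, critical = crit,
         outlier = if (G > crit) names(x)[which.max(dev)] else NA_character_)
  }
  res <- one_pass(x)
  removed <- character(0)
  if (iterate) {
    while (!is.na(res$outlier) && length(x) > 3) {
      removed <- c(removed, res$outlier)
      x <- x[names(x) != res$outlier]
      if (stats::sd(x) == 0) break
      res <- one_pass(x)
    }
    if (!is.na(res$outlier)) removed <- c(removed, res$outlier)
  }
  structure(c(res, list(alpha = alpha, n = length(values),
                        outliers = if (iterate) removed)),
            class = "grubbs_result")
}

#' Grubbs critical value
#'
#' Closed-form t-based critical value for the two-sided single-outlier test.
#'
#' @param n sample size.
#' @param alpha two-sided significance level.
#' @return critical value of G.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- stats::qt(alpha / (2 * n), n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}
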