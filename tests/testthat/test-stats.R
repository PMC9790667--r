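test_that("Mann-Whitney statistic and exact p behave on canonical cases", {
  ## complete separation
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-9)  # 2/C(6,3)*... enumerated below
  expect_equal(r$p, mw_enumeration_p(c(1, 2, 3), c(4, 5, 6)))
  ## identical multisets: U = n^2/2, p ~ 1
  r <- mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$U, 8)
  expect_equal(r$p, 1, tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "spindlespa_parameter_error")
})

test_that("exact p equals exhaustive enumeration, with and without ties", {
  set.seed(401)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- round(rnorm(n1), sample(0:1, 1))   # rounding induces ties
    b <- round(rnorm(n2), 1)
    expect_equal(mann_whitney_u(a, b)$p, mw_enumeration_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("exact p matches wilcox.test when there are no ties", {
  set.seed(402)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(mann_whitney_u(a, b)$p,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(403)
  a <- rnorm(25); b <- rnorm(25)  # 625 > 400
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal_tie_corrected")
  expect_equal(r$p, wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("chi-square matches the Pearson formula", {
  r <- chi_square_binary(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  expect_equal(chi_square_binary(matrix(c(20, 0, 0, 20), 2))$chisq, 40)
  ## cohort sex split: 6/13 UCP female vs 13/27 typical female
  tab <- matrix(c(6, 13 - 6, 13, 27 - 13), 2)
  expect_gt(chi_square_binary(tab)$p, 0.05)
  expect_error(chi_square_binary(matrix(c(0, 0, 5, 5), 2)),
               class = "spindlespa_parameter_error")
})

test_that("Shapiro-Wilk gate flags non-normal samples", {
  expect_lt(shapiro_wilk(c(rep(0, 20), rep(10, 20)))$p, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), class = "spindlespa_parameter_error")
  expect_error(shapiro_wilk(rnorm(60)), class = "spindlespa_parameter_error")
  set.seed(404)
  ok <- mean(vapply(1:100, function(i) shapiro_wilk(rnorm(40))$p > 0.05,
                    logical(1)))
  expect_gte(ok, 0.9)
})

test_that("Nagelkerke R2 spans its bounds and matches the formula", {
  n <- 10
  ll0 <- sum(dbinom(c(rep(1, 5), rep(0, 5)), 1, 0.5, log = TRUE))
  expect_equal(nagelkerke_r2(ll0, ll0, n), 0)
  expect_equal(nagelkerke_r2(ll0, -1e-9, n), 1, tolerance = 1e-6)
  ll1 <- ll0 + 2.3
  r2cs <- 1 - exp(-2 * 2.3 / n)
  expect_equal(nagelkerke_r2(ll0, ll1, n), r2cs / (1 - exp(2 * ll0 / n)))
  expect_error(nagelkerke_r2(ll0, ll1, 0), class = "spindlespa_parameter_error")
})

test_that("AUC equals the concordant-pair oracle and reverses cleanly", {
  ## perfect separation (all positive SPA below all negative SPA)
  r <- roc_auc(c(0.5, 0.6, 0.9, 1.0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  set.seed(405)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    s <- round(runif(n), 1)
    l <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    expect_equal(roc_auc(s, l)$auc, auc_pair_oracle(s, l), tolerance = 1e-12)
    expect_equal(roc_auc(s, l, "higher_positive")$auc,
                 1 - roc_auc(s, l)$auc, tolerance = 1e-12)
  }
  ## labels independent of scores -> AUC near 1/2
  set.seed(406)
  r <- roc_auc(runif(2000), rep(c(TRUE, FALSE), 1000))
  expect_equal(r$auc, 0.5, tolerance = 0.05)
  expect_error(roc_auc(1:5, rep(TRUE, 5)),
               class = "spindlespa_parameter_error")
})

test_that("AUC and CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(407)
  s <- c(rlnorm(13, log(0.6), 0.3), rlnorm(27, 0, 0.25))
  l <- rep(c(TRUE, FALSE), c(13, 27))
  ours <- roc_auc(s, l)
  theirs <- pROC::roc(response = l, predictor = s, direction = ">",
                      levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
})

test_that("cut-off diagnostics are internally consistent", {
  d <- diagnostic_metrics(c(0.56, 0.60, 1.00, 0.92), c(1, 1, 0, 0), 0.65)
  expect_equal(c(d$sensitivity, d$specificity, d$ppv, d$npv), rep(1, 4))
  ## boundary value counts as typical
  d2 <- diagnostic_metrics(c(0.65, 0.9), c(1, 0), cutoff = 0.65)
  expect_equal(d2$fn, 1)
  expect_equal(d2$tn, 1)
  ## stated confusion table arithmetic
  sc <- c(rep(0.5, 13), rep(0.7, 2), rep(0.9, 25))
  lb <- c(rep(1, 15), rep(0, 25))
  d3 <- diagnostic_metrics(sc, lb, 0.65)
  expect_equal(c(d3$tp, d3$fp, d3$tn, d3$fn), c(13, 0, 25, 2))
  expect_equal(d3$sensitivity, 13 / 15)
  expect_equal(d3$ppv, 1)
  expect_equal(d3$npv, 25 / 27)
  expect_equal(d3$tp + d3$fp + d3$tn + d3$fn, length(sc))
})

test_that("Grubbs test flags single outliers against t-based criticals", {
  r <- grubbs_test(c(1, 1, 1, 1, 10))
  expect_false(is.na(r$outlier))
  expect_equal(r$outlier, "5")
  expect_true(is.na(grubbs_test(c(-1, 0, 1))$outlier))
  ## published two-sided 5% critical values
  expect_equal(grubbs_critical(5), 1.715, tolerance = 0.01)
  expect_equal(grubbs_critical(10), 2.290, tolerance = 0.01)
  expect_equal(grubbs_critical(20), 2.709, tolerance = 0.01)
  expect_error(grubbs_test(rep(2, 5)), class = "spindlespa_domain_error")
  ## iterative removal reports all removed points
  set.seed(408)
  x <- c(rnorm(20), 8, 12)
  ri <- grubbs_test(x, iterate = TRUE)
  expect_gte(length(ri$outliers), 1)
})
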