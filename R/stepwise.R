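#' Forward-conditional logistic model selection
#'
#' Stepwise binary logistic regression starting from the constant model:
#' at each step the candidate with the smallest score-test (Rao) p-value
#' enters if it is at most `p_enter`; after each entry, any predictor whose
#' likelihood-ratio removal p-value is at least `p_remove` is removed.
#' Iteration stops when no candidate can enter and none must leave.
#'
#' Rows with missing values in any candidate are dropped (listwise deletion).
#' Complete or quasi-complete separation is flagged; reported coefficients
#' then come from a weakly ridge-penalized refit so that Wald statistics stay
#' finite, while selection p-values (score and likelihood-ratio tests) are
#' unaffected.
#'
#' @param data data frame holding candidates and outcome.
#' @param candidates character vector of candidate column names.
#' @param outcome outcome column name; must be binary (logical, 0/1, or a
#'   two-level factor where the second level is the positive class).
#' @param p_enter score-test entry threshold.
#' @param p_remove likelihood-ratio removal threshold.
#' @param ridge_lambda penalty used only for the separation fallback.
#' @return list of class `logistic_selection`: `selected` (in entry order),
#'   `steps` (per-step log), `coefficients` (data frame with estimates, SE,
#'   Wald chi-square, p), `nagelkerke_r2`, `classification_accuracy` (at
#'   probability 0.5), `separation` flag, `n`.
#' @export
forward_conditional_logistic <- function(data, candidates, outcome,
                                         p_enter = 0.05, p_remove = 0.1,
                                         ridge_lambda = 1e-2) {
  assert_that(length(candidates) >= 1, "parameter",
              "need at least one candidate predictor")
  y <- data[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y) | y == 1)
  keep <- stats::complete.cases(data[, candidates, drop = FALSE]) & !is.na(y)
  df <- data[keep, candidates, drop = FALSE]
  y <- y[keep]
  n <- length(y)
  assert_that(length(unique(y)) == 2, "parameter",
              "both outcome classes must be present")
  df$.y <- y

  selected <- character(0)
  steps <- list()
  fit_model <- function(vars) {
    f <- if (length(vars)) {
      stats::reformulate(vars, response = ".y")
    } else ".y ~ 1"
    suppressWarnings(stats::glm(stats::as.formula(f), family = stats::binomial(),
                                data = df, control = list(maxit = 50)))
  }
  fit <- fit_model(selected)

  repeat {
    changed <- FALSE
    ## Entry: smallest score-test p among remaining candidates
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      scope <- stats::reformulate(c(selected, remaining), response = ".y")
      a1 <- suppressWarnings(stats::add1(fit, scope = scope, test = "Rao"))
      pvals <- stats::setNames(a1[["Pr(>Chi)"]], rownames(a1))[remaining]
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) && min(pvals) <= p_enter) {
        enter <- names(pvals)[which.min(pvals)]
        selected <- c(selected, enter)
        fit <- fit_model(selected)
        steps[[length(steps) + 1L]] <- list(action = "enter", term = enter,
                                            p = unname(min(pvals)))
        changed <- TRUE
      }
    }
    ## Removal: largest likelihood-ratio p at or above p_remove
    if (length(selected)) {
      d1 <- suppressWarnings(stats::drop1(fit, test = "LRT"))
      pvals <- stats::setNames(d1[["Pr(>Chi)"]], rownames(d1))[selected]
      pvals <- pvals[!is.na(pvals)]
      while (length(pvals) && max(pvals) >= p_remove) {
        leave <- names(pvals)[which.max(pvals)]
        selected <- setdiff(selected, leave)
        fit <- fit_model(selected)
        steps[[length(steps) + 1L]] <- list(action = "remove", term = leave,
                                            p = unname(max(pvals)))
        changed <- TRUE
        if (!length(selected)) break
        d1 <- suppressWarnings(stats::drop1(fit, test = "LRT"))
        pvals <- stats::setNames(d1[["Pr(>Chi)"]], rownames(d1))[selected]
        pvals <- pvals[!is.na(pvals)]
      }
    }
    if (!changed) break
    if (length(steps) > 4 * length(candidates)) break  # cycling guard
  }

  separation <- length(selected) > 0 &&
    (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15) ||
       any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8))
  coefs <- summarize_logistic(fit, df, selected, separation, ridge_lambda)
  ll_null <- as.numeric(stats::logLik(fit_model(character(0))))
  ll_model <- as.numeric(stats::logLik(fit))
  acc <- mean((fit$fitted.values >= 0.5) == (y == 1))
  if (separation) {
    warning("complete or quasi-complete separation detected; ",
            "coefficients from penalized fallback")
  }
  structure(list(selected = selected, steps = steps, coefficients = coefs,
                 nagelkerke_r2 = nagelkerke_r2(ll_null, ll_model, n),
                 classification_accuracy = acc,
                 loglik = c(null = ll_null, model = ll_model),
                 separation = separation, n = n,
                 p_enter = p_enter, p_remove = p_remove),
            class = "logistic_selection")
}

summarize_logistic <- function(fit, df, selected, separation, ridge_lambda) {
  if (!length(selected)) {
    s <- summary(fit)$coefficients
    return(data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
                      wald = s[, 3]^2,
                      p = stats::pchisq(s[, 3]^2, 1, lower.tail = FALSE),
                      row.names = NULL))
  }
  if (separation) {
    X <- cbind(`(Intercept)` = 1, as.matrix(df[, selected, drop = FALSE]))
    rf <- ridge_logistic(X, df$.y, lambda = ridge_lambda)
    est <- rf$beta; se <- rf$se
  } else {
    s <- summary(fit)$coefficients
    est <- s[, 1]; se <- s[, 2]
  }
  wald <- (est / se)^2
  data.frame(term = names(est) %||% c("(Intercept)", selected),
             estimate = unname(est), se = unname(se), wald = unname(wald),
             p = stats::pchisq(unname(wald), 1, lower.tail = FALSE),
             row.names = NULL)
}

## L2-penalized logistic regression by iteratively reweighted least squares;
## the intercept is not penalized. Used only as a reporting fallback under
## separation.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + pen
    g <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se = se)
}

#' @export
print.logistic_selection <- function(x, ...) {
  cat("Forward-conditional logistic selection\n")
  if (!length(x$selected)) {
    cat("  no predictor entered the model\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = " -> "), "\n")
  }
  cat(sprintf("  Nagelkerke R2 = %.3f, accuracy at 0.5 = %.3f (n = %d)%s\n",
              x$nagelkerke_r2, x$classification_accuracy, x$n,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}
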