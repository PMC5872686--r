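#' Unconditional logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares with a step-halving safeguard, so the log-likelihood is
#' non-decreasing across iterations.  Convergence is declared when the
#' largest absolute score (gradient) component falls below \code{tol}.
#' Complete or quasi-complete separation is detected (a diverging
#' coefficient with fitted probabilities pinned to the outcome) and raised
#' as an error naming the offending column; a small ridge penalty can be
#' requested instead via \code{ridge}.
#'
#' @param x numeric design matrix including the intercept column; columns
#'   must be named.
#' @param y binary outcome vector (0/1), both classes present.
#' @param tol convergence tolerance on the maximum absolute score.
#' @param max_iter maximum IRLS iterations.
#' @param ridge optional ridge penalty lambda (0 = plain ML).
#' @return an object of class \code{helio_fit}: list with
#'   \code{coefficients}, \code{vcov} (inverse observed information),
#'   \code{converged}, \code{n_iter}, \code{loglik}, \code{loglik_trace},
#'   \code{n}, \code{model = "logistic"}.
#' @examples
#' set.seed(1)
#' x <- cbind("(Intercept)" = 1, expo = rbinom(200, 1, 0.5))
#' y <- rbinom(200, 1, plogis(-0.3 + 0.8 * x[, "expo"]))
#' fit_logistic(x, y)$coefficients
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 50L, ridge = 0) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("design matrix columns must be uniquely named")
  y <- as.numeric(y)
  if (any(is.na(x)) || any(is.na(y))) stop("design contains missing values")
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: both classes must be present")
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("more columns than informative rows")

  loglik <- function(beta) {
    eta <- drop(x %*% beta)
    sum(y * eta - log1p(exp(eta))) - 0.5 * ridge * sum(beta^2)
  }
  beta <- numeric(p)
  ll <- loglik(beta)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  repeat {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(x, y - mu)) - ridge * beta
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    w <- mu * (1 - mu)
    info <- crossprod(x, x * w) + diag(ridge, p)
    step <- tryCatch(solve(info, score), error = function(e)
      stop("information matrix is singular: check for collinear columns"))
    # step halving: never let the penalized log-likelihood decrease
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      h <- h / 2
      if (h < 2^-30) { cand <- beta; llc <- ll; break }
    }
    beta <- cand
    ll <- llc
    trace <- c(trace, ll)
    # under (quasi-)complete separation the likelihood is monotone in some
    # coefficient and the score vanishes as it diverges; catch the divergence
    if (ridge == 0 && max(abs(beta)) > 15) {
      j <- which.max(abs(beta))
      stop(sprintf(
        "separation suspected: coefficient for '%s' diverging (|beta| = %.1f)",
        colnames(x)[j], abs(beta[j])))
    }
  }
  mu <- plogis(drop(x %*% beta))
  info <- crossprod(x, x * (mu * (1 - mu))) + diag(ridge, p)
  vc <- solve(info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(coefficients = setNames(drop(beta), colnames(x)),
                 vcov = vc, converged = converged, n_iter = iter,
                 loglik = ll, loglik_trace = trace, n = n,
                 model = "logistic"),
            class = "helio_fit")
}

#' Conditional logistic regression for matched sets
#'
#' Maximizes the matched-set conditional likelihood
#' \deqn{\prod_s \exp(x_{case} \beta) / \sum_{m \in s} \exp(x_m \beta)}
#' by Newton iteration with step halving.  Each set must contain exactly one
#' case and at least one control.  Sets whose members share identical
#' covariate rows carry no information about \eqn{\beta}; they are counted
#' and excluded, and fitting fails if no informative set remains.
#'
#' @param x numeric covariate matrix (no intercept: it cancels from the
#'   conditional likelihood); named columns.
#' @param y binary case indicator.
#' @param strata matched-set identifier, one per row.
#' @inheritParams fit_logistic
#' @return a \code{helio_fit} with \code{model = "conditional_logistic"} and
#'   \code{n_uninformative}, the number of excluded concordant sets.
#' @export
fit_conditional_logistic <- function(x, y, strata, tol = 1e-8,
                                     max_iter = 50L) {
  x <- as.matrix(x)
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop("covariate matrix columns must be uniquely named")
  y <- as.numeric(y)
  if (any(is.na(x)) || any(is.na(y))) stop("design contains missing values")
  sets <- split(seq_len(nrow(x)), strata)
  ncase <- vapply(sets, function(i) sum(y[i]), numeric(1))
  if (any(ncase != 1) || any(lengths(sets) < 2L))
    stop("every matched set needs exactly one case and at least one control")
  informative <- vapply(sets, function(i) {
    xi <- x[i, , drop = FALSE]
    any(xi != rep(xi[1L, ], each = nrow(xi)))
  }, logical(1))
  n_uninf <- sum(!informative)
  sets <- sets[informative]
  if (length(sets) == 0L)
    stop("all matched sets are concordant: beta is unidentifiable")
  p <- ncol(x)

  eval_fit <- function(beta) {
    grad <- numeric(p)
    info <- matrix(0, p, p)
    for (i in sets) {
      xi <- x[i, , drop = FALSE]
      eta <- drop(xi %*% beta)
      w <- exp(eta - max(eta))
      w <- w / sum(w)
      xc <- xi[y[i] == 1, ]
      xbar <- drop(crossprod(w, xi))
      grad <- grad + xc - xbar
      info <- info + crossprod(xi * sqrt(w)) - tcrossprod(xbar)
    }
    list(grad = grad, info = info)
  }
  cond_loglik <- function(beta) {
    s <- 0
    for (i in sets) {
      eta <- drop(x[i, , drop = FALSE] %*% beta)
      m <- max(eta)
      s <- s + eta[y[i] == 1] - (m + log(sum(exp(eta - m))))
    }
    s
  }

  beta <- numeric(p)
  ll <- cond_loglik(beta)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  repeat {
    ev <- eval_fit(beta)
    if (max(abs(ev$grad)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    step <- tryCatch(solve(ev$info, ev$grad), error = function(e)
      stop("conditional information matrix is singular"))
    h <- 1
    repeat {
      cand <- beta + h * step
      llc <- cond_loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      h <- h / 2
      if (h < 2^-30) { cand <- beta; llc <- ll; break }
    }
    beta <- cand
    ll <- llc
    trace <- c(trace, ll)
    if (max(abs(beta)) > 15) {
      j <- which.max(abs(beta))
      stop(sprintf(
        "separation suspected: coefficient for '%s' diverging (|beta| = %.1f)",
        colnames(x)[j], abs(beta[j])))
    }
  }
  ev <- eval_fit(beta)
  vc <- solve(ev$info)
  dimnames(vc) <- list(colnames(x), colnames(x))
  structure(list(coefficients = setNames(drop(beta), colnames(x)),
                 vcov = vc, converged = converged, n_iter = iter,
                 loglik = ll, loglik_trace = trace,
                 n = length(y), n_sets = length(sets),
                 n_uninformative = n_uninf,
                 model = "conditional_logistic"),
            class = "helio_fit")
}

#' @export
print.helio_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d obs, loglik %.4f, %s in %d iterations\n",
              x$model, x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, se = se,
                   z = x$coefficients / se))
  invisible(x)
}

#' Wald odds ratio and confidence interval for a fitted term
#'
#' @param fit a converged \code{helio_fit}.
#' @param term coefficient name.
#' @param scale multiplier applied to the coefficient before
#'   exponentiation (e.g. report an OR per 10 units with \code{scale = 10}).
#' @param level confidence level (normal quantile; 0.95 uses z = 1.96).
#' @param note free-text scale annotation carried into the output.
#' @return one-row data frame: \code{term}, \code{odds_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{scale_note}.
#' @export
wald_or <- function(fit, term, scale = 1, level = 0.95, note = "") {
  stopifnot(inherits(fit, "helio_fit"))
  if (!fit$converged) stop("fit did not converge; odds ratios not reported")
  if (!term %in% names(fit$coefficients))
    stop(sprintf("term '%s' not in fit", term))
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- -qnorm((1 - level) / 2)
  p <- if (se > 0) 2 * pnorm(-abs(b / se)) else as.numeric(b == 0)
  data.frame(term = term,
             odds_ratio = exp(b * scale),
             ci_low = exp((b - z * se) * scale),
             ci_high = exp((b + z * se) * scale),
             p_value = p,
             scale_note = note,
             stringsAsFactors = FALSE)
}
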