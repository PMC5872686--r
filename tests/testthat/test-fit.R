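test_that("logistic fit reproduces the 2x2 cross-product ratio exactly", {
  set.seed(61)
  for (rep in 1:25) {
    tab <- sample(5:60, 4)
    d <- table_2x2_data(tab[1], tab[2], tab[3], tab[4])
    fit <- fit_logistic(d$x, d$y, tol = 1e-12)
    expect_equal(exp(fit$coefficients[["expo"]]), d$or, tolerance = 1e-10)
  }
})

test_that("logistic fit agrees with glm on a multi-covariate design", {
  set.seed(62)
  n <- 400
  x <- cbind("(Intercept)" = 1, a = rnorm(n), b = rbinom(n, 1, .4),
             c = runif(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x[, "a"] - 0.6 * x[, "b"]))
  fit <- fit_logistic(x, y, tol = 1e-10)
  g <- glm(y ~ a + b + c, data = as.data.frame(x[, -1]), family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("logistic null covariate stays within 3 SE of zero", {
  set.seed(63)
  n <- 1000
  x <- cbind("(Intercept)" = 1, z = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_logistic(x, y)
  expect_lt(abs(fit$coefficients[["z"]] / sqrt(fit$vcov["z", "z"])), 3)
})

test_that("degenerate outcomes and separation fail loudly; ridge rescues", {
  x <- cbind("(Intercept)" = 1, z = c(0, 0, 1, 1, 0, 1))
  expect_error(fit_logistic(x, rep(1, 6)), "both classes")
  # perfectly separating covariate
  xs <- cbind("(Intercept)" = 1, sep = c(rep(0, 20), rep(1, 20)))
  ys <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(xs, ys, max_iter = 100), "separation.*sep")
  rfit <- fit_logistic(xs, ys, ridge = 1e-2, max_iter = 200)
  expect_true(is.finite(rfit$coefficients[["sep"]]))
})

test_that("log-likelihood never decreases across IRLS/Newton iterations", {
  set.seed(64)
  n <- 300
  x <- cbind("(Intercept)" = 1, a = rnorm(n, sd = 3), b = rbinom(n, 1, .5))
  y <- rbinom(n, 1, plogis(2 * x[, "a"]))
  fit <- fit_logistic(x, y, max_iter = 100)
  expect_true(all(diff(fit$loglik_trace) >= -1e-12))
  xp <- cbind(expo = rnorm(40))
  yp <- rep(c(1, 0), 20)
  st <- rep(1:20, each = 2)
  cfit <- fit_conditional_logistic(xp, yp, st)
  expect_true(all(diff(cfit$loglik_trace) >= -1e-12))
})

test_that("conditional logistic equals the discordant-pair ratio on 1:1 pairs", {
  # 10 pairs case-exposed only, 5 control-exposed only, 7 concordant
  xp <- c(rep(c(1, 0), 10), rep(c(0, 1), 5), rep(c(1, 1), 4),
          rep(c(0, 0), 3))
  yp <- rep(c(1, 0), 22)
  st <- rep(seq_len(22), each = 2)
  fit <- fit_conditional_logistic(cbind(expo = xp), yp, st, tol = 1e-12)
  expect_equal(exp(fit$coefficients[["expo"]]), 2, tolerance = 1e-8)
  expect_equal(fit$n_uninformative, 7L)
  # fully concordant data carry no information at all
  xc <- rep(c(1, 1), 6)
  expect_error(fit_conditional_logistic(cbind(expo = xc), rep(c(1, 0), 6),
                                        rep(1:6, each = 2)),
               "concordant")
})

test_that("conditional logistic agrees with survival::clogit", {
  skip_if_not_installed("survival")
  set.seed(65)
  n_sets <- 60
  x <- cbind(a = rnorm(3 * n_sets), b = rbinom(3 * n_sets, 1, .5))
  st <- rep(seq_len(n_sets), each = 3)
  y <- unlist(lapply(split(seq_len(3 * n_sets), st), function(i) {
    p <- exp(0.7 * x[i, "a"])
    tabulate(sample(1:3, 1, prob = p), 3)
  }))
  fit <- fit_conditional_logistic(x, y, st, tol = 1e-10)
  d <- data.frame(x, st = st, y = y)
  cl <- survival::coxph(survival::Surv(rep(1, nrow(d)), y) ~ a + b +
                          survival::strata(st),
                        data = d, method = "exact")
  expect_equal(unname(fit$coefficients), unname(coef(cl)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(vcov(cl)))), tolerance = 1e-5)
})

test_that("conditional log-likelihood optimum matches a direct grid evaluation", {
  # 3 sets of size 3, small integer covariate
  x <- cbind(z = c(0, 1, 2,  1, 0, 2,  2, 1, 0))
  y <- c(0, 1, 0,  1, 0, 0,  1, 0, 0)
  st <- rep(1:3, each = 3)
  fit <- fit_conditional_logistic(x, y, st, tol = 1e-12)
  direct_ll <- function(b) {
    sum(vapply(split(seq_len(9), st), function(i) {
      eta <- x[i, 1] * b
      eta[y[i] == 1] - log(sum(exp(eta)))
    }, numeric(1)))
  }
  grid <- seq(-3, 3, by = 1e-4)
  ll_grid <- vapply(grid, direct_ll, numeric(1))
  b_star <- grid[which.max(ll_grid)]
  expect_equal(fit$coefficients[["z"]], b_star, tolerance = 1e-3)
  expect_equal(fit$loglik, direct_ll(fit$coefficients[["z"]]),
               tolerance = 1e-10)
  expect_gte(fit$loglik, max(ll_grid) - 1e-6)
})

test_that("wald_or implements the closed-form interval and p-value", {
  fit <- structure(list(coefficients = c(b0 = 0, b1 = log(2), b2 = -0.635),
                        vcov = diag(c(0.5, 0, 0.29)^2,
                                    names = FALSE) |>
                          `dimnames<-`(list(c("b0", "b1", "b2"),
                                            c("b0", "b1", "b2"))),
                        converged = TRUE, model = "logistic"),
                   class = "helio_fit")
  r0 <- wald_or(fit, "b0")
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$ci_low, exp(-qnorm(.975) * 0.5))
  expect_equal(r0$ci_high, exp(qnorm(.975) * 0.5))
  r1 <- wald_or(fit, "b1")   # degenerate SE = 0
  expect_equal(c(r1$ci_low, r1$odds_ratio, r1$ci_high), rep(2, 3))
  r2 <- wald_or(fit, "b2")
  expect_equal(r2$odds_ratio, exp(-0.635), tolerance = 1e-12)
  expect_equal(r2$ci_low, exp(-0.635 - qnorm(.975) * 0.29))
  expect_equal(r2$ci_high, exp(-0.635 + qnorm(.975) * 0.29))
  expect_equal(round(c(r2$odds_ratio, r2$ci_low, r2$ci_high), 2),
               c(0.53, 0.30, 0.94))
  nc <- fit; nc$converged <- FALSE
  expect_error(wald_or(nc, "b0"), "converge")
  expect_error(wald_or(fit, "nope"), "not in fit")
})
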