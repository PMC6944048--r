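test_that("unpenalized fit matches glm and zero-penalty limit", {
  d <- toy_logit_data(n = 300, seed = 2)
  ref <- glm(d$y ~ d$x, family = binomial())
  f0 <- fit_logistic(d$x, d$y, penalty = "none")
  expect_equal(unname(f0$intercept), unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(f0$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-8)
  # lambda1 = lambda2 = 0 falls back to the unpenalized solution
  f1 <- fit_logistic(d$x, d$y, penalty = "l1", lambda1 = 0)
  expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-6)
  expect_error(fit_logistic(d$x, rep(1, 300)), "degenerate")
})

test_that("large lambda1 zeroes penalized coefficients but not covariates", {
  d <- toy_logit_data(n = 250, seed = 3)
  covs <- cbind(age = psmsnp:::with_seed(9, rnorm(250, 50, 8)))
  X <- cbind(d$x, covs)
  f <- fit_logistic(X, d$y, penalty = "l1", lambda1 = 1e5,
                    unpenalized = "age")
  expect_identical(unname(f$coefficients[c("a", "b")]), c(0, 0))
  # the unpenalized covariate matches its own glm fit (SNP terms all zero)
  ref <- glm(d$y ~ covs, family = binomial())
  expect_equal(unname(f$coefficients["age"]), unname(coef(ref)[2]),
               tolerance = 1e-4)
})

test_that("penalized objective matches a direct numerical optimizer", {
  d <- toy_logit_data(n = 80, seed = 4)
  for (pen in list(list(p = "l1", l1 = 8, l2 = 0),
                   list(p = "elastic_net", l1 = 5, l2 = 3))) {
    f <- fit_logistic(d$x, d$y, penalty = pen$p, lambda1 = pen$l1,
                      lambda2 = pen$l2, standardize = FALSE)
    obj_fit <- penalized_objective(c(f$intercept, f$coefficients), d$x, d$y,
                                   pen$l1, pen$l2, penalized_idx = 1:2)
    oracle <- oracle_penalized_fit(d$x, d$y, pen$l1, pen$l2,
                                   penalized_idx = 1:2)
    expect_equal(obj_fit, oracle$value, tolerance = 1e-6)
  }
})

test_that("objective parity holds with an unpenalized covariate", {
  d <- toy_logit_data(n = 100, seed = 5)
  covs <- cbind(z = psmsnp:::with_seed(6, rnorm(100)))
  X <- cbind(d$x, covs)
  f <- fit_logistic(X, d$y, penalty = "l1", lambda1 = 6,
                    unpenalized = "z", standardize = FALSE)
  obj_fit <- penalized_objective(c(f$intercept, f$coefficients), X, d$y,
                                 6, 0, penalized_idx = 1:2)
  oracle <- oracle_penalized_fit(X, d$y, 6, 0, penalized_idx = 1:2)
  expect_equal(obj_fit, oracle$value, tolerance = 1e-6)
})

test_that("CV lambda selection behaves under noise and signal", {
  # one overwhelming predictor survives at lambda.min
  psmsnp:::with_seed(31, {
    x <- cbind(sig = rnorm(400), matrix(rnorm(400 * 10), 400,
                                        dimnames = list(NULL, paste0("n", 1:10))))
    y <- rbinom(400, 1, 1 / (1 + exp(-3 * x[, "sig"])))
  })
  cv <- cv_select_lambda(x, y, rule = "min", seed = 1)
  f <- fit_logistic(x, y, penalty = "l1", lambda1 = cv$lambda1)
  expect_true(f$coefficients["sig"] != 0)

  # one_se lambda is never below the min-rule lambda
  cv1 <- cv_select_lambda(x, y, rule = "one_se", seed = 1)
  expect_gte(cv1$lambda1, cv$lambda1)

  # pure noise with the conservative rule: empty selection in most replicates
  empty <- vapply(1:10, function(s) {
    psmsnp:::with_seed(100 + s, {
      xn <- matrix(rnorm(800 * 20), 800,
                   dimnames = list(NULL, paste0("x", 1:20)))
      yn <- rbinom(800, 1, 0.4)
    })
    cvn <- cv_select_lambda(xn, yn, rule = "one_se", seed = s)
    fn <- fit_logistic(xn, yn, penalty = "l1", lambda1 = cvn$lambda1)
    sum(fn$coefficients != 0) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.9)
})

test_that("nonzero-coefficient count is non-increasing in lambda on the CV grid", {
  psmsnp:::with_seed(33, {
    x <- matrix(rnorm(300 * 15), 300, dimnames = list(NULL, paste0("x", 1:15)))
    eta <- x[, 1] - 0.8 * x[, 2] + 0.5 * x[, 3]
    y <- rbinom(300, 1, 1 / (1 + exp(-eta)))
  })
  cv <- cv_select_lambda(x, y, seed = 2)
  # lambda_grid is decreasing, so nzero must be non-decreasing along it
  expect_true(all(diff(cv$nzero) >= 0))
})

test_that("predictions, tidiers and serialization are consistent", {
  d <- toy_logit_data(n = 200, seed = 7)
  f <- fit_logistic(d$x, d$y)
  p <- predict(f, d$x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(predict(f, d$x, type = "link"), psmsnp::logit(p),
               tolerance = 1e-10)
  td <- tidy(f)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 3)
  gl <- glance(f)
  expect_identical(gl$penalty, "none")
  path <- tempfile(fileext = ".json")
  write_model_json(f, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$intercept, f$intercept, tolerance = 1e-12)
})

test_that("separation is flagged and coefficients capped", {
  x <- cbind(v = c(rep(0, 20), rep(1, 20)))
  y <- c(rep(0, 20), rep(1, 20))
  f <- fit_logistic(x, y, penalty = "none")
  expect_true(f$separation)
  expect_false(f$converged)
  expect_true(all(is.finite(predict(f, x))))
})
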