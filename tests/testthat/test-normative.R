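test_that("noiseless linear data is fitted exactly and zero SD is refused", {
  n <- 20
  ages <- seq(5, 18, length.out = n)
  sexes <- rep(c("male", "female"), n / 2)
  y <- cbind(f1 = 1 + 2 * ages)
  expect_error(fit_normative_model(y, ages, sexes), "constant in controls")
  # with a second noisy feature the noiseless one still errors
  y2 <- cbind(y, f2 = rnorm(n))
  expect_error(fit_normative_model(y2, ages, sexes), "f1")
})

test_that("coefficients are recovered within sampling error", {
  set.seed(101)
  n <- 500
  ages <- runif(n, 5, 18)
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  beta <- c(3, 0.8, -1.5)
  y <- cbind(f = beta[1] + beta[2] * ages +
               beta[3] * (sexes == "male") + rnorm(n))
  m <- fit_normative_model(y, ages, sexes)
  # standard errors are ~0.15 at this n; 3 SE corridor
  expect_equal(unname(m$coefficients[, "f"]), beta, tolerance = 0.15)
  expect_lt(abs(m$residual_mean["f"]), 1e-8)
  expect_gt(m$residual_sd["f"], 0.85)
  expect_lt(m$residual_sd["f"], 1.15)
})

test_that("intercept-only signal: age coefficient within its null CI", {
  set.seed(102)
  n <- 200
  ages <- runif(n, 5, 18)
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  y <- cbind(f = 3 + rnorm(n))
  m <- fit_normative_model(y, ages, sexes)
  se_age <- summary(lm(y ~ ages + I(sexes == "male")))$coefficients[2, 2]
  expect_lt(abs(m$coefficients["age", "f"]), qnorm(0.995) * se_age)
})

test_that("degenerate designs are rejected", {
  ages <- rep(10, 20)
  sexes <- rep(c("male", "female"), 10)
  y <- cbind(f = rnorm(20))
  expect_error(fit_normative_model(y, ages, sexes), "rank-deficient")
  expect_error(fit_normative_model(y, runif(20, 5, 15), rep("male", 20)),
               "one sex")
  expect_error(fit_normative_model(y[1:4, , drop = FALSE], runif(4, 5, 15),
                                   c("male", "female", "male", "female")),
               "too few")
})

test_that("Z-scores are standardized on the training controls", {
  set.seed(103)
  n <- 80
  ages <- runif(n, 5, 18)
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  y <- cbind(a = 2 + 0.5 * ages + rnorm(n), b = 10 + rnorm(n, 0, 3))
  m <- fit_normative_model(y, ages, sexes)
  z <- t(sapply(seq_len(n), function(i)
    zscore_features(m, y[i, ], ages[i], sexes[i])))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-10)
})

test_that("zscore_patient matches the forced arithmetic example", {
  # coefficients (1, 2, 0), residual mean 0, sd 2; value 9 at age 3:
  # prediction 1 + 2*3 = 7, z = (9 - 7)/2 = 1
  m <- structure(list(coefficients = matrix(c(1, 2, 0), 3, 1,
                                            dimnames = list(NULL, "f")),
                      residual_mean = c(f = 0), residual_sd = c(f = 2),
                      features = "f", age_range = c(1, 10),
                      terms = c("intercept", "age", "sex_male")),
                 class = "normative_model")
  expect_equal(zscore_patient(m, "f", 9, age = 3, sex = "female"), 1)
  expect_equal(zscore_patient(m, "f", 7, age = 3, sex = "female"), 0)
})

test_that("affine shifts move the intercept only, Z-scores unchanged", {
  set.seed(104)
  n <- 60
  ages <- runif(n, 5, 18)
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  y <- cbind(f = 1 + 0.3 * ages + rnorm(n))
  m1 <- fit_normative_model(y, ages, sexes)
  m2 <- fit_normative_model(y + 100, ages, sexes)
  expect_equal(m2$coefficients["intercept", ],
               m1$coefficients["intercept", ] + 100)
  expect_equal(m2$coefficients["age", ], m1$coefficients["age", ])
  expect_equal(zscore_patient(m2, "f", y[1] + 100 + 1.7, ages[1], sexes[1]),
               zscore_patient(m1, "f", y[1] + 1.7, ages[1], sexes[1]))
})

test_that("abnormal burden counts strictly outside the threshold", {
  expect_equal(abnormal_burden(c(0, 1.9, -1.9), 2)$n_abnormal_total, 0)
  b <- abnormal_burden(c(2.5, -3, 1), 2)
  expect_equal(b$n_abnormal_total, 2)
  expect_equal(b$n_above, 1)
  expect_equal(b$n_below, 1)
  expect_equal(abnormal_burden(c(2, -2), 2)$n_abnormal_total, 0)
  expect_error(abnormal_burden(c(1, NaN), 2), "non-finite")
  expect_error(abnormal_burden(c(1, 2), 0), "positive")
})

test_that("normal tail: |Z|>2 fraction near 2*pnorm(-2) on null draws", {
  set.seed(105)
  n <- 20000
  z <- rnorm(n)
  frac <- abnormal_burden(z, 2)$n_abnormal_total / n
  expect_lt(abs(frac - 2 * pnorm(-2)), 3.5 * sqrt(0.0455 * 0.9545 / n))
})

test_that("extrapolation outside the control age range warns, not errors", {
  set.seed(106)
  ages <- runif(30, 8, 16)
  sexes <- rep(c("male", "female"), 15)
  m <- fit_normative_model(cbind(f = rnorm(30)), ages, sexes)
  expect_warning(residuals_normative(m, 0.5, age = 4, sex = "male"),
                 "extrapolating")
})

test_that("injected shifts on a feature are recovered in mean residual", {
  set.seed(107)
  n <- 100
  ages <- runif(n, 5, 18)
  sexes <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  y <- cbind(f = 5 + 0.2 * ages + rnorm(n))
  m <- fit_normative_model(y, ages, sexes)
  delta <- 2.5
  res <- sapply(1:50, function(i) {
    age <- runif(1, 6, 17); sex <- sample(c("male", "female"), 1)
    val <- 5 + 0.2 * age + rnorm(1) + delta
    residuals_normative(m, val, age, sex, warn_extrapolation = FALSE)
  })
  expect_equal(mean(res), delta, tolerance = 0.5)
})
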