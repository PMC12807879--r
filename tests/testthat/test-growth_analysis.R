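test_that("LMS z-scores follow the Box-Cox form", {
  expect_equal(lms_zscore(16, L = -1.6, M = 16, S = 0.14), 0)
  expect_equal(lms_zscore(11, L = 1, M = 10, S = 0.1), 1)
  expect_equal(lms_zscore(20, L = -1.6, M = 16, S = 0.14), 1.34,
               tolerance = 0.005)
  # L = 0 branch is the log form
  expect_equal(lms_zscore(exp(0.2), L = 0, M = 1, S = 0.1), 2)
  expect_error(lms_zscore(-1, 1, 10, 0.1), "positive")
  expect_error(lms_zscore(10, 1, 10, 0), "positive")
})

test_that("LMS z-score inverts exactly", {
  set.seed(601)
  for (i in 1:200) {
    L <- stats::runif(1, -2, 2)
    M <- stats::runif(1, 5, 120)
    S <- stats::runif(1, 0.03, 0.2)
    z <- stats::runif(1, -3.5, 3.5)
    x <- lms_invert(z, L, M, S)
    if (x <= 0) next  # extreme Box-Cox corner, measurement not realizable
    expect_equal(lms_zscore(x, L, M, S), z, tolerance = 1e-9)
  }
})

test_that("restricted-tail adjustment linearizes beyond |z| = 3", {
  L <- -0.2; M <- 14; S <- 0.12
  x_hi <- lms_invert(4, L, M, S)
  sd3 <- lms_invert(3, L, M, S); sd2 <- lms_invert(2, L, M, S)
  expect_equal(lms_zscore(x_hi, L, M, S, adjust_tails = TRUE),
               3 + (x_hi - sd3) / (sd3 - sd2))
  x_lo <- lms_invert(-4, L, M, S)
  sd3n <- lms_invert(-3, L, M, S); sd2n <- lms_invert(-2, L, M, S)
  expect_equal(lms_zscore(x_lo, L, M, S, adjust_tails = TRUE),
               -3 + (x_lo - sd3n) / (sd3n - sd2n))
  # inside the band the adjustment is a no-op
  x_mid <- lms_invert(1.7, L, M, S)
  expect_equal(lms_zscore(x_mid, L, M, S, adjust_tails = TRUE),
               lms_zscore(x_mid, L, M, S))
})

test_that("child z-scores interpolate the reference by age and sex", {
  lms <- synthetic_lms_table()
  m24 <- lms[lms$sex == "male" & lms$measure == "weight" &
             lms$age_months == 24, ]
  child <- data.frame(child_id = "C1", sex = "male", age = 2,
                      weight = m24$M, height = 90, hair_hg = 0.5,
                      stringsAsFactors = FALSE)
  scored <- zscore_for_child(child, lms)
  expect_equal(scored$waz, 0, tolerance = 1e-12)

  # interpolation fixed point: identical neighbouring rows give the same z
  flat <- data.frame(sex = "male",
                     age_months = rep(c(24, 25), times = 2),
                     measure = rep(c("weight", "height"), each = 2),
                     L = 1, M = rep(c(12, 88), each = 2), S = 0.1)
  child$age <- 24.5 / 12
  child$weight <- 13
  scored <- zscore_for_child(child, flat)
  expect_equal(scored$waz, lms_zscore(13, 1, 12, 0.1))

  # round trip through a known latent z
  z_true <- 1.5
  w <- interpolate_lms(lms, "female", "weight", 30)
  child2 <- data.frame(child_id = "C2", sex = "female", age = 30 / 12,
                       weight = lms_invert(z_true, w$L, w$M, w$S),
                       height = 92, hair_hg = 0.5, stringsAsFactors = FALSE)
  expect_equal(zscore_for_child(child2, lms)$waz, z_true, tolerance = 1e-9)

  expect_error(zscore_for_child(transform(child2, age = 9), lms),
               "outside")
})

test_that("hair-mercury exposure dichotomizes at the cutoff and partitions", {
  expect_equal(as.character(classify_hg_exposure(1.11)), "high")
  expect_equal(as.character(classify_hg_exposure(1.00)), "low")
  expect_equal(as.character(classify_hg_exposure(0)), "low")
  expect_error(classify_hg_exposure(-0.1), "nonnegative")
  set.seed(602)
  hair <- stats::rlnorm(500, -0.26, 0.854)
  cls <- classify_hg_exposure(hair)
  expect_equal(sum(cls == "high") + sum(cls == "low"), 500)
  expect_equal(levels(cls), c("low", "high"))
})

test_that("univariate screening keeps p < 0.2 candidates in order", {
  set.seed(603)
  n <- 300
  d <- data.frame(y = stats::rnorm(n))
  d$strong <- d$y + stats::rnorm(n, 0, 0.1)
  d$noise <- stats::rnorm(n)
  d$flat <- 1
  d$cat3 <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  d$y2 <- d$y + ifelse(d$cat3 == "b", 2, 0)

  expect_warning(sel <- screen_covariates(d, "y", c("strong", "flat")),
                 "constant")
  expect_equal(as.character(sel), "strong")

  sel <- screen_covariates(d, "y2", c("cat3", "strong"))
  expect_equal(as.character(sel), c("cat3", "strong"))  # order preserved
  expect_true(all(attr(sel, "p_values")[c("cat3", "strong")] < 0.2))

  expect_length(screen_covariates(d, "y", character(0)), 0)
})

test_that("pure-noise candidates pass the screen at about the 0.2 rate", {
  set.seed(604)
  hits <- vapply(1:1000, function(i) {
    d <- data.frame(y = stats::rnorm(1000), x = stats::rnorm(1000))
    length(screen_covariates(d, "y", "x")) == 1
  }, logical(1))
  expect_equal(mean(hits), 0.2, tolerance = 0.15)  # 0.2 +/- 0.03 absolute
  expect_true(abs(mean(hits) - 0.2) <= 0.03)
})

test_that("growth model returns OLS estimates with Wald intervals", {
  d3 <- data.frame(x = c(0, 1, 2), y = c(0, 1, 2) * 1.0)
  d3$y <- d3$y + c(1e-9, -2e-9, 1e-9)  # break exact singularity of the fit
  fit <- suppressWarnings(fit_growth_model(d3, "y", "x"))  # perfect fit
  expect_equal(fit$beta[fit$is_exposure], 1, tolerance = 1e-6)

  set.seed(605)
  d <- data.frame(x = stats::runif(40))
  d$y <- 2 * d$x
  fit <- suppressWarnings(fit_growth_model(d, "y", "x"))  # perfect fit
  row <- fit[fit$is_exposure, ]
  expect_equal(row$beta, 2, tolerance = 1e-8)
  expect_equal(row$ci_high - row$ci_low, 0, tolerance = 1e-8)
  expect_true(row$ci_low <= row$beta && row$beta <= row$ci_high)
  expect_equal(row$n, 40)

  d$x2 <- 2 * d$x
  expect_error(fit_growth_model(d, "y", "x", "x2"), "collinear")

  d$y[1] <- NA
  expect_message(fit <- suppressWarnings(fit_growth_model(d, "y", "x")),
                 "listwise")
  expect_equal(fit$n[1], 39)
})

test_that("model fitting agrees with a normal-equations oracle", {
  set.seed(606)
  for (i in 1:20) {
    n <- 60
    k <- sample(1:7, 1)
    X <- matrix(stats::rnorm(n * k), n, k)
    d <- as.data.frame(X)
    names(d) <- paste0("v", seq_len(k))
    d$y <- stats::rnorm(n)
    fit <- fit_growth_model(d, "y", "v1",
                            if (k > 1) paste0("v", 2:k) else character(0))
    Xd <- cbind(1, X)
    beta_hat <- solve(t(Xd) %*% Xd, t(Xd) %*% d$y)
    expect_equal(fit$beta, as.numeric(beta_hat), tolerance = 1e-8)
  }
})

test_that("confidence intervals cover a known slope at the nominal rate", {
  set.seed(607)
  true_beta <- 0.8
  covered <- vapply(1:1000, function(i) {
    x <- stats::rnorm(60)
    d <- data.frame(x = x, y = 1 + true_beta * x + stats::rnorm(60))
    r <- fit_growth_model(d, "y", "x")
    row <- r[r$is_exposure, ]
    row$ci_low <= true_beta && true_beta <= row$ci_high
  }, logical(1))
  expect_true(abs(mean(covered) - 0.95) <= 0.02)
})
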