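library(dplyr)

test_that("Spearman correlations hit the rank extremes and handle ties", {
  d <- tibble(beta_logpower = 1:20, rt_ms = (1:20)^2,
              duration_ms = -(1:20))
  ck <- correlate_beta_kinematics(d)
  expect_equal(ck$rho[ck$metric == "rt_ms"], 1)
  expect_equal(ck$rho[ck$metric == "duration_ms"], -1)
  withr::with_seed(61, {
    dt <- tibble(beta_logpower = sample(rep(1:5, 6)),
                 rt_ms = sample(rep(1:3, 10)),
                 duration_ms = rnorm(30))
    ck2 <- correlate_beta_kinematics(dt)
    # brute-force oracle: average ranks then Pearson
    want <- cor(rank(dt$beta_logpower), rank(dt$rt_ms))
    expect_equal(ck2$rho[ck2$metric == "rt_ms"], want, tolerance = 1e-12)
  })
  flat <- tibble(beta_logpower = rep(1, 10), rt_ms = 1:10,
                 duration_ms = rnorm(10))
  expect_equal(unique(correlate_beta_kinematics(flat)$flag), "constant input")
  expect_error(correlate_beta_kinematics(d[1:4, ]), "at least 5")
})

test_that("beta-error regression reports the slope F test", {
  d <- tibble(beta_logpower = 1:10,
              endpoint_error_deg = -(2 * (1:10) + 3))
  r <- regress_beta_error(d)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_lt(r$p, 1e-20)
  expect_equal(unname(c(r$df1, r$df2)), c(1, 8))
  # constructed orthogonality: slope exactly zero
  d0 <- tibble(beta_logpower = c(-2, -1, 0, 1, 2),
               endpoint_error_deg = c(1, -1, 0, -1, 1))
  expect_equal(regress_beta_error(d0)$F, 0, tolerance = 1e-12)
  withr::with_seed(62, {
    dr <- tibble(beta_logpower = rnorm(40), endpoint_error_deg = rnorm(40))
    rr <- regress_beta_error(dr)
    r2 <- rr$r_squared
    expect_equal(rr$F, r2 / (1 - r2) * (40 - 2), tolerance = 1e-10)
  })
  flat <- tibble(beta_logpower = rep(1, 10), endpoint_error_deg = rnorm(10))
  expect_equal(regress_beta_error(flat)$flag, "zero-variance predictor")
})

test_that("epoch contrasts recover planted offsets exactly on noise-free data", {
  n <- 12
  d <- tibble(
    epoch = rep(c("Baseline", "EA", "LA"), each = n),
    rt_ms = rep(seq(-1, 1, length.out = n), 3),     # orthogonal to epoch
    duration_ms = rep(seq(-1, 1, length.out = n)^2, 3),
    beta_logpower = rep(c(0, -0.5, 0.25), each = n) +
      0.3 * rep(seq(-1, 1, length.out = n), 3)
  )
  ct <- epoch_contrast(d)
  td <- tidy(ct)
  expect_equal(td$estimate[td$epoch_a == "Baseline" & td$epoch_b == "EA"],
               0.5, tolerance = 1e-10)
  expect_equal(td$estimate[td$epoch_a == "Baseline" & td$epoch_b == "LA"],
               -0.25, tolerance = 1e-10)
  expect_equal(ct$covariates$coefficient[1], 0.3, tolerance = 1e-10)
  # identical epochs with orthogonal covariates: omnibus F = 0
  d0 <- mutate(d, beta_logpower = 0.3 * rt_ms)
  expect_equal(glance(epoch_contrast(d0))$F, 0, tolerance = 1e-20)
})

test_that("contrast coefficients match the normal-equations oracle", {
  withr::with_seed(63, {
    d <- tibble(
      epoch = sample(c("Baseline", "EA", "LA", "EAft"), 80, TRUE),
      rt_ms = rnorm(80, 300, 40), duration_ms = rnorm(80, 320, 30),
      beta_logpower = rnorm(80)
    )
    ct <- epoch_contrast(d)
    X <- model.matrix(~ factor(epoch) + rt_ms + duration_ms, d)
    beta_hat <- solve(t(X) %*% X, t(X) %*% d$beta_logpower)
    expect_equal(unname(coef(ct$fit)), unname(drop(beta_hat)),
                 tolerance = 1e-8)
  })
})

test_that("contrast machinery agrees with emmeans and car", {
  skip_if_not_installed("emmeans")
  skip_if_not_installed("car")
  withr::with_seed(64, {
    d <- tibble(
      epoch = sample(c("Baseline", "EA", "LA"), 60, TRUE),
      rt_ms = rnorm(60, 300, 40), duration_ms = rnorm(60, 320, 30),
      beta_logpower = rnorm(60)
    )
    ct <- epoch_contrast(d)
    fit <- lm(beta_logpower ~ epoch + rt_ms + duration_ms, data = d)
    em <- emmeans::emmeans(fit, ~ epoch)
    expect_equal(ct$adjusted$adj_mean, summary(em)$emmean, tolerance = 1e-10)
    pr <- summary(emmeans::contrast(em, "pairwise", adjust = "bonferroni"))
    expect_equal(ct$pairwise$estimate, pr$estimate, tolerance = 1e-10)
    expect_equal(ct$pairwise$p_bonferroni, pr$p.value, tolerance = 1e-10)
    a2 <- car::Anova(fit, type = 2)
    expect_equal(glance(ct)$F, a2$`F value`[1], tolerance = 1e-10)
  })
})

test_that("subject enters as a fixed factor and rank deficiency is named", {
  withr::with_seed(65, {
    d <- tibble(
      epoch = rep(c("Baseline", "EA"), each = 30),
      subject = rep(rep(c("s1", "s2", "s3"), each = 10), 2),
      rt_ms = rnorm(60, 300, 30), duration_ms = rnorm(60, 320, 30),
      beta_logpower = rnorm(60)
    )
    ct <- epoch_contrast(d, subject = "subject")
    fit <- lm(beta_logpower ~ epoch + rt_ms + duration_ms + subject, d)
    em <- emmeans::emmeans(fit, ~ epoch)
    expect_equal(ct$pairwise$estimate,
                 summary(emmeans::contrast(em, "pairwise", adjust = "none"))$estimate,
                 tolerance = 1e-10)
    dup <- mutate(d, duration_ms = rt_ms)
    expect_error(epoch_contrast(dup), "aliased")
  })
})

test_that("balanced bootstrap balances, flags and reproduces", {
  d <- tibble(beta_logpower = rep(2.5, 40),
              epoch = rep(c("A", "B"), c(30, 10)))
  b <- bootstrap_balanced(d, seed = 5)
  expect_equal(b$m, 10)
  expect_equal(tidy(b)$estimate, 0)
  expect_equal(c(tidy(b)$ci_lo, tidy(b)$ci_hi), c(0, 0))
  withr::with_seed(66, {
    dr <- tibble(beta_logpower = c(rnorm(40, 1), rnorm(15, 2), rnorm(25, 0.5)),
                 epoch = rep(c("Baseline", "EA", "LA"), c(40, 15, 25)))
  })
  br <- bootstrap_balanced(dr, seed = 6)
  # Monte-Carlo consistency: bootstrap mean near the sample mean
  expect_true(all(abs(br$conditions$boot_mean - br$conditions$observed_mean)
                  < 3 * br$conditions$boot_se))
  expect_identical(bootstrap_balanced(dr, seed = 6), br)
  expect_false(identical(bootstrap_balanced(dr, seed = 7)$pairwise,
                         br$pairwise))
  d1 <- tibble(beta_logpower = c(rnorm(10), 1), epoch = rep(c("A", "B"), c(10, 1)))
  expect_match(bootstrap_balanced(d1, seed = 8)$flag, "degenerate")
})
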