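test_that("response probability factorises when the components are independent", {
  rule <- rule_at_least(0)
  # symmetric threshold, even-odds binary criterion: 0.5 * 0.5
  expect_equal(response_probability(joint_params(), 0, rule), 0.25,
               tolerance = 1e-8)
  # general gamma2 = 0 closed form: Phi-term times Lambda-term
  set.seed(8)
  for (i in 1:10) {
    p <- joint_params(alpha = rnorm(1), theta = rnorm(1),
                      sigma = runif(1, 0.5, 2), gamma0 = rnorm(1),
                      gamma1 = rnorm(1), gamma2 = 0)
    z <- rbinom(1, 1, 0.5)
    tau <- rnorm(1)
    mu <- p$alpha + p$theta * z
    closed <- pnorm((mu - tau) / p$sigma) * plogis(p$gamma0 + p$gamma1 * z)
    expect_equal(response_probability(p, z, rule_at_least(tau)), closed,
                 tolerance = 1e-8)
  }
})

test_that("response probability has the right limits and monotonicity in tau", {
  p <- joint_params(alpha = 0, theta = 0.5, sigma = 1, gamma0 = 1,
                    gamma1 = 0, gamma2 = 0.8)
  expect_lt(response_probability(p, 0, rule_at_least(40)), 1e-10)
  sure <- joint_params(gamma0 = 30)
  expect_equal(response_probability(sure, 0, rule_at_least(-40)), 1,
               tolerance = 1e-8)
  taus <- seq(-3, 3, by = 0.5)
  probs <- vapply(taus, function(t)
    response_probability(p, 1, rule_at_least(t)), numeric(1))
  expect_true(all(diff(probs) <= 1e-10))
  probs2 <- vapply(taus, function(t)
    response_probability(p, 1, rule_at_most(t)), numeric(1))
  expect_true(all(diff(probs2) >= -1e-10))
})

test_that("quadrature agrees with a Monte-Carlo simulation of the model", {
  p <- joint_params(alpha = 0, theta = 0.5, sigma = 1, gamma0 = 1,
                    gamma1 = 0, gamma2 = 0.8)
  set.seed(99)
  n <- 1e6
  y <- rnorm(n, p$alpha + p$theta, p$sigma)     # z = 1
  b <- runif(n) < plogis(p$gamma0 + p$gamma2 * y)
  mc <- mean(y >= 0 & b)
  mc_se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(response_probability(p, 1, rule_at_least(0)) - mc),
            3 * mc_se)
})

test_that("a treatment arm that copies the control gives a null contrast", {
  set.seed(12)
  y <- rnorm(80); b <- rbinom(80, 1, plogis(1 + 0.5 * y))
  dat <- trial_data(arm = rep(c(0, 1), each = 80), y = c(y, y), b = c(b, b))
  aug <- augbin_analysis(dat, rule_at_least(0))
  expect_equal(aug$diff, 0, tolerance = 1e-8)
  expect_equal(aug$log_or, 0, tolerance = 1e-7)
  bin <- binary_analysis(dat, rule_at_least(0))
  expect_identical(bin$diff, 0)
  expect_identical(bin$log_or, 0)
})

test_that("delta-method SEs agree with a nonparametric bootstrap", {
  sc <- scenario_config(n_per_arm = 200, seed = 31)
  dat <- simulate_trial(sc)
  aug <- augbin_analysis(dat, sc$rule)
  set.seed(31)
  boot <- replicate(500, {
    idx0 <- sample(which(dat$arm == 0), replace = TRUE)
    idx1 <- sample(which(dat$arm == 1), replace = TRUE)
    res <- tryCatch(augbin_analysis(dat[c(idx0, idx1), ], sc$rule),
                    error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$diff
  })
  boot_se <- sd(boot, na.rm = TRUE)
  expect_lt(abs(aug$se_diff - boot_se) / boot_se, 0.15)
})

test_that("binary analysis reproduces the 2x2 odds-ratio arithmetic", {
  dat <- trial_data(arm = rep(c(0, 1), each = 100),
                    y = c(rep(1, 30), rep(-1, 70), rep(1, 50), rep(-1, 50)),
                    b = rep(1, 200))
  res <- binary_analysis(dat, rule_at_least(0))
  expect_equal(res$log_or, log(7 / 3), tolerance = 1e-12)
  expect_equal(res$diff, 0.2, tolerance = 1e-12)
  expect_equal(res$se_log_or,
               sqrt(1 / 30 + 1 / 70 + 1 / 50 + 1 / 50), tolerance = 1e-12)
  # equal counts in both arms: exact null
  dat2 <- trial_data(arm = rep(c(0, 1), each = 10),
                     y = rep(c(1, -1), 10), b = rep(1, 20))
  res2 <- binary_analysis(dat2, rule_at_least(0))
  expect_identical(res2$diff, 0)
  expect_identical(res2$log_or, 0)
})

test_that("zero cells follow the continuity-correction setting", {
  dat <- trial_data(arm = rep(c(0, 1), each = 50),
                    y = c(rep(-1, 50), rep(c(1, -1), 25)), b = rep(1, 100))
  expect_error(binary_analysis(dat, rule_at_least(0),
                               zero_cell_correction = FALSE),
               "degenerate")
  res <- binary_analysis(dat, rule_at_least(0))
  expect_true(res$corrected)
  expect_true(is.finite(res$log_or) && is.finite(res$se_log_or))
})

test_that("undetermined subjects are dropped by the binary analysis only", {
  dat <- sim_data(n = 150, seed = 13, miss_y = 0.2, miss_b = 0.2)
  bin <- binary_analysis(dat, rule_at_least(0))
  expect_gt(bin$n_undetermined, 0)
  expect_lt(bin$n0 + bin$n1, nrow(dat))
  aug <- augbin_analysis(dat, rule_at_least(0))
  n_all_missing <- sum(is.na(dat$y) & is.na(dat$b))
  expect_equal(aug$fit$n_used, nrow(dat) - n_all_missing)
})

test_that("response weights interpolate the responder indicator", {
  sc <- scenario_config(n_per_arm = 150, seed = 17)
  dat <- simulate_trial(sc)
  fit <- fit_joint_model(dat)
  w <- response_weights(fit, dat, sc$rule)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(w[!is.na(dat$b) & dat$b == 0] == 0))
  # far above threshold with criterion met: weight ~ 1
  far <- trial_data(arm = 0, y = fit$params$sigma * 7, b = 1)
  expect_gt(response_weights(fit, far, sc$rule), 0.999)
  # exactly at the threshold: weight one half
  at <- trial_data(arm = 0, y = 0, b = 1)
  expect_equal(response_weights(fit, at, sc$rule), 0.5, tolerance = 1e-12)
  # monotone in y among subjects meeting the binary criterion
  i <- which(!is.na(dat$b) & dat$b == 1 & !is.na(dat$y))
  o <- i[order(dat$y[i])]
  expect_true(all(diff(w[o]) >= -1e-12))
  # model-based variant drops the hard gate
  wm <- response_weights(fit, trial_data(arm = 0, y = 2, b = 0), sc$rule,
                         variant = "model_based")
  expect_gt(wm, 0)
  # missing components get model-based predictive weights
  miss <- trial_data(arm = c(0, 0, 1), y = c(NA, NA, NA), b = c(1, 0, NA))
  wmiss <- response_weights(fit, miss, sc$rule)
  expect_true(all(wmiss >= 0 & wmiss <= 1))
  expect_identical(wmiss[2], 0)
  expect_equal(wmiss[3], response_probability(fit$params, 1, sc$rule),
               tolerance = 1e-6)
})

test_that("both analyses agree on the effect direction when it is large", {
  for (seed in c(41, 42)) {
    sc <- scenario_config(n_per_arm = 500,
                          params = joint_params(alpha = 0, theta = 0.6,
                                                sigma = 1, gamma0 = 2,
                                                gamma1 = 0, gamma2 = 0.5),
                          seed = seed)
    dat <- simulate_trial(sc)
    aug <- augbin_analysis(dat, sc$rule)
    bin <- binary_analysis(dat, sc$rule)
    expect_gt(aug$diff, 0); expect_gt(bin$diff, 0)
    expect_gt(aug$ci_diff[1], 0); expect_gt(bin$ci_diff[1], 0)
  }
})

test_that("the weights figure renders from a fitted model", {
  sc <- scenario_config(n_per_arm = 60, seed = 27)
  dat <- simulate_trial(sc)
  fit <- fit_joint_model(dat)
  path <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(path)
  w <- plot_response_weights(fit, dat, sc$rule)
  grDevices::dev.off()
  expect_length(w, nrow(dat))
  expect_true(file.size(path) > 0)
})

test_that("analysis arguments are validated", {
  dat <- sim_data(n = 50, seed = 2)
  expect_error(augbin_analysis(dat, rule_at_least(0), conf_level = 1.2),
               "conf_level")
  expect_error(binary_analysis(dat, rule_at_least(0), conf_level = 0),
               "conf_level")
  expect_error(response_probability(joint_params(), 2, rule_at_least(0)),
               "must be 0 or 1")
  expect_error(response_probability(joint_params(), 0, "not a rule"),
               "composite_rule")
})
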