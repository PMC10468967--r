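# Wald ratio, IVW, Cochran Q, MR-Egger, and effect-scale conversions.

test_that("Wald ratio is the scaled outcome effect with delta-method SE", {
  r <- wald_ratio(0.5, 0.05, 0.25, 0.10)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.2)
  expect_identical(r$nsnp, 1L)
  expect_identical(r$method, "wald_ratio")
  expect_true(is.na(r$Q) && is.na(r$p_pleio))

  null <- wald_ratio(1.0, 0.1, 0.0, 0.3)
  expect_equal(null$beta, 0)
  expect_equal(null$se, 0.3)
  expect_equal(null$p_mr, 1.0)

  expect_error(wald_ratio(0, 0.1, 0.2, 0.1), "zero")
})

test_that("second-order delta SE matches a Monte-Carlo ratio SD", {
  set.seed(99)
  b_gx <- 0.5; se_gx <- 0.04; b_gy <- 0.2; se_gy <- 0.05
  r2 <- wald_ratio(b_gx, se_gx, b_gy, se_gy, second_order = TRUE)
  draws <- rnorm(1e5, b_gy, se_gy) / rnorm(1e5, b_gx, se_gx)
  expect_equal(r2$se, sd(draws), tolerance = 0.05)
  # and exceeds the first-order SE
  expect_gt(r2$se, wald_ratio(b_gx, se_gx, b_gy, se_gy)$se)
})

test_that("IVW reduces to the mean for identical-precision identical ratios", {
  inst <- make_instruments(rep(1, 3), rep(0.01, 3), rep(0.2, 3), rep(0.1, 3))
  r <- ivw_estimate(inst, mode = "fixed")
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.1 / sqrt(3))
  expect_equal(r$Q, 0)
})

test_that("IVW matches hand-computed weighted-mean arithmetic", {
  # ratios 0.1 (se 0.1) and 0.4 (se 0.2): w = 100, 25
  inst <- make_instruments(c(1, 1), c(0.1, 0.1), c(0.1, 0.4), c(0.1, 0.2))
  r <- ivw_estimate(inst, mode = "fixed")
  expect_equal(r$beta, 0.16)
  expect_equal(r$se, sqrt(1 / 125))
  expect_equal(r$Q, 1.80)
  expect_identical(r$Q_df, 1L)
  expect_equal(r$Q_pval, pchisq(1.8, 1, lower.tail = FALSE))
  # multiplicative-random SE inflates by sqrt(Q/df) when Q > df
  rr <- ivw_estimate(inst, mode = "multiplicative_random")
  expect_equal(rr$se, sqrt(1 / 125) * sqrt(1.8))
  expect_error(ivw_estimate(inst[1, ]), "wald_ratio")
})

test_that("IVW and Q agree with an independent weighted-arithmetic oracle", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    inst <- make_instruments(runif(k, 0.1, 0.5) * sample(c(-1, 1), k, TRUE),
                             runif(k, 0.01, 0.05),
                             rnorm(k, 0.1, 0.1), runif(k, 0.02, 0.2))
    r <- ivw_estimate(inst, mode = "fixed")
    ratio <- inst$beta_gy / inst$beta_gx
    w <- (inst$beta_gx / inst$se_gy)^2
    expect_equal(r$beta, sum(w * ratio) / sum(w), tolerance = 1e-10)
    expect_equal(r$se, 1 / sqrt(sum(w)), tolerance = 1e-10)
    expect_equal(r$Q, sum(w * (ratio - r$beta)^2), tolerance = 1e-10)
    # invariant to instrument order
    perm <- sample(k)
    rp <- ivw_estimate(inst[perm, ], mode = "fixed")
    expect_equal(rp$beta, r$beta, tolerance = 1e-12)
    expect_equal(rp$Q, r$Q, tolerance = 1e-12)
  }
})

test_that("Egger recovers an exact affine relationship", {
  inst <- make_instruments(c(0.1, 0.2, 0.3, 0.4), rep(0.01, 4),
                           0.1 + 0.5 * c(0.1, 0.2, 0.3, 0.4),
                           c(0.05, 0.02, 0.07, 0.03))
  e <- egger_regression(inst)
  expect_equal(e$intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$slope, 0.5, tolerance = 1e-10)
  expect_error(egger_regression(inst[1:2, ]), "3 instruments")
})

test_that("Egger WLS matches an independent normal-equations oracle", {
  set.seed(31)
  for (rep in 1:10) {
    inst <- make_instruments(runif(5, 0.05, 0.5), rep(0.01, 5),
                             rnorm(5, 0.1, 0.1), runif(5, 0.02, 0.2))
    e <- egger_regression(inst)
    X <- cbind(1, inst$beta_gx)
    W <- diag(1 / inst$se_gy^2)
    coef <- solve(t(X) %*% W %*% X, t(X) %*% W %*% inst$beta_gy)
    expect_equal(e$intercept, coef[1], tolerance = 1e-10)
    expect_equal(e$slope, coef[2], tolerance = 1e-10)
    # analytic covariance with over-dispersion floored at 1
    resid <- inst$beta_gy - X %*% coef
    phi <- max(1, sqrt(sum(resid^2 / inst$se_gy^2) / (5 - 2)))
    V <- solve(t(X) %*% W %*% X)
    expect_equal(e$intercept_se, sqrt(V[1, 1]) * phi, tolerance = 1e-10)
  }
})

test_that("Egger orientation makes the slope invariant to pair sign flips", {
  set.seed(41)
  inst <- make_instruments(runif(6, 0.1, 0.4), rep(0.01, 6),
                           rnorm(6, 0.1, 0.05), runif(6, 0.02, 0.1))
  flipped <- inst
  flip <- c(1, -1, 1, -1, -1, 1)
  flipped$beta_gx <- inst$beta_gx * flip
  flipped$beta_gy <- inst$beta_gy * flip
  expect_equal(egger_regression(flipped), egger_regression(inst))
})

test_that("Egger slope equals IVW when the fitted intercept is zero", {
  # points on an exact line through the origin
  bx <- c(0.1, 0.2, 0.3, 0.5)
  inst <- make_instruments(bx, rep(0.01, 4), 0.4 * bx, rep(0.05, 4))
  e <- egger_regression(inst)
  r <- ivw_estimate(inst, mode = "fixed")
  expect_equal(e$intercept, 0, tolerance = 1e-12)
  expect_equal(e$slope, r$beta, tolerance = 1e-10)
})

test_that("effect_to_or_ci reproduces printed table arithmetic", {
  t4 <- effect_to_or_ci(-0.346, 0.135)
  expect_equal(round(t4$or_, 3), 0.708)
  expect_equal(round(t4$ci_low, 3), 0.543, tolerance = 2e-3)
  expect_equal(round(t4$ci_high, 3), 0.922, tolerance = 2e-3)
  t3 <- effect_to_or_ci(0.683, 0.283)
  expect_equal(round(t3$or_, 2), 1.98)
  expect_equal(round(t3$ci_low, 3), 1.137)
  expect_equal(round(t3$ci_high, 3), 3.448)
  # null effect: OR 1 with multiplicatively symmetric CI
  z <- effect_to_or_ci(0, 0.3)
  expect_equal(z$or_, 1)
  expect_equal(z$ci_low * z$ci_high, 1)
  expect_error(effect_to_or_ci(0.1, 0), "positive")
})

test_that("run_univariable_mr dispatches on instrument count", {
  # one strong instrument at e8 -> Wald ratio, diagnostics NA
  sim1 <- simulate_exposure_outcome(sim_config(
    n_exposures = 1, n_causal = 1, theta = 0.5, k_instruments = 1,
    inst_effect_range = c(0.2, 0.25), block_size = 1, n_null_blocks = 2,
    seed = 2))
  r1 <- suppressMessages(run_univariable_mr(sim1$exposures[[1]], sim1$outcome,
                                            sim1$ld, levels = "e8"))
  expect_identical(r1$method, "wald_ratio")
  expect_true(is.na(r1$Q) && is.na(r1$p_pleio))

  # 14 instruments at e5 -> IVW with Q and Egger intercept present
  sim14 <- simulate_exposure_outcome(sim_config(
    n_exposures = 1, n_causal = 1, theta = 0.5, k_instruments = 14,
    block_size = 1, n_null_blocks = 0, seed = 3))
  r14 <- suppressMessages(run_univariable_mr(sim14$exposures[[1]], sim14$outcome,
                                             sim14$ld, levels = "e5"))
  expect_identical(r14$method, "ivw")
  expect_identical(r14$nsnp, 14L)
  expect_false(is.na(r14$Q_pval))
  expect_false(is.na(r14$p_pleio))

  # known truth recovered within 3 SE
  expect_lt(abs(r14$beta - 0.5), 3 * r14$se)
})
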