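test_that("Lin's concordance matches hand-computed and limiting cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(lins_ccc(x, x)$est, 1)
  expect_equal(lins_ccc(x, x)$ci[2], 1)

  # shift by 10: rho_c = 2 s2 / (2 s2 + 100) with s2 = 2 (n-denominator)
  r <- lins_ccc(x, x + 10)
  expect_equal(r$est, 4 / 104)
  expect_equal(r$est, 0.0385, tolerance = 1e-3)

  xc <- x - mean(x)
  expect_equal(lins_ccc(xc, -xc)$est, -1)

  expect_error(lins_ccc(rep(1, 5), rep(2, 5)), "constant")
})

test_that("concordance agrees with the mean-squared-difference identity oracle", {
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    x <- rnorm(n, 100, 20)
    y <- 0.8 * x + rnorm(n, 5, 10)
    expect_equal(lins_ccc(x, y)$est, ccc_by_identity(x, y), tolerance = 1e-12)
  }
})

test_that("concordance is bounded by Pearson and invariant under joint affine maps", {
  set.seed(15)
  for (i in 1:20) {
    x <- rnorm(30, 100, 25)
    y <- x * runif(1, 0.5, 1.5) + rnorm(30, 0, 15)
    r <- lins_ccc(x, y)
    expect_lte(abs(r$est), abs(r$pearson) + 1e-12)
    expect_lte(r$c_b, 1 + 1e-12)
    expect_true(r$ci[1] <= r$est && r$est <= r$ci[2])
    expect_true(abs(r$ci[1]) <= 1 && abs(r$ci[2]) <= 1)

    s <- runif(1, 0.1, 4); c0 <- rnorm(1, 0, 50)
    expect_equal(lins_ccc(s * x + c0, s * y + c0)$est, r$est, tolerance = 1e-10)
    # but NOT invariant under rescaling only one method
    expect_false(isTRUE(all.equal(lins_ccc(2 * x, y)$est, r$est)))
  }
})

test_that("concordance CI covers the population value at roughly the nominal rate", {
  set.seed(16)
  rho <- 0.8
  n <- 50
  # bivariate normal, equal moments: population rho_c = rho
  hits <- replicate(400, {
    z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    ci <- lins_ccc(100 + 20 * z1, 100 + 20 * z2)$ci
    ci[1] <= rho && rho <= ci[2]
  })
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 0.99)
})

test_that("Bland-Altman reproduces printed-summary arithmetic and antisymmetry", {
  x <- c(10, 12, 9, 14)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(unname(ba0$loa), c(0, 0))

  # limits recomputed from printed mean/SD land on the printed limits
  loa <- loa_from_summary(4.19, 6.04)
  expect_equal(loa[["upper"]], 16.0284)
  expect_equal(loa[["lower"]], -7.6484)

  set.seed(2)
  y <- x + rnorm(4)
  f <- bland_altman(x, y); b <- bland_altman(y, x)
  expect_equal(b$mean_diff, -f$mean_diff)
  expect_equal(unname(b$loa), -rev(unname(f$loa)))
  expect_equal(b$points$mean, f$points$mean)
})

test_that("paired MSE satisfies its decomposition identity", {
  expect_equal(mse_paired(1:5, 1:5), 0)
  expect_equal(mse_paired(c(3, 0), c(0, 3)), 9)
  set.seed(8)
  x <- rnorm(20, 100, 30); y <- x + rnorm(20, 4, 6)
  d <- x - y; n <- 20
  expect_equal(mse_paired(x, y), mean(d)^2 + var(d) * (n - 1) / n)
  expect_equal(mse_from_summary(mean(d), sd(d), n), mse_paired(x, y))
  expect_equal(mse_from_summary(mean(d), sd(d), n, "n-1"),
               mean(d)^2 + var(d))
})

test_that("paired t handles symmetric and degenerate differences as specified", {
  r <- paired_t(c(1, -1), c(0, 0))
  expect_equal(r$t, 0)
  expect_false(r$degenerate)

  z <- paired_t(c(2, 3), c(2, 3))
  expect_true(z$degenerate)
  expect_equal(z$t, 0)

  expect_error(paired_t(c(2, 3), c(1, 2)), "undefined")

  set.seed(4)
  x <- rnorm(15, 100, 10); y <- x + rnorm(15, 3, 4)
  r <- paired_t(x, y)
  d <- x - y
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(15)))
  expect_identical(r$df, 14)
  expect_equal(r$ci, mean(d) + c(-1, 1) * qt(0.975, 14) * sd(d) / sqrt(15))
})

test_that("t statistics are recoverable from printed mean differences and CIs", {
  set.seed(6)
  x <- rnorm(20, 150, 30); y <- x + rnorm(20, -10, 8)
  direct <- paired_t(x, y)
  rec <- t_from_summary(direct$mean_diff, direct$ci[1], direct$ci[2], 20)
  expect_equal(rec$t, direct$t, tolerance = 1e-10)
  expect_equal(rec$p, direct$p, tolerance = 1e-10)
})

test_that("normality check delegates correctly and flags degenerate input", {
  set.seed(10)
  d <- rnorm(20)
  r <- normality_check(d)
  sw <- shapiro.test(d)
  expect_equal(r$W, unname(sw$statistic))
  expect_equal(r$p, sw$p.value)
  expect_error(normality_check(rep(1, 10)), "constant")
  expect_error(normality_check(rnorm(2)), "3 <= n")

  # power against a strongly bimodal mixture at n = 50
  rej <- replicate(200, {
    d <- c(rnorm(25, -2, 0.5), rnorm(25, 2, 0.5))
    normality_check(d)$p < 0.05
  })
  expect_gt(mean(rej), 0.8)
})

test_that("the agreement bundle is coherent and serialises losslessly", {
  set.seed(12)
  truth <- runif(20, 80, 230)
  x <- truth + rnorm(20, 0, 5)
  y <- truth + rnorm(20, -4, 5)
  a <- agreement(x, y, labels = c("pdp", "vrps"))

  expect_s3_class(a, "agreement")
  expect_equal(a$ccc, lins_ccc(x, y)$est)
  expect_equal(a$mse, mse_paired(x, y))
  expect_equal(a$mean_diff, mean(x - y))
  expect_true(a$loa[["lower"]] <= a$mean_diff &&
                a$mean_diff <= a$loa[["upper"]])
  expect_true(a$ccc_ci[1] <= a$ccc && a$ccc <= a$ccc_ci[2])
  expect_equal(residuals(a), x - y)
  expect_equal(unname(coef(a)[["ccc"]]), a$ccc)

  f <- local_tempfile(".json")
  agreement_json(a, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$ccc, a$ccc)
  expect_equal(back$mse, a$mse)
  expect_equal(back$loa$upper, a$loa[["upper"]])
  expect_equal(back$t_stat, a$t_stat)

  # identical vectors: everything collapses, normality flagged not fatal
  id <- agreement(x, x)
  expect_equal(id$ccc, 1)
  expect_equal(id$mse, 0)
  expect_equal(unname(id$loa), c(0, 0))
  expect_true(is.na(id$normality$W))
  expect_false(is.na(id$normality$note))
})

test_that("agreement recovers an injected bias within sampling error", {
  set.seed(13)
  truth <- runif(200, 80, 230)
  bias <- 7; sdn <- 5
  a <- agreement(truth + bias + rnorm(200, 0, sdn), truth,
                 labels = c("biased", "truth"))
  expect_lt(abs(a$mean_diff - bias), 2 * sdn / sqrt(200))
})

test_that("data-frame input selects columns and labels", {
  df <- data.frame(pdp = c(1, 2, 3, 4), vrps = c(1.1, 2.2, 2.9, 4.3))
  a <- agreement(df, x_col = "pdp", y_col = "vrps")
  expect_identical(a$labels, c("pdp", "vrps"))
  expect_equal(a$mean_diff, mean(df$pdp - df$vrps))
})
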