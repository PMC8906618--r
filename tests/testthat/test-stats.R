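test_that("normality screen accepts Gaussian and rejects uniform samples", {
  set.seed(31)
  r <- anderson_darling_normal(stats::rnorm(1000))
  expect_identical(r$status, "ok")
  expect_gt(r$p_value, 0.05)
  expect_true(r$pass)
  # power: 200 uniform draws rejected in > 95% of replicates
  rej <- replicate(60, {
    anderson_darling_normal(stats::runif(200))$p_value < 0.05
  })
  expect_gt(mean(rej), 0.95)
  expect_identical(anderson_darling_normal(stats::rnorm(5))$status,
                   "insufficient")
  deg <- anderson_darling_normal(rep(1.5, 40))
  expect_identical(deg$status, "degenerate")
  expect_false(deg$pass)
})

# brute-force oracle: sweep the ECDF difference over all sample points
ks_d_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

test_that("KS statistic equals the exhaustive ECDF sweep", {
  a <- c(1, 2, 3, 4); b <- c(1.5, 2.5, 3.5, 4.5)
  r <- ks_two_sample(a, b)
  expect_equal(r$statistic, ks_d_oracle(a, b))
  expect_equal(r$statistic, 0.25)
  # identity and full separation
  expect_equal(ks_two_sample(a, a)$statistic, 0)
  expect_equal(ks_two_sample(stats::runif(20), stats::runif(15) + 2)$statistic,
               1)
  set.seed(5)
  for (i in 1:20) {
    a <- stats::rnorm(sample(5:40, 1))
    b <- stats::rnorm(sample(5:40, 1), mean = stats::runif(1, -1, 1))
    r <- ks_two_sample(a, b)
    expect_equal(r$statistic, ks_d_oracle(a, b), tolerance = 1e-12)
    # symmetry and monotone-transform invariance
    expect_equal(ks_two_sample(b, a)$statistic, r$statistic)
    expect_equal(ks_two_sample(exp(a), exp(b))$statistic, r$statistic)
  }
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("RMS curve score matches its elementwise oracle and closed forms", {
  tpl <- 120 + 15 * sin(2 * pi * (0:100) / 100)
  expect_equal(rms_curve_error(tpl, tpl), 0)
  expect_equal(rms_curve_error(tpl, tpl + 5), 5)
  set.seed(9)
  for (i in 1:10) {
    a <- stats::rnorm(101); b <- stats::rnorm(101)
    expect_equal(rms_curve_error(a, b), sqrt(sum((a - b)^2) / 101))
    # triangle inequality (scaled Euclidean norm)
    c_ <- stats::rnorm(101)
    expect_lte(rms_curve_error(a, c_),
               rms_curve_error(a, b) + rms_curve_error(b, c_) + 1e-12)
  }
  expect_error(rms_curve_error(1:100, 1:100), "101")
})

test_that("pass-rate marginals use the correct denominators", {
  res <- data.frame(trial = rep(c("t1", "t2"), each = 4),
                    parameter = rep(c("p1", "p2", "p3", "p4"), 2),
                    pass = c(TRUE, TRUE, TRUE, TRUE,
                             FALSE, TRUE, NA, FALSE))
  m <- summarize_pass_rates(res)
  pp <- m$per_parameter
  expect_equal(pp$pct_pass[pp$parameter == "p1"], 50)
  expect_equal(pp$n_cases[pp$parameter == "p3"], 1L)  # NA excluded
  expect_equal(pp$pct_pass[pp$parameter == "p3"], 100)
  pt <- m$per_trial
  expect_equal(pt$pct_pass[pt$trial == "t1"], 100)
  expect_equal(pt$n_parameters[pt$trial == "t2"], 3L)
  expect_equal(pt$pct_pass[pt$trial == "t2"], 100 / 3)
})

test_that("comparison matrix runs 3 x 53 tests and keeps missing cells", {
  set.seed(17)
  fake_table <- function(mu = 0) {
    tab <- as.data.frame(matrix(stats::rnorm(20 * 53, mean = mu), 20, 53))
    names(tab) <- parameter_registry()
    tab
  }
  tables <- list(reference = fake_table(), harness = fake_table(),
                 harness_leash = fake_table())
  cm <- comparison_matrix(tables)
  expect_identical(nrow(cm$table), 159L)
  expect_identical(length(unique(cm$table$comparison)), 3L)
  expect_false(anyNA(cm$table$p_value))
  # identically distributed synthetic trials: about 5% rejections
  rej <- mean(!cm$table$same_distribution)
  expect_lt(rej, 0.12)
  # a missing parameter yields missing cells, never silent drops
  tables$harness$rom_spine_L7_sag <- NA_real_
  cm2 <- comparison_matrix(tables)
  expect_identical(nrow(cm2$table), 159L)
  miss <- cm2$table[cm2$table$parameter == "rom_spine_L7_sag", ]
  expect_true(all(is.na(miss$p_value[miss$comparison !=
                                       "reference_vs_harness_leash"])))
  # a true shift is detected
  tables2 <- list(reference = fake_table(), harness = fake_table(mu = 3))
  cm3 <- comparison_matrix(tables2)
  expect_gt(mean(!cm3$table$same_distribution), 0.9)
})

test_that("the normality report covers every trial-parameter cell", {
  an <- cached_analysis()
  tabs <- list(reference = an$parameters, harness = an$parameters)
  nr <- normality_screen(tabs)
  expect_identical(nrow(nr$table), 2L * 53L)
  expect_identical(nrow(nr$per_parameter), 53L)
  expect_identical(nrow(nr$per_trial), 2L)
  # 8 cycles: enough for the test to run on every parameter with data
  expect_true(all(nr$table$status %in%
                    c("ok", "insufficient", "degenerate")))
})
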