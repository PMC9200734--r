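test_that("paired_series validates and drops incomplete pairs", {
  expect_error(paired_series(1:3, 1:4), class = "echolvm_validation_error")
  expect_message(p <- paired_series(c(1, 2, NA, 4), c(1, 2, 3, 4)),
                 "dropped 1")
  expect_equal(length(p$values_x), 3)
  expect_error(paired_series(c(1, NA), c(NA, 2)),
               class = "echolvm_validation_error")
})

test_that("Bland-Altman matches direct computation", {
  x <- c(100, 150, 200); y <- c(110, 150, 210) # differences 10, 0, 10
  ba <- bland_altman(paired_series(x, y))
  d <- y - x
  expect_equal(ba$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba$bias, 6.666667, tolerance = 1e-6)
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_high, 17.98273, tolerance = 1e-5)
  # paired-t oracle
  expect_equal(ba$p_value, t.test(d)$p.value, tolerance = 1e-12)

  ident <- bland_altman(paired_series(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$bias, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))

  off <- bland_altman(paired_series(c(1, 2, 3), c(6, 7, 8)))
  expect_equal(off$bias, 5)
  expect_equal(off$sd_diff, 0)
  expect_equal(c(off$loa_low, off$loa_high), c(5, 5))
  expect_equal(off$prop_bias_slope, 0, tolerance = 1e-10)
})

test_that("coefficient of variation conventions", {
  x <- c(100, 150, 200); y <- c(110, 150, 210)
  p <- paired_series(x, y)
  cv <- cv_percent(p)
  expect_equal(cv$cv_percent, 100 * sd(y - x) / mean(c(x, y)),
               tolerance = 1e-12)
  expect_equal(cv$cv_percent, 3.765328, tolerance = 1e-6)
  expect_identical(cv$convention, "sd_diff")
  ws <- cv_percent(p, "within_subject")
  expect_equal(ws$cv_percent, cv$cv_percent / sqrt(2), tolerance = 1e-12)
  expect_equal(cv_percent(paired_series(x, x))$cv_percent, 0)
  # scale invariance
  expect_equal(cv_percent(paired_series(2 * x, 2 * y))$cv_percent,
               cv$cv_percent, tolerance = 1e-12)
  expect_error(cv_percent(paired_series(c(-1, 1), c(1, -1))),
               class = "echolvm_domain_error")
})

test_that("ICC(2,1) matches the ANOVA-decomposition oracle", {
  x <- c(100, 110, 120, 150, 160, 170)
  y <- c(104, 108, 126, 148, 165, 171)
  got <- icc(paired_series(x, y))
  # frozen from the two-way ANOVA decomposition (independent oracle below)
  expect_equal(got$value, 0.9913359, tolerance = 1e-6)

  # independent route: stats::aov mean squares
  df <- data.frame(value = c(x, y),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(value ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + (2 - 1) * mse + 2 * (msc - mse) / 6)
  expect_equal(got$value, oracle, tolerance = 1e-10)

  # identical pairs with between-subject spread
  expect_equal(icc(paired_series(c(1, 5, 9), c(1, 5, 9)))$value, 1)
  # anticorrelated symmetric data
  z <- c(-2, -1, 0, 1, 2)
  expect_lte(icc(paired_series(z, -z))$value, 0)
  # degenerate: zero total variance
  flat <- icc(paired_series(c(3, 3, 3), c(3, 3, 3)))
  expect_false(flat$defined)
  expect_true(is.na(flat$value))
})

test_that("hypertrophy classification reproduces every cutoff boundary", {
  cuts <- default_cutoffs()
  expect_equal(nrow(cuts), 8)
  example_method <- c(cmr_based = "NOVEL", ase_te_al = "TE", ase_dev = "DEV")
  for (i in seq_len(nrow(cuts))) {
    row <- cuts[i, ]
    age <- if (is.finite(row$age_max)) {
      (max(row$age_min, 20) + row$age_max) / 2
    } else {
      max(row$age_min, 20) + 10
    }
    s <- subject("b", age, row$sex, bsa_m2 = 2.0)
    m <- example_method[[row$group]]
    expect_true(classify_hypertrophy((row$threshold_g_m2 + 0.1) * 2, s, m))
    expect_true(classify_hypertrophy(row$threshold_g_m2 * 2, s, m))
    expect_false(classify_hypertrophy((row$threshold_g_m2 - 0.1) * 2, s, m))
  }
  # spot checks at stated values
  expect_true(classify_hypertrophy(200, subject("a", 45, "M", 2), "NOVEL"))
  expect_false(classify_hypertrophy(150, subject("a", 50, "F", 2), "NOVEL"))
  expect_false(classify_hypertrophy(230, subject("a", 45, "M", 2), "DEV"))
})

test_that("classification is monotone in mass and antitone in BSA", {
  s <- subject("a", 45, "M", 2)
  masses <- seq(100, 300, by = 10)
  calls <- vapply(masses, classify_hypertrophy, logical(1), subj = s,
                  method = "NOVEL")
  expect_true(all(diff(as.integer(calls)) >= 0))
  bsas <- seq(1.5, 2.5, by = 0.1)
  calls_b <- vapply(bsas, function(b) {
    classify_hypertrophy(180, subject("a", 45, "M", b), "NOVEL")
  }, logical(1))
  expect_true(all(diff(as.integer(calls_b)) <= 0))
  expect_error(classify_hypertrophy(100, s, "X9"),
               class = "echolvm_config_error")
})

test_that("dilatation cutoffs load and classify indexed EDV", {
  cuts <- default_dilatation_cutoffs()
  expect_equal(nrow(cuts), 4)
  s <- subject("a", 45, "M", 2)
  expect_true(classify_indexed(101, s, "edv_index", cuts))
  expect_false(classify_indexed(100.9, s, "edv_index", cuts))
})

test_that("diagnostic performance is the standard 2x2 arithmetic", {
  perfect <- diagnostic_performance(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  # TP = 2, FP = 1, FN = 1, TN = 6
  pred <- c(rep(TRUE, 3), rep(FALSE, 7))
  truth <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  got <- diagnostic_performance(pred, truth)
  expect_equal(unname(got), c(200 / 3, 600 / 7, 200 / 3, 600 / 7),
               tolerance = 1e-10)
  # all-positive predictor on balanced truth (NPV denominator is empty)
  ap <- suppressWarnings(
    diagnostic_performance(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  )
  expect_equal(unname(ap[c("sensitivity", "specificity")]), c(100, 0))
  expect_warning(out <- diagnostic_performance(c(TRUE, FALSE), c(FALSE, FALSE)),
                 "sensitivity undefined")
  expect_true(is.na(out[["sensitivity"]]))
})
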