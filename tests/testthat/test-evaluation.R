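test_that("MSPE matches hand arithmetic and a loop oracle", {
  expect_equal(mspe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mspe(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  set.seed(1)
  for (i in 1:20) {
    o <- rnorm(50); p <- rnorm(50)
    acc <- 0
    for (j in seq_along(o)) acc <- acc + (o[j] - p[j])^2
    expect_equal(mspe(o, p), acc / 50, tolerance = 1e-12)
  }
  expect_error(mspe(1:3, 1:4), "length")
})

test_that("the MSPE decomposition matches its defining constructions", {
  o <- c(2, 4, 6, 9)
  d <- decompose_mspe(o, o + 1)          # pure mean bias
  expect_equal(unname(d), c(1, 0, 0), tolerance = 1e-12)
  # pure slope bias: p = 2 o, re-centered to equal means (r = 1)
  p <- 2 * o - mean(2 * o) + mean(o)
  d2 <- decompose_mspe(o, p)
  so <- sqrt(mean((o - mean(o))^2)); sp <- sqrt(mean((p - mean(p))^2))
  expect_equal(d2[["ECT"]], 0, tolerance = 1e-12)
  expect_equal(d2[["ED"]], 0, tolerance = 1e-12)
  expect_equal(d2[["ER"]], (sp - so)^2, tolerance = 1e-12)
  expect_error(decompose_mspe(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("ECT + ER + ED = MSPE on 1000 random vectors", {
  set.seed(2)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    o <- rnorm(n, 10, 3); p <- rnorm(n, 10, 3)
    d <- decompose_mspe(o, p)
    expect_equal(sum(d), mspe(o, p), tolerance = 1e-9)
  }
})

test_that("RMSPE% follows its definition and is scale-invariant", {
  expect_equal(rmspe_pct(c(10, 10), c(9, 11)), 10)
  expect_equal(rmspe_pct(c(5, 7), c(5, 7)), 0)
  set.seed(3)
  o <- runif(30, 5, 15); p <- o + rnorm(30)
  expect_equal(rmspe_pct(3 * o, 3 * p), rmspe_pct(o, p), tolerance = 1e-12)
  expect_error(rmspe_pct(c(-5, -7), c(1, 2)), "positive")
})

test_that("concordance analysis matches hand arithmetic", {
  perfect <- ccc_analysis(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(perfect), c(1, 1, 1, 1, 0), tolerance = 1e-12)
  shifted <- ccc_analysis(c(1, 2, 3), c(2, 3, 4))
  expect_equal(shifted[["r"]], 1)
  expect_equal(shifted[["v"]], 1)
  expect_equal(shifted[["mu"]], -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(shifted[["Cb"]], 4 / 7, tolerance = 1e-12)
  expect_equal(shifted[["CCC"]], 4 / 7, tolerance = 1e-12)
})

test_that("component and direct CCC forms agree to 1e-12", {
  set.seed(4)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    o <- rnorm(n, 12, 4); p <- 0.8 * o + rnorm(n, 2, 1)
    cc <- ccc_analysis(o, p)
    so <- sqrt(mean((o - mean(o))^2)); sp <- sqrt(mean((p - mean(p))^2))
    direct <- 2 * cor(o, p) * so * sp /
      (so^2 + sp^2 + (mean(o) - mean(p))^2)
    expect_equal(cc[["CCC"]], direct, tolerance = 1e-12)
    expect_lte(cc[["CCC"]], abs(cc[["r"]]) + 1e-12)
    # overprediction sign convention
    expect_equal(cc[["mu"]] < 0, mean(p) > mean(o))
  }
})

test_that("RMSPE% and CCC are scale-invariant but ECT is not", {
  set.seed(5)
  o <- runif(40, 5, 20); p <- o + rnorm(40, 1, 2)
  cc1 <- ccc_analysis(o, p); cc2 <- ccc_analysis(5 * o, 5 * p)
  expect_equal(cc1[["CCC"]], cc2[["CCC"]], tolerance = 1e-12)
  d1 <- decompose_mspe(o, p); d2 <- decompose_mspe(5 * o, 5 * p)
  expect_equal(d2[["ECT"]], 25 * d1[["ECT"]], tolerance = 1e-9)
})

test_that("equation evaluation drops unusable records per equation", {
  d <- generate_database(synthetic_config("combined", n_studies = 20,
                                          treatments_per_study = 4,
                                          seed = 41))
  d <- as.data.frame(d)
  d$mei_mj_d[1:10] <- NA  # MEI missing for some records
  tab <- evaluate_equations(d, c("eq1c", "eq2c", "ipcc2006"))
  expect_equal(tab$equation, c("eq1c", "eq2c", "ipcc2006"))
  expect_equal(tab$n_used[1], nrow(d))
  expect_equal(tab$n_used[2], nrow(d) - 10)
  # shares sum to 100 and CCC = r * Cb
  expect_equal(tab$ECT_pct + tab$ER_pct + tab$ED_pct, rep(100, 3),
               tolerance = 1e-9)
  expect_equal(tab$CCC, tab$r * tab$Cb, tolerance = 1e-12)
})

test_that("a perfect equation scores RMSPE 0 and CCC 1; the true equation wins", {
  cfg <- synthetic_config("combined", n_studies = 60,
                          treatments_per_study = 4, study_intercept_sd = 0,
                          study_slope_sd = 0, residual_sd = 0, seed = 43)
  d <- generate_database(cfg)
  tab <- evaluate_equations(d, c("eq1c", "ipcc2006", "mills_linear"))
  expect_equal(tab$RMSPE_pct[1], 0, tolerance = 1e-9)
  expect_equal(tab$CCC[1], 1, tolerance = 1e-9)
  expect_true(all(tab$RMSPE_pct[1] < tab$RMSPE_pct[-1]))
})

test_that("constant predictions decompose as the algebra dictates", {
  set.seed(6)
  o <- rnorm(30, 10, 2)
  const_eq <- ch4meta:::new_equation("const", "extant", "external", "linear",
                                     intercept = mean(o),
                                     terms = c(DMI = 0))
  d <- data.frame(DMI = runif(30, 2, 25), dmi_kg_d = runif(30, 2, 25),
                  ch4_mj_d = o)
  tab <- evaluate_equations(d, list(const_eq))
  expect_equal(tab$ECT, 0, tolerance = 1e-9)
  expect_equal(tab$ECT_pct + tab$ER_pct + tab$ED_pct, 100, tolerance = 1e-9)
  const_off <- ch4meta:::new_equation("off", "extant", "external", "linear",
                                      intercept = mean(o) + 2,
                                      terms = c(DMI = 0))
  tab2 <- evaluate_equations(d, list(const_off))
  expect_equal(tab2$ECT, 4, tolerance = 1e-9)
})

test_that("correlation screen matches the explicit r and t-transform", {
  set.seed(7)
  n <- 200
  d <- data.frame(dmi_kg_d = runif(n, 2, 25))
  d$ch4_mj_d <- 1 + d$dmi_kg_d + rnorm(n, 0, 2)
  d$noise <- rnorm(n)
  scr <- correlation_screen(d, c("dmi_kg_d", "noise"))
  r_oracle <- sum((d$dmi_kg_d - mean(d$dmi_kg_d)) *
                    (d$ch4_mj_d - mean(d$ch4_mj_d))) /
    sqrt(sum((d$dmi_kg_d - mean(d$dmi_kg_d))^2) *
           sum((d$ch4_mj_d - mean(d$ch4_mj_d))^2))
  t_stat <- r_oracle * sqrt(n - 2) / sqrt(1 - r_oracle^2)
  p_oracle <- 2 * pt(-abs(t_stat), n - 2)
  expect_equal(scr$r[1], r_oracle, tolerance = 1e-12)
  expect_equal(scr$p_value[1], p_oracle, tolerance = 1e-12)
  expect_equal(scr$R2[1], r_oracle^2, tolerance = 1e-12)
  expect_lt(abs(scr$r[2]), 0.2)
  # identical variable -> r = 1
  d$self <- d$ch4_mj_d
  expect_equal(correlation_screen(d, "self")$r, 1, tolerance = 1e-12)
  # insufficient pairs are skipped with a note
  d$sparse <- NA_real_; d$sparse[1:2] <- 1:2
  expect_equal(correlation_screen(d, "sparse")$note, "insufficient pairs")
})

test_that("residual diagnostics recover mean bias in the intercept", {
  set.seed(8)
  o <- runif(40, 5, 20)
  rd <- residual_diagnostics(o, o)
  expect_equal(rd$slope, 0, tolerance = 1e-12)
  expect_equal(rd$intercept, 0, tolerance = 1e-12)
  rd2 <- residual_diagnostics(o, o + 1)
  expect_equal(rd2$slope, 0, tolerance = 1e-12)
  expect_equal(rd2$intercept, -1, tolerance = 1e-12)
  p <- 0.7 * o + rnorm(40)
  rd3 <- residual_diagnostics(o, p)
  expect_equal(rd3$intercept, mean(o) - mean(p), tolerance = 1e-12)
})
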