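test_that("a gross outlier on an otherwise exact line is the only flag", {
  set.seed(42)
  d <- data.frame(x = seq(1, 30))
  d$y <- 2 + 0.5 * d$x + rnorm(30, 0, 0.01)
  d$y[17] <- d$y[17] + 25
  flagged <- detect_outliers(d, "y", "x")
  expect_equal(unname(as.integer(flagged)), 17L)
})

test_that("under the null the flagged fraction stays small", {
  set.seed(7)
  frac <- replicate(20, {
    d <- data.frame(x = rnorm(100), y = rnorm(100))
    length(detect_outliers(d, "y", "x")) / 100
  })
  expect_lt(mean(frac), 0.10)
})

test_that("outlier screening errors on rank-deficient problems", {
  d <- data.frame(x1 = rnorm(2), x2 = rnorm(2), y = rnorm(2))
  expect_error(detect_outliers(d, "y", c("x1", "x2")), "at least 10")
  d <- data.frame(x1 = rnorm(11), x2 = rnorm(11), x3 = rnorm(11),
                  x4 = rnorm(11), x5 = rnorm(11), x6 = rnorm(11),
                  x7 = rnorm(11), x8 = rnorm(11), x9 = rnorm(11),
                  x10 = rnorm(11), y = rnorm(11))
  expect_error(detect_outliers(d, "y", paste0("x", 1:10)), "fewer records")
})

test_that("Cook's distances match a brute-force leave-one-out oracle", {
  set.seed(11)
  d <- data.frame(x1 = rnorm(25), x2 = rnorm(25))
  d$y <- 1 + d$x1 - 0.5 * d$x2 + rnorm(25, 0, 0.5)
  flagged <- detect_outliers(d, "y", c("x1", "x2"))
  got <- attr(flagged, "cooks_d")
  full <- lm(y ~ x1 + x2, data = d)
  p <- length(coef(full))
  s2 <- sum(resid(full)^2) / (25 - p)
  oracle <- vapply(seq_len(25), function(i) {
    fi <- lm(y ~ x1 + x2, data = d[-i, ])
    yhat_full <- predict(full, d)
    yhat_loo <- predict(fi, d)
    sum((yhat_full - yhat_loo)^2) / (p * s2)
  }, 0)
  expect_equal(unname(got), oracle, tolerance = 1e-9)
})

test_that("VIF equals the auxiliary-regression closed form", {
  set.seed(3)
  n <- 400
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2)
  v <- compute_vif(d, c("x1", "x2"))
  r2 <- cor(x1, x2)^2
  expect_equal(unname(v), rep(1 / (1 - r2), 2), tolerance = 1e-10)
  # orthogonal-by-construction pair
  x3 <- rnorm(n); x4 <- resid(lm(rnorm(n) ~ x3))
  v2 <- compute_vif(data.frame(x3 = x3, x4 = x4), c("x3", "x4"))
  expect_equal(unname(v2), c(1, 1), tolerance = 1e-10)
  # exact collinearity -> infinite, not an error
  v3 <- compute_vif(data.frame(a = x1, b = 2 * x1), c("a", "b"))
  expect_true(all(is.infinite(v3)))
})

test_that("VIF matches car::vif on random design matrices", {
  set.seed(19)
  for (i in 1:5) {
    d <- as.data.frame(matrix(rnorm(60 * 4), 60, 4))
    names(d) <- paste0("x", 1:4)
    d$x2 <- d$x2 + 0.6 * d$x1
    d$y <- rnorm(60)
    ours <- compute_vif(d, paste0("x", 1:4))
    theirs <- car::vif(lm(y ~ x1 + x2 + x3 + x4, data = d))
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
  }
})

test_that("noiseless data reproduce the generating line exactly", {
  set.seed(5)
  d <- linear_records(b0 = 1, b1 = 0.8)
  fit <- fit_mixed_linear(d, "ch4_mj_d", "dmi_kg_d")
  expect_equal(unname(fit$coefficients), c(1, 0.8), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("mixed fit reduces to weighted OLS when estimated random variance is zero", {
  # with no true study effects the REML variance estimates land on the zero
  # boundary in a fraction of replicates; exactly there the mixed fit must
  # coincide with the weighted regression
  set.seed(6)
  boundary_seen <- FALSE
  for (i in 1:10) {
    d <- linear_records(resid_sd = 0.3)
    fit <- fit_mixed_linear(d, "ch4_mj_d", "dmi_kg_d")
    ols <- lm(ch4_mj_d ~ dmi_kg_d, data = d, weights = n_animals)
    study_var <- fit$varcomp[grep("^study", names(fit$varcomp))]
    if (fit$structure == "FE" || all(abs(study_var) < 1e-8)) {
      boundary_seen <- TRUE
      expect_equal(unname(fit$coefficients), unname(coef(ols)),
                   tolerance = 1e-6)
    } else {
      # away from the boundary the two estimators still agree closely
      expect_equal(unname(fit$coefficients), unname(coef(ols)),
                   tolerance = 0.05)
    }
  }
  expect_true(boundary_seen)
})

test_that("coefficients are invariant to rescaling all weights", {
  set.seed(8)
  d <- linear_records(intercept_sd = 1, slope_sd = 0.1, resid_sd = 1.5)
  f1 <- fit_mixed_linear(d, "ch4_mj_d", "dmi_kg_d")
  d2 <- d; d2$n_animals <- d2$n_animals * 2L
  f2 <- fit_mixed_linear(d2, "ch4_mj_d", "dmi_kg_d")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("UN and VC covariance structures are both reachable", {
  set.seed(9)
  d <- linear_records(intercept_sd = 1.5, slope_sd = 0.15, resid_sd = 1)
  f_un <- fit_mixed_linear(d, "ch4_mj_d", "dmi_kg_d", covariance = "UN")
  f_vc <- fit_mixed_linear(d, "ch4_mj_d", "dmi_kg_d", covariance = "VC")
  expect_equal(f_un$structure, "UN")
  expect_equal(f_vc$structure, "VC")
  expect_true("study_cov" %in% names(f_un$varcomp))
  expect_false("study_cov" %in% names(f_vc$varcomp))
  auto <- fit_mixed_linear(d, "ch4_mj_d", "dmi_kg_d", covariance = "auto")
  expect_true(auto$structure %in% c("UN", "VC"))
})

test_that("collinear candidate sets are rejected before fitting", {
  set.seed(10)
  d <- linear_records(resid_sd = 0.5)
  d$dmi2 <- 2 * d$dmi_kg_d
  expect_error(backward_eliminate(d, "ch4_mj_d", c("dmi_kg_d", "dmi2")),
               "VIF")
})

test_that("a single strong candidate survives with a one-step trace", {
  set.seed(12)
  d <- linear_records(resid_sd = 0.5)
  be <- backward_eliminate(d, "ch4_mj_d", "dmi_kg_d")
  expect_equal(be$formula, "dmi_kg_d")
  expect_equal(nrow(be$trace), 1L)
  expect_false(be$trace$removed[1])
})

test_that("the elimination trace is deterministic given the data", {
  set.seed(14)
  d <- linear_records(intercept_sd = 0.5, resid_sd = 1)
  b1 <- backward_eliminate(d, "ch4_mj_d",
                           c("dmi_kg_d", "bw_kg", "roughage_g_kg"))
  b2 <- backward_eliminate(d, "ch4_mj_d",
                           c("dmi_kg_d", "bw_kg", "roughage_g_kg"))
  expect_identical(b1$trace, b2$trace)
  expect_identical(b1$formula, b2$formula)
})

test_that("noiseless nonlinear data recover their generating parameters", {
  set.seed(15)
  x <- runif(120, 2, 26)
  recs <- data.frame(study_id = rep(sprintf("S%02d", 1:12), each = 10),
                     dmi_kg_d = x, n_animals = 8L)
  recs$ch4_mj_d <- 2 * exp(0.1 * x)
  fe <- fit_nonlinear_mixed(recs, "exponential")
  expect_equal(unname(fe$coefficients[c("b", "c")]), c(2, 0.1),
               tolerance = 1e-4)
  recs$ch4_mj_d <- 0.9 * x^1.1
  fp <- fit_nonlinear_mixed(recs, "power")
  expect_equal(unname(fp$coefficients[c("b", "c")]), c(0.9, 1.1),
               tolerance = 1e-4)
  recs$ch4_mj_d <- 36 - (36 + 1) * exp(-0.1 * x)
  fm <- fit_nonlinear_mixed(recs, "monomolecular")
  expect_equal(unname(fm$coefficients[c("a", "b", "c")]), c(36, 1, 0.1),
               tolerance = 1e-3)
})

test_that("gompertz fits recover the asymptote from noisy clustered data", {
  a_true <- 36.23; b_true <- 0.956; c_true <- 0.1058
  ests <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- runif(120, 2, 26)
    y <- b_true * exp((1 - exp(-c_true * x)) *
                        log((a_true + 2 * b_true) / b_true)) - 2 * b_true +
      rnorm(120, 0, 0.5)
    recs <- data.frame(study_id = rep(sprintf("S%02d", 1:12), each = 10),
                       dmi_kg_d = x, ch4_mj_d = y, n_animals = 8L)
    fit <- fit_nonlinear_mixed(recs, "gompertz")
    fit$coefficients[["a"]]
  }, 0)
  expect_lt(abs(mean(ests) - a_true) / a_true, 0.15)
})

test_that("BIC selection prefers the minimum and breaks ties by parsimony", {
  f1 <- ch4meta:::fit_result(c(a = 1), c(a = 0.1), c(residual = 1), 1, 0.9,
                             bic = 100, TRUE, 50, "FE")
  f2 <- ch4meta:::fit_result(c(a = 1, b = 2), c(a = 0.1, b = 0.1),
                             c(residual = 1), 1, 0.9, bic = 105, TRUE, 50,
                             "FE")
  expect_identical(select_best(list(f1, f2)), f1)
  expect_identical(select_best(list(f2)), f2)
  f3 <- ch4meta:::fit_result(c(a = 1, b = 2, d = 3),
                             c(a = 0.1, b = 0.1, d = 0.1), c(residual = 1),
                             1, 0.9, bic = 100, TRUE, 50, "FE")
  expect_identical(select_best(list(f3, f1)), f1)  # tie -> fewer parameters
  f_bad <- ch4meta:::fit_result(c(a = 1), c(a = 0.1), c(residual = 1), 1,
                                0.9, bic = 1, FALSE, 50, "FE")
  expect_error(select_best(list(f_bad)), "no converged")
})

test_that("adding the true model to a candidate pool can only help", {
  set.seed(23)
  x <- runif(100, 2, 26)
  recs <- data.frame(study_id = rep(sprintf("S%02d", 1:10), each = 10),
                     dmi_kg_d = x, n_animals = 8L)
  recs$ch4_mj_d <- 0.9 * x^1.1
  f_exp <- fit_nonlinear_mixed(recs, "exponential")
  sel_small <- select_best(list(f_exp))
  f_pow <- fit_nonlinear_mixed(recs, "power")
  sel_big <- select_best(list(f_exp, f_pow))
  expect_lte(sel_big$bic, sel_small$bic)
  expect_equal(sel_big$form, "power")
})
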