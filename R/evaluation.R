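# Model-comparison calculus: MSPE, RMSPE as % of the observed mean, the
# mean/slope/random decomposition of MSPE, and the concordance correlation
# coefficient family. Population (divide-by-n) SDs are used throughout so
# the decomposition identity ECT + ER + ED = MSPE is exact.

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

check_series <- function(obs, pred, min_n = 2) {
  if (length(obs) != length(pred)) {
    stop("observed and predicted series differ in length")
  }
  if (length(obs) < min_n) stop("need at least ", min_n, " paired values")
  if (any(!is.finite(obs)) || any(!is.finite(pred))) {
    stop("non-finite values in input series")
  }
  invisible(NULL)
}

#' Mean squared prediction error
#'
#' `MSPE = sum((O_i - P_i)^2) / n`.
#'
#' @param obs,pred Equal-length finite numeric vectors (n >= 2).
#' @return MSPE, (MJ/day)^2 when inputs are MJ/day.
#' @export
mspe <- function(obs, pred) {
  check_series(obs, pred)
  mean((obs - pred)^2)
}

#' Decompose MSPE into mean, slope and random components
#'
#' `ECT = (Pbar - Obar)^2` (error of central tendency / mean bias),
#' `ER = (S_p - r S_o)^2` (error due to regression / slope bias),
#' `ED = (1 - r^2) S_o^2` (error due to disturbance / random error), with
#' population SDs, so that `ECT + ER + ED = MSPE` holds by construction.
#'
#' @param obs,pred Non-degenerate series (positive variance each).
#' @return Named vector `c(ECT, ER, ED)`.
#' @export
#' @examples
#' o <- c(1, 2, 3); decompose_mspe(o, o + 1)  # ECT = 1, ER = ED = 0
decompose_mspe <- function(obs, pred) {
  check_series(obs, pred)
  so <- pop_sd(obs); sp <- pop_sd(pred)
  if (so == 0 || sp == 0) {
    stop("decompose_mspe: zero variance in observed or predicted series")
  }
  r <- cor(obs, pred)
  c(ECT = (mean(pred) - mean(obs))^2,
    ER = (sp - r * so)^2,
    ED = (1 - r^2) * so^2)
}

#' RMSPE as a percentage of the observed mean
#'
#' @param obs,pred Series as in [mspe()]; `mean(obs)` must be positive.
#' @return `100 sqrt(MSPE) / mean(obs)`.
#' @export
rmspe_pct <- function(obs, pred) {
  check_series(obs, pred)
  if (mean(obs) <= 0) stop("rmspe_pct: observed mean must be positive")
  100 * sqrt(mspe(obs, pred)) / mean(obs)
}

#' Concordance correlation analysis
#'
#' Lin's concordance family with population SDs: Pearson `r` (precision),
#' scale shift `v = S_o / S_p`, location shift
#' `mu = (Obar - Pbar) / sqrt(S_o S_p)` (negative mu indicates
#' overprediction), bias-correction factor `Cb = 2 / (v + 1/v + mu^2)`
#' (accuracy), and `CCC = r Cb`. The direct form
#' `CCC = 2 r S_o S_p / (S_o^2 + S_p^2 + (Obar - Pbar)^2)` is algebraically
#' identical and is used as a cross-check in the test suite.
#'
#' @param obs,pred Non-degenerate series.
#' @return Named vector `c(r, CCC, Cb, v, mu)`.
#' @export
#' @examples
#' ccc_analysis(c(1, 2, 3), c(2, 3, 4))  # r = 1, CCC = 4/7, mu < 0
ccc_analysis <- function(obs, pred) {
  check_series(obs, pred)
  so <- pop_sd(obs); sp <- pop_sd(pred)
  if (so == 0 || sp == 0) {
    stop("ccc_analysis: zero variance in observed or predicted series")
  }
  r <- cor(obs, pred)
  v <- so / sp
  mu <- (mean(obs) - mean(pred)) / sqrt(so * sp)
  cb <- 2 / (v + 1 / v + mu^2)
  c(r = r, CCC = r * cb, Cb = cb, v = v, mu = mu)
}

#' Evaluate prediction equations on a record table
#'
#' One metrics row per equation, computed on observed CH4 (MJ/day) against
#' the equation's predictions. Records missing any predictor an equation
#' needs are dropped for that equation only (no imputation at evaluation
#' time); `n_used` reports the records actually compared. Equations with
#' fewer than 2 usable records, or a degenerate prediction series, yield a
#' row of NAs with a warning.
#'
#' @param records Record table with observed `ch4_mj_d`.
#' @param equations List of `ch4_equation` objects or character ids.
#' @return Data frame with columns `equation`, `n_used`, `mean_obs`,
#'   `mean_pred`, `MSPE`, `RMSPE`, `RMSPE_pct`, `ECT`, `ER`, `ED`,
#'   `ECT_pct`, `ER_pct`, `ED_pct`, `r`, `CCC`, `Cb`, `v`, `mu`, in input
#'   order.
#' @export
evaluate_equations <- function(records, equations) {
  if (is.character(equations)) equations <- lapply(equations, get_equation)
  if (inherits(equations, "ch4_equation")) equations <- list(equations)
  obs_all <- col_or_na(records, "ch4_mj_d")
  px <- as_predictors(records)
  rows <- lapply(equations, function(eq) {
    if (is.character(eq)) eq <- get_equation(eq)
    need <- required_inputs(eq)
    usable <- !is.na(obs_all)
    for (p in need) usable <- usable & !is.na(px[[p]])
    na_row <- data.frame(equation = eq$id, n_used = sum(usable),
                         mean_obs = NA_real_, mean_pred = NA_real_,
                         MSPE = NA_real_, RMSPE = NA_real_,
                         RMSPE_pct = NA_real_, ECT = NA_real_, ER = NA_real_,
                         ED = NA_real_, ECT_pct = NA_real_, ER_pct = NA_real_,
                         ED_pct = NA_real_, r = NA_real_, CCC = NA_real_,
                         Cb = NA_real_, v = NA_real_, mu = NA_real_,
                         stringsAsFactors = FALSE)
    if (sum(usable) < 2) {
      warning("equation '", eq$id, "' skipped: ", sum(usable),
              " usable record(s)")
      return(na_row)
    }
    obs <- obs_all[usable]
    pred <- predict_methane(eq, px[usable, , drop = FALSE])
    m <- mspe(obs, pred)
    dec <- decompose_mspe_safe(obs, pred)
    ccc <- if (pop_sd(pred) > 0) {
      ccc_analysis(obs, pred)
    } else {
      c(r = NA, CCC = NA, Cb = NA, v = NA, mu = NA)
    }
    data.frame(equation = eq$id, n_used = length(obs), mean_obs = mean(obs),
               mean_pred = mean(pred), MSPE = m, RMSPE = sqrt(m),
               RMSPE_pct = rmspe_pct(obs, pred),
               ECT = dec[["ECT"]], ER = dec[["ER"]], ED = dec[["ED"]],
               ECT_pct = 100 * dec[["ECT"]] / m,
               ER_pct = 100 * dec[["ER"]] / m,
               ED_pct = 100 * dec[["ED"]] / m,
               r = ccc[["r"]], CCC = ccc[["CCC"]], Cb = ccc[["Cb"]],
               v = ccc[["v"]], mu = ccc[["mu"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# decomposition tolerant of constant predictions (ER/ED still defined with
# sp = 0: ER = r-free (r undefined) -> fold the non-mean error into ED)
decompose_mspe_safe <- function(obs, pred) {
  if (pop_sd(pred) == 0 || pop_sd(obs) == 0) {
    ect <- (mean(pred) - mean(obs))^2
    c(ECT = ect, ER = 0, ED = mspe(obs, pred) - ect)
  } else {
    decompose_mspe(obs, pred)
  }
}

#' Correlation screen of candidate predictors
#'
#' Pearson correlation (with two-sided p-value) between observed CH4
#' (MJ/day) and each candidate variable, pairwise-complete. `R2` is
#' reported as `r^2`.
#'
#' @param records Record table with `ch4_mj_d`.
#' @param variables Columns to screen.
#' @param min_pairs Minimum complete pairs per variable (default 3);
#'   variables with fewer are returned with NA and a note.
#' @return Data frame `variable`, `n`, `r`, `p_value`, `R2`, `note`.
#' @export
correlation_screen <- function(records, variables, min_pairs = 3) {
  y <- col_or_na(records, "ch4_mj_d")
  rows <- lapply(variables, function(v) {
    x <- col_or_na(records, v)
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < min_pairs) {
      return(data.frame(variable = v, n = sum(ok), r = NA_real_,
                        p_value = NA_real_, R2 = NA_real_,
                        note = "insufficient pairs", stringsAsFactors = FALSE))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(variable = v, n = sum(ok), r = unname(ct$estimate),
               p_value = ct$p.value, R2 = unname(ct$estimate)^2, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual-versus-centered-prediction diagnostics
#'
#' Regresses the residual `obs - pred` on the centered prediction
#' `pred - mean(pred)`. By construction the intercept equals the mean bias
#' `mean(obs) - mean(pred)`; a nonzero slope indicates slope bias.
#'
#' @param obs,pred Non-degenerate series.
#' @return Named list with `slope`, `intercept`, `slope_se`, `intercept_se`
#'   and the underlying `lm` fit.
#' @export
residual_diagnostics <- function(obs, pred) {
  check_series(obs, pred, min_n = 3)
  if (pop_sd(pred) == 0) {
    stop("residual_diagnostics: degenerate (constant) predictions")
  }
  resid_v <- obs - pred
  centered <- pred - mean(pred)
  fit <- lm(resid_v ~ centered)
  # summary.lm warns on an exactly perfect fit (pred == obs); that input is
  # legitimate here
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       intercept_se = sm[1, "Std. Error"], slope_se = sm[2, "Std. Error"],
       fit = fit)
}
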