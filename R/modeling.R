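# Equation-development procedure: outlier screening by Cook's distance,
# weighted linear mixed models with study random intercept/slope (UN
# covariance with VC fallback), VIF-guarded backward elimination, nonlinear
# mixed growth-curve fits, and BIC-based selection.

#' Flag influential records by Cook's distance
#'
#' Cook's D is computed from the fixed-effects (weighted) regression of the
#' response on the predictors; records with `D > cutoff` are reported, not
#' dropped. The default cutoff 4/n is an explicit, testable stand-in for
#' visual inspection of the D distribution.
#'
#' @param records Record table.
#' @param response,predictors Column names.
#' @param weights Optional column name of regression weights (animal counts).
#' @param cutoff Flagging threshold; default `4 / nrow(records)`.
#' @return Integer row indices of flagged records (possibly empty), with the
#'   Cook's distances as attribute `"cooks_d"`.
#' @export
detect_outliers <- function(records, response, predictors, weights = NULL,
                            cutoff = NULL) {
  n <- nrow(records)
  if (n < 10) stop("detect_outliers: need at least 10 records")
  if (n <= length(predictors) + 1) {
    stop("detect_outliers: fewer records than regression parameters")
  }
  if (is.null(cutoff)) cutoff <- 4 / n
  f <- as.formula(paste(response, "~", paste(predictors, collapse = " + ")))
  w <- if (is.null(weights)) NULL else records[[weights]]
  fit <- lm(f, data = records, weights = w)
  d <- cooks.distance(fit)
  flagged <- which(d > cutoff)
  attr(flagged, "cooks_d") <- d
  flagged
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` is from regressing predictor `k`
#' on the remaining predictors. Exact collinearity yields `Inf`, not an
#' error.
#'
#' @param records Record table (or data frame of predictors).
#' @param predictors Character vector of >= 2 column names.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
#' @examples
#' d <- data.frame(x1 = rnorm(50), x2 = rnorm(50))
#' compute_vif(d, c("x1", "x2"))
compute_vif <- function(records, predictors) {
  stopifnot(length(predictors) >= 2)
  x <- records[, predictors, drop = FALSE]
  x <- x[complete.cases(x), , drop = FALSE]
  vapply(predictors, function(k) {
    f <- as.formula(paste(k, "~", paste(setdiff(predictors, k),
                                        collapse = " + ")))
    r2 <- suppressWarnings(summary(lm(f, data = x))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

fit_result <- function(coefficients, se, varcomp, rmse, r2, bic, converged,
                       n_used, structure, model = NULL, form = "linear",
                       excluded = integer(0)) {
  structure(list(coefficients = coefficients, se = se, varcomp = varcomp,
                 rmse = rmse, r2 = r2, bic = bic, converged = converged,
                 n_used = n_used, structure = structure, model = model,
                 form = form, excluded_outliers = excluded),
            class = "ch4_fit")
}

#' @export
print.ch4_fit <- function(x, ...) {
  cat("<ch4_fit>", x$form, "| structure:", x$structure,
      "| converged:", x$converged, "| n =", x$n_used, "\n")
  est <- data.frame(estimate = x$coefficients,
                    se = x$se[names(x$coefficients)])
  print(round(est, 4))
  cat(sprintf("RMSE = %.4g, R2 = %.4g, BIC = %.4g\n", x$rmse, x$r2, x$bic))
  if (length(x$varcomp)) {
    cat("variance components:",
        paste(sprintf("%s=%.4g", names(x$varcomp), x$varcomp),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# number of estimated parameters of a fit (fixed + variance components)
n_par <- function(fit) length(fit$coefficients) + length(fit$varcomp)

#' Weighted linear mixed model with study random intercept and slope
#'
#' Fits, by REML,
#' `Y_ij = B0 + B1 X_ij (+ B2 X_ij^2) (+ further fixed terms) + s_i +
#' b_i X_ij + e_ij`, with study `i` random intercept `s_i` and random slope
#' `b_i` on the primary predictor, and per-record weights (animal counts).
#' The unstructured (UN) intercept-slope covariance is fitted first; when it
#' fails to converge or the covariance component is non-significant
#' (likelihood-ratio test at `alpha`), the variance-components (VC)
#' structure is used. When the random structure itself is degenerate (e.g.
#' noiseless data) the model falls back to the fixed-effects weighted
#' regression, reported as structure `"FE"`.
#'
#' R2 is the squared correlation between the observed response and the
#' fixed-effects predictions; RMSE is the residual SD at unit weight.
#'
#' @param records Record table.
#' @param response Response column (CH4 MJ/day).
#' @param predictors Fixed-effect predictor columns; the first is the
#'   primary predictor carrying the random slope.
#' @param quadratic Add the squared primary predictor as a fixed term.
#' @param weights Column of regression weights, or `NULL`.
#' @param covariance `"auto"` (UN then VC as described), `"UN"` or `"VC"`.
#' @param alpha Significance level of the covariance LRT in `"auto"`.
#' @return A `ch4_fit`.
#' @export
fit_mixed_linear <- function(records, response, predictors,
                             quadratic = FALSE, weights = "n_animals",
                             covariance = c("auto", "UN", "VC"),
                             alpha = 0.10) {
  covariance <- match.arg(covariance)
  primary <- predictors[1]
  fixed_terms <- predictors
  if (quadratic) fixed_terms <- c(fixed_terms, sprintf("I(%s^2)", primary))
  fixed_rhs <- paste(fixed_terms, collapse = " + ")
  w <- if (!is.null(weights) && weights %in% names(records)) {
    records[[weights]]
  } else {
    rep(1, nrow(records))
  }
  if (any(w <= 0, na.rm = TRUE)) stop("fit_mixed_linear: weights must be positive")
  dat <- records[, intersect(names(records),
                             unique(c(response, predictors, "study_id"))),
                 drop = FALSE]
  # normalize to mean 1: estimates are invariant to the weight scale and the
  # residual SD then reads on the observation scale
  dat$.w <- w / mean(w)
  keep <- complete.cases(dat)
  dat <- dat[keep, , drop = FALSE]

  mk <- function(rand) {
    as.formula(paste(response, "~", fixed_rhs, "+", rand))
  }
  f_un <- mk(sprintf("(1 + %s | study_id)", primary))
  f_vc <- mk(sprintf("(1 | study_id) + (0 + %s | study_id)", primary))

  try_lmer <- function(f) {
    tryCatch({
      fit <- suppressWarnings(suppressMessages(
        lmerTest::lmer(f, data = dat, weights = .w, REML = TRUE,
                       control = lme4::lmerControl(
                         check.conv.singular = "ignore",
                         calc.derivs = FALSE))))
      conv <- length(fit@optinfo$conv$lme4$messages) == 0
      list(fit = fit, converged = conv)
    }, error = function(e) NULL)
  }

  pick <- NULL; struct <- NA_character_
  if (covariance %in% c("auto", "UN")) {
    un <- try_lmer(f_un)
    if (covariance == "UN") {
      pick <- un; struct <- "UN"
    } else if (!is.null(un) && un$converged) {
      vc <- try_lmer(f_vc)
      if (!is.null(vc) && vc$converged) {
        # LRT for the intercept-slope covariance (1 df)
        lrt <- 2 * (as.numeric(logLik(un$fit)) - as.numeric(logLik(vc$fit)))
        p_cov <- 1 - stats::pchisq(max(lrt, 0), df = 1)
        if (p_cov > alpha) {
          pick <- vc; struct <- "VC"
        } else {
          pick <- un; struct <- "UN"
        }
      } else {
        pick <- un; struct <- "UN"
      }
    }
  }
  if (is.null(pick) && covariance %in% c("auto", "VC")) {
    vc <- try_lmer(f_vc)
    if (!is.null(vc)) { pick <- vc; struct <- "VC" }
  }

  obs <- dat[[response]]
  if (!is.null(pick)) {
    fit <- pick$fit
    fe <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    pred_fixed <- as.numeric(stats::model.matrix(fit) %*% fe)
    vc_tab <- as.data.frame(lme4::VarCorr(fit))
    vnames <- ifelse(is.na(vc_tab$var2),
                     ifelse(vc_tab$grp == "Residual", "residual",
                            paste0("study_", vc_tab$var1)),
                     "study_cov")
    varcomp <- setNames(vc_tab$vcov, vnames)
    return(fit_result(fe, se, varcomp, rmse = sigma(fit),
                      r2 = cor(obs, pred_fixed)^2, bic = BIC(fit),
                      converged = pick$converged, n_used = nrow(dat),
                      structure = struct, model = fit))
  }

  # fixed-effects fallback (degenerate random structure / non-convergence)
  flm <- lm(as.formula(paste(response, "~", fixed_rhs)), data = dat,
            weights = .w)
  sm <- summary(flm)
  fit_result(coef(flm), sm$coefficients[, "Std. Error"],
             varcomp = c(residual = sigma(flm)^2), rmse = sigma(flm),
             r2 = cor(obs, as.numeric(flm$fitted.values))^2, bic = BIC(flm),
             converged = TRUE, n_used = nrow(dat), structure = "FE",
             model = flm)
}

# p-values of fixed terms of a ch4_fit (Satterthwaite for lmer fits)
fixed_pvalues <- function(fit) {
  m <- fit$model
  if (inherits(m, "lmerModLmerTest")) {
    sm <- suppressMessages(summary(m))
    p <- sm$coefficients[, "Pr(>|t|)"]
  } else if (inherits(m, "merMod")) {
    tt <- fit$coefficients / fit$se
    p <- 2 * pnorm(-abs(tt))
  } else {
    p <- summary(m)$coefficients[, "Pr(>|t|)"]
  }
  p[setdiff(names(p), "(Intercept)")]
}

#' Backward elimination with a VIF guard
#'
#' Candidate sets containing any VIF >= `vif_cutoff` are rejected before any
#' model is fitted. The full model (study random intercept + random slope on
#' the primary predictor) is then reduced by removing, one at a time (worst
#' first), non-primary terms whose fixed effect is non-significant at
#' `alpha`; the primary predictor is removable only if additionally its
#' random slope is non-significant (likelihood-ratio test at `alpha`). The
#' trace records every fit and decision; the procedure is deterministic
#' given the data.
#'
#' @param records Record table.
#' @param response Response column.
#' @param candidates Candidate predictor columns; the first is the primary
#'   predictor (random slope carrier).
#' @param weights Weight column or `NULL`.
#' @param alpha Removal threshold (terms with p > `alpha` are removable).
#' @param vif_cutoff Collinearity guard (default 10).
#' @return List with `formula` (final predictor set), `fit` (final
#'   `ch4_fit`), and `trace` (data frame of steps).
#' @export
backward_eliminate <- function(records, response, candidates,
                               weights = "n_animals", alpha = 0.10,
                               vif_cutoff = 10) {
  stopifnot(length(candidates) >= 1)
  if (length(candidates) >= 2) {
    vif <- compute_vif(records, candidates)
    if (any(vif >= vif_cutoff)) {
      stop("backward_eliminate: candidate set rejected, VIF >= ", vif_cutoff,
           " for: ", paste(names(vif)[vif >= vif_cutoff], collapse = ", "))
    }
  }
  primary <- candidates[1]
  current <- candidates
  trace <- list()
  repeat {
    fit <- fit_mixed_linear(records, response, current, weights = weights)
    pv <- fixed_pvalues(fit)
    # map p-values back to candidate names (model.matrix names match here)
    pv <- pv[names(pv) %in% current]
    removable <- pv[pv > alpha]
    # the primary predictor may only leave if its random slope is also
    # non-significant
    if (primary %in% names(removable) && length(current) >= 1) {
      p_slope <- random_slope_pvalue(records, response, current, primary,
                                     weights)
      if (!is.na(p_slope) && p_slope <= alpha) {
        removable <- removable[names(removable) != primary]
      }
    }
    step <- data.frame(terms = paste(current, collapse = "+"),
                       worst = if (length(removable))
                         names(which.max(removable)) else NA_character_,
                       worst_p = if (length(removable))
                         max(removable) else NA_real_,
                       removed = length(removable) > 0,
                       bic = fit$bic, stringsAsFactors = FALSE)
    trace[[length(trace) + 1]] <- step
    if (!length(removable) || length(current) == 1 && !length(removable)) {
      break
    }
    if (!length(removable)) break
    drop_term <- names(which.max(removable))
    current <- setdiff(current, drop_term)
    if (!length(current)) break
    if (!primary %in% current) primary <- current[1]
  }
  final_fit <- fit_mixed_linear(records, response, current, weights = weights)
  list(formula = current, fit = final_fit, trace = do.call(rbind, trace))
}

# LRT p-value for the study random slope on `primary` (boundary-conservative)
random_slope_pvalue <- function(records, response, predictors, primary,
                                weights) {
  tryCatch({
    full <- fit_mixed_linear(records, response, predictors,
                             weights = weights, covariance = "VC")
    if (!inherits(full$model, "merMod")) return(NA_real_)
    dat <- stats::model.frame(full$model)
    f0 <- as.formula(paste(response, "~",
                           paste(predictors, collapse = " + "),
                           "+ (1 | study_id)"))
    m0 <- suppressWarnings(suppressMessages(
      lme4::lmer(f0, data = dat, weights = `(weights)`, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    lrt <- 2 * (as.numeric(logLik(full$model)) - as.numeric(logLik(m0)))
    1 - stats::pchisq(max(lrt, 0), df = 1)
  }, error = function(e) NA_real_)
}

# ---- nonlinear growth-curve fits -----------------------------------------

nl_fun <- function(form) {
  switch(form,
    monomolecular = function(x, a, b, c) a - (a + b) * exp(-c * x),
    mitscherlich = function(x, a, c) a * (1 - exp(-c * x)),
    gompertz = function(x, a, b, c)
      b * exp((1 - exp(-c * x)) * log((a + 2 * b) / b)) - 2 * b,
    exponential = function(x, b, c) b * exp(c * x),
    power = function(x, b, c) b * x^c,
    stop("unknown nonlinear form: ", form))
}

nl_param_names <- function(form) {
  switch(form, monomolecular = c("a", "b", "c"),
         mitscherlich = c("a", "c"), gompertz = c("a", "b", "c"),
         exponential = c("b", "c"), power = c("b", "c"))
}

# deterministic coarse grid of starting values over data-driven bounds
nl_grid_start <- function(form, x, y, n_grid = 10) {
  ymax <- max(y); ymin <- max(min(y), 1e-3)
  xmax <- max(x)
  gl <- function(lo, hi) exp(seq(log(lo), log(hi), length.out = n_grid))
  grids <- switch(form,
    monomolecular = expand.grid(a = gl(ymax, 5 * ymax),
                                b = gl(1e-3, ymax), c = gl(0.01 / xmax * 10, 10 / xmax)),
    mitscherlich = expand.grid(a = gl(ymax, 5 * ymax),
                               c = gl(0.1 / xmax, 10 / xmax)),
    gompertz = expand.grid(a = gl(ymax, 5 * ymax), b = gl(1e-2, ymax),
                           c = gl(0.1 / xmax, 10 / xmax)),
    exponential = expand.grid(b = gl(ymin / 2, ymax), c = gl(0.01 / xmax, 5 / xmax)),
    power = expand.grid(b = gl(ymin / 10, ymax), c = gl(0.2, 3)))
  f <- nl_fun(form)
  sse <- apply(grids, 1, function(p) {
    pred <- do.call(f, c(list(x = x), as.list(p)))
    s <- sum((y - pred)^2)
    if (is.finite(s)) s else Inf
  })
  as.list(grids[which.min(sse), , drop = TRUE])
}

#' Nonlinear mixed growth-curve fit
#'
#' Fits one of the registry's nonlinear forms with study-level random
#' effects on the parameters ("richest first" strategy): all parameters
#' random (diagonal covariance), then random `b` only, then a fixed-effects
#' nonlinear least-squares fit. Starting values come from a deterministic
#' coarse grid over data-driven bounds; no randomness is used.
#'
#' @param records Record table.
#' @param form One of `"monomolecular"`, `"mitscherlich"`, `"gompertz"`,
#'   `"exponential"`, `"power"`.
#' @param response Response column (CH4 MJ/day).
#' @param predictor Predictor column (DMI or MEI based).
#' @param weights Weight column or `NULL`.
#' @return A `ch4_fit` with the parameter estimates as coefficients and the
#'   random-effects level actually achieved in `$structure`
#'   (`"random_abc"`, `"random_b"` or `"FE"`).
#' @export
fit_nonlinear_mixed <- function(records, form, response = "ch4_mj_d",
                                predictor = "dmi_kg_d",
                                weights = "n_animals") {
  pn <- nl_param_names(form)
  dat <- data.frame(y = records[[response]], x = records[[predictor]],
                    study_id = records$study_id)
  dat$w <- if (!is.null(weights) && weights %in% names(records)) {
    records[[weights]]
  } else {
    rep(1, nrow(records))
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  start <- nl_grid_start(form, dat$x, dat$y)
  body_txt <- switch(form,
    monomolecular = "a - (a + b) * exp(-c * x)",
    mitscherlich = "a * (1 - exp(-c * x))",
    gompertz = "b * exp((1 - exp(-c * x)) * log((a + 2 * b) / b)) - 2 * b",
    exponential = "b * exp(c * x)",
    power = "b * x^c")
  model_f <- as.formula(paste("y ~", body_txt))

  mk_result <- function(est, se, varcomp, model, structure, converged) {
    pred <- do.call(nl_fun(form), c(list(x = dat$x), as.list(est)))
    rss <- sum((dat$y - pred)^2)
    fit_result(est, se, varcomp, rmse = sqrt(rss / (nrow(dat) - length(est))),
               r2 = if (sd(pred) > 0) cor(dat$y, pred)^2 else 0,
               bic = BIC(model), converged = converged, n_used = nrow(dat),
               structure = structure, model = model, form = form)
  }

  # 1) all parameters random (diagonal)
  res <- tryCatch({
    rf <- as.formula(paste(paste(pn, collapse = " + "), "~ 1 | study_id"))
    ff <- as.formula(paste(paste(pn, collapse = " + "), "~ 1"))
    m <- suppressWarnings(nlme::nlme(model_f, data = dat, fixed = ff,
                                     random = rf, groups = ~study_id,
                                     start = unlist(start),
                                     weights = nlme::varFixed(~1 / w),
                                     control = nlme::nlmeControl(
                                       maxIter = 200, msMaxIter = 200,
                                       returnObject = FALSE)))
    est <- nlme::fixef(m)
    vc <- diag(as.matrix(m$modelStruct$reStruct[[1]])) * m$sigma^2
    mk_result(est, sqrt(diag(vcov(m))),
              c(setNames(vc, paste0("study_", pn)), residual = m$sigma^2),
              m, "random_abc", TRUE)
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)

  # 2) random b only (random a for forms without b)
  rpar <- if ("b" %in% pn) "b" else pn[1]
  res <- tryCatch({
    rf <- as.formula(paste(rpar, "~ 1 | study_id"))
    ff <- as.formula(paste(paste(pn, collapse = " + "), "~ 1"))
    m <- suppressWarnings(nlme::nlme(model_f, data = dat, fixed = ff,
                                     random = rf, groups = ~study_id,
                                     start = unlist(start),
                                     weights = nlme::varFixed(~1 / w),
                                     control = nlme::nlmeControl(
                                       maxIter = 200, msMaxIter = 200,
                                       returnObject = FALSE)))
    est <- nlme::fixef(m)
    vc <- as.numeric(as.matrix(m$modelStruct$reStruct[[1]])) * m$sigma^2
    mk_result(est, sqrt(diag(vcov(m))),
              setNames(c(vc, m$sigma^2), c(paste0("study_", rpar), "residual")),
              m, "random_b", TRUE)
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)

  # 3) fixed-effects nonlinear least squares
  res <- tryCatch({
    m <- nls(model_f, data = dat, start = start, weights = dat$w,
             control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
    sm <- summary(m)
    mk_result(coef(m), sm$coefficients[, "Std. Error"],
              c(residual = sigma(m)^2), m, "FE", TRUE)
  }, error = function(e) NULL)
  if (!is.null(res)) return(res)
  res <- tryCatch({
    m <- minpack.lm::nlsLM(model_f, data = dat, start = start,
                           weights = dat$w,
                           control = minpack.lm::nls.lm.control(maxiter = 500))
    sm <- summary(m)
    mk_result(coef(m), sm$coefficients[, "Std. Error"],
              c(residual = sigma(m)^2), m, "FE", TRUE)
  }, error = function(e) NULL)
  if (is.null(res)) {
    stop("fit_nonlinear_mixed: no convergence for form '", form,
         "' at any random-effects level")
  }
  res
}

#' Select the best fit by BIC
#'
#' Returns the converged fit with minimal BIC; ties (within `tie_tol`) are
#' broken toward fewer estimated parameters.
#'
#' @param fits List of `ch4_fit` objects.
#' @param tie_tol Absolute BIC difference treated as a tie.
#' @return The selected `ch4_fit`.
#' @export
select_best <- function(fits, tie_tol = 1e-8) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop("select_best: no converged fit to select from")
  bics <- vapply(fits, `[[`, 0, "bic")
  best <- min(bics)
  tied <- which(bics <= best + tie_tol)
  if (length(tied) > 1) {
    tied <- tied[order(vapply(fits[tied], n_par, 0))]
  }
  fits[[tied[1]]]
}
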