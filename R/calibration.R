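# Per-database summary statistics (mean/min/max/SD) of the treatment-mean
# meta-analytic databases, used as calibration targets by the synthetic
# generator. Values are stored exactly as published.

.cal_vars <- c(
  "bw_kg", "dmi_kg_d", "gei_mj_d", "dei_mj_d", "mei_mj_d", "fl_multiple",
  "om_g_kg", "cp_g_kg", "ee_g_kg", "ndf_g_kg", "adf_g_kg", "nfc_g_kg",
  "roughage_g_kg",
  "dig_dm_g_kg", "dig_om_g_kg", "dig_ge_g_kg", "dig_omdm_g_kg",
  "dig_cp_g_kg", "dig_ndf_g_kg", "dig_adf_g_kg", "dig_ee_g_kg",
  "ch4_g_d", "ch4_mj_d", "ch4_g_kg_dm", "ch4_g_kg_om", "ch4_mj_kg_dm",
  "ch4_pct_ge", "ch4_pct_de", "ch4_g_kg_ddm", "ch4_g_kg_dom"
)

# columns: mean, min, max, sd — row order follows .cal_vars
.cal_beef <- matrix(c(
  404.58, 163,   616,   120.2,
  7.45,   2.29,  23.7,  4.07,
  134.29, 41.5,  426,   75.77,
  93.91,  30.4,  328,   55.36,
  70.75,  22.2,  285,   49.73,
  2.78,   0.47,  10.47, 1.94,
  922,    831,   963,   23.02,
  153.78, 42,    276,   52.07,
  55.18,  8,     318,   43.99,
  352.65, 93,    776,   169.13,
  273.43, 73,    491,   106.36,
  361,    93.4,  644,   140.04,
  682.51, 100,   1000,  250,
  673.32, 493,   837,   81.57,
  698.16, 503,   837,   76.52,
  692.41, 496,   866,   74.86,
  713.52, 500,   861,   78.4,
  650.06, 401,   841,   95.41,
  539.31, 236,   740,   116.66,
  433.92, 244,   658,   101.51,
  758.24, 82,    942,   219.14,
  127.83, 50.3,  418,   70.79,
  7.07,   2.64,  23.3,  3.97,
  18.6,   6.61,  34.1,  5.87,
  19.99,  6.8,   39.9,  6.56,
  1.03,   0.37,  1.9,   0.32,
  5.81,   2.2,   11.5,  1.99,
  8.36,   2.89,  16.9,  3.12,
  27.68,  9.58,  54.89, 9.36,
  28.23,  9.58,  59,    10.34
), ncol = 4, byrow = TRUE)

.cal_dairy <- matrix(c(
  515.9,  263,   734,   118.37,
  13.92,  4.8,   26.2,  5.79,
  259.31, 87.4,  491.6, 114.59,
  176.55, 63.8,  341.3, 84.00,
  133.91, 25.1,  262.9, 73.93,
  4.90,   0.49,  12,    3.34,
  918.66, 815,   965,   40.87,
  165.29, 96.3,  210,   24.76,
  36.42,  21,    62.6,  11.15,
  386.43, 271,   599,   70.16,
  219.85, 131,   347,   53.60,
  328.95, 150,   464,   77.22,
  624.68, 50,    1000,  242.59,
  713.26, 543,   819,   58.78,
  721.91, 595,   826,   62.37,
  708.38, 566,   804,   62.19,
  772.18, 603,   859,   56.41,
  686.59, 407,   839,   82.99,
  581.02, 403,   718,   96.44,
  533.12, 293,   707,   105.20,
  760.57, 553,   897,   102.39,
  286.00, 95.9,  540,   125.54,
  15.79,  5.6,   30.1,  7.01,
  20.25,  12.2,  28.9,  4.07,
  22.80,  12.5,  42.3,  5.11,
  1.12,   0.68,  1.58,  0.22,
  6.42,   2.86,  10.86, 1.35,
  9.06,   3.49,  17.9,  2.62,
  29.31,  15.04, 57.06, 7.23,
  29.48,  14.62, 55.41, 7.59
), ncol = 4, byrow = TRUE)

.cal_combined <- matrix(c(
  453.15, 163,   734,   131.55,
  10.28,  2.29,  26.2,  5.86,
  188.83, 41.5,  491.6, 113.17,
  128.55, 30.4,  341.3, 80.00,
  93.72,  22.2,  285,   66.97,
  3.56,   0.47,  12,    2.74,
  920.90, 815,   965,   32.11,
  158.80, 42,    276,   42.76,
  47.00,  8,     318,   35.10,
  367.39, 93,    776,   136.22,
  250.47, 73,    491,   91.65,
  347.02, 93.4,  644,   117.94,
  657.28, 50,    1000,  248.46,
  690.74, 493,   837,   75.17,
  708.81, 503,   837,   71.51,
  698.32, 496,   866,   70.86,
  734.34, 500,   861,   76.70,
  670.05, 401,   841,   90.67,
  556.35, 236,   740,   110.77,
  479.39, 244,   707,   114.45,
  759.38, 82,    942,   172.48,
  196.83, 50.3,  540,   125.91,
  10.87,  2.64,  30.1,  7.00,
  19.32,  6.61,  34.1,  5.23,
  21.22,  6.8,   42.3,  6.13,
  1.07,   0.37,  1.9,   0.29,
  6.08,   2.2,   11.5,  1.77,
  8.65,   2.89,  17.9,  2.94,
  28.39,  9.58,  57.06, 8.54,
  28.80,  9.58,  59,    9.23
), ncol = 4, byrow = TRUE)

#' Per-database calibration table
#'
#' Summary statistics (mean, minimum, maximum, SD) of every variable in the
#' beef, dairy and combined treatment-mean databases. These are the targets
#' the synthetic generator ([generate_database()]) is calibrated against.
#'
#' @param database One of `"beef"`, `"dairy"`, `"combined"`.
#' @return A data frame with columns `variable`, `mean`, `min`, `max`, `sd`,
#'   one row per database variable, of class `ch4_calibration`.
#' @export
#' @examples
#' cal <- calibration_table("combined")
#' cal[cal$variable == "dmi_kg_d", ]
calibration_table <- function(database = c("beef", "dairy", "combined")) {
  database <- match.arg(database)
  m <- switch(database, beef = .cal_beef, dairy = .cal_dairy,
              combined = .cal_combined)
  out <- data.frame(variable = .cal_vars, mean = m[, 1], min = m[, 2],
                    max = m[, 3], sd = m[, 4], stringsAsFactors = FALSE)
  attr(out, "database") <- database
  class(out) <- c("ch4_calibration", "data.frame")
  out
}

#' @export
print.ch4_calibration <- function(x, ...) {
  cat("<ch4_calibration> database:", attr(x, "database"),
      "-", nrow(x), "variables\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

cal_row <- function(cal, variable) {
  i <- match(variable, cal$variable)
  if (is.na(i)) stop("unknown calibration variable: ", variable)
  cal[i, , drop = FALSE]
}

# ---- truncated-normal machinery ------------------------------------------

# Closed-form mean and SD of N(mu, sigma^2) truncated to [lo, hi].
tn_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  if (z < .Machine$double.eps) {
    # degenerate: all mass outside; collapse to nearest bound
    m <- if (mu < lo) lo else hi
    return(c(mean = m, sd = 0))
  }
  da <- dnorm(a); db <- dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for parent (mu, sigma) such that the [lo, hi]-truncated normal has
# the target mean and SD. Published summary statistics are moments of the
# *observed* (range-limited) variable, so matching the truncated moments --
# not the parent moments -- is what makes large-sample means reproduce the
# calibration table. Minimizes standardized squared moment error; when the
# target is not exactly attainable inside the family the best-fitting member
# is returned together with the residual error.
tn_calibrate <- function(mean, sd, lo, hi) {
  stopifnot(lo < hi, sd > 0, mean >= lo, mean <= hi)
  obj <- function(p) {
    mm <- tn_moments(p[1], exp(p[2]), lo, hi)
    ((mm["mean"] - mean) / sd)^2 + ((mm["sd"] - sd) / sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  # polish from a second start in case the first stalls
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
  if (fit2$value < fit$value) fit <- fit2
  mm <- tn_moments(fit$par[1], exp(fit$par[2]), lo, hi)
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lo = lo, hi = hi,
       mean = unname(mm["mean"]), sd = unname(mm["sd"]),
       moment_error = sqrt(fit$value))
}

# Inverse-CDF sampler for the truncated normal (exact, vectorized).
rtnorm <- function(n, mu, sigma, lo, hi) {
  plo <- pnorm(lo, mu, sigma)
  phi <- pnorm(hi, mu, sigma)
  qnorm(runif(n, plo, phi), mu, sigma)
}

.cal_cache <- new.env(parent = emptyenv())

# Calibrated parent parameters for one variable of one database (cached).
tn_params <- function(database, variable) {
  key <- paste(database, variable, sep = ".")
  if (!is.null(.cal_cache[[key]])) return(.cal_cache[[key]])
  cr <- cal_row(calibration_table(database), variable)
  p <- tn_calibrate(cr$mean, cr$sd, cr$min, cr$max)
  .cal_cache[[key]] <- p
  p
}

# Draw n calibrated values for one variable of one database.
draw_calibrated <- function(n, database, variable, sd_scale = 1) {
  cr <- cal_row(calibration_table(database), variable)
  if (sd_scale == 0) return(rep(cr$mean, n))
  p <- tn_params(database, variable)
  rtnorm(n, p$mu, p$sigma * sd_scale, p$lo, p$hi)
}
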