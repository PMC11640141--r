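# Registry of CH4 prediction equations: published ("extant") equations and
# the database-derived ("developed") linear, quadratic and growth-curve
# equations, as evaluable objects. All coefficients are stored exactly as
# printed in their sources.

new_equation <- function(id, source, database, form,
                         intercept = NA_real_, terms = NULL, quad = NULL,
                         params = NULL, predictor = NA_character_,
                         reported_rmse = NA_real_, reported_r2 = NA_real_,
                         sign_anomaly = FALSE, aliases = character(0)) {
  structure(list(id = id, source = source, database = database, form = form,
                 intercept = intercept, terms = terms, quad = quad,
                 params = params, predictor = predictor,
                 reported_rmse = reported_rmse, reported_r2 = reported_r2,
                 sign_anomaly = sign_anomaly, aliases = aliases),
            class = "ch4_equation")
}

#' @export
print.ch4_equation <- function(x, ...) {
  cat("<ch4_equation>", x$id, sprintf("[%s, %s, %s]\n",
                                      x$source, x$database, x$form))
  if (x$form %in% c("linear", "quadratic")) {
    parts <- sprintf("%.4g", x$intercept)
    if (!is.null(x$terms)) {
      parts <- c(parts, sprintf("%.4g x %s", x$terms, names(x$terms)))
    }
    if (!is.null(x$quad)) {
      parts <- c(parts, sprintf("%.4g x %s^2", x$quad, names(x$quad)))
    }
    cat("  CH4 (MJ/day) =", paste(parts, collapse = " + "), "\n")
  } else {
    cat("  form:", x$form, " a =", x$params[["a"]], " b =", x$params[["b"]],
        " c =", x$params[["c"]], " on", x$predictor, "\n")
    if (isTRUE(x$sign_anomaly)) {
      cat("  note: printed b is negative; |b| used unless literal_sign = TRUE\n")
    }
  }
  invisible(x)
}

.registry_cache <- new.env(parent = emptyenv())

build_registry <- function() {
  lin <- function(id, source, database, intercept, terms,
                  rmse = NA, r2 = NA, aliases = character(0)) {
    new_equation(id, source, database, "linear", intercept = intercept,
                 terms = terms, reported_rmse = rmse, reported_r2 = r2,
                 aliases = aliases)
  }
  nl <- function(id, source, database, form, a, b, c, predictor,
                 rmse = NA, r2 = NA, aliases = character(0)) {
    new_equation(id, source, database, form,
                 params = c(a = a, b = b, c = c), predictor = predictor,
                 reported_rmse = rmse, reported_r2 = r2,
                 sign_anomaly = (form == "exponential" && b < 0),
                 aliases = aliases)
  }
  list(
    # ---- extant (published) equations ----
    lin("mills_linear", "extant", "external", 5.93, c(DMI = 0.92)),
    nl("mills_mono", "extant", "external", "monomolecular",
       a = 56.27, b = 0, c = 0.028, predictor = "DMI"),
    lin("ipcc2006", "extant", "external", 0, c(GEI = 0.065)),
    lin("ellis2007", "extant", "external", 3.272, c(DMI = 0.736)),
    lin("yan2009", "extant", "external", 0.582, c(DMI = 1.40)),
    new_equation("ramin_huhtanen2013", "extant", "external", "quadratic",
                 intercept = 0.797, terms = c(DMI = 1.427),
                 quad = c(DMI = -0.020)),
    nl("patra", "extant", "external", "monomolecular",
       a = 35.21, b = 0.25, c = 0.0354, predictor = "DMI",
       aliases = c("patra2015", "patra2017")),
    # ---- developed, beef ----
    lin("eq1b", "developed", "beef", 0.9188, c(DMI = 0.8196), 2.13, 0.83),
    lin("eq2b", "developed", "beef", 2.4904, c(MEI = 0.0657), 2.24, 0.76),
    lin("eq3b", "developed", "beef", 2.5492, c(NDFI = 1.8401), 1.96, 0.73),
    lin("eq4b", "developed", "beef", 0.9462,
        c(DMI = 0.4368, NDFI = 1.1567), 1.57, 0.83),
    lin("eq5b", "developed", "beef", 0.019,
        c(DMI = 0.8058, ADFI = 0.649), 2.11, 0.7),
    lin("eq6b", "developed", "beef", -0.8848,
        c(MEI = 0.0669, ADFI = 2.1255), 1.98, 0.73),
    lin("eq7b", "developed", "beef", 1.6836,
        c(MEI = 0.0342, NDFI = 1.2202), 1.57, 0.83),
    lin("eq8b", "developed", "beef", 1.6063,
        c(DMI = 0.4256, NDFI = 1.2213, ADFI = -0.475), 1.55, 0.83),
    nl("beef_exp1", "developed", "beef", "exponential",
       a = NA, b = -1.264, c = 0.3094, predictor = "DMI", 1.21, 0.73),
    nl("beef_exp2", "developed", "beef", "exponential",
       a = NA, b = -3.002, c = 0.0172, predictor = "MEI", 2.33, 0.70),
    nl("beef_power", "developed", "beef", "power",
       a = NA, b = 1.039, c = 0.9474, predictor = "DMI", 2.28, 0.67),
    # ---- developed, dairy ----
    lin("eq1d", "developed", "dairy", -6.9931, c(BW = 0.0448), 4.58, 0.55),
    lin("eq2d", "developed", "dairy", 0.7567, c(DMI = 1.0917), 2.73, 0.84),
    lin("eq3d", "developed", "dairy", 5.5616, c(MEI = 0.0789), 4.43, 0.79),
    lin("eq4d", "developed", "dairy", 1.6799, c(NDFI = 2.7698), 3.45, 0.74),
    lin("eq5d", "developed", "dairy", 0.3989,
        c(DMI = 0.8685, NDFI = 0.6675), 2.66, 0.85),
    lin("eq6d", "developed", "dairy", 0.8642,
        c(DMI = 1.1024, ADFI = -0.1051), 2.73, 0.84),
    lin("eq7d", "developed", "dairy", 2.9962,
        c(MEI = 0.0646, ADFI = 1.8279), 4.24, 0.62),
    lin("eq8d", "developed", "dairy", 1.7105,
        c(MEI = 0.0084, NDFI = 2.5447), 3.43, 0.75),
    lin("eq9d", "developed", "dairy", 0.5246,
        c(DMI = 0.8805, NDFI = 0.6691, ADFI = -0.1237), 2.65, 0.88),
    lin("eq10d", "developed", "dairy", -3.0617,
        c(MEI = 0.0147, NDFI = 2.4028, roughage = 0.007), 3.18, 0.78),
    nl("dairy_gompertz", "developed", "dairy", "gompertz",
       a = 39.31, b = 1.396, c = 0.1002, predictor = "DMI", 3.34, 0.8),
    nl("dairy_exp1", "developed", "dairy", "exponential",
       a = NA, b = -4.076, c = 0.0765, predictor = "DMI", 1.27, 0.86),
    nl("dairy_exp2", "developed", "dairy", "exponential",
       a = NA, b = -4.84, c = 0.0055, predictor = "MEI", 1.5, 0.69),
    nl("dairy_power", "developed", "dairy", "power",
       a = NA, b = 0.887, c = 1.085, predictor = "DMI", 2.62, 0.88),
    # ---- developed, combined ----
    lin("eq1c", "developed", "combined", 0.0529, c(DMI = 1.0469), 3.04, 0.83),
    lin("eq2c", "developed", "combined", 3.88, c(MEI = 0.071), 1.36, 0.81),
    lin("eq3c", "developed", "combined", 0.9454, c(NDFI = 2.6638), 1.43, 0.78),
    lin("eq4c", "developed", "combined", -0.3821,
        c(DMI = 0.5932, NDFI = 1.3849), 0.54, 0.85),
    lin("eq5c", "developed", "combined", -0.6042,
        c(DMI = 1.0088, ADFI = 0.5422), 1.45, 0.79),
    lin("eq6c", "developed", "combined", -0.2924,
        c(MEI = 0.0702, ADFI = 2.3215), 1.52, 0.61),
    lin("eq7c", "developed", "combined", 0.7085,
        c(MEI = 0.0167, NDFI = 2.3096), 1.56, 0.79),
    lin("eq8c", "developed", "combined", -0.3496,
        c(DMI = 0.5941, NDFI = 1.388, ADFI = -0.0276), 1.47, 0.85),
    nl("combined_gompertz", "developed", "combined", "gompertz",
       a = 36.23, b = 0.956, c = 0.1058, predictor = "DMI", 3.34, 0.74),
    nl("combined_exp", "developed", "combined", "exponential",
       a = NA, b = -3.667, c = 0.0855, predictor = "DMI", 1.62, 0.81),
    nl("combined_power1", "developed", "combined", "power",
       a = NA, b = 0.782, c = 1.1087, predictor = "DMI", 2.63, 0.84),
    nl("combined_power2", "developed", "combined", "power",
       a = NA, b = 0.205, c = 0.8528, predictor = "MEI", 3.58, 0.7)
  )
}

#' Registry of CH4 prediction equations
#'
#' All extant (published) and developed (database-derived) prediction
#' equations as a named list of `ch4_equation` objects.
#'
#' @param source Optional filter: `"extant"` or `"developed"`.
#' @param database Optional filter: `"beef"`, `"dairy"`, `"combined"`,
#'   `"external"`.
#' @return Named list of `ch4_equation` objects.
#' @export
#' @examples
#' length(equation_registry("extant"))  # 7
#' equation_registry()$eq1c
equation_registry <- function(source = NULL, database = NULL) {
  if (is.null(.registry_cache$reg)) {
    reg <- build_registry()
    names(reg) <- vapply(reg, `[[`, "", "id")
    .registry_cache$reg <- reg
  }
  reg <- .registry_cache$reg
  if (!is.null(source)) {
    reg <- Filter(function(e) e$source %in% source, reg)
  }
  if (!is.null(database)) {
    reg <- Filter(function(e) e$database %in% database, reg)
  }
  reg
}

#' Look up one equation by id (or alias)
#'
#' @param id Equation id, e.g. `"eq1c"`, `"ipcc2006"`.
#' @return A `ch4_equation` object.
#' @export
get_equation <- function(id) {
  reg <- equation_registry()
  if (id %in% names(reg)) return(reg[[id]])
  for (e in reg) if (id %in% e$aliases) return(e)
  stop("unknown equation id: ", id)
}

#' Predictors an equation requires
#'
#' @param eq A `ch4_equation` (or an id string).
#' @return Character vector of required predictor names (among `DMI`, `MEI`,
#'   `GEI`, `NDFI`, `ADFI`, `BW`, `roughage`).
#' @export
#' @examples
#' required_inputs("ipcc2006")  # "GEI"
required_inputs <- function(eq) {
  if (is.character(eq)) eq <- get_equation(eq)
  if (eq$form %in% c("linear", "quadratic")) {
    unique(c(names(eq$terms), names(eq$quad)))
  } else {
    eq$predictor
  }
}

#' Build a predictor table from treatment-mean records
#'
#' Maps record columns to the predictor vocabulary of the equation registry:
#' `DMI` (kg/day), `MEI`, `GEI` (MJ/day), `NDFI`, `ADFI` (kg/day, computed
#' as `DMI x concentration / 1000` when not supplied directly), `BW` (kg),
#' `roughage` (g/kg).
#'
#' @param records Record table.
#' @return Data frame with the predictor columns (NA where underivable).
#' @export
as_predictors <- function(records) {
  dmi <- col_or_na(records, "dmi_kg_d")
  ndfi <- col_or_na(records, "ndfi_kg_d")
  adfi <- col_or_na(records, "adfi_kg_d")
  miss <- is.na(ndfi)
  ndfi[miss] <- dmi[miss] * col_or_na(records, "ndf_g_kg")[miss] / 1000
  miss <- is.na(adfi)
  adfi[miss] <- dmi[miss] * col_or_na(records, "adf_g_kg")[miss] / 1000
  data.frame(DMI = dmi, MEI = col_or_na(records, "mei_mj_d"),
             GEI = col_or_na(records, "gei_mj_d"),
             NDFI = ndfi, ADFI = adfi, BW = col_or_na(records, "bw_kg"),
             roughage = col_or_na(records, "roughage_g_kg"))
}

#' Evaluate a prediction equation
#'
#' Functional forms: linear/quadratic `B0 + sum(coef x) (+ coef x^2)`;
#' monomolecular `a - (a + b) exp(-c x)`; mitscherlich `a (1 - exp(-c x))`
#' (the monomolecular with `b = 0`); gompertz
#' `b exp[(1 - exp(-c x)) ln((a + 2b)/b)] - 2b`; exponential `|b| exp(c x)`;
#' power `b x^c`. Exponential equations whose printed intercept `b` is
#' negative (which would force negative methane) are evaluated with `|b|`
#' and carry a `sign_anomaly` flag; `literal_sign = TRUE` restores the
#' printed sign for audit. Predictions are not clipped.
#'
#' @param eq A `ch4_equation` or id string.
#' @param newdata Data frame of predictors (either predictor-vocabulary
#'   columns `DMI`, `MEI`, ... or record columns, which are mapped through
#'   [as_predictors()]).
#' @param literal_sign Use the printed (negative) `b` of flagged exponential
#'   equations instead of `|b|`.
#' @return Numeric vector of predicted CH4, MJ/day.
#' @export
#' @examples
#' predict_methane("mills_linear", data.frame(DMI = 10))  # 15.13
#' predict_methane("ipcc2006", data.frame(GEI = 200))     # 13.0
predict_methane <- function(eq, newdata, literal_sign = FALSE) {
  if (is.character(eq)) eq <- get_equation(eq)
  if (!all(required_inputs(eq) %in% names(newdata))) {
    newdata <- as_predictors(newdata)
  }
  for (p in required_inputs(eq)) {
    if (is.null(newdata[[p]]) || all(is.na(newdata[[p]]))) {
      stop("predict_methane: equation '", eq$id,
           "' requires missing predictor '", p, "'")
    }
  }
  out <- if (eq$form %in% c("linear", "quadratic")) {
    y <- rep(eq$intercept, nrow(newdata))
    for (p in names(eq$terms)) y <- y + eq$terms[[p]] * newdata[[p]]
    for (p in names(eq$quad)) y <- y + eq$quad[[p]] * newdata[[p]]^2
    y
  } else {
    x <- newdata[[eq$predictor]]
    a <- eq$params[["a"]]; b <- eq$params[["b"]]; cc <- eq$params[["c"]]
    switch(eq$form,
      monomolecular = a - (a + b) * exp(-cc * x),
      mitscherlich = a * (1 - exp(-cc * x)),
      gompertz = b * exp((1 - exp(-cc * x)) * log((a + 2 * b) / b)) - 2 * b,
      exponential = {
        bb <- if (literal_sign) b else abs(b)
        bb * exp(cc * x)
      },
      power = b * x^cc,
      stop("unknown equation form: ", eq$form))
  }
  bad <- !is.finite(out) & !is.na(out)
  if (any(bad)) {
    stop("predict_methane: non-finite prediction from '", eq$id, "'")
  }
  out
}

# ---- plain-text serialization --------------------------------------------

#' Serialize the registry to a flat table
#'
#' One row per equation with full-precision coefficients, suitable for
#' shipping as a versioned plain-text file. [read_equation_registry()] and
#' [write_equation_registry()] round-trip the table bit-exactly.
#'
#' @return Data frame with columns `id`, `source`, `database`, `form`,
#'   `intercept`, `terms`, `quad`, `a`, `b`, `c`, `predictor`,
#'   `reported_rmse`, `reported_r2`, `sign_anomaly`.
#' @export
equation_table <- function() {
  reg <- equation_registry()
  fmt <- function(x) {
    if (is.null(x) || length(x) == 0) return("")
    paste(sprintf("%s=%.17g", names(x), unname(x)), collapse = ";")
  }
  num <- function(x) if (is.null(x)) NA_real_ else x
  do.call(rbind, lapply(reg, function(e) {
    data.frame(id = e$id, source = e$source, database = e$database,
               form = e$form, intercept = num(e$intercept),
               terms = fmt(e$terms), quad = fmt(e$quad),
               a = num(e$params[["a"]]), b = num(e$params[["b"]]),
               c = num(e$params[["c"]]), predictor = e$predictor,
               reported_rmse = e$reported_rmse, reported_r2 = e$reported_r2,
               sign_anomaly = e$sign_anomaly, stringsAsFactors = FALSE)
  })) -> tab
  rownames(tab) <- NULL
  tab
}

#' @rdname equation_table
#' @param path File path for the tab-separated registry table.
#' @export
write_equation_registry <- function(path) {
  tab <- equation_table()
  num_cols <- c("intercept", "a", "b", "c", "reported_rmse", "reported_r2")
  for (cn in num_cols) tab[[cn]] <- sprintf("%.17g", tab[[cn]])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname equation_table
#' @export
read_equation_registry <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  parse_named <- function(s) {
    if (is.na(s) || s == "") return(NULL)
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
             vapply(kv, `[[`, "", 1))
  }
  eqs <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    params <- if (r$form %in% c("linear", "quadratic")) NULL else
      c(a = as.numeric(r$a), b = as.numeric(r$b), c = as.numeric(r$c))
    new_equation(r$id, r$source, r$database, r$form,
                 intercept = as.numeric(r$intercept),
                 terms = parse_named(r$terms), quad = parse_named(r$quad),
                 params = params, predictor = r$predictor,
                 reported_rmse = as.numeric(r$reported_rmse),
                 reported_r2 = as.numeric(r$reported_r2),
                 sign_anomaly = as.logical(r$sign_anomaly))
  })
  names(eqs) <- tab$id
  eqs
}
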