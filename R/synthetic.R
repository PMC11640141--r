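# Seeded synthetic treatment-mean databases with the distributional and
# study-clustering structure the meta-analysis assumes: marginals are
# moment-matched truncated normals calibrated to the per-database summary
# table, CH4 is generated from a true prediction equation plus study random
# intercept/slope and residual noise, and all derived fields are completed
# through the harmonization calculus.

#' Configuration of the synthetic-database generator
#'
#' @param database `"beef"`, `"dairy"` or `"combined"`; selects the
#'   calibration table and the default true equation (the corresponding
#'   DMI-only developed linear equation: `eq1b`, `eq2d`, `eq1c`).
#' @param n_studies Number of studies (clusters).
#' @param treatments_per_study Treatments (records) per study; scalar or
#'   length-2 range sampled uniformly per study.
#' @param true_equation Equation id or `ch4_equation` used as the
#'   data-generating mean of CH4 (MJ/day).
#' @param study_intercept_sd SD of the study random intercept, MJ/day.
#' @param study_slope_sd SD of the study random slope on DMI,
#'   (MJ/day)/(kg/day).
#' @param residual_sd Residual SD, MJ/day. Defaults to the reported RMSE of
#'   the database's DMI-only developed equation (beef 2.13, dairy 2.73,
#'   combined 3.04).
#' @param animals_per_treatment Range (length 2) of animal counts per
#'   treatment, sampled uniformly; used downstream as regression weights.
#' @param sd_scale Multiplier on all marginal SDs (0 collapses every
#'   variable to its calibration mean; used for degenerate checks).
#' @param ch4_floor Lower bound on generated CH4, MJ/day.
#' @param seed Integer seed; fully determines the output.
#' @return A validated `ch4_synth_config` list.
#' @export
synthetic_config <- function(database = c("combined", "beef", "dairy"),
                             n_studies = 34,
                             treatments_per_study = c(3, 6),
                             true_equation = NULL,
                             study_intercept_sd = 1.0,
                             study_slope_sd = 0.1,
                             residual_sd = NULL,
                             animals_per_treatment = c(4, 16),
                             sd_scale = 1,
                             ch4_floor = 0.1,
                             seed = 1L) {
  database <- match.arg(database)
  if (is.null(true_equation)) {
    true_equation <- switch(database, beef = "eq1b", dairy = "eq2d",
                            combined = "eq1c")
  }
  if (is.character(true_equation)) true_equation <- get_equation(true_equation)
  if (is.null(residual_sd)) {
    residual_sd <- switch(database, beef = 2.13, dairy = 2.73,
                          combined = 3.04)
  }
  stopifnot(n_studies >= 1, all(treatments_per_study >= 1),
            study_intercept_sd >= 0, study_slope_sd >= 0, residual_sd >= 0,
            length(animals_per_treatment) == 2,
            animals_per_treatment[1] >= 1, sd_scale >= 0, ch4_floor > 0)
  structure(list(database = database, n_studies = as.integer(n_studies),
                 treatments_per_study = as.integer(treatments_per_study),
                 true_equation = true_equation,
                 study_intercept_sd = study_intercept_sd,
                 study_slope_sd = study_slope_sd, residual_sd = residual_sd,
                 animals_per_treatment = as.integer(animals_per_treatment),
                 sd_scale = sd_scale, ch4_floor = ch4_floor,
                 seed = as.integer(seed)),
            class = "ch4_synth_config")
}

#' @export
print.ch4_synth_config <- function(x, ...) {
  cat("<ch4_synth_config>", x$database, "|", x$n_studies, "studies x",
      paste(x$treatments_per_study, collapse = "-"), "treatments | true eq:",
      x$true_equation$id, "| SDs (intercept/slope/residual):",
      x$study_intercept_sd, x$study_slope_sd, x$residual_sd, "| seed",
      x$seed, "\n")
  invisible(x)
}

# negative NDF -> OM-digestibility dependence induced structurally: OMD is
# drawn conditionally on the record's NDF with correlation rho, then clipped
# to the calibration range.
.omd_ndf_rho <- -0.5

#' Draw animal and diet variables for one study's treatments
#'
#' Draws BW, DMI, diet chemistry (OM, CP, EE, NDF, ADF, roughage) and
#' digestibilities from the calibrated truncated-normal marginals of the
#' configured database; NFC is computed by closure `OM - CP - EE - NDF`
#' (the composition block is re-drawn, up to 100 times, for records whose
#' closure value falls outside the calibration range); ADF is capped at the
#' record's NDF; OM digestibility is drawn negatively correlated with NDF
#' and GE/DM digestibilities are derived from it (plus noise) so the
#' digestibility set is internally consistent. Draws come from the current
#' RNG stream: seed it (or call via [generate_database()]) for
#' reproducibility.
#'
#' @param config A [synthetic_config()].
#' @param study_index Integer study id.
#' @param n Number of treatment records to draw.
#' @return Draft record table (no CH4 or energy fields yet).
#' @export
sample_diet_and_animal <- function(config, study_index = 1L, n = 1L) {
  stopifnot(inherits(config, "ch4_synth_config"))
  db <- config$database
  s <- config$sd_scale
  cal <- calibration_table(db)
  draw <- function(var, m = n) draw_calibrated(m, db, var, sd_scale = s)

  bw <- draw("bw_kg")
  dmi <- draw("dmi_kg_d")
  roughage <- draw("roughage_g_kg")

  # composition block with bounded re-draw for NFC closure
  nfc_cal <- cal_row(cal, "nfc_g_kg")
  om <- draw("om_g_kg"); cp <- draw("cp_g_kg"); ee <- draw("ee_g_kg")
  ndf <- draw("ndf_g_kg")
  nfc <- om - cp - ee - ndf
  if (s > 0) {
    for (iter in seq_len(100)) {
      bad <- which(nfc < nfc_cal$min | nfc > nfc_cal$max)
      if (!length(bad)) break
      m <- length(bad)
      om[bad] <- draw("om_g_kg", m); cp[bad] <- draw("cp_g_kg", m)
      ee[bad] <- draw("ee_g_kg", m); ndf[bad] <- draw("ndf_g_kg", m)
      nfc <- om - cp - ee - ndf
    }
    nfc <- pmin(pmax(nfc, nfc_cal$min), nfc_cal$max)
  }
  adf <- pmin(draw("adf_g_kg"), ndf)

  # digestibilities: OMD | NDF with negative correlation, then the GE/DM
  # members derived through the imputation regressions plus noise
  k <- regression_constants()
  ndf_cal <- cal_row(cal, "ndf_g_kg")
  omd_cal <- cal_row(cal, "dig_om_g_kg")
  z_ndf <- if (s > 0) (ndf - ndf_cal$mean) / ndf_cal$sd else rep(0, n)
  omd_mu <- omd_cal$mean + .omd_ndf_rho * omd_cal$sd * z_ndf
  omd_sd <- omd_cal$sd * sqrt(1 - .omd_ndf_rho^2) * s
  omd <- if (s > 0) {
    rtnorm(n, omd_mu, pmax(omd_sd, 1e-9), omd_cal$min, omd_cal$max)
  } else {
    rep(omd_cal$mean, n)
  }
  ged_cal <- cal_row(cal, "dig_ge_g_kg")
  ged <- k$ged_from_omd[["intercept"]] + k$ged_from_omd[["slope"]] * omd +
    rnorm(n, 0, 7.9 * s)
  ged <- pmin(pmax(ged, ged_cal$min), ged_cal$max)
  dmd_cal <- cal_row(cal, "dig_dm_g_kg")
  dmd <- (ged - k$ged_from_dmd[["intercept"]]) / k$ged_from_dmd[["slope"]] +
    rnorm(n, 0, 15 * s)
  dmd <- pmin(pmax(dmd, dmd_cal$min), dmd_cal$max)

  n_animals <- config$animals_per_treatment[1] +
    floor(runif(n) * (diff(config$animals_per_treatment) + 1))

  # cattle class: beef/dairy databases are homogeneous; for the combined
  # database a fixed 56/44 beef share (implied by the combined mean BW)
  # labels the records
  cls <- switch(db, beef = rep("beef", n), dairy = rep("dairy", n),
                combined = ifelse(runif(n) < 0.56, "beef", "dairy"))

  data.frame(study_id = sprintf("S%03d", study_index),
             treatment_id = seq_len(n), n_animals = as.integer(n_animals),
             cattle_class = cls, bw_kg = bw, dmi_kg_d = dmi,
             om_g_kg = om, cp_g_kg = cp, ee_g_kg = ee, ndf_g_kg = ndf,
             adf_g_kg = adf, nfc_g_kg = nfc, roughage_g_kg = roughage,
             dig_dm_g_kg = dmd, dig_om_g_kg = omd, dig_ge_g_kg = ged,
             dig_cp_g_kg = draw("dig_cp_g_kg"),
             dig_ndf_g_kg = draw("dig_ndf_g_kg"),
             dig_adf_g_kg = pmin(draw("dig_adf_g_kg"), 1000),
             dig_ee_g_kg = draw("dig_ee_g_kg"),
             stringsAsFactors = FALSE)
}

#' Assign the true CH4 signal and complete energy fields
#'
#' `CH4 (MJ/day) = true_equation(record) + study intercept + study slope x
#' DMI + residual`, floored at `config$ch4_floor`; GE intake is computed
#' from diet chemistry, DE intake from GE digestibility, ME intake from a
#' realistic ME:DE ratio, and FE/UE are back-derived so the energy-balance
#' identities hold exactly. All CH4 unit variants are derived from the
#' MJ/day value via [convert_methane()].
#'
#' @param records Draft record table from [sample_diet_and_animal()].
#' @param config A [synthetic_config()].
#' @param study_effects List with numeric `intercept` and `slope` (one study's
#'   draws; recycled over rows).
#' @return Completed record table.
#' @export
assign_true_methane <- function(records, config,
                                study_effects = list(intercept = 0, slope = 0)) {
  stopifnot(inherits(config, "ch4_synth_config"))
  n <- nrow(records)
  for (p in required_inputs(config$true_equation)) {
    x <- as_predictors(records)[[p]]
    if (any(is.na(x))) {
      stop("assign_true_methane: required input '", p, "' missing")
    }
  }

  # energy chain (before CH4, which feeds back into MEI)
  records$gei_mj_d <- ge_intake(records$dmi_kg_d, records)
  records$dei_mj_d <- records$gei_mj_d * records$dig_ge_g_kg / 1000
  records$fe_mj_d <- records$gei_mj_d - records$dei_mj_d

  mu <- predict_methane(config$true_equation, records)
  # treatment means from more animals are less noisy: residual SD scales as
  # sqrt(w_ref / n_animals) with w_ref = 10 (the midpoint animal count), the
  # same precision structure the animal-count regression weights assume
  rsd <- config$residual_sd * sqrt(10 / records$n_animals)
  noise <- rnorm(n, 0, rsd)
  ch4 <- mu + study_effects$intercept + study_effects$slope * records$dmi_kg_d +
    noise
  records$ch4_mj_d <- pmax(ch4, config$ch4_floor)

  # ME:DE ratio calibrated to the published energy means; UE back-derived so
  # MEI = DEI - CH4 - UE holds exactly
  me_de <- pmin(pmax(rnorm(n, 0.729, 0.05 * config$sd_scale), 0.5), 0.9)
  records$mei_mj_d <- pmin(me_de * records$dei_mj_d,
                           records$dei_mj_d - records$ch4_mj_d - 0.01)
  records$ue_mj_d <- records$dei_mj_d - records$ch4_mj_d - records$mei_mj_d
  records$q_ratio <- records$mei_mj_d / records$gei_mj_d
  records$fl_multiple <- feeding_level(records$mei_mj_d, records$bw_kg,
                                       records$q_ratio)
  records$dig_omdm_g_kg <- omd_at_maintenance(records$dig_om_g_kg,
                                              records$dmi_kg_d, records$bw_kg)

  ctx <- records
  for (u in c("g_d", "l_d", "g_kg_dm", "g_kg_om", "mj_kg_dm",
              "pct_ge", "pct_de")) {
    records[[paste0("ch4_", u)]] <- convert_methane(records$ch4_mj_d, "mj_d",
                                                    u, ctx)
  }
  records
}

#' Generate a seeded synthetic treatment-mean database
#'
#' Generates `n_studies x treatments_per_study` records; records within a
#' study share the study random intercept and slope; output is fully
#' determined by `config$seed` and writable via [write_records()].
#'
#' @param config A [synthetic_config()].
#' @return Record table of class `ch4_records` with provenance initialized
#'   (generated fields are `observed` from the pipeline's point of view).
#' @export
#' @examples
#' db <- generate_database(synthetic_config("combined", n_studies = 5,
#'                                          treatments_per_study = 3, seed = 7))
#' nrow(db)
generate_database <- function(config) {
  stopifnot(inherits(config, "ch4_synth_config"))
  set.seed(config$seed)
  tps <- config$treatments_per_study
  out <- vector("list", config$n_studies)
  for (i in seq_len(config$n_studies)) {
    n_i <- if (length(tps) == 1) tps else
      tps[1] + floor(runif(1) * (tps[2] - tps[1] + 1))
    eff <- list(intercept = rnorm(1, 0, config$study_intercept_sd) *
                  (config$study_intercept_sd > 0),
                slope = rnorm(1, 0, config$study_slope_sd) *
                  (config$study_slope_sd > 0))
    rec <- sample_diet_and_animal(config, study_index = i, n = n_i)
    out[[i]] <- assign_true_methane(rec, config, eff)
  }
  db <- do.call(rbind, out)
  rownames(db) <- NULL
  db <- prov_init(db)
  class(db) <- c("ch4_records", "data.frame")
  attr(db, "config") <- config
  db
}
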