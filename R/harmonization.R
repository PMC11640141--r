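# Harmonization calculus: completes missing energy, digestibility,
# feeding-level and CH4-unit fields of treatment-mean records, recording a
# provenance flag ("observed", "derived", "imputed") for every filled cell.

#' Gross-energy concentration of a diet
#'
#' GE concentration (MJ/kg DM) from proximate diet chemistry:
#' `(23.6 CP + 39.8 EE + 17.3 NFC + 18.9 NDF) / 1000`, all components in
#' g/kg DM.
#'
#' @param comp A list or data frame with columns `cp_g_kg`, `ee_g_kg`,
#'   `nfc_g_kg`, `ndf_g_kg` (vectorized).
#' @return GE concentration in MJ/kg DM.
#' @export
#' @examples
#' ge_concentration(list(cp_g_kg = 160, ee_g_kg = 40,
#'                       nfc_g_kg = 400, ndf_g_kg = 360))  # 19.092
ge_concentration <- function(comp) {
  k <- regression_constants()
  need <- c("cp_g_kg", "ee_g_kg", "nfc_g_kg", "ndf_g_kg")
  for (f in need) {
    if (is.null(comp[[f]])) {
      stop("ge_concentration: missing diet component '", f, "'")
    }
  }
  (k$ge_cp * comp$cp_g_kg + k$ge_ee * comp$ee_g_kg +
     k$ge_nfc * comp$nfc_g_kg + k$ge_ndf * comp$ndf_g_kg) / 1000
}

#' Gross-energy intake
#'
#' @param dmi Dry-matter intake, kg/day (> 0).
#' @param comp Diet composition as in [ge_concentration()].
#' @return GE intake in MJ/day.
#' @export
ge_intake <- function(dmi, comp) {
  if (any(!is.finite(dmi)) || any(dmi <= 0)) {
    stop("ge_intake: dmi must be positive")
  }
  dmi * ge_concentration(comp)
}

#' Feeding level as a multiple of maintenance
#'
#' `FL = MEI / ME_m` with the maintenance metabolizable-energy requirement
#' `ME_m = 0.53 (BW / 1.08)^0.67 / (0.35 q + 0.503)`, where `q = ME:GE` is
#' the metabolizability of the diet. FL is dimensionless; FL = 1 means the
#' animal eats exactly its maintenance requirement.
#'
#' @param mei Metabolizable-energy intake, MJ/day (> 0).
#' @param bw Body weight, kg (> 0).
#' @param q Metabolizability ME:GE, strictly in (0, 1).
#' @return Feeding level (multiple of maintenance).
#' @export
#' @examples
#' feeding_level(100, 500, 0.55)  # ~2.148
feeding_level <- function(mei, bw, q) {
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("feeding_level: q must lie strictly in (0, 1)")
  }
  if (any(mei <= 0) || any(bw <= 0)) {
    stop("feeding_level: mei and bw must be positive")
  }
  k <- regression_constants()
  me_m <- k$maint_scale * (bw / k$maint_bw_div)^k$maint_bw_exp /
    (k$maint_q_a * q + k$maint_q_b)
  mei / me_m
}

#' DM intake per kg body weight at a given feeding level
#'
#' Linear relation `DMI/BW (g/kg) = 13.8 + 2.195 FL`; evaluated at `fl = 1`
#' it gives the maintenance reference used by [omd_at_maintenance()].
#'
#' @param fl Feeding level (multiple of maintenance).
#' @return DM intake per body weight, g/kg.
#' @export
dmi_bw_at_maintenance <- function(fl = 1) {
  k <- regression_constants()
  k$dmi_bw_fl[["intercept"]] + k$dmi_bw_fl[["slope"]] * fl
}

#' Organic-matter digestibility adjusted to the maintenance feeding level
#'
#' Digestibility declines as intake rises, so observed OM digestibility is
#' adjusted to the maintenance level: `OMDm = OMD + 1.83 (DMI/BW_actual -
#' DMI/BW_maintenance)` with both intake ratios in g/kg and the maintenance
#' ratio taken at FL = 1 ([dmi_bw_at_maintenance()]).
#'
#' @param omd Observed OM digestibility, g/kg.
#' @param dmi DM intake, kg/day.
#' @param bw Body weight, kg.
#' @return OM digestibility at maintenance, g/kg.
#' @export
#' @examples
#' omd_at_maintenance(700, 10, 500)  # ~707.33
omd_at_maintenance <- function(omd, dmi, bw) {
  if (any(omd <= 0) || any(dmi <= 0) || any(bw <= 0)) {
    stop("omd_at_maintenance: all inputs must be positive")
  }
  k <- regression_constants()
  omd + k$omd_fl_slope * (1000 * dmi / bw - dmi_bw_at_maintenance(1))
}

#' Impute missing digestibilities
#'
#' Completes a partial digestibility set with the imputation regressions,
#' applied in precedence order until no further field can be filled:
#' \enumerate{
#'   \item `OM  = 40.4 + 0.966 x GE digestibility`
#'   \item `GE  = 9.6  + 0.84  x OM digestibility`
#'   \item `GE  = 16.2 + 0.765 x DM digestibility`
#' }
#' Observed values are never overwritten.
#'
#' @param dig Named list or one-row data frame with any of `dm`, `om`, `ge`
#'   digestibility values in g/kg (missing entries `NA` or absent).
#' @return A named list with `dm`, `om`, `ge` (imputed where derivable) and
#'   an `imputed` character vector naming the filled fields.
#' @export
#' @examples
#' impute_digestibility(list(ge = 700))$om  # 716.6
impute_digestibility <- function(dig) {
  k <- regression_constants()
  get1 <- function(f) {
    v <- dig[[f]]
    if (is.null(v) || length(v) == 0 || is.na(v)) NA_real_ else as.numeric(v)
  }
  out <- list(dm = get1("dm"), om = get1("om"), ge = get1("ge"))
  if (all(is.na(unlist(out)))) {
    stop("impute_digestibility: need at least one of OM, GE, DM digestibility")
  }
  imputed <- character(0)
  repeat {
    changed <- FALSE
    if (is.na(out$om) && !is.na(out$ge)) {
      out$om <- k$omd_from_ged[["intercept"]] + k$omd_from_ged[["slope"]] * out$ge
      imputed <- c(imputed, "om"); changed <- TRUE
    } else if (is.na(out$ge) && !is.na(out$om)) {
      out$ge <- k$ged_from_omd[["intercept"]] + k$ged_from_omd[["slope"]] * out$om
      imputed <- c(imputed, "ge"); changed <- TRUE
    } else if (is.na(out$ge) && !is.na(out$dm)) {
      out$ge <- k$ged_from_dmd[["intercept"]] + k$ged_from_dmd[["slope"]] * out$dm
      imputed <- c(imputed, "ge"); changed <- TRUE
    }
    if (!changed) break
  }
  out$imputed <- imputed
  out
}

# ---- CH4 unit conversion --------------------------------------------------

.ch4_units <- c("g_d", "l_d", "mj_d", "kcal_d",
                "g_kg_dm", "g_kg_om", "mj_kg_dm", "pct_ge", "pct_de")

# family of each unit: mass (g), volume (L) or energy (MJ) after the
# intensity denominator is removed
.ch4_family <- c(g_d = "g", l_d = "l", mj_d = "mj", kcal_d = "mj",
                 g_kg_dm = "g", g_kg_om = "g", mj_kg_dm = "mj",
                 pct_ge = "mj", pct_de = "mj")

ch4_context_value <- function(unit, context) {
  need <- switch(unit,
    g_kg_dm = "dmi_kg_d", mj_kg_dm = "dmi_kg_d",
    g_kg_om = c("dmi_kg_d", "om_g_kg"),
    pct_ge = "gei_mj_d", pct_de = "dei_mj_d",
    NULL)
  if (is.null(need)) return(NULL)
  for (f in need) {
    v <- context[[f]]
    if (is.null(v) || any(is.na(v))) {
      stop("convert_methane: unit '", unit, "' needs context field '", f, "'")
    }
  }
  switch(unit,
    g_kg_dm = , mj_kg_dm = context$dmi_kg_d,
    g_kg_om = context$dmi_kg_d * context$om_g_kg / 1000,
    pct_ge = context$gei_mj_d / 100,
    pct_de = context$dei_mj_d / 100)
}

#' Convert a CH4 quantity between units
#'
#' Exact chained conversion among daily mass (`g_d`), volume (`l_d`),
#' energy (`mj_d`, `kcal_d`) and intensity units (`g_kg_dm`, `g_kg_om`,
#' `mj_kg_dm`, `pct_ge`, `pct_de`). Published factors are used as printed:
#' 0.714 g/L, 39.54 kJ/L, 55.65 kJ/g, 4.184 kJ/kcal. Litre-based values are
#' converted to energy with 39.54 kJ/L directly (never via grams), so every
#' from/to pair round-trips to machine precision even though the printed
#' constants are not mutually consistent.
#'
#' @param value Numeric quantity (vectorized).
#' @param from,to Unit codes among
#'   `r paste0('\x60', c("g_d","l_d","mj_d","kcal_d","g_kg_dm","g_kg_om","mj_kg_dm","pct_ge","pct_de"), '\x60', collapse = ", ")`.
#' @param context List or one-row record supplying `dmi_kg_d`, `om_g_kg`,
#'   `gei_mj_d`, `dei_mj_d` as required by intensity/percentage units.
#' @return Converted quantity.
#' @export
#' @examples
#' convert_methane(100, "g_d", "mj_d")  # 5.565
#' convert_methane(1, "l_d", "g_d")     # 0.714
convert_methane <- function(value, from, to, context = list()) {
  from <- match.arg(from, .ch4_units)
  to <- match.arg(to, .ch4_units)
  if (from == to) return(value)
  k <- regression_constants()

  # strip intensity denominator -> daily value in the unit's own family
  denom_from <- ch4_context_value(from, context)
  daily <- if (is.null(denom_from)) value else value * denom_from
  fam_from <- .ch4_family[[from]]
  if (from == "kcal_d") daily <- daily * k$kj_per_kcal / 1000  # -> MJ/d

  fam_to <- .ch4_family[[to]]
  daily_to <- if (fam_from == fam_to) {
    daily
  } else if (fam_from == "g" && fam_to == "mj") {
    daily * k$kj_per_g_ch4 / 1000
  } else if (fam_from == "mj" && fam_to == "g") {
    daily * 1000 / k$kj_per_g_ch4
  } else if (fam_from == "l" && fam_to == "g") {
    daily * k$g_per_l_ch4
  } else if (fam_from == "g" && fam_to == "l") {
    daily / k$g_per_l_ch4
  } else if (fam_from == "l" && fam_to == "mj") {
    daily * k$kj_per_l_ch4 / 1000
  } else if (fam_from == "mj" && fam_to == "l") {
    daily * 1000 / k$kj_per_l_ch4
  } else {
    stop("convert_methane: no conversion path from '", from, "' to '", to, "'")
  }
  if (to == "kcal_d") daily_to <- daily_to * 1000 / k$kj_per_kcal

  denom_to <- ch4_context_value(to, context)
  if (is.null(denom_to)) daily_to else daily_to / denom_to
}

# ---- provenance helpers ---------------------------------------------------

#' Provenance flags of a record table
#'
#' Harmonization records, for every numeric cell it fills, whether the value
#' was `observed` (present in the input), `derived` (exact arithmetic on
#' observed values) or `imputed` (from an imputation regression).
#'
#' @param records A record table processed by [harmonize()].
#' @return A character data frame parallel to `records`, or `NULL` if the
#'   table carries no provenance.
#' @export
provenance <- function(records) attr(records, "provenance")

prov_init <- function(records) {
  p <- attr(records, "provenance")
  if (!is.null(p)) return(records)
  p <- as.data.frame(lapply(records, function(col) {
    ifelse(is.na(col), NA_character_, "observed")
  }), stringsAsFactors = FALSE)
  attr(records, "provenance") <- p
  records
}

prov_mark <- function(records, rows, col, flag) {
  p <- attr(records, "provenance")
  if (!col %in% names(p)) p[[col]] <- NA_character_
  p[rows, col] <- flag
  attr(records, "provenance") <- p
  records
}

# fill records[[col]] where missing and `values` is available; mark provenance
fill_field <- function(records, col, values, flag) {
  if (!col %in% names(records)) records[[col]] <- NA_real_
  idx <- which(is.na(records[[col]]) & !is.na(values))
  if (length(idx)) {
    records[[col]][idx] <- values[idx]
    records <- prov_mark(records, idx, col, flag)
  }
  records
}

col_or_na <- function(records, col) {
  if (col %in% names(records)) records[[col]] else rep(NA_real_, nrow(records))
}

# ---- energy balance -------------------------------------------------------

#' Complete the energy-balance identity chain of a record table
#'
#' Fills every derivable member of `DEI = GEI - FE` and
#' `MEI = DEI - CH4 - UE` (all MJ/day), and `q = MEI / GEI` when both are
#' known, iterating until no further field can be derived. Filled fields are
#' flagged `derived`; underdetermined fields stay missing. When all members
#' of an identity are present but disagree by more than `tol` (relative),
#' a consistency error is raised.
#'
#' @param records Record table (see [read_records()] for the schema).
#' @param tol Relative tolerance for the consistency check (default 0.005,
#'   i.e. 0.5%, matching the rounding of published treatment means).
#' @return The completed record table with updated provenance.
#' @export
complete_energy_balance <- function(records, tol = 0.005) {
  records <- prov_init(records)
  gei <- function() col_or_na(records, "gei_mj_d")
  dei <- function() col_or_na(records, "dei_mj_d")
  mei <- function() col_or_na(records, "mei_mj_d")
  fe  <- function() col_or_na(records, "fe_mj_d")
  ue  <- function() col_or_na(records, "ue_mj_d")
  ch4 <- function() col_or_na(records, "ch4_mj_d")

  # consistency of fully observed identities, before any filling
  full1 <- !is.na(gei()) & !is.na(dei()) & !is.na(fe())
  bad1 <- full1 & abs(gei() - fe() - dei()) > tol * pmax(gei(), 1e-9)
  full2 <- !is.na(dei()) & !is.na(mei()) & !is.na(ue()) & !is.na(ch4())
  bad2 <- full2 & abs(dei() - ch4() - ue() - mei()) > tol * pmax(dei(), 1e-9)
  if (any(bad1, na.rm = TRUE) || any(bad2, na.rm = TRUE)) {
    stop("complete_energy_balance: energy identities violated beyond ",
         tol * 100, "% in row(s) ",
         paste(which(bad1 | bad2), collapse = ", "))
  }

  repeat {
    before <- list(gei(), dei(), mei(), fe(), ue(), ch4())
    records <- fill_field(records, "dei_mj_d", gei() - fe(), "derived")
    records <- fill_field(records, "gei_mj_d", dei() + fe(), "derived")
    records <- fill_field(records, "fe_mj_d",  gei() - dei(), "derived")
    records <- fill_field(records, "mei_mj_d", dei() - ch4() - ue(), "derived")
    records <- fill_field(records, "dei_mj_d", mei() + ch4() + ue(), "derived")
    records <- fill_field(records, "ue_mj_d",  dei() - ch4() - mei(), "derived")
    records <- fill_field(records, "ch4_mj_d", dei() - mei() - ue(), "derived")
    after <- list(gei(), dei(), mei(), fe(), ue(), ch4())
    if (identical(before, after)) break
  }
  records <- fill_field(records, "q_ratio", mei() / gei(), "derived")
  records
}

# ---- full harmonization ---------------------------------------------------

validate_records <- function(records) {
  pos_fields <- c("bw_kg", "dmi_kg_d", "gei_mj_d", "dei_mj_d", "mei_mj_d",
                  "ch4_mj_d", "ch4_g_d", "n_animals")
  bad <- character(0)
  for (f in intersect(pos_fields, names(records))) {
    if (any(records[[f]] <= 0, na.rm = TRUE)) bad <- c(bad, f)
  }
  if ("q_ratio" %in% names(records) &&
      any(records$q_ratio <= 0 | records$q_ratio >= 1, na.rm = TRUE)) {
    bad <- c(bad, "q_ratio")
  }
  if (all(c("ndf_g_kg", "adf_g_kg") %in% names(records)) &&
      any(records$adf_g_kg > records$ndf_g_kg, na.rm = TRUE)) {
    bad <- c(bad, "adf_g_kg>ndf_g_kg")
  }
  if (length(bad)) {
    stop("record validation failed for field(s): ", paste(bad, collapse = ", "))
  }
  invisible(records)
}

#' Harmonize a treatment-mean record table
#'
#' Applies, in order: schema validation and composition closure
#' (`NFC = OM - CP - EE - NDF` filled when missing, closure violations
#' beyond `closure_tol` rejected); recovery of daily CH4 values from
#' whichever unit was reported; GE intake from diet chemistry; the
#' energy-balance chain ([complete_energy_balance()]); digestibility
#' imputation ([impute_digestibility()]); feeding level ([feeding_level()]);
#' OM digestibility at maintenance ([omd_at_maintenance()]); and completion
#' of all remaining CH4 units. Fields that remain underivable stay missing;
#' every change is recorded in the provenance table; the operation is
#' idempotent.
#'
#' @param records Record table (see [read_records()]).
#' @param tol Relative tolerance of the energy-identity consistency check.
#' @param closure_tol Allowed excess of `CP + EE + NDF + NFC` over OM,
#'   g/kg DM (default 20, the rounding scale of published treatment means).
#' @return Harmonized record table with a provenance attribute
#'   ([provenance()]).
#' @export
harmonize <- function(records, tol = 0.005, closure_tol = 20) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  validate_records(records)
  records <- prov_init(records)
  n <- nrow(records)

  # composition closure
  comp_ok <- all(c("om_g_kg", "cp_g_kg", "ee_g_kg", "ndf_g_kg") %in%
                   names(records))
  if (comp_ok) {
    nfc_calc <- records$om_g_kg - records$cp_g_kg - records$ee_g_kg -
      records$ndf_g_kg
    records <- fill_field(records, "nfc_g_kg", pmax(nfc_calc, 0), "derived")
    sums <- records$cp_g_kg + records$ee_g_kg + records$ndf_g_kg +
      col_or_na(records, "nfc_g_kg")
    bad <- which(sums - records$om_g_kg > closure_tol)
    if (length(bad)) {
      stop("harmonize: composition closure violated (CP+EE+NDF+NFC > OM + ",
           closure_tol, " g/kg) in row(s) ", paste(bad, collapse = ", "))
    }
  }

  # recover daily CH4 from whatever was reported
  dmi <- col_or_na(records, "dmi_kg_d")
  ctx <- list(dmi_kg_d = dmi, om_g_kg = col_or_na(records, "om_g_kg"),
              gei_mj_d = col_or_na(records, "gei_mj_d"),
              dei_mj_d = col_or_na(records, "dei_mj_d"))
  ctx_ok <- function(unit) {
    switch(unit, g_kg_dm = , mj_kg_dm = !is.na(ctx$dmi_kg_d),
           g_kg_om = !is.na(ctx$dmi_kg_d) & !is.na(ctx$om_g_kg),
           pct_ge = !is.na(ctx$gei_mj_d),
           pct_de = !is.na(ctx$dei_mj_d),
           rep(TRUE, n))
  }
  safe_conv <- function(value, from, to) {
    out <- rep(NA_real_, n)
    ok <- !is.na(value) & ctx_ok(from) & ctx_ok(to)
    if (any(ok)) {
      out[ok] <- convert_methane(value[ok], from, to,
                                 lapply(ctx, function(v) v[ok]))
    }
    out
  }
  records <- fill_field(records, "ch4_mj_d",
                        safe_conv(col_or_na(records, "ch4_g_d"), "g_d", "mj_d"),
                        "derived")
  records <- fill_field(records, "ch4_mj_d",
                        safe_conv(col_or_na(records, "ch4_l_d"), "l_d", "mj_d"),
                        "derived")
  records <- fill_field(records, "ch4_mj_d",
                        safe_conv(col_or_na(records, "ch4_mj_kg_dm"),
                                  "mj_kg_dm", "mj_d"), "derived")
  records <- fill_field(records, "ch4_mj_d",
                        safe_conv(col_or_na(records, "ch4_g_kg_dm"),
                                  "g_kg_dm", "mj_d"), "derived")
  records <- fill_field(records, "ch4_g_d",
                        safe_conv(col_or_na(records, "ch4_mj_d"), "mj_d", "g_d"),
                        "derived")

  # GE intake from diet chemistry
  if (comp_ok && "dmi_kg_d" %in% names(records)) {
    ok <- !is.na(dmi) & dmi > 0 & !is.na(records$cp_g_kg) &
      !is.na(records$ee_g_kg) & !is.na(col_or_na(records, "nfc_g_kg")) &
      !is.na(records$ndf_g_kg)
    gei_calc <- rep(NA_real_, n)
    if (any(ok)) {
      gei_calc[ok] <- ge_intake(dmi[ok], records[ok, , drop = FALSE])
    }
    records <- fill_field(records, "gei_mj_d", gei_calc, "derived")
  }

  # energy balance (also refreshes ctx fields used below)
  records <- complete_energy_balance(records, tol = tol)

  # digestibility imputation
  dig_cols <- c(dm = "dig_dm_g_kg", om = "dig_om_g_kg", ge = "dig_ge_g_kg")
  if (any(dig_cols %in% names(records))) {
    dmv <- col_or_na(records, dig_cols[["dm"]])
    omv <- col_or_na(records, dig_cols[["om"]])
    gev <- col_or_na(records, dig_cols[["ge"]])
    for (i in seq_len(n)) {
      if (all(is.na(c(dmv[i], omv[i], gev[i])))) next
      res <- impute_digestibility(list(dm = dmv[i], om = omv[i], ge = gev[i]))
      for (f in res$imputed) {
        col <- dig_cols[[f]]
        if (!col %in% names(records)) records[[col]] <- NA_real_
        if (is.na(records[[col]][i])) {
          records[[col]][i] <- res[[f]]
          records <- prov_mark(records, i, col, "imputed")
        }
      }
    }
  }

  # feeding level
  mei <- col_or_na(records, "mei_mj_d")
  q <- col_or_na(records, "q_ratio")
  bw <- col_or_na(records, "bw_kg")
  ok <- !is.na(mei) & !is.na(bw) & !is.na(q) & q > 0 & q < 1 & mei > 0 & bw > 0
  fl <- rep(NA_real_, n)
  if (any(ok)) fl[ok] <- feeding_level(mei[ok], bw[ok], q[ok])
  records <- fill_field(records, "fl_multiple", fl, "derived")

  # OM digestibility at maintenance
  omd <- col_or_na(records, "dig_om_g_kg")
  ok <- !is.na(omd) & !is.na(dmi) & !is.na(bw) & omd > 0 & dmi > 0 & bw > 0
  omdm <- rep(NA_real_, n)
  if (any(ok)) omdm[ok] <- omd_at_maintenance(omd[ok], dmi[ok], bw[ok])
  records <- fill_field(records, "dig_omdm_g_kg", omdm, "derived")

  # complete remaining CH4 units from the MJ/day value
  ctx <- list(dmi_kg_d = dmi, om_g_kg = col_or_na(records, "om_g_kg"),
              gei_mj_d = col_or_na(records, "gei_mj_d"),
              dei_mj_d = col_or_na(records, "dei_mj_d"))
  mj <- col_or_na(records, "ch4_mj_d")
  for (u in c("g_d", "l_d", "g_kg_dm", "g_kg_om", "mj_kg_dm",
              "pct_ge", "pct_de")) {
    records <- fill_field(records, paste0("ch4_", u),
                          safe_conv(mj, "mj_d", u), "derived")
  }
  records
}
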