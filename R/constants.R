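#' Fixed constants of the harmonization calculus
#'
#' Returns the fixed coefficients used when completing treatment-mean records:
#' the gross-energy concentration coefficients (MJ/kg per g/kg of crude
#' protein, ether extract, non-fibrous carbohydrate and NDF), the
#' digestibility imputation regressions, the feeding-level / maintenance
#' constants, the intake-dependence slope of organic-matter digestibility,
#' and the CH4 / energy unit-conversion factors.
#'
#' The conversion factors are used exactly as published even though they are
#' not mutually consistent (0.714 g/L x 55.65 kJ/g = 39.73 kJ/L, not 39.54):
#' litre-based quantities are converted to energy with 39.54 kJ/L directly
#' and never chained through grams, so each from/to pair round-trips exactly.
#'
#' @return A named list of constants, invariant across calls.
#' @export
#' @examples
#' regression_constants()$kj_per_g_ch4  # 55.65
regression_constants <- function() {
  list(
    # GE concentration (MJ/kg DM) = sum(coef * g/kg)/1000
    ge_cp = 23.6, ge_ee = 39.8, ge_nfc = 17.3, ge_ndf = 18.9,
    # digestibility imputation (g/kg), in precedence order
    omd_from_ged  = c(intercept = 40.4, slope = 0.966),
    ged_from_omd  = c(intercept = 9.6,  slope = 0.84),
    ged_from_dmd  = c(intercept = 16.2, slope = 0.765),
    # DMI/BW (g/kg) as a function of feeding level
    dmi_bw_fl     = c(intercept = 13.8, slope = 2.195),
    # OM digestibility shift per g/kg of DMI/BW above maintenance
    omd_fl_slope  = 1.83,
    # maintenance ME requirement scale (MJ per kg^0.67 unit, see feeding_level)
    maint_scale   = 0.53,
    maint_bw_div  = 1.08,
    maint_bw_exp  = 0.67,
    maint_q_a     = 0.35,
    maint_q_b     = 0.503,
    # unit conversions
    g_per_l_ch4   = 0.714,
    kj_per_l_ch4  = 39.54,
    kj_per_g_ch4  = 55.65,
    kj_per_kcal   = 4.184
  )
}
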