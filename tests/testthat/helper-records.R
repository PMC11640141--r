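# Shared fixtures: small record tables built in code.

# a fully specified, internally consistent single record
consistent_record <- function() {
  gei <- 190.92 # 10 kg/d x 19.092 MJ/kg
  dei <- 130
  ch4 <- 10
  ue <- 6
  data.frame(study_id = "S001", treatment_id = 1L, n_animals = 8L,
             cattle_class = "beef", bw_kg = 500, dmi_kg_d = 10,
             om_g_kg = 960, cp_g_kg = 160, ee_g_kg = 40, ndf_g_kg = 360,
             adf_g_kg = 250, nfc_g_kg = 400, roughage_g_kg = 600,
             gei_mj_d = gei, dei_mj_d = dei, mei_mj_d = dei - ch4 - ue,
             fe_mj_d = gei - dei, ue_mj_d = ue,
             dig_om_g_kg = 700, ch4_mj_d = ch4,
             stringsAsFactors = FALSE)
}

# clustered records with a known linear CH4 signal in DMI and pure noise
# covariates, for model-development tests
linear_records <- function(n_studies = 12, per_study = 8, b0 = 1, b1 = 0.8,
                           intercept_sd = 0, slope_sd = 0, resid_sd = 0) {
  n <- n_studies * per_study
  study <- rep(sprintf("S%03d", seq_len(n_studies)), each = per_study)
  dmi <- runif(n, 3, 25)
  s_i <- rep(rnorm(n_studies, 0, intercept_sd), each = per_study)
  b_i <- rep(rnorm(n_studies, 0, slope_sd), each = per_study)
  data.frame(study_id = study, n_animals = sample(4:16, n, replace = TRUE),
             dmi_kg_d = dmi, bw_kg = runif(n, 200, 700),
             roughage_g_kg = runif(n, 100, 1000),
             ch4_mj_d = b0 + (b1 + b_i) * dmi + s_i + rnorm(n, 0, resid_sd),
             stringsAsFactors = FALSE)
}
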