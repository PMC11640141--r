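test_that("GE concentration and intake follow the diet-chemistry formula", {
  comp <- list(cp_g_kg = 160, ee_g_kg = 40, nfc_g_kg = 400, ndf_g_kg = 360)
  expect_equal(ge_concentration(comp),
               (23.6 * 160 + 39.8 * 40 + 17.3 * 400 + 18.9 * 360) / 1000)
  expect_equal(ge_concentration(list(cp_g_kg = 0, ee_g_kg = 0, nfc_g_kg = 0,
                                     ndf_g_kg = 0)), 0)
  expect_equal(ge_concentration(list(cp_g_kg = 1000, ee_g_kg = 0,
                                     nfc_g_kg = 0, ndf_g_kg = 0)), 23.6)
  expect_equal(ge_intake(10, comp), 190.92)
  expect_equal(ge_intake(4, comp), 2 * ge_intake(2, comp))  # linearity
  expect_error(ge_intake(0, comp), "positive")
  expect_error(ge_concentration(list(cp_g_kg = 1)), "ee_g_kg")
})

test_that("feeding level matches the maintenance-requirement form", {
  me_m <- 0.53 * (500 / 1.08)^0.67 / (0.35 * 0.55 + 0.503)
  expect_equal(feeding_level(100, 500, 0.55), 100 / me_m)
  expect_equal(feeding_level(me_m, 500, 0.55), 1)  # maintenance itself
  fl <- feeding_level(c(50, 100, 150), 500, 0.55)
  expect_true(all(diff(fl) > 0))  # monotone in MEI
  expect_error(feeding_level(100, 500, 1.2), "q")
})

test_that("maintenance DMI/BW and the OMDm adjustment are as specified", {
  expect_equal(dmi_bw_at_maintenance(1), 15.995)
  expect_equal(dmi_bw_at_maintenance(0), 13.8)
  expect_equal(dmi_bw_at_maintenance(3) - dmi_bw_at_maintenance(2), 2.195)
  expect_equal(omd_at_maintenance(700, 10, 500), 700 + 1.83 * (20 - 15.995))
  # zero adjustment exactly at the maintenance intake ratio
  bw <- 500; dmi <- 15.995 * bw / 1000 / 1000 * 1000
  expect_equal(omd_at_maintenance(700, dmi, bw), 700)
  # slope of the adjustment is 1.83 per g/kg of DMI/BW
  d1 <- omd_at_maintenance(700, 10, 500)
  d2 <- omd_at_maintenance(700, 10.5, 500)  # +1 g/kg DMI/BW
  expect_equal(d2 - d1, 1.83)
})

test_that("digestibility imputation follows the printed precedence", {
  expect_equal(impute_digestibility(list(ge = 700))$om, 40.4 + 0.966 * 700)
  expect_equal(impute_digestibility(list(om = 700))$ge, 9.6 + 0.84 * 700)
  expect_equal(impute_digestibility(list(dm = 700))$ge, 16.2 + 0.765 * 700)
  # observed values never overwritten
  both <- impute_digestibility(list(om = 700, ge = 650))
  expect_equal(both$om, 700)
  expect_equal(both$ge, 650)
  expect_length(both$imputed, 0)
  expect_error(impute_digestibility(list()), "at least one")
})

test_that("imputation cascade agrees with a brute-force precedence oracle", {
  # oracle: apply the three rules exhaustively, but record which rule fires
  # first for each missing field under the listed order
  oracle <- function(dm, om, ge) {
    rules <- list(
      list(target = "om", source = "ge", f = function(v) 40.4 + 0.966 * v),
      list(target = "ge", source = "om", f = function(v) 9.6 + 0.84 * v),
      list(target = "ge", source = "dm", f = function(v) 16.2 + 0.765 * v))
    s <- list(dm = dm, om = om, ge = ge)
    repeat {
      fired <- FALSE
      for (r in rules) {
        if (is.na(s[[r$target]]) && !is.na(s[[r$source]])) {
          s[[r$target]] <- r$f(s[[r$source]]); fired <- TRUE; break
        }
      }
      if (!fired) break
    }
    s
  }
  cases <- expand.grid(dm = c(NA, 650), om = c(NA, 700), ge = c(NA, 690))
  cases <- cases[rowSums(!is.na(cases)) > 0, ]
  for (i in seq_len(nrow(cases))) {
    got <- impute_digestibility(as.list(cases[i, ]))
    want <- oracle(cases$dm[i], cases$om[i], cases$ge[i])
    expect_equal(got[c("dm", "om", "ge")], want, tolerance = 1e-12)
  }
})

test_that("CH4 unit conversions reproduce the published constants", {
  expect_equal(convert_methane(1, "g_d", "mj_d") * 1000, 55.65)
  expect_equal(convert_methane(1, "l_d", "g_d"), 0.714)
  expect_equal(convert_methane(1, "l_d", "mj_d") * 1000, 39.54)
  expect_equal(convert_methane(1000, "kcal_d", "mj_d"), 4.184)
  expect_equal(convert_methane(100, "g_d", "mj_d"), 5.565)
  ctx <- list(dmi_kg_d = 10, om_g_kg = 920, gei_mj_d = 200, dei_mj_d = 140)
  expect_equal(convert_methane(10, "mj_d", "pct_ge", ctx), 5)
  expect_equal(convert_methane(10, "mj_d", "g_kg_dm", ctx),
               10 * 1000 / 55.65 / 10)
  expect_error(convert_methane(10, "mj_d", "pct_ge", list()), "gei_mj_d")
})

test_that("unit conversions are invertible to 1e-12 relative", {
  ctx <- list(dmi_kg_d = 12.3, om_g_kg = 915, gei_mj_d = 210, dei_mj_d = 150)
  units <- c("g_d", "l_d", "mj_d", "kcal_d", "g_kg_dm", "g_kg_om",
             "mj_kg_dm", "pct_ge", "pct_de")
  for (from in units) {
    for (to in units) {
      v <- 7.77
      back <- convert_methane(convert_methane(v, from, to, ctx), to, from, ctx)
      expect_equal(back, v, tolerance = 1e-12)
    }
  }
})

test_that("energy balance fills derivable members and flags them", {
  r <- data.frame(study_id = "S1", dei_mj_d = 128.55, ch4_mj_d = 10.87,
                  ue_mj_d = 5, stringsAsFactors = FALSE)
  out <- complete_energy_balance(r)
  expect_equal(out$mei_mj_d, 128.55 - 10.87 - 5)
  expect_equal(provenance(out)$mei_mj_d, "derived")
  r2 <- data.frame(study_id = "S1", gei_mj_d = 200, fe_mj_d = 60)
  expect_equal(complete_energy_balance(r2)$dei_mj_d, 140)
  # fully observed consistent record: untouched, no derived flags
  rc <- consistent_record()
  out <- complete_energy_balance(rc)
  expect_equal(as.data.frame(out)[names(rc)], rc, ignore_attr = TRUE)
  num_cols <- names(rc)[vapply(rc, is.numeric, TRUE)]
  expect_false(any(provenance(out)[num_cols] == "derived", na.rm = TRUE))
  # contradiction beyond tolerance is an error
  bad <- consistent_record()
  bad$dei_mj_d <- bad$gei_mj_d - bad$fe_mj_d + 5
  expect_error(complete_energy_balance(bad), "identities violated")
})

test_that("harmonize completes a minimal record and is idempotent", {
  r <- data.frame(study_id = "S1", n_animals = 8L, bw_kg = 500,
                  dmi_kg_d = 10, om_g_kg = 960, cp_g_kg = 160, ee_g_kg = 40,
                  ndf_g_kg = 360, adf_g_kg = 250,
                  ch4_g_d = 180, stringsAsFactors = FALSE)
  h <- harmonize(r)
  expect_equal(h$nfc_g_kg, 960 - 160 - 40 - 360)
  expect_equal(h$gei_mj_d, 10 * 19.092)
  expect_equal(h$ch4_mj_d, 180 * 55.65 / 1000)
  expect_equal(h$ch4_pct_ge, 100 * h$ch4_mj_d / h$gei_mj_d)
  expect_equal(provenance(h)$gei_mj_d, "derived")
  expect_equal(provenance(h)$ch4_g_d, "observed")
  h2 <- harmonize(h)
  expect_equal(as.data.frame(h2), as.data.frame(h), ignore_attr = TRUE)
  # fully complete consistent record is a fixed point
  rc <- harmonize(consistent_record())
  expect_equal(as.data.frame(harmonize(rc)), as.data.frame(rc),
               ignore_attr = TRUE)
})

test_that("energy monotonicity GEI >= DEI >= MEI holds after harmonization", {
  db <- generate_database(synthetic_config("combined", n_studies = 8,
                                           treatments_per_study = 4,
                                           seed = 21))
  h <- harmonize(as.data.frame(db))
  expect_true(all(h$gei_mj_d >= h$dei_mj_d - 1e-9))
  expect_true(all(h$dei_mj_d >= h$mei_mj_d - 1e-9))
})

test_that("harmonize never overwrites observed fields", {
  r <- consistent_record()
  r$ch4_pct_ge <- 99  # deliberately inconsistent observed value
  h <- harmonize(r)
  expect_equal(h$ch4_pct_ge, 99)
  expect_equal(provenance(h)$ch4_pct_ge, "observed")
})

test_that("schema violations are rejected with the offending fields", {
  r <- consistent_record()
  r$bw_kg <- -5
  expect_error(harmonize(r), "bw_kg")
  r <- consistent_record()
  r$adf_g_kg <- r$ndf_g_kg + 50
  expect_error(harmonize(r), "adf")
})
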