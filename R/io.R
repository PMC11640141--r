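# Fixed CSV schema for treatment-mean records. Column names encode units;
# one row = one treatment mean; missing = empty cell. Unknown columns are
# preserved as passthrough.

.schema_numeric <- c(
  "n_animals", "bw_kg", "dmi_kg_d",
  "om_g_kg", "cp_g_kg", "ee_g_kg", "ndf_g_kg", "adf_g_kg", "nfc_g_kg",
  "roughage_g_kg",
  "gei_mj_d", "dei_mj_d", "mei_mj_d", "fe_mj_d", "ue_mj_d", "q_ratio",
  "fl_multiple",
  "dig_dm_g_kg", "dig_om_g_kg", "dig_ge_g_kg", "dig_omdm_g_kg",
  "dig_cp_g_kg", "dig_ndf_g_kg", "dig_adf_g_kg", "dig_ee_g_kg",
  "ch4_g_d", "ch4_mj_d", "ch4_l_d", "ch4_g_kg_dm", "ch4_g_kg_om",
  "ch4_mj_kg_dm", "ch4_pct_ge", "ch4_pct_de")

.schema_mandatory <- c("study_id", "dmi_kg_d")

#' Record-table CSV schema
#'
#' @return Character vector of the recognized column names (`study_id`,
#'   `treatment_id`, `cattle_class` plus the numeric unit-suffixed columns).
#' @export
record_schema <- function() {
  c("study_id", "treatment_id", "cattle_class", .schema_numeric)
}

#' Read a treatment-mean record table
#'
#' Reads the pipeline CSV schema with typed, unit-checked columns. The
#' mandatory columns are `study_id` and `dmi_kg_d`; unknown columns are kept
#' as passthrough; malformed numeric cells and negative quantities are
#' reported with their row.
#'
#' @param path CSV file path.
#' @return Record table (`ch4_records` data frame).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("read_records: no such file: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE)
  missing_cols <- setdiff(.schema_mandatory, names(raw))
  if (length(missing_cols)) {
    stop("read_records: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- raw
  for (cn in intersect(.schema_numeric, names(raw))) {
    v <- raw[[cn]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      stop("read_records: malformed numeric cell in column '", cn,
           "', row(s) ", paste(bad, collapse = ", "))
    }
    neg <- which(num < 0)
    if (length(neg)) {
      stop("read_records: negative value in column '", cn, "', row(s) ",
           paste(neg, collapse = ", "))
    }
    out[[cn]] <- num
  }
  if ("n_animals" %in% names(out)) out$n_animals <- as.integer(out$n_animals)
  if ("treatment_id" %in% names(out)) {
    out$treatment_id <- suppressWarnings(as.integer(out$treatment_id))
  }
  out <- prov_init(out)
  class(out) <- c("ch4_records", "data.frame")
  out
}

#' Write a record table (and optional provenance sidecar)
#'
#' @param records Record table.
#' @param path Output CSV path.
#' @param provenance_path Optional path for the provenance sidecar CSV
#'   (written only when the table carries provenance).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, provenance_path = NULL) {
  write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  p <- provenance(records)
  if (!is.null(provenance_path) && !is.null(p)) {
    write.csv(p, provenance_path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @export
print.ch4_records <- function(x, ...) {
  cat("<ch4_records>", nrow(x), "treatment means,",
      length(unique(x$study_id)), "studies\n")
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
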