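#' Reproduce the cohort analysis end to end
#'
#' Runs the full modality-concordance analysis on a planning cohort (by
#' default the packaged 24-patient table): per-modality target-volume
#' medians and ranges; Lin CCC (with 95\% CI) and R-squared of each planning
#' modality against the post-therapy PET/CT reference, over the full cohort
#' and the selective, changed-administration-excluded, and combined
#' subgroups; and the fictitious 1 GBq dose comparison. Because the cohort
#' table does not carry per-patient TNR, tumor volume or shunt fraction, the
#' dose comparison draws those from the cohort-level distributions
#' (TNR 2.6 +/- 1.5, HPS 6.9\% +/- 3.4\%) under the given seed, so its dose
#' medians are simulation-conditioned and are reported as non-reproducible
#' published quantities, with the reason recorded.
#'
#' Each published value the analysis can recompute is checked after rounding
#' to the published precision (1 decimal for ml medians, 2 for CCC). Checks
#' whose published value is inconsistent with the published per-patient
#' table itself (the table is the ground truth here) are marked
#' `discrepant_in_source` and reported with the computed value rather than
#' counted as failures; see the package vignette for the audit.
#'
#' @param out_dir If non-`NULL`, directory (created if needed) receiving
#'   `report.json` and `report.md`.
#' @param seed Integer seed for the synthetic dosimetric inputs.
#' @param cohort A `cohort_table` (default: the packaged fixture).
#' @return A `re_report` list: `medians`, `agreement`, `dose_summary`,
#'   `approach_tests`, `checks`, `all_pass`, `seed`.
#' @examples
#' rep <- reproduce_analysis(seed = 1)
#' rep$all_pass
#' @export
reproduce_analysis <- function(out_dir = NULL, seed = 1L,
                            cohort = load_cohort("builtin")) {
  seed <- as.integer(seed)

  ## --- volume medians -------------------------------------------------
  med_row <- function(modality, values) {
    s <- median_summary(values)
    data.frame(modality = modality, n = s$n, median_ml = s$median,
               min_ml = s$min, max_ml = s$max, stringsAsFactors = FALSE)
  }
  medians <- rbind(
    med_row("cect", cohort$tgv_cect_ml),
    med_row("cbct", cohort$tgv_cbct_ml[!is.na(cohort$tgv_cbct_ml)]),
    med_row("maa", cohort$tgv_maa_ml),
    med_row("pet", cohort$tgv_pet_ml))

  ## --- agreement ------------------------------------------------------
  agree_row <- function(label, modality, subgroup) {
    sub <- select_subgroup(cohort, subgroup)
    x <- sub[[paste0("tgv_", modality, "_ml")]]
    y <- sub$tgv_pet_ml
    cc <- lin_ccc(x, y)
    r2 <- tryCatch(r_squared(x, y)$r2, error = function(e) NA_real_)
    data.frame(analysis = label, modality = modality, subgroup = subgroup,
               n = cc$n, ccc = cc$ccc, ci_low = cc$ci_low,
               ci_high = cc$ci_high, r2 = r2, stringsAsFactors = FALSE)
  }
  sel_cohort <- select_subgroup(cohort, "selective_only")
  agreement <- rbind(
    agree_row("ccc_cect_all", "cect", "all"),
    agree_row("ccc_cbct_available", "cbct", "all"),
    agree_row("ccc_maa_all", "maa", "all"),
    agree_row("ccc_maa_exclude_changed", "maa", "exclude_changed"),
    agree_row("ccc_cect_selective", "cect", "selective_only"),
    agree_row("ccc_cbct_selective", "cbct", "selective_only"),
    agree_row("ccc_maa_selective", "maa", "selective_only"),
    agree_row("ccc_maa_selective_exclude_changed", "maa",
              "selective_exclude_changed"),
    agree_row("ccc_cbct_selective_exclude_changed", "cbct",
              "selective_exclude_changed"))

  ## --- fictitious 1 GBq dose comparison -------------------------------
  set.seed(seed)
  n <- nrow(cohort)
  tnr <- rnorm_trunc(n, 2.6, 1.5, lower = 1)
  hps <- rnorm_trunc(n, 0.069, 0.034, lower = 0, upper = 0.2)
  min_tgv <- pmin(cohort$tgv_cect_ml, cohort$tgv_maa_ml, cohort$tgv_pet_ml,
                  cohort$tgv_cbct_ml, na.rm = TRUE)
  patients <- data.frame(patient_id = cohort$patient_id,
                         tumor_ml = stats::runif(n, 0.15, 0.45) * min_tgv,
                         tnr = tnr, hps = hps,
                         tgv_cect_ml = cohort$tgv_cect_ml,
                         tgv_cbct_ml = cohort$tgv_cbct_ml,
                         tgv_maa_ml = cohort$tgv_maa_ml,
                         tgv_pet_ml = cohort$tgv_pet_ml,
                         lobar_or_total = cohort$lobar_or_total,
                         stringsAsFactors = FALSE)
  dose_tab <- modality_dose_table(patients, activity_gbq = 1)
  dose_sum <- summary(dose_tab)

  ## --- reproduction checks against the published summary values -------
  ref <- published_reference()
  checks <- list()
  add_check <- function(name, computed, published, status, note = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, computed = computed, published = published,
      pass = identical(status, "reproduced") ||
             (status == "expected" && !is.na(published) &&
              computed == published),
      status = if (status == "expected")
        ifelse(computed == published, "reproduced", "failed") else status,
      note = note, stringsAsFactors = FALSE)
  }
  for (m in medians$modality) {
    add_check(paste0("median_tgv_", m),
              round(medians$median_ml[medians$modality == m], 1),
              ref$medians[[m]], "expected")
  }
  for (nm in names(ref$ccc_reproducible)) {
    add_check(nm, round(agreement$ccc[agreement$analysis == nm], 2),
              ref$ccc_reproducible[[nm]], "expected")
  }
  for (nm in names(ref$ccc_discrepant)) {
    add_check(nm, round(agreement$ccc[agreement$analysis == nm], 2),
              ref$ccc_discrepant[[nm]], "discrepant_in_source",
              "published value inconsistent with the published per-patient table; computed value reported")
  }
  r2_rows <- c(r2_cect_all = "ccc_cect_all",
               r2_cbct_available = "ccc_cbct_available",
               r2_maa_all = "ccc_maa_all")
  for (nm in names(r2_rows)) {
    add_check(nm, round(agreement$r2[agreement$analysis == r2_rows[[nm]]], 2),
              ref$r2[[nm]], "discrepant_in_source",
              "published value inconsistent with the published per-patient table; computed value reported")
  }
  for (nm in names(ref$dose_medians)) {
    add_check(nm,
              round(dose_sum$doses$median_dose_tumor_gy[
                dose_sum$doses$modality == sub("median_tumor_dose_", "", nm)],
                0),
              ref$dose_medians[[nm]], "not_reproducible",
              "per-patient TNR and tumor volumes are not published; dose inputs are simulated, so this median is simulation-conditioned")
  }
  checks <- do.call(rbind, checks)
  all_pass <- !any(checks$status == "failed")

  report <- structure(list(medians = medians, agreement = agreement,
                           dose_summary = dose_sum,
                           dose_table = dose_tab,
                           checks = checks, all_pass = all_pass,
                           seed = seed, schema_version = "1.0"),
                      class = "re_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, out_dir)
  }
  report
}

# Published cohort-level summary values used only to flag, in the report,
# which recomputed quantities reproduce the published analysis.
published_reference <- function() {
  list(
    medians = c(cect = 558.5, cbct = 626, maa = 798.5, pet = 957),
    ccc_reproducible = c(ccc_cect_all = 0.72, ccc_cbct_available = 0.71,
                         ccc_maa_all = 0.85, ccc_maa_exclude_changed = 0.97,
                         ccc_cbct_selective = 0.67,
                         ccc_maa_selective_exclude_changed = 0.95,
                         ccc_cbct_selective_exclude_changed = 0.73),
    ccc_discrepant = c(ccc_cect_selective = 0.5, ccc_maa_selective = 0.71),
    r2 = c(r2_cect_all = 0.68, r2_cbct_available = 0.66, r2_maa_all = 0.96),
    dose_medians = c(median_tumor_dose_cect = 152,
                     median_tumor_dose_cbct = 125,
                     median_tumor_dose_maa = 116,
                     median_tumor_dose_reference = 102))
}

write_report <- function(report, out_dir) {
  json_path <- file.path(out_dir, "report.json")
  payload <- list(schema_version = report$schema_version, seed = report$seed,
                  all_pass = report$all_pass,
                  medians = report$medians, agreement = report$agreement,
                  dose_summary = report$dose_summary$doses,
                  checks = report$checks)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)

  md <- c("# Radioembolization planning cohort report", "",
          sprintf("Seed: %d. Schema %s.", report$seed,
                  report$schema_version), "",
          "## Target volume medians (ml)", "",
          df_md(report$medians), "",
          "## Agreement with the PET/CT reference volume", "",
          df_md(transform(report$agreement,
                          ccc = round(ccc, 3), ci_low = round(ci_low, 3),
                          ci_high = round(ci_high, 3), r2 = round(r2, 3))),
          "",
          "## Fictitious 1 GBq dose comparison (simulated TNR / tumor volume / HPS)",
          "", df_md(round_df(report$dose_summary$doses, 1)), "",
          "## Reproduction checks", "", df_md(report$checks), "",
          sprintf("All reproducible checks pass: %s",
                  ifelse(report$all_pass, "yes", "no")))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

df_md <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE) else as.character(col)
  })
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  c(header, sep, body)
}

#' @export
print.re_report <- function(x, ...) {
  cat("Radioembolization cohort reproduction report (seed", x$seed, ")\n\n")
  cat("Target volume medians (ml):\n")
  print(round_df(x$medians, 1), row.names = FALSE)
  cat("\nAgreement with the PET/CT reference volume:\n")
  print(round_df(x$agreement[c("analysis", "n", "ccc", "ci_low", "ci_high",
                               "r2")], 3), row.names = FALSE)
  cat("\nChecks:", sum(x$checks$status == "reproduced"), "reproduced,",
      sum(x$checks$status == "failed"), "failed,",
      sum(x$checks$status == "discrepant_in_source"),
      "discrepant in source,",
      sum(x$checks$status == "not_reproducible"), "not reproducible\n")
  cat("All reproducible checks pass:", ifelse(x$all_pass, "yes", "no"), "\n")
  invisible(x)
}
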