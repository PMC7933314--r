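#' Load a radioembolization planning cohort
#'
#' Reads a cohort table of per-patient target volumes (TgV) obtained with the
#' imaging modalities used during radioembolization work-up: contrast-enhanced
#' CT (CECT), C-arm cone-beam CT (CBCT), 99mTc-MAA SPECT/CT, and the
#' post-therapy 90Y PET/CT reference. The package ships a built-in 24-patient
#' cohort (`path = "builtin"`) with, per patient, the MAA injection sites and
#' split fractions, the four TgVs in ml, the prescribed 90Y activities per
#' artery in GBq, and two subgroup flags: pure lobar/total administrations and
#' patients whose administration changed between the MAA simulation and the
#' 90Y treatment.
#'
#' The CSV dialect is comma-separated UTF-8 with a header row, one row per
#' patient. An empty `tgv_cbct_ml` cell means CBCT volumetry was not
#' evaluable for that patient. The `maa_injections` and `prescribed_gbq`
#' columns hold semicolon-joined `label:value` pairs; MAA values are split
#' fractions in \[0, 1\], prescription values are activities in GBq.
#'
#' @param path Path to a cohort CSV, or `"builtin"` for the packaged fixture.
#' @return A validated `cohort_table`: a data frame with one row per patient
#'   and columns `patient_id`, `maa_injections`, `tgv_cect_ml`,
#'   `tgv_cbct_ml`, `tgv_maa_ml`, `prescribed_gbq`, `tgv_pet_ml`,
#'   `lobar_or_total`, `changed_administration`.
#' @examples
#' cohort <- load_cohort()
#' nrow(cohort)                       # 24
#' sum(is.na(cohort$tgv_cbct_ml))     # 5 patients without evaluable CBCT
#' @seealso [select_subgroup()], [write_cohort()], [injection_table()]
#' @export
load_cohort <- function(path = "builtin") {
  if (identical(path, "builtin")) {
    path <- system.file("extdata", "table1_cohort.csv", package = "rembo",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(
                           patient_id = "integer",
                           maa_injections = "character",
                           tgv_cect_ml = "numeric",
                           tgv_cbct_ml = "numeric",
                           tgv_maa_ml = "numeric",
                           prescribed_gbq = "character",
                           tgv_pet_ml = "numeric",
                           lobar_or_total = "integer",
                           changed_administration = "integer"))
  required <- c("patient_id", "maa_injections", "tgv_cect_ml", "tgv_cbct_ml",
                "tgv_maa_ml", "prescribed_gbq", "tgv_pet_ml",
                "lobar_or_total", "changed_administration")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[required]
  raw$lobar_or_total <- as.logical(raw$lobar_or_total)
  raw$changed_administration <- as.logical(raw$changed_administration)
  cohort <- as_cohort_table(raw, provenance = path)
  cohort
}

#' Construct and validate a cohort table
#'
#' @param x A data frame with the columns documented in [load_cohort()].
#' @param provenance Free-text origin tag stored as an attribute.
#' @return A `cohort_table`.
#' @export
as_cohort_table <- function(x, provenance = "in-memory") {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  validate_cohort(x)
  class(x) <- c("cohort_table", "data.frame")
  attr(x, "provenance") <- provenance
  x
}

# Validation enforces the domain invariants: positive volumes where present,
# unique sorted patient ids, MAA split fractions summing to 1 within 0.01.
# Errors name the offending row so malformed files are diagnosable.
validate_cohort <- function(x) {
  n <- nrow(x)
  if (n == 0) return(invisible(x))
  if (anyNA(x$patient_id)) {
    stop("cohort row ", which(is.na(x$patient_id))[1],
         ": missing patient_id", call. = FALSE)
  }
  if (anyDuplicated(x$patient_id)) {
    stop("duplicate patient_id: ",
         x$patient_id[duplicated(x$patient_id)][1], call. = FALSE)
  }
  if (is.unsorted(x$patient_id)) {
    stop("patient_id values must be sorted increasingly", call. = FALSE)
  }
  for (col in c("tgv_cect_ml", "tgv_maa_ml", "tgv_pet_ml")) {
    bad <- which(is.na(x[[col]]) | x[[col]] <= 0)
    if (length(bad) > 0) {
      stop("cohort row ", bad[1], " (patient ", x$patient_id[bad[1]],
           "): ", col, " must be a positive volume", call. = FALSE)
    }
  }
  bad_cbct <- which(!is.na(x$tgv_cbct_ml) & x$tgv_cbct_ml <= 0)
  if (length(bad_cbct) > 0) {
    stop("cohort row ", bad_cbct[1], " (patient ",
         x$patient_id[bad_cbct[1]],
         "): tgv_cbct_ml must be positive when present", call. = FALSE)
  }
  if (anyNA(x$lobar_or_total) || anyNA(x$changed_administration)) {
    stop("subgroup flags must be TRUE/FALSE with no missing values",
         call. = FALSE)
  }
  for (i in seq_len(n)) {
    inj <- parse_injections(x$maa_injections[i])
    if (nrow(inj) == 0) {
      stop("cohort row ", i, " (patient ", x$patient_id[i],
           "): no MAA injection sites", call. = FALSE)
    }
    if (any(inj$value < 0 | inj$value > 1)) {
      stop("cohort row ", i, " (patient ", x$patient_id[i],
           "): MAA split fractions must lie in [0, 1]", call. = FALSE)
    }
    if (abs(sum(inj$value) - 1) > 0.01 + 1e-9) {
      stop("cohort row ", i, " (patient ", x$patient_id[i],
           "): MAA split fractions sum to ", format(sum(inj$value)),
           ", expected 1 within 0.01", call. = FALSE)
    }
    rx <- parse_injections(x$prescribed_gbq[i])
    if (any(rx$value < 0)) {
      stop("cohort row ", i, " (patient ", x$patient_id[i],
           "): prescribed activities must be non-negative", call. = FALSE)
    }
  }
  invisible(x)
}

# "label:value;label:value" -> data.frame(artery, value)
parse_injections <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(artery = character(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2)) {
    stop("malformed injection field: '", s, "'", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
  if (anyNA(vals)) stop("malformed injection field: '", s, "'", call. = FALSE)
  data.frame(artery = vapply(kv, `[`, "", 1), value = vals,
             stringsAsFactors = FALSE)
}

serialize_injections <- function(df) {
  paste(sprintf("%s:%s", df$artery, format(df$value, trim = TRUE,
                                           scientific = FALSE)),
        collapse = ";")
}

#' Per-artery injections for one patient
#'
#' @param cohort A `cohort_table`.
#' @param patient_id Patient identifier.
#' @param what `"maa"` for the MAA split fractions (sum to 1), or
#'   `"prescribed"` for the prescribed 90Y activities in GBq.
#' @return A data frame with columns `artery` and `value`.
#' @examples
#' injection_table(load_cohort(), 1, "maa")
#' @export
injection_table <- function(cohort, patient_id, what = c("maa", "prescribed")) {
  what <- match.arg(what)
  i <- match(patient_id, cohort$patient_id)
  if (is.na(i)) stop("no patient with id ", patient_id, call. = FALSE)
  col <- if (what == "maa") "maa_injections" else "prescribed_gbq"
  parse_injections(cohort[[col]][i])
}

#' Select an analysis subgroup of the cohort
#'
#' Subgroups mirror the analyses of interest in modality-concordance studies:
#' restricting to selective (segmental/subsegmental) administrations,
#' excluding patients whose administration changed between the MAA simulation
#' and the treatment, or keeping only patients with evaluable CBCT volumetry.
#'
#' @param cohort A `cohort_table`.
#' @param selector One of `"all"`, `"selective_only"` (drop pure lobar/total
#'   rows), `"exclude_changed"`, `"selective_exclude_changed"`,
#'   `"cbct_available"`.
#' @return A `cohort_table` with the selected rows.
#' @examples
#' nrow(select_subgroup(load_cohort(), "selective_only"))   # 17
#' nrow(select_subgroup(load_cohort(), "exclude_changed"))  # 20
#' @export
select_subgroup <- function(cohort,
                            selector = c("all", "selective_only",
                                         "exclude_changed",
                                         "selective_exclude_changed",
                                         "cbct_available")) {
  selector <- match.arg(selector)
  keep <- switch(selector,
    all = rep(TRUE, nrow(cohort)),
    selective_only = !cohort$lobar_or_total,
    exclude_changed = !cohort$changed_administration,
    selective_exclude_changed =
      !cohort$lobar_or_total & !cohort$changed_administration,
    cbct_available = !is.na(cohort$tgv_cbct_ml))
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "provenance") <- paste0(attr(cohort, "provenance"),
                                    " [", selector, "]")
  out
}

#' Write a cohort table to CSV
#'
#' Inverse of [load_cohort()]: `load_cohort(write_cohort(x, f))` returns a
#' table identical to `x`.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  out$lobar_or_total <- as.integer(out$lobar_or_total)
  out$changed_administration <- as.integer(out$changed_administration)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Radioembolization cohort:", nrow(x), "patients",
      sprintf("(%d without CBCT, %d lobar/total, %d changed administration)\n",
              sum(is.na(x$tgv_cbct_ml)), sum(x$lobar_or_total),
              sum(x$changed_administration)))
  cat("Provenance:", attr(x, "provenance"), "\n\n")
  print.data.frame(x, ...)
  invisible(x)
}
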