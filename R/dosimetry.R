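#' Physical constants for 90Y dosimetry
#'
#' The MIRD dose factor for yttrium-90 under local energy deposition,
#' 49.67 Gy.kg/GBq, a soft-tissue density of 1.03 g/ml used to convert
#' volumes to masses, and the conventional 1.0 kg lung mass. All three are
#' exposed so alternative conventions can be plugged in.
#'
#' @param dose_gy_kg_per_gbq Absorbed dose per unit activity concentration
#'   (Gy.kg/GBq) for complete 90Y decay.
#' @param density_g_ml Tissue density (g/ml) for volume-to-mass conversion.
#' @param lung_mass_kg Reference lung mass (kg).
#' @return Named list of the three constants.
#' @export
dose_constants <- function(dose_gy_kg_per_gbq = 49.67,
                           density_g_ml = 1.03,
                           lung_mass_kg = 1.0) {
  stopifnot(dose_gy_kg_per_gbq > 0, density_g_ml > 0, lung_mass_kg > 0)
  list(dose_gy_kg_per_gbq = dose_gy_kg_per_gbq,
       density_g_ml = density_g_ml,
       lung_mass_kg = lung_mass_kg)
}

#' Partition-model absorbed doses for radioembolization
#'
#' Splits an administered 90Y activity A among lung, tumor and normal-liver
#' compartments and converts each to an absorbed dose. The lung receives the
#' hepatopulmonary shunt fraction, \eqn{A_{lung} = A \cdot HPS}; the hepatic
#' remainder \eqn{A_h = A (1 - HPS)} is partitioned by activity
#' concentration, with the tumor concentrating `tnr` times the normal
#' parenchyma:
#' \deqn{A_t = A_h \frac{TNR \cdot M_t}{TNR \cdot M_t + M_n}, \qquad
#'       A_n = A_h - A_t,}
#' where masses are \eqn{M = V \rho / 1000} kg. Each compartment dose is
#' \eqn{D = 49.67 \, A / M} Gy with the lung mass fixed at 1 kg.
#'
#' @param activity_gbq Administered activity A (GBq), >= 0.
#' @param tumor_ml Tumor volume V_t (ml), >= 0.
#' @param normal_ml Non-tumoral (normal liver) volume V_n within the target
#'   (ml), > 0.
#' @param tnr Tumor-to-normal activity concentration ratio, > 0.
#' @param hps Hepatopulmonary shunt fraction in \[0, 1).
#' @param constants See [dose_constants()].
#' @return A `dose_report`: list with `dose_tumor_gy`, `dose_normal_gy`,
#'   `dose_lung_gy`, `activity_tumor_gbq`, `activity_normal_gbq`,
#'   `activity_lung_gbq`, and the echoed inputs.
#' @examples
#' partition_dose(1, tumor_ml = 100, normal_ml = 900, tnr = 2.6, hps = 0.069)
#' @export
partition_dose <- function(activity_gbq, tumor_ml, normal_ml, tnr, hps = 0,
                           constants = dose_constants()) {
  stopifnot(is.numeric(activity_gbq), activity_gbq >= 0,
            is.numeric(tumor_ml), tumor_ml >= 0,
            is.numeric(normal_ml), normal_ml > 0,
            is.numeric(tnr), tnr > 0,
            is.numeric(hps), hps >= 0, hps < 1)
  rho <- constants$density_g_ml
  m_t <- tumor_ml * rho / 1000   # kg
  m_n <- normal_ml * rho / 1000
  if (m_n <= 0) stop("normal compartment mass must be positive", call. = FALSE)

  a_lung <- activity_gbq * hps
  a_hep <- activity_gbq - a_lung
  w_t <- tnr * m_t / (tnr * m_t + m_n)
  a_t <- a_hep * w_t
  a_n <- a_hep - a_t

  k <- constants$dose_gy_kg_per_gbq
  d_t <- if (m_t > 0) k * a_t / m_t else 0
  d_n <- k * a_n / m_n
  d_lung <- k * a_lung / constants$lung_mass_kg

  structure(list(dose_tumor_gy = d_t, dose_normal_gy = d_n,
                 dose_lung_gy = d_lung,
                 activity_tumor_gbq = a_t, activity_normal_gbq = a_n,
                 activity_lung_gbq = a_lung,
                 activity_gbq = activity_gbq, tumor_ml = tumor_ml,
                 normal_ml = normal_ml, tnr = tnr, hps = hps),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, digits = 2, ...) {
  cat("Partition-model dose report (A =", format(x$activity_gbq), "GBq, TNR =",
      format(x$tnr), ", HPS =", format(x$hps), ")\n")
  m <- rbind(tumor = c(x$activity_tumor_gbq, x$dose_tumor_gy),
             normal = c(x$activity_normal_gbq, x$dose_normal_gy),
             lung = c(x$activity_lung_gbq, x$dose_lung_gy))
  colnames(m) <- c("activity_gbq", "dose_gy")
  print(round(m, digits))
  invisible(x)
}

#' Single-compartment (uniform) absorbed dose
#'
#' The single-compartment MIRD model assumes the hepatic activity is
#' distributed uniformly within the target volume:
#' \eqn{D = 49.67 \, A (1 - HPS) / (\rho \, TgV / 1000)} Gy.
#' Equivalent to [partition_dose()] with `tnr = 1` (both compartments then
#' receive this same dose).
#'
#' @param activity_gbq Administered activity (GBq).
#' @param tgv_ml Target volume (ml), > 0.
#' @param hps Hepatopulmonary shunt fraction in \[0, 1).
#' @param constants See [dose_constants()].
#' @return Absorbed dose in Gy.
#' @examples
#' uniform_dose(1, 957)  # about 50.4 Gy
#' @export
uniform_dose <- function(activity_gbq, tgv_ml, hps = 0,
                         constants = dose_constants()) {
  stopifnot(is.numeric(tgv_ml))
  if (any(tgv_ml <= 0)) stop("target volume must be positive", call. = FALSE)
  mass_kg <- tgv_ml * constants$density_g_ml / 1000
  constants$dose_gy_kg_per_gbq * activity_gbq * (1 - hps) / mass_kg
}

#' Activity prescription policy
#'
#' Thresholds for the prescription rules: the safe normal-liver dose cap
#' (40 Gy, protecting against radioembolization-induced liver disease), the
#' tumoricidal tumor-dose floor (strictly above 100 Gy), the target-volume
#' fraction below which a target is considered "small" (60\% of the whole
#' liver), and the spared-volume fraction below which a cirrhotic patient is
#' dosed by the safety cap (40\%).
#'
#' @param cirrhotic Whether the patient has cirrhosis (impaired reserve).
#' @param normal_cap_gy Maximum safe normal-compartment dose (Gy).
#' @param tumoricidal_floor_gy Tumor dose that must be strictly exceeded (Gy).
#' @param small_tgv_fraction TgV/whole-liver cut for the "small target" rule.
#' @param spared_fraction_cut Spared-volume fraction cut for cirrhotic rule.
#' @param epsilon_gy Margin used to realise the strict ">" of the floor.
#' @return A `prescription_policy` list.
#' @export
prescription_policy <- function(cirrhotic = FALSE, normal_cap_gy = 40,
                                tumoricidal_floor_gy = 100,
                                small_tgv_fraction = 0.60,
                                spared_fraction_cut = 0.40,
                                epsilon_gy = 1e-6) {
  stopifnot(normal_cap_gy > 0, tumoricidal_floor_gy > 0,
            small_tgv_fraction > 0, spared_fraction_cut > 0, epsilon_gy > 0)
  structure(list(cirrhotic = isTRUE(cirrhotic), normal_cap_gy = normal_cap_gy,
                 tumoricidal_floor_gy = tumoricidal_floor_gy,
                 small_tgv_fraction = small_tgv_fraction,
                 spared_fraction_cut = spared_fraction_cut,
                 epsilon_gy = epsilon_gy),
            class = "prescription_policy")
}

#' Prescribe an administered activity
#'
#' Solves the partition model (linear in A) for the activity satisfying the
#' binding constraint of the applicable rule:
#' \itemize{
#'   \item cirrhotic patient with spared volume fraction below the cut:
#'     the largest A keeping the normal-compartment dose at or below the
#'     40 Gy cap (binding: D_n = cap);
#'   \item non-cirrhotic patient with a small target
#'     (TgV/whole liver below 60\%): the smallest A making the tumor dose
#'     strictly exceed 100 Gy (binding: D_t = floor + epsilon);
#'   \item otherwise: the smaller of the two candidate activities, so the
#'     safety cap can never be exceeded.
#' }
#'
#' @param policy A [prescription_policy()].
#' @param tumor_ml,normal_ml Tumor and normal volumes within the target (ml).
#' @param whole_liver_ml Whole liver volume (ml); must be at least the TgV.
#' @param tnr Tumor-to-normal ratio.
#' @param hps Hepatopulmonary shunt fraction.
#' @param constants See [dose_constants()].
#' @return List with `activity_gbq`, `rule` (one of `"safety_cap"`,
#'   `"tumoricidal"`, `"combined"`), `rationale` text, and the `dose_report`
#'   at the prescribed activity.
#' @export
prescribe_activity <- function(policy, tumor_ml, normal_ml, whole_liver_ml,
                               tnr, hps = 0, constants = dose_constants()) {
  stopifnot(inherits(policy, "prescription_policy"),
            tumor_ml >= 0, normal_ml > 0, whole_liver_ml > 0)
  tgv <- tumor_ml + normal_ml
  if (tgv > whole_liver_ml) {
    stop("target volume (", format(tgv), " ml) exceeds whole liver (",
         format(whole_liver_ml), " ml)", call. = FALSE)
  }
  per_gbq <- partition_dose(1, tumor_ml, normal_ml, tnr, hps, constants)
  a_cap <- policy$normal_cap_gy / per_gbq$dose_normal_gy
  a_floor <- if (per_gbq$dose_tumor_gy > 0) {
    (policy$tumoricidal_floor_gy + policy$epsilon_gy) / per_gbq$dose_tumor_gy
  } else Inf

  spared <- 1 - tgv / whole_liver_ml
  tgv_frac <- tgv / whole_liver_ml
  if (policy$cirrhotic && spared < policy$spared_fraction_cut) {
    a <- a_cap; rule <- "safety_cap"
    rationale <- sprintf(
      "cirrhotic with spared volume %.0f%% < %.0f%%: activity set so normal dose = %g Gy",
      100 * spared, 100 * policy$spared_fraction_cut, policy$normal_cap_gy)
  } else if (!policy$cirrhotic && tgv_frac < policy$small_tgv_fraction) {
    a <- a_floor; rule <- "tumoricidal"
    rationale <- sprintf(
      "non-cirrhotic, TgV %.0f%% < %.0f%% of liver: smallest activity with tumor dose > %g Gy",
      100 * tgv_frac, 100 * policy$small_tgv_fraction,
      policy$tumoricidal_floor_gy)
  } else {
    a <- min(a_cap, a_floor); rule <- "combined"
    rationale <- sprintf(
      "intermediate case: min of safety-cap (%.3f GBq) and tumoricidal (%.3f GBq) activities, cap binding",
      a_cap, a_floor)
  }
  list(activity_gbq = a, rule = rule, rationale = rationale,
       dose_report = partition_dose(a, tumor_ml, normal_ml, tnr, hps,
                                    constants))
}

#' Split a prescribed activity across feeding arteries
#'
#' When a tumor is fed by several arteries, the total activity is divided in
#' proportion to the tumor volume perfused by each feeding artery (as
#' assessed, e.g., on cone-beam CT).
#'
#' @param per_artery_tumor_ml Non-negative perfused tumor volumes, at least
#'   one positive.
#' @param total_activity_gbq Total activity to distribute (GBq).
#' @return Numeric vector of per-artery activities summing to the total;
#'   names are preserved.
#' @examples
#' split_activity(c(seg_VIII = 32, seg_IV = 68), 1.0)  # 0.32 and 0.68 GBq
#' @export
split_activity <- function(per_artery_tumor_ml, total_activity_gbq) {
  v <- per_artery_tumor_ml
  stopifnot(is.numeric(v), all(v >= 0), total_activity_gbq >= 0)
  if (sum(v) <= 0) stop("all perfused volumes are zero", call. = FALSE)
  total_activity_gbq * v / sum(v)
}

#' Percent change of absorbed dose relative to a planning modality
#'
#' \eqn{100 (D_{ref} - D_{mod}) / D_{mod}}: positive when the reference
#' (post-therapy) dose exceeds the dose predicted with the planning
#' modality's target volume, negative when the planning modality
#' overestimated the dose.
#'
#' @param dose_ref_gy Reference dose (Gy), e.g. from the post-therapy volume.
#' @param dose_modality_gy Planning-modality dose (Gy), > 0.
#' @return Percent change (vectorized).
#' @export
percent_change <- function(dose_ref_gy, dose_modality_gy) {
  if (any(dose_modality_gy <= 0)) {
    stop("modality dose must be positive", call. = FALSE)
  }
  100 * (dose_ref_gy - dose_modality_gy) / dose_modality_gy
}

#' Per-patient, per-modality dose comparison at a fixed activity
#'
#' For each patient, runs the partition model once per imaging modality,
#' holding the tumor volume, TNR and HPS fixed (TNR is always the one
#' measured on MAA SPECT/CT) and letting only the target volume vary by
#' modality; the normal compartment is `TgV_modality - tumor_ml`. A fixed
#' fictitious activity (default 1 GBq) makes the dose differences attributable
#' purely to the volumetry. Tumor and normal doses of each planning modality
#' are then compared with the reference-modality doses via [percent_change()].
#'
#' Rows where a modality TgV does not exceed the tumor volume cannot form a
#' positive normal compartment; they are excluded for that modality and
#' recorded in the `excluded` attribute.
#'
#' @param patients Data frame with columns `patient_id`, `tumor_ml`, `tnr`,
#'   `hps`, one TgV column per planning modality (named in `modalities`), a
#'   reference TgV column (`reference`), and optionally `lobar_or_total` for
#'   subgroup summaries.
#' @param modalities Named character vector mapping modality label to TgV
#'   column name.
#' @param reference Name of the reference TgV column.
#' @param activity_gbq Fictitious activity (GBq) applied to every patient.
#' @param constants See [dose_constants()].
#' @return A `modality_dose_table`: long data frame with one row per patient
#'   and modality (including the reference), doses, and percent changes
#'   versus the reference. Attributes: `excluded` (data frame of skipped
#'   rows) and `activity_gbq`.
#' @export
modality_dose_table <- function(patients,
                                modalities = c(cect = "tgv_cect_ml",
                                               cbct = "tgv_cbct_ml",
                                               maa = "tgv_maa_ml"),
                                reference = "tgv_pet_ml",
                                activity_gbq = 1,
                                constants = dose_constants()) {
  needed <- c("patient_id", "tumor_ml", "tnr", "hps", reference)
  stopifnot(all(needed %in% names(patients)))
  cols <- c(modalities, reference = reference)
  rows <- list(); excluded <- list()
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    ref_dose <- NULL
    for (mod in names(cols)) {
      tgv <- p[[cols[[mod]]]]
      if (is.na(tgv)) next
      v_n <- tgv - p$tumor_ml
      if (v_n <= 0) {
        excluded[[length(excluded) + 1]] <- data.frame(
          patient_id = p$patient_id, modality = mod, tgv_ml = tgv,
          reason = "TgV does not exceed tumor volume",
          stringsAsFactors = FALSE)
        next
      }
      dr <- partition_dose(activity_gbq, p$tumor_ml, v_n, p$tnr, p$hps,
                           constants)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = p$patient_id, modality = mod, tgv_ml = tgv,
        dose_tumor_gy = dr$dose_tumor_gy, dose_normal_gy = dr$dose_normal_gy,
        lobar_or_total = if ("lobar_or_total" %in% names(p))
          p$lobar_or_total else NA,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # percent change of each planning modality against the reference doses
  ref <- out[out$modality == "reference", ]
  out$pct_change_tumor <- NA_real_
  out$pct_change_normal <- NA_real_
  idx <- match(out$patient_id, ref$patient_id)
  plan <- out$modality != "reference" & !is.na(idx)
  out$pct_change_tumor[plan] <- percent_change(
    ref$dose_tumor_gy[idx[plan]], out$dose_tumor_gy[plan])
  out$pct_change_normal[plan] <- percent_change(
    ref$dose_normal_gy[idx[plan]], out$dose_normal_gy[plan])
  rownames(out) <- NULL
  structure(out,
            excluded = if (length(excluded)) do.call(rbind, excluded)
                       else NULL,
            activity_gbq = activity_gbq,
            class = c("modality_dose_table", "data.frame"))
}

#' Summarise a modality dose table
#'
#' Per-modality medians (and ranges) of tumor and normal doses, median and
#' mean percent changes versus the reference, and, when approach flags are
#' present, the lobar/total versus selective comparison of tumor-dose percent
#' change ([approach_comparison()]).
#'
#' @param object A [modality_dose_table()].
#' @param ... Unused.
#' @return A list with `doses` (data frame of per-modality summaries) and
#'   `approach_tests` (per-modality t-test results or `NULL`).
#' @export
summary.modality_dose_table <- function(object, ...) {
  mods <- unique(object$modality)
  doses <- do.call(rbind, lapply(mods, function(m) {
    d <- object[object$modality == m, ]
    data.frame(modality = m, n = nrow(d),
               median_dose_tumor_gy = stats::median(d$dose_tumor_gy),
               min_dose_tumor_gy = min(d$dose_tumor_gy),
               max_dose_tumor_gy = max(d$dose_tumor_gy),
               median_dose_normal_gy = stats::median(d$dose_normal_gy),
               median_pct_change_tumor = stats::median(d$pct_change_tumor),
               mean_pct_change_tumor = mean(d$pct_change_tumor),
               median_pct_change_normal = stats::median(d$pct_change_normal),
               stringsAsFactors = FALSE)
  }))
  approach_tests <- NULL
  if (!all(is.na(object$lobar_or_total))) {
    plan_mods <- setdiff(mods, "reference")
    approach_tests <- lapply(stats::setNames(plan_mods, plan_mods),
      function(m) {
        d <- object[object$modality == m, ]
        ok <- !is.na(d$lobar_or_total)
        tryCatch(approach_comparison(d$pct_change_tumor[ok],
                                     d$lobar_or_total[ok]),
                 error = function(e) NULL)
      })
  }
  list(doses = doses, approach_tests = approach_tests,
       excluded = attr(object, "excluded"))
}
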