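#' Patient specification for the synthetic cohort generator
#'
#' @param patient_id Label.
#' @param sex `"F"` or `"M"`. Breast DVHs are generated, and breast risk
#'   modelled, only for female patients.
#' @param prescription_gy Prescribed dose in Gy; involved-field Hodgkin
#'   lymphoma prescriptions span 20-36 Gy.
#' @param organs Organ labels to generate; defaults to heart and lung plus
#'   breast for female patients.
#' @return An object of class `patient_spec`.
#' @export
patient_spec <- function(patient_id, sex = c("F", "M"), prescription_gy,
                         organs = NULL) {
  sex <- match.arg(sex)
  if (!is_number(prescription_gy) || prescription_gy <= 0)
    stopf("prescription_gy must be > 0")
  if (is.null(organs))
    organs <- c("heart", "lung", if (sex == "F") "breast")
  structure(list(patient_id = as.character(patient_id), sex = sex,
                 prescription_gy = prescription_gy, organs = organs),
            class = "patient_spec")
}

#' Default modality/organ shape profiles of the DVH generator
#'
#' Calibration constants of the synthetic generator, not published values:
#' for each (modality, organ) pair, the fraction of organ volume near the
#' prescription dose (`in_field_fraction`), the fraction in the low-dose bath
#' (`bath_fraction`, exponentially distributed with scale `bath_scale_gy`),
#' the spread of the high-dose shoulder (`penumbra_gy`) and the RBE weighting
#' of the dose axis (`rbe_factor`, 1.1 for protons). The defaults encode the
#' qualitative modality contrasts of thoracic involved-field plans: helical
#' tomotherapy (HT) trades high-dose volume for a much larger low-dose bath
#' than 3D conformal photons (3DCRT), while intensity-modulated proton
#' therapy (IMPT) reduces both.
#'
#' @param path Optional CSV with the same columns, to override the shipped
#'   defaults.
#' @return A data.frame with one row per (modality, organ).
#' @export
default_modality_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "modality_profiles.csv", package = "dvhrisk")
  prof <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("modality", "organ", "in_field_fraction", "bath_fraction",
            "bath_scale_gy", "penumbra_gy", "rbe_factor")
  missing_cols <- setdiff(need, names(prof))
  if (length(missing_cols))
    stopf("profile file %s: missing column(s) %s", path,
          paste(missing_cols, collapse = ", "))
  bad <- prof$in_field_fraction < 0 | prof$bath_fraction < 0 |
    prof$in_field_fraction + prof$bath_fraction > 1 |
    prof$bath_scale_gy <= 0 | prof$penumbra_gy <= 0 | prof$rbe_factor <= 0
  if (any(bad))
    stopf("profile file %s: invalid shape parameters in row %d", path, which(bad)[1])
  prof
}

# Per-patient jitter constants of the generator, not user-facing dials.
# Fractions are jittered on the logit scale so 0 and 1 are fixed points
# (an organ fully inside or outside the field stays so); for the small
# fractions of the default profiles this is ~8% relative spread.
.JITTER_FRACTION <- 0.08
.JITTER_SCALE <- 0.15
.JITTER_MEAN_GY <- 0.3
.BIN_W <- 0.1       # default generated bin width, Gy
.VMAX_FRAC <- 1.08  # planning ceiling: no dose above 108% of prescription

#' Generate a synthetic organ DVH for one patient and modality
#'
#' Draws a three-component mixture binned at 0.1 Gy: a high-dose in-field
#' component, normally distributed around `rbe_factor * prescription` with
#' spread `penumbra_gy` and truncated at the 108% planning ceiling; an
#' exponential low-dose bath; and a zero-dose remainder. Component weights
#' and the bath scale receive per-patient lognormal jitter. The draw is
#' deterministic given `(seed, patient_id, modality, organ)` — each triple
#' owns a hashed substream, so adding organs or patients never perturbs other
#' draws — and the caller's RNG state is left untouched.
#'
#' @param spec A [patient_spec()].
#' @param profile One row of [default_modality_profiles()] (data.frame row or
#'   list) for the requested modality and organ.
#' @param organ Organ label, must be in `spec$organs`.
#' @param seed Master integer seed.
#' @return A `differential_dvh`; `dose_kind` is `"rbe_weighted_gy"` when
#'   `rbe_factor > 1`.
#' @export
generate_organ_dvh <- function(spec, profile, organ, seed) {
  stopifnot(inherits(spec, "patient_spec"))
  if (!organ %in% spec$organs)
    stopf("organ '%s' not in patient %s's organ set", organ, spec$patient_id)
  pr <- as.list(profile)
  if (pr$in_field_fraction + pr$bath_fraction > 1)
    stopf("profile fractions sum above 1 for %s/%s", pr$modality, organ)
  presc <- spec$prescription_gy * pr$rbe_factor
  cap <- .VMAX_FRAC * presc
  sub <- substream_seed(seed, spec$patient_id, pr$modality, organ)
  z <- with_local_seed(sub, stats::rnorm(4))
  jitter_frac <- function(f, z1) {
    if (f <= 0 || f >= 1) return(f)
    stats::plogis(stats::qlogis(f) + .JITTER_FRACTION / (1 - f) * z1)
  }
  in_f <- jitter_frac(pr$in_field_fraction, z[1])
  bath_f <- jitter_frac(pr$bath_fraction, z[2])
  tot <- in_f + bath_f
  if (tot > 1) { in_f <- in_f / tot; bath_f <- bath_f / tot }
  bath_scale <- pr$bath_scale_gy * exp(.JITTER_SCALE * z[3])
  mu_if <- presc + .JITTER_MEAN_GY * z[4]
  mu_if <- min(max(mu_if, 0.9 * presc), cap)

  edges <- seq(0, ceiling(cap / .BIN_W) * .BIN_W, by = .BIN_W)
  m <- length(edges) - 1L
  lo <- edges[-length(edges)]; hi <- edges[-1]
  frac <- numeric(m)
  if (in_f > 0) {
    w <- stats::pnorm(hi, mu_if, pr$penumbra_gy) - stats::pnorm(lo, mu_if, pr$penumbra_gy)
    frac <- frac + in_f * w / sum(w)   # renormalize: mass above the ceiling folds back
  }
  if (bath_f > 0) {
    w <- stats::pexp(hi, 1 / bath_scale) - stats::pexp(lo, 1 / bath_scale)
    frac <- frac + bath_f * w / sum(w)
  }
  frac[1] <- frac[1] + (1 - in_f - bath_f)
  keep <- max(which(frac > 0))
  differential_dvh(lo[1:keep], hi[1:keep], frac[1:keep], organ = organ,
                   dose_kind = if (pr$rbe_factor > 1) "rbe_weighted_gy" else "physical_gy")
}

#' Bundle one patient's DVHs for one modality
#'
#' @param patient A [patient_spec()].
#' @param modality Modality label.
#' @param dvhs Named list of `differential_dvh` objects, one per organ.
#' @return An object of class `patient_plan`. Validation checks every DVH and
#'   the planning ceiling: no organ dose above 108% of the (RBE-weighted)
#'   prescription.
#' @export
patient_plan <- function(patient, modality, dvhs) {
  stopifnot(inherits(patient, "patient_spec"))
  plan <- structure(list(patient = patient, modality = modality, dvhs = dvhs),
                    class = "patient_plan")
  for (organ in names(dvhs)) {
    d <- validate_differential_dvh(dvhs[[organ]])
    rbe <- if (identical(d$dose_kind, "rbe_weighted_gy")) 1.1 else 1.0
    ceiling_gy <- .VMAX_FRAC * rbe * patient$prescription_gy
    if (max(d$hi[d$frac_volume > 0]) > ceiling_gy + .BIN_W + 1e-9)
      stopf("patient %s %s %s: dose exceeds the 108%% planning ceiling",
            patient$patient_id, modality, organ)
  }
  plan
}

# Prescriptions and sexes emulating a 20-patient involved-field Hodgkin
# lymphoma cohort: doses span 20-36 Gy, 9 female / 11 male.
.DEFAULT_DOSE_TABLE <- c(20, rep(21, 9), 26.5, rep(30, 3), rep(30.6, 5), 36)
.DEFAULT_SEXES <- c("F", "M", "F", "M", "M", "F", "F", "M", "M", "M",
                    "M", "M", "F", "M", "M", "M", "F", "F", "F", "F")

#' Generate a synthetic multi-modality DVH cohort
#'
#' For each patient, generates one [patient_plan()] per modality (3DCRT, HT,
#' IMPT) over a shared [patient_spec()]: heart and lung DVHs for everyone,
#' combined-breast DVHs for female patients. Defaults emulate a 20-patient
#' involved-field Hodgkin lymphoma cohort (prescriptions 20, 21 (x9), 26.5,
#' 30 (x3), 30.6 (x5), 36 Gy; 9 female / 11 male). The default profiles are
#' calibrated so generated cohorts reproduce the qualitative modality
#' ordering of secondary-cancer risk (HT > 3DCRT > IMPT for lung and breast
#' EAR) while cardiac risk shows no systematic ordering.
#'
#' @param n_patients Number of patients, `>= 1`. When it differs from 20 the
#'   default dose table and sex pattern are recycled/truncated.
#' @param seed Master integer seed; the only source of randomness.
#' @param dose_table Optional prescriptions, length `n_patients`.
#' @param sexes Optional `"F"`/`"M"` vector, length `n_patients`.
#' @param profiles Profile data.frame as from [default_modality_profiles()].
#' @param modalities Modalities to generate.
#' @return A list of `patient_plan` objects (patients x modalities) with
#'   class `dvh_cohort`.
#' @examples
#' plans <- generate_cohort(n_patients = 2, seed = 1)
#' length(plans)  # 6 plans: 2 patients x 3 modalities
#' @export
generate_cohort <- function(n_patients = 20, seed = 1, dose_table = NULL,
                            sexes = NULL, profiles = default_modality_profiles(),
                            modalities = c("3DCRT", "HT", "IMPT")) {
  if (!is_number(n_patients) || n_patients < 1) stopf("n_patients must be >= 1")
  n_patients <- as.integer(n_patients)
  if (is.null(dose_table)) {
    dose_table <- rep_len(.DEFAULT_DOSE_TABLE, n_patients)
  } else if (length(dose_table) != n_patients) {
    stopf("dose_table length (%d) must equal n_patients (%d)",
          length(dose_table), n_patients)
  }
  if (is.null(sexes)) {
    sexes <- rep_len(.DEFAULT_SEXES, n_patients)
  } else if (length(sexes) != n_patients) {
    stopf("sexes length (%d) must equal n_patients (%d)", length(sexes), n_patients)
  }
  plans <- list()
  for (i in seq_len(n_patients)) {
    spec <- patient_spec(sprintf("P%02d", i), sexes[i], dose_table[i])
    for (mod in modalities) {
      dvhs <- list()
      for (organ in spec$organs) {
        row <- profiles[profiles$modality == mod & profiles$organ == organ, ]
        if (nrow(row) != 1L)
          stopf("no unique profile for modality %s, organ %s", mod, organ)
        dvhs[[organ]] <- generate_organ_dvh(spec, row, organ, seed)
      }
      plans[[length(plans) + 1L]] <- patient_plan(spec, mod, dvhs)
    }
  }
  structure(plans, class = "dvh_cohort")
}

#' Write a cohort to a directory of CSV files
#'
#' Emits `dvhs.csv` in the differential DVH dialect plus `patients.csv` with
#' columns `patient_id, sex, prescription_gy`. [read_cohort_csv()] inverts
#' the operation bit-identically.
#'
#' @param plans A `dvh_cohort` (list of `patient_plan`).
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(plans, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  meta <- list()
  for (plan in plans) {
    for (organ in names(plan$dvhs)) {
      records[[length(records) + 1L]] <-
        list(patient_id = plan$patient$patient_id, modality = plan$modality,
             dvh = plan$dvhs[[organ]])
    }
    meta[[plan$patient$patient_id]] <-
      data.frame(patient_id = plan$patient$patient_id, sex = plan$patient$sex,
                 prescription_gy = plan$patient$prescription_gy,
                 stringsAsFactors = FALSE)
  }
  write_dvh_csv(records, file.path(dir, "dvhs.csv"))
  meta_df <- do.call(rbind, meta[order(names(meta))])
  utils::write.csv(meta_df, file.path(dir, "patients.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort_csv()]
#'
#' @param dir Directory containing `dvhs.csv` and `patients.csv`.
#' @return A `dvh_cohort` list of `patient_plan` objects.
#' @export
read_cohort_csv <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  need <- c("patient_id", "sex", "prescription_gy")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stopf("patients.csv: missing column(s) %s", paste(missing_cols, collapse = ", "))
  dset <- read_dvh_csv(file.path(dir, "dvhs.csv"), form = "differential")
  meta$patient_id <- as.character(meta$patient_id)
  plans <- list()
  keys <- unique(vapply(dset, function(r) paste(r$patient_id, r$modality, sep = "\r"),
                        character(1)))
  for (key in keys) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    pid <- parts[1]; mod <- parts[2]
    row <- meta[meta$patient_id == pid, ]
    if (nrow(row) != 1L) stopf("patients.csv: no unique metadata row for %s", pid)
    dvhs <- list()
    for (r in dset)
      if (r$patient_id == pid && r$modality == mod) dvhs[[r$dvh$organ]] <- r$dvh
    spec <- patient_spec(pid, row$sex, row$prescription_gy, organs = names(dvhs))
    plans[[length(plans) + 1L]] <- patient_plan(spec, mod, dvhs)
  }
  structure(plans, class = "dvh_cohort")
}

#' @export
print.patient_plan <- function(x, ...) {
  cat(sprintf("<patient_plan> %s (%s, %g Gy) %s: %s\n",
              x$patient$patient_id, x$patient$sex, x$patient$prescription_gy,
              x$modality, paste(names(x$dvhs), collapse = ", ")))
  invisible(x)
}
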