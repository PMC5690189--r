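#' Run the full cohort risk pipeline
#'
#' Generates (or reads back) a DVH cohort, computes the per-patient risk
#' table, the modality comparison (risk ratios and paired t-tests) and,
#' optionally, the two sensitivity analyses, then writes everything to
#' `out_dir`:
#' \itemize{
#'   \item `cohort/` — the cohort CSVs (when generating);
#'   \item `risks.csv` — long-format risk table; `risks_wide.csv` — one row
#'     per patient and endpoint, one column per modality;
#'   \item `comparison.csv` — mean risk ratios, ratio of means, paired
#'     t-tests per endpoint and modality;
#'   \item `sensitivity_dose.csv`, `sensitivity_neutron.csv` — worst-case
#'     changes under a relative dose error and an IMPT neutron bath;
#'   \item `dvh_<patient>_<organ>.png` cumulative-DVH overlays and
#'     `relative_risk.png` (per-patient ratio scatter) — diagnostic figures;
#'     plotting failures degrade to warnings;
#'   \item `run_log.txt` — package version, seed, file manifest.
#' }
#' All randomness flows from `seed`; a rerun with the same configuration
#' produces byte-identical CSVs.
#'
#' @param out_dir Output directory, created if absent.
#' @param seed Master seed.
#' @param n_patients Cohort size when generating.
#' @param cohort_dir Existing cohort directory (as written by
#'   [write_cohort_csv()]) to analyze instead of generating; overrides
#'   `n_patients`.
#' @param params_file Optional model parameter config for
#'   [read_model_params()]; defaults to the shipped parameter sets.
#' @param profiles_file Optional generator profile CSV.
#' @param dose_delta Relative dose error for the sensitivity analysis
#'   (default 0.10); `NULL` skips it.
#' @param neutron_msv_per_gy Neutron bath in mSv/Gy for the IMPT sensitivity
#'   (default 50); `NULL` skips it.
#' @param make_plots Draw the diagnostic figures (default `TRUE`).
#' @return Invisibly, a list with the risk table, comparison table and
#'   sensitivity summaries.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_patients = 20,
                         cohort_dir = NULL, params_file = NULL,
                         profiles_file = NULL, dose_delta = 0.10,
                         neutron_msv_per_gy = 50, make_plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- read_model_params(params_file)
  seriality <- params[["heart.cardiac_mortality"]]
  lung <- params[["lung.lung_cancer"]]
  breast <- params[["breast.breast_cancer"]]
  if (is.null(seriality) || is.null(lung) || is.null(breast))
    stopf("parameter config must define heart.cardiac_mortality, lung.lung_cancer and breast.breast_cancer")

  if (is.null(cohort_dir)) {
    plans <- generate_cohort(n_patients = n_patients, seed = seed,
                             profiles = default_modality_profiles(profiles_file))
    write_cohort_csv(plans, file.path(out_dir, "cohort"))
  } else {
    plans <- read_cohort_csv(cohort_dir)
  }

  risks <- compute_cohort_risks(plans, seriality = seriality,
                                lung = lung, breast = breast)
  write_csv_stable(risks, file.path(out_dir, "risks.csv"))
  wide <- stats::reshape(
    as.data.frame(risks)[c("patient_id", "endpoint", "modality", "value")],
    idvar = c("patient_id", "endpoint"), timevar = "modality",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$endpoint, wide$patient_id), ]
  write_csv_stable(wide, file.path(out_dir, "risks_wide.csv"))

  comparison <- compare_modalities(risks)
  write_csv_stable(comparison, file.path(out_dir, "comparison.csv"))

  sens_dose <- NULL
  if (!is.null(dose_delta)) {
    sens_dose <- dose_uncertainty_sensitivity(plans, dose_delta,
                                              seriality = seriality,
                                              lung = lung, breast = breast)
    write_csv_stable(sens_dose$summary, file.path(out_dir, "sensitivity_dose.csv"))
  }
  sens_neutron <- NULL
  if (!is.null(neutron_msv_per_gy) && any(vapply(plans, function(p)
      identical(p$modality, "IMPT"), logical(1)))) {
    sens_neutron <- neutron_bath_sensitivity(plans, neutron_msv_per_gy,
                                             seriality = seriality,
                                             lung = lung, breast = breast)
    write_csv_stable(sens_neutron$summary,
                     file.path(out_dir, "sensitivity_neutron.csv"))
  }

  if (make_plots) {
    tryCatch(plot_report(plans, risks, out_dir),
             error = function(e) warning("plotting failed: ",
                                         conditionMessage(e), call. = FALSE))
  }

  writeLines(c(
    sprintf("dvhrisk %s", as.character(utils::packageVersion("dvhrisk"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("patients: %d", length(unique(vapply(plans, function(p)
      p$patient$patient_id, character(1))))),
    sprintf("outputs: %s", paste(sort(list.files(out_dir)), collapse = ", "))),
    file.path(out_dir, "run_log.txt"))

  invisible(list(risks = risks, comparison = comparison,
                 sensitivity_dose = sens_dose,
                 sensitivity_neutron = sens_neutron))
}

# Deterministic CSV writer: fixed column order, no row names, full precision.
write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cl in names(df)[num]) df[[cl]] <- sprintf("%.15g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# Diagnostic figures: cumulative DVH overlays per patient/organ and a
# per-patient relative-risk scatter against the reference modality.
plot_report <- function(plans, risks, out_dir) {
  by_patient <- split(seq_along(plans), vapply(plans, function(p)
    p$patient$patient_id, character(1)))
  for (pid in names(by_patient)) {
    idx <- by_patient[[pid]]
    organs <- unique(unlist(lapply(plans[idx], function(p) names(p$dvhs))))
    for (organ in organs) {
      file <- file.path(out_dir, sprintf("dvh_%s_%s.png", pid, organ))
      grDevices::png(file, width = 640, height = 480)
      graphics::plot(NULL, xlim = c(0, max(vapply(plans[idx], function(p)
        max(p$dvhs[[organ]]$hi), numeric(1)))), ylim = c(0, 1),
        xlab = "Dose (Gy)", ylab = "Volume fraction >= dose",
        main = sprintf("%s %s", pid, organ))
      cols <- c("3DCRT" = "black", HT = "blue", IMPT = "red")
      for (i in idx) {
        cd <- differential_to_cumulative(plans[[i]]$dvhs[[organ]])
        graphics::lines(cd$dose_gy, cd$frac_ge, type = "s",
                        col = cols[[plans[[i]]$modality]])
      }
      graphics::legend("topright", legend = names(cols), col = unlist(cols), lty = 1)
      grDevices::dev.off()
    }
  }
  file <- file.path(out_dir, "relative_risk.png")
  grDevices::png(file, width = 720, height = 480)
  endpoints <- unique(risks$endpoint)
  graphics::plot(NULL, xlim = c(0.5, length(endpoints) + 0.5), ylim = c(0, 4),
                 xaxt = "n", xlab = "", ylab = "Risk relative to 3DCRT")
  graphics::axis(1, at = seq_along(endpoints), labels = endpoints)
  graphics::abline(h = 1, lty = 2)
  for (k in seq_along(endpoints)) {
    for (mod in c("HT", "IMPT")) {
      rr <- tryCatch(risk_ratio(risks, endpoints[k], mod), error = function(e) NULL)
      if (is.null(rr)) next
      x <- k + if (mod == "HT") -0.12 else 0.12
      graphics::points(rep(x, nrow(rr$per_patient)),
                       pmin(rr$per_patient$ratio, 4),
                       col = if (mod == "HT") "black" else "red",
                       pch = if (mod == "HT") 1 else 4)
    }
  }
  graphics::legend("topright", legend = c("HT", "IMPT"), col = c("black", "red"),
                   pch = c(1, 4))
  grDevices::dev.off()
}
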