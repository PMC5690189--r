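#' Read DVHs from a CSV file
#'
#' Two CSV dialects are supported (UTF-8, header required):
#' \describe{
#'   \item{differential}{columns `patient_id, modality, organ, bin_lo_gy,
#'     bin_hi_gy, frac_volume`; one row per bin.}
#'   \item{cumulative}{columns `patient_id, modality, organ, dose_gy,
#'     frac_volume_ge`; one row per point.}
#' }
#' Rows are grouped by `(patient_id, modality, organ)`; each group becomes one
#' DVH object and is validated against all DVH invariants.
#'
#' @param path Path to the CSV file.
#' @param form `"differential"` or `"cumulative"`.
#' @param dose_kind Dose kind label applied to modalities; a named character
#'   vector `c(modality = kind)` or a single kind for all. Defaults to
#'   `"rbe_weighted_gy"` for modality `"IMPT"` and `"physical_gy"` otherwise.
#' @return A list of records, each `list(patient_id, modality, dvh)`, with
#'   class `dvh_set`.
#' @seealso [write_dvh_csv()]
#' @export
read_dvh_csv <- function(path, form = c("differential", "cumulative"),
                         dose_kind = NULL) {
  form <- match.arg(form)
  if (!file.exists(path)) stopf("DVH file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (form == "differential")
    c("patient_id", "modality", "organ", "bin_lo_gy", "bin_hi_gy", "frac_volume")
  else
    c("patient_id", "modality", "organ", "dose_gy", "frac_volume_ge")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("malformed DVH CSV %s: missing column(s) %s",
          path, paste(missing_cols, collapse = ", "))
  kind_for <- function(modality) {
    if (is.null(dose_kind))
      return(if (identical(modality, "IMPT")) "rbe_weighted_gy" else "physical_gy")
    if (!is.null(names(dose_kind)) && modality %in% names(dose_kind))
      return(dose_kind[[modality]])
    dose_kind[[1]]
  }
  key <- interaction(df$patient_id, df$modality, df$organ, drop = TRUE, sep = "\r")
  out <- lapply(split(df, key), function(g) {
    g <- g[order(if (form == "differential") g$bin_lo_gy else g$dose_gy), ]
    dvh <- tryCatch(
      if (form == "differential")
        differential_dvh(g$bin_lo_gy, g$bin_hi_gy, g$frac_volume,
                         organ = g$organ[1], dose_kind = kind_for(g$modality[1]))
      else
        cumulative_dvh(g$dose_gy, g$frac_volume_ge,
                       organ = g$organ[1], dose_kind = kind_for(g$modality[1])),
      error = function(e)
        stopf("invalid DVH for patient %s, modality %s, organ %s in %s: %s",
              g$patient_id[1], g$modality[1], g$organ[1], path, conditionMessage(e)))
    list(patient_id = as.character(g$patient_id[1]),
         modality = as.character(g$modality[1]), dvh = dvh)
  })
  names(out) <- NULL
  structure(out, class = "dvh_set")
}

#' Write differential DVHs to a CSV file
#'
#' Inverse of [read_dvh_csv()] for the differential dialect; a write-read
#' round trip reproduces every bin bit-identically (doses are printed with
#' full double precision).
#'
#' @param records A `dvh_set`, or a list of `list(patient_id, modality, dvh)`
#'   records with differential DVHs.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    stopifnot(inherits(r$dvh, "differential_dvh"))
    data.frame(patient_id = r$patient_id, modality = r$modality,
               organ = r$dvh$organ, bin_lo_gy = r$dvh$lo, bin_hi_gy = r$dvh$hi,
               frac_volume = r$dvh$frac_volume, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  # format doubles at full precision so the round trip is exact
  num <- c("bin_lo_gy", "bin_hi_gy", "frac_volume")
  for (cl in num) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
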