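# Fixtures are built in code; nothing is read from disk.

# Uniform-dose DVH: all volume in one narrow bin centred on `dose`.
uniform_dvh <- function(dose, organ = "other", width = 0.1,
                        dose_kind = "physical_gy") {
  differential_dvh(dose - width / 2, dose + width / 2, 1,
                   organ = organ, dose_kind = dose_kind)
}

# Random contiguous differential DVH on a uniform grid starting at 0.
random_dvh <- function(n_bins = 50, width = 0.1, organ = "other") {
  v <- stats::runif(n_bins)
  v <- v / sum(v)
  edges <- width * (0:n_bins)
  differential_dvh(edges[-length(edges)], edges[-1], v, organ = organ)
}

# Voxel doses drawn on the 0.1-Gy bin-midpoint grid (0.05, 0.15, ...), so a
# binned DVH represents them without discretization error; isolates the
# combination formulas from midpoint error in oracle comparisons.
random_grid_doses <- function(n, width = 0.1, max_dose = 60) {
  (sample.int(round(max_dose / width), n, replace = TRUE) - 0.5) * width
}

# Differential DVH of a voxel list with equal voxel volumes.
dvh_from_voxels <- function(doses, width = 0.1, organ = "other") {
  idx <- pmin(floor(doses / width), floor(max(doses) / width)) + 1L
  m <- max(idx)
  frac <- tabulate(idx, nbins = m) / length(doses)
  edges <- width * (0:m)
  differential_dvh(edges[-length(edges)], edges[-1], frac, organ = organ)
}

# Minimal hand-built plan: one patient, one modality, uniform organ doses.
uniform_plan <- function(patient_id = "X1", sex = "F", prescription = 21,
                         modality = "3DCRT", heart = 5, lung = 8, breast = 3) {
  spec <- patient_spec(patient_id, sex, prescription)
  dvhs <- list(heart = uniform_dvh(heart, organ = "heart"),
               lung = uniform_dvh(lung, organ = "lung"))
  if (sex == "F") dvhs$breast <- uniform_dvh(breast, organ = "breast")
  patient_plan(spec, modality, dvhs)
}
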