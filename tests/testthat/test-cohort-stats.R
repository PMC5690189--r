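test_that("risk table covers patients x modalities x endpoints", {
  plans <- generate_cohort(n_patients = 20, seed = 2)
  tab <- compute_cohort_risks(plans)
  expect_identical(nrow(tab), 147L)  # 20*3 cardiac + 20*3 lung + 9*3 breast
  expect_false(any(duplicated(tab[c("patient_id", "modality", "endpoint")])))
  expect_true(all(tab$value[tab$endpoint == "cardiac_mortality"] >= 0 &
                  tab$value[tab$endpoint == "cardiac_mortality"] <= 1))
  expect_true(all(tab$value[tab$endpoint != "cardiac_mortality"] >= 0))
  expect_identical(unique(tab$horizon_years[tab$endpoint == "cardiac_mortality"]), 15)
  expect_identical(unique(tab$horizon_years[tab$endpoint == "lung_cancer"]), 30)
  # male patients contribute no breast rows
  males <- unique(tab$patient_id[tab$sex == "M"])
  expect_false(any(tab$patient_id %in% males & tab$endpoint == "breast_cancer"))
  # pure function: identical rerun
  expect_identical(compute_cohort_risks(plans), tab)
})

test_that("a uniform 70.3 Gy heart yields cardiac risk 0.5", {
  plan <- uniform_plan(heart = 70.3, prescription = 70.3, sex = "M")
  tab <- compute_cohort_risks(list(plan))
  expect_equal(tab$value[tab$endpoint == "cardiac_mortality"], 0.5,
               tolerance = 1e-10)
})

test_that("missing organ DVHs are reported with patient context", {
  plan <- uniform_plan(sex = "M")
  plan$dvhs$lung <- NULL
  expect_error(compute_cohort_risks(list(plan)), "X1.*lung")
  plan_f <- uniform_plan(sex = "F")
  plan_f$dvhs$breast <- NULL
  expect_error(compute_cohort_risks(list(plan_f)), "breast")
})

test_that("risk ratios: identity, hand example, zero-reference exclusion", {
  tab <- compute_cohort_risks(generate_cohort(n_patients = 4, seed = 3))
  rr_id <- risk_ratio(tab, "lung_cancer", "HT", reference = "HT")
  expect_true(all(rr_id$per_patient$ratio == 1))
  expect_identical(rr_id$mean_ratio, 1)

  hand <- data.frame(patient_id = c("a", "b", "a", "b"), sex = "M",
                     modality = c("HT", "HT", "3DCRT", "3DCRT"),
                     endpoint = "lung_cancer",
                     value = c(1, 4.5, 2, 3), horizon_years = 30)
  rr <- risk_ratio(hand, "lung_cancer", "HT")
  expect_equal(sort(rr$per_patient$ratio), c(0.5, 1.5))
  expect_equal(rr$mean_ratio, 1)
  expect_equal(rr$ratio_of_means, 5.5 / 5)

  zero <- hand
  zero$value[zero$patient_id == "a" & zero$modality == "3DCRT"] <- 0
  rr0 <- risk_ratio(zero, "lung_cancer", "HT")
  expect_identical(rr0$n_excluded, 1L)
  expect_equal(rr0$per_patient$ratio, 1.5)
  expect_error(risk_ratio(hand, "lung_cancer", "IMPT"), "no patients")
})

test_that("paired t-test matches the hand-computed example", {
  tt <- paired_t_test(c(1, 2, 3), c(1, 3, 5))
  expect_equal(tt$t, -sqrt(3), tolerance = 1e-12)
  expect_identical(tt$df, 2L)
  expect_equal(tt$p_value, 0.225403330758517, tolerance = 1e-9)
  expect_false(tt$degenerate)
})

test_that("paired t-test conventions: degeneracy, antisymmetry, oracle", {
  same <- paired_t_test(c(2, 2, 5), c(2, 2, 5))
  expect_true(same$degenerate)
  expect_identical(same$p_value, 1)
  expect_error(paired_t_test(1, 2), "at least 2")
  expect_error(paired_t_test(1:3, 1:2), "equal length")

  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    a <- stats::rnorm(n); b <- stats::rnorm(n)
    mine <- paired_t_test(a, b)
    swap <- paired_t_test(b, a)
    expect_equal(swap$t, -mine$t, tolerance = 1e-12)
    expect_equal(swap$p_value, mine$p_value, tolerance = 1e-12)
    ref <- stats::t.test(a, b, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("modality comparison table spans endpoints and modalities", {
  tab <- compute_cohort_risks(generate_cohort(n_patients = 6, seed = 19))
  cmp <- compare_modalities(tab)
  expect_identical(nrow(cmp), 6L)  # 3 endpoints x {HT, IMPT}
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  expect_true(all(cmp$reference == "3DCRT"))
})

test_that("zero dose perturbation is an exact no-op", {
  plans <- generate_cohort(n_patients = 3, seed = 6)
  sens <- dose_uncertainty_sensitivity(plans, delta = 0)
  expect_true(all(sens$summary$max_change == 0))
  expect_identical(sens$base$value, sens$high$value)
  neut <- neutron_bath_sensitivity(plans, bath_msv_per_gy = 0)
  expect_true(all(neut$deltas$delta == 0))
})

test_that("small dose errors propagate ~linearly to EAR in the low-dose regime", {
  # organ entirely in the LNT regime: EAR ~ mu * mean dose, so a relative
  # dose error of delta moves EAR by ~delta
  low <- patient_plan(patient_spec("L1", "M", 21), "3DCRT", list(
    heart = uniform_dvh(0.5, organ = "heart"),
    lung = uniform_dvh(0.8, organ = "lung")))
  sens <- dose_uncertainty_sensitivity(list(low), delta = 0.05)
  rel <- sens$summary$max_change[sens$summary$endpoint == "lung_cancer"]
  expect_equal(rel, 0.05, tolerance = 0.1)
})

test_that("a 10% dose error moves cardiac risk far less than the cancer EARs", {
  plans <- generate_cohort(n_patients = 6, seed = 8)
  sens <- dose_uncertainty_sensitivity(plans, delta = 0.10)
  cardiac_pp <- sens$summary$max_change[sens$summary$endpoint == "cardiac_mortality"]
  ear_rel <- sens$summary$max_change[sens$summary$endpoint == "lung_cancer"]
  expect_lt(cardiac_pp, 0.5)      # percentage points
  expect_gt(ear_rel, 0.05)        # relative change on the order of delta
  expect_lt(cardiac_pp / 100, ear_rel)
})

test_that("the neutron bath adds ~mu * bath dose to a low-dose EAR", {
  plan <- patient_plan(patient_spec("N1", "M", 21), "IMPT", list(
    heart = uniform_dvh(0.2, organ = "heart", dose_kind = "rbe_weighted_gy"),
    lung = uniform_dvh(0.2, organ = "lung", dose_kind = "rbe_weighted_gy")))
  neut <- neutron_bath_sensitivity(list(plan), bath_msv_per_gy = 50)
  bath_gy <- 50 / 1000 * 21   # 1.05 Gy-equivalent
  d_lung <- neut$deltas$delta[neut$deltas$endpoint == "lung_cancer"]
  p_lung <- default_schneider_params("lung")
  # exact closed-form increment (EAR linear in volume, uniform organ)
  expect_equal(d_lung, ear_density(0.2 + bath_gy, p_lung) - ear_density(0.2, p_lung),
               tolerance = 1e-10)
  # and on the LNT scale it is ~mu * bath dose
  expect_equal(d_lung, p_lung$mu * bath_gy, tolerance = 0.1)
  d_heart <- neut$deltas$delta[neut$deltas$endpoint == "cardiac_mortality"]
  expect_lt(abs(d_heart), 1e-3)
  # only IMPT rows are perturbed, and cardiac stays flat for any plausible bath
  plans <- generate_cohort(n_patients = 2, seed = 10)
  neut2 <- neutron_bath_sensitivity(plans, bath_msv_per_gy = 100)
  base <- compute_cohort_risks(plans)
  expect_identical(nrow(neut2$deltas), sum(base$modality == "IMPT"))
  expect_true(all(abs(neut2$deltas$delta[neut2$deltas$endpoint == "cardiac_mortality"]) < 1e-3))
})
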