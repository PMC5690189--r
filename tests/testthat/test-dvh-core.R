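test_that("differential DVH constructor enforces its invariants", {
  expect_s3_class(differential_dvh(c(0, 10), c(10, 20), c(0.6, 0.4)),
                  "differential_dvh")
  expect_error(differential_dvh(c(0, 11), c(10, 20), c(0.6, 0.4)), "contiguous")
  expect_error(differential_dvh(c(0, 10), c(10, 20), c(0.6, 0.3)), "sums to")
  expect_error(differential_dvh(10, 10, 1), "hi > lo")
  expect_error(differential_dvh(c(10, 0), c(20, 10), c(0.5, 0.5)), "sorted")
  expect_error(differential_dvh(-1, 1, 1), ">= 0")
})

test_that("cumulative DVH constructor enforces its invariants", {
  c1 <- cumulative_dvh(c(0, 10, 20), c(1, 0.4, 0))
  expect_identical(c1$frac_ge[1], 1)
  # a leading (0, 1) point is prepended when the export starts above 0 Gy
  c2 <- cumulative_dvh(c(5, 10), c(1, 0))
  expect_identical(c2$dose_gy[1], 0)
  expect_error(cumulative_dvh(c(0, 10, 20), c(1, 0.4, 0.6)), "non-increasing")
  expect_error(cumulative_dvh(c(0, 10, 10), c(1, 0.5, 0)), "strictly increasing")
  expect_error(cumulative_dvh(c(0, 10), c(0.8, 0)), "first point")
})

test_that("differential CSV round trip is exact and errors are specific", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,modality,organ,bin_lo_gy,bin_hi_gy,frac_volume",
               "P1,3DCRT,lung,0,10,0.5", "P1,3DCRT,lung,10,20,0.3",
               "P1,3DCRT,lung,20,30,0.2"), path)
  dset <- read_dvh_csv(path, form = "differential")
  expect_length(dset, 1)
  expect_equal(dset[[1]]$dvh$frac_volume, c(0.5, 0.3, 0.2))
  expect_identical(dset[[1]]$dvh$organ, "lung")

  # write -> read reproduces generator output bit-identically
  spec <- patient_spec("P7", "F", 21)
  prof <- default_modality_profiles()
  d <- generate_organ_dvh(spec, prof[prof$modality == "HT" & prof$organ == "lung", ],
                          "lung", seed = 11)
  out <- withr::local_tempfile(fileext = ".csv")
  write_dvh_csv(list(list(patient_id = "P7", modality = "HT", dvh = d)), out)
  back <- read_dvh_csv(out, form = "differential")[[1]]$dvh
  expect_identical(back$lo, d$lo)
  expect_identical(back$hi, d$hi)
  expect_identical(back$frac_volume, d$frac_volume)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,modality,bin_lo_gy,bin_hi_gy,frac_volume",
               "P1,3DCRT,0,10,1"), bad)
  expect_error(read_dvh_csv(bad, form = "differential"), "organ")

  inc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,modality,organ,dose_gy,frac_volume_ge",
               "P1,HT,heart,0,1", "P1,HT,heart,5,0.2", "P1,HT,heart,10,0.6"),
             inc)
  expect_error(read_dvh_csv(inc, form = "cumulative"), "non-increasing")
})

test_that("cumulative -> differential takes first differences", {
  c1 <- cumulative_dvh(c(0, 10, 20), c(1, 0.4, 0))
  d1 <- cumulative_to_differential(c1)
  expect_equal(d1$lo, c(0, 10))
  expect_equal(d1$frac_volume, c(0.6, 0.4))

  # uniform-dose organ: all volume lands in the top bin
  c2 <- cumulative_dvh(c(0, 30, 31), c(1, 1, 0))
  d2 <- cumulative_to_differential(c2)
  expect_equal(d2$frac_volume, c(0, 1))

  expect_error(cumulative_to_differential(cumulative_dvh(0, 1)), "2 points")
  expect_error(
    cumulative_to_differential(cumulative_dvh(c(0, 10), c(1, 0.3))),
    "last fraction")
})

test_that("differential -> cumulative matches a brute-force tail sum", {
  d <- differential_dvh(c(0, 10), c(10, 20), c(0.6, 0.4))
  cd <- differential_to_cumulative(d)
  expect_equal(cd$frac_ge[match(10, cd$dose_gy)], 0.4)
  expect_equal(cd$frac_ge[match(20, cd$dose_gy)], 0)

  # single bin away from zero: curve starts at (0, 1) and holds 1 at 21 Gy
  cd2 <- differential_to_cumulative(uniform_dvh(21.05))
  expect_equal(cd2$frac_ge[match(21, cd2$dose_gy)], 1)

  set.seed(42)
  d3 <- random_dvh(500)
  cd3 <- differential_to_cumulative(d3)
  tail_sum <- vapply(cd3$dose_gy,
                     function(x) sum(d3$frac_volume[d3$lo >= x - 1e-12]),
                     numeric(1))
  tail_sum[1] <- 1
  expect_equal(cd3$frac_ge, pmin(tail_sum, 1), tolerance = 1e-12)
})

test_that("differential <-> cumulative round trip is the identity on the grid", {
  set.seed(7)
  for (i in 1:20) {
    d <- random_dvh(n_bins = sample(3:80, 1))
    d2 <- cumulative_to_differential(differential_to_cumulative(d))
    expect_equal(d2$lo, d$lo)
    expect_equal(d2$frac_volume, d$frac_volume, tolerance = 1e-12)
  }
})

test_that("rebin conserves volume exactly and mean dose within half a width", {
  set.seed(1)
  d <- random_dvh(n_bins = 40, width = 0.1)
  expect_equal(rebin(d, 0.1), d, tolerance = 1e-12)  # own grid: identity

  merged <- rebin(differential_dvh(c(0, 0.05), c(0.05, 0.1), c(0.5, 0.5)), 0.1)
  expect_equal(merged$frac_volume, 1)
  expect_equal(merged$hi, 0.1)

  for (width in c(0.01, 0.3, 1.7)) {
    r <- rebin(d, width)
    expect_equal(sum(r$frac_volume), 1, tolerance = 1e-12)
    expect_lt(abs(mean_dose(r) - mean_dose(d)), 0.5 * width + 1e-12)
  }
})

test_that("vx and mean_dose behave as dose-volume metrics", {
  u <- uniform_dvh(21)
  expect_equal(vx(u, 20), 1)
  expect_equal(vx(u, 22), 0)
  expect_equal(mean_dose(u), 21)
  expect_equal(mean_dose(differential_dvh(c(0, 10), c(10, 20), c(0.5, 0.5))), 10)

  set.seed(3)
  d <- random_dvh(60)
  expect_equal(vx(d, 0), 1)
  th <- sort(stats::runif(10, 0, 7))
  expect_true(all(diff(vapply(th, vx, numeric(1), d = d)) <= 1e-12))

  # voxelwise oracle for the mean
  doses <- random_grid_doses(400, max_dose = 30)
  expect_equal(mean_dose(dvh_from_voxels(doses)), mean(doses), tolerance = 1e-9)
})

test_that("scale_dose and shift_dose move the dose axis only", {
  u <- uniform_dvh(21)
  expect_equal(scale_dose(u, 1), u)
  s <- scale_dose(u, 1.1, dose_kind = "rbe_weighted_gy")
  expect_equal(mean_dose(s), 23.1)
  expect_identical(s$dose_kind, "rbe_weighted_gy")
  expect_error(scale_dose(u, 0), "> 0")
  expect_error(scale_dose(u, -1), "> 0")

  set.seed(9)
  for (i in 1:10) {
    d <- random_dvh(30)
    f <- stats::runif(1, 0.5, 2)
    expect_equal(mean_dose(scale_dose(d, f)), f * mean_dose(d), tolerance = 1e-12)
    expect_equal(mean_dose(shift_dose(d, 2.5)), mean_dose(d) + 2.5,
                 tolerance = 1e-12)
  }
})

test_that("eqd2 transform matches the closed form for uniform DVHs", {
  ab <- 3; n <- 15
  for (D in c(2, 21, 36)) {
    e <- eqd2_dvh(uniform_dvh(D, width = 1e-6), alpha_beta = ab, n_fractions = n)
    expect_equal(mean_dose(e), D * (D / n + ab) / (2 + ab), tolerance = 1e-4)
  }
  expect_error(eqd2_dvh(uniform_dvh(2), alpha_beta = 0, n_fractions = 10), "> 0")
})
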