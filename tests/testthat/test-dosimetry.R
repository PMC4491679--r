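# small raster shared by the unit tests
mk_grid <- function(values, shape = c(4, 4, 4), spacing = c(1, 1, 1)) {
  dose_grid(array(values, dim = shape), spacing)
}
mk_mask <- function(sel, shape = c(4, 4, 4), spacing = c(1, 1, 1), label = "ctv") {
  m <- array(FALSE, dim = shape)
  m[sel] <- TRUE
  structure_mask(m, spacing, label = label)
}

test_that("containers validate geometry and values", {
  expect_error(dose_grid(array(-1, c(2, 2, 2)), c(1, 1, 1)), ">= 0")
  expect_error(dose_grid(matrix(1, 2, 2), c(1, 1, 1)), "3-D")
  expect_error(dose_grid(array(1, c(2, 2, 2)), c(1, 0, 1)), "positive")
  g <- mk_grid(1)
  m <- mk_mask(1:8)
  bad <- structure_mask(array(TRUE, c(2, 2, 2)), c(1, 1, 1))
  expect_error(mask_mean(g, bad), "geometries differ")
  empty <- mk_mask(integer(0))
  expect_error(mask_mean(g, empty), "empty")
})

test_that("normalization fixes the CTV mean and is idempotent and scale-equivariant", {
  g <- mk_grid(38)
  ctv <- mk_mask(1:16)
  norm <- normalize_to_ctv_mean(g, ctv)
  expect_equal(mask_mean(norm, ctv), 76, tolerance = 1e-12)
  expect_equal(unclass(norm)[1], 76)  # uniform grid scaled by 2
  again <- normalize_to_ctv_mean(norm, ctv)
  expect_equal(unclass(again), unclass(norm), tolerance = 1e-12)
  scaled <- dose_grid(unclass(g) * 3.7, attr(g, "spacing"))
  expect_equal(unclass(normalize_to_ctv_mean(scaled, ctv)), unclass(norm),
               tolerance = 1e-12)
  zero <- mk_grid(0)
  expect_error(normalize_to_ctv_mean(zero, ctv), "zero")
})

test_that("field combination scales each field to 34.5 Gy CTV mean and sums", {
  set.seed(11)
  ctv <- mk_mask(sample(64, 20))
  f1 <- mk_grid(runif(64, 0.5, 2))
  f2 <- mk_grid(runif(64, 0.5, 2))
  comb <- combine_fields(list(f1, f2), ctv)
  expect_equal(mask_mean(comb, ctv), 69, tolerance = 1e-12)
  one <- combine_fields(list(f1), ctv)
  expect_equal(mask_mean(one, ctv), 34.5, tolerance = 1e-12)
  # permutation invariance
  swap <- combine_fields(list(f2, f1), ctv)
  expect_equal(unclass(swap), unclass(comb), tolerance = 1e-12)
  other <- dose_grid(array(1, c(3, 3, 3)), c(1, 1, 1))
  expect_error(combine_fields(list(f1, other), ctv), "mismatched")
  expect_error(combine_fields(list(), ctv), "non-empty")
})

test_that("cumulative DVH matches hand enumeration and stays monotone", {
  # uniform dose: a step function
  g <- mk_grid(5)
  m <- mk_mask(1:10)
  dv <- cumulative_dvh(g, m, bin_width = 1)
  expect_equal(dv$volume_pct[dv$dose_gy <= 5], rep(100, 6))
  expect_equal(dv$volume_pct[dv$dose_gy > 5], 0)
  # two voxels at 10 and 30 Gy, 10 Gy bins
  g2 <- mk_grid(0, shape = c(2, 1, 1))
  vals <- array(c(10, 30), c(2, 1, 1))
  g2 <- dose_grid(vals, c(1, 1, 1))
  m2 <- structure_mask(array(TRUE, c(2, 1, 1)), c(1, 1, 1))
  dv2 <- cumulative_dvh(g2, m2, bin_width = 10)
  expect_equal(dv2$dose_gy, c(0, 10, 20, 30, 40))
  expect_equal(dv2$volume_pct, c(100, 100, 50, 50, 0))
  expect_true(all(diff(dv2$volume_pct) <= 0))
  expect_error(cumulative_dvh(g, m, bin_width = 0), "positive")
})

test_that("DVH agrees with a voxel-enumeration oracle on random grids", {
  set.seed(7)
  for (rep in 1:5) {
    shape <- c(10, 10, 10)  # 1000 voxels
    g <- dose_grid(array(runif(1000, 0, 80), shape), c(0.5, 0.5, 0.5))
    m <- structure_mask(array(runif(1000) < 0.3, shape), c(0.5, 0.5, 0.5))
    dv <- cumulative_dvh(g, m, bin_width = 2)
    d <- unclass(g)[unclass(m)]
    oracle <- vapply(dv$dose_gy, function(e) 100 * sum(d >= e) / length(d),
                     numeric(1))
    expect_equal(dv$volume_pct, oracle)
    expect_true(all(diff(dv$volume_pct) <= 0))
    expect_equal(dv$volume_pct[1], 100)
    expect_equal(dv$volume_pct[nrow(dv)], 0)
    # Riemann sum over the curve recovers the mean within one bin width
    mean_from_curve <- sum(dv$volume_pct / 100) * attr(dv, "bin_width")
    expect_lt(abs(mean_from_curve - mean(d)), attr(dv, "bin_width"))
  }
})

test_that("plan summaries report per-organ max/mean and flag empty masks", {
  g <- mk_grid(5)
  masks <- list(mk_mask(1:8, label = "ctv"), mk_mask(9:20, label = "rectum"))
  s <- dose_summary(g, masks, plan = "uniform")
  expect_equal(s$max_gy, c(5, 5))
  expect_equal(s$mean_gy, c(5, 5))
  expect_true(all(is.na(s$error)))
  with_empty <- dose_summary(g, c(masks, list(mk_mask(integer(0), label = "void"))))
  expect_equal(with_empty$error[3], "empty mask")
  expect_true(is.na(with_empty$mean_gy[3]))
})

test_that("summary comparison reproduces the printed per-organ deltas", {
  soc <- plan_summary_fixture("soc")
  expect_equal(soc$mean_gy[soc$organ == "ctv"], 75.90)
  mlc_rc <- plan_summary_fixture("mlc_rc")
  mlc <- plan_summary_fixture("mlc_only")
  d1 <- compare_summaries(soc, mlc_rc)
  expect_equal(d1$delta_mean_gy[d1$organ == "bladder"], -0.69)  # 12.18 - 12.87
  d2 <- compare_summaries(soc, mlc)
  expect_equal(d2$delta_mean_gy[d2$organ == "rectum"], 0.03,
               tolerance = 1e-9)  # 16.76 - 16.73
  expect_equal(d2$delta_mean_gy[d2$organ == "ctv"], 0)
  same <- compare_summaries(soc, soc)
  expect_true(all(same$delta_mean_gy == 0) && all(same$delta_max_gy == 0))
  expect_error(compare_summaries(soc, mlc[1:3, ]), "organ sets")
  # the printed anterior-rectal-wall inconsistency is preserved, not corrected
  expect_equal(attr(soc, "suspect_rows"), "anterior_rectal_wall")
  expect_equal(mlc$mean_gy[mlc$organ == "anterior_rectal_wall"], 75.90)
})

test_that("grid and mask NIfTI round-trip preserves values and spacing", {
  skip_if_not_installed("RNifti")
  g <- mk_grid(runif(64, 0, 10))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_dose_grid(g, p)
  back <- read_dose_grid(p)
  expect_equal(unclass(back), unclass(g), ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(attr(back, "spacing"), attr(g, "spacing"), tolerance = 1e-6)
  m <- mk_mask(1:13)
  pm <- withr::local_tempfile(fileext = ".nii.gz")
  write_structure_mask(m, pm)
  mb <- read_structure_mask(pm, label = "ctv")
  expect_equal(unclass(mb), unclass(m), ignore_attr = TRUE)
})
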