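ref <- regimen(79.2, 44)

test_that("BED follows D * (1 + d/ab) and validates its inputs", {
  expect_equal(compute_bed(ref, 3)$bed, 126.72)
  expect_equal(compute_bed(regimen(76, 38), 3)$bed, 76 * 5 / 3)
  # infinitesimal-fraction limit: BED equals the physical dose
  lim <- regimen(total_dose = 10, n_fractions = 5, fraction_size = 0,
                 zero_fraction_ok = TRUE)
  expect_equal(compute_bed(lim, 3)$bed, 10)
  expect_error(regimen(total_dose = 10, n_fractions = 5, fraction_size = 0),
               "positive")
  expect_error(regimen(-79.2, 44), "positive")
  expect_error(regimen(79.2, 44, 2), "inconsistent")
  expect_error(compute_bed(ref, -3), "alpha_beta")
  expect_gte(compute_bed(ref, 1)$bed, ref$total_dose)
})

test_that("isoeffect solve recovers known totals and refuses mismatched alpha/beta", {
  b3 <- compute_bed(ref, 3)
  expect_equal(isoeffective_total_dose(44, b3), 79.2, tolerance = 1e-12)
  expect_equal(isoeffective_total_dose(1, b3), 18.06, tolerance = 1e-3)
  expect_equal(isoeffective_total_dose(1, compute_bed(ref, 1)),
               0.5 * (-1 + sqrt(888.04)), tolerance = 1e-12)
  expect_error(isoeffective_total_dose(1, b3, alpha_beta = 5), "match")
  expect_error(isoeffective_total_dose(0, b3), "positive whole")
  expect_error(isoeffective_total_dose(1, 126.72), "alpha_beta required")
})

test_that("closed form agrees with an independent root-finding oracle", {
  set.seed(42)
  for (i in 1:1000) {
    ab <- runif(1, 0.5, 20)
    n <- sample(1:100, 1)
    bed <- runif(1, 10, 300)
    closed <- isoeffective_total_dose(n, bed, alpha_beta = ab)
    # oracle: bisection on n*d*(1 + d/ab) = BED in d
    root <- uniroot(function(d) n * d * (1 + d / ab) - bed,
                    c(1e-9, 1000), tol = 1e-12)$root
    expect_equal(closed, n * root, tolerance = 1e-8)
  }
})

test_that("inversion closure: BED of the isoeffective regimen recovers the input BED", {
  for (ab in c(0.5, 1, 3, 5, 10, 20)) {
    bed0 <- compute_bed(ref, ab)
    for (n in c(1:10, 25, 50, 100)) {
      D <- isoeffective_total_dose(n, bed0)
      expect_equal(compute_bed(regimen(D, n), ab)$bed, bed0$bed,
                   tolerance = 1e-9)
    }
  }
})

test_that("isoeffective dose is monotone in n and BED; fraction size decreases in n", {
  b <- compute_bed(ref, 3)
  totals <- vapply(1:60, isoeffective_total_dose, numeric(1), bed = b)
  expect_true(all(diff(totals) > 0))
  expect_true(all(diff(totals / (1:60)) < 0))
  beds <- seq(50, 250, by = 10)
  at_n10 <- vapply(beds, isoeffective_total_dose, numeric(1), n = 10,
                   alpha_beta = 3)
  expect_true(all(diff(at_n10) > 0))
})

test_that("photon-to-proton conversion divides by the RBE", {
  expect_equal(photon_to_proton_dose(79.2), 72)
  expect_equal(photon_to_proton_dose(5, rbe = 1), 5)
  expect_equal(round(photon_to_proton_dose(18.0554, 1.1), 1), 16.4)
  expect_error(photon_to_proton_dose(10, rbe = 0), "positive")
  expect_error(photon_to_proton_dose(10, rbe = 0.9), ">= 1")
  expect_error(photon_to_proton_dose(-1), "non-negative")
})

test_that("uncertainty ratio flags clinical significance against the 1.05-1.10 band", {
  u <- uncertainty_ratio(c(13.09, 16.42, 18.95))
  expect_equal(u$ratio, 18.95 / 13.09)
  expect_true(u$clinically_significant)
  same <- uncertainty_ratio(c(60, 60, 60))
  expect_equal(same$ratio, 1)
  expect_false(same$clinically_significant)
  expect_false(same$borderline)
  mid <- uncertainty_ratio(c(100, 108))
  expect_false(mid$clinically_significant)
  expect_true(mid$borderline)
  expect_error(uncertainty_ratio(c(1)), "two totals")
  expect_error(uncertainty_ratio(c(-1, 2)), "positive")
})

test_that("equivalence table is sorted, internally consistent and anchored at n = 44", {
  eq <- equivalence_table()
  expect_equal(eq$n, sort(eq$n))
  un <- attr(eq, "unrounded")
  # totals = n * fraction size before rounding
  for (ab in c(1, 3, 5))
    expect_equal(un[[paste0("total_", ab)]],
                 un$n * un[[paste0("frac_", ab)]], tolerance = 1e-12)
  # fixed point: at the reference fraction count every alpha/beta returns
  # the reference total over the RBE, and the ratio is exactly 1
  row44 <- un[un$n == 44, ]
  for (ab in c(1, 3, 5))
    expect_equal(row44[[paste0("total_", ab)]], 72, tolerance = 1e-12)
  expect_equal(row44$ratio, 1, tolerance = 1e-12)
  expect_false(eq$clinically_significant[eq$n == 44])
  expect_error(equivalence_table(alpha_beta = numeric(0)), "non-empty")
  expect_error(equivalence_table(n_grid = integer(0)), "non-empty")
})

test_that("equivalence CSV round-trips with the min/mid/max layout", {
  eq <- equivalence_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_equivalence_csv(eq, path)
  back <- read.csv(path)
  expect_named(back, c("n", "frac_min", "frac_mid", "frac_max",
                       "total_min", "total_mid", "total_max", "ratio"))
  expect_equal(back$total_mid[back$n == 1], 16.4)
  expect_equal(back$ratio[back$n == 20], 1.14)
})
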