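# Frozen expected values below were computed by direct hand evaluation of the
# published formulas with natural logarithms (independent arithmetic, not the
# package's evaluator).

test_that("published equations reproduce hand-evaluated cohort medians", {
  med <- median_record()
  expect_equal(estimate_eq1(med), 5.053889, tolerance = 1e-6)
  expect_equal(estimate_eq2(med), 5.142773, tolerance = 1e-6)
  expect_equal(estimate_eq3(med), 5.358384, tolerance = 1e-6)
})

test_that("all log terms vanish at 1 so the intercept is returned", {
  rec <- data.frame(albumin = 0, d25_3 = 1, d25_2 = 1, vdbp = 1,
                    d1_25_3 = 1, d24_25_3 = 1, ipth = 1,
                    phenotype = "Gc1f/Gc1f")
  expect_equal(estimate_eq1(rec), 12.202)
  expect_equal(estimate_eq2(rec), 12.779)
  expect_equal(estimate_eq3(rec), 3.098)
})

test_that("Gc diplotype offsets shift eq2 estimates by the published amounts", {
  offsets <- c("Gc1f/Gc1f" = 0, "Gc1f/Gc1s" = 0.019716,
               "Gc1s/Gc1s" = 0.002741, "Gc2/Gc1f" = -0.394562,
               "Gc2/Gc1s" = -0.1283514, "Gc2/Gc2" = -0.1381116)
  ref <- estimate_eq2(median_record("Gc1f/Gc1f"))
  for (ph in names(offsets)) {
    expect_equal(estimate_eq2(median_record(ph)) - ref, unname(offsets[ph]),
                 tolerance = 1e-12)
  }
  # pairwise difference quoted for the two most common heterozygotes
  expect_equal(estimate_eq2(median_record("Gc1f/Gc1s")) -
                 estimate_eq2(median_record("Gc1s/Gc1s")),
               0.019716 - 0.002741, tolerance = 1e-12)
})

test_that("missing or non-positive inputs fail loudly", {
  med <- median_record()
  expect_error(estimate_eq1(med[, setdiff(names(med), "vdbp")]), "vdbp")
  bad <- med; bad$d25_3 <- 0
  expect_error(estimate_eq1(bad), "non-positive")
  expect_error(evaluate_equation(eq2_spec(),
                                 transform(med, phenotype = NA)),
               "phenotype")
})

test_that("estimates respond linearly to a coefficient perturbation", {
  med <- median_record()
  delta <- 0.125
  spec <- eq1_spec()
  base <- evaluate_equation(spec, med)
  i <- which(spec$terms$variable == "d1_25_3")
  spec$terms$coefficient[i] <- spec$terms$coefficient[i] + delta
  expect_equal(evaluate_equation(spec, med) - base, delta * log(40.2),
               tolerance = 1e-10)
  # interaction coefficient likewise
  spec <- eq1_spec()
  spec$interactions$coefficient <- spec$interactions$coefficient + delta
  expect_equal(evaluate_equation(spec, med) - base,
               delta * log(20.3) * log(1.7), tolerance = 1e-10)
})

test_that("eq2 shares eq1's term structure plus diplotype offsets", {
  e1 <- eq1_spec(); e2 <- eq2_spec()
  expect_setequal(e2$terms$variable, e1$terms$variable)
  expect_null(e1$phenotype_offsets)
  expect_named(e2$phenotype_offsets, gc_diplotypes())
  expect_identical(e2$phenotype_offsets[["Gc1f/Gc1f"]], 0)
})

test_that("Bikle estimate matches the hand computation at cohort medians", {
  med <- median_record()
  est <- estimate_bikle(med)
  expect_equal(est, 5.312667, tolerance = 1e-6)
  # implied equilibrium denominator ~ 3883
  expect_equal((20.3 + 0.33) * 1000 / est, 3883.17, tolerance = 1e-4)
})

test_that("Bikle estimate has the correct equilibrium limits", {
  free_total <- estimate_bikle(data.frame(d25_3 = 20, d25_2 = 0, vdbp = 0,
                                          albumin = 0))
  expect_equal(free_total, 20000) # pg/mL: free equals total
  # strictly decreasing in VDBP
  grid <- data.frame(d25_3 = 20.3, d25_2 = 0.33, albumin = 4.3,
                     vdbp = c(50, 150, 253.3, 400, 800))
  expect_true(all(diff(estimate_bikle(grid)) < 0))
  # and in albumin
  grid2 <- data.frame(d25_3 = 20.3, d25_2 = 0.33, vdbp = 253.3,
                      albumin = c(1, 2.5, 4.3, 5.5))
  expect_true(all(diff(estimate_bikle(grid2)) < 0))
  expect_error(estimate_bikle(data.frame(d25_3 = 20, vdbp = -1, albumin = 4)),
               "non-negative")
})

test_that("Bikle estimate agrees with an all-molar brute-force evaluation", {
  # independent route: convert total 25(OH)D itself to molar, solve the
  # equilibrium on the molar scale, convert back to pg/mL
  k <- binding_constants()
  set.seed(41)
  d <- data.frame(d25_3 = runif(50, 5, 60), d25_2 = runif(50, 0.2, 5),
                  vdbp = runif(50, 120, 450), albumin = runif(50, 2.5, 5.2))
  denom <- 1 + k$ka_dbp * to_molar(d$vdbp, "VDBP", k) +
    k$ka_alb * to_molar(d$albumin, "albumin", k)
  total_molar <- to_molar(d$d25_3 + d$d25_2, "25(OH)D-total", k)
  oracle_pg_ml <- from_molar(total_molar / denom, "25(OH)D-total", k) * 1000
  expect_equal(estimate_bikle(d, k), oracle_pg_ml, tolerance = 1e-9)
  # free fraction bounded in (0, 1]
  frac <- estimate_bikle(d, k) / ((d$d25_3 + d$d25_2) * 1000)
  expect_true(all(frac > 0 & frac <= 1))
})

test_that("vitamin D metabolite ratio is 100 x 24,25(OH)2D3 / 25(OH)D3", {
  expect_equal(vmr(0, 20.3), 0)
  expect_equal(vmr(1.7, 20.3), 8.374384, tolerance = 1e-6)
  expect_equal(vmr(2, 20), vmr(4, 40)) # scale invariance
  expect_error(vmr(1.7, 0), "positive")
  expect_error(vmr(-0.1, 20.3), "non-negative")
})

test_that("negative estimates are flagged, not clipped", {
  # extreme inputs push eq1 negative
  rec <- data.frame(albumin = 2, d25_3 = 1.1, d25_2 = 0.2, vdbp = 600,
                    d1_25_3 = 90, d24_25_3 = 9)
  expect_warning(est <- estimate_eq1(rec), "negative")
  expect_true(est < 0)
  expect_equal(floor_estimates(est), 0.1)
})
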