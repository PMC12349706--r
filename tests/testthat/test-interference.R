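# Perkins distances, CoC/interference and the Z-tests.

test_that("Perkins distance follows the tetrad formula", {
  all_T <- tetrad_class_counts(c(B = 100))          # every tetrad a tetratype
  expect_equal(perkins_distance(all_T, 1)$distance, 50)
  all_P <- tetrad_class_counts(c(A = 100))
  expect_equal(perkins_distance(all_P, 1)$distance, 0)
  ex <- tetrad_class_counts(c(A = 878, B = 120, D = 2))
  d <- perkins_distance(ex, 1)
  expect_equal(d$distance, 100 * (60 + 6) / 1000)   # 6.6 cM
  expect_identical(c(d$T_count, d$N_count), c(120L, 2L))
  expect_error(perkins_distance(tetrad_class_counts(c(A = 0)), 1), "n = 0")
})

test_that("Perkins distance depends only on ditypes, not class letters", {
  # move tetratype counts between classes sharing ditype_I1 = T
  a <- tetrad_class_counts(c(A = 800, B = 100, F = 40, G = 30, H = 20, I = 10))
  b <- tetrad_class_counts(c(A = 800, B = 100, F = 10, G = 20, H = 30, I = 40))
  expect_equal(perkins_distance(a, 1)$distance, perkins_distance(b, 1)$distance)
  expect_equal(coc_interference(a)$interference, coc_interference(b)$interference)
})

test_that("recombinant frequencies count each tetrad once", {
  all_P <- tetrad_class_counts(c(A = 50))
  expect_equal(unname(recombinant_frequencies(all_P)), c(0, 0, 0))
  mix <- tetrad_class_counts(c(A = 68, B = 20, C = 10, F = 2))
  expect_equal(unname(recombinant_frequencies(mix)), c(0.22, 0.12, 0.02))
})

test_that("CoC is 1 (interference 0) under exact independence", {
  cc <- tetrad_class_counts(c(A = 720, B = 180, C = 80, F = 20))
  est <- coc_interference(cc)
  expect_equal(est$coc, 1)
  expect_equal(est$interference, 0)
  expect_identical(est$flags, character(0))
})

test_that("zero doubles flag and undefined CoC error behave as documented", {
  nod <- tetrad_class_counts(c(A = 900, B = 60, C = 40))
  est <- coc_interference(nod)
  expect_equal(est$interference, 1)
  expect_true("no_doubles" %in% est$flags)
  expect_error(coc_interference(tetrad_class_counts(c(A = 99, B = 1))),
               "undefined")
})

test_that("f12 is compatible with f1*f2 on no-interference simulations", {
  s <- simulate_tetrads(50000, map_10_10(), params_poisson(), seed = 71)
  est <- coc_interference(tabulate_tetrads(s))
  expect_lt(abs(est$interference), 3 * est$se_interference)
})

test_that("delta-method SE agrees with the tetrad-resampling bootstrap", {
  s <- simulate_tetrads(2000, map_10_10(), pathway_params(), seed = 81)
  cc <- tabulate_tetrads(s)
  se_d <- coc_interference(cc)$se_interference
  se_b <- coc_interference(cc, se_method = "bootstrap",
                           boot_reps = 10000, boot_seed = 2)$se_interference
  expect_lt(abs(se_d - se_b) / se_b, 0.15)
})

test_that("two-proportion Z-test matches the pooled-variance formula", {
  eq <- ztest_proportions(25, 100, 50, 200)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  z <- ztest_proportions(30, 100, 10, 100)
  # oracle: pooled p = 0.2, z = 0.2 / sqrt(0.2*0.8*(1/100+1/100))
  expect_equal(z$statistic, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(round(z$statistic, 3), 3.536)
  # equals the square root of the uncorrected chi-square statistic
  x2 <- stats::prop.test(c(30, 10), c(100, 100), correct = FALSE)$statistic
  expect_equal(z$statistic^2, unname(x2), tolerance = 1e-12)

  z2 <- ztest_proportions(10, 100, 30, 100)
  expect_equal(z2$statistic, -z$statistic)
  expect_equal(z2$p_value, z$p_value)
  expect_error(ztest_proportions(0, 50, 0, 60), "degenerate")
})

test_that("interference Z-test is null on identical tables and calibrated power", {
  cc <- tetrad_class_counts(c(A = 720, B = 180, C = 80, F = 10))
  zi <- ztest_interference(cc, cc)
  expect_equal(zi$statistic, 0)
  expect_equal(zi$p_value, 1)

  # power: no-interference vs strong-interference genotypes are separated
  hits <- 0L
  for (r in 1:200) {
    c1 <- tabulate_tetrads(simulate_tetrads(
      5000, map_10_10(), pathway_params(nu = 1, frac_class2 = 0), seed = 3000 + 2 * r))
    c2 <- tabulate_tetrads(simulate_tetrads(
      5000, map_10_10(), params_interfering(), seed = 3001 + 2 * r))
    if (ztest_interference(c1, c2)$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("estimated interference is non-decreasing in the gamma shape", {
  vals <- ses <- numeric(5)
  nus <- c(1, 2, 4, 8, 16)
  for (i in seq_along(nus)) {
    s <- simulate_tetrads(50000, map_10_10(),
                          pathway_params(nu = nus[i], frac_class2 = 0),
                          seed = 90 + i)
    e <- coc_interference(tabulate_tetrads(s))
    vals[i] <- e$interference; ses[i] <- e$se_interference
  }
  for (i in 2:5) {
    expect_gt(vals[i] - vals[i - 1], -2 * sqrt(ses[i]^2 + ses[i - 1]^2))
  }
  expect_gt(vals[5], vals[1])  # strictly separated at the extremes
})

test_that("Perkins distance recovers the simulated map", {
  map <- interval_pair_map(d1 = 6, d2 = 12)
  cc <- tabulate_tetrads(simulate_tetrads(50000, map, pathway_params(), seed = 101))
  expect_lt(abs(perkins_distance(cc, 1)$distance - 6), 0.5)
  expect_lt(abs(perkins_distance(cc, 2)$distance - 12), 0.5)
})

test_that("per-plant and pooled estimates are consistent", {
  one <- tetrad_class_counts(c(A = 720, B = 180, C = 80, F = 20), plant = 1)
  res1 <- per_plant_and_pooled(list(one))
  expect_equal(res1$per_plant_mean[["distance1"]],
               res1$pooled_distance1$distance)
  two <- per_plant_and_pooled(list(one, one))
  expect_equal(two$per_plant_mean[["interference"]], two$pooled$interference)

  # 8 simulated plants: pooled within 2 bootstrap SE of the per-plant mean
  plants <- lapply(1:8, function(p)
    tabulate_tetrads(simulate_tetrads(600, map_10_10(), pathway_params(),
                                      seed = 500 + p), plant = p))
  res <- per_plant_and_pooled(plants)
  se_b <- coc_interference(
    tetrad_class_counts(Reduce(`+`, lapply(plants, `[[`, "counts"))),
    se_method = "bootstrap", boot_reps = 2000, boot_seed = 3)$se_interference
  expect_lt(abs(res$pooled$interference - res$per_plant_mean[["interference"]]),
            2 * se_b)
})
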