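# Two-pathway crossover simulator: point processes, chromatid assignment,
# tetrad formation, metaphase cells and foci counts.

test_that("zero-rate processes yield no crossovers and bad parameters error", {
  set.seed(1)
  expect_identical(place_class1_crossovers(1, nu = 5, rate1 = 0), numeric(0))
  expect_identical(place_class2_crossovers(1, rate2 = 0), numeric(0))
  expect_identical(place_class2_crossovers(0, rate2 = 3), numeric(0))
  expect_error(place_class1_crossovers(-1, 5, 2), "span")
  expect_error(place_class1_crossovers(1, 0, 2), "nu")
  expect_error(place_class1_crossovers(1, 5, -1), "rate1")
  expect_error(place_class2_crossovers(1, -0.1), "rate2")
})

test_that("nu = 1 reduces to a Poisson process (mean count and exponential gaps)", {
  set.seed(42)
  reps <- 10000
  counts <- integer(reps)
  for (i in seq_len(reps)) {
    counts[i] <- length(place_class1_crossovers(1, nu = 1, rate1 = 2))
  }
  se <- stats::sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - 2), 3 * se)
  # gap law checked on one long realisation (short windows truncate gaps)
  gaps <- diff(place_class1_crossovers(5000, nu = 1, rate1 = 2))
  ks <- stats::ks.test(gaps, "pexp", rate = 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("Class II counts are Poisson with independent disjoint subspans", {
  set.seed(17)
  reps <- 10000
  n_left <- n_right <- integer(reps)
  for (i in seq_len(reps)) {
    p <- place_class2_crossovers(0.5, rate2 = 2)
    n_left[i] <- sum(p < 0.25)
    n_right[i] <- sum(p >= 0.25)
  }
  tot <- n_left + n_right
  expect_lt(abs(mean(tot) - 1), 3 * stats::sd(tot) / sqrt(reps))
  expect_lt(abs(stats::cor(n_left, n_right)), 0.05)
})

test_that("gamma shape controls inter-event regularity (CV ~ 1/sqrt(nu))", {
  set.seed(7)
  pos <- place_class1_crossovers(6000, nu = 10, rate1 = 2)
  g <- diff(pos)  # interior gaps, equilibrium first draw excluded
  expect_gt(length(g), 10000)
  cv <- stats::sd(g) / mean(g)
  expect_lt(abs(cv - 1 / sqrt(10)), 0.02)
})

test_that("chromatid assignment is uniform over the four non-sister pairings", {
  set.seed(11)
  ev <- data.frame(position = rep(0.5, 100000), pathway = "class1")
  ev <- assign_chromatids(ev)
  f <- table(ev$chromatid_a, ev$chromatid_b) / nrow(ev)
  expect_true(all(abs(f - 0.25) < 0.005))

  # two events per bivalent: pairings independent across events
  n <- 100000
  e1 <- assign_chromatids(data.frame(position = rep(0.1, n), pathway = "x"))
  e2 <- assign_chromatids(data.frame(position = rep(0.2, n), pathway = "x"))
  p1 <- (e1$chromatid_a - 1L) * 2L + (e1$chromatid_b - 3L)
  p2 <- (e2$chromatid_a - 1L) * 2L + (e2$chromatid_b - 3L)
  expect_gt(suppressWarnings(stats::chisq.test(table(p1, p2))$p.value), 0.01)
})

test_that("no crossovers gives a parental ditype and 2:2 segregation always holds", {
  set.seed(3)
  t0 <- generate_tetrad(map_10_10(), pathway_params(total_rate = 0))
  codes <- sort(spore_codes(t0), decreasing = TRUE)
  expect_identical(codes, c(7L, 7L, 0L, 0L))

  for (p in list(params_poisson(), params_interfering(), pathway_params())) {
    s <- simulate_tetrads(2000, map_10_10(), p, seed = 5)
    for (bit in c(4L, 2L, 1L)) {
      carriers <- matrix(bitwAnd(s$codes, bit) > 0L, nrow(s$codes), 4L)
      expect_true(all(rowSums(carriers) == 2L))
    }
  }
})

test_that("recombinant spore fraction matches map distance for a small interval", {
  map <- interval_pair_map(d1 = 6, d2 = 6)
  s <- simulate_tetrads(20000, map, params_poisson(), seed = 9)
  m1 <- matrix(bitwAnd(s$codes, 4L) > 0L, nrow(s$codes), 4L)
  m2 <- matrix(bitwAnd(s$codes, 2L) > 0L, nrow(s$codes), 4L)
  rec_per_tetrad <- rowSums(m1 != m2)
  frac <- mean(rec_per_tetrad) / 4
  se <- stats::sd(rec_per_tetrad / 4) / sqrt(nrow(s$codes))
  # exact Poisson expectation (Haldane): r = (1 - exp(-2d))/2; at this
  # sample size the Monte-Carlo precision resolves the multi-CO correction,
  # so the exact value is the reference and 0.06 the small-d approximation
  r_exact <- (1 - exp(-2 * 0.06)) / 2
  expect_lt(abs(frac - r_exact), 3 * se)
  expect_lt(abs(frac - 0.06), 0.005)
})

test_that("simulation is reproducible under a fixed seed and validates n", {
  a <- simulate_tetrads(500, map_10_10(), pathway_params(), seed = 123)
  b <- simulate_tetrads(500, map_10_10(), pathway_params(), seed = 123)
  expect_identical(a$codes, b$codes)
  expect_identical(a$n_class1, b$n_class1)
  expect_error(simulate_tetrads(0, map_10_10(), pathway_params(), seed = 1), "n")
})

test_that("downstream interference responds to the simulated pathway mix", {
  # pure Poisson: interference compatible with 0
  s0 <- simulate_tetrads(5000, map_10_10(), params_poisson(), seed = 21)
  e0 <- coc_interference(tabulate_tetrads(s0))
  expect_lt(abs(e0$interference), 3 * e0$se_interference)
  # strong Class I interference
  s1 <- simulate_tetrads(5000, map_10_10(), params_interfering(), seed = 22)
  e1 <- coc_interference(tabulate_tetrads(s1))
  expect_gt(e1$interference, 0.3)
})

test_that("metaphase cell simulation produces consistent shapes and truth", {
  z <- simulate_metaphase_cells(200, per_arm_expected_co = 0, seed = 1)
  expect_true(all(z$univalent_pairs == 5))
  expect_true(all(z$true_chiasmata == 0))

  hi <- simulate_metaphase_cells(300, per_arm_expected_co = 15, seed = 2)
  expect_true(all(hi$ring == 5))
  est <- vapply(seq_len(nrow(hi)), function(i) chiasma_count(hi[i, ]), numeric(1))
  expect_lt(mean(est), mean(hi$true_chiasmata))  # ring=2 undercounts

  mid <- simulate_metaphase_cells(400, per_arm_expected_co = 0.9, seed = 3)
  expect_lt(abs(mean(mid$true_chiasmata) - 9), 0.5)
  expect_gt(sum(mid$ring), 0)
  expect_gt(sum(mid$rod), 0)
})

test_that("foci simulation hits the family mean and handles edge cases", {
  x <- simulate_foci(10000, "poisson", list(mean = 8.4), seed = 4)
  expect_lt(abs(mean(x) - 8.4), 3 * stats::sd(x) / sqrt(length(x)))

  z <- simulate_foci(10000, "zero_inflated_poisson", list(pi = 0.9, lambda = 20),
                     seed = 5)
  expect_gte(mean(z == 0), 0.85)

  nb <- simulate_foci(10000, "negative_binomial", list(mean = 10, size = 2),
                      seed = 6)
  expect_lt(abs(mean(nb) - 10), 3 * stats::sd(nb) / sqrt(length(nb)))
  expect_gt(stats::var(nb), mean(nb))  # overdispersed

  expect_identical(simulate_foci(0, "poisson", list(mean = 5), seed = 1),
                   integer(0))
  expect_error(simulate_foci(10, "gamma", list(), seed = 1))
})
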