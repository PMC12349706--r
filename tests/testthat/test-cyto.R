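# Chiasma scoring, bivalent and foci summaries, and the nonparametric tests.

test_that("chiasma scoring is the documented weighted sum", {
  expect_equal(chiasma_count(list(ring = 5, rod = 0)), 10)
  expect_equal(chiasma_count(list(ring = 3, rod = 2)), 8)
  expect_equal(chiasma_count(list(ring = 2, ring3 = 1, rod = 2)), 9)
  expect_equal(chiasma_count(list(ring = 0, rod = 0, univalent_pairs = 5)), 0)
  expect_error(chiasma_count(list(ring = 4, rod = 2)), "5 bivalents")
  # additive over bivalents
  expect_equal(chiasma_count(list(ring = 2, rod = 1)),
               chiasma_count(list(ring = 2)) + chiasma_count(list(rod = 1)))
})

test_that("shape-based estimate never exceeds the true chiasma count", {
  cells <- simulate_metaphase_cells(500, per_arm_expected_co = 1.2, seed = 12)
  est <- 2 * cells$ring + cells$rod
  expect_true(all(est <= cells$true_chiasmata))
})

test_that("bivalent summaries report mean, SD and distribution", {
  df <- data.frame(genotype = "m", bivalents = c(1, 1, 2))
  res <- mean_bivalents(df)
  expect_equal(res$summary$mean, 4 / 3)
  expect_equal(res$summary$n, 3L)
  expect_equal(sum(res$distribution["m", ]), 100)

  zero <- mean_bivalents(data.frame(genotype = "z", bivalents = rep(0, 5)))
  expect_equal(zero$summary$mean, 0)

  shapes <- data.frame(genotype = c("a", "a"), ring = c(1, 0), rod = c(2, 1))
  expect_equal(mean_bivalents(shapes)$summary$mean, 2)
  expect_error(mean_bivalents(data.frame(genotype = character(0),
                                         bivalents = numeric(0))))
})

test_that("foci bins partition counts with closed edges as printed", {
  h <- bin_foci(data.frame(genotype = "g", count = c(0, 2, 5, 15, 30, 60)))
  expect_equal(unname(unlist(h[1, -1])), rep(100 / 6, 6), tolerance = 1e-12)

  edges <- bin_foci(data.frame(genotype = "g",
                               count = c(1, 2, 3, 10, 11, 20, 21, 50, 51)))
  expect_equal(unname(unlist(edges[1, c("1-2", "3-10", "11-20", "21-50", ">50")])),
               100 * c(2, 2, 2, 2, 1) / 9, tolerance = 1e-12)
  expect_equal(sum(unlist(edges[1, -1])), 100, tolerance = 0.01)
  expect_error(bin_foci(data.frame(genotype = character(0), count = numeric(0))))
  expect_error(bin_foci(data.frame(genotype = "g", count = -1)), "negative")
})

test_that("Mann-Whitney exact branch matches enumeration and flags degeneracy", {
  same <- mann_whitney(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_identical(same$flags, "degenerate")

  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(mw$statistic), 0)
  expect_equal(mw$p_value, 0.1)  # 2 * (1/20): complete separation of 3 vs 3
  expect_match(mw$method, "exact")
})

test_that("Mann-Whitney approximation tracks the exact law and a permutation oracle", {
  # exact vs approximate branch on random tie-free 15 vs 15 samples
  set.seed(77)
  maxdiff <- 0
  for (r in 1:200) {
    x <- sample(1000, 30)
    a <- x[1:15]; b <- x[16:30]
    pe <- mann_whitney(a, b, exact_max = 400)$p_value
    pa <- mann_whitney(a, b, force_approx = TRUE)$p_value
    maxdiff <- max(maxdiff, abs(pe - pa))
  }
  expect_lt(maxdiff, 0.005)

  # 50 vs 50 tie-free: approximate p within 0.005 of a permutation p
  set.seed(78)
  x <- sample(10000, 100)
  a <- x[1:50] + 40; b <- x[51:100]
  obs <- mann_whitney(a, b)
  pool <- c(a, b)
  stat <- function(idx) {
    rk <- rank(pool)
    sum(rk[idx]) - 50 * 51 / 2
  }
  u_obs <- unname(obs$statistic)
  mu <- 50 * 50 / 2
  perm <- replicate(1e5, {
    idx <- sample.int(100, 50)
    stat(idx)
  })
  p_perm <- mean(abs(perm - mu) >= abs(u_obs - mu))
  expect_lt(abs(obs$p_value - p_perm), 0.005)
})

test_that("Kruskal-Wallis + Dunn agree with direct rank computation", {
  idg <- kruskal_dunn(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(idg$statistic, 0)
  expect_equal(idg$p_value, 1)

  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kd <- kruskal_dunn(g)
  # brute-force H from the rank formula (no ties)
  rk <- rank(unlist(g)); N <- 9
  Rbar <- tapply(rk, rep(names(g), each = 3), sum)
  H <- 12 / (N * (N + 1)) * sum(Rbar^2 / 3) - 3 * (N + 1)
  expect_equal(kd$statistic, H)
  expect_identical(nrow(kd$pairwise), 3L)
  expect_true(all(kd$pairwise$p_adjusted >= kd$pairwise$p_unadjusted))
  expect_error(kruskal_dunn(list(a = 1:3, b = numeric(0))), "empty")
})

test_that("Kruskal-Wallis type-I error is calibrated under the null", {
  set.seed(99)
  rej <- 0L
  for (r in 1:1000) {
    g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    if (kruskal_dunn(g)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("unpaired t-test matches hand computation and is scale invariant", {
  same <- ttest_unpaired(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  tt <- ttest_unpaired(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(round(tt$statistic, 4), -1.0954)
  ts <- ttest_unpaired(10 * c(1, 2, 3, 4), 10 * c(2, 3, 4, 5))
  expect_equal(ts$statistic, tt$statistic)

  deg <- ttest_unpaired(c(2, 2), c(2, 2))
  expect_identical(deg$flags, "degenerate")
  w <- ttest_unpaired(c(1, 2, 3, 4), c(2, 3, 4, 50), welch = TRUE)
  expect_match(w$method, "Welch")
})

test_that("normality screen separates normal from skewed samples", {
  set.seed(13)
  nn <- normality_screen(rnorm(500))
  expect_gt(nn$p_value, 0.001)
  ex <- normality_screen(rexp(500))
  expect_lt(ex$p_value, 0.01)
  expect_error(normality_screen(1:5), "n >= 8")
})
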