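# Perkins map distances, coefficient of coincidence, interference, and
# Z-tests between genotypes.

# Resolve class counts into per-interval T/N counts and the 2x2
# recombinant/non-recombinant tetrad table, via the canonical class table
# (letters themselves never enter the arithmetic).
counts_by_ditype <- function(class_counts) {
  stopifnot(inherits(class_counts, "tetrad_class_counts"))
  tab <- enumerate_tetrad_classes()
  cnt <- class_counts$counts[tab$label]
  r1 <- tab$ditype_I1 %in% c("T", "N")
  r2 <- tab$ditype_I2 %in% c("T", "N")
  list(
    n = class_counts$n,
    T1 = sum(cnt[tab$ditype_I1 == "T"]), N1 = sum(cnt[tab$ditype_I1 == "N"]),
    T2 = sum(cnt[tab$ditype_I2 == "T"]), N2 = sum(cnt[tab$ditype_I2 == "N"]),
    n10 = sum(cnt[r1 & !r2]),   # recombinant in I1 only
    n01 = sum(cnt[!r1 & r2]),   # recombinant in I2 only
    n11 = sum(cnt[r1 & r2]),    # recombinant in both
    n00 = sum(cnt[!r1 & !r2])
  )
}

#' Perkins map distance of one interval
#'
#' Tetrad-based genetic distance, `X = 100 * (T/2 + 3 * NPD) / n` cM, with
#' a multinomial delta-method standard error over the (T, NPD) counts.
#'
#' @param class_counts A `tetrad_class_counts` object.
#' @param interval_index 1 or 2.
#' @return List with `distance` (cM), `se`, `n`, `T_count`, `N_count`.
#' @examples
#' cc <- tetrad_class_counts(c(A = 878, B = 120, D = 2), genotype = "wt")
#' perkins_distance(cc, 1)$distance  # 100*(60 + 6)/1000 = 6.6 cM
#' @export
perkins_distance <- function(class_counts, interval_index) {
  d <- counts_by_ditype(class_counts)
  if (d$n == 0L) stop("no tetrads: n = 0")
  Tc <- if (interval_index == 1L) d$T1 else if (interval_index == 2L) d$T2 else
    stop("`interval_index` must be 1 or 2")
  Nc <- if (interval_index == 1L) d$N1 else d$N2
  n <- d$n
  pT <- Tc / n; pN <- Nc / n
  dist <- 100 * (pT / 2 + 3 * pN)
  v <- (100^2 / n) * (0.25 * pT * (1 - pT) + 9 * pN * (1 - pN) -
                        2 * 1.5 * pT * pN)
  list(distance = dist, se = sqrt(max(v, 0)), n = n,
       T_count = Tc, N_count = Nc)
}

#' Per-interval and joint recombinant tetrad frequencies
#'
#' A tetrad is recombinant in an interval if its ditype there is T or N;
#' each tetrad is counted once regardless of ditype (an NPD is not
#' double-weighted). `f12` is the fraction recombinant in both intervals.
#'
#' @param class_counts A `tetrad_class_counts` object.
#' @return Named numeric vector `c(f1, f2, f12)`.
#' @export
recombinant_frequencies <- function(class_counts) {
  d <- counts_by_ditype(class_counts)
  if (d$n == 0L) stop("no tetrads: n = 0")
  c(f1 = (d$n10 + d$n11) / d$n,
    f2 = (d$n01 + d$n11) / d$n,
    f12 = d$n11 / d$n)
}

#' Coefficient of coincidence and interference
#'
#' `CoC = f12 / (f1 * f2)` where `f1`, `f2` are the per-interval
#' recombinant-tetrad frequencies and `f12` the double-recombinant
#' frequency; interference is `1 - CoC`, so 0 indicates absence of
#' interference and values near 1 indicate strong positive interference.
#' The standard error of interference is computed by the multinomial delta
#' method on the 2x2 recombinant/non-recombinant tetrad table, with a
#' seeded tetrad-resampling bootstrap available as the reference method.
#'
#' If no double recombinants are observed while `f1, f2 > 0`, interference
#' is 1 with the `no_doubles` flag set (the delta-method SE is then 0 and
#' the bootstrap SE is more trustworthy).
#'
#' @param class_counts A `tetrad_class_counts` object.
#' @param se_method `"delta"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed Bootstrap replicates and seed.
#' @return Object of class `coc_estimate`: list with `f1`, `f2`, `f12`,
#'   `coc`, `interference`, `se_interference`, `n`, `flags`.
#' @export
coc_interference <- function(class_counts, se_method = c("delta", "bootstrap"),
                             boot_reps = 1000, boot_seed = 1) {
  se_method <- match.arg(se_method)
  d <- counts_by_ditype(class_counts)
  if (d$n == 0L) stop("no tetrads: n = 0")
  f <- recombinant_frequencies(class_counts)
  if (f[["f1"]] == 0 || f[["f2"]] == 0) {
    stop(sprintf(
      "CoC undefined: single-interval recombinant count is zero (n10=%d, n01=%d, n11=%d, n=%d)",
      d$n10, d$n01, d$n11, d$n))
  }
  coc <- f[["f12"]] / (f[["f1"]] * f[["f2"]])
  flags <- character(0)
  if (d$n11 == 0L) flags <- c(flags, "no_doubles")

  se <- switch(se_method,
    delta = coc_delta_se(d$n10, d$n01, d$n11, d$n),
    bootstrap = coc_boot_se(d$n10, d$n01, d$n11, d$n, boot_reps, boot_seed)
  )
  structure(
    list(f1 = unname(f[["f1"]]), f2 = unname(f[["f2"]]),
         f12 = unname(f[["f12"]]), coc = coc, interference = 1 - coc,
         se_interference = se, n = d$n, se_method = se_method, flags = flags),
    class = "coc_estimate"
  )
}

# Delta-method SE of interference (= SE of CoC) from the 2x2 tetrad table.
# g(p) = p11 / ((p10+p11)(p01+p11)); multinomial covariance of proportions.
coc_delta_se <- function(n10, n01, n11, n) {
  p <- c(n10, n01, n11) / n
  f1 <- p[1] + p[3]; f2 <- p[2] + p[3]
  g <- p[3] / (f1 * f2)
  grad <- c(-g / f1,
            -g / f2,
            1 / (f1 * f2) - g / f1 - g / f2)
  Sigma <- (diag(p) - tcrossprod(p)) / n
  v <- drop(t(grad) %*% Sigma %*% grad)
  sqrt(max(v, 0))
}

coc_boot_se <- function(n10, n01, n11, n, reps, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  pr <- c(n10, n01, n11, n - n10 - n01 - n11) / n
  draws <- stats::rmultinom(reps, n, pr)
  ii <- apply(draws, 2, function(x) {
    f1 <- (x[1] + x[3]) / n; f2 <- (x[2] + x[3]) / n
    if (f1 == 0 || f2 == 0) return(NA_real_)
    1 - (x[3] / n) / (f1 * f2)
  })
  stats::sd(ii, na.rm = TRUE)
}

#' @export
print.coc_estimate <- function(x, ...) {
  cat(sprintf(
    "CoC = %.4f, interference = %.4f (SE %.4f, %s), n = %d\n  f1 = %.4f, f2 = %.4f, f12 = %.5f%s\n",
    x$coc, x$interference, x$se_interference, x$se_method, x$n,
    x$f1, x$f2, x$f12,
    if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Two-proportion Z-test
#'
#' Pooled-variance two-proportion Z with a two-sided normal p-value, as used
#' to compare per-interval recombinant frequencies between genotypes.
#'
#' @param x1,n1,x2,n2 Successes and trials in the two groups.
#' @return List with `statistic`, `p_value`, `method`, `estimate` (the two
#'   proportions).
#' @export
ztest_proportions <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("need 0 <= x <= n")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    stop("degenerate test: pooled proportion is 0 or 1")
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
       method = "two-proportion Z-test (pooled variance)",
       estimate = c(p1 = p1, p2 = p2))
}

#' Z-test comparing interference between two genotypes
#'
#' `z = (I1 - I2) / sqrt(se1^2 + se2^2)` with delta-method (default) or
#' bootstrap standard errors of interference, and a two-sided normal
#' p-value.
#'
#' @param counts_g1,counts_g2 `tetrad_class_counts` for the two genotypes.
#' @param se_method Passed to [coc_interference()].
#' @param ... Further arguments (e.g. `boot_reps`) passed on.
#' @return List with `statistic`, `p_value`, `method`, and the two
#'   `coc_estimate` objects.
#' @export
ztest_interference <- function(counts_g1, counts_g2,
                               se_method = c("delta", "bootstrap"), ...) {
  se_method <- match.arg(se_method)
  e1 <- coc_interference(counts_g1, se_method = se_method, ...)
  e2 <- coc_interference(counts_g2, se_method = se_method, ...)
  se <- sqrt(e1$se_interference^2 + e2$se_interference^2)
  z <- if (se == 0 && e1$interference == e2$interference) 0 else
    (e1$interference - e2$interference) / se
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
       method = sprintf("interference Z-test (%s SE)", se_method),
       group1 = e1, group2 = e2)
}

#' Per-plant and pooled interference estimates
#'
#' FTL experiments score several plants per genotype; plots show per-plant
#' values with a mean bar while totals give the pooled estimate. Both are
#' returned. Plants in which either interval shows no recombinant tetrads
#' (CoC undefined) are excluded from the per-plant interference mean and
#' listed in the exclusion log.
#'
#' @param counts_list List of `tetrad_class_counts`, one per plant (same
#'   genotype).
#' @return List with `per_plant` (data frame: plant, n, distance1,
#'   distance2, interference), `per_plant_mean`, `pooled` (full
#'   `coc_estimate` on summed counts), `pooled_distance1/2`, `excluded`
#'   (plant labels with undefined CoC).
#' @export
per_plant_and_pooled <- function(counts_list) {
  if (!length(counts_list)) stop("need at least one plant")
  stopifnot(all(vapply(counts_list, inherits, logical(1), "tetrad_class_counts")))

  per <- lapply(counts_list, function(cc) {
    d1 <- perkins_distance(cc, 1L)$distance
    d2 <- perkins_distance(cc, 2L)$distance
    intf <- tryCatch(coc_interference(cc)$interference,
                     error = function(e) NA_real_)
    data.frame(plant = as.character(cc$plant), n = cc$n,
               distance1 = d1, distance2 = d2, interference = intf,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)

  total <- counts_list[[1]]$counts
  for (cc in counts_list[-1]) total <- total + cc$counts
  pooled_cc <- tetrad_class_counts(total,
                                   genotype = counts_list[[1]]$genotype,
                                   flagged = sum(vapply(counts_list,
                                                        `[[`, integer(1),
                                                        "flagged")))
  list(
    per_plant = per,
    per_plant_mean = c(
      distance1 = mean(per$distance1), distance2 = mean(per$distance2),
      interference = mean(per$interference, na.rm = TRUE)),
    pooled = coc_interference(pooled_cc),
    pooled_distance1 = perkins_distance(pooled_cc, 1L),
    pooled_distance2 = perkins_distance(pooled_cc, 2L),
    excluded = per$plant[is.na(per$interference)]
  )
}
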