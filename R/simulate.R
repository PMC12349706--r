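# Forward simulator of two-pathway meiotic crossovers and tetrad formation.
#
# Class I crossovers follow a stationary gamma-renewal process on genetic
# coordinates (shape nu, mean inter-event distance 1/rate1); the first event
# is drawn from the equilibrium (length-biased residual) distribution so the
# process is stationary and interval position on the chromosome is
# irrelevant. Class II crossovers are homogeneous Poisson. The two processes
# are independent and superposed.
#
# Spore genotypes are obtained by path traversal over the exchanges: each
# crossover is an exchange between one template chromatid of each homolog
# (no chromatid interference), and the four spores are the paths that start
# on the four templates and switch template at every crossover involving the
# template they currently occupy. This guarantees 2:2 segregation at every
# position.

#' Place Class I (interfering) crossovers on a bivalent
#'
#' Draws one realisation of the stationary gamma-renewal process used for
#' the interference-sensitive Class I pathway. The first inter-event
#' distance is drawn from the equilibrium residual distribution of the
#' Gamma(shape = `nu`, mean = 1/`rate1`) inter-event law, sampled as
#' U * Gamma(nu + 1) (a uniform fraction of a length-biased interval), so
#' the expected number of events over a span S is `rate1 * S` regardless of
#' where the span lies.
#'
#' @param span_morgans Genetic span of the bivalent in Morgans (> 0).
#' @param nu Gamma shape (> 0); `nu = 1` gives a Poisson process.
#' @param rate1 Expected Class I crossovers per Morgan (>= 0).
#' @return Ordered numeric vector of positions in \[0, `span_morgans`\].
#' @examples
#' set.seed(1)
#' place_class1_crossovers(1, nu = 8, rate1 = 2)
#' @export
place_class1_crossovers <- function(span_morgans, nu, rate1) {
  if (!is.numeric(span_morgans) || length(span_morgans) != 1L ||
      !is.finite(span_morgans) || span_morgans <= 0) {
    stop("`span_morgans` must be a single number > 0")
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("`nu` must be a single number > 0")
  }
  if (!is.numeric(rate1) || length(rate1) != 1L || !is.finite(rate1) ||
      rate1 < 0) {
    stop("`rate1` must be a single number >= 0")
  }
  if (rate1 == 0) return(numeric(0))
  beta <- nu * rate1
  pos <- stats::runif(1) * stats::rgamma(1, shape = nu + 1, rate = beta)
  out <- numeric(0)
  while (pos <= span_morgans) {
    out <- c(out, pos)
    pos <- pos + stats::rgamma(1, shape = nu, rate = beta)
  }
  out
}

#' Place Class II (non-interfering) crossovers on a bivalent
#'
#' Homogeneous Poisson positions: the event count is Poisson(`rate2 *
#' span_morgans`) and positions are uniform on the span.
#'
#' @param span_morgans Genetic span in Morgans (>= 0).
#' @param rate2 Expected Class II crossovers per Morgan (>= 0).
#' @return Ordered numeric vector of positions.
#' @export
place_class2_crossovers <- function(span_morgans, rate2) {
  if (!is.numeric(span_morgans) || length(span_morgans) != 1L ||
      !is.finite(span_morgans) || span_morgans < 0) {
    stop("`span_morgans` must be a single number >= 0")
  }
  if (!is.numeric(rate2) || length(rate2) != 1L || !is.finite(rate2) ||
      rate2 < 0) {
    stop("`rate2` must be a single number >= 0")
  }
  if (rate2 == 0 || span_morgans == 0) return(numeric(0))
  n <- stats::rpois(1, rate2 * span_morgans)
  sort(stats::runif(n, 0, span_morgans))
}

#' Assign chromatids to crossover events
#'
#' Each event independently receives one template chromatid from each sister
#' pair, uniformly: `chromatid_a` in \{1, 2\} (homolog carrying the
#' fluorophores) and `chromatid_b` in \{3, 4\}. All four non-sister pairings
#' are equiprobable and independent across events (no chromatid
#' interference).
#'
#' @param events Data frame with columns `position` and `pathway` (one row
#'   per crossover), e.g. as built by [crossover_events()].
#' @return The same data frame with columns `chromatid_a`, `chromatid_b`
#'   filled in.
#' @export
assign_chromatids <- function(events) {
  stopifnot(is.data.frame(events), "position" %in% names(events))
  m <- nrow(events)
  events$chromatid_a <- if (m) sample.int(2L, m, replace = TRUE) else integer(0)
  events$chromatid_b <- if (m) sample.int(2L, m, replace = TRUE) + 2L else integer(0)
  events
}

#' Build a crossover event table from pathway positions
#'
#' @param pos1,pos2 Positions (Morgans) of Class I and Class II events.
#' @return Data frame with columns `position`, `pathway`, ordered by
#'   position; chromatids unset.
#' @export
crossover_events <- function(pos1 = numeric(0), pos2 = numeric(0)) {
  m <- length(pos1) + length(pos2)
  ev <- data.frame(
    position = c(pos1, pos2),
    pathway = rep(c("class1", "class2"), c(length(pos1), length(pos2))),
    chromatid_a = rep(NA_integer_, m), chromatid_b = rep(NA_integer_, m),
    stringsAsFactors = FALSE
  )
  ev[order(ev$position), , drop = FALSE]
}

# Path-traversal genotypes for one tetrad. `events` must be ordered by
# position and carry chromatid assignments. Returns a 4 x 3 logical matrix:
# rows are spores (paths starting on templates 1..4), columns are markers,
# TRUE = fluorophore present. Templates 1,2 are the fluorophore-carrying
# homolog.
events_to_spores <- function(events, mpos) {
  occ <- 1:4  # occ[t] = path currently on template t
  spores <- matrix(FALSE, 4, 3)
  done <- 0L
  ord <- events[order(events$position), , drop = FALSE]
  record <- function(m) spores[occ[1:2], m] <<- TRUE
  for (m in seq_along(mpos)) {
    while (done < nrow(ord) && ord$position[done + 1L] < mpos[m]) {
      done <- done + 1L
      i <- ord$chromatid_a[done]; j <- ord$chromatid_b[done]
      tmp <- occ[i]; occ[i] <- occ[j]; occ[j] <- tmp
    }
    record(m)
  }
  rownames(spores) <- paste0("spore", 1:4)
  colnames(spores) <- paste0("m", 1:3)
  spores
}

#' Generate a single tetrad
#'
#' Simulates crossovers on one bivalent under the two-pathway model and
#' returns the four spore phenotypes. The markers are in coupling: with no
#' crossover the tetrad is a parental ditype, two spores carrying all three
#' fluorophores and two carrying none.
#'
#' @param map An [interval_pair_map()].
#' @param params A [pathway_params()].
#' @return An object of class `tetrad`: list with `spores` (4 x 3 logical
#'   matrix, TRUE = fluorophore present) and `events` (the crossover
#'   provenance table).
#' @examples
#' set.seed(42)
#' generate_tetrad(interval_pair_map(d1 = 10, d2 = 10), pathway_params())
#' @export
generate_tetrad <- function(map, params) {
  stopifnot(inherits(map, "interval_pair_map"), inherits(params, "pathway_params"))
  span <- chrom_span_morgans(map)
  rate1 <- params$total_rate * (1 - params$frac_class2)
  rate2 <- params$total_rate * params$frac_class2
  ev <- crossover_events(
    place_class1_crossovers(span, params$nu, rate1),
    place_class2_crossovers(span, rate2)
  )
  ev <- assign_chromatids(ev)
  spores <- events_to_spores(ev, marker_positions_morgans(map))
  structure(list(spores = spores, events = ev), class = "tetrad")
}

#' @export
print.tetrad <- function(x, ...) {
  pat <- apply(x$spores, 1, function(r) paste(as.integer(r), collapse = ""))
  cat("Tetrad:", paste(pat, collapse = " "),
      sprintf(" (%d crossovers)\n", nrow(x$events)))
  invisible(x)
}

# Vectorised batch simulation. Returns list(codes, n_class1, n_class2):
# codes is an n x 4 integer matrix of spore phenotype codes 0..7
# (bit 4 = marker 1, bit 2 = marker 2, bit 1 = marker 3), one row per
# tetrad; n_class1/n_class2 count crossovers per bivalent by pathway.
sim_codes <- function(n, map, params) {
  span <- chrom_span_morgans(map)
  mpos <- marker_positions_morgans(map)
  rate1 <- params$total_rate * (1 - params$frac_class2)
  rate2 <- params$total_rate * params$frac_class2

  tid <- integer(0); pos <- numeric(0)
  if (rate1 > 0) {
    beta <- params$nu * rate1
    cur <- stats::runif(n) * stats::rgamma(n, shape = params$nu + 1, rate = beta)
    idx <- which(cur <= span)
    cur <- cur[idx]
    tl <- list(); pl <- list(); step <- 0L
    while (length(idx)) {
      step <- step + 1L
      tl[[step]] <- idx; pl[[step]] <- cur
      cur <- cur + stats::rgamma(length(idx), shape = params$nu, rate = beta)
      keep <- cur <= span
      idx <- idx[keep]; cur <- cur[keep]
    }
    tid <- unlist(tl, use.names = FALSE)
    pos <- unlist(pl, use.names = FALSE)
    if (is.null(tid)) { tid <- integer(0); pos <- numeric(0) }
  }
  n1 <- tabulate(tid, nbins = n)

  n2 <- if (rate2 > 0) stats::rpois(n, rate2 * span) else integer(n)
  tid2 <- rep.int(seq_len(n), n2)
  pos2 <- stats::runif(length(tid2), 0, span)

  tid <- c(tid, tid2); pos <- c(pos, pos2)
  m <- length(tid)
  ia <- if (m) sample.int(2L, m, replace = TRUE) else integer(0)
  ib <- if (m) sample.int(2L, m, replace = TRUE) + 2L else integer(0)
  o <- order(tid, pos)
  codes <- occupancy_codes(n, tid[o], pos[o], ia[o], ib[o], mpos)
  list(codes = codes, n_class1 = n1, n_class2 = as.integer(n2))
}

# Core genotype computation over many tetrads at once. Events must be sorted
# by (tid, pos). Tetrads are processed in groups sharing the same event
# count; within a group the occupancy permutation is advanced one exchange
# at a time with matrix column swaps, and each marker's carriers are read
# off at the exchange count reached to its left.
occupancy_codes <- function(n, tid, pos, ia, ib, mpos) {
  bit <- c(4L, 2L, 1L)
  codes <- matrix(0L, n, 4L)
  k <- tabulate(tid, nbins = n)

  noev <- k == 0L
  if (any(noev)) {
    codes[noev, 1L] <- 7L
    codes[noev, 2L] <- 7L
  }
  if (!length(tid)) return(codes)

  off <- cumsum(k)  # last event row of each tetrad
  for (g in sort(unique(k[k > 0L]))) {
    rows <- which(k == g)           # tetrad ids in this group
    nk <- length(rows)
    idx <- outer(off[rows] - g + 1L, 0:(g - 1L), `+`)  # nk x g event rows
    P <- matrix(pos[idx], nk, g)
    IA <- matrix(ia[idx], nk, g)
    IB <- matrix(ib[idx], nk, g)
    # exchanges strictly left of each marker
    cm <- vapply(mpos, function(mp) rowSums(P < mp), numeric(nk))
    cm <- matrix(cm, nk, 3L)
    O <- matrix(rep(1:4, each = nk), nk, 4L)  # O[, t] = path on template t
    r <- seq_len(nk)
    for (t in 0:g) {
      for (mk in 1:3) {
        rr <- which(cm[, mk] == t)
        if (length(rr)) {
          codes[cbind(rows[rr], O[cbind(rr, rep(1L, length(rr)))])] <-
            codes[cbind(rows[rr], O[cbind(rr, rep(1L, length(rr)))])] + bit[mk]
          codes[cbind(rows[rr], O[cbind(rr, rep(2L, length(rr)))])] <-
            codes[cbind(rows[rr], O[cbind(rr, rep(2L, length(rr)))])] + bit[mk]
        }
      }
      if (t < g) {
        i <- IA[, t + 1L]; j <- IB[, t + 1L]
        tmp <- O[cbind(r, i)]
        O[cbind(r, i)] <- O[cbind(r, j)]
        O[cbind(r, j)] <- tmp
      }
    }
  }
  codes
}

#' Simulate a sample of tetrads
#'
#' Simulates `n` independent tetrads under the two-pathway model,
#' reproducibly under a fixed seed.
#'
#' @param n Number of tetrads (>= 1).
#' @param map An [interval_pair_map()].
#' @param params A [pathway_params()].
#' @param seed Integer seed; all randomness in the call flows from it.
#' @return An object of class `tetrad_sample`: list with `codes` (n x 4
#'   integer matrix of spore phenotype codes 0..7, bit order marker1 =
#'   4, marker2 = 2, marker3 = 1), `n_class1` and `n_class2` (crossovers per
#'   bivalent by pathway), and the `map`, `params`, `seed`, `n` used.
#' @examples
#' s <- simulate_tetrads(500, interval_pair_map(d1 = 10, d2 = 10),
#'                       pathway_params(), seed = 1)
#' table(rowSums(s$codes == 7))  # spores carrying all three fluorophores
#' @export
simulate_tetrads <- function(n, map, params, seed) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("`n` must be a single integer >= 1")
  }
  n <- as.integer(n)
  stopifnot(inherits(map, "interval_pair_map"), inherits(params, "pathway_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sim <- sim_codes(n, map, params)
  structure(
    list(codes = sim$codes, n_class1 = sim$n_class1, n_class2 = sim$n_class2,
         map = map, params = params, seed = as.integer(seed), n = n),
    class = "tetrad_sample"
  )
}

#' @export
print.tetrad_sample <- function(x, ...) {
  cat(sprintf("Tetrad sample: %d tetrads (seed %d)\n", x$n, x$seed))
  print(x$map)
  print(x$params)
  invisible(x)
}

#' Simulate metaphase I cells with ring/rod bivalent shapes
#'
#' Each cell carries 5 bivalents (Arabidopsis); each bivalent arm receives a
#' Poisson number of crossovers with mean `per_arm_expected_co`. A bivalent
#' is a ring if both arms have at least one crossover, a rod if exactly one
#' arm does, and a univalent pair if neither. The true crossover (chiasma)
#' count is retained so the bias of shape-based chiasma scoring can be
#' assessed.
#'
#' @param n_cells Number of cells to simulate.
#' @param per_arm_expected_co Expected crossovers per chromosome arm (>= 0).
#' @param seed Integer seed.
#' @return Data frame with one row per cell: `cell_id`, `ring`, `rod`,
#'   `univalent_pairs`, `true_chiasmata`.
#' @export
simulate_metaphase_cells <- function(n_cells, per_arm_expected_co, seed) {
  if (!is.numeric(per_arm_expected_co) || per_arm_expected_co < 0) {
    stop("`per_arm_expected_co` must be >= 0")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n_cells <- as.integer(n_cells)
  nb <- 5L * n_cells
  a1 <- stats::rpois(nb, per_arm_expected_co)
  a2 <- stats::rpois(nb, per_arm_expected_co)
  ring <- a1 > 0 & a2 > 0
  rod <- xor(a1 > 0, a2 > 0)
  cell <- rep(seq_len(n_cells), each = 5L)
  data.frame(
    cell_id = seq_len(n_cells),
    ring = as.integer(tapply(ring, cell, sum)),
    rod = as.integer(tapply(rod, cell, sum)),
    univalent_pairs = as.integer(tapply(!ring & !rod, cell, sum)),
    true_chiasmata = as.integer(tapply(a1 + a2, cell, sum))
  )
}

#' Simulate per-nucleus foci counts
#'
#' Draws reproducible counts emulating cytological focus data (e.g.
#' MLH1/HEI10 Class I crossover foci, or DNA-damage-induced RAD51 foci).
#'
#' @param n_cells Number of nuclei.
#' @param family One of `"poisson"` (parameter `mean`),
#'   `"negative_binomial"` (`mean`, `size`), or `"zero_inflated_poisson"`
#'   (`pi` = probability of a structural zero, `lambda`).
#' @param params Named list of family parameters.
#' @param seed Integer seed.
#' @return Integer vector of counts of length `n_cells`.
#' @examples
#' simulate_foci(10, "poisson", list(mean = 8.4), seed = 1)
#' @export
simulate_foci <- function(n_cells, family, params, seed) {
  family <- match.arg(family,
                      c("poisson", "negative_binomial", "zero_inflated_poisson"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  n_cells <- as.integer(n_cells)
  if (n_cells == 0L) return(integer(0))
  switch(family,
    poisson = stats::rpois(n_cells, params$mean),
    negative_binomial = stats::rnbinom(n_cells, mu = params$mean,
                                       size = params$size),
    zero_inflated_poisson = {
      zero <- stats::runif(n_cells) < params$pi
      x <- stats::rpois(n_cells, params$lambda)
      x[zero] <- 0L
      x
    }
  )
}
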