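# Marker layout and crossover-pathway parameters.

#' Define a pair of adjacent genetic intervals on three linked markers
#'
#' Three ordered fluorescent markers delimit two adjacent genetic intervals
#' (e.g. the `I1b`/`I1c` pair of the I1bc FTL on chromosome 1). Interval
#' lengths are genetic lengths in centimorgans; optional flanks describe
#' chromosome outside the marked region so that whole-bivalent quantities
#' (such as total crossover number) can be simulated.
#'
#' @param d1,d2 Genetic lengths (cM) of the left and right interval. Must be
#'   positive.
#' @param marker_names Character vector of three marker labels, left to right.
#' @param flank_left,flank_right Genetic lengths (cM) of chromosome outside
#'   the outermost markers. Default 0 (chromosome reduced to the marked
#'   region; because the Class I process is stationary this does not affect
#'   interval statistics).
#' @return An object of class `interval_pair_map`.
#' @examples
#' interval_pair_map(d1 = 7.4, d2 = 6.1, marker_names = c("YFP", "RFP", "CFP"))
#' @export
interval_pair_map <- function(d1, d2, marker_names = c("M1", "M2", "M3"),
                              flank_left = 0, flank_right = 0) {
  if (length(marker_names) != 3L) {
    stop("`marker_names` must give exactly 3 ordered marker labels")
  }
  for (nm in c("d1", "d2", "flank_left", "flank_right")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("`%s` must be a single finite number", nm))
    }
  }
  if (d1 <= 0 || d2 <= 0) stop("interval lengths `d1` and `d2` must be > 0 cM")
  if (flank_left < 0 || flank_right < 0) stop("flank lengths must be >= 0 cM")
  structure(
    list(marker_names = as.character(marker_names),
         d1 = d1, d2 = d2,
         flank_left = flank_left, flank_right = flank_right),
    class = "interval_pair_map"
  )
}

#' @export
print.interval_pair_map <- function(x, ...) {
  cat("Interval pair:",
      sprintf("%s -[%.3g cM]- %s -[%.3g cM]- %s",
              x$marker_names[1], x$d1, x$marker_names[2], x$d2,
              x$marker_names[3]), "\n")
  if (x$flank_left > 0 || x$flank_right > 0) {
    cat(sprintf("Flanks: %.3g cM (left), %.3g cM (right)\n",
                x$flank_left, x$flank_right))
  }
  invisible(x)
}

# Marker positions in Morgans from the left chromosome end.
marker_positions_morgans <- function(map) {
  cumsum(c(map$flank_left, map$d1, map$d2)) / 100
}

# Whole-bivalent genetic span in Morgans.
chrom_span_morgans <- function(map) {
  (map$flank_left + map$d1 + map$d2 + map$flank_right) / 100
}

#' Parameters of the two-pathway crossover model
#'
#' Crossovers arise from the superposition of two independent processes on
#' the bivalent: an interfering Class I (ZMM) pathway modelled as a
#' stationary gamma-renewal process with shape `nu`, and a non-interfering
#' Class II (MUS81) pathway modelled as a homogeneous Poisson process. The
#' total expected crossover density is split between the pathways by
#' `frac_class2`.
#'
#' @param nu Gamma shape of Class I inter-crossover distances
#'   (dimensionless, > 0). `nu = 1` is a Poisson process (no interference);
#'   larger values give more evenly spaced Class I crossovers and stronger
#'   interference. Default 8, in the range estimated for Arabidopsis.
#' @param frac_class2 Fraction of expected crossovers contributed by the
#'   Class II pathway, in \[0, 1\]. Default 0.15 (the roughly 15--20% of
#'   wild-type crossovers that are MUS81-dependent).
#' @param total_rate Expected crossovers per bivalent per Morgan. Default 2,
#'   so that a crossover density of 2 per Morgan on the four-chromatid
#'   bivalent makes the recombinant-spore fraction match map distance (one
#'   crossover recombines 2 of the 4 chromatids).
#' @return An object of class `pathway_params`.
#' @examples
#' pathway_params()                      # wild-type-like defaults
#' pathway_params(frac_class2 = 0)       # pure Class I
#' pathway_params(nu = 1, frac_class2 = 1)  # pure Poisson, no interference
#' @export
pathway_params <- function(nu = 8, frac_class2 = 0.15, total_rate = 2) {
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= 0) {
    stop("`nu` must be a single number > 0")
  }
  if (!is.numeric(frac_class2) || length(frac_class2) != 1L ||
      is.na(frac_class2) || frac_class2 < 0 || frac_class2 > 1) {
    stop("`frac_class2` must lie in [0, 1]")
  }
  if (!is.numeric(total_rate) || length(total_rate) != 1L ||
      !is.finite(total_rate) || total_rate < 0) {
    stop("`total_rate` must be a single number >= 0")
  }
  structure(
    list(nu = nu, frac_class2 = frac_class2, total_rate = total_rate),
    class = "pathway_params"
  )
}

#' @export
print.pathway_params <- function(x, ...) {
  cat(sprintf(
    "Two-pathway crossover parameters: nu = %.3g, frac_class2 = %.3g, total_rate = %.3g /Morgan\n",
    x$nu, x$frac_class2, x$total_rate))
  invisible(x)
}
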