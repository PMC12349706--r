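# Classification of three-marker tetrad phenotypes.
#
# A tetrad is a multiset of four spore phenotypes; each phenotype is the
# presence/absence of three fluorophores, encoded as an integer 0..7 with
# bit 4 = marker 1, bit 2 = marker 2, bit 1 = marker 3. Spore order is never
# meaningful: all logic operates on the sorted code multiset.

.tetraco_cache <- new.env(parent = emptyenv())

# ---- spore code helpers ----------------------------------------------------

#' Convert spore phenotypes to integer codes
#'
#' Accepts a 4 x 3 logical/0-1 matrix (rows = spores, columns = markers), a
#' `tetrad` object, or a character vector of four 3-bit strings such as
#' `"101"`.
#'
#' @param tetrad Tetrad in any of the accepted representations.
#' @return Integer vector of four codes in 0..7.
#' @export
spore_codes <- function(tetrad) {
  if (inherits(tetrad, "tetrad")) tetrad <- tetrad$spores
  if (is.character(tetrad)) {
    if (length(tetrad) != 4L || any(nchar(tetrad) != 3L) ||
        any(!grepl("^[01]{3}$", tetrad))) {
      stop("character tetrads must be four 3-bit strings like \"101\"")
    }
    return(strtoi(tetrad, base = 2L))
  }
  if (is.matrix(tetrad) && all(dim(tetrad) == c(4L, 3L))) {
    m <- matrix(as.integer(tetrad), 4L, 3L)
    if (any(is.na(m)) || any(m != 0L & m != 1L)) {
      stop("spore matrix entries must be 0/1 or logical")
    }
    return(m[, 1L] * 4L + m[, 2L] * 2L + m[, 3L])
  }
  stop("cannot interpret `tetrad`; give a 4x3 matrix, a tetrad object, ",
       "or four 3-bit strings")
}

code_key <- function(codes4) {
  paste(sort.int(codes4, decreasing = TRUE), collapse = "")
}

# Descending sort of each row of a 4-column code matrix (comparator
# network), then paste into keys. Vectorised for large samples.
row_keys <- function(codes) {
  a <- codes[, 1L]; b <- codes[, 2L]; c <- codes[, 3L]; d <- codes[, 4L]
  swp <- function(x, y) list(hi = pmax.int(x, y), lo = pmin.int(x, y))
  s1 <- swp(a, b); a <- s1$hi; b <- s1$lo
  s2 <- swp(c, d); c <- s2$hi; d <- s2$lo
  s3 <- swp(a, c); a <- s3$hi; c <- s3$lo
  s4 <- swp(b, d); b <- s4$hi; d <- s4$lo
  s5 <- swp(b, c); b <- s5$hi; c <- s5$lo
  paste0(a, b, c, d)
}

check_2to2 <- function(codes4) {
  bits <- c(4L, 2L, 1L)
  vapply(bits, function(bt) sum(bitwAnd(codes4, bt) > 0L), integer(1)) == 2L
}

# ---- per-interval ditype ---------------------------------------------------

#' Ditype of one interval of a tetrad
#'
#' Restricts each spore to the interval's two flanking markers and returns
#' the classical tetrad type for that marker pair: `"P"` (parental ditype,
#' two parental two-marker genotypes twice each), `"N"` (non-parental
#' ditype, two recombinant genotypes twice each), or `"T"` (tetratype, all
#' four genotypes distinct). Markers are in coupling, so the parental
#' genotypes are both-present and both-absent.
#'
#' @param tetrad A tetrad (see [spore_codes()] for accepted forms).
#' @param interval_index 1 (markers 1-2) or 2 (markers 2-3).
#' @return One of `"P"`, `"T"`, `"N"`.
#' @examples
#' interval_ditype(c("111", "000", "100", "011"), 1)  # "T"
#' @export
interval_ditype <- function(tetrad, interval_index) {
  codes <- spore_codes(tetrad)
  if (!interval_index %in% 1:2) stop("`interval_index` must be 1 or 2")
  seg <- check_2to2(codes)
  if (!all(seg)) {
    bitstr <- vapply(codes, function(x)
      paste(as.integer(intToBits(x))[3:1], collapse = ""), character(1))
    stop(sprintf(
      "tetrad %s violates 2:2 segregation at marker(s) %s; aberrant tetrads are discarded in FTL scoring",
      paste(bitstr, collapse = "/"), paste(which(!seg), collapse = ",")))
  }
  pair_ditype(codes, interval_index)
}

# ditype from codes, no validation; interval 1 uses bits (4,2), interval 2
# bits (2,1)
pair_ditype <- function(codes, interval_index) {
  bits <- if (interval_index == 1L) c(4L, 2L) else c(2L, 1L)
  g <- (bitwAnd(codes, bits[1L]) > 0L) * 2L + (bitwAnd(codes, bits[2L]) > 0L)
  tab <- tabulate(g + 1L, 4L)  # counts of genotypes 00,01,10,11
  if (all(tab == 1L)) return("T")
  if (tab[1L] == 2L && tab[4L] == 2L) return("P")
  if (tab[2L] == 2L && tab[3L] == 2L) return("N")
  stop("unclassifiable two-marker genotype multiset (aberrant segregation)")
}

# ---- canonical enumeration -------------------------------------------------

#' Enumerate the canonical tetrad classes
#'
#' Brute-force enumeration of every tetrad phenotype multiset reachable with
#' 0--2 crossovers per interval over all chromatid (template) assignments
#' and event orders. Exactly 12 distinct multisets exist; they coincide with
#' all multisets of four 3-marker phenotypes satisfying 2:2 segregation, so
#' classification is total on valid tetrads.
#'
#' Letters are assigned in a documented canonical order: A = (P,P); single
#' crossover classes B = (T,P), C = (P,T); double-within-interval classes
#' D = (N,P), E = (P,N); the four double-across-interval (T,T) classes F--I
#' ordered by strand configuration (2-strand, the two 3-strand forms,
#' 4-strand); then J = (T,N), K = (N,T), L = (N,N). Users of count tables
#' with a different letter key can remap columns (see
#' [read_tetrad_table()]).
#'
#' @return Data frame with one row per class: `label`, `key` (sorted spore
#'   codes), `spores` (the four 3-bit phenotype strings), `ditype_I1`,
#'   `ditype_I2`, `subtype`.
#' @examples
#' enumerate_tetrad_classes()
#' @export
enumerate_tetrad_classes <- function() {
  if (!is.null(.tetraco_cache$classes)) return(.tetraco_cache$classes)

  mpos <- c(0.1, 0.2, 0.3)
  seen <- new.env(parent = emptyenv())
  for (k1 in 0:2) {
    for (k2 in 0:2) {
      ktot <- k1 + k2
      pos <- c(seq_len(k1) * 0.02 + 0.1, seq_len(k2) * 0.02 + 0.2)
      combos <- if (ktot) expand.grid(rep(list(1:4), ktot)) else
        data.frame(row.names = 1)
      for (ci in seq_len(nrow(combos))) {
        pick <- if (ktot) as.integer(combos[ci, ]) else integer(0)
        ev <- data.frame(
          position = pos,
          pathway = rep("enum", ktot),
          chromatid_a = ((pick - 1L) %/% 2L) + 1L,
          chromatid_b = ((pick - 1L) %% 2L) + 3L
        )
        codes <- sort.int(spore_codes(events_to_spores(ev, mpos)),
                          decreasing = TRUE)
        key <- paste(codes, collapse = "")
        if (is.null(seen[[key]])) {
          seen[[key]] <- list(codes = codes, k1 = k1, k2 = k2, pick = pick)
        }
      }
    }
  }

  keys <- ls(seen)
  rows <- lapply(keys, function(k) {
    info <- seen[[k]]
    data.frame(
      key = k,
      spores = paste(vapply(info$codes, function(x)
        paste(as.integer(intToBits(x))[3:1], collapse = ""), character(1)),
        collapse = "/"),
      ditype_I1 = pair_ditype(info$codes, 1L),
      ditype_I2 = pair_ditype(info$codes, 2L),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  stopifnot(nrow(tab) == 12L)

  # canonical ordering of ditype pairs, (T,T) subtypes by descending key
  # (2-strand, 3-strand-a, 3-strand-b, 4-strand)
  pair_rank <- c("PP" = 1, "TP" = 2, "PT" = 3, "NP" = 4, "PN" = 5,
                 "TT" = 6, "TN" = 7, "NT" = 8, "NN" = 9)
  pr <- pair_rank[paste0(tab$ditype_I1, tab$ditype_I2)]
  tab <- tab[order(pr, -xtfrm(tab$key)), , drop = FALSE]
  tab$label <- LETTERS[1:12]
  tab$subtype <- ""
  tt <- tab$ditype_I1 == "T" & tab$ditype_I2 == "T"
  tab$subtype[tt] <- c("2-strand", "3-strand-a", "3-strand-b", "4-strand")
  rownames(tab) <- NULL
  tab <- tab[, c("label", "key", "spores", "ditype_I1", "ditype_I2", "subtype")]
  .tetraco_cache$classes <- tab
  tab
}

#' Classify a single tetrad
#'
#' Maps a tetrad's phenotype multiset to its canonical class. Tetrads whose
#' multiset is not in the canonical table (aberrant, non-2:2 segregation)
#' are assigned the overflow label `"X"` and flagged, never silently
#' dropped.
#'
#' @param tetrad A tetrad (see [spore_codes()]).
#' @return One-row data frame with `label`, `ditype_I1`, `ditype_I2`,
#'   `subtype`, `flagged`.
#' @examples
#' classify_tetrad(c("111", "111", "000", "000"))  # class A, (P,P)
#' @export
classify_tetrad <- function(tetrad) {
  codes <- spore_codes(tetrad)
  tab <- enumerate_tetrad_classes()
  i <- match(code_key(codes), tab$key)
  if (is.na(i)) {
    return(data.frame(label = "X", ditype_I1 = NA_character_,
                      ditype_I2 = NA_character_, subtype = "overflow",
                      flagged = TRUE, stringsAsFactors = FALSE))
  }
  out <- tab[i, c("label", "ditype_I1", "ditype_I2", "subtype")]
  out$flagged <- FALSE
  rownames(out) <- NULL
  out
}

#' Classify every tetrad of a sample
#'
#' @param sample A `tetrad_sample` (from [simulate_tetrads()]) or an n x 4
#'   integer matrix of spore codes.
#' @return Character vector of class labels (`"A"`..`"L"`, or `"X"` for
#'   flagged aberrant tetrads).
#' @export
classify_tetrads <- function(sample) {
  codes <- if (inherits(sample, "tetrad_sample")) sample$codes else sample
  stopifnot(is.matrix(codes), ncol(codes) == 4L)
  tab <- enumerate_tetrad_classes()
  lab <- tab$label[match(row_keys(codes), tab$key)]
  lab[is.na(lab)] <- "X"
  lab
}

#' Tabulate tetrad class counts
#'
#' Counts classified tetrads per canonical class. Flagged (aberrant)
#' tetrads are excluded from `n` but reported in `flagged`, so input length
#' = `n` + `flagged`.
#'
#' @param sample A `tetrad_sample`, code matrix, or character vector of
#'   labels from [classify_tetrads()].
#' @param genotype,plant Labels stored with the counts.
#' @return Object of class `tetrad_class_counts`: list with `genotype`,
#'   `plant`, `counts` (named integer vector A..L), `n`, `flagged`.
#' @export
tabulate_tetrads <- function(sample, genotype = "unknown", plant = NA) {
  labels <- if (is.character(sample)) sample else classify_tetrads(sample)
  tab <- enumerate_tetrad_classes()
  counts <- vapply(tab$label, function(l) sum(labels == l), integer(1))
  flagged <- sum(labels == "X")
  structure(
    list(genotype = genotype, plant = plant, counts = counts,
         n = sum(counts), flagged = flagged),
    class = "tetrad_class_counts"
  )
}

#' Build class counts directly from a named count vector
#'
#' @param counts Named vector with entries among A..L (missing classes are
#'   zero).
#' @param genotype,plant Labels stored with the counts.
#' @param flagged Count of aberrant tetrads excluded from `n`.
#' @return A `tetrad_class_counts` object.
#' @export
tetrad_class_counts <- function(counts, genotype = "unknown", plant = NA,
                                flagged = 0L) {
  tab <- enumerate_tetrad_classes()
  if (is.null(names(counts)) || !all(names(counts) %in% tab$label)) {
    stop("`counts` must be named with class letters A..L")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("class counts must be non-negative integers")
  }
  full <- stats::setNames(integer(12L), tab$label)
  full[names(counts)] <- as.integer(counts)
  structure(
    list(genotype = genotype, plant = plant, counts = full,
         n = sum(full), flagged = as.integer(flagged)),
    class = "tetrad_class_counts"
  )
}

#' @export
print.tetrad_class_counts <- function(x, ...) {
  cat(sprintf("Tetrad class counts: %s%s, n = %d (%d flagged)\n",
              x$genotype,
              if (is.na(x$plant)) "" else paste0(" / plant ", x$plant),
              x$n, x$flagged))
  print(x$counts)
  invisible(x)
}
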