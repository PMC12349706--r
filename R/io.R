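# Readers and writers for the CSV layouts used by FTL tetrad and cytology
# data, fixture generation, and the end-to-end pipeline runners.
#
# Canonical dialects (header row required, TSV auto-detected by extension):
#   raw tetrads:   genotype, plant, spore1..spore4 (3-bit strings, "101")
#   class counts:  interval_pair, genotype, plant, A..L, n  (sum(A..L) == n)
#   foci:          kind, genotype, treatment, cell_id, count
#   bivalents:     genotype, cell_id, ring, ring3, rod, univalent_pairs

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a tetrad table (raw spores or class counts)
#'
#' Reads either layout and validates it. Raw layout: columns
#' `spore1`..`spore4` holding 3-bit fluorophore strings. Class-count
#' layout: columns `A`..`L` plus `n`; every row must satisfy
#' `sum(A..L) == n`, and malformed rows are rejected with their line
#' numbers. A letter remap may be supplied for count tables whose letter
#' key differs from the canonical one (see [enumerate_tetrad_classes()]).
#'
#' @param path CSV or TSV file.
#' @param remap Optional named character vector mapping the file's letters
#'   to canonical letters, e.g. `c(A = "A", B = "C", ...)`, or the path of
#'   a two-column CSV (`from`, `to`).
#' @return For the raw layout, a data frame of validated tetrad rows; for
#'   the count layout, a list of `tetrad_class_counts` (one per row) with
#'   attribute `"interval_pair"` carrying that column if present.
#' @export
read_tetrad_table <- function(path, remap = NULL) {
  df <- read_delim_auto(path)
  if (all(paste0("spore", 1:4) %in% names(df))) {
    for (i in 1:4) {
      col <- df[[paste0("spore", i)]]
      # leading zeros are lost if the column was parsed as numeric
      if (is.numeric(col)) col <- sprintf("%03d", col)
      df[[paste0("spore", i)]] <- col
      bad <- !grepl("^[01]{3}$", col)
      if (any(bad)) {
        stop(sprintf("malformed spore strings at line(s) %s of %s",
                     paste(which(bad) + 1L, collapse = ", "), basename(path)))
      }
    }
    return(df)
  }
  if (all(LETTERS[1:12] %in% names(df)) && "n" %in% names(df)) {
    if (!is.null(remap)) {
      if (is.character(remap) && length(remap) == 1L && file.exists(remap)) {
        rm_df <- utils::read.csv(remap, stringsAsFactors = FALSE)
        remap <- stats::setNames(rm_df$to, rm_df$from)
      }
      if (!setequal(names(remap), LETTERS[1:12]) ||
          !setequal(unname(remap), LETTERS[1:12])) {
        stop("`remap` must be a bijection over the letters A..L")
      }
      cnt_cols <- df[, LETTERS[1:12]]
      names(cnt_cols) <- unname(remap[names(cnt_cols)])
      df[, LETTERS[1:12]] <- cnt_cols[, LETTERS[1:12]]
    }
    cnts <- as.matrix(df[, LETTERS[1:12]])
    if (any(cnts != round(cnts)) || any(cnts < 0)) {
      bad <- which(apply(cnts, 1, function(r) any(r != round(r) | r < 0)))
      stop(sprintf("non-integer or negative counts at line(s) %s of %s",
                   paste(bad + 1L, collapse = ", "), basename(path)))
    }
    bad <- rowSums(cnts) != df$n
    if (any(bad)) {
      stop(sprintf("class counts do not sum to n at line(s) %s of %s",
                   paste(which(bad) + 1L, collapse = ", "), basename(path)))
    }
    out <- lapply(seq_len(nrow(df)), function(i) {
      tetrad_class_counts(
        stats::setNames(as.integer(cnts[i, ]), LETTERS[1:12]),
        genotype = if ("genotype" %in% names(df)) df$genotype[i] else "unknown",
        plant = if ("plant" %in% names(df)) df$plant[i] else NA
      )
    })
    if ("interval_pair" %in% names(df)) {
      attr(out, "interval_pair") <- df$interval_pair
    }
    return(out)
  }
  stop("unrecognised layout: need spore1..spore4 columns, or A..L and n")
}

#' Write a simulated tetrad sample as a raw tetrad CSV
#'
#' One row per tetrad: spore phenotypes as 3-bit strings plus the class
#' label.
#'
#' @param sample A `tetrad_sample`.
#' @param path Output CSV path.
#' @param genotype,plant Labels written with every row.
#' @return The path, invisibly.
#' @export
write_tetrads <- function(sample, path, genotype = "sim", plant = 1) {
  stopifnot(inherits(sample, "tetrad_sample"))
  to_bits <- function(v) {
    paste0((v %/% 4L) %% 2L, (v %/% 2L) %% 2L, v %% 2L)
  }
  df <- data.frame(
    genotype = genotype, plant = plant,
    spore1 = to_bits(sample$codes[, 1L]), spore2 = to_bits(sample$codes[, 2L]),
    spore3 = to_bits(sample$codes[, 3L]), spore4 = to_bits(sample$codes[, 4L]),
    class = classify_tetrads(sample),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write class counts in the standard count-table layout
#'
#' @param counts_list List of `tetrad_class_counts`.
#' @param path Output CSV path.
#' @param interval_pair Label for the interval pair column (e.g. "I1bc").
#' @return The path, invisibly.
#' @export
write_class_counts <- function(counts_list, path, interval_pair = "I1") {
  if (inherits(counts_list, "tetrad_class_counts")) counts_list <- list(counts_list)
  rows <- lapply(counts_list, function(cc) {
    data.frame(interval_pair = interval_pair, genotype = cc$genotype,
               plant = cc$plant, as.list(cc$counts), n = cc$n,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a foci-count table
#'
#' @param path CSV with columns `kind`, `genotype`, `treatment`, `cell_id`,
#'   `count` (kind/treatment optional).
#' @return Validated data frame.
#' @export
read_foci_table <- function(path) {
  df <- read_delim_auto(path)
  need <- c("genotype", "count")
  if (!all(need %in% names(df))) {
    stop("foci table needs at least columns: ", paste(need, collapse = ", "))
  }
  bad <- !is.finite(df$count) | df$count < 0 | df$count != round(df$count)
  if (any(bad)) {
    stop(sprintf("invalid focus counts at line(s) %s of %s",
                 paste(which(bad) + 1L, collapse = ", "), basename(path)))
  }
  df
}

#' Read a bivalent-configuration table
#'
#' @param path CSV with columns `genotype`, `cell_id`, `ring`, `rod` and
#'   optionally `ring3`, `univalent_pairs`.
#' @return Validated data frame (missing optional columns filled with 0).
#' @export
read_bivalent_table <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("genotype", "ring", "rod") %in% names(df))) {
    stop("bivalent table needs columns genotype, ring, rod")
  }
  for (col in c("ring3", "univalent_pairs")) {
    if (!col %in% names(df)) df[[col]] <- 0L
  }
  shp <- df[, c("ring", "ring3", "rod", "univalent_pairs")]
  bad <- apply(shp, 1, function(r) any(r < 0 | r != round(r)) || sum(r) > 5)
  if (any(bad)) {
    stop(sprintf("invalid shape counts (negative, non-integer, or > 5 bivalents) at line(s) %s of %s",
                 paste(which(bad) + 1L, collapse = ", "), basename(path)))
  }
  df
}

#' Generate small example data files
#'
#' Writes deterministic example CSVs used by tests and documentation: a raw
#' tetrad file and class-count file with two simulated genotypes (one with
#' strong interference, one with none), a foci file and a bivalent file.
#'
#' @param outdir Writable output directory (created if absent).
#' @param seed Integer seed; the same seed yields byte-identical files.
#' @return Named character vector of the written paths.
#' @export
generate_fixtures <- function(outdir, seed = 1) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  map <- interval_pair_map(d1 = 10, d2 = 10)
  n <- 3000
  hi <- simulate_tetrads(n, map, pathway_params(nu = 8, frac_class2 = 0),
                         seed = seed)
  no <- simulate_tetrads(n, map, pathway_params(nu = 1, frac_class2 = 1),
                         seed = seed + 1)

  paths <- c(
    tetrads = file.path(outdir, "example_tetrads.csv"),
    class_counts = file.path(outdir, "example_class_counts.csv"),
    foci = file.path(outdir, "example_foci.csv"),
    bivalents = file.path(outdir, "example_bivalents.csv")
  )

  tmp1 <- tempfile(); tmp2 <- tempfile()
  write_tetrads(hi, tmp1, genotype = "high_interference")
  write_tetrads(no, tmp2, genotype = "no_interference")
  both <- rbind(utils::read.csv(tmp1, colClasses = "character"),
                utils::read.csv(tmp2, colClasses = "character"))
  unlink(c(tmp1, tmp2))
  utils::write.csv(both, paths[["tetrads"]], row.names = FALSE, quote = FALSE)

  cc <- list(
    tabulate_tetrads(hi, genotype = "high_interference", plant = 1),
    tabulate_tetrads(no, genotype = "no_interference", plant = 1)
  )
  write_class_counts(cc, paths[["class_counts"]], interval_pair = "sim10x10")

  foci <- rbind(
    data.frame(kind = "MLH1", genotype = "high_interference",
               treatment = "none",
               cell_id = 1:60,
               count = simulate_foci(60, "poisson", list(mean = 9.2),
                                     seed = seed + 2)),
    data.frame(kind = "MLH1", genotype = "no_interference",
               treatment = "none",
               cell_id = 1:60,
               count = simulate_foci(60, "poisson", list(mean = 8.4),
                                     seed = seed + 3))
  )
  utils::write.csv(foci, paths[["foci"]], row.names = FALSE, quote = FALSE)

  cells <- simulate_metaphase_cells(50, per_arm_expected_co = 1, seed = seed + 4)
  cells <- data.frame(genotype = "sim", cells[, c("cell_id", "ring", "rod",
                                                  "univalent_pairs")],
                      ring3 = 0L)
  utils::write.csv(cells, paths[["bivalents"]], row.names = FALSE, quote = FALSE)
  paths
}

#' Per-genotype interference report from class-count tables
#'
#' The computation behind genotype comparisons of CO frequency and
#' interference: per genotype and interval pair it reports Perkins
#' distances, recombinant frequencies, CoC and interference (pooled counts
#' and per-plant mean), and Z-tests of each genotype against the reference.
#'
#' @param counts Either the path of a class-count CSV (see
#'   [read_tetrad_table()]) or a list of `tetrad_class_counts`.
#' @param reference Genotype used as the comparison baseline; default the
#'   first genotype in the table.
#' @param remap Optional letter remap passed to [read_tetrad_table()].
#' @return Object of class `repro_report`: list with `estimates` (data
#'   frame), `tests` (data frame), `exclusions`.
#' @export
reproduce_interference <- function(counts, reference = NULL, remap = NULL) {
  if (is.character(counts)) counts <- read_tetrad_table(counts, remap = remap)
  ip <- attr(counts, "interval_pair")
  if (is.null(ip)) ip <- rep("interval_pair", length(counts))
  genos <- vapply(counts, `[[`, character(1), "genotype")

  keys <- unique(data.frame(ip = ip, geno = genos, stringsAsFactors = FALSE))
  est_rows <- list(); test_rows <- list(); excl <- character(0)
  pooled_by_key <- list()

  for (i in seq_len(nrow(keys))) {
    sel <- which(ip == keys$ip[i] & genos == keys$geno[i])
    res <- per_plant_and_pooled(counts[sel])
    pooled_by_key[[paste(keys$ip[i], keys$geno[i], sep = "\r")]] <- counts[sel]
    excl <- c(excl, res$excluded)
    est_rows[[i]] <- data.frame(
      interval_pair = keys$ip[i], genotype = keys$geno[i],
      n = res$pooled$n, n_plants = length(sel),
      distance1_cM = res$pooled_distance1$distance,
      distance1_se = res$pooled_distance1$se,
      distance2_cM = res$pooled_distance2$distance,
      distance2_se = res$pooled_distance2$se,
      f1 = res$pooled$f1, f2 = res$pooled$f2, f12 = res$pooled$f12,
      coc = res$pooled$coc,
      interference = res$pooled$interference,
      interference_se = res$pooled$se_interference,
      interference_plant_mean = res$per_plant_mean[["interference"]],
      flags = paste(res$pooled$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  estimates <- do.call(rbind, est_rows)

  ti <- 0L
  for (pair in unique(keys$ip)) {
    gs <- keys$geno[keys$ip == pair]
    ref <- if (!is.null(reference) && reference %in% gs) reference else gs[1]
    pool_counts <- function(g) {
      lst <- pooled_by_key[[paste(pair, g, sep = "\r")]]
      total <- lst[[1]]$counts
      for (cc in lst[-1]) total <- total + cc$counts
      tetrad_class_counts(total, genotype = g)
    }
    ref_cc <- pool_counts(ref)
    for (g in setdiff(gs, ref)) {
      g_cc <- pool_counts(g)
      zi <- ztest_interference(ref_cc, g_cc)
      d_ref <- counts_by_ditype(ref_cc); d_g <- counts_by_ditype(g_cc)
      z1 <- ztest_proportions(d_ref$n10 + d_ref$n11, d_ref$n,
                              d_g$n10 + d_g$n11, d_g$n)
      z2 <- ztest_proportions(d_ref$n01 + d_ref$n11, d_ref$n,
                              d_g$n01 + d_g$n11, d_g$n)
      ti <- ti + 1L
      test_rows[[ti]] <- data.frame(
        interval_pair = pair, reference = ref, genotype = g,
        z_interference = zi$statistic, p_interference = zi$p_value,
        z_f1 = z1$statistic, p_f1 = z1$p_value,
        z_f2 = z2$statistic, p_f2 = z2$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(estimates = estimates,
         tests = if (ti) do.call(rbind, test_rows) else NULL,
         exclusions = excl),
    class = "repro_report"
  )
}

#' @export
print.repro_report <- function(x, ...) {
  cat("Interference report\n===================\n")
  print(x$estimates, digits = 4)
  if (!is.null(x$tests)) {
    cat("\nGenotype comparisons (Z-tests)\n")
    print(x$tests, digits = 4)
  }
  if (length(x$exclusions)) {
    cat("\nPlants excluded from per-plant interference mean:",
        paste(x$exclusions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' In-silico test of the pathway re-channeling mechanism
#'
#' Simulates two scenarios with the same total crossover rate but different
#' Class II fractions and compares: mean Class I crossovers per bivalent
#' (the MLH1-focus proxy), per-interval CO frequency (Perkins distance),
#' and interference. Re-channeling Class II crossovers into Class I
#' (lowering `frac_class2` at constant `total_rate`) should raise
#' interference and the Class I count while leaving CO frequency unchanged
#' -- the signature of a mutant that shifts the Class I/Class II balance
#' without changing total crossover number.
#'
#' @param map An [interval_pair_map()].
#' @param params_a,params_b `pathway_params` for the two scenarios; their
#'   `total_rate` must be equal (the experiment's defining constraint).
#' @param n Tetrads per scenario.
#' @param seed Integer seed.
#' @return Object of class `headline_sim`: list with `scenarios` (data
#'   frame: frac_class2, class1_per_bivalent, distance1/2 + SEs,
#'   interference + SE), `delta` (b minus a with combined SEs).
#' @export
headline_simulation <- function(map, params_a, params_b, n = 50000, seed = 1) {
  stopifnot(inherits(params_a, "pathway_params"),
            inherits(params_b, "pathway_params"))
  if (!isTRUE(all.equal(params_a$total_rate, params_b$total_rate))) {
    stop("scenarios must share the same `total_rate`: ",
         "the comparison is defined at constant total crossover number")
  }
  one <- function(params, sd) {
    s <- simulate_tetrads(n, map, params, seed = sd)
    cc <- tabulate_tetrads(s, genotype = sprintf("frac2=%g", params$frac_class2))
    est <- coc_interference(cc)
    d1 <- perkins_distance(cc, 1L); d2 <- perkins_distance(cc, 2L)
    data.frame(
      frac_class2 = params$frac_class2, nu = params$nu, n = n,
      class1_per_bivalent = mean(s$n_class1),
      class1_se = stats::sd(s$n_class1) / sqrt(n),
      distance1_cM = d1$distance, distance1_se = d1$se,
      distance2_cM = d2$distance, distance2_se = d2$se,
      interference = est$interference, interference_se = est$se_interference
    )
  }
  a <- one(params_a, seed); b <- one(params_b, seed + 1)
  sc <- rbind(a, b)
  delta <- data.frame(
    d_interference = b$interference - a$interference,
    d_interference_se = sqrt(a$interference_se^2 + b$interference_se^2),
    d_class1 = b$class1_per_bivalent - a$class1_per_bivalent,
    d_class1_se = sqrt(a$class1_se^2 + b$class1_se^2),
    d_distance1 = b$distance1_cM - a$distance1_cM,
    d_distance1_se = sqrt(a$distance1_se^2 + b$distance1_se^2),
    d_distance2 = b$distance2_cM - a$distance2_cM,
    d_distance2_se = sqrt(a$distance2_se^2 + b$distance2_se^2)
  )
  structure(list(scenarios = sc, delta = delta, seed = seed),
            class = "headline_sim")
}

#' @export
print.headline_sim <- function(x, ...) {
  cat("Two-pathway re-channeling simulation\n")
  print(x$scenarios, digits = 4)
  cat("\nScenario B - scenario A:\n")
  print(x$delta, digits = 4)
  invisible(x)
}
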