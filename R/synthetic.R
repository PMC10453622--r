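# Seeded synthetic-data generators. Each generator emulates one input type of
# the analysis pipeline so every stage is testable offline: a poly-alanine
# PDB chain with designated high-B-factor sites, an alignment whose column
# compositions are met by exact quota (deterministic, no sampling), and
# first-order decay time courses with multiplicative Gaussian noise.

#' Generate a synthetic PDB structure with controlled CA B-factors
#'
#' Writes a valid fixed-column PDB text for a poly-alanine chain with one CA
#' atom per residue. B-factors are drawn from `Normal(baseline_mean,
#' baseline_sd)` (clamped to the `[0, 999.99]` field capacity) except at
#' `flexible_sites`, which carry their target values exactly (to the 2-decimal
#' PDB field precision).
#'
#' @param n_residues Number of residues (>= 1).
#' @param flexible_sites Named numeric vector: names are residue numbers,
#'   values the target B-factors (must lie in `[0, 999.99]`).
#' @param baseline_mean,baseline_sd Baseline B-factor distribution (Å²).
#' @param seed Optional integer seed for the baseline draws.
#' @param chain Chain identifier (single character).
#' @param helix_ranges,sheet_ranges Optional lists of `c(start, end)` residue
#'   ranges emitted as HELIX/SHEET records (for testing secondary-structure
#'   labelling); omit both to produce a file without such records.
#' @return PDB-format text (single string).
#' @examples
#' txt <- synth_pdb(5, flexible_sites = c(`2` = 25, `3` = 30), seed = 7)
#' read_calpha_bfactors(txt)$b_factor
#' @export
synth_pdb <- function(n_residues, flexible_sites = NULL,
                      baseline_mean = 12, baseline_sd = 2, seed = NULL,
                      chain = "A", helix_ranges = NULL, sheet_ranges = NULL) {
  stopifnot(n_residues >= 1)
  if (!is.null(flexible_sites)) {
    if (is.null(names(flexible_sites))) {
      stop("'flexible_sites' must be named by residue number", call. = FALSE)
    }
    if (any(flexible_sites < 0 | flexible_sites > 999.99)) {
      stop("target B-factors must lie in [0, 999.99] (PDB field capacity)",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rnorm(n_residues, baseline_mean, baseline_sd)
  b <- pmin(pmax(b, 0), 999.99)
  if (!is.null(flexible_sites)) {
    idx <- as.integer(names(flexible_sites))
    if (any(idx < 1 | idx > n_residues)) {
      stop("flexible site outside 1..n_residues", call. = FALSE)
    }
    b[idx] <- flexible_sites
  }

  lines <- character(0)
  fmt_ss <- function(ranges, kind) {
    vapply(seq_along(ranges), function(i) {
      r <- ranges[[i]]
      if (kind == "helix") {
        sprintf("HELIX  %3d %3d ALA %s %4d  ALA %s %4d  1",
                i, i, chain, r[1], chain, r[2])
      } else {
        sprintf("SHEET  %3d %3s 1 ALA %s%4d  ALA %s%4d  0",
                i, LETTERS[i], chain, r[1], chain, r[2])
      }
    }, character(1))
  }
  if (!is.null(helix_ranges)) lines <- c(lines, fmt_ss(helix_ranges, "helix"))
  if (!is.null(sheet_ranges)) lines <- c(lines, fmt_ss(sheet_ranges, "sheet"))

  # extended-chain CA trace along x; coordinates are placeholders
  atoms <- vapply(seq_len(n_residues), function(i) {
    paste0(
      "ATOM  ", sprintf("%5d", i), "  CA  ALA ", chain, sprintf("%4d", i),
      "    ",
      sprintf("%8.3f%8.3f%8.3f", (i - 1) * 3.8, 0, 0),
      sprintf("%6.2f%6.2f", 1.00, b[i]),
      "           C"
    )
  }, character(1))
  lines <- c(lines, atoms,
             sprintf("TER   %5d      ALA %s%4d", n_residues + 1L, chain,
                     n_residues),
             "END")
  paste0(paste(lines, collapse = "\n"), "\n")
}

# Largest-remainder apportionment of n slots to the given fractions.
largest_remainder <- function(freqs, n) {
  if (abs(sum(freqs) - 1) > 1e-6) {
    stop("frequency map must sum to 1", call. = FALSE)
  }
  x <- freqs * n
  counts <- floor(x)
  need <- n - sum(counts)
  rem <- x - counts
  ord <- order(-rem, names(freqs))
  if (need > 0) counts[ord[seq_len(need)]] <- counts[ord[seq_len(need)]] + 1
  stats::setNames(as.integer(counts), names(freqs))
}

#' Generate a synthetic aligned FASTA with exact column compositions
#'
#' Builds an alignment of `n_sequences` sequences (the query included, as the
#' last record) in which the residue composition of each specified column is
#' met by exact quota (largest-remainder apportionment) rather than random
#' sampling, so realized frequencies match the request deterministically and
#' bit-identically across platforms. Unspecified columns carry a fixed
#' consensus letter.
#'
#' @param n_sequences Total number of sequences, query included.
#' @param n_columns Alignment length.
#' @param column_freqs Named list: names are column positions (integers as
#'   strings), values named frequency vectors summing to 1.
#' @param query_wt Optional named character vector giving the query's residue
#'   at specified columns (default: the column's most frequent residue). The
#'   query residue must have a positive quota in its column, otherwise the
#'   quota is infeasible and an error is raised.
#' @param consensus Letter used at unspecified columns.
#' @param query_id Identifier of the query record.
#' @return Aligned FASTA text (single string).
#' @examples
#' fa <- synth_msa(10, 5, list(`3` = c(L = .4, Q = .3, N = .3)),
#'                 query_wt = c(`3` = "N"))
#' aln <- read_alignment(fa, "query")
#' column_frequencies(aln, 3)$counts  # L 4, N 3, Q 3
#' @export
synth_msa <- function(n_sequences, n_columns, column_freqs,
                      query_wt = NULL, consensus = "T", query_id = "query") {
  stopifnot(n_sequences >= 2, n_columns >= 1)
  mat <- matrix(consensus, nrow = n_sequences, ncol = n_columns)
  for (colname in names(column_freqs)) {
    j <- as.integer(colname)
    if (is.na(j) || j < 1 || j > n_columns) {
      stop(sprintf("column '%s' outside 1..%d", colname, n_columns),
           call. = FALSE)
    }
    freqs <- column_freqs[[colname]]
    counts <- largest_remainder(freqs, n_sequences)
    qaa <- if (!is.null(query_wt) && colname %in% names(query_wt)) {
      toupper(query_wt[[colname]])
    } else {
      names(counts)[order(-counts, names(counts))][1]
    }
    if (!qaa %in% names(counts) || counts[[qaa]] < 1L) {
      stop(sprintf(
        "quota infeasible: query residue '%s' has zero quota in column %d",
        qaa, j), call. = FALSE)
    }
    counts[[qaa]] <- counts[[qaa]] - 1L
    # deterministic fill order: descending count, then alphabetical
    ord <- order(-counts, names(counts))
    fill <- rep(names(counts)[ord], counts[ord])
    mat[seq_len(n_sequences - 1L), j] <- fill
    mat[n_sequences, j] <- qaa
  }
  ids <- c(sprintf("seq%03d", seq_len(n_sequences - 1L)), query_id)
  seqs <- apply(mat, 1, paste, collapse = "")
  paste0(paste0(">", ids, "\n", seqs, collapse = "\n"), "\n")
}

#' Generate synthetic inactivation time courses
#'
#' Simulates residual-activity series under first-order decay with
#' multiplicative Gaussian noise:
#' `residual(t) = 100 * exp(-t * ln 2 / t_half) * (1 + e)`,
#' `e ~ Normal(0, sigma)`, clipped at 0; the `t = 0` row is forced to 100
#' (activities are normalized to the untreated measurement). Multiplicative
#' noise reflects assay error scaling with signal.
#'
#' @param t_half Numeric vector of true half-lives (min), optionally named by
#'   mutant id.
#' @param times Sampling grid in minutes (default `seq(0, 30, 5)`).
#' @param sigma Noise standard deviation as a fraction (default 0.02).
#' @param temperature Incubation temperature recorded in the output.
#' @param seed Optional integer seed.
#' @return Long-format data.frame: `mutant_id`, `temperature_C`, `time_min`,
#'   `residual_pct`.
#' @examples
#' tc <- synth_timecourses(c(WT = 23.14), sigma = 0)
#' fit_first_order(tc)$t_half
#' @export
synth_timecourses <- function(t_half, times = seq(0, 30, 5), sigma = 0.02,
                              temperature = 65, seed = NULL) {
  stopifnot(all(t_half > 0), sigma >= 0, all(times >= 0))
  ids <- names(t_half) %||% sprintf("mut%02d", seq_along(t_half))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(t_half), function(i) {
    mu <- 100 * exp(-times * log(2) / t_half[i])
    res <- mu * (1 + stats::rnorm(length(times), 0, sigma))
    res <- pmax(res, 0)
    res[times == 0] <- 100
    data.frame(mutant_id = ids[i], temperature_C = temperature,
               time_min = times, residual_pct = res,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
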