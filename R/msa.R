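#' Construct an alignment set
#'
#' Lightweight container for a multiple sequence alignment plus the identity
#' of the query sequence whose (ungapped) coordinates anchor all
#' position-based operations.
#'
#' @param sequences Named character vector of aligned sequences (equal
#'   lengths; gaps as `-` or `.`). Names are sequence identifiers.
#' @param query_id Identifier of the query; must occur exactly once.
#' @return An object of class `alignment_set`.
#' @export
alignment_set <- function(sequences, query_id) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("'sequences' must be a named character vector", call. = FALSE)
  }
  sequences <- toupper(gsub(".", "-", sequences, fixed = TRUE))
  if (length(unique(nchar(sequences))) != 1L) {
    stop("aligned sequences must all have equal length", call. = FALSE)
  }
  nq <- sum(names(sequences) == query_id)
  if (nq != 1L) {
    stop(sprintf("query_id '%s' must occur exactly once (found %d)",
                 query_id, nq), call. = FALSE)
  }
  structure(list(sequences = sequences, query_id = query_id),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat(sprintf("alignment_set: %d sequences x %d columns (query '%s')\n",
              length(x$sequences), nchar(x$sequences[1]), x$query_id))
  invisible(x)
}

#' Read a multiple sequence alignment from FASTA or Clustal
#'
#' Thin wrapper around [seqinr::read.alignment()] returning an
#' [alignment_set()]. `file` may also be literal alignment text.
#'
#' @param file Path to an aligned FASTA or Clustal (`.aln`) file, or the file
#'   content as a single string.
#' @param query_id Identifier of the query sequence.
#' @param format `"fasta"` or `"clustal"`.
#' @return An `alignment_set`.
#' @export
read_alignment <- function(file, query_id, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (length(file) == 1L && grepl("\n", file, fixed = TRUE)) {
    path <- tempfile(fileext = if (format == "fasta") ".fasta" else ".aln")
    on.exit(unlink(path), add = TRUE)
    writeLines(read_text_lines(file), path)
    file <- path
  }
  aln <- seqinr::read.alignment(file, format = format, forceToLower = FALSE)
  seqs <- toupper(unlist(aln$seq, use.names = FALSE))
  names(seqs) <- aln$nam
  alignment_set(seqs, query_id)
}

#' Map ungapped query positions to alignment columns
#'
#' @param alignment An [alignment_set()].
#' @return Named integer vector: names are 1-based ungapped query positions
#'   `1..L`, values the corresponding 1-based alignment column indices, in
#'   order.
#' @examples
#' aln <- alignment_set(c(q = "A-CD", s = "ABCD"), "q")
#' map_query_columns(aln)  # c(`1` = 1, `2` = 3, `3` = 4)
#' @export
map_query_columns <- function(alignment) {
  stopifnot(inherits(alignment, "alignment_set"))
  q <- seq_chars(alignment$sequences[[alignment$query_id]])
  cols <- which(q != "-")
  if (length(cols) == 0L) {
    stop("query sequence contains no non-gap characters", call. = FALSE)
  }
  stats::setNames(cols, seq_along(cols))
}

#' Residue frequency spectrum of the alignment column at a query position
#'
#' Counts residues (gaps excluded) over all sequences — query included — in
#' the alignment column that the query's `query_pos`-th residue occupies.
#'
#' @param alignment An [alignment_set()].
#' @param query_pos 1-based position in the ungapped query sequence.
#' @param include_gaps If `TRUE`, frequencies are divided by the total number
#'   of sequences rather than by the number of non-gap characters.
#' @return An object of class `column_profile`: a list with `query_pos`,
#'   `query_aa`, `column` (1-based alignment column), `counts` (named integer,
#'   gaps excluded), `n_nongap` and `freqs` (named numeric; empty when the
#'   column is all gaps).
#' @export
column_frequencies <- function(alignment, query_pos, include_gaps = FALSE) {
  stopifnot(inherits(alignment, "alignment_set"))
  map <- map_query_columns(alignment)
  if (!as.character(query_pos) %in% names(map)) {
    stop(sprintf("query_pos %s outside 1..%d", query_pos, length(map)),
         call. = FALSE)
  }
  col <- map[[as.character(query_pos)]]
  chars <- toupper(substr(alignment$sequences, col, col))
  qaa <- substr(alignment$sequences[[alignment$query_id]], col, col)
  nongap <- chars[chars != "-"]
  counts <- table(nongap)
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_nongap <- length(nongap)
  denom <- if (include_gaps) length(chars) else n_nongap
  freqs <- if (n_nongap > 0L) counts / denom else stats::setNames(numeric(0), character(0))
  structure(list(query_pos = as.integer(query_pos), query_aa = toupper(qaa),
                 column = col, counts = counts, n_nongap = n_nongap,
                 freqs = freqs),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("column_profile: query pos %d (%s), column %d, %d non-gap\n",
              x$query_pos, x$query_aa, x$column, x$n_nongap))
  if (length(x$freqs)) {
    f <- sort(x$freqs, decreasing = TRUE)
    cat(paste(sprintf("  %s %.3f", names(f), f), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Propose substitution candidates from a column profile
#'
#' Implements the top-k / frequency-threshold consensus rule: the candidate
#' set is the union of (a) the `top_k` most frequent residues in the column
#' and (b) every residue with frequency at least `freq_threshold`, with the
#' wild-type residue removed afterwards. Residues qualifying via (a) are
#' labelled `"top2"` (also when both rules fire); the rest
#' `"freq_ge_threshold"`. Results are ordered by decreasing frequency, ties
#' alphabetical; ties at the top-k boundary are also broken alphabetically so
#' the outcome is deterministic.
#'
#' @param profile A `column_profile` from [column_frequencies()].
#' @param wt_aa Wild-type residue at this position; defaults to the query's.
#' @param top_k Number of top-frequency residues to take (default 2).
#' @param freq_threshold Frequency cutoff for rule (b); inclusive (default
#'   0.10). Set `inclusive = FALSE` for a strict `>` comparison.
#' @param inclusive Use `>=` (default) rather than `>` for the threshold rule.
#' @return Data.frame with columns `query_pos`, `wt_aa`, `proposed_aa`,
#'   `freq`, `rule`; zero rows when nothing qualifies (e.g. a fully conserved
#'   wild-type column).
#' @examples
#' aln <- alignment_set(c(q = "N", a = "L", b = "L", c = "L", d = "L",
#'                        e = "Q", f = "Q", g = "Q", h = "N"), "q")
#' propose_candidates(column_frequencies(aln, 1))
#' @export
propose_candidates <- function(profile, wt_aa = profile$query_aa,
                               top_k = 2, freq_threshold = 0.10,
                               inclusive = TRUE) {
  stopifnot(inherits(profile, "column_profile"))
  if (profile$n_nongap == 0L) {
    stop("column has no non-gap characters; no frequencies available",
         call. = FALSE)
  }
  f <- profile$freqs
  ord <- order(-f, names(f))
  ranked <- names(f)[ord]
  topset <- ranked[seq_len(min(top_k, length(ranked)))]
  thrset <- names(f)[if (inclusive) f >= freq_threshold else f > freq_threshold]
  cand <- union(topset, thrset)
  cand <- setdiff(cand, toupper(wt_aa))
  cand <- cand[order(-f[cand], cand)]
  data.frame(
    query_pos = rep(profile$query_pos, length(cand)),
    wt_aa = rep(toupper(wt_aa), length(cand)),
    proposed_aa = cand,
    freq = unname(f[cand]),
    rule = ifelse(cand %in% topset, "top2", "freq_ge_threshold"),
    stringsAsFactors = FALSE
  )
}

#' Propose candidates at several query positions
#'
#' Convenience wrapper applying [column_frequencies()] +
#' [propose_candidates()] across positions.
#'
#' @inheritParams column_frequencies
#' @inheritParams propose_candidates
#' @param positions Integer vector of 1-based ungapped query positions, or a
#'   selection string like `"18,97-101,143"`.
#' @return Row-bound candidate data.frame (see [propose_candidates()]).
#' @export
propose_candidates_at <- function(alignment, positions, top_k = 2,
                                  freq_threshold = 0.10, inclusive = TRUE,
                                  include_gaps = FALSE) {
  positions <- parse_positions(positions)
  out <- lapply(positions, function(p) {
    prof <- column_frequencies(alignment, p, include_gaps = include_gaps)
    if (prof$n_nongap == 0L) return(NULL)
    propose_candidates(prof, top_k = top_k, freq_threshold = freq_threshold,
                       inclusive = inclusive)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(query_pos = integer(0), wt_aa = character(0),
                      proposed_aa = character(0), freq = numeric(0),
                      rule = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
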