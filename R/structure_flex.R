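#' Extract per-residue C-alpha B-factors from a PDB file
#'
#' Reads the fixed-column ATOM records of a PDB file and returns one row per
#' residue that has a C-alpha atom, carrying the CA B-factor (Å²) — the
#' standard per-residue flexibility proxy in crystal structures — together
#' with a secondary-structure label taken from HELIX/SHEET records.
#'
#' Parsing rules: only the first MODEL is read (parsing stops at the first
#' ENDMDL); HETATM records are ignored; when a CA has alternate locations the
#' highest-occupancy one is kept (ties go to the first encountered); a blank
#' occupancy field counts as 1.0. Residues covered by a HELIX (SHEET) range
#' are labelled `"helix"` (`"sheet"`), everything else `"coil"`; if the file
#' has no HELIX/SHEET records at all the label is `"unknown"`.
#'
#' @param pdb Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param chain Optional chain identifier(s) to keep; `NULL` keeps all chains.
#' @return A data.frame with columns `chain`, `resseq` (author numbering),
#'   `icode` (insertion code, `""` if none), `aa` (one-letter code, `"X"` for
#'   non-standard residues), `b_factor` (Å²) and `ss`
#'   (`helix`/`sheet`/`coil`/`unknown`), ordered by chain then
#'   (`resseq`, `icode`).
#' @examples
#' txt <- synth_pdb(5, flexible_sites = c(`2` = 25, `3` = 30), seed = 1)
#' read_calpha_bfactors(txt)
#' @seealso [nominate_flexible_sites()]
#' @export
read_calpha_bfactors <- function(pdb, chain = NULL) {
  lines <- read_text_lines(pdb)
  rectype <- trimws(substr(lines, 1L, 6L))

  # first model only
  endmdl <- which(rectype == "ENDMDL")
  if (length(endmdl) > 0L) {
    keep <- seq_len(endmdl[1] - 1L)
    lines <- lines[keep]
    rectype <- rectype[keep]
  }

  atom_ln <- which(rectype == "ATOM")
  al <- lines[atom_ln]
  is_ca <- trimws(substr(al, 13L, 16L)) == "CA"
  ca_ln <- atom_ln[is_ca]
  if (length(ca_ln) == 0L) {
    stop("empty structure: no ATOM records with a CA atom found", call. = FALSE)
  }
  cal <- lines[ca_ln]

  ch <- substr(cal, 22L, 22L)
  resseq <- suppressWarnings(as.integer(substr(cal, 23L, 26L)))
  icode <- sub(" ", "", substr(cal, 27L, 27L), fixed = TRUE)
  aa3 <- trimws(substr(cal, 18L, 20L))
  occ_raw <- trimws(substr(cal, 55L, 60L))
  b_raw <- trimws(substr(cal, 61L, 66L))
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[!nzchar(occ_raw)] <- 1.0
  b <- suppressWarnings(as.numeric(b_raw))

  bad <- which(is.na(resseq) | is.na(occ) | is.na(b) | !nzchar(b_raw))
  if (length(bad) > 0L) {
    stop(sprintf("malformed ATOM record at line %d", ca_ln[bad[1]]),
         call. = FALSE)
  }

  if (!is.null(chain)) {
    sel <- ch %in% chain
    if (!any(sel)) {
      stop(sprintf("empty structure: no CA atoms in chain '%s'",
                   paste(chain, collapse = ",")), call. = FALSE)
    }
    ch <- ch[sel]; resseq <- resseq[sel]; icode <- icode[sel]
    aa3 <- aa3[sel]; occ <- occ[sel]; b <- b[sel]
  }

  # altloc resolution: per residue keep the highest-occupancy CA, tie -> first
  key <- paste(ch, resseq, icode, sep = "\r")
  pick <- vapply(split(seq_along(key), factor(key, levels = unique(key))),
                 function(i) i[which.max(occ[i])], integer(1))
  pick <- sort(unname(pick))

  aa <- unname(AA3TO1[aa3[pick]])
  aa[is.na(aa)] <- "X"
  res <- data.frame(
    chain = ch[pick], resseq = resseq[pick], icode = icode[pick],
    aa = aa, b_factor = b[pick], ss = "unknown",
    stringsAsFactors = FALSE
  )
  res <- res[order(res$chain, res$resseq, res$icode), , drop = FALSE]
  rownames(res) <- NULL

  ss_ranges <- parse_ss_records(lines, rectype)
  if (!is.null(ss_ranges)) {
    res$ss <- "coil"
    for (r in seq_len(nrow(ss_ranges))) {
      hit <- res$chain == ss_ranges$chain[r] &
        res$resseq >= ss_ranges$start[r] & res$resseq <= ss_ranges$end[r]
      res$ss[hit] <- ss_ranges$type[r]
    }
  }
  res
}

# HELIX/SHEET ranges; NULL when the file carries no such records.
parse_ss_records <- function(lines, rectype) {
  hl <- lines[rectype == "HELIX"]
  sl <- lines[rectype == "SHEET"]
  if (length(hl) + length(sl) == 0L) return(NULL)
  out <- list()
  if (length(hl) > 0L) {
    out$h <- data.frame(
      type = "helix",
      chain = substr(hl, 20L, 20L),
      start = as.integer(substr(hl, 22L, 25L)),
      end = as.integer(substr(hl, 34L, 37L)),
      stringsAsFactors = FALSE
    )
  }
  if (length(sl) > 0L) {
    out$s <- data.frame(
      type = "sheet",
      chain = substr(sl, 22L, 22L),
      start = as.integer(substr(sl, 23L, 26L)),
      end = as.integer(substr(sl, 34L, 37L)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Nominate flexible candidate sites from C-alpha B-factors
#'
#' Residues whose CA B-factor strictly exceeds `threshold` are candidate
#' flexible sites; each is either selected or carries an exclusion reason.
#' Residues at or below the threshold are omitted from the output entirely.
#'
#' Three exclusion predicates are supported, applied in this order (the first
#' that fires is reported): an explicit residue list (`exclude`), coil
#' secondary structure (`exclude_coil`), and proximity to a chain terminus
#' (`terminus_margin`: the first/last `k` residues of each chain are
#' excluded). By default B-factors are used raw, matching the absolute-cutoff
#' convention; `normalize = TRUE` instead thresholds z-scored B-factors.
#'
#' @param records Data.frame from [read_calpha_bfactors()].
#' @param threshold Flexibility cutoff (Å², or standard deviations when
#'   `normalize = TRUE`). Strictly-greater comparison. Default 21.
#' @param exclude Integer vector of residue numbers to reject explicitly.
#' @param exclude_coil Reject candidates labelled `"coil"`?
#' @param terminus_margin Reject candidates within this many residues of
#'   either chain terminus (0 = off).
#' @param normalize Threshold `(b - mean(b)) / sd(b)` instead of raw values.
#' @return Data.frame with columns `chain`, `resseq`, `aa`, `b_factor`, `ss`,
#'   `selected` (logical) and `exclusion_reason` (`""` when selected).
#' @examples
#' rec <- read_calpha_bfactors(synth_pdb(5, c(`2` = 25, `3` = 30, `5` = 22),
#'                                       seed = 1))
#' nominate_flexible_sites(rec, threshold = 21)
#' @export
nominate_flexible_sites <- function(records, threshold = 21,
                                    exclude = NULL,
                                    exclude_coil = FALSE,
                                    terminus_margin = 0,
                                    normalize = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data.frame of residue records",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0) {
    stop("invalid parameter: 'threshold' must be a single non-negative number",
         call. = FALSE)
  }

  b <- records$b_factor
  if (normalize) b <- (b - mean(b)) / stats::sd(b)

  # distance (in residues) from the nearer terminus of each chain, 0-based
  idx <- stats::ave(seq_len(nrow(records)), records$chain,
                    FUN = function(i) {
                      r <- seq_along(i) - 1L
                      pmin(r, rev(r))
                    })

  keep <- b > threshold
  cand <- records[keep, , drop = FALSE]
  cand_dist <- idx[keep]

  reason <- character(nrow(cand))
  if (!is.null(exclude)) {
    hit <- reason == "" & cand$resseq %in% exclude
    reason[hit] <- "on explicit exclusion list"
  }
  if (exclude_coil) {
    hit <- reason == "" & cand$ss == "coil"
    reason[hit] <- "coil secondary structure"
  }
  if (terminus_margin > 0) {
    hit <- reason == "" & cand_dist < terminus_margin
    reason[hit] <- sprintf("within %d residues of a chain terminus",
                           as.integer(terminus_margin))
  }

  out <- data.frame(
    chain = cand$chain, resseq = cand$resseq, aa = cand$aa,
    b_factor = cand$b_factor, ss = cand$ss,
    selected = reason == "", exclusion_reason = reason,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
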