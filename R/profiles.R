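# Bundled per-residue property scales.
#
# kyte_doolittle: Kyte & Doolittle (1982) hydropathy index.
# bp_flexibility: Bhaskaran & Ponnuswamy (1988) average flexibility index.
# Both are the 20-value tables used by the ExPASy ProtScale service; together
# with a 9-residue unweighted window they reproduce standard ProtScale
# hydrophobicity and average-flexibility profiles.
.scales <- list(
  kyte_doolittle = c(
    A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
  ),
  bp_flexibility = c(
    A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346,
    Q = 0.493, E = 0.497, G = 0.544, H = 0.323, I = 0.462,
    L = 0.365, K = 0.466, M = 0.295, F = 0.314, P = 0.509,
    S = 0.507, T = 0.444, W = 0.305, Y = 0.420, V = 0.386
  )
)

#' Bundled amino-acid property scales
#'
#' Returns one of the package's immutable 20-value property tables:
#' `"kyte_doolittle"` (hydropathy; positive = hydrophobic) or
#' `"bp_flexibility"` (average flexibility index; higher = more flexible).
#'
#' @param name Scale name.
#' @return Named numeric vector of 20 values (one per canonical residue),
#'   with attribute `scale_name`.
#' @examples
#' protein_scale("kyte_doolittle")[c("L", "N", "R")]
#' @export
protein_scale <- function(name = c("kyte_doolittle", "bp_flexibility")) {
  if (length(name) == 1L && !name %in% names(.scales)) {
    stop(sprintf("unknown scale '%s'; available: %s", name,
                 paste(names(.scales), collapse = ", ")), call. = FALSE)
  }
  name <- match.arg(name)
  structure(.scales[[name]], scale_name = name)
}

resolve_scale <- function(scale) {
  if (is.character(scale) && length(scale) == 1L) return(protein_scale(scale))
  if (is.numeric(scale) && length(scale) == 20L && !is.null(names(scale)) &&
      setequal(names(scale), AMINO1)) {
    if (is.null(attr(scale, "scale_name"))) attr(scale, "scale_name") <- "custom"
    return(scale)
  }
  stop("'scale' must be a bundled scale name or a named 20-value vector",
       call. = FALSE)
}

#' Sliding-window property profile of a protein sequence
#'
#' Computes the unweighted centered mean of a per-residue property scale over
#' a window of odd width, the convention of ProtScale with relative edge
#' weight 1. Positions whose full window does not fit inside the sequence
#' carry no score, so every emitted value has identical semantics; defined
#' positions are exactly `(w+1)/2 ... L-(w-1)/2` (1-based).
#'
#' @param sequence Amino-acid sequence (single string or character vector)
#'   over the 20 canonical one-letter codes; length >= `window`.
#' @param scale A bundled scale name or a named 20-value numeric vector.
#' @param window Odd window width >= 1 (default 9).
#' @param sequence_id Label stored on the result.
#' @return Data.frame (class `profile_result`) with columns `position`, `aa`,
#'   `score`, plus attributes `scale_name`, `window`, `sequence_id`.
#' @examples
#' windowed_profile(strrep("L", 9), "kyte_doolittle")$score  # 3.8
#' @export
windowed_profile <- function(sequence, scale = "kyte_doolittle", window = 9,
                             sequence_id = "seq") {
  sc <- resolve_scale(scale)
  if (window < 1 || window %% 2 == 0) {
    stop("'window' must be an odd integer >= 1", call. = FALSE)
  }
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (L < window) {
    stop("sequence shorter than the window", call. = FALSE)
  }
  unknown <- which(!chars %in% AMINO1)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown amino-acid letter '%s' at position %d",
                 chars[unknown[1]], unknown[1]), call. = FALSE)
  }
  vals <- unname(sc[chars])
  h <- (window - 1L) / 2L
  means <- as.numeric(stats::filter(vals, rep(1 / window, window), sides = 2))
  posn <- seq.int(h + 1L, L - h)
  out <- data.frame(position = posn, aa = chars[posn], score = means[posn],
                    stringsAsFactors = FALSE)
  attr(out, "scale_name") <- attr(sc, "scale_name")
  attr(out, "window") <- as.integer(window)
  attr(out, "sequence_id") <- sequence_id
  class(out) <- c("profile_result", "data.frame")
  out
}

#' Windowed-score change caused by a point substitution
#'
#' For an unweighted window of width `w`, substituting one residue shifts the
#' profile by a constant `(scale[new] - scale[wt]) / w` at every position
#' whose window covers the substituted residue, and leaves all other
#' positions untouched. This function reports that shift and the affected
#' position range (clipped to positions with a full window).
#'
#' @inheritParams windowed_profile
#' @param position 1-based position of the substitution.
#' @param new_aa Replacement residue (one-letter code).
#' @return An object of class `mutation_delta`: list with `position`, `wt`,
#'   `new`, `scale_name`, `window`, `delta_center` (the per-position shift)
#'   and `affected_positions` (integer vector). Substituting a residue by
#'   itself warns and yields a zero delta.
#' @examples
#' d <- mutation_delta(strrep("A", 21), 11, "L", "kyte_doolittle")
#' d$delta_center  # (3.8 - 1.8) / 9
#' @export
mutation_delta <- function(sequence, position, new_aa,
                           scale = "kyte_doolittle", window = 9) {
  sc <- resolve_scale(scale)
  if (window < 1 || window %% 2 == 0) {
    stop("'window' must be an odd integer >= 1", call. = FALSE)
  }
  chars <- seq_chars(sequence)
  L <- length(chars)
  if (position < 1 || position > L) {
    stop(sprintf("position %d outside 1..%d", position, L), call. = FALSE)
  }
  new_aa <- toupper(new_aa)
  if (!new_aa %in% AMINO1) {
    stop(sprintf("'%s' is not a canonical amino-acid letter", new_aa),
         call. = FALSE)
  }
  wt <- chars[position]
  if (!wt %in% AMINO1) {
    stop(sprintf("wild-type residue '%s' at position %d is not canonical",
                 wt, position), call. = FALSE)
  }
  if (new_aa == wt) {
    warning("substitution replaces a residue by itself; delta is zero",
            call. = FALSE)
  }
  h <- (window - 1L) / 2L
  delta <- (unname(sc[new_aa]) - unname(sc[wt])) / window
  affected <- intersect(seq.int(position - h, position + h),
                        seq.int(h + 1L, L - h))
  structure(list(position = as.integer(position), wt = wt, new = new_aa,
                 scale_name = attr(sc, "scale_name"),
                 window = as.integer(window),
                 delta_center = delta,
                 affected_positions = as.integer(affected)),
            class = "mutation_delta")
}

#' @export
print.mutation_delta <- function(x, ...) {
  cat(sprintf(
    "%s%d%s on scale '%s' (window %d): delta %+.4f at positions %d..%d\n",
    x$wt, x$position, x$new, x$scale_name, x$window, x$delta_center,
    min(x$affected_positions), max(x$affected_positions)))
  invisible(x)
}
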