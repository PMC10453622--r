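#' Activity score
#'
#' Relative activity expressed as points: the wild type (100% activity)
#' scores 100 and each 1% change scores 1 point, so the score equals the
#' relative activity numerically.
#'
#' @param rel_activity Relative extracellular activity (% of wild type),
#'   vectorized, >= 0.
#' @return Score in points.
#' @export
activity_score <- function(rel_activity) {
  if (any(rel_activity < 0, na.rm = TRUE)) {
    stop("relative activity must be >= 0", call. = FALSE)
  }
  rel_activity
}

#' Thermostability score
#'
#' Half-life expressed as points relative to the wild type: the wild type
#' scores 100 and each 1% change in half-life scores 1 point, i.e.
#' `100 * t_half / t_half_wt`.
#'
#' @param t_half Mutant half-life (min), vectorized, > 0.
#' @param t_half_wt Wild-type half-life (min), > 0.
#' @return Score in points.
#' @examples
#' thermostability_score(62.96, 23.14)  # 272.08
#' @export
thermostability_score <- function(t_half, t_half_wt) {
  if (any(t_half <= 0, na.rm = TRUE) || any(t_half_wt <= 0)) {
    stop("half-lives must be positive", call. = FALSE)
  }
  100 * t_half / t_half_wt
}

#' Composite score
#'
#' Geometric (exponent-weighted) combination of the thermostability and
#' activity scores: `ts^w_thermo * as^w_activity`. At unit weights the wild
#' type (100, 100) scores exactly 10,000, and the composite is symmetric and
#' strictly increasing in both scores. A weighted product — rather than a
#' weighted sum — is the only combination for which "both weights equal 1"
#' and "wild type = 10,000" hold simultaneously.
#'
#' @param ts Thermostability score (points), >= 0, vectorized.
#' @param as Activity score (points), >= 0, vectorized.
#' @param w_thermo,w_activity Non-negative exponent weights (default 1).
#' @return Composite score in points.
#' @examples
#' composite_score(100, 100)          # 10000
#' composite_score(272.08, 75.73)     # ~20605
#' @export
composite_score <- function(ts, as, w_thermo = 1, w_activity = 1) {
  if (w_thermo < 0 || w_activity < 0) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (any(ts < 0, na.rm = TRUE) || any(as < 0, na.rm = TRUE)) {
    stop("scores must be >= 0", call. = FALSE)
  }
  ts^w_thermo * as^w_activity
}

#' Parse substitution identifiers like "N18L" or "N18L/R143L/S97A"
#'
#' @param mutant_id Character vector of identifiers; substitutions within one
#'   mutant are separated by `/`. The empty string (or `"WT"`) denotes the
#'   wild type (no substitutions).
#' @return A list (one element per input) of data.frames with columns `wt`,
#'   `pos`, `new`.
#' @export
parse_substitutions <- function(mutant_id) {
  lapply(mutant_id, function(id) {
    if (is.na(id) || id %in% c("", "WT", "wild type", "Wild type")) {
      return(data.frame(wt = character(0), pos = integer(0),
                        new = character(0), stringsAsFactors = FALSE))
    }
    parts <- strsplit(id, "/", fixed = TRUE)[[1]]
    ok <- grepl("^[A-Za-z][0-9]+[A-Za-z]$", parts)
    if (!all(ok)) {
      stop(sprintf("cannot parse substitution '%s' in mutant '%s'",
                   parts[!ok][1], id), call. = FALSE)
    }
    data.frame(
      wt = toupper(sub("^([A-Za-z]).*$", "\\1", parts)),
      pos = as.integer(sub("^[A-Za-z]([0-9]+)[A-Za-z]$", "\\1", parts)),
      new = toupper(sub("^.*([A-Za-z])$", "\\1", parts)),
      stringsAsFactors = FALSE
    )
  })
}

#' Score a table of mutant measurements
#'
#' Computes activity, thermostability and composite scores for each mutant in
#' a measurement table, relative to the wild-type row. Scores are computed
#' from the unrounded inputs; any rounding is left to output time.
#'
#' @param measurements Data.frame with columns `mutant_id`,
#'   `rel_activity_pct` (% of wild type) and `t_half_min` (minutes). Rows
#'   with missing half-life (e.g. mutants too inactive to characterize) get
#'   `NA` scores.
#' @param wt_id Identifier of the wild-type row (default `"WT"`).
#' @param w_thermo,w_activity Composite exponent weights.
#' @return Data.frame of score cards: `mutant_id`, `activity_score`,
#'   `thermostability_score`, `composite_score`, `w_thermo`, `w_activity`,
#'   ordered by decreasing composite score (wild type included).
#' @examples
#' score_mutants(pb92_single_mutants())
#' @export
score_mutants <- function(measurements, wt_id = "WT",
                          w_thermo = 1, w_activity = 1) {
  need <- c("mutant_id", "rel_activity_pct", "t_half_min")
  if (!all(need %in% names(measurements))) {
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  wt <- measurements[measurements$mutant_id == wt_id, , drop = FALSE]
  if (nrow(wt) != 1L) {
    stop(sprintf("wild-type id '%s' must occur exactly once in measurements",
                 wt_id), call. = FALSE)
  }
  if (is.na(wt$t_half_min) || wt$t_half_min <= 0) {
    stop("wild-type half-life must be a positive number", call. = FALSE)
  }
  as_ <- activity_score(measurements$rel_activity_pct)
  ts <- ifelse(is.na(measurements$t_half_min), NA_real_,
               thermostability_score(measurements$t_half_min, wt$t_half_min))
  cs <- ifelse(is.na(ts) | is.na(as_), NA_real_,
               composite_score(ifelse(is.na(ts), 0, ts),
                               ifelse(is.na(as_), 0, as_),
                               w_thermo, w_activity))
  out <- data.frame(mutant_id = measurements$mutant_id,
                    activity_score = as_, thermostability_score = ts,
                    composite_score = cs,
                    w_thermo = w_thermo, w_activity = w_activity,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$composite_score, out$mutant_id, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the best mutant per site (or site group)
#'
#' Within each group of positions, the single mutant with the highest
#' composite score wins; ties resolve to the higher thermostability score,
#' then alphabetically by identifier. A winner is `advanced` — i.e. worth
#' carrying into combination mutants — only when its composite score exceeds
#' the wild type's by at least the factor `advance_min_ratio`; merely
#' matching the wild type (or beating it marginally) is not treated as a
#' meaningful improvement.
#'
#' @param scores Score-card data.frame from [score_mutants()] (single-point
#'   mutants only; identifiers must parse as one substitution each).
#' @param wt_id Wild-type identifier present in `scores`.
#' @param site_groups Optional named list mapping group labels to integer
#'   position vectors; every scored mutant must fall in exactly one group.
#'   Default: each position forms its own group.
#' @param advance_min_ratio Minimum composite-score ratio over the wild type
#'   for a winner to advance (default 1.2, i.e. a 20% improvement).
#' @return Data.frame with one row per non-empty group: `group`, `positions`,
#'   `mutant_id`, `composite_score`, `thermostability_score`, `advanced`.
#'   Groups with no scorable member are skipped with a warning.
#' @examples
#' sel <- select_per_site_best(score_mutants(pb92_single_mutants()))
#' sel[sel$advanced, ]
#' @export
select_per_site_best <- function(scores, wt_id = "WT", site_groups = NULL,
                                 advance_min_ratio = 1.2) {
  wt <- scores[scores$mutant_id == wt_id, , drop = FALSE]
  if (nrow(wt) != 1L) {
    stop(sprintf("wild-type id '%s' must occur exactly once", wt_id),
         call. = FALSE)
  }
  mut <- scores[scores$mutant_id != wt_id & !is.na(scores$composite_score), ,
                drop = FALSE]
  subs <- parse_substitutions(mut$mutant_id)
  nsub <- vapply(subs, nrow, integer(1))
  if (any(nsub != 1L)) {
    stop("per-site selection expects single-substitution mutants; offending: ",
         paste(mut$mutant_id[nsub != 1L], collapse = ", "), call. = FALSE)
  }
  pos <- vapply(subs, function(s) s$pos[1], integer(1))

  if (is.null(site_groups)) {
    site_groups <- lapply(sort(unique(pos)), identity)
    names(site_groups) <- as.character(sort(unique(pos)))
  }
  membership <- vapply(pos, function(p) {
    g <- names(site_groups)[vapply(site_groups, function(v) p %in% v, logical(1))]
    if (length(g) != 1L) {
      stop(sprintf("position %d belongs to %d groups; expected exactly one",
                   p, length(g)), call. = FALSE)
    }
    g
  }, character(1))

  rows <- lapply(names(site_groups), function(g) {
    m <- mut[membership == g, , drop = FALSE]
    if (nrow(m) == 0L) {
      warning(sprintf("site group '%s' has no scorable mutants; skipped", g),
              call. = FALSE)
      return(NULL)
    }
    m <- m[order(-m$composite_score, -m$thermostability_score, m$mutant_id), ,
           drop = FALSE]
    data.frame(group = g,
               positions = paste(sort(unique(pos[membership == g])),
                                 collapse = ","),
               mutant_id = m$mutant_id[1],
               composite_score = m$composite_score[1],
               thermostability_score = m$thermostability_score[1],
               advanced = m$composite_score[1] >
                 advance_min_ratio * wt$composite_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plan combination mutants around a loop region
#'
#' Given single-site winners, builds the standard combination plan: the
#' non-loop winners form a fixed base; proposals are (1) the base alone,
#' (2) the base plus each loop winner individually, and (3) the base plus all
#' loop winners jointly. Loop positions (e.g. a contiguous surface loop) are
#' treated as one structural unit explored separately. Proposal identifiers
#' encode the substitution count (`M2`, `M3-1`, ..., `M6`).
#'
#' @param winners Character vector of single-substitution identifiers (e.g.
#'   `c("N18L", "S97A", ...)`), or the data.frame returned by
#'   [select_per_site_best()] (its `advanced` winners are used).
#' @param loop Integer vector of loop positions; must be a subset of the
#'   winner positions. Empty loop: the plan is the base alone.
#' @return An object of class `combination_plan`: list with
#'   `base_substitutions`, `loop_substitutions` and `proposals` (data.frame
#'   with `id`, `mutant_id`, `n_substitutions`).
#' @examples
#' plan <- propose_combinations(c("N18L", "S97A", "G98R", "S99L", "G100A",
#'                                "R143L"), loop = 97:100)
#' plan$proposals
#' @export
propose_combinations <- function(winners, loop = integer()) {
  if (is.data.frame(winners)) {
    if ("advanced" %in% names(winners)) winners <- winners[winners$advanced, ]
    winners <- winners$mutant_id
  }
  if (length(winners) == 0L) stop("no winners supplied", call. = FALSE)
  subs <- parse_substitutions(winners)
  nsub <- vapply(subs, nrow, integer(1))
  if (any(nsub != 1L)) {
    stop("winners must be single-substitution identifiers", call. = FALSE)
  }
  pos <- vapply(subs, function(s) s$pos[1], integer(1))
  if (anyDuplicated(pos)) {
    stop("overlapping positions among winners: ",
         paste(pos[duplicated(pos)], collapse = ", "), call. = FALSE)
  }
  loop <- parse_positions(loop)
  if (!all(loop %in% pos)) {
    stop("loop positions not among winner positions: ",
         paste(setdiff(loop, pos), collapse = ", "), call. = FALSE)
  }

  ord <- order(pos)
  winners <- winners[ord]; pos <- pos[ord]
  base <- winners[!pos %in% loop]
  loop_w <- winners[pos %in% loop]
  nb <- length(base)
  g <- length(loop_w)

  combos <- list()
  ids <- character(0)
  if (nb > 0L) {
    combos[[length(combos) + 1L]] <- base
    ids <- c(ids, sprintf("M%d", nb))
  }
  for (i in seq_len(g)) {
    combos[[length(combos) + 1L]] <- c(base, loop_w[i])
    ids <- c(ids, sprintf("M%d-%d", nb + 1L, i))
  }
  if (g > 1L) {  # joint loop proposal duplicates the single one when g == 1
    combos[[length(combos) + 1L]] <- c(base, loop_w)
    ids <- c(ids, sprintf("M%d", nb + g))
  }

  proposals <- data.frame(
    id = ids,
    mutant_id = vapply(combos, paste, character(1), collapse = "/"),
    n_substitutions = vapply(combos, length, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(base_substitutions = base, loop_substitutions = loop_w,
                 proposals = proposals),
            class = "combination_plan")
}

#' @export
print.combination_plan <- function(x, ...) {
  cat("combination plan\n  base:", paste(x$base_substitutions, collapse = "/"),
      "\n  loop:", paste(x$loop_substitutions, collapse = ", "), "\n")
  print(x$proposals, row.names = FALSE)
  invisible(x)
}
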