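#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Numeric-looking values are converted to numbers.
#'
#' @param path Path to the configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed config line: ", lines[bad][1], call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n) && grepl("^[0-9.eE+-]+$", v)) n else v
  })
  stats::setNames(out, keys)
}

#' Run the full design-analysis pipeline
#'
#' Ties the stages together: flexible-site nomination from a PDB file,
#' substitution candidates from an alignment, scoring of measured mutants,
#' per-site winner selection, and a combination plan around a loop region.
#' Stages whose input file is missing from the configuration are skipped with
#' a notice on stderr; measured quantities always enter as files and are
#' never computed. A JSON manifest (input hashes, parameters, versions, seed)
#' makes the run reproducible.
#'
#' @param config Named list (or path to a `key = value` file, see
#'   [read_run_config()]) with any of: `pdb`, `msa`, `measurements` (file
#'   paths); `query_id`, `wt_id`; `threshold`, `exclude`, `top_k`,
#'   `freq_threshold`, `window`, `w_thermo`, `w_activity`, `advance_min_ratio`,
#'   `loop` (e.g. `"97-100"`), `positions`; `seed`.
#' @param out_dir Output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return Invisibly, a list with the stage results (`sites`, `candidates`,
#'   `scores`, `winners`, `plan`) and the paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  out_dir <- out_dir %||% config$out_dir %||%
    stop("no output directory given", call. = FALSE)

  notice <- function(...) message(sprintf(...))
  inputs <- list(pdb = config$pdb, msa = config$msa,
                 measurements = config$measurements)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  missing_in <- !vapply(inputs, file.exists, logical(1))
  if (any(missing_in)) {
    stop("input file(s) not found: ",
         paste(unlist(inputs[missing_in]), collapse = ", "), call. = FALSE)
  }

  # validate measurements (wt_id present) before producing any output
  wt_id <- config$wt_id %||% "WT"
  meas <- NULL
  if (!is.null(config$measurements)) {
    meas <- read_tsv(config$measurements)
    if (nrow(meas) > 0L && !wt_id %in% meas$mutant_id) {
      stop(sprintf("wild-type id '%s' absent from measurements", wt_id),
           call. = FALSE)
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  paths <- character(0)
  res <- list()

  if (!is.null(config$pdb)) {
    rec <- read_calpha_bfactors(config$pdb, chain = config$chain)
    res$sites <- nominate_flexible_sites(
      rec,
      threshold = config$threshold %||% 21,
      exclude = if (!is.null(config$exclude)) parse_positions(config$exclude),
      exclude_coil = isTRUE(config$exclude_coil),
      terminus_margin = config$terminus_margin %||% 0
    )
    paths["sites"] <- file.path(out_dir, "sites.tsv")
    write_tsv(res$sites, paths["sites"])
  } else {
    notice("pipeline: no PDB input; site-nomination stage skipped")
  }

  if (!is.null(config$msa)) {
    positions <- if (!is.null(config$positions)) {
      parse_positions(config$positions)
    } else if (!is.null(res$sites)) {
      res$sites$resseq[res$sites$selected]
    } else {
      stop("msa stage needs 'positions' or a PDB-derived site list",
           call. = FALSE)
    }
    aln <- read_alignment(config$msa,
                          query_id = config$query_id %||%
                            stop("msa stage needs 'query_id'", call. = FALSE),
                          format = config$msa_format %||% "fasta")
    res$candidates <- propose_candidates_at(
      aln, positions,
      top_k = config$top_k %||% 2,
      freq_threshold = config$freq_threshold %||% 0.10
    )
    paths["candidates"] <- file.path(out_dir, "candidates.tsv")
    write_tsv(res$candidates, paths["candidates"])
  } else {
    notice("pipeline: no alignment input; candidate stage skipped")
  }

  if (!is.null(meas) && nrow(meas) > 0L) {
    res$scores <- score_mutants(meas, wt_id = wt_id,
                                w_thermo = config$w_thermo %||% 1,
                                w_activity = config$w_activity %||% 1)
    paths["scores"] <- file.path(out_dir, "scores.tsv")
    write_tsv(res$scores, paths["scores"])

    single <- vapply(parse_substitutions(res$scores$mutant_id), nrow,
                     integer(1)) == 1L
    singles <- res$scores[single | res$scores$mutant_id == wt_id, ,
                          drop = FALSE]
    res$winners <- select_per_site_best(
      singles, wt_id = wt_id,
      advance_min_ratio = config$advance_min_ratio %||% 1.2)
    paths["winners"] <- file.path(out_dir, "winners.tsv")
    write_tsv(res$winners, paths["winners"])

    if (!is.null(config$loop)) {
      res$plan <- propose_combinations(res$winners,
                                       loop = parse_positions(config$loop))
      paths["plan"] <- file.path(out_dir, "plan.json")
      jsonlite::write_json(
        list(base_substitutions = res$plan$base_substitutions,
             loop_substitutions = res$plan$loop_substitutions,
             proposals = res$plan$proposals),
        paths["plan"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  } else {
    notice("pipeline: no (non-empty) measurement input; scoring stage skipped")
  }

  manifest <- list(
    package = "thermorank",
    package_version = as.character(utils::packageVersion("thermorank")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("pdb", "msa", "measurements", "out_dir"))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = as.list(paths)
  )
  paths["manifest"] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")

  invisible(c(res, list(paths = paths)))
}
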