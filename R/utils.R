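# internal helpers shared across modules

# Accept either a file path or literal text (possibly multi-line) and return
# a character vector of lines.
read_text_lines <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "")
}

# Split a sequence given as a single string (or already a character vector of
# single letters) into uppercase one-letter codes.
seq_chars <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "", fixed = TRUE)[[1]]
  }
  toupper(sequence)
}

# Parse position selections like "18,97-101,143" into an integer vector.
parse_positions <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- trimws(strsplit(paste(x, collapse = ","), ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  out <- lapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq.int(ab[1], ab[2])
    } else {
      as.integer(p)
    }
  })
  unique(unlist(out))
}

AMINO1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
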