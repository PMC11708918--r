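.format_cell <- function(x) {
  if (is.double(x)) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  } else {
    as.character(x)
  }
}

#' Write a result table as TSV with a metadata header
#'
#' Tab-delimited output with `#`-prefixed metadata lines (tool version,
#' caller-supplied key-value pairs, timestamp) ahead of the header row.
#' Doubles are serialized with 17 significant digits so a round trip through
#' [read_drive_tsv()] reproduces them bit-exactly. The data section is a
#' pure function of the data (the timestamp line can be suppressed for
#' byte-reproducible files).
#'
#' @param x A data frame (trajectory, threshold grid, vector field, ...).
#' @param path Output path, or `""` for standard output.
#' @param meta Named list of metadata to record in the header.
#' @param timestamp Include a timestamp header line?
#' @return `path`, invisibly.
#' @export
write_drive_tsv <- function(x, path, meta = list(), timestamp = FALSE) {
  stopifnot(is.data.frame(x))
  hdr <- c(sprintf("# medeadyn %s", as.character(utils::packageVersion("medeadyn"))),
           sprintf("# %s: %s", names(meta), vapply(meta, function(v)
             paste(.format_cell(v), collapse = ","), character(1))))
  if (timestamp) hdr <- c(hdr, sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  cells <- vapply(x, .format_cell, character(nrow(x)))
  if (nrow(x) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(hdr, paste(names(x), collapse = "\t"),
             apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, if (identical(path, "")) stdout() else path)
  invisible(path)
}

#' Read a TSV written by [write_drive_tsv()]
#'
#' Skips `#` metadata lines and restores numeric columns at full precision.
#'
#' @param path File path.
#' @return A tibble; header metadata is attached as attribute `"meta"`.
#' @export
read_drive_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  out <- as_tibble(df)
  attr(out, "meta") <- meta
  out
}

#' Write scalar results as JSON
#'
#' Serializes a named list of scalar results (equilibria, thresholds) to
#' UTF-8 JSON at full double precision.
#'
#' @param x A named list.
#' @param path Output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_drive_json <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          na = "null")
  writeLines(txt, if (identical(path, "")) stdout() else path)
  invisible(path)
}
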