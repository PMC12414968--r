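#' Read and write pattern files
#'
#' Plain-text pattern file format: one pattern per line as space-separated
#' sorted 0-based active indices; lines starting with `#` are comments, and
#' a header comment of the form `# N=.. S=.. D=..` records the parameters.
#' Indices are converted to/from the package's 1-based internal
#' representation at this boundary.
#'
#' @param patterns list of 1-based active-index vectors.
#' @param path file path.
#' @param params optional [network_params()] recorded in the header.
#' @return `write_pattern_file` returns `path` invisibly;
#'   `read_pattern_file` returns the list of 1-based patterns, with a
#'   `params` attribute (named integer vector) when the header is present.
#' @export
write_pattern_file <- function(patterns, path, params = NULL) {
  lines <- character(0)
  if (!is.null(params)) {
    lines <- sprintf("# N=%d S=%d D=%d", params$N, params$S, params$D)
  }
  lines <- c(lines, vapply(patterns, function(p) {
    paste(sort(as.integer(p)) - 1L, collapse = " ")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pattern_file
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  patterns <- lapply(strsplit(trimws(body), "\\s+"), function(x) {
    sort(as.integer(x) + 1L)
  })
  hp <- regmatches(header, regexec("N=(\\d+) S=(\\d+) D=(\\d+)", header))
  hp <- Filter(function(m) length(m) == 4L, hp)
  if (length(hp)) {
    attr(patterns, "params") <- stats::setNames(
      as.integer(hp[[1]][2:4]), c("N", "S", "D"))
  }
  patterns
}

#' Read and write connectivity-matrix files
#'
#' Plain-text matrix format: first line `N`, then `N` lines of `N`
#' space-separated 0/1 values, row = input unit.
#'
#' @param W binary `N x N` matrix.
#' @param path file path.
#' @return `write_matrix_file` returns `path` invisibly;
#'   `read_matrix_file` returns the integer matrix.
#' @export
write_matrix_file <- function(W, path) {
  lines <- c(as.character(nrow(W)),
             apply(W, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_file
#' @export
read_matrix_file <- function(path) {
  lines <- readLines(path)
  N <- as.integer(lines[1L])
  rows <- strsplit(trimws(lines[1L + seq_len(N)]), "\\s+")
  W <- do.call(rbind, lapply(rows, as.integer))
  if (!identical(dim(W), c(N, N)) || !all(W %in% c(0L, 1L))) {
    stop("malformed matrix file", call. = FALSE)
  }
  W
}

# CSV with '# key: value' metadata header lines; read back with comment.char
write_table_with_metadata <- function(df, path, metadata = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k, paste(metadata[[k]], collapse = " ")),
               con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
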