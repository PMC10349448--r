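`%||%` <- function(x, y) if (is.null(x)) y else x

#' Atomically write text lines to a file
#'
#' Writes to a temporary file in the destination directory and renames it into
#' place, so readers never observe a half-written file. All text is UTF-8.
#'
#' @param lines character vector of lines
#' @param path destination path
#' @keywords internal
atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("destination directory does not exist: ", dir, call. = FALSE)
  }
  tmp <- tempfile(pattern = paste0(".", basename(path), "-"), tmpdir = dir)
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeLines(enc2utf8(lines), con = con, sep = "\n", useBytes = TRUE)
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok && file.exists(tmp)) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write to ", path, call. = FALSE)
  }
  invisible(path)
}

read_utf8_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines
}

#' Read a JSON Lines file
#' @param path file path
#' @return list with one element per non-empty line
#' @keywords internal
read_jsonl <- function(path) {
  lines <- read_utf8_lines(path)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    out[[i]] <- tryCatch(
      jsonlite::fromJSON(lines[idx[i]], simplifyVector = TRUE,
                         simplifyDataFrame = TRUE, simplifyMatrix = FALSE),
      error = function(e) {
        stop("malformed JSON on line ", idx[i], " of ", path, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
  }
  attr(out, "line_numbers") <- idx
  out
}

#' Write a list of records as JSON Lines
#' @param records list of R objects, one per line
#' @param path destination
#' @keywords internal
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA))
  }, character(1))
  atomic_write_lines(lines, path)
}

# data.frame rows -> list of named lists (for JSONL output)
df_to_records <- function(df) {
  if (nrow(df) == 0) return(list())
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
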