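# Plain-format image I/O. Images travel as portable graymaps (PGM): binary
# P5 for speed, ASCII P2 for human-readable fixtures. Values are stored
# quantised to maxval and mapped back to [0, 1] on read.

#' Write a matrix as a PGM image
#'
#' @param m numeric matrix in `[0, 1]` (or logical; `TRUE` -> maxval).
#' @param path output path.
#' @param maxval maximum gray value (255 or 65535).
#' @param ascii write ASCII `P2` instead of binary `P5`.
#' @export
write_pgm <- function(m, path, maxval = 255L, ascii = FALSE) {
  if (is.logical(m)) m <- m * 1
  stopifnot(is.matrix(m), maxval %in% c(255L, 65535L))
  q <- round(pmin(pmax(m, 0), 1) * maxval)
  # PGM is row-major (English reading order)
  qt <- as.integer(t(q))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
    writeLines(paste(qt, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", ncol(m), nrow(m), maxval), con,
              eos = NULL)
    if (maxval == 255L) {
      writeBin(as.raw(qt), con)
    } else {
      writeBin(qt, con, size = 2L, endian = "big")
    }
  }
  invisible(path)
}

#' Read a PGM image into a `[0, 1]` matrix
#' @param path path to a P2 or P5 PGM file.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) break
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file")
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  n <- w * h
  if (magic == "P5") {
    vals <- if (maxval < 256L) {
      as.integer(readBin(con, "raw", n))
    } else {
      readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    vals <- integer(0)
    while (length(vals) < n) {
      tok <- read_token()
      if (!nzchar(tok)) break
      vals <- c(vals, as.integer(tok))
    }
  }
  if (length(vals) != n) stop("truncated PGM file")
  matrix(vals / maxval, h, w, byrow = TRUE)
}

#' Read a pipeline configuration from JSON
#'
#' Returns the parsed list; missing blocks are filled by stage defaults at
#' use time.
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
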