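# Grayscale image I/O: PGM (P2 plain / P5 binary) and PNG. Images are
# matrices with row 0 at the top; values are scaled to [0, 1] on read.

#' Read a grayscale image
#'
#' PGM (P2 or P5) or PNG by file extension. Pixel values are scaled to
#' \[0, 1\]; RGB(A) PNG input is reduced to grayscale by averaging the color
#' channels.
#'
#' @param path input file.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = read_pgm(path),
         png = {
           a <- png::readPNG(path)
           if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]),
                                                  drop = FALSE], c(1, 2), mean)
           a
         },
         stop("unsupported image extension '", ext, "' (use pgm or png)",
              call. = FALSE))
}

#' Write a grayscale image
#'
#' Values are clipped to \[0, 1\] and quantised to `maxval` levels for PGM;
#' PNG goes through [png::writePNG()].
#'
#' @param image numeric matrix.
#' @param path output file (`.pgm` or `.png`).
#' @param maxval PGM maximum gray value.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, maxval = 255L) {
  ext <- tolower(tools::file_ext(path))
  img <- pmin(pmax(image, 0), 1)
  switch(ext,
         pgm = write_pgm(img, path, maxval = maxval),
         png = png::writePNG(img, path),
         stop("unsupported image extension '", ext, "' (use pgm or png)",
              call. = FALSE))
  invisible(path)
}

#' @rdname read_image
#' @export
read_pgm <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  # header: magic, width, height, maxval, with '#' comments allowed
  tokens <- character(0)
  magic <- NULL
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      next
    }
    # accumulate a token
    tok <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        break
      }
      tok <- paste0(tok, ch)
    }
    tokens <- c(tokens, tok)
    if (is.null(magic)) magic <- tokens[1]
    if (length(tokens) == 4L) break
  }
  if (!(magic %in% c("P2", "P5")))
    stop("not a PGM file (magic '", magic, "')", call. = FALSE)
  w <- as.integer(tokens[2]); h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  n <- w * h
  vals <- if (magic == "P2") {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval > 255L) {
      as.integer(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                         endian = "big"))
    } else {
      as.integer(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
    }
  }
  if (length(vals) != n) stop("truncated PGM payload", call. = FALSE)
  matrix(vals / maxval, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname write_image
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  v <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval)),
             con, sep = "\n")
  apply(v, 1L, function(row)
    writeLines(paste(row, collapse = " "), con, sep = "\n"))
  invisible(path)
}

#' Write a line profile as CSV
#'
#' Columns `index` (0-based column coordinate) and `value`.
#'
#' @param profile numeric vector (see [line_profile()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(
    data.frame(index = seq_along(profile) - 1L, value = profile),
    path, row.names = FALSE)
  invisible(path)
}
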