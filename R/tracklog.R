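# Bit-exact writer and parser for the line-oriented pseudo-function tracking
# grammar:
#
#   ==========               ten equal signs precede every level
#   level(#:#:#)             level number : canvas width : canvas height
#       t(#,#,#:bool)        triangle x, y, leg size : half-tone?   (4-space indent)
#       c(#,#,#:bool)        circle x, y, radius : half-tone?       (4-space indent)
#   m(#,#:#^#_#)             move: x, y : brush width ^ ray count _ rotation
#   r()                      refinement action
#   g(#)                     guess of the gray-circle count
#
# x is the column and y the row (screen coordinates). Booleans are written
# "true"/"false". Newlines are LF on output; CRLF and a missing final newline
# are tolerated on input. Events are represented as a data.frame, one row per
# event, with NA in the fields a variant does not use.

track_cols <- c("type", "level", "width", "height", "x", "y", "size",
                "halftone", "n_rays", "rotation", "guess")

empty_events <- function() {
  data.frame(type = character(), level = integer(), width = integer(),
             height = integer(), x = integer(), y = integer(),
             size = integer(), halftone = logical(), n_rays = integer(),
             rotation = integer(), guess = integer(),
             stringsAsFactors = FALSE)
}

event_row <- function(type, ...) {
  row <- list(type = type, level = NA_integer_, width = NA_integer_,
              height = NA_integer_, x = NA_integer_, y = NA_integer_,
              size = NA_integer_, halftone = NA, n_rays = NA_integer_,
              rotation = NA_integer_, guess = NA_integer_)
  args <- list(...)
  row[names(args)] <- args
  structure(row, class = "data.frame", row.names = c(NA_integer_, -1L))
}

#' Track-event constructors
#'
#' Build single-row event data frames for the tracking grammar: a level
#' start, a triangle or circle of the level's hidden image, a brush move, a
#' refinement, or a guess. Bind rows to assemble a log.
#'
#' @param level level number.
#' @param width,height canvas dimensions in pixels.
#' @param x,y 0-based column (x) and row (y) coordinates.
#' @param size triangle leg length or circle radius in pixels.
#' @param halftone is the shape tumor-gray (`TRUE`) or full-tone?
#' @param n_rays rays in the star.
#' @param rotation brush rotation in degrees (always 0 in recorded play).
#' @param count the guessed number of gray circles.
#' @return one-row data.frame of the event.
#' @name track_events
NULL

#' @rdname track_events
#' @export
ev_level <- function(level, width, height)
  event_row("level", level = as.integer(level), width = as.integer(width),
            height = as.integer(height))

#' @rdname track_events
#' @export
ev_triangle <- function(x, y, size, halftone)
  event_row("triangle", x = as.integer(x), y = as.integer(y),
            size = as.integer(size), halftone = as.logical(halftone))

#' @rdname track_events
#' @export
ev_circle <- function(x, y, size, halftone)
  event_row("circle", x = as.integer(x), y = as.integer(y),
            size = as.integer(size), halftone = as.logical(halftone))

#' @rdname track_events
#' @export
ev_move <- function(x, y, width, n_rays, rotation = 0L)
  event_row("move", x = as.integer(x), y = as.integer(y),
            width = as.integer(width), n_rays = as.integer(n_rays),
            rotation = as.integer(rotation))

#' @rdname track_events
#' @export
ev_refine <- function() event_row("refine")

#' @rdname track_events
#' @export
ev_guess <- function(count) event_row("guess", guess = as.integer(count))

bool_word <- function(b) ifelse(b, "true", "false")

#' Serialize track events to the tracking grammar
#'
#' Byte-deterministic: one pseudo-function per line, LF newlines, a
#' ten-equal-signs separator line before every level record, exactly four
#' spaces before every shape line. Shape events must fall inside a level
#' block (after a level record).
#'
#' @param events event data.frame (see [ev_level()] and friends).
#' @return a single character scalar, `""` for an empty log.
#' @export
serialize_track <- function(events) {
  if (nrow(events) == 0L) return("")
  if (events$type[1] != "level")
    stop("track logs must begin with a level record", call. = FALSE)
  first_level <- match("level", events$type)
  shp <- which(events$type %in% c("triangle", "circle"))
  if (any(shp < first_level))
    stop("shape record outside a level block", call. = FALSE)
  lines <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    lines[i] <- switch(
      e$type,
      level = sprintf("level(%d:%d:%d)", e$level, e$width, e$height),
      triangle = sprintf("    t(%d,%d,%d:%s)", e$x, e$y, e$size,
                         bool_word(e$halftone)),
      circle = sprintf("    c(%d,%d,%d:%s)", e$x, e$y, e$size,
                       bool_word(e$halftone)),
      move = sprintf("m(%d,%d:%d^%d_%d)", e$x, e$y, e$width, e$n_rays,
                     e$rotation),
      refine = "r()",
      guess = sprintf("g(%d)", e$guess),
      stop("unknown event type '", e$type, "' at row ", i, call. = FALSE)
    )
  }
  is_level <- events$type == "level"
  lines[is_level] <- paste0("==========\n", lines[is_level])
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a tracking log
#'
#' Inverse of [serialize_track()]. Tolerates CRLF line endings, trailing
#' whitespace and a missing final newline; rejects malformed
#' pseudo-functions, wrong indentation, unknown function names and shape
#' records outside a level block, reporting the offending line number.
#'
#' @param text the log as a single string (or a vector of lines).
#' @return event data.frame.
#' @export
parse_track <- function(text) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- sub("[ \t\r]+$", "", text)
  nonblank <- which(text != "")
  lines <- text[nonblank]
  lineno <- nonblank

  rows <- vector("list", length(lines))
  seen_level <- FALSE
  expect_level <- FALSE
  perr <- function(i, msg)
    stop(sprintf("track parse error at line %d: %s", lineno[i], msg),
         call. = FALSE)

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "==========") {
      expect_level <- TRUE
      next
    }
    if (expect_level && !grepl("^level\\(", ln))
      perr(i, "expected a level(...) record after '=========='")
    if (grepl("^level\\(", ln)) {
      m <- regmatches(ln, regexec("^level\\((\\d+):(\\d+):(\\d+)\\)$", ln))[[1]]
      if (length(m) == 0L) perr(i, "malformed level record")
      if (!expect_level)
        perr(i, "level record not preceded by '=========='")
      expect_level <- FALSE
      seen_level <- TRUE
      rows[[i]] <- ev_level(as.integer(m[2]), as.integer(m[3]),
                            as.integer(m[4]))
    } else if (grepl("^\\s*[tc]\\(", ln)) {
      m <- regmatches(
        ln, regexec("^    ([tc])\\((\\d+),(\\d+),(\\d+):(true|false)\\)$",
                    ln))[[1]]
      if (length(m) == 0L)
        perr(i, "malformed shape record (shapes need a 4-space indent)")
      if (!seen_level) perr(i, "shape record outside a level block")
      fn <- if (m[2] == "t") ev_triangle else ev_circle
      rows[[i]] <- fn(as.integer(m[3]), as.integer(m[4]), as.integer(m[5]),
                      m[6] == "true")
    } else if (grepl("^m\\(", ln)) {
      m <- regmatches(
        ln, regexec("^m\\((\\d+),(\\d+):(\\d+)\\^(\\d+)_(\\d+)\\)$", ln))[[1]]
      if (length(m) == 0L) perr(i, "malformed move record")
      rows[[i]] <- ev_move(as.integer(m[2]), as.integer(m[3]),
                           as.integer(m[4]), as.integer(m[5]),
                           as.integer(m[6]))
    } else if (ln == "r()") {
      rows[[i]] <- ev_refine()
    } else if (grepl("^g\\(", ln)) {
      m <- regmatches(ln, regexec("^g\\((\\d+)\\)$", ln))[[1]]
      if (length(m) == 0L) perr(i, "malformed guess record")
      rows[[i]] <- ev_guess(as.integer(m[2]))
    } else {
      perr(i, paste0("unknown pseudo-function '",
                     substr(ln, 1, 20), "'"))
    }
  }
  if (expect_level && length(lines) > 0L)
    stop("track parse error: log ends after a '==========' separator",
         call. = FALSE)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_events())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a tracking log file
#'
#' Canonical file extension `.cttrack`; the same byte stream may be sent to
#' any connection.
#'
#' @param events event data.frame.
#' @param path file path (or connection).
#' @return `write_track` returns `path` invisibly; `read_track` the parsed
#'   event data.frame.
#' @export
write_track <- function(events, path) {
  txt <- serialize_track(events)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  parse_track(readLines(path, warn = FALSE))
}

#' Level-description events of a phantom
#'
#' The level record plus one shape record per shape, in draw order -- the
#' sidecar that makes a phantom reconstructible from its log.
#'
#' @param phantom a `ct_phantom`.
#' @return event data.frame.
#' @export
phantom_events <- function(phantom) {
  stopifnot(inherits(phantom, "ct_phantom"))
  lv <- ev_level(ifelse(is.na(phantom$level), 0L, phantom$level),
                 phantom$dims[2], phantom$dims[1])
  sh <- lapply(seq_len(nrow(phantom$shapes)), function(i) {
    s <- phantom$shapes[i, ]
    if (s$kind == "circle") ev_circle(s$x, s$y, s$size, s$halftone)
    else ev_triangle(s$x, s$y, s$size, s$halftone)
  })
  out <- do.call(rbind, c(list(lv), sh))
  rownames(out) <- NULL
  out
}
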