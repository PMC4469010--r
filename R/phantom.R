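# Procedural hidden-image ("level") generator. Tones: background 0, full-tone
# 1, half-tone (tumor gray) 0.5; inverted levels swap background and
# full-tone. All randomness uses R's global RNG stream, so callers seed with
# set.seed() (the session layer derives per-level seeds for stable replays).

#' Canvas dimensions for a level
#'
#' The base canvas is 256 x 256; each dimension is independently increased by
#' 128 pixels times a uniform draw from `{0, ..., floor(level / 5)}`, so the
#' range of possible sizes grows every 5 levels (height drawn first, then
#' width).
#'
#' @param level difficulty level, >= 1.
#' @return integer (height, width).
#' @export
canvas_dims <- function(level) {
  stopifnot(level >= 1)
  kmax <- floor(level / 5)
  h <- 256L + 128L * (sample.int(kmax + 1L, 1L) - 1L)
  w <- 256L + 128L * (sample.int(kmax + 1L, 1L) - 1L)
  c(h, w)
}

#' Number of shapes for a canvas
#'
#' `floor(mindim / 64) + random(floor(mindim / 11) - floor(mindim / 64))`
#' with `random(k)` uniform on the integers `[0, k)` (Java-style semantics),
#' where `mindim` is the smaller canvas dimension.
#'
#' @param mindim minimum canvas dimension in pixels, >= 64.
#' @return integer shape count.
#' @export
num_shapes <- function(mindim) {
  if (mindim < 64) stop("mindim must be >= 64", call. = FALSE)
  base <- mindim %/% 64
  spread <- mindim %/% 11 - base
  if (spread <= 0) return(as.integer(base))
  as.integer(base + sample.int(spread, 1L) - 1L)
}

#' Is a level grayscale-inverted?
#'
#' Below level 8 the background is always black. From level 8 on, every level
#' whose last digit is 8 is inverted (white background, black full-tone
#' objects); any other level past 8 is inverted with probability 1/6.
#'
#' @param level difficulty level, >= 1.
#' @return logical flag.
#' @export
is_inverted <- function(level) {
  stopifnot(level >= 1)
  if (level < 8) return(FALSE)
  if (level %% 10 == 8) return(TRUE)
  if (level > 8) return(stats::runif(1) < 1 / 6)
  FALSE
}

# paint one shape onto the owner map; returns updated owner matrix.
# x is the column and y the row of the shape origin (circle centre /
# triangle right-angle corner); triangles are right isosceles with
# axis-aligned legs extending toward +x and +y.
paint_shape <- function(owner, shape, idx_row, idx_col) {
  if (shape$kind == "circle") {
    m <- (idx_col - shape$x)^2 + (idx_row - shape$y)^2 <= shape$size^2
  } else {
    dx <- idx_col - shape$x
    dy <- idx_row - shape$y
    m <- dx >= 0 & dy >= 0 & (dx + dy) <= shape$size
  }
  owner[m] <- shape$id
  owner
}

#' Generate a phantom (hidden image) on an explicit canvas
#'
#' Draws `n_shapes` shapes, each uniformly a circle or triangle, uniformly
#' half-tone (tumor gray) or full-tone, positioned uniformly on the canvas,
#' with size uniform on `[mindim / 32, mindim / 8]` (circle radius /
#' triangle leg; shapes may be clipped by the canvas). Shapes are painted in
#' draw order (later shapes occlude earlier ones). The shape set is redrawn
#' until at least one gray circle exists and no gray circle is fully
#' occluded, so the level's answer -- the number of gray circles -- is
#' always well defined and visible in principle.
#'
#' @param height,width canvas dimensions in pixels (min >= 64).
#' @param n_shapes shape count; default drawn via [num_shapes()].
#' @param inverted white-background level?
#' @param level level number to record on the phantom (metadata only).
#' @param max_attempts redraw cap for the gray-circle guard.
#' @return a `ct_phantom`: list with `level`, `dims`, `shapes` (data.frame
#'   `kind`, `x`, `y`, `size`, `halftone`), `inverted`, `image` (matrix with
#'   values in {0, 0.5, 1}), and `answer` (number of gray circles).
#' @export
generate_phantom <- function(height, width, n_shapes = NULL,
                             inverted = FALSE, level = NA_integer_,
                             max_attempts = 100L) {
  dims <- check_dims(c(height, width))
  mindim <- min(dims)
  if (mindim < 64) stop("canvas must be at least 64 pixels on a side",
                        call. = FALSE)
  if (is.null(n_shapes)) n_shapes <- num_shapes(mindim)
  stopifnot(n_shapes >= 1)
  smin <- max(1L, mindim %/% 32L)
  smax <- max(smin, mindim %/% 8L)
  idx_row <- matrix(seq_len(dims[1]) - 1L, dims[1], dims[2])
  idx_col <- matrix(seq_len(dims[2]) - 1L, dims[1], dims[2], byrow = TRUE)

  for (attempt in seq_len(max_attempts)) {
    shapes <- data.frame(
      kind = sample(c("circle", "triangle"), n_shapes, replace = TRUE),
      x = sample.int(dims[2], n_shapes, replace = TRUE) - 1L,
      y = sample.int(dims[1], n_shapes, replace = TRUE) - 1L,
      size = sample(seq.int(smin, smax), n_shapes, replace = TRUE),
      halftone = sample(c(TRUE, FALSE), n_shapes, replace = TRUE),
      stringsAsFactors = FALSE
    )
    gray_circ <- which(shapes$kind == "circle" & shapes$halftone)
    if (length(gray_circ) == 0L) next

    owner <- matrix(0L, dims[1], dims[2])
    for (i in seq_len(n_shapes)) {
      owner <- paint_shape(owner, list(kind = shapes$kind[i],
                                       x = shapes$x[i], y = shapes$y[i],
                                       size = shapes$size[i], id = i),
                           idx_row, idx_col)
    }
    visible <- unique(owner[owner > 0L])
    if (!all(gray_circ %in% visible)) next

    tones <- if (inverted) c(bg = 1, full = 0, half = 0.5)
             else c(bg = 0, full = 1, half = 0.5)
    image <- matrix(tones[["bg"]], dims[1], dims[2])
    painted <- owner > 0L
    image[painted] <- ifelse(shapes$halftone[owner[painted]],
                             tones[["half"]], tones[["full"]])
    return(structure(
      list(level = level, dims = dims, shapes = shapes, inverted = inverted,
           image = image, answer = length(gray_circ)),
      class = "ct_phantom"))
  }
  stop("failed to place a visible gray circle in ", max_attempts,
       " attempts", call. = FALSE)
}

#' Generate the phantom for a difficulty level
#'
#' Applies the level rules in order: canvas dimensions ([canvas_dims()]),
#' inversion ([is_inverted()]), shape count ([num_shapes()]), then the shape
#' draw of [generate_phantom()]. Reproducible: a fixed `set.seed()` before
#' the call yields an identical phantom.
#'
#' @param level difficulty level, >= 1.
#' @return a `ct_phantom`.
#' @export
generate_level <- function(level) {
  stopifnot(level >= 1)
  dims <- canvas_dims(level)
  inv <- is_inverted(level)
  n <- num_shapes(min(dims))
  generate_phantom(dims[1], dims[2], n_shapes = n, inverted = inv,
                   level = as.integer(level))
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf(
    "<ct_phantom> level %s, %dx%d, %d shapes (%d gray circles)%s\n",
    ifelse(is.na(x$level), "?", x$level), x$dims[1], x$dims[2],
    nrow(x$shapes), x$answer, if (x$inverted) ", inverted" else ""))
  invisible(x)
}

#' @export
plot.ct_phantom <- function(x, ...) {
  plot_image(x$image, main = sprintf("phantom (level %s, %d gray circles)",
                                     ifelse(is.na(x$level), "?", x$level),
                                     x$answer), ...)
}

#' Display an image matrix with screen orientation
#'
#' Row 0 at the top, grayscale 0..1.
#'
#' @param image numeric matrix.
#' @param ... passed to [graphics::image()].
#' @export
plot_image <- function(image, ...) {
  graphics::image(t(image)[, nrow(image):1, drop = FALSE],
                  col = grDevices::gray.colors(256, 0, 1),
                  zlim = range(0, 1, image), asp = nrow(image) / ncol(image),
                  axes = FALSE, ...)
}
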