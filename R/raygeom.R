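#' @useDynLib ctbrush, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- coordinate conventions -------------------------------------------------
# Pixels are 0-based (row, col), rows indexing downward. Angles are degrees in
# [0, 180), measured clockwise from horizontal (so 0 deg runs along a row and
# 90 deg down a column). A ray and its 180-degree opposite are the same line.

check_dims <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be two positive integers (height, width)", call. = FALSE)
  dims
}

in_grid <- function(p, dims) {
  p[1] >= 0 && p[1] <= dims[1] - 1 && p[2] >= 0 && p[2] <= dims[2] - 1
}

#' Canonical ray identity from a line through an anchor
#'
#' Two rays are the same ray exactly when they are the same geometric line:
#' the key combines the view angle (mod 180, quantised at 1e-7 degree) with
#' the line's signed perpendicular offset from the origin (quantised at 1e-9
#' pixel). The key is therefore invariant under traversal reversal and under
#' moving the anchor along the line, and distinct lines keep distinct keys
#' even when staircase rasterization truncates them to the same pixel set --
#' which is how unique-ray dose is counted.
#'
#' @param anchor numeric (row, col), 0-based; any point the line passes
#'   through (need not be on the grid).
#' @param angle degrees; reduced mod 180.
#' @return a character scalar key.
#' @export
line_key <- function(anchor, angle) {
  a <- angle %% 180
  rad <- a * pi / 180
  off <- anchor[1] * cos(rad) - anchor[2] * sin(rad)
  k1 <- sprintf("%.0f", a * 1e7)
  k2 <- sprintf("%.0f", off * 1e9)
  k1[k1 == "-0"] <- "0"
  k2[k2 == "-0"] <- "0"
  paste0(k1, "|", k2)
}

new_ray <- function(anchor, angle, pixels) {
  structure(
    list(angle = angle %% 180, anchor = as.numeric(anchor), pixels = pixels,
         key = line_key(anchor, angle)),
    class = "ct_ray"
  )
}

#' Rasterize one edge-to-edge staircase ray
#'
#' Traces the full line through `anchor` at `angle` across the grid as a
#' midpoint (Bresenham-style) staircase: one pixel per step along the
#' dominant axis, minor coordinate rounded half-up to the nearest pixel
#' centre. The result is a binary (unweighted, non-anti-aliased) ray: an
#' 8-connected pixel chain whose first and last pixels touch a grid edge.
#'
#' @param anchor integer (row, col), 0-based, inside the grid.
#' @param angle degrees in \[0, 180).
#' @param dims integer (height, width).
#' @return a `ct_ray`: list with `angle`, `anchor`, `pixels` (an n x 2
#'   0-based (row, col) matrix ordered along the dominant axis) and `key`
#'   (see [line_key()]).
#' @examples
#' r <- rasterize_ray(c(1, 2), 0, c(4, 4))
#' r$pixels  # row 1, all four columns
#' @export
rasterize_ray <- function(anchor, angle, dims) {
  dims <- check_dims(dims)
  if (!in_grid(anchor, dims))
    stop("anchor (", anchor[1], ",", anchor[2], ") lies outside the ",
         dims[1], "x", dims[2], " grid", call. = FALSE)
  if (angle < 0 || angle >= 180)
    stop("angle must be in [0, 180)", call. = FALSE)
  px <- cpp_rasterize(anchor[1], anchor[2], angle, dims[1], dims[2])
  new_ray(anchor, angle, px)
}

# internal: rasterize without the on-grid anchor requirement (used for
# width-offset rays whose rounded anchor may fall outside the canvas);
# returns NULL when the line misses the grid entirely.
rasterize_any <- function(anchor, angle, dims) {
  px <- cpp_rasterize(anchor[1], anchor[2], angle %% 180, dims[1], dims[2])
  if (nrow(px) == 0L) return(NULL)
  new_ray(anchor, angle, px)
}

#' Canonical key of a ray
#'
#' @param ray a `ct_ray`.
#' @return character scalar; equal for two rays exactly when they are the
#'   same geometric line (see [line_key()]).
#' @export
canonical_key <- function(ray) {
  stopifnot(inherits(ray, "ct_ray"))
  ray$key
}

#' @export
print.ct_ray <- function(x, ...) {
  cat(sprintf("<ct_ray> angle %.4f deg through (%g,%g): %d pixels [%s..%s]\n",
              x$angle, x$anchor[1], x$anchor[2], nrow(x$pixels),
              paste(x$pixels[1, ], collapse = ","),
              paste(x$pixels[nrow(x$pixels), ], collapse = ",")))
  invisible(x)
}

#' Build the star of rays of a CT brush placement
#'
#' A star is `n_rays` views equally spaced over \[0, 180) degrees
#' (`rotation + k * 180 / n_rays`), all passing through the central point.
#' For `width > 1`, each view contributes `width` parallel rays at integer
#' perpendicular offsets centred on the view (offsets `-(w-1)/2 .. (w-1)/2`
#' for odd `w`, `-w/2+1 .. w/2` for even `w`), with offset anchors rounded to
#' pixel positions. Rays whose offset pushes them entirely off the grid are
#' dropped. No deduplication is performed here; that is the registry's job.
#'
#' @param center integer (row, col), 0-based, inside the grid.
#' @param dims integer (height, width).
#' @param n_rays number of views, 1..180.
#' @param width rays per view, >= 1.
#' @param rotation degrees added to every view angle (0 in recorded play).
#' @return list of `ct_ray`.
#' @export
make_star <- function(center, dims, n_rays = 8L, width = 1L, rotation = 0) {
  dims <- check_dims(dims)
  if (!in_grid(center, dims))
    stop("star center (", center[1], ",", center[2], ") lies outside the ",
         dims[1], "x", dims[2], " grid", call. = FALSE)
  n_rays <- as.integer(n_rays)
  width <- as.integer(width)
  stopifnot(n_rays >= 1L, n_rays <= 180L, width >= 1L)
  offsets <- if (width %% 2L == 1L) {
    seq.int(-(width - 1L) / 2L, (width - 1L) / 2L)
  } else {
    seq.int(-width / 2L + 1L, width / 2L)
  }
  rays <- vector("list", n_rays * width)
  m <- 0L
  for (k in seq_len(n_rays) - 1L) {
    ang <- (rotation + k * 180 / n_rays) %% 180
    rad <- ang * pi / 180
    dr <- sin(rad); dc <- cos(rad)
    for (o in offsets) {
      # perpendicular unit vector to the view direction is (cos, -sin)
      anc <- c(round(center[1] + o * dc), round(center[2] - o * dr))
      ray <- rasterize_any(anc, ang, dims)
      if (!is.null(ray)) {
        m <- m + 1L
        rays[[m]] <- ray
      }
    }
  }
  rays[seq_len(m)]
}

#' Count geometrically unique rays over a set of star placements
#'
#' Places one view at each given angle through each given center and counts
#' distinct rays under the line-identity key of [line_key()]. Views with
#' irrational tangents contribute one ray per center; views whose tangent is
#' rational (0 degrees in particular, where all centers in a row share one
#' ray) collapse. With stars at every pixel of an N x N grid and only the
#' 0-degree tangent rational, the count equals [unique_total_T()].
#'
#' @param dims integer (height, width).
#' @param angles degrees, each in \[0, 180).
#' @param centers n x 2 matrix of 0-based (row, col) centers.
#' @return integer count of distinct rays.
#' @export
count_unique_rays <- function(dims, angles, centers) {
  dims <- check_dims(dims)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (any(centers[, 1] < 0) || any(centers[, 1] > dims[1] - 1) ||
      any(centers[, 2] < 0) || any(centers[, 2] > dims[2] - 1))
    stop("all centers must lie inside the grid", call. = FALSE)
  keys <- character(0)
  for (a in angles) {
    am <- a %% 180
    rad <- am * pi / 180
    off <- centers[, 1] * cos(rad) - centers[, 2] * sin(rad)
    k2 <- sprintf("%.0f", off * 1e9)
    k2[k2 == "-0"] <- "0"
    k1 <- sprintf("%.0f", am * 1e7)
    if (k1 == "-0") k1 <- "0"
    keys <- c(keys, paste0(k1, "|", k2))
  }
  length(unique(keys))
}

#' Closed-form total of unique rays for all-pixel star coverage
#'
#' Total number of unique rays T when a star of `n_views` views is placed at
#' every pixel of an N x N grid: `T = R * N^2` when every view angle has an
#' irrational tangent, minus the `N * (N - 1)` overlap of the 0-degree view
#' (whose tangent is rational, so its N^2 placements yield only N distinct
#' rows) when that view is present.
#'
#' @param n_views number of views R per star.
#' @param N grid side in pixels.
#' @param has_zero_ray does the star include the 0-degree view?
#' @return exact count (double holding an integer).
#' @examples
#' unique_total_T(5, 256)          # 262400
#' unique_total_T(5, 4, FALSE)     # 80
#' @export
unique_total_T <- function(n_views, N, has_zero_ray = TRUE) {
  stopifnot(n_views >= 1, N >= 1)
  n_views * N^2 - if (has_zero_ray) N * (N - 1) else 0
}

#' Equally spaced parallel-ray count across a square at one angle
#'
#' Number of width-1 equally spaced parallel rays intersecting an N x N
#' square at angle theta: `N * (1 + |tan theta|) * |cos theta|`, evaluated in
#' the numerically stable form `N * (|cos theta| + |sin theta|)` (finite at
#' 90 degrees). Symmetric under reflection about 45 degrees and under
#' 90-degree rotation; bounded by N and N * sqrt(2).
#'
#' @param angle degrees (vectorised).
#' @param N square side in pixels.
#' @return real-valued ray count(s).
#' @export
n_theta <- function(angle, N) {
  rad <- angle * pi / 180
  N * (abs(cos(rad)) + abs(sin(rad)))
}

#' Emitted dose of a set of equally spaced views
#'
#' Sums the per-view parallel-ray count [n_theta()] over the given view
#' angles, applying a per-view rounding rule first. The default (per-view
#' ceiling) reproduces the 5-view (1,618) and 9-view (2,930) emitted-dose
#' figures for N = 256; no single simple rounding reproduces every tabulated
#' value, so the rule is a parameter.
#'
#' @param angles view angles in degrees.
#' @param N square side in pixels.
#' @param rounding per-view rule: "ceiling" (default), "round", "floor", or
#'   "none" (exact real sum).
#' @return total emitted dose.
#' @examples
#' emitted_dose_E(seq(0, 144, by = 36), 256)  # 1618
#' @export
emitted_dose_E <- function(angles, N,
                           rounding = c("ceiling", "round", "floor", "none")) {
  stopifnot(length(angles) >= 1)
  rounding <- match.arg(rounding)
  v <- n_theta(angles, N)
  v <- switch(rounding,
              ceiling = ceiling(v),
              round = round(v),
              floor = floor(v),
              none = v)
  sum(v)
}
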