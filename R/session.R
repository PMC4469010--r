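# Headless gameplay: mutable session state, stroke application with mouse
# interpolation, dose accounting, level progression, and replay.

clamp <- function(x, lo, hi) max(lo, min(hi, x))

# deterministic per-(seed, level, visit) sub-seed, kept below 2^31
derive_seed <- function(seed, level, visit = 1L) {
  ((seed %% 2147483647) +
     ((level * 2654435761 + visit * 40503) %% 2147483647)) %% 2147483647
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647)
  expr
}

#' Linearly interpolated pixel path between two points
#'
#' Every integer point of the segment from `p0` to `p1`, stepping once per
#' increment of the dominant axis with the minor coordinate rounded half-up
#' (the same midpoint rule as the ray rasterizer). Endpoints included, no
#' repeats; consecutive points are 8-connected. This reconstructs the
#' continuous brush trajectory from sparsely sampled mouse positions.
#'
#' @param p0,p1 integer (row, col) points.
#' @return n x 2 integer matrix of (row, col) points, from `p0` to `p1`.
#' @export
interpolate <- function(p0, p1) {
  p0 <- as.integer(p0); p1 <- as.integer(p1)
  d <- p1 - p0
  if (all(d == 0L)) return(matrix(p0, 1, 2))
  if (abs(d[2]) >= abs(d[1])) {
    cols <- seq.int(p0[2], p1[2])
    rows <- floor(p0[1] + (cols - p0[2]) * (d[1] / d[2]) + 0.5)
  } else {
    rows <- seq.int(p0[1], p1[1])
    cols <- floor(p0[2] + (rows - p0[1]) * (d[2] / d[1]) + 0.5)
  }
  cbind(as.integer(rows), as.integer(cols))
}

start_level <- function(ses, level) {
  ses$level <- as.integer(level)
  key <- as.character(level)
  ses$visits[[key]] <- (if (is.null(ses$visits[[key]])) 0L
                        else ses$visits[[key]]) + 1L
  phantom <- with_seed(derive_seed(ses$seed, level, ses$visits[[key]]),
                       generate_level(level))
  ses$phantom <- phantom
  ses$recon <- new_recon(phantom$dims)
  ses$stroke_counts <- integer()
  ses$events <- rbind(ses$events, phantom_events(phantom))
  invisible(ses)
}

#' Start a headless CT brush session
#'
#' A session holds the current level's hidden phantom (never exposed to
#' play-facing queries except through raysums of emitted rays), the
#' reconstruction state, the brush configuration and the event log. It is an
#' environment-backed mutable object: the play operations modify it in place
#' and return it (or a flag) for chaining.
#'
#' @param seed master seed; with the event log it fully determines replayed
#'   outcomes. Per-level phantoms use sub-seeds derived from
#'   (seed, level, visit).
#' @param level starting difficulty level.
#' @param n_rays star views, clamped to 1..180.
#' @param width rays per view, clamped to 1..9.
#' @return a `ct_session`.
#' @export
new_session <- function(seed, level = 1L, n_rays = 8L, width = 1L) {
  ses <- new.env(parent = emptyenv())
  ses$seed <- as.integer(seed)
  ses$brush <- list(center = NULL,
                    n_rays = as.integer(clamp(n_rays, 1L, 180L)),
                    width = as.integer(clamp(width, 1L, 9L)),
                    rotation = 0L)
  ses$events <- empty_events()
  ses$visits <- list()
  class(ses) <- "ct_session"
  start_level(ses, level)
  ses
}

#' @export
print.ct_session <- function(x, ...) {
  cat(sprintf(
    "<ct_session> level %d (%dx%d), dose %d unique rays, brush %d rays x width %d\n",
    x$level, x$phantom$dims[1], x$phantom$dims[2], x$recon$n,
    x$brush$n_rays, x$brush$width))
  invisible(x)
}

#' Play-facing session queries
#'
#' `session_estimate` returns the current canvas (reconstruction estimate),
#' `session_dose` the emitted dose (unique rays measured so far),
#' `session_brush` the brush configuration, `session_dims` the canvas
#' dimensions. None of them reveal hidden-image pixels.
#'
#' @param session a `ct_session`.
#' @name session_queries
NULL

#' @rdname session_queries
#' @export
session_estimate <- function(session) session$recon$estimate

#' @rdname session_queries
#' @export
session_dose <- function(session) session$recon$n

#' @rdname session_queries
#' @export
session_brush <- function(session) session$brush

#' @rdname session_queries
#' @export
session_dims <- function(session) session$phantom$dims

#' Apply a brush stroke
#'
#' Interpolates the sampled mouse positions into a connected pixel path
#' ([interpolate()]), places the brush star at every path point, and
#' processes each not-yet-registered ray (measure once, one MART update).
#' Dose grows only by geometrically new rays; re-stroking covered ground
#' adds nothing. Every irradiated central point is appended to the event log
#' as a move record.
#'
#' @param session a `ct_session` (mutated in place).
#' @param samples n x 2 matrix (or single (row, col) vector) of 0-based
#'   sampled brush positions, all inside the canvas.
#' @return number of newly added unique rays, invisibly.
#' @export
stroke <- function(session, samples) {
  samples <- matrix(as.integer(samples), ncol = 2)
  if (nrow(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  dims <- session$phantom$dims
  for (i in seq_len(nrow(samples)))
    if (!in_grid(samples[i, ], dims))
      stop("sample (", samples[i, 1], ",", samples[i, 2],
           ") outside the canvas", call. = FALSE)
  path <- samples[1, , drop = FALSE]
  if (nrow(samples) > 1L) {
    for (i in seq_len(nrow(samples) - 1L)) {
      seg <- interpolate(samples[i, ], samples[i + 1L, ])
      path <- rbind(path, seg[-1L, , drop = FALSE])
    }
  }
  added <- 0L
  b <- session$brush
  hidden <- session$phantom$image
  moves <- vector("list", nrow(path))
  for (i in seq_len(nrow(path))) {
    p <- path[i, ]
    star <- make_star(p, dims, n_rays = b$n_rays, width = b$width,
                      rotation = b$rotation)
    for (ray in star)
      if (process_new_ray(session$recon, ray, hidden)) added <- added + 1L
    moves[[i]] <- ev_move(p[2], p[1], b$width, b$n_rays, b$rotation)
  }
  session$brush$center <- path[nrow(path), ]
  session$events <- rbind(session$events, do.call(rbind, moves))
  session$stroke_counts <- c(session$stroke_counts, added)
  invisible(added)
}

#' Adjust the brush
#'
#' Change the number of rays (clamped to 1..180) or the ray width (clamped
#' to 1..9). No dose is added and no event recorded: the next move record
#' carries the new values.
#'
#' @param session a `ct_session` (mutated in place).
#' @param delta signed change.
#' @return the session, invisibly.
#' @export
adjust_rays <- function(session, delta) {
  session$brush$n_rays <-
    as.integer(clamp(session$brush$n_rays + delta, 1L, 180L))
  invisible(session)
}

#' @rdname adjust_rays
#' @export
adjust_width <- function(session, delta) {
  session$brush$width <- as.integer(clamp(session$brush$width + delta, 1L, 9L))
  invisible(session)
}

#' Run one refinement pass in a session
#'
#' One dose-free pass of MART updates over all measured rays; appends an
#' `r()` record.
#'
#' @param session a `ct_session` (mutated in place).
#' @return the session, invisibly.
#' @export
refine_action <- function(session) {
  refine(session$recon)
  session$events <- rbind(session$events, ev_refine())
  invisible(session)
}

#' Guess the number of gray circles and move on
#'
#' Compares the guess with the level's answer. A correct guess advances to
#' the next level; a wrong one demotes by one level (never below 1). Either
#' way a `g()` record is appended and a fresh level begins (new phantom, new
#' all-ones estimate, zero dose; brush settings persist).
#'
#' @param session a `ct_session` (mutated in place).
#' @param count guessed number of gray circles, >= 0.
#' @return list with `outcome` ("advance"/"demote"), `correct`, and
#'   `next_level`.
#' @export
guess <- function(session, count) {
  stopifnot(count >= 0)
  correct <- as.integer(count) == session$phantom$answer
  outcome <- if (correct) "advance" else "demote"
  next_level <- if (correct) session$level + 1L
                else max(1L, session$level - 1L)
  session$events <- rbind(session$events, ev_guess(count))
  start_level(session, next_level)
  list(outcome = outcome, correct = correct, next_level = next_level)
}

#' Dose report for the current level
#'
#' Emitted dose (unique rays), per-stroke new-ray counts, and -- for square
#' canvases -- the all-pixel reference totals for the current brush: T from
#' [unique_total_T()] (the star includes the 0-degree view, so the rational-
#' tangent correction applies), E from [emitted_dose_E()], and the percent
#' of each that the session's dose represents.
#'
#' @param session a `ct_session`.
#' @return a `ct_dose_report` list.
#' @export
dose_report <- function(session) {
  dims <- session$phantom$dims
  R <- session$brush$n_rays
  square <- dims[1] == dims[2]
  T_ref <- if (square) unique_total_T(R, dims[1], has_zero_ray = TRUE)
           else NA_real_
  E_ref <- if (square)
    emitted_dose_E((seq_len(R) - 1) * 180 / R, dims[1]) else NA_real_
  dose <- session$recon$n
  structure(list(
    unique_rays = dose,
    per_stroke = session$stroke_counts,
    n_rays = R,
    width = session$brush$width,
    dims = dims,
    T_ref = T_ref,
    E_ref = E_ref,
    pct_T = if (square) 100 * dose / T_ref else NA_real_,
    pct_E = if (square) 100 * dose / E_ref else NA_real_
  ), class = "ct_dose_report")
}

#' @export
print.ct_dose_report <- function(x, ...) {
  cat(sprintf("<ct_dose_report> %d unique rays over %d strokes (brush %d x %d)\n",
              x$unique_rays, length(x$per_stroke), x$n_rays, x$width))
  if (!is.na(x$T_ref))
    cat(sprintf("  all-pixel references at R=%d, N=%d: T=%s (%.3g%%), E=%s (%.3g%%)\n",
                x$n_rays, x$dims[1], format(x$T_ref, big.mark = ","),
                x$pct_T, format(x$E_ref, big.mark = ","), x$pct_E))
  invisible(x)
}

#' Replay a tracking log
#'
#' Re-executes a recorded log against phantoms regenerated from the master
#' seed: each level record starts the corresponding level (the logged shape
#' list is cross-checked against the regenerated phantom and a mismatch is
#' an error, since the grammar does not carry the tone-inversion flag); each
#' move record is one irradiated central point and is re-stamped as such --
#' the recorder already logs the full interpolated trajectory, so no
#' re-interpolation happens (interpolating would bridge separate strokes,
#' which the grammar cannot delimit); refine and guess records are
#' re-applied. With the recording seed, replay reproduces the original dose
#' and estimate exactly.
#'
#' @param events event data.frame or a path to a `.cttrack` file.
#' @param seed the master seed the log was recorded under.
#' @return the replayed `ct_session`; its `$summary` field is a data.frame
#'   with one row per completed level.
#' @export
replay_track <- function(events, seed) {
  if (is.character(events)) events <- read_track(events)
  if (nrow(events) == 0L) stop("empty track log", call. = FALSE)
  if (events$type[1] != "level")
    stop("track log must start with a level record", call. = FALSE)
  ses <- NULL
  summary <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    switch(e$type,
      level = {
        if (is.null(ses)) {
          ses <- new_session(seed, level = e$level)
        } else if (ses$level != e$level) {
          stop("replay drifted: log expects level ", e$level,
               " but session is at level ", ses$level, call. = FALSE)
        }
        if (!identical(unname(ses$phantom$dims),
                       c(e$height, e$width)))
          stop("replay mismatch: regenerated canvas is ",
               ses$phantom$dims[1], "x", ses$phantom$dims[2],
               " but log says ", e$height, "x", e$width,
               " (wrong seed?)", call. = FALSE)
      },
      triangle = ,
      circle = NULL,  # descriptive only; validated against the level block
      move = {
        ses$brush$n_rays <- as.integer(clamp(e$n_rays, 1L, 180L))
        ses$brush$width <- as.integer(clamp(e$width, 1L, 9L))
        stroke(ses, matrix(c(e$y, e$x), 1, 2))
      },
      refine = refine_action(ses),
      guess = {
        lvl <- ses$level
        dose <- ses$recon$n
        res <- guess(ses, e$guess)
        summary[[length(summary) + 1L]] <-
          data.frame(level = lvl, guess = e$guess, correct = res$correct,
                     outcome = res$outcome, dose = dose)
      }
    )
    if (e$type == "level") {
      # cross-check the logged shape list for this level
      sh <- shapes_of_block(events, i)
      ref <- ses$phantom$shapes
      ok <- nrow(sh) == nrow(ref) &&
        all(sh$kind == ref$kind) && all(sh$x == ref$x) &&
        all(sh$y == ref$y) && all(sh$size == ref$size) &&
        all(sh$halftone == ref$halftone)
      if (!ok)
        stop("replay mismatch: logged shapes for level ", e$level,
             " differ from the regenerated phantom (wrong seed?)",
             call. = FALSE)
    }
  }
  ses$summary <- if (length(summary)) do.call(rbind, summary)
                 else data.frame()
  ses
}

# shape rows belonging to the level block starting at row i
shapes_of_block <- function(events, i) {
  j <- i + 1L
  n <- nrow(events)
  rows <- integer()
  while (j <= n && events$type[j] %in% c("triangle", "circle")) {
    rows <- c(rows, j)
    j <- j + 1L
  }
  sh <- events[rows, , drop = FALSE]
  data.frame(kind = ifelse(sh$type == "circle", "circle", "triangle"),
             x = sh$x, y = sh$y, size = sh$size, halftone = sh$halftone,
             stringsAsFactors = FALSE)
}
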