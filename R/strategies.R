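# Scripted players. A strategy is a function(ctx) -> action, where ctx is a
# list with the play-facing view of the session (estimate, dose, brush,
# dims, level, step -- never hidden pixels) and an action is one of
#   list(type = "stroke", samples = <n x 2 matrix>)
#   list(type = "rays",   delta = <int>)
#   list(type = "width",  delta = <int>)
#   list(type = "refine")
#   list(type = "guess",  count = <int>)
# A strategy may keep private state in its closure; randomness draws from
# R's global RNG so runs are reproducible under the driver's seed.

#' Count gray blobs in an estimate
#'
#' Crude tumor counter used by the built-in strategies: thresholds pixels
#' near the half-tone value (|value - 0.5| < `band`), labels 4-connected
#' components, and counts those of at least `min_px` pixels. A playing aid,
#' not a detector with guarantees.
#'
#' @param estimate numeric matrix.
#' @param band half-width of the gray band around 0.5.
#' @param min_px minimum component size in pixels.
#' @return integer blob count.
#' @export
count_gray_blobs <- function(estimate, band = 0.15, min_px = 20L) {
  m <- abs(estimate - 0.5) < band
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  nlab <- 0L
  sizes <- integer()
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    queue <- start
    lab[start] <- nlab
    sz <- 0L
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      r <- (p - 1L) %% H + 1L
      c <- (p - 1L) %/% H + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < H) p + 1L,
                  if (c > 1L) p - H, if (c < W) p + H)) {
        if (m[q] && lab[q] == 0L) {
          lab[q] <- nlab
          queue <- c(queue, q)
        }
      }
    }
    sizes[nlab] <- sz
  }
  sum(sizes >= min_px)
}

#' Built-in scripted strategies
#'
#' `strategy_grid_sweep` drags the brush along every `step`-th row
#' (serpentine), refines, and guesses the gray-blob count -- with `step = 1`
#' it irradiates a star at every pixel, the maximum-dose play.
#' `strategy_random_walk` plays `n_strokes` random short strokes, refines,
#' and guesses; it uses a fraction of the sweep's dose.
#'
#' @param step row stride of the sweep.
#' @param n_strokes number of random strokes.
#' @return a strategy function.
#' @export
strategy_grid_sweep <- function(step = 1L) {
  rows_done <- NULL
  function(ctx) {
    H <- ctx$dims[1]; W <- ctx$dims[2]
    if (is.null(rows_done)) rows_done <<- 0L
    todo <- seq.int(0L, H - 1L, by = step)
    if (rows_done < length(todo)) {
      r <- todo[rows_done + 1L]
      rows_done <<- rows_done + 1L
      samples <- if (rows_done %% 2L == 1L) rbind(c(r, 0L), c(r, W - 1L))
                 else rbind(c(r, W - 1L), c(r, 0L))
      return(list(type = "stroke", samples = samples))
    }
    if (rows_done == length(todo)) {
      rows_done <<- rows_done + 1L
      return(list(type = "refine"))
    }
    rows_done <<- NULL
    list(type = "guess", count = count_gray_blobs(ctx$estimate))
  }
}

#' @rdname strategy_grid_sweep
#' @export
strategy_random_walk <- function(n_strokes = 20L) {
  done <- NULL
  function(ctx) {
    H <- ctx$dims[1]; W <- ctx$dims[2]
    if (is.null(done)) done <<- 0L
    if (done < n_strokes) {
      done <<- done + 1L
      p0 <- c(sample.int(H, 1L) - 1L, sample.int(W, 1L) - 1L)
      p1 <- c(sample.int(H, 1L) - 1L, sample.int(W, 1L) - 1L)
      return(list(type = "stroke", samples = rbind(p0, p1)))
    }
    if (done == n_strokes) {
      done <<- done + 1L
      return(list(type = "refine"))
    }
    done <<- NULL
    list(type = "guess", count = count_gray_blobs(ctx$estimate))
  }
}

strategy_registry <- function(name, ...) {
  switch(name,
         "grid-sweep" = strategy_grid_sweep(...),
         "random-walk" = strategy_random_walk(...),
         stop("unknown strategy '", name,
              "' (available: grid-sweep, random-walk)", call. = FALSE))
}

#' Run a strategy through the session layer
#'
#' Drives `strategy` against `session` until it guesses (one level), then
#' repeats for `levels` levels in total. The session's event log accumulates
#' a complete replayable record.
#'
#' @param session a `ct_session`.
#' @param strategy a strategy function (see [strategy_grid_sweep()]).
#' @param levels number of levels to play.
#' @param max_actions safety cap on actions per level.
#' @return data.frame with one row per played level: `level`, `height`,
#'   `width`, `dose`, `answer_guessed`, `correct`, `outcome`.
#' @export
play_strategy <- function(session, strategy, levels = 1L,
                          max_actions = 10000L) {
  out <- list()
  for (lv in seq_len(levels)) {
    acted <- 0L
    repeat {
      acted <- acted + 1L
      if (acted > max_actions)
        stop("strategy exceeded ", max_actions, " actions without guessing",
             call. = FALSE)
      ctx <- list(estimate = session_estimate(session),
                  dose = session_dose(session),
                  brush = session_brush(session),
                  dims = session_dims(session),
                  level = session$level, step = acted)
      act <- strategy(ctx)
      done <- FALSE
      switch(act$type,
             stroke = stroke(session, act$samples),
             rays = adjust_rays(session, act$delta),
             width = adjust_width(session, act$delta),
             refine = refine_action(session),
             guess = {
               lvl <- session$level
               dims <- session_dims(session)
               dose <- session_dose(session)
               res <- guess(session, act$count)
               out[[length(out) + 1L]] <-
                 data.frame(level = lvl, height = dims[1], width = dims[2],
                            dose = dose, answer_guessed = act$count,
                            correct = res$correct, outcome = res$outcome)
               done <- TRUE
             },
             stop("strategy returned unknown action type '", act$type, "'",
                  call. = FALSE))
      if (done) break
    }
  }
  do.call(rbind, out)
}
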