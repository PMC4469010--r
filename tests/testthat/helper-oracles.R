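# Independent oracles, kept deliberately naive and separate from the
# package's compiled paths.

# Brute-force midpoint line trace: walk the continuous line in fine steps,
# snap to the nearest pixel centre, keep in-grid pixels in traversal order.
oracle_trace <- function(anchor, angle, dims) {
  rad <- angle * pi / 180
  dr <- sin(rad); dc <- cos(rad)
  L <- 2 * (dims[1] + dims[2])
  seen <- character(0)
  px <- NULL
  if (abs(dc) >= abs(dr)) {
    for (c in 0:(dims[2] - 1)) {
      r <- floor(anchor[1] + (c - anchor[2]) * dr / dc + 0.5)
      if (r >= 0 && r <= dims[1] - 1) px <- rbind(px, c(r, c))
    }
  } else {
    for (r in 0:(dims[1] - 1)) {
      c <- floor(anchor[2] + (r - anchor[1]) * dc / dr + 0.5)
      if (c >= 0 && c <= dims[2] - 1) px <- rbind(px, c(r, c))
    }
  }
  px
}

# Hand-rolled per-pixel multiplicative update: scale every masked pixel so
# the masked sum hits the target; the reference for the compiled update.
oracle_mart_update <- function(A, mask, target) {
  Si <- sum(A[mask])
  out <- A
  if (target == 0) {
    out[mask] <- 0
  } else if (Si > 0) {
    for (i in seq_along(A)) if (mask[i]) out[i] <- target * A[i] / Si
  }
  out
}

mask_of_ray <- function(ray, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[ray$pixels[, 1] + ray$pixels[, 2] * dims[1] + 1L] <- TRUE
  m
}

# Random but valid track-event lists for round-trip properties.
random_events <- function(n_levels = 1L) {
  out <- list()
  for (l in seq_len(n_levels)) {
    out[[length(out) + 1L]] <-
      ev_level(sample.int(50, 1), sample(c(256L, 384L, 512L), 1),
               sample(c(256L, 384L, 512L), 1))
    for (s in seq_len(sample.int(4, 1))) {
      f <- if (stats::runif(1) < 0.5) ev_circle else ev_triangle
      out[[length(out) + 1L]] <-
        f(sample.int(512, 1) - 1L, sample.int(512, 1) - 1L,
          sample.int(60, 1), stats::runif(1) < 0.5)
    }
    for (k in seq_len(sample.int(5, 1))) {
      roll <- stats::runif(1)
      out[[length(out) + 1L]] <- if (roll < 0.6)
        ev_move(sample.int(512, 1) - 1L, sample.int(512, 1) - 1L,
                sample.int(9, 1), sample.int(180, 1),
                0L)
      else ev_refine()
    }
    out[[length(out) + 1L]] <- ev_guess(sample.int(8, 1) - 1L)
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  ev
}

# Small deterministic phantom for reconstruction tests: dark background,
# one bright square and one gray disc.
toy_hidden <- function(n = 32L) {
  img <- matrix(0, n, n)
  q <- max(2L, n %/% 6L)
  img[(q + 1):(2 * q), (q + 1):(2 * q)] <- 1
  rr <- row(img) - 1; cc <- col(img) - 1
  img[(rr - 2 * n / 3)^2 + (cc - 2 * n / 3)^2 <= max(1, n / 8)^2] <- 0.5
  img
}
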