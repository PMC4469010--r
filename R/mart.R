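# MART core: raysum measurement, per-ray multiplicative updates, the
# insertion-ordered ray registry, refinement, and full-view emulation.

ray_index <- function(ray, H) ray$pixels[, 1] + ray$pixels[, 2] * H + 1L

#' Raysum of an image along a ray
#'
#' The unweighted sum of image values over the ray's staircase pixels (binary
#' mask: every covered pixel has weight 1).
#'
#' @param image numeric matrix, values >= 0.
#' @param ray a `ct_ray` rasterized on a grid of the same dimensions.
#' @return numeric scalar.
#' @export
raysum <- function(image, ray) {
  stopifnot(inherits(ray, "ct_ray"))
  if (nrow(ray$pixels) == 0L) stop("ray has no pixels", call. = FALSE)
  if (max(ray$pixels[, 1]) >= nrow(image) ||
      max(ray$pixels[, 2]) >= ncol(image))
    stop("ray pixels fall outside the image", call. = FALSE)
  sum(image[ray_index(ray, nrow(image))])
}

#' One multiplicative (MART) update of an estimate along a ray
#'
#' Scales every pixel on the ray by `target / current raysum`, so that the
#' ray's raysum equals `target` afterwards (to floating tolerance); pixels
#' off the ray are untouched. A zero target zeroes the ray (a raysum of zero
#' stays zero under MART). If the current raysum is zero while the target is
#' positive the update is skipped and a warning raised (division guard;
#' cannot occur from the all-ones initialization).
#'
#' @param estimate numeric matrix.
#' @param ray a `ct_ray`.
#' @param target measured raysum, >= 0.
#' @return the updated estimate matrix.
#' @export
mart_update <- function(estimate, ray, target) {
  if (target < 0) stop("target raysum must be >= 0", call. = FALSE)
  idx <- ray_index(ray, nrow(estimate))
  if (target == 0) {
    estimate[idx] <- 0
    return(estimate)
  }
  si <- sum(estimate[idx])
  if (si <= 0) {
    warning("current raysum is 0 with positive target; update skipped")
    return(estimate)
  }
  estimate[idx] <- estimate[idx] * (target / si)
  estimate
}

#' Fresh reconstruction state
#'
#' An environment-backed mutable state (reference semantics): the estimate
#' grid initialized to all ones (a uniform start must avoid zeros, since
#' MART can never raise a zero pixel), plus the insertion-ordered registry of
#' measured rays. The registry maps canonical line keys to the ray's pixel
#' indices and its measured raysum; its size is the emitted dose.
#'
#' @param dims integer (height, width).
#' @return a `ct_recon` object.
#' @export
new_recon <- function(dims) {
  dims <- check_dims(dims)
  st <- new.env(parent = emptyenv())
  st$dims <- dims
  st$estimate <- matrix(1, dims[1], dims[2])
  st$lookup <- new.env(parent = emptyenv(), hash = TRUE)
  st$rays <- list()      # 1-based linear index vectors, insertion order
  st$keys <- character() # matching canonical keys
  st$S <- numeric()      # matching measured raysums
  st$n <- 0L
  st$refine_count <- 0L
  st$skipped <- 0L
  st$last_residual <- NA_real_
  st$converged <- NA
  class(st) <- "ct_recon"
  st
}

#' @export
print.ct_recon <- function(x, ...) {
  cat(sprintf(
    "<ct_recon> %dx%d estimate, %d unique rays (dose), %d refine passes\n",
    x$dims[1], x$dims[2], x$n, x$refine_count))
  invisible(x)
}

#' Registry size (emitted dose) of a reconstruction state
#' @param state a `ct_recon`.
#' @return integer count of unique rays measured so far.
#' @export
registry_size <- function(state) state$n

#' Process one ray against the hidden image
#'
#' If the ray's canonical key is already registered nothing happens (zero
#' added dose: re-measuring a static pseudoprojection cannot improve the
#' image). Otherwise the hidden raysum is measured once, stored in the
#' registry, and one MART update applied to the estimate.
#'
#' @param state a `ct_recon` (mutated in place).
#' @param ray a `ct_ray`.
#' @param hidden the hidden image matrix, same dimensions as the estimate.
#' @return logical: was the ray newly added?
#' @export
process_new_ray <- function(state, ray, hidden) {
  stopifnot(inherits(state, "ct_recon"), inherits(ray, "ct_ray"))
  if (!identical(dim(hidden), dim(state$estimate)))
    stop("hidden image dimensions do not match the estimate", call. = FALSE)
  key <- ray$key
  if (!is.null(state$lookup[[key]])) return(FALSE)
  idx <- ray_index(ray, state$dims[1])
  s <- sum(hidden[idx])
  n <- state$n + 1L
  state$lookup[[key]] <- n
  state$rays[[n]] <- idx
  state$keys[n] <- key
  state$S[n] <- s
  state$n <- n
  # inline mart_update on the live estimate
  if (s == 0) {
    state$estimate[idx] <- 0
  } else {
    si <- sum(state$estimate[idx])
    if (si <= 0) {
      state$skipped <- state$skipped + 1L
    } else {
      state$estimate[idx] <- state$estimate[idx] * (s / si)
    }
  }
  TRUE
}

#' One refinement pass
#'
#' Re-applies the MART update for every registered ray, in insertion order,
#' against its stored raysum. Refining never touches the registry, so it
#' adds no dose.
#'
#' @param state a `ct_recon` (mutated in place).
#' @return the state, invisibly; `state$last_residual` holds the pass's
#'   maximum pre-update relative residual.
#' @export
refine <- function(state) {
  stopifnot(inherits(state, "ct_recon"))
  if (state$n == 0L) {
    state$refine_count <- state$refine_count + 1L
    state$last_residual <- 0
    return(invisible(state))
  }
  out <- cpp_refine(state$estimate, state$rays[seq_len(state$n)],
                    state$S[seq_len(state$n)],
                    tol = 0, max_passes = 1L, eps = 1e-12)
  state$estimate <- out$estimate
  state$refine_count <- state$refine_count + 1L
  state$skipped <- state$skipped + out$skipped
  state$last_residual <- out$residuals[length(out$residuals)]
  invisible(state)
}

#' Refine until the registered raysums are satisfied
#'
#' Repeats refinement passes until the maximum over registered rays of
#' `|S_i - S| / max(S, 1e-12)` falls below `tol`, or `max_passes` is
#' reached. Consistent systems (raysums measured from a real hidden image)
#' converge; inconsistent (perturbed) targets terminate by the pass cap.
#'
#' @param state a `ct_recon` (mutated in place).
#' @param tol relative-residual threshold, > 0.
#' @param max_passes cap on refinement passes.
#' @return the state, invisibly; `state$converged` says whether `tol`
#'   terminated the loop and `state$residual_history` holds per-pass maxima.
#' @export
refine_to_convergence <- function(state, tol = 1e-6, max_passes = 200L) {
  stopifnot(inherits(state, "ct_recon"), tol > 0)
  if (state$n == 0L) {
    state$converged <- TRUE
    state$residual_history <- numeric()
    return(invisible(state))
  }
  out <- cpp_refine(state$estimate, state$rays[seq_len(state$n)],
                    state$S[seq_len(state$n)],
                    tol = tol, max_passes = as.integer(max_passes),
                    eps = 1e-12)
  state$estimate <- out$estimate
  state$refine_count <- state$refine_count + out$passes
  state$skipped <- state$skipped + out$skipped
  state$last_residual <- out$residuals[length(out$residuals)]
  state$residual_history <- out$residuals
  state$converged <- out$converged
  invisible(state)
}

#' Full-view MART emulation
#'
#' Emulates standard equally-spaced-view MART by looping the central point of
#' a width-1 star over every pixel of the hidden image (row-major), measuring
#' each geometrically new ray once, applying its update, and then refining
#' until convergence. Runs in compiled code; an all-ones start and the same
#' update rule as [process_new_ray()] / [refine()].
#'
#' @param hidden numeric matrix (values >= 0), the hidden image.
#' @param n_views views per star, 1..180.
#' @param tol convergence threshold on the maximum relative residual.
#' @param max_passes cap on refinement passes.
#' @return a `ct_fullview` list: `estimate`, `n_unique` (emitted dose),
#'   `residuals` (per refine pass), `passes`, `converged`, `skipped`.
#' @export
full_view_reconstruction <- function(hidden, n_views, tol = 1e-6,
                                     max_passes = 200L) {
  stopifnot(is.matrix(hidden), all(hidden >= 0))
  n_views <- as.integer(n_views)
  if (n_views < 1L || n_views > 180L)
    stop("n_views must be in [1, 180]", call. = FALSE)
  out <- cpp_full_view(hidden, n_views, tol, as.integer(max_passes), 1e-12)
  out$n_views <- n_views
  class(out) <- "ct_fullview"
  out
}

#' @export
print.ct_fullview <- function(x, ...) {
  cat(sprintf(
    "<ct_fullview> %d views, %s unique rays, %d refine passes (%s, final max residual %.3g)\n",
    x$n_views, format(x$n_unique, big.mark = ","), x$passes,
    if (isTRUE(x$converged)) "converged" else "pass cap reached",
    x$residuals[length(x$residuals)]))
  invisible(x)
}

#' Horizontal line profile of an image
#'
#' @param image numeric matrix.
#' @param row 0-based row (the y-coordinate of the profile).
#' @return numeric vector of length `ncol(image)`.
#' @export
line_profile <- function(image, row) {
  row <- as.integer(row)
  if (row < 0 || row >= nrow(image))
    stop("profile row ", row, " outside image (0..", nrow(image) - 1, ")",
         call. = FALSE)
  image[row + 1L, ]
}

#' Relative L2 reconstruction error
#'
#' `||estimate - reference|| / ||reference||` over all pixels.
#'
#' @param estimate,reference numeric matrices of equal dimensions.
#' @return numeric scalar.
#' @export
recon_error <- function(estimate, reference) {
  stopifnot(identical(dim(estimate), dim(reference)))
  sqrt(sum((estimate - reference)^2)) / sqrt(sum(reference^2))
}
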