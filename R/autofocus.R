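#' Tamura-of-gradient sharpness score
#'
#' Sharpness metric used for automated refocus-distance selection: the
#' Tamura coefficient `sqrt(sd(g) / mean(g))` of the gradient-magnitude
#' image `g = |grad(amplitude)|`, computed with central differences on the
#' interior pixels. Larger is sharper; the score is invariant to adding a
#' constant offset to the amplitude, and a constant image scores 0 by
#' convention (`mean(g) = 0`).
#'
#' @param amplitude Finite numeric matrix (at least 3 x 3).
#' @return A single non-negative sharpness score.
#' @export
sharpness_score <- function(amplitude) {
  if (!is.matrix(amplitude) || !is.numeric(amplitude))
    stop("amplitude must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(amplitude)))
    stop("amplitude must be finite everywhere", call. = FALSE)
  nr <- nrow(amplitude); nc <- ncol(amplitude)
  if (nr < 3L || nc < 3L)
    stop("amplitude must be at least 3 x 3", call. = FALSE)
  ri <- 2L:(nr - 1L); ci <- 2L:(nc - 1L)
  gy <- (amplitude[ri + 1L, ci] - amplitude[ri - 1L, ci]) / 2
  gx <- (amplitude[ri, ci + 1L] - amplitude[ri, ci - 1L]) / 2
  g <- sqrt(gx^2 + gy^2)
  m <- mean(g)
  if (m == 0) return(0)
  sqrt(stats::sd(g) / m)
}

#' Automated refocus-distance selection
#'
#' Scans candidate refocus distances, scoring the amplitude of a single
#' backpropagation at each with [sharpness_score()], and returns the
#' scan with the sharpest distance. Ties break toward the smaller
#' distance. With `refine = TRUE`, a golden-section pass within one grid
#' step of the coarse optimum polishes the estimate; the refined point is
#' appended to the scan.
#'
#' @param holo A normalised [hologram_frame()].
#' @param h_min,h_max Scan range in um, `0 < h_min < h_max`.
#' @param step Scan step in um (> 0).
#' @param refine Logical; golden-section refinement within `+/- step` of the
#'   coarse optimum.
#' @param pad_factor Grid enlargement for the backpropagations (default 2).
#' @return An object of class `focus_scan` with elements `candidates`,
#'   `scores` and `best_h`.
#' @export
autofocus <- function(holo, h_min, h_max, step, refine = FALSE,
                      pad_factor = 2L) {
  if (!is.numeric(h_min) || !is.numeric(h_max) || !is.numeric(step) ||
      !(h_min > 0) || !(h_max > h_min) || !(step > 0))
    stop("require 0 < h_min < h_max and step > 0", call. = FALSE)
  candidates <- seq(h_min, h_max, by = step)
  if (length(candidates) == 0L)
    stop("empty focus scan grid", call. = FALSE)
  u0 <- initial_wavefield(holo)
  score_at <- function(h)
    sharpness_score(Mod(backpropagate(u0, h, pad_factor)$values))
  scores <- vapply(candidates, score_at, numeric(1))
  best_i <- which(scores == max(scores))[1L]  # ties -> smallest h
  best_h <- candidates[best_i]

  if (isTRUE(refine)) {
    lo <- max(h_min, best_h - step)
    hi <- min(h_max, best_h + step)
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- score_at(x1); f2 <- score_at(x2)
    for (k in seq_len(25L)) {
      if (b - a < step / 100) break
      if (f1 < f2) {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- score_at(x2)
      } else {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- score_at(x1)
      }
    }
    h_ref <- if (f1 >= f2) x1 else x2
    s_ref <- max(f1, f2)
    if (s_ref >= max(scores)) {
      candidates <- c(candidates, h_ref)
      scores <- c(scores, s_ref)
      best_h <- h_ref
    }
  }
  structure(list(candidates = candidates, scores = scores, best_h = best_h),
            class = "focus_scan")
}

#' @export
print.focus_scan <- function(x, ...) {
  cat(sprintf("<focus_scan> %d candidates in [%.1f, %.1f] um; best_h = %.2f um\n",
              length(x$candidates), min(x$candidates), max(x$candidates),
              x$best_h))
  invisible(x)
}

#' Twin-image suppression ratio
#'
#' Quantifies how much the iterative reconstruction cleans the background
#' relative to a single backpropagation: the ratio of background amplitude
#' standard deviations, `sd(bp background) / sd(gs background)`. The
#' background is the complement of the object mask eroded by 5 pixels, so
#' pixels hugging grain boundaries are excluded. Values above 1 mean the
#' iterative result suppressed the twin-image ringing.
#'
#' @param bp [reconstruction_result()] of the single backpropagation.
#' @param gs [reconstruction_result()] of the iterative reconstruction.
#' @param object_mask Logical matrix marking object pixels.
#' @return A single positive ratio.
#' @export
twin_suppression_ratio <- function(bp, gs, object_mask) {
  if (!inherits(bp, "reconstruction_result") ||
      !inherits(gs, "reconstruction_result"))
    stop("bp and gs must be reconstruction_result objects", call. = FALSE)
  if (!is.matrix(object_mask) || !is.logical(object_mask) ||
      !identical(dim(object_mask), dim(bp$amplitude)) ||
      !identical(dim(bp$amplitude), dim(gs$amplitude)))
    stop("object_mask must be a logical matrix matching both amplitudes",
         call. = FALSE)
  bg <- !object_mask
  # erode the background by 5 px so the band adjacent to grains is excluded
  bg_eroded <- EBImage::erode(bg * 1, EBImage::makeBrush(11L, shape = "disc"))
  bg <- bg_eroded > 0.5
  if (!any(bg))
    stop("degenerate input: empty background after erosion", call. = FALSE)
  sd_bp <- stats::sd(bp$amplitude[bg])
  sd_gs <- stats::sd(gs$amplitude[bg])
  if (sd_gs == 0 && sd_bp == 0) return(1)
  sd_bp / sd_gs
}
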