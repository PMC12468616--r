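#' Specification of a synthetic mitotic detection field
#'
#' A patch grid whose per-patch detection counts are Poisson at a low
#' background rate, with an elevated rate inside a planted circular
#' hotspot — the situation a pathologist faces when searching a slide for
#' the most mitotically active 2 mm^2 region.
#'
#' @param n_rows,n_cols Grid size in patches.
#' @param background_rate Mean detections per patch outside the hotspot.
#' @param hotspot_rate Mean detections per patch inside the hotspot.
#' @param hotspot_center Length-2 integer (row, col), 1-based grid cell.
#' @param hotspot_radius_patches Hotspot radius in patches (Euclidean).
#' @param patch_size_px Patch side in pixels (for detection coordinates).
#' @param seed Integer seed.
#' @return An object of class `hotspot_field_spec`.
#' @export
hotspot_field_spec <- function(n_rows = 40L, n_cols = 40L,
                               background_rate = 0.05,
                               hotspot_rate = 5,
                               hotspot_center = NULL,
                               hotspot_radius_patches = 3,
                               patch_size_px = 512L,
                               seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1, background_rate >= 0, hotspot_rate >= 0,
            hotspot_radius_patches >= 0, patch_size_px > 0)
  if (is.null(hotspot_center))
    hotspot_center <- c(ceiling(n_rows / 2), ceiling(n_cols / 2))
  if (hotspot_center[1] < 1 || hotspot_center[1] > n_rows ||
      hotspot_center[2] < 1 || hotspot_center[2] > n_cols)
    abort("hotspot_center must lie inside the grid")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 background_rate = background_rate,
                 hotspot_rate = hotspot_rate,
                 hotspot_center = as.integer(hotspot_center),
                 hotspot_radius_patches = hotspot_radius_patches,
                 patch_size_px = as.integer(patch_size_px),
                 seed = as.integer(seed)),
            class = "hotspot_field_spec")
}

# Independent brute-force maximum window sum ("same" mode, zero padding):
# plain double loop, deliberately not sharing code with sliding_sum().
brute_force_max_window <- function(counts, window) {
  h <- (window - 1) %/% 2
  nr <- nrow(counts); nc <- ncol(counts)
  best <- -Inf; best_rc <- c(1L, 1L)
  for (r in 1:nr) for (c in 1:nc) {
    s <- sum(counts[max(1, r - h):min(nr, r + h),
                    max(1, c - h):min(nc, c + h)])
    if (s > best) { best <- s; best_rc <- c(r, c) }
  }
  list(value = best, row = best_rc[1], col = best_rc[2])
}

#' Generate a synthetic detection field with brute-force hotspot truth
#'
#' @param spec A [hotspot_field_spec()].
#' @param truth_window Window side used for the brute-force ground-truth
#'   maximum (default 11 patches = 2 mm^2 at the standard geometry).
#' @return A list: `detections` (tibble `x`, `y`, `score` in 0-based level-0
#'   pixels), `counts` (per-patch count matrix), and `truth` (brute-force
#'   max window sum, its position, and the planted centre).
#' @export
gen_detection_field <- function(spec, truth_window = 11L) {
  stopifnot(inherits(spec, "hotspot_field_spec"))
  with_seed_(spec$seed, {
    rr <- matrix(rep(1:spec$n_rows, spec$n_cols), spec$n_rows)
    cc <- matrix(rep(1:spec$n_cols, each = spec$n_rows), spec$n_rows)
    d2 <- (rr - spec$hotspot_center[1])^2 + (cc - spec$hotspot_center[2])^2
    rate <- ifelse(d2 <= spec$hotspot_radius_patches^2,
                   spec$hotspot_rate, spec$background_rate)
    counts <- matrix(rpois(length(rate), rate), spec$n_rows, spec$n_cols)
    idx <- which(counts > 0, arr.ind = TRUE)
    n_per <- counts[counts > 0]
    P <- spec$patch_size_px
    det <- if (length(n_per)) {
      row <- rep(idx[, 1], n_per); col <- rep(idx[, 2], n_per)
      n <- length(row)
      tibble::tibble(x = (col - 1) * P + runif(n, 0, P),
                     y = (row - 1) * P + runif(n, 0, P),
                     score = runif(n, 0.5, 1))
    } else tibble::tibble(x = numeric(), y = numeric(), score = numeric())
    truth <- brute_force_max_window(counts, truth_window)
    truth$planted_center <- spec$hotspot_center
    list(detections = det, counts = counts, truth = truth)
  })
}
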