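#' Patch grid geometry of a slide
#'
#' @param n_rows,n_cols Grid dimensions in patches.
#' @param patch_size_px Patch side in level-0 pixels.
#' @param mpp Physical resolution in micrometres per pixel.
#' @param tumor_mask Optional logical matrix (`n_rows x n_cols`); grid cells
#'   outside the tumour mask are excluded from density maps.
#' @return An object of class `patch_grid`.
#' @export
patch_grid <- function(n_rows, n_cols, patch_size_px = 512L, mpp = 0.2525,
                       tumor_mask = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, patch_size_px > 0, mpp > 0)
  if (!is.null(tumor_mask)) {
    tumor_mask <- matrix(as.logical(tumor_mask), nrow(tumor_mask), ncol(tumor_mask))
    if (!all(dim(tumor_mask) == c(n_rows, n_cols)))
      abort("tumor_mask shape must match the grid")
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 patch_size_px = as.integer(patch_size_px), mpp = mpp,
                 tumor_mask = tumor_mask),
            class = "patch_grid")
}

#' Side of the summation window, in patches, covering a target tissue area
#'
#' Mitotic counts are reported per 2 mm^2 of tissue; at 0.2525 um/px and
#' 512-px patches that area corresponds to an 11 x 11 patch window
#' (5632 x 5632 pixels). The side is `round(sqrt(area) * 1000 / (mpp *
#' patch_px))`.
#'
#' @param area_mm2 Target area in square millimetres.
#' @param mpp Micrometres per pixel.
#' @param patch_px Patch side in pixels.
#' @return Integer window side in patches (at least 1).
#' @export
#' @examples
#' window_patches_for_area(2, 0.2525, 512) # 11
window_patches_for_area <- function(area_mm2, mpp = 0.2525, patch_px = 512L) {
  if (any(c(area_mm2, mpp, patch_px) <= 0))
    abort("area_mm2, mpp and patch_px must all be positive")
  max(1L, as.integer(round(sqrt(area_mm2) * 1000 / (mpp * patch_px))))
}

#' Quantise point detections onto the patch grid
#'
#' Counts score-thresholded detections per grid cell. Coordinates are
#' 0-based level-0 pixels with `x` along columns; a detection at `(x, y)`
#' falls in the half-open cell `[col*P, (col+1)*P) x [row*P, (row+1)*P)`.
#' Out-of-bounds detections are dropped with a warning.
#'
#' @param detections Data frame with columns `x`, `y` and (optionally)
#'   `score`; a missing score column counts every detection.
#' @param grid A [patch_grid()].
#' @param score_threshold Minimum score for a detection to be counted.
#' @return Integer matrix (`n_rows x n_cols`) of per-patch counts.
#' @export
quantize_detections <- function(detections, grid, score_threshold = 0.5) {
  stopifnot(inherits(grid, "patch_grid"))
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  if (is.null(detections) || nrow(detections) == 0) return(counts)
  stopifnot(all(c("x", "y") %in% names(detections)))
  score <- if ("score" %in% names(detections)) detections$score else
    rep(1, nrow(detections))
  keep <- score >= score_threshold
  x <- detections$x[keep]; y <- detections$y[keep]
  P <- grid$patch_size_px
  col <- floor(x / P) + 1L
  row <- floor(y / P) + 1L
  inb <- x >= 0 & y >= 0 & row <= grid$n_rows & col <= grid$n_cols
  if (any(!inb))
    warn(sprintf("dropped %d detections outside the %d x %d patch grid",
                 sum(!inb), grid$n_rows, grid$n_cols))
  idx <- cbind(row[inb], col[inb])
  if (nrow(idx)) {
    tab <- table(factor(idx[, 1], levels = 1:grid$n_rows),
                 factor(idx[, 2], levels = 1:grid$n_cols))
    counts <- matrix(as.integer(tab), grid$n_rows, grid$n_cols)
  }
  counts
}

new_density_map <- function(values, kind, window_patches) {
  structure(list(values = values, kind = kind,
                 window_patches = as.integer(window_patches)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map kind=%s window=%d %d x %d, %d missing>\n",
              x$kind, x$window_patches, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' Sliding window sum over a per-patch count grid
#'
#' Passes a `window x window` summation filter (stride 1) over the
#' quantised detection counts, so each position holds the number of mitotic
#' figures in the corresponding tissue area (e.g. 11 patches = 2 mm^2).
#' `"same"` mode zero-pads the borders and keeps the grid shape; `"valid"`
#' keeps only fully covered positions. With a tumour mask, non-tumour cells
#' contribute zero to their neighbours' windows and receive a missing value
#' themselves.
#'
#' @param counts Numeric matrix of per-patch counts.
#' @param window Window side in patches (odd for `"same"` mode).
#' @param mode `"same"` or `"valid"`.
#' @param mask Optional logical matrix the shape of `counts`.
#' @return A `density_map` of kind `"mitotic_2mm2"`.
#' @export
sliding_sum <- function(counts, window = 11L, mode = c("same", "valid"),
                        mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(counts), window >= 1)
  window <- as.integer(window)
  if (mode == "same" && window %% 2 == 0)
    abort("window must be odd in 'same' mode (centred filter)")
  if (mode == "valid" && (window > nrow(counts) || window > ncol(counts)))
    abort("window larger than the grid in 'valid' mode")
  x <- counts
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(counts)))
    x[!mask] <- 0
  }
  out <- .sliding_sum_cpp(matrix(as.numeric(x), nrow(x), ncol(x)),
                          window, if (mode == "same") 0L else 1L)
  if (!is.null(mask)) {
    if (mode == "same") {
      out[!mask] <- NA_real_
    } else {
      # a valid-mode position (r, c) is centred on grid cell
      # (r + (window-1)/2, c + (window-1)/2)
      h <- (window - 1L) %/% 2L
      out[!mask[(seq_len(nrow(out))) + h, (seq_len(ncol(out))) + h,
                drop = FALSE]] <- NA_real_
    }
  }
  new_density_map(out, "mitotic_2mm2", window)
}

#' Hotspot of a density map
#'
#' The clinically reported value: the window position with the highest
#' local count (for mitotic maps, the 2 mm^2 area with the most mitoses).
#' Ties resolve to the first position in row-major order.
#'
#' @param map A `density_map`.
#' @return A one-row tibble: `value`, `row`, `col` (1-based grid position).
#' @export
hotspot <- function(map) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  if (all(is.na(v))) abort("density map has no non-missing values")
  best <- max(v, na.rm = TRUE)
  hits <- which(t(v) == best)  # transpose: row-major scan order
  first <- hits[1] - 1L
  tibble::tibble(value = best,
                 row = as.integer(first %/% ncol(v)) + 1L,
                 col = as.integer(first %% ncol(v)) + 1L)
}

#' Per-patch Ki-67 index map
#'
#' Arranges per-patch Ki-67 indices on the slide grid. Unqualified patches
#' (fewer than the minimum cell count) are missing; a map that is entirely
#' missing is rejected downstream when building histograms.
#'
#' @param per_patch Data frame with `grid_row`, `grid_col` (0-based),
#'   `index_pct` and `qualifies` — the output of [ki67_index_patchset()].
#' @param grid A [patch_grid()].
#' @return A `density_map` of kind `"ki67_index"` with `window_patches = 1`.
#' @export
ki67_index_map <- function(per_patch, grid) {
  stopifnot(inherits(grid, "patch_grid"),
            all(c("grid_row", "grid_col", "index_pct", "qualifies") %in%
                  names(per_patch)))
  r <- per_patch$grid_row + 1L
  c <- per_patch$grid_col + 1L
  if (any(r < 1 | r > grid$n_rows | c < 1 | c > grid$n_cols))
    abort("grid coordinates outside the grid")
  if (anyDuplicated(cbind(r, c))) abort("duplicate grid coordinates")
  v <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  ok <- per_patch$qualifies
  v[cbind(r[ok], c[ok])] <- per_patch$index_pct[ok]
  if (!is.null(grid$tumor_mask)) v[!grid$tumor_mask] <- NA_real_
  new_density_map(v, "ki67_index", 1L)
}
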