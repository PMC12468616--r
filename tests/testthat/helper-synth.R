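# Shared fixtures built in code.

# A small, fast configuration for unit tests: 512-px patches, relaxed
# minimum cell count. Acceptance tests use the full-size defaults.
small_ki67_config <- function(min_cells = 40L) {
  ki67_config(patch_size_px = 512L, min_cells = min_cells)
}

small_patch_spec <- function(n_cells = 60L, positive_fraction = 0.3,
                             seed = 1L, ...) {
  ihc_patch_spec(n_cells = n_cells, positive_fraction = positive_fraction,
                 patch_size_px = 512L, seed = seed, ...)
}

# Binary mask with planted disks (pixel (i, j) is inside a disk when its
# 0-based centre distance is <= radius).
make_disk_mask <- function(centers_xy, radii, dim_px) {
  m <- matrix(FALSE, dim_px[1], dim_px[2])
  for (i in seq_len(nrow(centers_xy))) {
    cx <- centers_xy[i, 1]; cy <- centers_xy[i, 2]; r <- radii[i]
    rows <- max(1, floor(cy - r)):min(dim_px[1], ceiling(cy + r + 2))
    cols <- max(1, floor(cx - r)):min(dim_px[2], ceiling(cx + r + 2))
    d2 <- outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, `+`)
    m[rows, cols] <- m[rows, cols] | (d2 <= r^2)
  }
  m
}

# Independent double-loop window sum ("same" mode): the brute-force oracle
# used against sliding_sum().
oracle_window_sum <- function(counts, window) {
  h <- (window - 1) %/% 2
  out <- matrix(0, nrow(counts), ncol(counts))
  for (r in seq_len(nrow(counts))) for (c in seq_len(ncol(counts))) {
    rs <- max(1, r - h):min(nrow(counts), r + h)
    cs <- max(1, c - h):min(ncol(counts), c + h)
    out[r, c] <- sum(counts[rs, cs])
  }
  out
}

feature_names_for_test <- function() {
  c(sprintf("mito_%02d", 0:48), sprintf("ki67_%03d", 0:100))
}

midog_fixture <- function() {
  system.file("extdata", "midog_synthetic_mini.json", package = "nengrader")
}
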