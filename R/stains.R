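#' Default H-DAB optical-density stain matrix
#'
#' Rows are the unit optical-density vectors of haematoxylin, eosin and DAB
#' (Ruifrok-Johnston values), the community-standard basis for separating a
#' haematoxylin counterstain from the brown DAB chromogen in Ki-67
#' immunohistochemistry. Override any row via [ki67_config()] when a
#' scanner-specific calibration is available.
#'
#' @return A 3x3 numeric matrix with rownames `c("hematoxylin", "eosin",
#'   "dab")` and unit-norm rows.
#' @export
#' @examples
#' hdab_stain_matrix()
hdab_stain_matrix <- function() {
  m <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    eosin       = c(0.072, 0.990, 0.105),
    dab         = c(0.268, 0.570, 0.776)
  )
  m / sqrt(rowSums(m^2))
}

#' Configuration for classical Ki-67 patch quantification
#'
#' Bundles every tunable of the Ki-67 chain: evaluation patch size, the
#' minimum cell count for a patch to qualify (clinical practice requires at
#' least 500 assessed cells), the mask expansion radius, the circular Hough
#' search parameters and the stain optical-density matrix.
#'
#' @param patch_size_px Side of the square evaluation patch in pixels.
#' @param min_cells Minimum number of detected cells (haematoxylin-channel
#'   circles) for the patch index to qualify.
#' @param expansion_radius_px Radius of the disk used to dilate the binary
#'   cell masks before circle detection.
#' @param hough_params List with `min_radius_px`, `max_radius_px`,
#'   `min_center_distance_px` and `accumulator_threshold`. The defaults cover
#'   nuclear radii of roughly 2-10 micrometres at 0.2525 micrometres per
#'   pixel; the vote threshold was fixed once against synthetic fixtures.
#' @param stain_matrix 3x3 matrix of stain optical-density vectors (rows:
#'   haematoxylin, eosin, DAB); rows are renormalised to unit length.
#' @return An object of class `ki67_config`.
#' @export
ki67_config <- function(patch_size_px = 1536L,
                        min_cells = 500L,
                        expansion_radius_px = 5L,
                        hough_params = list(min_radius_px = 8,
                                            max_radius_px = 40,
                                            min_center_distance_px = 16,
                                            accumulator_threshold = 30),
                        stain_matrix = hdab_stain_matrix()) {
  stopifnot(length(patch_size_px) == 1, patch_size_px > 0,
            min_cells >= 0, expansion_radius_px >= 0)
  hp <- modifyList(list(min_radius_px = 8, max_radius_px = 40,
                        min_center_distance_px = 16,
                        accumulator_threshold = 30), hough_params)
  if (hp$min_radius_px >= hp$max_radius_px)
    abort("hough_params: min_radius_px must be smaller than max_radius_px")
  stain_matrix <- as.matrix(stain_matrix)
  if (!all(dim(stain_matrix) == c(3, 3)) || any(!is.finite(stain_matrix)))
    abort("stain_matrix must be a finite 3x3 matrix")
  stain_matrix <- stain_matrix / sqrt(rowSums(stain_matrix^2))
  structure(list(patch_size_px = as.integer(patch_size_px),
                 min_cells = as.integer(min_cells),
                 expansion_radius_px = as.integer(expansion_radius_px),
                 hough_params = hp,
                 stain_matrix = stain_matrix),
            class = "ki67_config")
}

as_rgb_array <- function(patch) {
  if (is.character(patch)) patch <- read_patch(patch)
  if (!is.array(patch) || length(dim(patch)) != 3 || dim(patch)[3] < 3)
    abort("patch must be an RGB array (rows x cols x 3)")
  if (any(dim(patch)[1:2] == 0)) abort("patch is empty")
  patch <- patch[, , 1:3, drop = FALSE]
  if (is.integer(patch) || max(patch) > 1) patch <- patch / 255
  patch
}

#' Separate an RGB patch into haematoxylin and DAB planes
#'
#' Optical-density colour deconvolution: pixel intensities are converted to
#' optical densities (Beer-Lambert, white background has zero density) and
#' projected onto the stain basis. Only the haematoxylin (all nuclei) and
#' DAB (Ki-67 positive nuclei) concentration planes are returned; eosin is
#' discarded.
#'
#' @param patch RGB array (`rows x cols x 3`, values in \[0,1\] or 0-255) or
#'   a path to a PNG/TIFF image.
#' @param stain_matrix 3x3 stain optical-density matrix; see
#'   [hdab_stain_matrix()].
#' @return A list with matrices `hematoxylin` and `dab` (non-negative stain
#'   concentrations, same shape as the patch).
#' @export
separate_stains <- function(patch, stain_matrix = hdab_stain_matrix()) {
  patch <- as_rgb_array(patch)
  stain_matrix <- as.matrix(stain_matrix)
  stain_matrix <- stain_matrix / sqrt(rowSums(stain_matrix^2))
  d <- dim(patch)
  rgb <- matrix(patch, ncol = 3)
  od <- -log10(pmax(rgb, 1 / 255))
  conc <- od %*% solve(stain_matrix)[, c(1, 3)]  # keep H and DAB only
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
       dab         = matrix(conc[, 2], d[1], d[2]))
}

#' Binarise a stain concentration plane with Otsu's method
#'
#' Foreground (cells) are pixels whose stain concentration exceeds the Otsu
#' threshold computed over 256 levels of the plane's dynamic range. Planes
#' with (near-)zero dynamic range — e.g. the DAB plane of a patch with no
#' positive cells — yield an all-background mask rather than thresholding
#' numerical noise; the minimum amplitude for thresholding is 0.05 optical
#' density units.
#'
#' @param channel Numeric matrix of non-negative stain concentrations.
#' @param min_amplitude Minimum dynamic range below which the plane is
#'   treated as stain-free.
#' @return Logical matrix, `TRUE` = cell foreground.
#' @export
binarize_channel <- function(channel, min_amplitude = 0.05) {
  stopifnot(is.matrix(channel), all(is.finite(channel)))
  lo <- min(channel); hi <- max(channel)
  if (hi - lo < min_amplitude)
    return(matrix(FALSE, nrow(channel), ncol(channel)))
  scaled <- (channel - lo) / (hi - lo)
  th <- EBImage::otsu(scaled, range = c(0, 1), levels = 256)
  scaled > th
}

disk_kernel <- function(radius) {
  i <- seq(-radius, radius)
  outer(i, i, function(a, b) as.numeric(a^2 + b^2 <= radius^2))
}

#' Dilate a binary mask by a disk
#'
#' Morphological dilation with a Euclidean disk structuring element; used to
#' close small gaps in the Otsu cell masks before circle detection. Radius 0
#' is the identity.
#'
#' @param mask Logical or 0/1 matrix.
#' @param radius Disk radius in pixels (non-negative integer).
#' @return Logical matrix, a superset of the input foreground.
#' @export
expand_mask <- function(mask, radius = 5L) {
  if (length(radius) != 1 || is.na(radius) || radius < 0)
    abort("radius must be a non-negative integer")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (radius == 0) return(m > 0)
  EBImage::dilate(m, disk_kernel(radius)) > 0
}

#' Detect circles in a binary mask with a circular Hough transform
#'
#' Gradient-voting circular Hough transform: edge pixels of the mask vote
#' along their gradient normals at every radius in the search range;
#' accumulator peaks above the vote threshold become centres, thinned so no
#' two centres are closer than `min_center_distance_px`; each circle's
#' radius is the modal edge distance from its centre.
#'
#' @param mask Logical or 0/1 matrix.
#' @param params List as in [ki67_config()]'s `hough_params`.
#' @return A tibble with columns `x`, `y` (0-based pixel coordinates,
#'   `x` = column), `radius` and `votes`; zero rows for an empty mask.
#' @export
detect_circles <- function(mask,
                           params = ki67_config()$hough_params) {
  stopifnot(is.matrix(mask))
  p <- modifyList(ki67_config()$hough_params, params)
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  empty <- tibble::tibble(x = numeric(), y = numeric(),
                          radius = numeric(), votes = numeric())
  if (!any(m == 1L)) return(empty)
  res <- .hough_circles_cpp(m,
                            as.integer(p$min_radius_px),
                            as.integer(p$max_radius_px),
                            as.numeric(p$min_center_distance_px),
                            as.numeric(p$accumulator_threshold))
  if (nrow(res) == 0) return(empty)
  tibble::as_tibble(res)
}

#' Ki-67 proliferation index of a single IHC patch
#'
#' Runs the full classical chain on one patch: colour deconvolution into
#' haematoxylin and DAB planes, Otsu binarisation, disk dilation, and
#' independent circle detection in each plane. The index is the percentage
#' of DAB-channel circles (positive cells) over haematoxylin-channel circles
#' (all cells). Patches with fewer than `min_cells` detected cells do not
#' qualify and must not be aggregated downstream; with zero detected cells
#' the index is undefined (`NA`).
#'
#' @param patch RGB array or path to a PNG/TIFF image; side must equal
#'   `config$patch_size_px`.
#' @param config A [ki67_config()].
#' @return A one-row tibble: `n_total`, `n_positive`, `index_pct`,
#'   `qualifies`.
#' @export
#' @examples
#' p <- gen_ihc_patch(ihc_patch_spec(n_cells = 40, positive_fraction = 0.25,
#'                                   patch_size_px = 384, seed = 1))
#' ki67_patch_index(p$image, ki67_config(patch_size_px = 384, min_cells = 30))
ki67_patch_index <- function(patch, config = ki67_config()) {
  stopifnot(inherits(config, "ki67_config"))
  patch <- as_rgb_array(patch)
  if (!all(dim(patch)[1:2] == config$patch_size_px))
    abort(sprintf("patch must be %d x %d pixels", config$patch_size_px,
                  config$patch_size_px))
  planes <- separate_stains(patch, config$stain_matrix)
  count_plane <- function(ch) {
    mask <- expand_mask(binarize_channel(ch), config$expansion_radius_px)
    nrow(detect_circles(mask, config$hough_params))
  }
  n_total <- count_plane(planes$hematoxylin)
  n_positive <- count_plane(planes$dab)
  index <- if (n_total > 0) 100 * n_positive / n_total else NA_real_
  tibble::tibble(n_total = n_total, n_positive = n_positive,
                 index_pct = index,
                 qualifies = n_total >= config$min_cells)
}

#' Ki-67 indices for a gridded set of patches
#'
#' Batch form of [ki67_patch_index()] driven by a grid manifest, the on-disk
#' layout produced by fixed non-overlapping patch extraction from a slide.
#'
#' @param manifest Data frame (or CSV path) with columns `patch_path`,
#'   `grid_row`, `grid_col` (0-based grid coordinates).
#' @param config A [ki67_config()].
#' @return A tibble with `grid_row`, `grid_col`, `n_total`, `n_positive`,
#'   `index_pct`, `qualifies` — the per-slide CSV contract.
#' @export
ki67_index_patchset <- function(manifest, config = ki67_config()) {
  if (is.character(manifest))
    manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  stopifnot(all(c("patch_path", "grid_row", "grid_col") %in% names(manifest)))
  purrr::pmap_dfr(manifest, function(patch_path, grid_row, grid_col, ...) {
    dplyr::bind_cols(tibble::tibble(grid_row = grid_row, grid_col = grid_col),
                     ki67_patch_index(patch_path, config))
  })
}
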