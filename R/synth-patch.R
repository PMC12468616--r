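#' Specification of a synthetic Ki-67 IHC patch
#'
#' Describes a patch of well-separated nuclei rendered as anti-aliased disks
#' on a white background via the Beer-Lambert law: negative nuclei carry
#' only haematoxylin optical density, positive nuclei a mixed DAB +
#' haematoxylin density (so the haematoxylin channel counts *all* cells, as
#' required for the index denominator). Ground truth (centre, radius,
#' positivity per nucleus) is returned alongside the image.
#'
#' @param n_cells Number of nuclei.
#' @param positive_fraction Fraction of nuclei rendered Ki-67 positive;
#'   exactly `round(n_cells * positive_fraction)` nuclei are positive.
#' @param patch_size_px Side of the square patch in pixels.
#' @param radius_px_range Length-2 numeric, min/max nuclear radius in px.
#' @param min_separation_px Minimum distance between nucleus centres;
#'   enforced by placing centres on a jittered lattice.
#' @param background_rgb Background colour in \[0,1\].
#' @param stain_matrix Stain optical-density basis used for rendering; the
#'   default matches the quantifier's default so recovery is a fair test of
#'   the thresholding and circle-detection stages.
#' @param seed Integer seed; same seed gives byte-identical output.
#' @param positive_ids Optional integer indices of the nuclei to render
#'   positive, overriding `positive_fraction`; with a fixed seed this keeps
#'   the nucleus layout and per-nucleus stain draws identical across nested
#'   positive sets (used for monotonicity experiments).
#' @return An object of class `ihc_patch_spec`.
#' @export
ihc_patch_spec <- function(n_cells = 700L,
                           positive_fraction = 0.3,
                           patch_size_px = 1536L,
                           radius_px_range = c(9, 15),
                           min_separation_px = 44,
                           background_rgb = c(1, 1, 1),
                           stain_matrix = hdab_stain_matrix(),
                           seed = 1L,
                           positive_ids = NULL) {
  stopifnot(n_cells >= 0, positive_fraction >= 0, positive_fraction <= 1,
            patch_size_px > 0, length(radius_px_range) == 2,
            radius_px_range[1] <= radius_px_range[2],
            min_separation_px > 0, length(background_rgb) == 3)
  if (!is.null(positive_ids)) {
    positive_ids <- as.integer(positive_ids)
    stopifnot(all(positive_ids >= 1), all(positive_ids <= n_cells),
              !anyDuplicated(positive_ids))
  }
  structure(list(n_cells = as.integer(n_cells),
                 positive_ids = positive_ids,
                 positive_fraction = positive_fraction,
                 patch_size_px = as.integer(patch_size_px),
                 radius_px_range = radius_px_range,
                 min_separation_px = min_separation_px,
                 background_rgb = background_rgb,
                 stain_matrix = stain_matrix,
                 seed = as.integer(seed)),
            class = "ihc_patch_spec")
}

#' Generate a synthetic IHC patch with per-nucleus ground truth
#'
#' @param spec An [ihc_patch_spec()].
#' @return A list with `image` (RGB array, values in \[0,1\]) and `truth`
#'   (tibble: `center_x`, `center_y` 0-based pixel coordinates, `radius`,
#'   `positive`).
#' @export
#' @examples
#' p <- gen_ihc_patch(ihc_patch_spec(n_cells = 30, patch_size_px = 384, seed = 7))
#' sum(p$truth$positive)
gen_ihc_patch <- function(spec) {
  stopifnot(inherits(spec, "ihc_patch_spec"))
  with_seed_(spec$seed, {
    P <- spec$patch_size_px
    jitter <- min(3, (spec$min_separation_px - 1) / 2)
    spacing <- spec$min_separation_px + 2 * jitter
    margin <- spec$radius_px_range[2] + 2
    sites_1d <- seq(margin, P - 1 - margin, by = spacing)
    sites <- expand.grid(cx = sites_1d, cy = sites_1d)
    if (nrow(sites) < spec$n_cells)
      abort(sprintf(
        "cannot place %d nuclei at separation %.0f in a %d-px patch",
        spec$n_cells, spec$min_separation_px, P))
    pick <- sites[sample.int(nrow(sites), spec$n_cells), , drop = FALSE]
    cx <- pick$cx + runif(spec$n_cells, -jitter, jitter)
    cy <- pick$cy + runif(spec$n_cells, -jitter, jitter)
    radius <- runif(spec$n_cells, spec$radius_px_range[1],
                    spec$radius_px_range[2])
    positive <- rep(FALSE, spec$n_cells)
    if (!is.null(spec$positive_ids)) {
      positive[spec$positive_ids] <- TRUE
    } else {
      n_pos <- round(spec$n_cells * spec$positive_fraction)
      if (n_pos > 0) positive[sample.int(spec$n_cells, n_pos)] <- TRUE
    }

    # per-nucleus stain concentrations (optical-density units)
    c_h <- ifelse(positive, runif(spec$n_cells, 0.40, 0.65),
                            runif(spec$n_cells, 0.70, 1.00))
    c_d <- ifelse(positive, runif(spec$n_cells, 0.70, 1.00), 0)

    img <- array(rep(spec$background_rgb, each = P * P), dim = c(P, P, 3))
    M <- spec$stain_matrix
    for (i in seq_len(spec$n_cells)) {
      r <- radius[i]
      rows <- max(1, floor(cy[i] - r)):min(P, ceiling(cy[i] + r + 2))
      cols <- max(1, floor(cx[i] - r)):min(P, ceiling(cx[i] + r + 2))
      d <- sqrt(outer((rows - 1 - cy[i])^2, (cols - 1 - cx[i])^2, `+`))
      cov <- pmin(1, pmax(0, r + 0.5 - d))
      if (!any(cov > 0)) next
      od <- c_h[i] * M[1, ] + c_d[i] * M[3, ]
      for (ch in 1:3)
        img[rows, cols, ch] <- img[rows, cols, ch] * 10^(-od[ch] * cov)
    }
    list(image = img,
         truth = tibble::tibble(center_x = cx, center_y = cy,
                                radius = radius, positive = positive))
  })
}
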