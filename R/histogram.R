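#' Histogram configuration for slide-level density features
#'
#' The mitotic histogram spans integer counts 0..48 (49 bins; slide values
#' above 48 are clipped, well above the G3 threshold of 20). The Ki-67
#' histogram spans integer indices 0..100 (101 bins).
#'
#' @param kind `"mitotic"` or `"ki67"`.
#' @param support_min,support_max Integer bin support; defaults depend on
#'   `kind`.
#' @param clip Clip out-of-support values into the end bins (default) rather
#'   than dropping them.
#' @return An object of class `histogram_config`.
#' @export
histogram_config <- function(kind = c("mitotic", "ki67"),
                             support_min = 0L,
                             support_max = NULL,
                             clip = TRUE) {
  kind <- match.arg(kind)
  if (is.null(support_max)) support_max <- if (kind == "mitotic") 48L else 100L
  stopifnot(support_min < support_max)
  structure(list(kind = kind, support_min = as.integer(support_min),
                 support_max = as.integer(support_max), clip = clip),
            class = "histogram_config")
}

#' Slide-level histogram of a density map
#'
#' The slide representation: non-missing density values are rounded
#' half-up to integers, clipped into the support, tallied into unit-width
#' bins and normalised to sum to one. Captures the full distribution of
#' proliferative activity across the slide rather than a single hotspot.
#'
#' @param map A `density_map` (or a bare numeric vector/matrix of values).
#' @param config A [histogram_config()]; its `kind` must match the map.
#' @return An object of class `slide_histogram` with fields `frequencies`
#'   (named numeric, length = bin count), `kind` and `n_values`.
#' @export
#' @examples
#' m <- sliding_sum(matrix(rpois(100, 1), 10, 10), window = 3)
#' build_histogram(m, histogram_config("mitotic"))
build_histogram <- function(map, config = histogram_config()) {
  stopifnot(inherits(config, "histogram_config"))
  if (inherits(map, "density_map")) {
    map_kind <- if (map$kind == "mitotic_2mm2") "mitotic" else "ki67"
    if (map_kind != config$kind)
      abort(sprintf("map kind '%s' does not match histogram kind '%s'",
                    map$kind, config$kind))
    v <- as.vector(map$values)
  } else {
    v <- as.vector(as.numeric(map))
  }
  v <- v[!is.na(v)]
  if (length(v) == 0)
    abort("density map has no non-missing values; slide is unrepresentable")
  b <- round_half_up(v)
  if (config$clip)
    b <- pmin(pmax(b, config$support_min), config$support_max)
  else
    b <- b[b >= config$support_min & b <= config$support_max]
  support <- config$support_min:config$support_max
  freq <- tabulate(b - config$support_min + 1L, nbins = length(support))
  freq <- freq / sum(freq)
  structure(list(frequencies = setNames(freq, support),
                 kind = config$kind, n_values = length(v)),
            class = "slide_histogram")
}

#' @export
print.slide_histogram <- function(x, ...) {
  cat(sprintf("<slide_histogram kind=%s bins=%d n=%d mass@0=%.3f>\n",
              x$kind, length(x$frequencies), x$n_values, x$frequencies[[1]]))
  invisible(x)
}

#' @describeIn build_histogram Tidy a slide histogram into a `(bin,
#'   frequency)` tibble.
#' @param x A `slide_histogram`.
#' @param ... Unused.
#' @export
tidy.slide_histogram <- function(x, ...) {
  tibble::tibble(bin = as.integer(names(x$frequencies)),
                 frequency = unname(x$frequencies),
                 kind = x$kind)
}

#' Concatenated dual-stain feature vector
#'
#' Joins a slide's mitotic-activity histogram (49 bins) and Ki-67 histogram
#' (101 bins) into a single 150-dimensional feature vector for a single
#' classifier over both stains.
#'
#' @param mitotic A `slide_histogram` of kind `"mitotic"`.
#' @param ki67 A `slide_histogram` of kind `"ki67"`.
#' @return Named numeric vector of length 150 (`mito_00..mito_48`,
#'   `ki67_000..ki67_100`).
#' @export
concat_features <- function(mitotic, ki67) {
  if (is.null(mitotic) || is.null(ki67))
    abort("both stains are required; fall back to a single-stain model")
  stopifnot(inherits(mitotic, "slide_histogram"),
            inherits(ki67, "slide_histogram"))
  if (mitotic$kind != "mitotic" || ki67$kind != "ki67")
    abort("arguments must be a mitotic and a ki67 histogram, in that order")
  setNames(c(mitotic$frequencies, ki67$frequencies), feature_names())
}

feature_names <- function() {
  c(sprintf("mito_%02d", 0:48), sprintf("ki67_%03d", 0:100))
}

#' Majority vote over patch-level grade predictions
#'
#' Slide-level roll-up of per-patch grade calls: the modal grade, with ties
#' broken toward the higher grade (the clinical convention that the highest
#' grade takes precedence).
#'
#' @param patch_grades Vector of grades in `{1, 2, 3}`.
#' @return A single grade (integer).
#' @export
#' @examples
#' majority_vote(c(1, 1, 2)) # 1
#' majority_vote(c(2, 3))    # 3
majority_vote <- function(patch_grades) {
  g <- as_grade(patch_grades)
  if (length(g) == 0) abort("no patch grades supplied")
  counts <- tabulate(g, nbins = 3)
  max(which(counts == max(counts)))  # highest grade wins ties
}
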