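#' Read an RGB image patch from PNG or TIFF
#'
#' @param path Path to an 8-bit PNG or TIFF image.
#' @return Numeric array `rows x cols x channels`, values in \[0, 1\].
#' @export
read_patch <- function(path) {
  if (!file.exists(path)) abort(sprintf("patch file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                abort(sprintf("unsupported image format '.%s': %s", ext, path)))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img
}

#' Write an RGB patch to PNG
#'
#' @param image Array `rows x cols x 3`, values in \[0, 1\].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_patch <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read a detection table (CSV or JSON)
#'
#' The CSV dialect is fixed: comma-separated, UTF-8, header `x,y,score`,
#' 0-based level-0 pixel coordinates with `x` along columns. JSON files
#' hold a list of objects with the same fields.
#'
#' @param path Path to a `.csv` or `.json` detection file.
#' @return A tibble with columns `x`, `y`, `score`.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) abort(sprintf("detection file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  d <- if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else if (ext == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else abort(sprintf("unsupported detection format '.%s'", ext))
  if (!all(c("x", "y") %in% names(d)))
    abort("detection file must have columns x and y")
  if (!"score" %in% names(d)) d$score <- 1
  tibble::as_tibble(d[c("x", "y", "score")])
}

#' @rdname read_detections
#' @param detections Data frame with `x`, `y`, `score`.
#' @param path Output path (`.csv` or `.json`).
#' @export
write_detections <- function(detections, path) {
  ext <- tolower(tools::file_ext(path))
  d <- detections[c("x", "y", "score")]
  if (ext == "csv") readr::write_csv(d, path)
  else if (ext == "json")
    jsonlite::write_json(d, path, dataframe = "rows", digits = NA)
  else abort(sprintf("unsupported detection format '.%s'", ext))
  invisible(path)
}

#' Read MIDOG-style (COCO-like) mitotic-figure annotations
#'
#' Parses an annotation JSON with `images`, `annotations` (bounding boxes)
#' and `categories` tables, keeps only annotations whose category is a
#' mitotic figure (the category table is consulted at parse time — ids are
#' never hard-coded; names such as "non-mitotic figure", "not mitotic
#' figure", "hard negative" or "impostor" are excluded), and reduces each
#' box to its centre point.
#'
#' @param path Path to the annotation JSON.
#' @return A tibble: `image_id`, `file_name` (if present), `x`, `y`
#'   (box-centre pixel coordinates), `score` (1).
#' @export
read_midog_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  j <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                error = function(e) abort(sprintf(
                  "malformed annotation JSON %s: %s", path, conditionMessage(e))))
  if (is.null(j$categories) || is.null(j$annotations))
    abort("annotation file lacks a categories or annotations table")
  cats <- tibble::as_tibble(j$categories)
  nm <- tolower(cats$name)
  mitotic_ids <- cats$id[grepl("mitotic", nm) &
                           !grepl("non|not|hard|impostor|imposter", nm)]
  if (length(mitotic_ids) == 0)
    abort("no mitotic-figure category found in the category table")
  ann <- tibble::as_tibble(j$annotations)
  ann <- ann[ann$category_id %in% mitotic_ids, , drop = FALSE]
  bbox <- do.call(rbind, lapply(ann$bbox, as.numeric))
  out <- tibble::tibble(image_id = ann$image_id,
                        x = if (nrow(ann)) bbox[, 1] + bbox[, 3] / 2 else numeric(),
                        y = if (nrow(ann)) bbox[, 2] + bbox[, 4] / 2 else numeric(),
                        score = rep(1, nrow(ann)))
  if (!is.null(j$images) && !is.null(j$images$file_name)) {
    imgs <- tibble::tibble(image_id = j$images$id,
                           file_name = j$images$file_name)
    out <- dplyr::left_join(out, imgs, by = "image_id")
    out <- out[c("image_id", "file_name", "x", "y", "score")]
  }
  message(sprintf("read %d mitotic-figure annotations from %s",
                  nrow(out), basename(path)))
  out
}

#' Read a tumour/tissue mask and pool it to the patch grid
#'
#' Accepts a grid-resolution mask (one pixel per grid cell, passed through)
#' or a pixel-resolution mask whose dimensions are an integer multiple of
#' the grid; pixel masks are pooled by mean coverage, a cell participating
#' when at least half its pixels are foreground.
#'
#' @param path Path to a PNG/TIFF mask (nonzero = tissue/tumour).
#' @param grid A [patch_grid()].
#' @param min_coverage Minimum within-cell foreground fraction (default 0.5).
#' @return Logical matrix `n_rows x n_cols`.
#' @export
read_mask <- function(path, grid, min_coverage = 0.5) {
  stopifnot(inherits(grid, "patch_grid"))
  img <- read_patch(path)
  m <- img[, , 1] > 0.5
  pool_mask(m, grid, min_coverage)
}

pool_mask <- function(m, grid, min_coverage = 0.5) {
  if (all(dim(m) == c(grid$n_rows, grid$n_cols))) return(m)
  if (nrow(m) %% grid$n_rows != 0 || ncol(m) %% grid$n_cols != 0)
    abort(sprintf("mask %d x %d is not an integer multiple of the %d x %d grid",
                  nrow(m), ncol(m), grid$n_rows, grid$n_cols))
  br <- nrow(m) %/% grid$n_rows; bc <- ncol(m) %/% grid$n_cols
  rgrp <- rep(1:grid$n_rows, each = br)
  cgrp <- rep(1:grid$n_cols, each = bc)
  sums <- rowsum(t(rowsum(m + 0, rgrp)), cgrp)  # n_cols x n_rows
  t(sums) / (br * bc) >= min_coverage
}

#' Serialise a slide histogram
#'
#' CSV form is a `(bin, frequency)` table; JSON keeps kind and counts.
#'
#' @param hist A `slide_histogram`.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "slide_histogram"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    readr::write_csv(tidy(hist)[c("bin", "frequency")], path)
  } else if (ext == "json") {
    jsonlite::write_json(list(kind = hist$kind, n_values = hist$n_values,
                              bin = as.integer(names(hist$frequencies)),
                              frequency = unname(hist$frequencies)),
                         path, auto_unbox = TRUE, digits = NA)
  } else abort(sprintf("unsupported histogram format '.%s'", ext))
  invisible(path)
}

#' @rdname write_histogram
#' @param kind Histogram kind, required when reading from CSV.
#' @export
read_histogram <- function(path, kind = c("mitotic", "ki67")) {
  if (!file.exists(path)) abort(sprintf("histogram file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    kind <- match.arg(kind)
    d <- readr::read_csv(path, show_col_types = FALSE)
    freq <- setNames(d$frequency, d$bin)
    n <- NA_integer_
  } else {
    j <- jsonlite::fromJSON(path)
    kind <- j$kind
    freq <- setNames(j$frequency, j$bin)
    n <- j$n_values
  }
  structure(list(frequencies = freq, kind = kind, n_values = n),
            class = "slide_histogram")
}

#' Write a density map as CSV and an optional heatmap PNG
#'
#' @param map A `density_map`.
#' @param csv_path Output CSV path (a plain 2D table, `NA` for missing).
#' @param png_path Optional heatmap PNG path (linear grayscale, white =
#'   maximum, missing cells black).
#' @return `csv_path`, invisibly.
#' @export
write_density_map <- function(map, csv_path, png_path = NULL) {
  stopifnot(inherits(map, "density_map"))
  utils::write.table(map$values, csv_path, sep = ",", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  if (!is.null(png_path)) {
    v <- map$values
    hi <- max(v, na.rm = TRUE)
    img <- v / max(hi, 1e-12)
    img[is.na(img)] <- 0
    png::writePNG(img, png_path)
  }
  invisible(csv_path)
}

#' @rdname write_density_map
#' @param kind Map kind of the CSV being read.
#' @param window_patches Window side recorded on the restored map.
#' @export
read_density_map <- function(csv_path, kind = c("mitotic_2mm2", "ki67_index"),
                             window_patches = 11L) {
  kind <- match.arg(kind)
  if (!file.exists(csv_path)) abort(sprintf("file not found: %s", csv_path))
  v <- as.matrix(utils::read.table(csv_path, sep = ",", na.strings = "NA"))
  dimnames(v) <- NULL
  new_density_map(v, kind, if (kind == "ki67_index") 1L else window_patches)
}

#' Read a cohort table
#'
#' Expected columns: `patient_id`, `slide_id`, `stain` (`HE`/`KI67`),
#' `grade`, `survival_years`, `event`, and optional covariates (`site`,
#' `differentiation`, `metastatic_at_dx`).
#'
#' @param path Cohort CSV path.
#' @return A tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("patient_id", "grade")
  if (!all(need %in% names(d)))
    abort(sprintf("cohort file must contain columns: %s",
                  paste(need, collapse = ", ")))
  d
}

#' Load and validate a run configuration (YAML or JSON)
#'
#' Nested configuration covering the whole pipeline. Unknown top-level keys
#' are rejected to catch typos. Recognised keys: `mpp`, `patch_size_he`,
#' `patch_size_ki67`, `window_area_mm2`, `score_threshold`, `ki67`,
#' `histogram`, `classifier`, `seed`.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` config, or `NULL` for
#'   defaults.
#' @return A named list of configuration values.
#' @export
run_config <- function(path = NULL) {
  defaults <- list(mpp = 0.2525, patch_size_he = 512L,
                   patch_size_ki67 = 1536L, window_area_mm2 = 2,
                   score_threshold = 0.5,
                   ki67 = list(), histogram = list(), classifier = list(),
                   seed = 1L)
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    abort(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  modifyList(defaults, user)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small stable FNV-1a hash; enough to tie artifacts to a config
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}
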