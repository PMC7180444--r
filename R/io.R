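#' Read an 8-bit grayscale B-scan image
#'
#' Reads PNG (or TIFF when the tiff package is available) into a [bscan()]
#' with gray levels in `[0, 255]`. Color images are converted to
#' luminance by channel averaging.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param id Identifier; defaults to the file name without extension.
#' @return A [bscan()].
#' @export
read_bscan <- function(path, id = NULL) {
  if (is.null(id)) id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF needs the tiff package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  bscan(round(arr * 255), id = id)
}

#' Write a B-scan (or mask) as an 8-bit grayscale PNG
#'
#' @param image A [bscan()], numeric matrix in `[0, 255]`, or logical
#'   mask (written as 0/255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bscan_png <- function(image, path) {
  px <- if (is.logical(image)) {
    matrix(as.numeric(image) * 255, nrow(image), ncol(image))
  } else {
    as_bscan(image)$pixels
  }
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Write layer boundaries as CSV
#'
#' Columns: `column`, `ilm_row`, `rpe_row` (1-based).
#'
#' @param boundaries A [layer_boundaries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_boundaries_csv <- function(boundaries, path) {
  readr::write_csv(tidy(boundaries), path)
  invisible(path)
}

#' Read layer boundaries from CSV
#'
#' @param path CSV with columns `column`, `ilm_row`, `rpe_row`.
#' @return A [layer_boundaries()].
#' @export
read_boundaries_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- df[order(df$column), ]
  layer_boundaries(df$ilm_row, df$rpe_row)
}

#' Write a feature table as CSV with the canonical header
#'
#' @param features Tibble from [extract_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Export the feature layout as JSON
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout_json <- function(path) {
  jsonlite::write_json(feature_layout(), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Serialize a ranking as JSON
#'
#' @param ranking An `oct_ranking`.
#' @param path Output path.
#' @param ... Extra provenance fields stored alongside (e.g. seed, fold).
#' @return `path`, invisibly.
#' @export
write_ranking_json <- function(ranking, path, ...) {
  payload <- c(
    list(
      selector = attr(ranking, "selector"),
      indices = ranking$index,
      scores = ranking$score,
      feature_names = ranking$name
    ),
    list(...)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
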