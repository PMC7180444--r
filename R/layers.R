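#' Normalized vertical intensity gradient
#'
#' Per-pixel vertical derivative of the requested polarity, min-max
#' normalized to `[0, 1]`. The image is first smoothed with a small
#' separable Gaussian (5-pixel wide, sigma 1) so speckle does not dominate
#' the derivative; central differences are used in the interior and
#' one-sided differences at the first and last row. Dark-to-light keeps the
#' positive part of the downward derivative (intensity increasing with row
#' index), light-to-dark the negative part.
#'
#' @param image A [bscan()] or numeric matrix of gray levels.
#' @param polarity `"dark_to_light"` (default) or `"light_to_dark"`.
#' @param smooth Apply the Gaussian pre-smoothing (default `TRUE`).
#' @return A numeric matrix in `[0, 1]` with the shape of the image; an
#'   all-constant image gives an all-zero gradient.
#' @export
vertical_gradient <- function(image,
                              polarity = c("dark_to_light", "light_to_dark"),
                              smooth = TRUE) {
  polarity <- match.arg(polarity)
  px <- as_bscan(image)$pixels
  if (smooth) px <- smooth_separable(px, gaussian_kernel_1d(5L, 1))
  h <- nrow(px)
  g <- matrix(0, h, ncol(px))
  if (h >= 3L) {
    g[2:(h - 1L), ] <- (px[3:h, , drop = FALSE] -
                          px[1:(h - 2L), , drop = FALSE]) / 2
  }
  g[1L, ] <- px[2L, ] - px[1L, ]
  g[h, ] <- px[h, ] - px[h - 1L, ]
  if (polarity == "light_to_dark") g <- -g
  g <- pmax(g, 0)
  top <- max(g)
  if (top == 0) return(g)
  bottom <- min(g)
  if (top > bottom) (g - bottom) / (top - bottom) else g / top
}

#' Edge weight between two pixels from their gradients
#'
#' `2 - (gradient_a + gradient_b) + w_min`: strictly positive for gradients
#' in `[0, 1]` and decreasing in both gradients, so strong dark-to-light
#' boundaries are the cheapest to traverse.
#'
#' @param gradient_a,gradient_b Gradient values in `[0, 1]` (vectorized).
#' @param w_min Small positive stabilizer (default `1e-5`).
#' @return Numeric edge weights.
#' @export
edge_weights <- function(gradient_a, gradient_b, w_min = 1e-5) {
  2 - (gradient_a + gradient_b) + w_min
}

#' Minimum-cost left-to-right path over a gradient image
#'
#' Dijkstra's algorithm on the pixel lattice: column-advancing moves
#' `{(+1,-1),(+1,0),(+1,+1)}` plus vertical moves within a column, edge
#' weights from [edge_weights()], and virtual endpoints so the path may
#' start and end at any row (each endpoint link costs `w_min`). Ties are
#' broken deterministically by `(cost, row, col)` extraction order.
#'
#' @param gradient Numeric matrix in `[0, 1]`.
#' @param w_min Small positive stabilizer (default `1e-5`).
#' @param blocked Optional logical matrix marking pixels the path may not
#'   enter.
#' @return A list with `rows` (per-column exit row of the path, 1-based
#'   integer vector of length `ncol(gradient)`), `cost` (total path cost
#'   including both endpoint links), and `path` (tibble of the visited
#'   pixels in order, columns `row` and `col`).
#' @export
shortest_path <- function(gradient, w_min = 1e-5, blocked = NULL) {
  if (!is.matrix(gradient) || ncol(gradient) < 2L) {
    stop("`gradient` must be a matrix with at least 2 columns", call. = FALSE)
  }
  if (is.null(blocked)) {
    blocked <- matrix(FALSE, nrow(gradient), ncol(gradient))
  }
  res <- lattice_dijkstra(gradient, w_min, blocked)
  path <- tibble::tibble(row = res$path[, 1], col = res$path[, 2])
  # exit row: last visited row within each column (path order)
  rows <- integer(ncol(gradient))
  rows[path$col] <- path$row   # later occurrences overwrite earlier ones
  list(rows = rows, cost = res$cost, path = path)
}

#' Segment the ILM and RPE boundaries
#'
#' Finds the two strongest dark-to-light boundaries of a B-scan: the first
#' shortest path over the vertical dark-to-light gradient, then a second
#' path after excluding a band of `exclusion_margin` rows on each side of
#' the first. The upper path is assigned to the inner limiting membrane
#' (ILM), the lower one to the retinal pigment epithelium (RPE).
#'
#' @inheritParams vertical_gradient
#' @param exclusion_margin Half-height in rows of the band excluded around
#'   the first path before the second search (default 10).
#' @param w_min Small positive stabilizer for edge weights.
#' @return A `layer_boundaries` object: list with integer vectors `ilm_row`
#'   and `rpe_row` (per-column, 1-based) and the image `width`.
#' @export
#' @examples
#' p <- generate_bscan(phantom_spec(seed = 3, speckle_shape = Inf))
#' b <- segment_ilm_rpe(p$image)
#' mean(abs(b$ilm_row - p$truth$ilm_true))
segment_ilm_rpe <- function(image, exclusion_margin = 10L, w_min = 1e-5,
                            smooth = TRUE) {
  img <- as_bscan(image)
  g <- vertical_gradient(img, "dark_to_light", smooth = smooth)
  p1 <- shortest_path(g, w_min = w_min)
  h <- nrow(g); w <- ncol(g)
  blocked <- matrix(FALSE, h, w)
  for (c in seq_len(w)) {
    lo <- max(1L, p1$rows[c] - exclusion_margin)
    hi <- min(h, p1$rows[c] + exclusion_margin)
    blocked[lo:hi, c] <- TRUE
  }
  p2 <- tryCatch(
    shortest_path(g, w_min = w_min, blocked = blocked),
    error = function(e) {
      stop(segmentation_failure(
        "second boundary search found no feasible path", p1$rows, NULL
      ))
    }
  )
  if (mean(p1$rows) <= mean(p2$rows)) {
    ilm <- p1$rows; rpe <- p2$rows
  } else {
    ilm <- p2$rows; rpe <- p1$rows
  }
  if (any(ilm >= rpe)) {
    stop(segmentation_failure(
      "ILM and RPE paths collide", p1$rows, p2$rows
    ))
  }
  layer_boundaries(ilm, rpe)
}

segmentation_failure <- function(msg, path1, path2) {
  structure(
    class = c("octcyst_segmentation_failure", "error", "condition"),
    list(message = msg, call = sys.call(-1), path1 = path1, path2 = path2)
  )
}

#' Construct a layer-boundaries object
#'
#' @param ilm_row,rpe_row Integer vectors of per-column row indices
#'   (1-based), one value per image column, with `ilm_row < rpe_row`
#'   everywhere.
#' @return A `layer_boundaries` object.
#' @export
layer_boundaries <- function(ilm_row, rpe_row) {
  if (length(ilm_row) != length(rpe_row)) {
    stop("ilm_row and rpe_row must have the same length", call. = FALSE)
  }
  if (any(ilm_row >= rpe_row)) {
    stop("layer_boundaries invariant violated: ilm_row < rpe_row for ",
         "every column", call. = FALSE)
  }
  structure(
    list(ilm_row = as.integer(ilm_row), rpe_row = as.integer(rpe_row),
         width = length(ilm_row)),
    class = "layer_boundaries"
  )
}

#' @export
print.layer_boundaries <- function(x, ...) {
  cat(sprintf(
    "<layer_boundaries> %d columns; ILM rows %d-%d, RPE rows %d-%d\n",
    x$width, min(x$ilm_row), max(x$ilm_row), min(x$rpe_row), max(x$rpe_row)
  ))
  invisible(x)
}

#' @export
tidy.layer_boundaries <- function(x, ...) {
  tibble::tibble(
    column = seq_len(x$width), ilm_row = x$ilm_row, rpe_row = x$rpe_row
  )
}

#' Region-of-interest mask between the ILM and the RPE
#'
#' @param boundaries A [layer_boundaries()] object.
#' @param shape Integer vector `c(height, width)` of the target image.
#' @return A logical matrix: `TRUE` where
#'   `ilm_row[c] <= r <= rpe_row[c]`.
#' @export
roi_mask <- function(boundaries, shape) {
  h <- shape[1]; w <- shape[2]
  if (boundaries$width != w) {
    stop("boundaries are defined for ", boundaries$width,
         " columns, image has ", w, call. = FALSE)
  }
  rows <- matrix(seq_len(h), h, w)
  rows >= matrix(boundaries$ilm_row, h, w, byrow = TRUE) &
    rows <= matrix(boundaries$rpe_row, h, w, byrow = TRUE)
}
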