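#' Extract overlapping square window centers inside the ROI
#'
#' Centers form a deterministic raster grid (row-major, `stride` apart)
#' restricted to positions whose `W x W` block lies fully inside the image
#' and whose center pixel is inside the ROI. No padding is used: blocks near
#' the border that would fall outside the image are skipped.
#'
#' @param image A [bscan()] or numeric matrix.
#' @param roi Logical ROI mask with the shape of the image.
#' @param W Odd window side in pixels (default 61).
#' @param stride Grid step in pixels, `1 <= stride <= W` (default
#'   `round(W / 2)`).
#' @return A tibble with one row per sample: `source_id`, `row`, `col`
#'   (1-based centers) and `W`. Empty (with a warning) if no window fits.
#' @export
extract_windows <- function(image, roi, W = 61L, stride = round(W / 2)) {
  img <- as_bscan(image)
  px <- img$pixels
  W <- as.integer(W); stride <- as.integer(stride)
  if (W %% 2L == 0L) stop("`W` must be odd", call. = FALSE)
  if (stride < 1L || stride > W) {
    stop("`stride` must be in [1, W]", call. = FALSE)
  }
  if (!identical(dim(roi), dim(px))) {
    stop("`roi` must have the shape of the image", call. = FALSE)
  }
  half <- (W - 1L) %/% 2L
  if (W > nrow(px) || W > ncol(px)) {
    warning("window size exceeds the image; no samples extracted")
    return(empty_sample_tbl())
  }
  ctr_rows <- seq.int(half + 1L, nrow(px) - half, by = stride)
  ctr_cols <- seq.int(half + 1L, ncol(px) - half, by = stride)
  grid <- expand.grid(col = ctr_cols, row = ctr_rows)[, c("row", "col")]
  keep <- roi[cbind(grid$row, grid$col)]
  tibble::tibble(
    source_id = img$id,
    row = as.integer(grid$row[keep]),
    col = as.integer(grid$col[keep]),
    W = W
  )
}

empty_sample_tbl <- function() {
  tibble::tibble(
    source_id = character(), row = integer(), col = integer(), W = integer()
  )
}

#' Extract the pixel block of a sample
#'
#' @param image A [bscan()] or numeric matrix.
#' @param row,col 1-based center of the window.
#' @param W Odd window side.
#' @return A `W x W` numeric matrix.
#' @export
window_block <- function(image, row, col, W = 61L) {
  px <- as_bscan(image)$pixels
  half <- (W - 1L) %/% 2L
  if (row - half < 1L || row + half > nrow(px) ||
      col - half < 1L || col + half > ncol(px)) {
    stop("window does not fit inside the image", call. = FALSE)
  }
  px[(row - half):(row + half), (col - half):(col + half), drop = FALSE]
}

# Sub-mask of any full-image logical mask under a window.
window_submask <- function(mask, row, col, W) {
  half <- (W - 1L) %/% 2L
  mask[(row - half):(row + half), (col - half):(col + half), drop = FALSE]
}

#' Label one window as cystoid or non-cystoid
#'
#' A window is cystoid iff the fraction of ROI pixels inside the block that
#' belong to the cyst mask reaches `tau`:
#' `(#cyst & roi pixels) / (#roi pixels) >= tau`.
#'
#' @param block_roi Logical `W x W` ROI sub-mask of the window.
#' @param block_cyst Logical `W x W` cyst sub-mask of the window.
#' @param tau Fraction threshold in `(0, 1]` (default 0.05).
#' @return `"cystoid"` or `"non_cystoid"`.
#' @export
label_window <- function(block_roi, block_cyst, tau = 0.05) {
  n_roi <- sum(block_roi)
  if (n_roi == 0L) {
    stop("cannot label a window with an empty ROI sub-mask", call. = FALSE)
  }
  frac <- sum(block_cyst & block_roi) / n_roi
  if (frac >= tau) "cystoid" else "non_cystoid"
}

#' Largest all-true axis-aligned rectangle inside a mask
#'
#' Maximum-area rectangle of `TRUE` cells; ties are broken by smallest
#' `(top, left)`. Uses the histogram-of-heights stack algorithm, O(rows x
#' cols).
#'
#' @param mask Logical matrix with at least one `TRUE` cell.
#' @return A list `(top, left, height, width)`, 1-based.
#' @export
max_inscribed_rect <- function(mask) {
  if (!any(mask)) {
    stop("mask has no TRUE cell; no inscribed rectangle exists",
         call. = FALSE)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  heights <- integer(nc)
  best <- list(area = 0L, top = NA_integer_, left = NA_integer_,
               height = 0L, width = 0L)
  consider <- function(top, left, height, width) {
    area <- height * width
    if (area > best$area ||
        (area == best$area &&
           (top < best$top || (top == best$top && left < best$left)))) {
      best <<- list(area = area, top = top, left = left,
                    height = height, width = width)
    }
  }
  for (r in seq_len(nr)) {
    heights <- ifelse(mask[r, ], heights + 1L, 0L)
    # largest rectangle in histogram, with sentinel column
    hh <- c(heights, 0L)
    stack_pos <- integer(0); stack_h <- integer(0)
    for (j in seq_along(hh)) {
      start <- j
      while (length(stack_h) && tail(stack_h, 1L) > hh[j]) {
        k <- length(stack_h)
        consider(
          top = r - stack_h[k] + 1L, left = stack_pos[k],
          height = stack_h[k], width = j - stack_pos[k]
        )
        start <- stack_pos[k]
        stack_pos <- stack_pos[-k]; stack_h <- stack_h[-k]
      }
      if (!length(stack_h) || tail(stack_h, 1L) < hh[j]) {
        stack_pos <- c(stack_pos, start); stack_h <- c(stack_h, hh[j])
      }
    }
  }
  best[c("top", "left", "height", "width")]
}

#' Build a labeled sample table from images with ground truth
#'
#' Runs the full sampling chain over a collection of images: delimit the
#' retina (either by graph-search segmentation or from the true
#' boundaries), extract windows, and label them against the cyst masks.
#' Optionally down-samples the majority class to near-balance.
#'
#' @param dataset A list of `(image, truth)` pairs as returned by
#'   [generate_dataset()], or any list with elements `image` ([bscan()])
#'   and `truth` (list with `cyst_mask` and, when
#'   `boundaries = "truth"`, `ilm_true`/`rpe_true`).
#' @param W,stride,tau Sampling parameters, see [extract_windows()] and
#'   [label_window()].
#' @param balance Down-sample the majority class to the minority count
#'   (seeded, reproducible).
#' @param boundaries `"segment"` (default) to delimit the ROI with
#'   [segment_ilm_rpe()], or `"truth"` to use the ground-truth boundaries.
#' @param seed Seed for the balancing down-sample.
#' @param rois Optional precomputed ROI masks from [compute_rois()]
#'   (avoids re-segmenting when the masks are reused downstream).
#' @return A tibble with columns `source_id`, `row`, `col`, `W`, `label`.
#'   Images where segmentation fails are skipped with a warning.
#' @export
build_dataset <- function(dataset, W = 61L, stride = round(W / 2),
                          tau = 0.05, balance = TRUE,
                          boundaries = c("segment", "truth"), seed = 1L,
                          rois = NULL) {
  boundaries <- match.arg(boundaries)
  if (!length(dataset)) stop("need at least one labeled image", call. = FALSE)
  if (is.null(rois)) rois <- compute_rois(dataset, boundaries)
  tables <- lapply(dataset, function(item) {
    img <- item$image
    truth <- item$truth
    roi <- rois[[img$id]]
    if (is.null(roi)) return(empty_sample_tbl())
    samples <- extract_windows(img, roi, W = W, stride = stride)
    if (!nrow(samples)) return(empty_sample_tbl())
    samples$label <- vapply(seq_len(nrow(samples)), function(i) {
      label_window(
        window_submask(roi, samples$row[i], samples$col[i], W),
        window_submask(truth$cyst_mask, samples$row[i], samples$col[i], W),
        tau = tau
      )
    }, character(1))
    samples
  })
  tbl <- dplyr::bind_rows(tables)
  if (!nrow(tbl)) stop("no samples could be extracted", call. = FALSE)
  counts <- table(factor(tbl$label, levels = c("cystoid", "non_cystoid")))
  if (balance) {
    missing_cls <- names(counts)[counts == 0]
    if (length(missing_cls)) {
      stop("cannot balance: class '", missing_cls[1],
           "' is absent from the sample table", call. = FALSE)
    }
    n_min <- min(counts)
    tbl <- withr::with_seed(
      derive_seed(seed, 17L),
      tbl |>
        dplyr::group_by(.data$label) |>
        dplyr::slice_sample(n = n_min) |>
        dplyr::ungroup() |>
        dplyr::arrange(.data$source_id, .data$row, .data$col)
    )
  }
  tbl
}

#' Compute ROI masks for a dataset
#'
#' Delimits the retina of every image either by graph-search segmentation
#' ([segment_ilm_rpe()]) or from the ground-truth boundaries, returning a
#' named list of logical ROI masks keyed by image id. Images where
#' segmentation fails get a `NULL` entry with a warning.
#'
#' @inheritParams build_dataset
#' @return Named list of logical matrices (or `NULL` for failures).
#' @export
compute_rois <- function(dataset, boundaries = c("segment", "truth")) {
  boundaries <- match.arg(boundaries)
  out <- lapply(dataset, function(item) {
    img <- item$image
    bnd <- if (boundaries == "truth") {
      layer_boundaries(item$truth$ilm_true, item$truth$rpe_true)
    } else {
      tryCatch(
        segment_ilm_rpe(img),
        octcyst_segmentation_failure = function(e) {
          warning("segmentation failed for image '", img$id, "': ",
                  conditionMessage(e), "; image skipped")
          NULL
        }
      )
    }
    if (is.null(bnd)) NULL else roi_mask(bnd, dim(img))
  })
  stats::setNames(out, vapply(dataset, function(it) it$image$id, character(1)))
}
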