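#' Full 510-value window descriptor
#'
#' Concatenates the eleven category extractors in canonical layout order
#' (see [feature_layout()]): GIBS, AIS, eigen-spectrum, LESH, GLCM, HOG,
#' Gabor, LBP, Laws, fractal (DBC) and GLRL. All categories operate on the
#' full pixel block except the eigen-spectrum features, which are
#' restricted to the largest rectangle inscribed in the ROI sub-mask. The
#' result is a pure function of `(block, roi_sub)`.
#'
#' @param block `W x W` numeric matrix of gray levels (W of at least 17;
#'   61 recommended).
#' @param roi_sub Logical ROI membership matrix, same shape; defaults to
#'   all `TRUE`.
#' @return Named numeric vector of length 510, all values finite.
#' @export
#' @examples
#' fv <- extract_features(matrix(runif(61 * 61, 0, 255), 61, 61))
#' length(fv)
extract_features <- function(block, roi_sub = NULL) {
  if (is.null(roi_sub)) roi_sub <- matrix(TRUE, nrow(block), ncol(block))
  parts <- list(
    GIBS = function() extract_gibs(block),
    AIS = function() extract_ais(block),
    EIG = function() extract_eigen(block, roi_sub),
    LESH = function() extract_lesh(block),
    GLCM = function() extract_glcm(block),
    HOG = function() extract_hog(block),
    GABOR = function() extract_gabor(block),
    LBP = function() extract_lbp(block),
    LAWS = function() extract_laws(block),
    FD = function() extract_fd(block),
    GLRL = function() extract_glrl(block)
  )
  out <- lapply(names(parts), function(cat) {
    v <- tryCatch(parts[[cat]](), error = function(e) {
      stop("feature category ", cat, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
    if (!all(is.finite(v))) {
      stop("feature category ", cat, " produced non-finite values",
           call. = FALSE)
    }
    v
  })
  vec <- unlist(out)
  stopifnot(length(vec) == 510L)
  vec
}

#' Feature table for a sample set
#'
#' Extracts the 510-value descriptor for every sample in a table produced
#' by [build_dataset()] (or [extract_windows()]), returning one row per
#' sample with the metadata columns followed by the 510 feature columns in
#' canonical order.
#'
#' @param dataset The image list the samples refer to (see
#'   [build_dataset()]); `source_id`s must match the image ids.
#' @param samples Tibble with `source_id`, `row`, `col`, `W` (and
#'   optionally `label`).
#' @param rois Optional named list of ROI masks (one per image id) used
#'   for the eigen-feature ROI restriction; computed with
#'   [segment_ilm_rpe()] when missing.
#' @return A tibble: the columns of `samples` plus 510 feature columns.
#' @export
extract_feature_table <- function(dataset, samples, rois = NULL) {
  images <- stats::setNames(
    lapply(dataset, function(it) it$image),
    vapply(dataset, function(it) it$image$id, character(1))
  )
  missing_ids <- setdiff(unique(samples$source_id), names(images))
  if (length(missing_ids)) {
    stop("samples reference unknown image ids: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (is.null(rois)) {
    rois <- lapply(images, function(img) {
      roi_mask(segment_ilm_rpe(img), dim(img))
    })
  }
  feats <- lapply(seq_len(nrow(samples)), function(i) {
    id <- samples$source_id[i]
    w <- samples$W[i]
    block <- window_block(images[[id]], samples$row[i], samples$col[i], w)
    roi_sub <- window_submask(rois[[id]], samples$row[i], samples$col[i], w)
    extract_features(block, roi_sub)
  })
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(samples, tibble::as_tibble(mat))
}
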