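#' Global intensity-based statistics (GIBS, 15 values)
#'
#' Maximum, minimum, mean, median, standard deviation, variance (population
#' convention), Shannon entropy in bits over the 256-level gray histogram,
#' 25th and 75th percentiles, and a normal-distribution fit: the maximum
#' likelihood estimates of mu and sigma followed by their 95% confidence
#' bounds (mu lower/upper from the t distribution, sigma lower/upper from
#' the chi-squared distribution of the sample variance).
#'
#' @param block Numeric matrix of gray levels.
#' @return Named numeric vector of length 15.
#' @export
extract_gibs <- function(block) {
  x <- as.numeric(block)
  n <- length(x)
  mu <- mean(x)
  s_pop <- pop_sd(x)
  s_smp <- if (n > 1) sd(x) else 0
  if (n > 1 && s_smp > 0) {
    half <- qt(0.975, n - 1) * s_smp / sqrt(n)
    mu_ci <- c(mu - half, mu + half)
    sig_ci <- s_smp * sqrt((n - 1) / qchisq(c(0.975, 0.025), n - 1))
  } else {
    mu_ci <- c(mu, mu)
    sig_ci <- c(0, 0)
  }
  out <- c(
    max(x), min(x), mu, median(x), s_pop, pop_var(x), shannon_entropy(x),
    quantile(x, 0.25, names = FALSE), quantile(x, 0.75, names = FALSE),
    mu, s_pop, mu_ci[1], mu_ci[2], sig_ci[1], sig_ci[2]
  )
  names(out) <- feature_names_for("GIBS")
  out
}

#' Axis intensity statistics (AIS, 12 values)
#'
#' Skewness and kurtosis (plain `m4/m2^2`, population moments) of every row
#' ("horizontal", statistics along each row) and every column ("vertical"),
#' collapsed to min, mean and max over the resulting series. Zero-variance
#' rows/columns contribute 0 to both moments. Slot order: minima, means,
#' maxima; within each group (skew-horizontal, skew-vertical,
#' kurt-horizontal, kurt-vertical).
#'
#' @param block Numeric matrix with at least 2 rows and 2 columns.
#' @return Named numeric vector of length 12.
#' @export
extract_ais <- function(block) {
  if (nrow(block) < 2L || ncol(block) < 2L) {
    stop("AIS needs a block with at least 2 rows and 2 columns",
         call. = FALSE)
  }
  skew_h <- apply(block, 1L, moment_skew)
  skew_v <- apply(block, 2L, moment_skew)
  kurt_h <- apply(block, 1L, moment_kurt)
  kurt_v <- apply(block, 2L, moment_kurt)
  series <- list(skew_h, skew_v, kurt_h, kurt_v)
  out <- c(
    vapply(series, min, numeric(1)),
    vapply(series, mean, numeric(1)),
    vapply(series, max, numeric(1))
  )
  names(out) <- feature_names_for("AIS")
  out
}

#' Eigen-spectrum features of the inscribed ROI rectangle (28 values)
#'
#' Spectral magnitudes are the singular values of the column-mean-centered
#' pixel rectangle — the largest all-true rectangle inscribed in `roi_sub`
#' ([max_inscribed_rect()]). When the rectangle is not square, a sliding
#' square window (side = the shorter rectangle side, stride = half a side)
#' is moved inside it and the per-window sorted spectra are averaged
#' element-wise. Emitted: the 4 largest magnitudes (descending), the 4
#' smallest (ascending), the 25th and 75th percentiles of the full
#' spectrum, the 16 pairwise ratios `max_i / min_j` (`i` major), and the
#' ratios `max1/max4` and `min1/min4`; any `x/0` or `0/0` ratio maps to 0.
#'
#' @param block Numeric matrix (the window's pixels).
#' @param roi_sub Logical matrix of ROI membership, same shape as `block`;
#'   defaults to all `TRUE`.
#' @return Named numeric vector of length 28. Rectangles smaller than 4x4
#'   produce a zero-padded degenerate spectrum with a warning.
#' @export
extract_eigen <- function(block, roi_sub = NULL) {
  if (is.null(roi_sub)) roi_sub <- matrix(TRUE, nrow(block), ncol(block))
  rect <- max_inscribed_rect(roi_sub)
  sub <- block[
    rect$top:(rect$top + rect$height - 1L),
    rect$left:(rect$left + rect$width - 1L),
    drop = FALSE
  ]
  if (rect$height < 4L || rect$width < 4L) {
    warning("inscribed ROI rectangle smaller than 4x4; ",
            "degenerate spectrum padded with zeros")
  }
  spec <- aggregate_spectrum(sub)
  m <- length(spec)                       # sorted descending
  lmax <- c(spec, 0, 0, 0)[1:4]
  smallest <- sort(tail(spec, 4L))        # ascending
  lmin <- c(smallest, 0, 0, 0)[1:4]
  if (m < 4L) lmin <- c(sort(spec), rep(0, 4 - m))[1:4]
  ratios <- as.vector(t(outer(lmax, lmin, safe_ratio)))
  out <- c(
    lmax, lmin,
    quantile(spec, 0.25, names = FALSE), quantile(spec, 0.75, names = FALSE),
    ratios, safe_ratio(lmax[1], lmax[4]), safe_ratio(lmin[1], lmin[4])
  )
  names(out) <- feature_names_for("EIG")
  out
}

# Sorted (descending) singular-value spectrum of the column-centered
# rectangle; non-square rectangles aggregate sliding square windows.
aggregate_spectrum <- function(sub) {
  h <- nrow(sub); w <- ncol(sub)
  sv <- function(m) {
    centered <- sweep(m, 2L, colMeans(m))
    sort(svd(centered, nu = 0L, nv = 0L)$d, decreasing = TRUE)
  }
  if (h == w) return(sv(sub))
  s <- min(h, w)
  stride <- max(1L, as.integer(round(s / 2)))
  starts <- function(total) {
    st <- seq.int(1L, total - s + 1L, by = stride)
    if (tail(st, 1L) != total - s + 1L) st <- c(st, total - s + 1L)
    st
  }
  wins <- if (h > w) {
    lapply(starts(h), function(r0) sub[r0:(r0 + s - 1L), , drop = FALSE])
  } else {
    lapply(starts(w), function(c0) sub[, c0:(c0 + s - 1L), drop = FALSE])
  }
  specs <- vapply(wins, sv, numeric(s))
  if (s == 1L) specs <- matrix(specs, nrow = 1L)
  rowMeans(specs)
}

feature_names_for <- function(cat) {
  layout <- feature_layout()
  layout$name[layout$category == cat]
}
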