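# Package-level cache (feature layout, filter banks keyed by block size).
.octcyst_cache <- new.env(parent = emptyenv())

#' Construct a B-scan object
#'
#' A `bscan` wraps a numeric pixel matrix (gray levels in `[0, 255]`, rows =
#' depth, columns = lateral position / A-scans) together with an identifier.
#'
#' @param pixels Numeric matrix of gray levels in `[0, 255]`.
#' @param id Character identifier for the scan.
#' @return An object of class `bscan`: a list with elements `pixels` and `id`.
#' @export
bscan <- function(pixels, id = "bscan") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 3L || ncol(pixels) < 2L) {
    stop("a B-scan needs at least 3 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must be finite gray levels in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, id = as.character(id)), class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf(
    "<bscan '%s'> %d x %d px, gray range [%g, %g]\n",
    x$id, nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

# Coerce matrices transparently so every image-facing function accepts either
# a bscan or a bare matrix.
as_bscan <- function(image, id = "bscan") {
  if (inherits(image, "bscan")) image else bscan(image, id = id)
}

# Deterministic child-seed derivation: keeps all derived seeds positive and
# strictly below 2^31 so they remain valid R integer seeds.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 2246822519 + 104729) %% 2147483647
  }
  as.integer(s)
}

# Shannon entropy (bits) of a gray-level histogram over 256 integer bins.
shannon_entropy <- function(x) {
  counts <- tabulate(pmin(pmax(floor(x), 0), 255) + 1L, nbins = 256L)
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Population moments helpers (n convention).
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# Skewness / kurtosis with the degenerate-moment convention: zero-variance
# series contribute 0 to both (kurtosis is plain m4/m2^2, not excess).
moment_skew <- function(x) {
  m2 <- pop_var(x)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}
moment_kurt <- function(x) {
  m2 <- pop_var(x)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# Small separable Gaussian smoother with replicated borders.
gaussian_kernel_1d <- function(width = 5L, sigma = 1) {
  half <- (width - 1L) / 2
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k / sum(k)
}

# Pad a matrix by edge replication.
pad_replicate <- function(m, top, bottom = top, left = top, right = left) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, top), seq_len(nr), rep(nr, bottom))
  ci <- c(rep(1L, left), seq_len(nc), rep(nc, right))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a symmetric 1-D kernel, replicate boundary.
smooth_separable <- function(m, k) {
  half <- (length(k) - 1L) %/% 2L
  p <- pad_replicate(m, half)
  # filter columns (vertical pass)
  out <- matrix(0, nrow(p), ncol(p))
  for (i in seq_along(k)) {
    shift <- i - half - 1L
    rows <- seq_len(nrow(p)) + shift
    rows <- pmin(pmax(rows, 1L), nrow(p))
    out <- out + k[i] * p[rows, , drop = FALSE]
  }
  out2 <- matrix(0, nrow(p), ncol(p))
  for (i in seq_along(k)) {
    shift <- i - half - 1L
    cols <- seq_len(ncol(p)) + shift
    cols <- pmin(pmax(cols, 1L), ncol(p))
    out2 <- out2 + k[i] * out[, cols, drop = FALSE]
  }
  out2[(half + 1L):(nrow(p) - half), (half + 1L):(ncol(p) - half), drop = FALSE]
}

# Valid-region 2-D filtering (cross-correlation) with a small kernel:
# out[i,j] = sum_{a,b} k[a,b] * m[i+a-1, j+b-1].
filter2_valid <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(m) - kr + 1L; nc <- ncol(m) - kc + 1L
  if (nr < 1L || nc < 1L) stop("kernel larger than the matrix", call. = FALSE)
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    if (k[a, b] != 0) {
      out <- out + k[a, b] * m[a:(a + nr - 1L), b:(b + nc - 1L), drop = FALSE]
    }
  }
  out
}

# Safe ratio with the 0/0 and x/0 -> 0 convention used across the package.
safe_ratio <- function(a, b) ifelse(b == 0, 0, a / b)
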