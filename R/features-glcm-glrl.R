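#' Gray-level co-occurrence statistics (GLCM, 16 values)
#'
#' Gray levels are quantized to 8 bins by uniform division of `[0, 255]`.
#' For each of the four offsets at distance 2 — 0 degrees `(0,+2)`, 45
#' `(-2,+2)`, 90 `(-2,0)` and 135 `(-2,-2)` (rows grow downward) — a
#' symmetric, sum-normalized co-occurrence matrix is accumulated and four
#' Haralick-style statistics are taken. Emission order follows the layout:
#' contrast at the four angles, then correlation, energy (angular second
#' moment) and homogeneity; a zero-variance matrix maps correlation to 0.
#'
#' @param block Numeric matrix of gray levels, at least 3x3.
#' @param n_levels Number of quantized gray levels (default 8).
#' @return Named numeric vector of length 16.
#' @export
extract_glcm <- function(block, n_levels = 8L) {
  if (nrow(block) < 3L || ncol(block) < 3L) {
    stop("GLCM needs a block of at least 3x3", call. = FALSE)
  }
  q <- quantize_gray(block, n_levels)
  offsets <- list(c(0L, 2L), c(-2L, 2L), c(-2L, 0L), c(-2L, -2L))
  stats <- lapply(offsets, function(off) {
    p <- glcm_matrix(q, off[1], off[2], n_levels)
    glcm_stats(p)
  })
  out <- c(
    vapply(stats, `[[`, numeric(1), "contrast"),
    vapply(stats, `[[`, numeric(1), "correlation"),
    vapply(stats, `[[`, numeric(1), "energy"),
    vapply(stats, `[[`, numeric(1), "homogeneity")
  )
  names(out) <- feature_names_for("GLCM")
  out
}

quantize_gray <- function(block, n_levels, full_range = 256) {
  lv <- floor(block * n_levels / full_range)
  matrix(as.integer(pmin(pmax(lv, 0), n_levels - 1L)) + 1L,
         nrow(block), ncol(block))
}

# Symmetric normalized co-occurrence matrix for one (dr, dc) offset.
glcm_matrix <- function(q, dr, dc, n_levels) {
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - dr):min(nr, nr - dr)
  c0 <- max(1L, 1L - dc):min(nc, nc - dc)
  a <- q[r0, c0, drop = FALSE]
  b <- q[r0 + dr, c0 + dc, drop = FALSE]
  counts <- tabulate((a - 1L) * n_levels + b, nbins = n_levels * n_levels)
  m <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

glcm_stats <- function(p) {
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (s_i == 0 || s_j == 0) 0 else {
    sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
  }
  list(
    contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j)))
  )
}

#' Gray-level run-length statistics (GLRL, 7 values)
#'
#' Gray levels are grouped from 256 into 51 (`floor(g * 51 / 256)`), maximal
#' same-level runs are accumulated along the four orientations 0, 45, 90 and
#' 135 degrees into one summed run-length matrix, and seven standard
#' statistics are emitted in layout order: SRE, LRE, GLN, RP, RLN, LGRE,
#' HGRE. Gray levels are 1-based in the emphasis terms; the run percentage
#' divides the total run count by the pixels scanned over all four
#' orientations.
#'
#' @param block Numeric matrix of gray levels, at least 2x2.
#' @return Named numeric vector of length 7.
#' @export
extract_glrl <- function(block) {
  if (nrow(block) < 2L || ncol(block) < 2L) {
    stop("GLRL needs a block of at least 2x2", call. = FALSE)
  }
  q <- quantize_gray(block, 51L)
  rl <- glrl_matrix(q, orientations = c(0, 45, 90, 135))
  out <- glrl_stats(rl, n_pixels_scanned = 4L * length(q))
  names(out) <- feature_names_for("GLRL")
  out
}

# Run-length matrix (levels x run length) summed over orientations.
glrl_matrix <- function(q, orientations) {
  nr <- nrow(q); nc <- ncol(q)
  lines <- list()
  if (0 %in% orientations) {
    lines <- c(lines, lapply(seq_len(nr), function(r) q[r, ]))
  }
  if (90 %in% orientations) {
    lines <- c(lines, lapply(seq_len(nc), function(c) q[, c]))
  }
  if (45 %in% orientations) {   # anti-diagonals, direction up-right
    lines <- c(lines, split(q[order(row(q) + col(q), -row(q))],
                            sort(as.vector(row(q) + col(q)))))
  }
  if (135 %in% orientations) {  # main diagonals, direction down-right
    lines <- c(lines, split(q[order(col(q) - row(q), row(q))],
                            sort(as.vector(col(q) - row(q)))))
  }
  max_len <- max(nr, nc)
  m <- matrix(0, 51L, max_len)
  for (ln in lines) {
    runs <- rle(as.integer(ln))
    for (k in seq_along(runs$lengths)) {
      m[runs$values[k], runs$lengths[k]] <- m[runs$values[k], runs$lengths[k]] + 1
    }
  }
  m
}

glrl_stats <- function(m, n_pixels_scanned) {
  n_runs <- sum(m)
  lev <- seq_len(nrow(m))
  len <- seq_len(ncol(m))
  p_lev <- rowSums(m)
  p_len <- colSums(m)
  c(
    sre = sum(sweep(m, 2L, len^2, `/`)) / n_runs,
    lre = sum(sweep(m, 2L, len^2, `*`)) / n_runs,
    gln = sum(p_lev^2) / n_runs,
    rp = n_runs / n_pixels_scanned,
    rln = sum(p_len^2) / n_runs,
    lgre = sum(p_lev / lev^2) / n_runs,
    hgre = sum(p_lev * lev^2) / n_runs
  )
}
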