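#' Local binary pattern features (LBP, 64 values)
#'
#' Rotation-variant LBP codes for all 32 combinations of neighbor count
#' `P` in {4, 8, 12, 16} and radius `R` in 1..8. Neighbors are sampled at
#' angles `2 pi p / P` on the circle of radius `R` with bilinear
#' interpolation; bit `p` is set when the interpolated neighbor is `>=`
#' the center. Codes are computed only at pixels whose full neighborhood
#' lies inside the block (no padding), and each code map is summarized by
#' its mean and standard deviation (population convention). Emission: 32
#' means (P-major, radius 1..8 within), then the 32 standard deviations.
#'
#' The comparison is evaluated on interpolated *differences*
#' (`sum w_i (x_i - x_c)`), which makes the features exactly invariant to
#' a global intensity shift.
#'
#' @param block Numeric matrix, at least 17x17 (radius 8 must fit).
#' @return Named numeric vector of length 64.
#' @export
extract_lbp <- function(block) {
  nr <- nrow(block); nc <- ncol(block)
  if (nr < 17L || nc < 17L) {
    stop("LBP needs a block of at least 17x17 (radius 8)", call. = FALSE)
  }
  configs <- expand.grid(R = 1:8, P = c(4L, 8L, 12L, 16L))
  means <- numeric(32L); sds <- numeric(32L)
  for (k in seq_len(nrow(configs))) {
    codes <- lbp_code_map(block, configs$P[k], configs$R[k])
    means[k] <- mean(codes)
    sds[k] <- pop_sd(codes)
  }
  out <- c(means, sds)
  names(out) <- feature_names_for("LBP")
  out
}

#' LBP code map for one (P, R) configuration
#'
#' @param block Numeric matrix.
#' @param P Number of neighbors.
#' @param R Circle radius in pixels.
#' @return Numeric matrix of codes in `[0, 2^P - 1]` over the valid
#'   (interior) pixels.
#' @export
lbp_code_map <- function(block, P, R) {
  nr <- nrow(block); nc <- ncol(block)
  marg <- as.integer(ceiling(R))
  if (nr - 2L * marg < 1L || nc - 2L * marg < 1L) {
    stop("block too small for radius ", R, call. = FALSE)
  }
  rows <- (marg + 1L):(nr - marg)
  cols <- (marg + 1L):(nc - marg)
  centers <- block[rows, cols, drop = FALSE]
  codes <- matrix(0, length(rows), length(cols))
  for (p in 0:(P - 1L)) {
    a <- 2 * pi * p / P
    dr <- R * sin(a)
    dc <- R * cos(a)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    d <- interp_diff(block, rows, cols, dr, dc, centers)
    codes <- codes + (d >= 0) * 2^p
  }
  codes
}

# Bilinear interpolation of block[r + dr, c + dc] minus the center value,
# computed on differences so a global shift cancels exactly.
interp_diff <- function(block, rows, cols, dr, dc, centers) {
  r0 <- floor(dr); c0 <- floor(dc)
  fr <- dr - r0; fc <- dc - c0
  g <- function(ro, co) {
    block[rows + ro, cols + co, drop = FALSE] - centers
  }
  out <- (1 - fr) * (1 - fc) * g(r0, c0)
  if (fc > 0) out <- out + (1 - fr) * fc * g(r0, c0 + 1)
  if (fr > 0) out <- out + fr * (1 - fc) * g(r0 + 1, c0)
  if (fr > 0 && fc > 0) out <- out + fr * fc * g(r0 + 1, c0 + 1)
  out
}
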