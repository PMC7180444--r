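#' Histogram of oriented gradients (HOG, 81 values)
#'
#' A 3x3 cell grid over the block; per cell, a 9-bin histogram of unsigned
#' gradient orientation (bin centers at 0, 20, ..., 160 degrees over
#' `[0, 180)`), weighted by gradient magnitude with linear interpolation
#' between the two nearest bin centers (circular over 180 degrees).
#' Gradients are central differences (one-sided at the borders). Each cell
#' histogram is L2-normalized with `eps = 1e-6` (all-zero cells stay zero);
#' there is no block-overlap renormalization. Emission is row-major over
#' cells, then bins within a cell.
#'
#' @param block Numeric matrix, at least 9x9.
#' @return Named numeric vector of length 81.
#' @export
extract_hog <- function(block) {
  nr <- nrow(block); nc <- ncol(block)
  if (nr < 9L || nc < 9L) stop("HOG needs a block of at least 9x9",
                               call. = FALSE)
  gx <- matrix(0, nr, nc)  # horizontal (along columns)
  gy <- matrix(0, nr, nc)  # vertical (along rows)
  gx[, 2:(nc - 1)] <- (block[, 3:nc] - block[, 1:(nc - 2)]) / 2
  gx[, 1] <- block[, 2] - block[, 1]
  gx[, nc] <- block[, nc] - block[, nc - 1]
  gy[2:(nr - 1), ] <- (block[3:nr, ] - block[1:(nr - 2), ]) / 2
  gy[1, ] <- block[2, ] - block[1, ]
  gy[nr, ] <- block[nr, ] - block[nr - 1, ]

  mag <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) * 180 / pi) %% 180   # unsigned orientation

  pos <- theta / 20                 # fractional bin position, centers at 20b
  b0 <- floor(pos)
  frac <- pos - b0
  b0 <- b0 %% 9       # numeric matrices; dims preserved
  b1 <- (b0 + 1) %% 9
  w0 <- mag * (1 - frac)
  w1 <- mag * frac

  row_grp <- cell_groups(nr)
  col_grp <- cell_groups(nc)
  out <- numeric(81L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    sel_r <- row_grp == i
    sel_c <- col_grp == j
    hb0 <- b0[sel_r, sel_c]; hb1 <- b1[sel_r, sel_c]
    hw0 <- w0[sel_r, sel_c]; hw1 <- w1[sel_r, sel_c]
    hist <- numeric(9L)
    for (b in 0:8) {
      hist[b + 1L] <- sum(hw0[hb0 == b]) + sum(hw1[hb1 == b])
    }
    nrm <- sqrt(sum(hist^2) + 1e-6^2)
    if (sum(hist) > 0) hist <- hist / nrm
    out[k + 1:9] <- hist
    k <- k + 9L
  }
  names(out) <- feature_names_for("HOG")
  out
}

# Split 1..n into 3 near-equal contiguous cell groups.
cell_groups <- function(n) {
  sizes <- rep(n %/% 3L, 3L)
  extra <- n %% 3L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(1:3, sizes)
}
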