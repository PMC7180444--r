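#' Laws' texture energy features (28 values)
#'
#' 2-D kernels are outer products of the 1-D Laws kernels
#' `L3 = [1 2 1]`, `E3 = [-1 0 1]`, `S3 = [-1 2 -1]`,
#' `L5 = [1 4 6 4 1]`, `E5 = [-1 -2 0 2 1]`, `S5 = [-1 0 2 0 -1]` and
#' `R5 = [1 -4 6 -4 1]`, within each size family. Transposed cross pairs
#' are averaged (energy maps averaged element-wise) and the pure smoothing
#' map (LL) of each family is dropped, giving 5 maps for the 3x3 family
#' (E3E3, S3S3, L3E3, L3S3, E3S3) and 9 for the 5x5 family (E5E5, S5S5,
#' R5R5, L5E5, L5S5, L5R5, E5S5, E5R5, S5R5). Energy is the absolute
#' filter response on the valid (fully-supported) region, with no
#' normalization by the smoothing map. Emission: the 14 map means, then
#' the 14 standard deviations (population convention).
#'
#' @param block Numeric matrix, at least 5x5.
#' @return Named numeric vector of length 28.
#' @export
extract_laws <- function(block) {
  if (nrow(block) < 5L || ncol(block) < 5L) {
    stop("Laws features need a block of at least 5x5", call. = FALSE)
  }
  k3 <- list(l = c(1, 2, 1), e = c(-1, 0, 1), s = c(-1, 2, -1))
  k5 <- list(l = c(1, 4, 6, 4, 1), e = c(-1, -2, 0, 2, 1),
             s = c(-1, 0, 2, 0, -1), r = c(1, -4, 6, -4, 1))
  energy <- function(kv, kh) {
    abs(filter2_valid(block, outer(kv, kh)))
  }
  map_single <- function(fam, a) energy(fam[[a]], fam[[a]])
  map_pair <- function(fam, a, b) {
    (energy(fam[[a]], fam[[b]]) + energy(fam[[b]], fam[[a]])) / 2
  }
  maps <- list(
    map_single(k3, "e"), map_single(k3, "s"),
    map_pair(k3, "l", "e"), map_pair(k3, "l", "s"), map_pair(k3, "e", "s"),
    map_single(k5, "e"), map_single(k5, "s"), map_single(k5, "r"),
    map_pair(k5, "l", "e"), map_pair(k5, "l", "s"), map_pair(k5, "l", "r"),
    map_pair(k5, "e", "s"), map_pair(k5, "e", "r"), map_pair(k5, "s", "r")
  )
  out <- c(
    vapply(maps, mean, numeric(1)),
    vapply(maps, pop_sd, numeric(1))
  )
  names(out) <- feature_names_for("LAWS")
  out
}

#' Differential box-counting fractal features (FD, 3 values)
#'
#' A local fractal-dimension map is computed with differential box counting
#' (DBC) on a sliding local window (default 16x16, stride 8): at each grid
#' scale `s` in {2, 3, 4, 6, 8} the window is divided into `s x s`-pixel
#' cells (partial edge cells included), the box height is
#' `h = s * G / M` with `G = 256` gray levels and `M` the window side, and
#' each cell contributes `floor((max - min) / h) + 1` boxes — the span
#' form, exactly invariant to a global intensity shift. The local
#' dimension is the least-squares slope of `log N(s)` versus `log(1/s)`.
#' Emitted: mean and standard deviation (population) of the local
#' dimension map, and lacunarity — `variance / mean^2` of the local
#' box-mass (finest-scale box count) distribution.
#'
#' @param block Numeric matrix, at least 8x8.
#' @param window Local window side `M` (default 16, clipped to the block).
#' @param stride Sliding stride (default 8).
#' @return Named numeric vector of length 3.
#' @export
extract_fd <- function(block, window = 16L, stride = 8L) {
  nr <- nrow(block); nc <- ncol(block)
  if (nr < 8L || nc < 8L) stop("FD needs a block of at least 8x8",
                               call. = FALSE)
  M <- min(window, nr, nc)
  scales <- c(2L, 3L, 4L, 6L, 8L)
  scales <- scales[scales <= M %/% 2L]
  r_starts <- seq.int(1L, nr - M + 1L, by = stride)
  c_starts <- seq.int(1L, nc - M + 1L, by = stride)
  dims <- numeric(0)
  masses <- numeric(0)
  for (r0 in r_starts) for (c0 in c_starts) {
    win <- block[r0:(r0 + M - 1L), c0:(c0 + M - 1L), drop = FALSE]
    counts <- vapply(scales, function(s) dbc_count(win, s, M), numeric(1))
    fit <- stats::lm.fit(cbind(1, log(1 / scales)), log(counts))
    dims <- c(dims, fit$coefficients[2])
    masses <- c(masses, counts[1])
  }
  lac <- if (mean(masses) == 0) 0 else pop_var(masses) / mean(masses)^2
  out <- c(mean(dims), pop_sd(dims), lac)
  names(out) <- feature_names_for("FD")
  out
}

# Total DBC box count of one window at grid scale s.
dbc_count <- function(win, s, M) {
  h <- s * 256 / M
  n <- nrow(win)
  grp <- (seq_len(n) - 1L) %/% s
  total <- 0
  for (gi in unique(grp)) for (gj in unique(grp)) {
    cell <- win[grp == gi, grp == gj, drop = FALSE]
    total <- total + floor((max(cell) - min(cell)) / h) + 1
  }
  total
}
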