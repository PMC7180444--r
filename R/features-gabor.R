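#' Gabor filter-bank features (128 values)
#'
#' A 64-filter bank of complex 2-D Gabor kernels: 8 frequencies
#' `f_k = f_max / sqrt(2)^k`, `k = 0..7`, with `f_max = 0.25` cycles/pixel,
#' crossed with 8 orientations `theta_j = j * pi / 8`, `j = 0..7`. Each
#' kernel is a Gaussian envelope (aspect `gamma = eta = sqrt(2)`, scale
#' `sigma = 0.56 / f`) modulated by a complex exponential along the
#' rotated axis, with the standard `f^2 / (pi * gamma * eta)` gain. The
#' block is filtered with reflective boundary handling (FFT convolution)
#' and the complex response magnitude is summarized per filter. Emission:
#' all 64 means (frequency-major), then all 64 standard deviations
#' (population convention). Kernels are truncated at
#' `min(ceil(2.5 sigma), 31)` pixels half-width.
#'
#' @param block Numeric matrix, at least 11x11.
#' @return Named numeric vector of length 128.
#' @export
extract_gabor <- function(block) {
  nr <- nrow(block); nc <- ncol(block)
  if (nr < 11L || nc < 11L) stop("Gabor needs a block of at least 11x11",
                                 call. = FALSE)
  bank <- gabor_bank(nr, nc)
  padded <- pad_reflect(block, bank$pad)
  f_img <- fft(padded)
  n_tot <- length(padded)
  means <- numeric(64L); sds <- numeric(64L)
  rows <- bank$pad + seq_len(nr); cols <- bank$pad + seq_len(nc)
  for (k in seq_len(64L)) {
    resp <- fft(f_img * bank$kernels_f[[k]], inverse = TRUE) / n_tot
    mag <- Mod(resp[rows, cols])
    means[k] <- mean(mag)
    sds[k] <- pop_sd(mag)
  }
  out <- c(means, sds)
  names(out) <- feature_names_for("GABOR")
  out
}

# Frequencies and orientations of the default bank, frequency-major.
gabor_bank_params <- function() {
  f <- 0.25 / sqrt(2)^(0:7)
  theta <- (0:7) * pi / 8
  list(f = rep(f, each = 8L), theta = rep(theta, times = 8L))
}

gabor_bank <- function(nr, nc) {
  key <- sprintf("gabor_%d_%d", nr, nc)
  cached <- get0(key, envir = .octcyst_cache)
  if (!is.null(cached)) return(cached)
  pars <- gabor_bank_params()
  gamma <- sqrt(2); eta <- sqrt(2)
  pad <- min(31L, nr - 1L, nc - 1L)
  L1 <- nr + 2L * pad; L2 <- nc + 2L * pad
  kernels_f <- vector("list", 64L)
  for (k in seq_len(64L)) {
    f <- pars$f[k]; theta <- pars$theta[k]
    sigma <- 0.56 / f
    half <- min(as.integer(ceiling(2.5 * sigma)), pad)
    off <- (-half):half
    x <- matrix(off, 2L * half + 1L, 2L * half + 1L, byrow = TRUE) # columns
    y <- matrix(off, 2L * half + 1L, 2L * half + 1L)               # rows
    xp <- x * cos(theta) + y * sin(theta)
    yp <- -x * sin(theta) + y * cos(theta)
    kern <- (f^2 / (pi * gamma * eta)) *
      exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
      exp(1i * 2 * pi * f * xp)
    kpad <- matrix(0 + 0i, L1, L2)
    ri <- ((off %% L1) + 1L); ci <- ((off %% L2) + 1L)
    kpad[ri, ci] <- kern
    kernels_f[[k]] <- fft(kpad)
  }
  bank <- list(pad = pad, kernels_f = kernels_f)
  assign(key, bank, envir = .octcyst_cache)
  bank
}

# Reflective padding (mirror about the edge, edge row not duplicated).
pad_reflect <- function(m, p) {
  nr <- nrow(m); nc <- ncol(m)
  if (p == 0L) return(m)
  if (p >= nr || p >= nc) stop("reflection padding wider than the block")
  ri <- c((p + 1L):2L, seq_len(nr), (nr - 1L):(nr - p))
  ci <- c((p + 1L):2L, seq_len(nc), (nc - 1L):(nc - p))
  m[ri, ci, drop = FALSE]
}
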