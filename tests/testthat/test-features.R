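test_that("feature layout matches the canonical category ranges", {
  layout <- feature_layout()
  expect_equal(nrow(layout), 510L)
  expect_equal(anyDuplicated(layout$name), 0L)
  cats <- feature_categories()
  expect_equal(cats$category,
               c("GIBS", "AIS", "EIG", "LESH", "GLCM", "HOG", "GABOR",
                 "LBP", "LAWS", "FD", "GLRL"))
  expect_equal(cats$size, c(15L, 12L, 28L, 128L, 16L, 81L, 128L, 64L,
                            28L, 3L, 7L))
  expect_equal(cats$start,
               c(1L, 16L, 28L, 56L, 184L, 200L, 281L, 409L, 473L, 501L,
                 504L))
  expect_equal(cats$end,
               c(15L, 27L, 55L, 183L, 199L, 280L, 408L, 472L, 500L, 503L,
                 510L))
})

# ---- GIBS ----------------------------------------------------------------

test_that("GIBS handles constant and two-level blocks exactly", {
  v <- extract_gibs(matrix(7, 10, 10))
  expect_equal(unname(v[c("gibs.max", "gibs.min", "gibs.mean",
                          "gibs.median", "gibs.p25", "gibs.p75",
                          "gibs.mle.mu")]),
               rep(7, 7))
  expect_equal(unname(v[c("gibs.sd", "gibs.var", "gibs.entropy",
                          "gibs.mle.sigma")]),
               rep(0, 4))
  expect_equal(unname(v["gibs.mle.mu.lo"]), 7)
  b <- matrix(c(0, 0, 255, 255), 2, 2)
  v2 <- extract_gibs(b)
  expect_equal(unname(v2["gibs.mean"]), 127.5)
  expect_equal(unname(v2["gibs.var"]), 16256.25)
  expect_equal(unname(v2["gibs.entropy"]), 1)
})

test_that("GIBS matches a naive loop oracle and shifts with the input", {
  set.seed(1)
  b <- random_block(9, 11)
  v <- extract_gibs(b)
  x <- as.vector(b); n <- length(x)
  mu <- sum(x) / n
  expect_equal(unname(v["gibs.mean"]), mu)
  expect_equal(unname(v["gibs.var"]), sum((x - mu)^2) / n)
  expect_equal(unname(v["gibs.sd"]), sqrt(sum((x - mu)^2) / n))
  s <- stats::sd(x)
  expect_equal(unname(v["gibs.mle.mu.hi"]),
               mu + stats::qt(0.975, n - 1) * s / sqrt(n))
  expect_equal(unname(v["gibs.mle.sigma.lo"]),
               s * sqrt((n - 1) / stats::qchisq(0.975, n - 1)))
  # mean shifts by the added constant (to machine precision)
  v2 <- extract_gibs(b + 20)
  expect_equal(unname(v2["gibs.mean"] - v["gibs.mean"]), 20,
               tolerance = 1e-12)
})

# ---- AIS -----------------------------------------------------------------

test_that("AIS degenerate and symmetric cases are exact", {
  expect_true(all(extract_ais(matrix(5, 6, 6)) == 0))
  # rows with a symmetric value distribution: zero horizontal skewness
  b <- matrix(rep(c(1, 3, 5, 7, 9), 4), 4, 5, byrow = TRUE)
  v <- extract_ais(b)
  expect_equal(unname(v["ais.min.skew.h"]), 0)
  expect_equal(unname(v["ais.max.skew.h"]), 0)
})

test_that("AIS matches per-row/column loop moments on a fixed block", {
  b <- matrix(c(1, 2, 3, 4,
                2, 2, 9, 4,
                0, 5, 5, 5,
                7, 1, 2, 250), 4, 4, byrow = TRUE)
  skew <- function(x) {
    m2 <- mean((x - mean(x))^2)
    if (m2 == 0) 0 else mean((x - mean(x))^3) / m2^1.5
  }
  kurt <- function(x) {
    m2 <- mean((x - mean(x))^2)
    if (m2 == 0) 0 else mean((x - mean(x))^4) / m2^2
  }
  sh <- apply(b, 1, skew); sv <- apply(b, 2, skew)
  kh <- apply(b, 1, kurt); kv <- apply(b, 2, kurt)
  v <- extract_ais(b)
  expect_equal(unname(v["ais.min.skew.h"]), min(sh))
  expect_equal(unname(v["ais.mean.skew.v"]), mean(sv))
  expect_equal(unname(v["ais.max.kurt.h"]), max(kh))
  expect_equal(unname(v["ais.mean.kurt.v"]), mean(kv))
})

# ---- Eigen ---------------------------------------------------------------

test_that("eigen spectrum handles degenerate and rank-1 rectangles", {
  v <- extract_eigen(matrix(9, 12, 12))
  expect_true(all(v == 0))
  u <- c(1, 3, 2, 5, 4, 8, 7, 6)
  w <- c(2, 1, 4, 3, 6, 5, 8, 7)
  b <- outer(u, w)
  v2 <- extract_eigen(b)
  spec <- v2[paste0("eig.max", 1:4)]
  expect_gt(spec[1], 0)
  expect_equal(unname(spec[2:4]), rep(0, 3), tolerance = 1e-8)
})

test_that("eigen magnitudes match an independent eigendecomposition", {
  set.seed(3)
  b <- random_block(8, 8)
  v <- extract_eigen(b)
  centered <- sweep(b, 2, colMeans(b))
  ev <- sqrt(abs(eigen(crossprod(centered), symmetric = TRUE,
                       only.values = TRUE)$values))
  ev <- sort(ev, decreasing = TRUE)
  expect_equal(unname(v[paste0("eig.max", 1:4)]), ev[1:4],
               tolerance = 1e-8)
  expect_equal(unname(v["eig.r.max1.min4"]),
               ev[1] / sort(utils::tail(ev, 4))[4], tolerance = 1e-8)
})

test_that("non-square ROI rectangles aggregate sliding square windows", {
  set.seed(4)
  b <- random_block(12, 12)
  roi <- matrix(FALSE, 12, 12)
  roi[3:8, ] <- TRUE                     # 6 x 12 rectangle
  expect_silent(v <- extract_eigen(b, roi))
  expect_true(all(is.finite(v)))
  # oracle: mean sorted spectra of 6x6 windows at stride 3 (+ final fit)
  sub <- b[3:8, ]
  starts <- unique(c(seq(1, 7, by = 3), 7))
  specs <- sapply(starts, function(c0) {
    m <- sub[, c0:(c0 + 5)]
    sort(svd(sweep(m, 2, colMeans(m)))$d, decreasing = TRUE)
  })
  agg <- rowMeans(specs)
  expect_equal(unname(v[paste0("eig.max", 1:4)]), agg[1:4],
               tolerance = 1e-8)
})

test_that("tiny ROI rectangles warn and pad the spectrum", {
  b <- random_block(10, 10)
  roi <- matrix(FALSE, 10, 10)
  roi[1:2, 1:2] <- TRUE
  expect_warning(v <- extract_eigen(b, roi), "4x4")
  expect_true(all(is.finite(v)))
})

# ---- LESH ----------------------------------------------------------------

test_that("LESH is zero on constant blocks and finds edge orientation", {
  expect_true(all(extract_lesh(matrix(120, 32, 32)) == 0))
  # vertical stripe: both edges vertical, orientation normal to them is
  # horizontal (o = 1); borders stay flat so the periodic FFT sees no
  # wrap-around discontinuity
  b <- matrix(40, 32, 32); b[, 13:20] <- 200
  v <- extract_lesh(b)
  m <- matrix(v, nrow = 8)               # orientations x partitions
  by_orient <- rowSums(m)
  expect_equal(which.max(by_orient), 1L)
  # the stripe edges cross partition columns 2-3 only
  part <- matrix(colSums(m), 4, 4, byrow = TRUE)  # partitions row-major
  expect_gt(sum(part[, 2:3]), sum(part[, c(1, 4)]))
})

test_that("LESH is invariant to global intensity scaling", {
  set.seed(5)
  b <- random_block(61, 61, 10, 120)
  v1 <- extract_lesh(b)
  v2 <- extract_lesh(b * 2)
  expect_lt(max(abs(v1 - v2)), 1e-6)
})

# ---- GLCM ----------------------------------------------------------------

test_that("GLCM degenerate and checkerboard cases are exact", {
  v <- extract_glcm(matrix(50, 8, 8))
  expect_equal(unname(v[paste0("glcm.energy.", c(0, 45, 90, 135))]),
               rep(1, 4))
  expect_equal(unname(v[paste0("glcm.contrast.", c(0, 45, 90, 135))]),
               rep(0, 4))
  expect_equal(unname(v[paste0("glcm.homogeneity.", c(0, 45, 90, 135))]),
               rep(1, 4))
  expect_equal(unname(v[paste0("glcm.correlation.", c(0, 45, 90, 135))]),
               rep(0, 4))
  # period-2 checkerboard: distance 2 pairs like with like at 0 degrees
  cb <- matrix(c(0, 255), 4, 4)
  cb <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) * 255)
  v2 <- extract_glcm(cb)
  expect_equal(unname(v2["glcm.contrast.0"]), 0)
})

test_that("GLCM matches the double-loop pair-counting oracle", {
  offs <- list(`0` = c(0, 2), `45` = c(-2, 2), `90` = c(-2, 0),
               `135` = c(-2, -2))
  set.seed(6)
  for (i in 1:30) {
    b <- random_block(6, 6)
    v <- extract_glcm(b)
    for (ang in names(offs)) {
      o <- oracle_glcm_stats(b, offs[[ang]][1], offs[[ang]][2])
      expect_equal(unname(v[paste0("glcm.contrast.", ang)]),
                   unname(o["contrast"]), tolerance = 1e-12)
      expect_equal(unname(v[paste0("glcm.correlation.", ang)]),
                   unname(o["correlation"]), tolerance = 1e-12)
      expect_equal(unname(v[paste0("glcm.energy.", ang)]),
                   unname(o["energy"]), tolerance = 1e-12)
      expect_equal(unname(v[paste0("glcm.homogeneity.", ang)]),
                   unname(o["homogeneity"]), tolerance = 1e-12)
    }
  }
})

# ---- HOG -----------------------------------------------------------------

test_that("HOG orientation binning behaves on canonical gradients", {
  expect_true(all(extract_hog(matrix(9, 12, 12)) == 0))
  # horizontal ramp: gradient along x, orientation 0 -> first bin per cell
  ramp <- matrix(rep(seq(0, 220, by = 20), each = 12), 12, 12)
  v <- extract_hog(ramp)
  m <- matrix(v, nrow = 9)
  expect_true(all(m[1, ] > 0.99))
  expect_true(all(m[-1, ] < 0.02))
  # vertical ramp: orientation 90 splits bins 5 and 6 (centers 80/100)
  vv <- extract_hog(t(ramp))
  mv <- matrix(vv, nrow = 9)
  expect_true(all(abs(mv[5, ] - mv[6, ]) < 1e-9))
  expect_true(all(mv[c(1:4, 7:9), ] < 0.02))
})

# ---- Gabor ---------------------------------------------------------------

test_that("Gabor responses are flat on constants and scale linearly", {
  v <- extract_gabor(matrix(77, 32, 32))
  sds <- v[grep("^gabor\\.sd\\.", names(v))]
  expect_lt(max(sds), 1e-8)
  set.seed(7)
  b <- random_block(32, 32)
  v1 <- extract_gabor(b)
  v2 <- extract_gabor(b * 0.5)
  expect_equal(unname(v2), unname(v1) * 0.5, tolerance = 1e-9)
})

test_that("a grating is matched by its own bank filter", {
  # grating at the bank frequency f3 = 0.25 / sqrt(2)^2, orientation 0
  f0 <- 0.25 / sqrt(2)^2
  xs <- matrix(seq_len(61), 61, 61, byrow = TRUE)
  grating <- 120 + 100 * cos(2 * pi * f0 * xs)
  v <- extract_gabor(grating)
  means <- matrix(v[1:64], nrow = 8)     # orientations x frequencies
  idx <- which(means == max(means), arr.ind = TRUE)
  expect_equal(unname(idx[1, "col"]), 3L)   # frequency index k = 3
  expect_equal(unname(idx[1, "row"]), 1L)   # orientation 0
})

# ---- LBP -----------------------------------------------------------------

test_that("LBP constants give the all-ones code with zero spread", {
  v <- extract_lbp(matrix(13, 20, 20))
  means <- v[grep("^lbp\\.mean\\.", names(v))]
  sds <- v[grep("^lbp\\.sd\\.", names(v))]
  expect_true(all(sds == 0))
  pr <- expand.grid(r = 1:8, p = c(4, 8, 12, 16))
  expect_equal(unname(means), 2^pr$p - 1)
})

test_that("LBP features are bit-identical under a +20 intensity shift", {
  set.seed(8)
  b <- random_block(24, 24, 0, 200)
  expect_identical(extract_lbp(b), extract_lbp(b + 20))
})

test_that("a hand-computed 3x3 neighborhood code is reproduced", {
  b <- matrix(0, 5, 5)
  b[2:4, 2:4] <- matrix(c(5, 9, 2,
                          7, 6, 6,
                          1, 8, 3), 3, 3, byrow = TRUE)
  # center (3,3) value 6; P = 4, R = 1 neighbors at angles 0, 90, 180, 270:
  # (3,4)=6 >=6 bit0; (4,3)=8 >=6 bit1; (3,2)=7 >=6 bit2; (2,3)=9 >=6 bit3
  codes <- lbp_code_map(b, P = 4L, R = 1L)
  expect_equal(codes[2, 2], 1 + 2 + 4 + 8)
  # P = 8, R = 1 with bilinear diagonals on an integer grid
  oracle <- oracle_lbp_codes(b, 8L, 1L)
  expect_equal(lbp_code_map(b, 8L, 1L), oracle)
})

test_that("LBP code maps match the per-pixel oracle", {
  set.seed(9)
  for (i in 1:10) {
    b <- random_block(12, 12)
    for (P in c(4L, 8L)) for (R in c(1L, 2L, 3L)) {
      expect_equal(lbp_code_map(b, P, R), oracle_lbp_codes(b, P, R))
    }
  }
})

# ---- Laws ----------------------------------------------------------------

test_that("Laws energies vanish on constants and ramps behave analytically", {
  expect_true(all(extract_laws(matrix(3, 10, 10)) == 0))
  ramp <- matrix(rep(seq(10, 100, by = 10), 10), 10, 10)  # vertical ramp
  v <- extract_laws(ramp)
  # spot and ripple maps see zero second/fourth differences, and the pure
  # cross kernel E3xE3 vanishes too (its row factor sums to zero)
  expect_equal(unname(v["laws.mean.s3s3"]), 0)
  expect_equal(unname(v["laws.mean.r5r5"]), 0)
  expect_equal(unname(v["laws.mean.e3e3"]), 0)
  # the smoothed edge map responds with constant magnitude along the ramp
  expect_gt(unname(v["laws.mean.l3e3"]), 0)
  expect_equal(unname(v["laws.sd.l3e3"]), 0)
})

test_that("Laws maps match the naive convolution oracle", {
  k3 <- list(l = c(1, 2, 1), e = c(-1, 0, 1), s = c(-1, 2, -1))
  k5 <- list(l = c(1, 4, 6, 4, 1), e = c(-1, -2, 0, 2, 1),
             s = c(-1, 0, 2, 0, -1), r = c(1, -4, 6, -4, 1))
  set.seed(10)
  for (i in 1:10) {
    b <- random_block(7, 7)
    v <- extract_laws(b)
    o_e3e3 <- abs(oracle_filter_valid(b, outer(k3$e, k3$e)))
    expect_equal(unname(v["laws.mean.e3e3"]), mean(o_e3e3),
                 tolerance = 1e-12)
    o_l5r5 <- (abs(oracle_filter_valid(b, outer(k5$l, k5$r))) +
                 abs(oracle_filter_valid(b, outer(k5$r, k5$l)))) / 2
    expect_equal(unname(v["laws.mean.l5r5"]), mean(o_l5r5),
                 tolerance = 1e-12)
    o_e5s5 <- (abs(oracle_filter_valid(b, outer(k5$e, k5$s))) +
                 abs(oracle_filter_valid(b, outer(k5$s, k5$e)))) / 2
    sdp <- function(x) sqrt(mean((x - mean(x))^2))
    expect_equal(unname(v["laws.sd.e5s5"]), sdp(o_e5s5),
                 tolerance = 1e-12)
  }
})

# ---- FD ------------------------------------------------------------------

test_that("FD on a flat surface matches the frozen oracle value", {
  v <- extract_fd(matrix(128, 32, 32))
  flat_dim <- oracle_dbc_dimension(matrix(128, 16, 16))
  expect_equal(unname(v["fd.mean"]), flat_dim, tolerance = 1e-9)
  expect_equal(unname(v["fd.sd"]), 0)
  expect_equal(unname(v["fd.lacunarity"]), 0)
})

test_that("FD is invariant to a global intensity shift", {
  set.seed(11)
  b <- random_block(32, 32, 0, 200)
  expect_equal(extract_fd(b), extract_fd(b + 30), tolerance = 1e-12)
})

test_that("local DBC dimensions match the loop oracle", {
  set.seed(12)
  for (i in 1:10) {
    win <- random_block(16, 16)
    counts <- vapply(c(2L, 3L, 4L, 6L, 8L),
                     function(s) octcyst:::dbc_count(win, s, 16L),
                     numeric(1))
    xs <- log(1 / c(2, 3, 4, 6, 8))
    slope <- stats::coef(stats::lm(log(counts) ~ xs))[2]
    expect_equal(unname(slope), oracle_dbc_dimension(win),
                 tolerance = 1e-9)
    # the sliding-window feature on the window itself reduces to one cell
    v <- extract_fd(win)
    expect_equal(unname(v["fd.mean"]), unname(slope), tolerance = 1e-9)
  }
})

# ---- GLRL ----------------------------------------------------------------

test_that("GLRL single-orientation constants follow the closed forms", {
  n <- 6L
  q <- octcyst:::quantize_gray(matrix(100, n, n), 51L)
  m <- octcyst:::glrl_matrix(q, orientations = 0)
  st <- octcyst:::glrl_stats(m, n_pixels_scanned = n * n)
  expect_equal(unname(st["sre"]), 1 / n^2)
  expect_equal(unname(st["lre"]), n^2)
  expect_equal(unname(st["rp"]), 1 / n)
  # strictly alternating stripes: all horizontal runs have length 1
  stripes <- matrix(rep(c(0, 255), 3), n, n, byrow = TRUE)
  q2 <- octcyst:::quantize_gray(stripes, 51L)
  m2 <- octcyst:::glrl_matrix(q2, orientations = 0)
  st2 <- octcyst:::glrl_stats(m2, n_pixels_scanned = n * n)
  expect_equal(unname(st2["sre"]), 1)
})

test_that("GLRL statistics match the scan-line oracle", {
  set.seed(13)
  for (i in 1:30) {
    b <- random_block(5, 5, 0, 255)
    v <- extract_glrl(b)
    o <- oracle_glrl(b)
    expect_equal(unname(v), unname(o), tolerance = 1e-12)
  }
})

# ---- composition ---------------------------------------------------------

test_that("extract_features assembles 510 deterministic values", {
  set.seed(14)
  b <- random_block(61, 61)
  v1 <- extract_features(b)
  v2 <- extract_features(b)
  expect_identical(v1, v2)
  expect_length(v1, 510L)
  expect_identical(names(v1), feature_layout()$name)
  expect_true(all(is.finite(v1)))
  # category boundaries land where the layout says
  expect_match(names(v1)[15], "^gibs\\.")
  expect_match(names(v1)[16], "^ais\\.")
  expect_match(names(v1)[55], "^eig\\.")
  expect_match(names(v1)[56], "^lesh\\.")
  expect_match(names(v1)[199], "^glcm\\.")
  expect_match(names(v1)[200], "^hog\\.")
  expect_match(names(v1)[408], "^gabor\\.")
  expect_match(names(v1)[409], "^lbp\\.")
  expect_match(names(v1)[500], "^laws\\.")
  expect_match(names(v1)[503], "^fd\\.")
  expect_match(names(v1)[510], "^glrl\\.")
})

test_that("a constant sample produces the expected degenerate assembly", {
  v <- extract_features(matrix(64, 61, 61))
  expect_true(all(v[grep("^(ais|hog|laws|lesh)\\.", names(v))] == 0))
  expect_true(all(v[grep("^lbp\\.sd\\.", names(v))] == 0))
  expect_equal(unname(v["glcm.energy.0"]), 1)
  expect_equal(unname(v["gibs.mean"]), 64)
})
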