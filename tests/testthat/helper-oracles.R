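# Independent brute-force oracles used across the test files. These are
# deliberately naive (per-pixel loops, explicit enumeration) and share no
# code with the package implementation.

# -- GLCM: double-loop pair counting ---------------------------------------
oracle_glcm_stats <- function(block, dr, dc, n_levels = 8L) {
  q <- floor(block * n_levels / 256)
  q <- pmin(pmax(q, 0), n_levels - 1L) + 1L
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(q); nc <- ncol(q)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
      counts[q[r, c], q[r2, c2]] <- counts[q[r, c], q[r2, c2]] + 1
      counts[q[r2, c2], q[r, c]] <- counts[q[r2, c2], q[r, c]] + 1
    }
  }
  p <- counts / sum(counts)
  iv <- row(p); jv <- col(p)
  mu_i <- sum(iv * p); mu_j <- sum(jv * p)
  s_i <- sqrt(sum((iv - mu_i)^2 * p)); s_j <- sqrt(sum((jv - mu_j)^2 * p))
  corr <- if (s_i == 0 || s_j == 0) 0 else
    sum((iv - mu_i) * (jv - mu_j) * p) / (s_i * s_j)
  c(contrast = sum((iv - jv)^2 * p), correlation = corr,
    energy = sum(p^2), homogeneity = sum(p / (1 + abs(iv - jv))))
}

# -- GLRL: explicit run enumeration along scan lines ----------------------
oracle_glrl <- function(block) {
  q <- floor(block * 51 / 256)
  q <- pmin(pmax(q, 0), 50) + 1L
  nr <- nrow(q); nc <- ncol(q)
  runs <- list()
  add_line <- function(v) {
    i <- 1L
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && v[j + 1L] == v[i]) j <- j + 1L
      runs[[length(runs) + 1L]] <<- c(level = v[i], len = j - i + 1L)
      i <- j + 1L
    }
  }
  for (r in seq_len(nr)) add_line(q[r, ])
  for (c in seq_len(nc)) add_line(q[, c])
  for (s in 2:(nr + nc)) {            # anti-diagonals r + c = s
    rr <- seq_len(nr); rr <- rr[s - rr >= 1 & s - rr <= nc]
    add_line(q[cbind(rr, s - rr)])
  }
  for (dd in (1 - nr):(nc - 1)) {     # main diagonals c - r = dd
    rr <- seq_len(nr); rr <- rr[rr + dd >= 1 & rr + dd <= nc]
    add_line(q[cbind(rr, rr + dd)])
  }
  m <- matrix(0, 51, max(nr, nc))
  for (run in runs) m[run["level"], run["len"]] <- m[run["level"], run["len"]] + 1
  n_runs <- sum(m)
  lev <- seq_len(nrow(m)); len <- seq_len(ncol(m))
  p_lev <- rowSums(m); p_len <- colSums(m)
  c(
    sre = sum(t(m) / len^2) / n_runs,
    lre = sum(t(m) * len^2) / n_runs,
    gln = sum(p_lev^2) / n_runs,
    rp = n_runs / (4 * nr * nc),
    rln = sum(p_len^2) / n_runs,
    lgre = sum(p_lev / lev^2) / n_runs,
    hgre = sum(p_lev * lev^2) / n_runs
  )
}

# -- Laws: naive 2-D cross-correlation, valid region ----------------------
oracle_filter_valid <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(m) - kr + 1L; nc <- ncol(m) - kc + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in seq_len(kr)) for (b in seq_len(kc)) {
      acc <- acc + k[a, b] * m[i + a - 1L, j + b - 1L]
    }
    out[i, j] <- acc
  }
  out
}

# -- LBP: per-pixel loop with plain value interpolation -------------------
oracle_lbp_codes <- function(block, P, R) {
  nr <- nrow(block); nc <- ncol(block)
  marg <- ceiling(R)
  interp <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c)
    fr <- r - r0; fc <- c - c0
    (1 - fr) * (1 - fc) * block[r0, c0] +
      (1 - fr) * fc * block[r0, min(c0 + 1, nc)] +
      fr * (1 - fc) * block[min(r0 + 1, nr), c0] +
      fr * fc * block[min(r0 + 1, nr), min(c0 + 1, nc)]
  }
  out <- matrix(0, nr - 2 * marg, nc - 2 * marg)
  for (r in (marg + 1):(nr - marg)) for (c in (marg + 1):(nc - marg)) {
    code <- 0
    for (p in 0:(P - 1)) {
      a <- 2 * pi * p / P
      dr <- R * sin(a); dc <- R * cos(a)
      if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
      if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
      if (interp(r + dr, c + dc) >= block[r, c]) code <- code + 2^p
    }
    out[r - marg, c - marg] <- code
  }
  out
}

# -- DBC: per-cell loop fractal dimension of one window -------------------
oracle_dbc_dimension <- function(win, scales = c(2L, 3L, 4L, 6L, 8L)) {
  M <- nrow(win)
  counts <- sapply(scales, function(s) {
    h <- s * 256 / M
    total <- 0
    for (i0 in seq(1, M, by = s)) for (j0 in seq(1, M, by = s)) {
      cell <- win[i0:min(i0 + s - 1, M), j0:min(j0 + s - 1, M), drop = FALSE]
      total <- total + floor((max(cell) - min(cell)) / h) + 1
    }
    total
  })
  xs <- log(1 / scales)
  unname(stats::coef(stats::lm(log(counts) ~ xs))[2])
}

# -- shortest path: exhaustive DFS over the full move set -----------------
# Enumerates every simple left-to-right path (column-advancing diagonals
# plus vertical moves), with branch-and-bound pruning. Returns the optimal
# total cost including the two w_min endpoint links.
oracle_path_cost <- function(grad, w_min = 1e-5) {
  H <- nrow(grad); W <- ncol(grad)
  best <- Inf
  visited <- matrix(FALSE, H, W)
  moves <- rbind(c(-1, 1), c(0, 1), c(1, 1), c(-1, 0), c(1, 0))
  dfs <- function(r, c, cost) {
    if (cost >= best) return()
    if (c == W) { best <<- min(best, cost + w_min); return() }
    for (k in seq_len(nrow(moves))) {
      nr <- r + moves[k, 1]; nc <- c + moves[k, 2]
      if (nr < 1 || nr > H || nc > W || visited[nr, nc]) next
      visited[nr, nc] <<- TRUE
      dfs(nr, nc, cost + 2 - grad[r, c] - grad[nr, nc] + w_min)
      visited[nr, nc] <<- FALSE
    }
  }
  for (r0 in seq_len(H)) {
    visited[] <- FALSE
    visited[r0, 1] <- TRUE
    dfs(r0, 1, w_min)
  }
  best
}

# Minimum cost over strictly monotone (one pixel per column) paths, by
# dynamic programming: an upper bound for the full move set.
oracle_monotone_cost <- function(grad, w_min = 1e-5) {
  H <- nrow(grad); W <- ncol(grad)
  d <- rep(w_min, H)
  for (c in 2:W) {
    nd <- rep(Inf, H)
    for (r in seq_len(H)) {
      for (pr in max(1, r - 1):min(H, r + 1)) {
        w <- 2 - grad[pr, c - 1] - grad[r, c] + w_min
        nd[r] <- min(nd[r], d[pr] + w)
      }
    }
    d <- nd
  }
  min(d) + w_min
}

# -- misc helpers ----------------------------------------------------------
random_block <- function(nr, nc = nr, lo = 0, hi = 255) {
  matrix(runif(nr * nc, lo, hi), nr, nc)
}

# Small, fast phantom used where the full default size is unnecessary.
small_phantom_spec <- function(seed, ...) {
  defaults <- list(width = 160L, height = 120L, ilm_baseline = 30L,
                   rpe_baseline = 85L, curvature_amplitude = 8,
                   n_cysts = 2L, cyst_axes_range = c(6, 14),
                   n_shadows = 1L, n_drusen = 1L, seed = seed)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}
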