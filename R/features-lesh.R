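#' Local energy-based shape histogram (LESH, 128 values)
#'
#' Phase congruency is computed with a log-Gabor filter bank (5 scales, 8
#' orientations; minimum wavelength 3 px, scale multiplier 2.1, log-Gabor
#' bandwidth parameter 0.55, angular spread sigma = 1.2 x (pi/8)) with the
#' standard Rayleigh-model noise compensation (threshold `k = 2` standard
#' deviations above the estimated noise energy, `eps = 1e-4`). Each pixel
#' is assigned the orientation of maximal summed filter amplitude; the
#' block is divided into a 4x4 partition grid and, per partition, an 8-bin
#' orientation histogram accumulates the phase congruency of the pixels
#' labeled with each orientation. The concatenated 16 x 8 = 128 histogram
#' is globally L2-normalized (an all-zero histogram is kept as zeros).
#' The block is contrast-normalized by its (population) standard
#' deviation before the filter bank, so the descriptor is exactly
#' unchanged under global intensity scaling — the invariance phase
#' congruency has by construction, enforced here to machine precision.
#'
#' @param block Numeric matrix, at least 16x16.
#' @return Named numeric vector of length 128.
#' @export
extract_lesh <- function(block) {
  nr <- nrow(block); nc <- ncol(block)
  if (nr < 16L || nc < 16L) stop("LESH needs a block of at least 16x16",
                                 call. = FALSE)
  s <- pop_sd(block)
  if (s > 0) block <- block / s
  pc <- phase_congruency(block)
  lab <- pc$orientation   # 1..8 per pixel
  pcv <- pc$pc_selected
  row_grp <- partition_groups(nr, 4L)
  col_grp <- partition_groups(nc, 4L)
  out <- numeric(128L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    sel <- outer(row_grp == i, col_grp == j, `&`)
    labs <- lab[sel]; vals <- pcv[sel]
    for (b in 1:8) {
      k <- k + 1L
      out[k] <- sum(vals[labs == b])
    }
  }
  nrm <- sqrt(sum(out^2))
  if (nrm > 0) out <- out / nrm
  names(out) <- feature_names_for("LESH")
  out
}

partition_groups <- function(n, g) {
  sizes <- rep(n %/% g, g)
  extra <- n %% g
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(g), sizes)
}

#' Phase congruency maps of a gray-level block
#'
#' @param block Numeric matrix.
#' @param n_scales,n_orient Bank size (defaults 5 scales, 8 orientations).
#' @param min_wavelength,mult,sigma_onf Log-Gabor parameters.
#' @param k Noise threshold in standard deviations (default 2).
#' @param eps Stabilizer (default 1e-4).
#' @return A list: `pc` (list of per-orientation phase congruency maps),
#'   `orientation` (per-pixel index of maximal summed amplitude),
#'   `pc_selected` (phase congruency at the selected orientation).
#' @export
phase_congruency <- function(block, n_scales = 5L, n_orient = 8L,
                             min_wavelength = 3, mult = 2.1,
                             sigma_onf = 0.55, k = 2, eps = 1e-4) {
  nr <- nrow(block); nc <- ncol(block)
  filts <- log_gabor_bank(nr, nc, n_scales, n_orient, min_wavelength,
                          mult, sigma_onf)
  f_img <- fft(block)
  n_tot <- nr * nc
  pc_list <- vector("list", n_orient)
  amp_list <- vector("list", n_orient)
  for (o in seq_len(n_orient)) {
    sumE <- matrix(0, nr, nc); sumO <- matrix(0, nr, nc)
    sumAn <- matrix(0, nr, nc)
    e_s <- vector("list", n_scales); o_s <- vector("list", n_scales)
    tau <- 0
    for (s in seq_len(n_scales)) {
      eo <- fft(f_img * filts[[o]][[s]], inverse = TRUE) / n_tot
      e_s[[s]] <- Re(eo); o_s[[s]] <- Im(eo)
      an <- Mod(eo)
      sumAn <- sumAn + an
      sumE <- sumE + e_s[[s]]
      sumO <- sumO + o_s[[s]]
      if (s == 1L) tau <- median(an) / sqrt(log(4))
    }
    x_energy <- sqrt(sumE^2 + sumO^2) + eps
    mean_e <- sumE / x_energy
    mean_o <- sumO / x_energy
    energy <- matrix(0, nr, nc)
    for (s in seq_len(n_scales)) {
      energy <- energy + e_s[[s]] * mean_e + o_s[[s]] * mean_o -
        abs(e_s[[s]] * mean_o - o_s[[s]] * mean_e)
    }
    # Rayleigh noise model from the smallest-scale amplitude response
    total_tau <- tau * (1 - (1 / mult)^n_scales) / (1 - 1 / mult)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sigma <- total_tau * sqrt((4 - pi) / 2)
    energy <- pmax(energy - (noise_mean + k * noise_sigma), 0)
    pc_list[[o]] <- energy / (sumAn + eps)
    amp_list[[o]] <- sumAn
  }
  # per-pixel orientation of maximal summed amplitude (ties -> lowest index)
  orientation <- matrix(1L, nr, nc)
  best <- amp_list[[1]]
  for (o in 2:n_orient) {
    better <- amp_list[[o]] > best
    orientation[better] <- o
    best[better] <- amp_list[[o]][better]
  }
  pc_selected <- matrix(0, nr, nc)
  for (o in seq_len(n_orient)) {
    sel <- orientation == o
    pc_selected[sel] <- pc_list[[o]][sel]
  }
  list(pc = pc_list, orientation = orientation, pc_selected = pc_selected)
}

# Cached log-Gabor x angular-spread frequency-domain filters.
log_gabor_bank <- function(nr, nc, n_scales, n_orient, min_wavelength,
                           mult, sigma_onf) {
  key <- sprintf("loggabor_%d_%d_%d_%d_%g_%g_%g", nr, nc, n_scales,
                 n_orient, min_wavelength, mult, sigma_onf)
  cached <- get0(key, envir = .octcyst_cache)
  if (!is.null(cached)) return(cached)

  freq_axis <- function(n) {
    f <- (seq_len(n) - 1) / n
    f[f >= 0.5] <- f[f >= 0.5] - 1
    f
  }
  fy <- matrix(freq_axis(nr), nr, nc)          # rows
  fx <- matrix(freq_axis(nc), nr, nc, byrow = TRUE)  # columns
  radius <- sqrt(fx^2 + fy^2)
  radius[1, 1] <- 1
  theta <- atan2(-fy, fx)
  lowpass <- 1 / (1 + (radius / 0.45)^30)

  sin_t <- sin(theta); cos_t <- cos(theta)
  sigma_theta <- 1.2 * (pi / n_orient)

  filts <- lapply(seq_len(n_orient), function(o) {
    angl <- (o - 1) * pi / n_orient
    ds <- sin_t * cos(angl) - cos_t * sin(angl)
    dc <- cos_t * cos(angl) + sin_t * sin(angl)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * sigma_theta^2))
    lapply(seq_len(n_scales), function(s) {
      wavelength <- min_wavelength * mult^(s - 1)
      f0 <- 1 / wavelength
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigma_onf)^2)) * lowpass
      lg[1, 1] <- 0
      lg * spread
    })
  })
  assign(key, filts, envir = .octcyst_cache)
  filts
}
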