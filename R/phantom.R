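#' Specification of a synthetic OCT-like B-scan
#'
#' Collects the parameters of the phantom generator. The phantom emulates the
#' image properties the pipeline assumes: bright layered retinal bands on a
#' dark background, a foveal dip, multiplicative gamma speckle, dark
#' elliptical/fusiform cystoid regions strictly between the ILM and the RPE,
#' vertical hyporeflective shadow columns, and hyperreflective drusen-like
#' bumps of the RPE.
#'
#' @param width,height Image size in pixels (each at least 61, so a default
#'   61x61 analysis window fits).
#' @param n_layers Number of bright bands each column crosses (including the
#'   inner limiting membrane band and the RPE band).
#' @param ilm_baseline,rpe_baseline Baseline row indices (1-based) of the ILM
#'   and RPE away from the fovea; `0 < ilm_baseline < rpe_baseline < height`.
#' @param curvature_amplitude Depth in pixels of the foveal dip (a negative
#'   Gaussian added to the layer rows, strongest at the ILM).
#' @param speckle_shape Shape `k` of the multiplicative gamma speckle (mean 1,
#'   variance `1/k`); `Inf` disables the noise.
#' @param tissue_mean,fluid_mean,background_mean Gray levels in `[0, 255]` of
#'   retinal tissue, intracystoid fluid (hyporeflective, so
#'   `fluid_mean < tissue_mean`), and the vitreous background.
#' @param n_cysts Number of cystoid regions drawn as filled rotated ellipses
#'   with Gaussian-feathered borders.
#' @param cyst_axes_range Length-2 numeric, min and max semi-axis in pixels.
#' @param n_shadows Number of vertical shadow columns.
#' @param shadow_attenuation Multiplicative attenuation factor in `(0, 1)`
#'   applied below a shadow's origin row.
#' @param n_drusen Number of drusen-like hyperreflective RPE bumps.
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return A `phantom_spec` object (named list).
#' @export
phantom_spec <- function(width = 512L, height = 384L, n_layers = 4L,
                         ilm_baseline = 100L, rpe_baseline = 260L,
                         curvature_amplitude = 25, speckle_shape = 16,
                         tissue_mean = 130, fluid_mean = 45,
                         background_mean = 25, n_cysts = 5L,
                         cyst_axes_range = c(10, 40), n_shadows = 2L,
                         shadow_attenuation = 0.6, n_drusen = 2L,
                         seed = 1L) {
  spec <- list(
    width = as.integer(width), height = as.integer(height),
    n_layers = as.integer(n_layers),
    ilm_baseline = as.integer(ilm_baseline),
    rpe_baseline = as.integer(rpe_baseline),
    curvature_amplitude = curvature_amplitude,
    speckle_shape = speckle_shape, tissue_mean = tissue_mean,
    fluid_mean = fluid_mean, background_mean = background_mean,
    n_cysts = as.integer(n_cysts), cyst_axes_range = as.numeric(cyst_axes_range),
    n_shadows = as.integer(n_shadows),
    shadow_attenuation = shadow_attenuation,
    n_drusen = as.integer(n_drusen), seed = as.integer(seed)
  )
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$fluid_mean >= spec$tissue_mean) {
    stop("phantom_spec invariant violated: fluid_mean < tissue_mean ",
         "(cysts are hyporeflective)", call. = FALSE)
  }
  if (!(0 < spec$ilm_baseline && spec$ilm_baseline < spec$rpe_baseline &&
        spec$rpe_baseline < spec$height)) {
    stop("phantom_spec invariant violated: ",
         "0 < ilm_baseline < rpe_baseline < height", call. = FALSE)
  }
  if (spec$width < 61L || spec$height < 61L) {
    stop("phantom_spec invariant violated: width and height must be >= 61",
         call. = FALSE)
  }
  if (spec$n_layers < 2L) {
    stop("phantom_spec invariant violated: n_layers must be >= 2 ",
         "(ILM and RPE bands)", call. = FALSE)
  }
  if (length(spec$cyst_axes_range) != 2L ||
      spec$cyst_axes_range[1] > spec$cyst_axes_range[2] ||
      spec$cyst_axes_range[1] <= 0) {
    stop("phantom_spec invariant violated: cyst_axes_range must be an ",
         "increasing positive pair", call. = FALSE)
  }
  if (spec$shadow_attenuation <= 0 || spec$shadow_attenuation >= 1) {
    stop("phantom_spec invariant violated: shadow_attenuation in (0, 1)",
         call. = FALSE)
  }
  if (!is.finite(spec$speckle_shape) && !is.infinite(spec$speckle_shape)) {
    stop("phantom_spec invariant violated: speckle_shape must be positive ",
         "or Inf", call. = FALSE)
  }
  if (spec$speckle_shape <= 0) {
    stop("phantom_spec invariant violated: speckle_shape must be positive",
         call. = FALSE)
  }
  invisible(spec)
}

#' Generate one synthetic B-scan with ground truth
#'
#' Renders a piecewise-smooth reflectance template (layered retina with a
#' foveal dip), carves feathered elliptical cysts between the ILM and the
#' RPE, raises drusen-like RPE bumps, attenuates shadow columns, applies
#' multiplicative gamma speckle (unit mean), and quantizes to 8 bits.
#' Identical `spec` (including its `seed`) gives bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @param id Identifier stored in the returned `bscan`.
#' @return A list with elements `image` (a [bscan()]) and `truth` (list with
#'   `cyst_mask` logical matrix, `ilm_true` and `rpe_true` per-column row
#'   indices, 1-based).
#' @export
#' @examples
#' p <- generate_bscan(phantom_spec(seed = 7))
#' dim(p$image)
generate_bscan <- function(spec, id = sprintf("phantom-%d", spec$seed)) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  withr::with_seed(spec$seed, generate_bscan_impl(spec, id))
}

generate_bscan_impl <- function(spec, id) {
  h <- spec$height; w <- spec$width
  cols <- seq_len(w)

  # Foveal dip: negative Gaussian centred laterally, plus a gentle random
  # tilt/undulation so boundaries are not perfectly flat.
  centre <- w * runif(1, 0.4, 0.6)
  dip <- spec$curvature_amplitude * exp(-((cols - centre)^2) / (2 * (w / 6)^2))
  tilt <- runif(1, -0.02, 0.02) * (cols - w / 2)
  wave <- runif(1, 0, 3) * sin(2 * pi * cols / runif(1, 200, 400))

  ilm <- spec$ilm_baseline + dip + tilt + wave
  # The dip decays with depth: full at the ILM, slight at the RPE.
  rpe <- spec$rpe_baseline + 0.15 * dip + tilt + 0.5 * wave
  ilm <- round(pmin(pmax(ilm, 2), h - 2))
  rpe <- round(pmin(pmax(rpe, ilm + 20), h - 2))

  tissue <- spec$tissue_mean
  band_hi <- min(tissue + 80, 250)      # RPE band (brightest)
  band_ilm <- min(tissue + 60, 245)     # inner band at the ILM
  band_mid <- tissue + 25               # faint internal plexiform-like bands
  interior <- tissue - 20
  dark_outer <- tissue - 45             # hyporeflective zone above the RPE

  row_idx <- matrix(seq_len(h), h, w)
  ilm_m <- matrix(ilm, h, w, byrow = TRUE)
  rpe_m <- matrix(rpe, h, w, byrow = TRUE)

  img <- matrix(spec$background_mean, h, w)
  inside <- row_idx >= ilm_m & row_idx <= rpe_m
  img[inside] <- interior

  band_thick <- 6L
  # n_layers bright bands: ILM band, RPE band, and n_layers - 2 internal ones.
  img[row_idx >= ilm_m & row_idx <= ilm_m + band_thick] <- band_ilm
  n_mid <- spec$n_layers - 2L
  if (n_mid > 0L) {
    for (j in seq_len(n_mid)) {
      frac <- j / (n_mid + 1.5)       # keep internal bands away from the RPE
      ctr <- ilm_m + frac * (rpe_m - ilm_m)
      img[abs(row_idx - ctr) <= band_thick / 2 & inside] <- band_mid
    }
  }
  # dark outer nuclear-like zone, then the bright RPE band
  img[row_idx > rpe_m - 16 & row_idx <= rpe_m - band_thick] <- dark_outer
  img[row_idx > rpe_m - band_thick & row_idx <= rpe_m] <- band_hi
  # choroid below the RPE
  below <- row_idx > rpe_m
  img[below] <- spec$background_mean + 20 *
    exp(-(row_idx[below] - rpe_m[below]) / 25)

  # Drusen: local upward bumps of the RPE band with hyperreflective fill.
  rpe_top <- rpe - band_thick
  if (spec$n_drusen > 0L) {
    for (d in seq_len(spec$n_drusen)) {
      dc <- runif(1, 0.1, 0.9) * w
      dh <- runif(1, 6, 14)
      dw <- runif(1, 10, 25)
      bump <- dh * exp(-((cols - dc)^2) / (2 * dw^2))
      new_top <- rpe_top - bump
      bump_zone <- row_idx > matrix(new_top, h, w, byrow = TRUE) &
        row_idx <= rpe_m & matrix(bump > 0.5, h, w, byrow = TRUE)
      img[bump_zone] <- band_hi
      rpe_top <- ifelse(bump > 0.5, new_top, rpe_top)
    }
  }
  # Ground-truth boundaries: first tissue row (ILM) and first row of the
  # bright RPE band complex, following any drusen deformation.
  ilm_true <- as.integer(ilm)
  rpe_true <- as.integer(floor(rpe_top) + 1)

  # Cysts: filled rotated ellipses, feathered borders, strictly inside the
  # retina. A fraction gets heavier feathering (blurred borders).
  cyst_mask <- matrix(FALSE, h, w)
  if (spec$n_cysts > 0L) {
    col_idx <- matrix(cols, h, w, byrow = TRUE)
    for (ci in seq_len(spec$n_cysts)) {
      a <- runif(1, spec$cyst_axes_range[1], spec$cyst_axes_range[2])
      b <- runif(1, spec$cyst_axes_range[1], spec$cyst_axes_range[2])
      theta <- runif(1, 0, pi)
      cc <- runif(1, 0.08, 0.92) * w
      depth <- runif(1, 0.25, 0.75)
      c_at <- round(pmin(pmax(cc, 1), w))
      top_lim <- ilm[c_at] + band_thick + 2
      bot_lim <- rpe[c_at] - band_thick - 2
      cr <- top_lim + depth * (bot_lim - top_lim)
      dx <- col_idx - cc
      dy <- row_idx - cr
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      d2 <- (u / a)^2 + (v / b)^2
      feather <- if (runif(1) < 0.3) 0.35 else 0.12   # blurred-border fraction
      alpha <- 1 / (1 + exp((sqrt(pmax(d2, 0)) - 1) / feather))
      # clip strictly between the boundaries (leave the bands and any
      # drusen-deformed RPE top intact)
      margin_ok <- row_idx > ilm_m + band_thick + 1 &
        row_idx < matrix(rpe_top, h, w, byrow = TRUE) - 1
      alpha[!margin_ok] <- 0
      img <- img * (1 - alpha) + spec$fluid_mean * alpha
      cyst_mask <- cyst_mask | (alpha > 0.5)
    }
  }

  # Shadows: columnar multiplicative attenuation below an origin row.
  if (spec$n_shadows > 0L) {
    for (si in seq_len(spec$n_shadows)) {
      sc <- round(runif(1, 0.05, 0.95) * w)
      sw <- round(runif(1, 6, 18))
      c0 <- max(1L, sc - sw %/% 2L); c1 <- min(w, sc + sw %/% 2L)
      origin <- ilm[sc] + band_thick + 2
      zone <- row_idx[, c0:c1, drop = FALSE] > origin
      sub <- img[, c0:c1, drop = FALSE]
      sub[zone] <- sub[zone] * spec$shadow_attenuation
      img[, c0:c1] <- sub
    }
  }

  # Multiplicative gamma speckle (shape k, scale 1/k, unit mean), 8-bit
  # quantization.
  if (is.finite(spec$speckle_shape)) {
    noise <- matrix(
      rgamma(h * w, shape = spec$speckle_shape, rate = spec$speckle_shape),
      h, w
    )
    img <- img * noise
  }
  img <- round(pmin(pmax(img, 0), 255))

  list(
    image = bscan(img, id = id),
    truth = list(cyst_mask = cyst_mask, ilm_true = ilm_true,
                 rpe_true = rpe_true)
  )
}

#' Generate a phantom dataset
#'
#' Generates `n_images` phantoms with per-image seeds derived
#' deterministically from `seed`. Image sizes are jittered within +/-15% of
#' the template, and roughly half the images are rendered without cysts so
#' that both classes are represented.
#'
#' @param spec_template A [phantom_spec()] used as template.
#' @param n_images Number of images (>= 1).
#' @param seed Master seed for the dataset.
#' @return A list of `n_images` elements, each as returned by
#'   [generate_bscan()].
#' @export
generate_dataset <- function(spec_template = phantom_spec(), n_images = 10L,
                             seed = 1L) {
  if (n_images < 1L) stop("n_images must be >= 1", call. = FALSE)
  if (!inherits(spec_template, "phantom_spec")) {
    spec_template <- do.call(phantom_spec, spec_template)
  }
  lapply(seq_len(n_images), function(i) {
    s <- derive_seed(seed, i)
    jit <- withr::with_seed(derive_seed(seed, i, 999L), {
      list(
        wj = runif(1, 0.85, 1.15), hj = runif(1, 0.85, 1.15),
        has_cysts = runif(1) < 0.5
      )
    })
    spec_i <- spec_template
    spec_i$width <- max(61L, as.integer(round(spec_template$width * jit$wj)))
    spec_i$height <- max(61L, as.integer(round(spec_template$height * jit$hj)))
    scale_h <- spec_i$height / spec_template$height
    spec_i$ilm_baseline <- as.integer(round(spec_template$ilm_baseline * scale_h))
    spec_i$rpe_baseline <- as.integer(round(spec_template$rpe_baseline * scale_h))
    if (!jit$has_cysts) spec_i$n_cysts <- 0L
    spec_i$seed <- s
    validate_phantom_spec(spec_i)
    generate_bscan(spec_i, id = sprintf("phantom-%03d", i))
  })
}
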