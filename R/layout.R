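#' Canonical 510-feature layout
#'
#' Returns the canonical registry of the 510 window descriptors: one row per
#' feature with its 1-based index, name and category. Category index ranges
#' are contiguous, disjoint, and cover 1..510:
#' GIBS 1-15, AIS 16-27, EIG 28-55, LESH 56-183, GLCM 184-199, HOG 200-280,
#' GABOR 281-408, LBP 409-472, LAWS 473-500, FD 501-503, GLRL 504-510.
#'
#' @return A tibble with columns `index`, `name`, `category`.
#' @export
#' @examples
#' layout <- feature_layout()
#' dplyr::count(layout, category)
feature_layout <- function() {
  cached <- get0("feature_layout", envir = .octcyst_cache)
  if (!is.null(cached)) return(cached)
  gibs <- paste0("gibs.", c(
    "max", "min", "mean", "median", "sd", "var", "entropy", "p25", "p75",
    "mle.mu", "mle.sigma", "mle.mu.lo", "mle.mu.hi", "mle.sigma.lo",
    "mle.sigma.hi"
  ))
  ais <- paste0("ais.", as.vector(outer(
    c("skew.h", "skew.v", "kurt.h", "kurt.v"),
    c("min", "mean", "max"),
    function(a, b) paste0(b, ".", a)
  )))
  eig <- paste0("eig.", c(
    paste0("max", 1:4), paste0("min", 1:4), "p25", "p75",
    as.vector(t(outer(1:4, 1:4, function(i, j) paste0("r.max", i, ".min", j)))),
    "r.max1.max4", "r.min1.min4"
  ))
  lesh <- paste0(
    "lesh.p", rep(1:16, each = 8), ".o", rep(1:8, times = 16)
  )
  angles <- c("0", "45", "90", "135")
  glcm <- paste0("glcm.", c(
    paste0("contrast.", angles), paste0("correlation.", angles),
    paste0("energy.", angles), paste0("homogeneity.", angles)
  ))
  hog <- paste0("hog.c", rep(1:9, each = 9), ".b", rep(1:9, times = 9))
  fo <- expand.grid(o = 1:8, f = 1:8)[, c("f", "o")]
  fo <- fo[order(fo$f, fo$o), ]
  gabor <- c(
    paste0("gabor.mean.f", fo$f, ".o", fo$o),
    paste0("gabor.sd.f", fo$f, ".o", fo$o)
  )
  pr <- expand.grid(r = 1:8, p = c(4, 8, 12, 16))
  lbp <- c(
    paste0("lbp.mean.p", pr$p, ".r", pr$r),
    paste0("lbp.sd.p", pr$p, ".r", pr$r)
  )
  laws_maps <- c(
    "e3e3", "s3s3", "l3e3", "l3s3", "e3s3",
    "e5e5", "s5s5", "r5r5", "l5e5", "l5s5", "l5r5", "e5s5", "e5r5", "s5r5"
  )
  laws <- c(paste0("laws.mean.", laws_maps), paste0("laws.sd.", laws_maps))
  fd <- paste0("fd.", c("mean", "sd", "lacunarity"))
  glrl <- paste0("glrl.", c("sre", "lre", "gln", "rp", "rln", "lgre", "hgre"))

  names_all <- c(gibs, ais, eig, lesh, glcm, hog, gabor, lbp, laws, fd, glrl)
  sizes <- c(
    GIBS = 15L, AIS = 12L, EIG = 28L, LESH = 128L, GLCM = 16L, HOG = 81L,
    GABOR = 128L, LBP = 64L, LAWS = 28L, FD = 3L, GLRL = 7L
  )
  stopifnot(length(names_all) == 510L, sum(sizes) == 510L)
  layout <- tibble::tibble(
    index = seq_len(510L),
    name = names_all,
    category = rep(names(sizes), sizes)
  )
  assign("feature_layout", layout, envir = .octcyst_cache)
  layout
}

#' Category index ranges of the feature layout
#'
#' @return A tibble with columns `category`, `start`, `end`, `size`.
#' @export
feature_categories <- function() {
  layout <- feature_layout()
  layout |>
    dplyr::group_by(category = .data$category) |>
    dplyr::summarise(
      start = min(.data$index), end = max(.data$index),
      size = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$start)
}
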