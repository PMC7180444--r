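#' Rank features by the trace-ratio criterion
#'
#' Supervised Fisher-style affinity graphs give each feature a
#' between-class scatter `b_i` (cross-class pair weight `1/n`) and a
#' within-class scatter `w_i` (same-class pair weight `1/n_c`); the
#' iterative trace-ratio algorithm then maximizes
#' `sum(b_i) / sum(w_i)` over subsets of size `k`: starting from the top-k
#' by `b_i`, iterate `lambda <- sum_sel(b) / sum_sel(w)` and re-select the
#' `k` largest `b_i - lambda * w_i` until the set is stable. Features are
#' z-scaled internally; the final ranking orders the selected `k` features
#' by `b_i - lambda* w_i` descending, ties broken by lower index. The
#' selector is deterministic (no seed).
#'
#' @param x Numeric matrix or data frame of features (samples x features).
#' @param y Binary labels (factor, character or 0/1), both classes present.
#' @param k Number of features to rank (default 100, at most `ncol(x)`).
#' @param max_iter Iteration cap; a warning is issued if the selected set
#'   has not stabilized (last iterate returned).
#' @return An `oct_ranking`: tibble with columns `rank`, `index`, `name`,
#'   `score`, with attributes `selector` and `lambda`.
#' @export
trace_ratio_rank <- function(x, y, k = 100L, max_iter = 100L) {
  d <- as_labeled_table(x, y)
  k <- min(as.integer(k), ncol(d$x))
  z <- z_scale(d$x)
  bw <- fisher_scatters(z, d$y)
  b <- bw$b; w <- bw$w
  order_desc <- function(score) order(-score, seq_along(score))
  sel <- sort(order_desc(b)[seq_len(k)])
  lambda <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lambda <- sum(b[sel]) / max(sum(w[sel]), .Machine$double.eps)
    new_sel <- sort(order_desc(b - lambda * w)[seq_len(k)])
    if (identical(new_sel, sel)) { converged <- TRUE; break }
    sel <- new_sel
  }
  if (!converged) {
    warning("trace-ratio selection did not stabilize after ", max_iter,
            " iterations; returning the last iterate")
  }
  score <- b - lambda * w
  idx <- sel[order(-score[sel], sel)]
  new_ranking(idx, score[idx], "trace_ratio", names_of(d$x),
              lambda = lambda)
}

# Per-feature between- and within-class scatters under the Fisher-style
# affinity weights (1/n cross-class, 1/n_c same-class).
fisher_scatters <- function(z, y) {
  n <- nrow(z)
  mu <- colMeans(z)
  st <- colSums(sweep(z, 2L, mu)^2)           # total scatter
  w <- numeric(ncol(z))
  for (cls in levels(y)) {
    zc <- z[y == cls, , drop = FALSE]
    w <- w + colSums(sweep(zc, 2L, colMeans(zc))^2)
  }
  weighted_within <- numeric(ncol(z))
  for (cls in levels(y)) {
    zc <- z[y == cls, , drop = FALSE]
    weighted_within <- weighted_within +
      (nrow(zc) / n) * colSums(sweep(zc, 2L, colMeans(zc))^2)
  }
  list(b = st - weighted_within, w = w)
}

#' Rank features with Relief-F
#'
#' Standard Relief-F weights: for every probe instance, the per-feature
#' distance to its `n_neighbors` nearest same-class hits is subtracted and
#' the distance to the nearest misses of the other class (weighted by the
#' class prior ratio) is added, averaged over probes and neighbors.
#' Per-feature distances are absolute differences normalized by the
#' feature range (features are z-scaled first; constant features get
#' weight 0). With `n_probes` equal to the sample count every instance is
#' probed in order; smaller values draw a seeded random subset.
#'
#' @inheritParams trace_ratio_rank
#' @param n_neighbors Nearest hits/misses per probe (default 10); every
#'   class must have more members than `n_neighbors`.
#' @param n_probes Number of probe instances (default: all samples).
#' @param seed Seed for the probe subsample (only used when
#'   `n_probes < n`).
#' @return An `oct_ranking` tibble (see [trace_ratio_rank()]).
#' @export
relief_f_rank <- function(x, y, k = 100L, n_neighbors = 10L,
                          n_probes = NULL, seed = 1L) {
  d <- as_labeled_table(x, y)
  n <- nrow(d$x)
  if (any(table(d$y) <= n_neighbors)) {
    stop("every class must have more than n_neighbors = ", n_neighbors,
         " members", call. = FALSE)
  }
  z <- z_scale(d$x)
  rng <- apply(z, 2L, function(col) diff(range(col)))
  rng[rng == 0] <- 1                      # constant features: diff is 0 anyway
  zn <- sweep(z, 2L, rng, `/`)            # range-normalized for diffs
  if (is.null(n_probes)) n_probes <- n
  probes <- if (n_probes >= n) seq_len(n) else {
    withr::with_seed(seed, sample.int(n, n_probes))
  }
  dmat <- as.matrix(stats::dist(zn, method = "manhattan"))
  priors <- table(d$y) / n
  wts <- numeric(ncol(zn))
  for (i in probes) {
    same <- which(d$y == d$y[i]); same <- setdiff(same, i)
    hits <- same[order(dmat[i, same], same)][seq_len(n_neighbors)]
    miss_contrib <- numeric(ncol(zn))
    for (cls in setdiff(levels(d$y), as.character(d$y[i]))) {
      others <- which(d$y == cls)
      misses <- others[order(dmat[i, others], others)][seq_len(n_neighbors)]
      pw <- priors[[cls]] / (1 - priors[[as.character(d$y[i])]])
      miss_contrib <- miss_contrib +
        pw * colSums(abs(zn[misses, , drop = FALSE] -
                           matrix(zn[i, ], n_neighbors, ncol(zn),
                                  byrow = TRUE)))
    }
    hit_contrib <- colSums(abs(zn[hits, , drop = FALSE] -
                                 matrix(zn[i, ], n_neighbors, ncol(zn),
                                        byrow = TRUE)))
    wts <- wts + (miss_contrib - hit_contrib)
  }
  wts <- wts / (length(probes) * n_neighbors)
  k <- min(as.integer(k), ncol(zn))
  idx <- order(-wts, seq_along(wts))[seq_len(k)]
  new_ranking(idx, wts[idx], "relief_f", names_of(d$x))
}

#' Rank features by extremely-randomized-trees importance
#'
#' Impurity-based importances from an extremely randomized trees ensemble
#' (ranger with the `extratrees` split rule, no bootstrap resampling).
#' Features are consumed raw (tree splits are scale-invariant). Ties and
#' all-zero importances fall back to index order.
#'
#' @inheritParams trace_ratio_rank
#' @param n_trees Ensemble size (default 100, at least 10).
#' @param seed Seed for the ensemble.
#' @return An `oct_ranking` tibble (see [trace_ratio_rank()]).
#' @export
forest_importance_rank <- function(x, y, k = 100L, n_trees = 100L,
                                   seed = 1L) {
  if (n_trees < 10L) stop("n_trees must be >= 10", call. = FALSE)
  d <- as_labeled_table(x, y)
  df <- as.data.frame(d$x)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- d$y
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = n_trees, splitrule = "extratrees",
    num.random.splits = 1L, replace = FALSE, sample.fraction = 1,
    importance = "impurity", seed = seed, num.threads = 1L
  )
  imp <- as.numeric(fit$variable.importance)
  k <- min(as.integer(k), ncol(d$x))
  idx <- order(-imp, seq_along(imp))[seq_len(k)]
  new_ranking(idx, imp[idx], "forest", names_of(d$x))
}

# ---- shared helpers ----

as_labeled_table <- function(x, y) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature table contains missing values", call. = FALSE)
  y <- factor(y)
  if (nlevels(y) < 2L) {
    stop("both classes must be present in the labels", call. = FALSE)
  }
  if (length(y) != nrow(x)) {
    stop("labels and feature rows disagree in length", call. = FALSE)
  }
  list(x = x, y = droplevels(y))
}

names_of <- function(x) {
  if (!is.null(colnames(x))) colnames(x) else paste0("f", seq_len(ncol(x)))
}

z_scale <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  sweep(sweep(x, 2L, center), 2L, scale, `/`)
}

new_ranking <- function(indices, scores, selector, feature_names, ...) {
  tbl <- tibble::tibble(
    rank = seq_along(indices),
    index = as.integer(indices),
    name = feature_names[indices],
    score = as.numeric(scores)
  )
  attr(tbl, "selector") <- selector
  extra <- list(...)
  for (nm in names(extra)) attr(tbl, nm) <- extra[[nm]]
  class(tbl) <- c("oct_ranking", class(tbl))
  tbl
}

#' @export
tidy.oct_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rank", "index", "name", "score")])
}

#' @export
print.oct_ranking <- function(x, ...) {
  cat(sprintf("<oct_ranking: %s> top %d features\n",
              attr(x, "selector"), nrow(x)))
  NextMethod()
}
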