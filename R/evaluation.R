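#' Cross-validation configuration
#'
#' Parameters of the evaluation protocol: repeated stratified k-fold
#' cross-validation with per-fold feature selection and progressive
#' feature subsets (sizes 1..`max_features`, nested prefixes of each
#' ranking).
#'
#' @param n_folds Folds per repeat (default 10, at least 2).
#' @param n_repeats Repeats (default 10).
#' @param max_features Largest feature-subset size (default 100, at most
#'   the number of features).
#' @param selectors Subset of `c("trace_ratio", "relief_f", "forest")`.
#' @param classifiers Subset of the seven supported classifiers (LDA,
#'   L2-ridge, linear and RBF SVM, distance-weighted kNN with k = 15,
#'   random forest, gradient boosting).
#' @param seed Master seed; every random element (fold assignment,
#'   stochastic selectors, tree ensembles) derives its seed from it.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_folds = 10L, n_repeats = 10L, max_features = 100L,
                      selectors = c("trace_ratio", "relief_f", "forest"),
                      classifiers = classifier_names(), seed = 1L) {
  selectors <- match.arg(selectors, c("trace_ratio", "relief_f", "forest"),
                         several.ok = TRUE)
  classifiers <- match.arg(classifiers, classifier_names(),
                           several.ok = TRUE)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  structure(
    list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
         max_features = as.integer(max_features), selectors = selectors,
         classifiers = classifiers, seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' Run the repeated cross-validation protocol
#'
#' For each repeat, samples are split into stratified folds; for each
#' fold, every selector is fitted on the training rows only, and every
#' classifier is trained on the training rows restricted to each nested
#' ranking prefix (subset sizes 1..`max_features`) and scored on the held
#' out fold. Features are z-scaled inside the fold with training
#' statistics for the linear/distance-based classifiers; tree ensembles
#' use raw features. Fully seeded and deterministic.
#'
#' @param table A tibble or data frame with a `label` column (binary) and
#'   feature columns (everything except `source_id`, `row`, `col`, `W`,
#'   `label`).
#' @param config A [cv_config()].
#' @return An `oct_cv` object: tibble of CV records with columns
#'   `repeat_id`, `fold`, `selector`, `classifier`, `subset_size`,
#'   `accuracy`, with the config and the per-fold rankings as attributes.
#' @export
run_cv <- function(table, config = cv_config()) {
  xy <- split_feature_table(table)
  x <- xy$x; y <- xy$y
  if (config$max_features > ncol(x)) {
    stop("max_features exceeds the number of features", call. = FALSE)
  }
  records <- list()
  rankings <- list()
  for (r in seq_len(config$n_repeats)) {
    folds <- stratified_folds(y, config$n_folds,
                              seed = derive_seed(config$seed, r))
    for (f in seq_len(config$n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      if (nlevels(droplevels(y[test_idx])) < 2L ||
          nlevels(droplevels(y[train_idx])) < 2L) {
        stop("stratification failed: a fold is missing a class",
             call. = FALSE)
      }
      x_tr <- x[train_idx, , drop = FALSE]
      y_tr <- y[train_idx]
      x_te <- x[test_idx, , drop = FALSE]
      y_te <- y[test_idx]
      ctr <- colMeans(x_tr)
      scl <- apply(x_tr, 2L, sd); scl[scl == 0 | !is.finite(scl)] <- 1
      x_tr_z <- z_scale(x_tr, ctr, scl)
      x_te_z <- z_scale(x_te, ctr, scl)
      for (sel in config$selectors) {
        sel_seed <- derive_seed(config$seed, r, f, match(sel, c(
          "trace_ratio", "relief_f", "forest"
        )))
        rk <- switch(sel,
          trace_ratio = trace_ratio_rank(x_tr, y_tr,
                                         k = config$max_features),
          relief_f = relief_f_rank(x_tr, y_tr, k = config$max_features,
                                   seed = sel_seed),
          forest = forest_importance_rank(x_tr, y_tr,
                                          k = config$max_features,
                                          seed = sel_seed)
        )
        rankings[[length(rankings) + 1L]] <- list(
          repeat_id = r, fold = f, selector = sel, ranking = rk
        )
        for (clf in config$classifiers) {
          scaled <- classifier_needs_scaling(clf)
          xtr <- if (scaled) x_tr_z else x_tr
          xte <- if (scaled) x_te_z else x_te
          accs <- numeric(config$max_features)
          for (m in seq_len(config$max_features)) {
            cols <- rk$index[seq_len(m)]
            pred <- fit_predict(
              clf, xtr[, cols, drop = FALSE], y_tr,
              xte[, cols, drop = FALSE],
              seed = derive_seed(sel_seed, match(clf, classifier_names()), m)
            )
            accs[m] <- mean(pred == y_te)
          }
          records[[length(records) + 1L]] <- tibble::tibble(
            repeat_id = r, fold = f, selector = sel, classifier = clf,
            subset_size = seq_len(config$max_features), accuracy = accs
          )
        }
      }
    }
  }
  out <- dplyr::bind_rows(records)
  attr(out, "config") <- config
  attr(out, "rankings") <- rankings
  class(out) <- c("oct_cv", class(out))
  out
}

# Stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin over folds.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in levels(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

# Separate metadata columns from feature columns and the label.
split_feature_table <- function(table) {
  tbl <- tibble::as_tibble(table)
  if (!"label" %in% names(tbl)) {
    stop("the table needs a `label` column", call. = FALSE)
  }
  meta <- intersect(c("source_id", "row", "col", "W", "label"), names(tbl))
  x <- as.matrix(tbl[setdiff(names(tbl), meta)])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature columns contain missing values", call. = FALSE)
  y <- factor(tbl$label)
  if (nlevels(y) < 2L) stop("both classes must be present", call. = FALSE)
  list(x = x, y = y, meta = tbl[meta])
}

#' @export
tidy.oct_cv <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("repeat_id", "fold", "selector",
                                 "classifier", "subset_size", "accuracy")])
}

#' @export
glance.oct_cv <- function(x, ...) {
  best_results(x)
}

#' Mean accuracy curves over subset sizes
#'
#' Mean and standard deviation of the test accuracy over all repeats and
#' folds, per (selector, classifier) and subset size.
#'
#' @param records An `oct_cv` object or its tidy tibble.
#' @return A tibble with `selector`, `classifier`, `subset_size`,
#'   `mean_accuracy`, `sd_accuracy`, `n`.
#' @export
accuracy_curves <- function(records) {
  tbl <- tibble::as_tibble(records)
  check_complete_records(tbl)
  tbl |>
    dplyr::group_by(.data$selector, .data$classifier, .data$subset_size) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = sd(.data$accuracy),
      n = dplyr::n(), .groups = "drop"
    )
}

check_complete_records <- function(tbl) {
  cells <- tbl |>
    dplyr::count(.data$selector, .data$classifier, .data$subset_size)
  if (length(unique(cells$n)) > 1L) {
    bad <- cells[cells$n < max(cells$n), ]
    stop("incomplete record set: missing cells for ",
         paste(utils::head(paste(bad$selector, bad$classifier,
                                 bad$subset_size), 5L), collapse = "; "),
         call. = FALSE)
  }
  invisible(tbl)
}

#' Best mean accuracy per selector and classifier
#'
#' The maximum of the mean accuracy curve and the (smallest) subset size
#' attaining it, plus milestone accuracies at sizes
#' {1, 5, 10, 20, 30, 50, 70, 100} (those available) and the
#' stabilization statistic: mean and standard deviation of the
#' successive-size accuracy differences over the last 50 subset sizes.
#'
#' @param records An `oct_cv` object or its tidy tibble.
#' @return A tibble with one row per (selector, classifier):
#'   `best_accuracy`, `best_size`, `milestones` (list column of named
#'   vectors), `tail_diff_mean`, `tail_diff_sd`.
#' @export
best_results <- function(records) {
  curves <- accuracy_curves(records)
  milestone_sizes <- c(1L, 5L, 10L, 20L, 30L, 50L, 70L, 100L)
  curves |>
    dplyr::group_by(.data$selector, .data$classifier) |>
    dplyr::arrange(.data$subset_size, .by_group = TRUE) |>
    dplyr::summarise(
      best_accuracy = max(.data$mean_accuracy),
      best_size = .data$subset_size[which.max(.data$mean_accuracy)],
      milestones = list({
        ms <- milestone_sizes[milestone_sizes <= max(.data$subset_size)]
        stats::setNames(.data$mean_accuracy[match(ms, .data$subset_size)],
                        ms)
      }),
      tail_diff_mean = mean(tail_diffs(.data$mean_accuracy)),
      tail_diff_sd = sd(tail_diffs(.data$mean_accuracy)),
      .groups = "drop"
    )
}

tail_diffs <- function(acc, n_tail = 50L) {
  d <- diff(acc)
  utils::tail(d, n_tail)
}

#' Absolute pairwise feature correlations
#'
#' Absolute Pearson correlations between all feature columns, with the
#' convention that constant features correlate 0, plus the mean
#' correlation per category pair, excluding the self-pair diagonal.
#'
#' @param table A feature table (metadata columns are dropped; a `label`
#'   column is optional here) with at least 3 rows.
#' @param layout Feature layout tibble mapping column names to
#'   categories; defaults to [feature_layout()] when the columns match
#'   it, otherwise every column is one category.
#' @return A list: `matrix` (absolute correlations) and `category_means`
#'   (tibble `category_a`, `category_b`, `mean_abs_correlation`).
#' @export
pairwise_correlation <- function(table, layout = NULL) {
  tbl <- tibble::as_tibble(table)
  meta <- intersect(c("source_id", "row", "col", "W", "label"), names(tbl))
  x <- as.matrix(tbl[setdiff(names(tbl), meta)])
  storage.mode(x) <- "double"
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  cm <- suppressWarnings(abs(cor(x)))
  cm[!is.finite(cm)] <- 0      # constant features
  if (is.null(layout)) {
    fl <- feature_layout()
    layout <- if (all(colnames(x) %in% fl$name)) fl else {
      tibble::tibble(name = colnames(x), category = colnames(x))
    }
  }
  cats <- layout$category[match(colnames(x), layout$name)]
  ucats <- unique(cats)
  pairs <- expand.grid(category_a = ucats, category_b = ucats,
                       stringsAsFactors = FALSE)
  pairs$mean_abs_correlation <- vapply(seq_len(nrow(pairs)), function(i) {
    sub <- cm[cats == pairs$category_a[i], cats == pairs$category_b[i],
              drop = FALSE]
    if (pairs$category_a[i] == pairs$category_b[i]) {
      n <- nrow(sub)
      if (n < 2L) return(0)
      sum(sub[upper.tri(sub) | lower.tri(sub)]) / (n * n - n)
    } else {
      mean(sub)
    }
  }, numeric(1))
  list(matrix = cm, category_means = tibble::as_tibble(pairs))
}

#' Category presence in top-100 rankings
#'
#' Absolute presence counts of each feature category in the top-`k`
#' rankings, averaged over folds, and the proportional presence: the
#' average count divided by `min(k, category size)` (the maximum
#' attainable presence for the category).
#'
#' @param rankings A list of `oct_ranking` objects (e.g. the `rankings`
#'   attribute of an `oct_cv`, or plain rankings), all over the canonical
#'   layout.
#' @param layout Feature layout (defaults to [feature_layout()]).
#' @param k Ranking depth (default 100).
#' @return A tibble per (selector, category): `mean_count`,
#'   `proportional_presence`.
#' @export
category_presence <- function(rankings, layout = feature_layout(),
                              k = 100L) {
  rk_tbl <- rankings_to_tbl(rankings, layout, k)
  cat_sizes <- layout |> dplyr::count(.data$category, name = "size")
  n_folds <- rk_tbl |> dplyr::distinct(.data$selector, .data$fold_key) |>
    dplyr::count(.data$selector, name = "n_folds")
  base <- tidyr::expand_grid(
    selector = unique(rk_tbl$selector),
    category = unique(layout$category)
  )
  counts <- rk_tbl |>
    dplyr::count(.data$selector, .data$fold_key, .data$category) |>
    dplyr::group_by(.data$selector, .data$category) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  base |>
    dplyr::left_join(counts, by = c("selector", "category")) |>
    dplyr::left_join(n_folds, by = "selector") |>
    dplyr::left_join(cat_sizes, by = "category") |>
    dplyr::mutate(
      mean_count = dplyr::coalesce(.data$total, 0L) / .data$n_folds,
      proportional_presence = .data$mean_count / pmin(k, .data$size)
    ) |>
    dplyr::select("selector", "category", "mean_count",
                  "proportional_presence")
}

#' Category relevance score from best achieved rank
#'
#' For each category and selector, the best (minimum) 1-based rank `r`
#' achieved by any of its features across all folds is mapped to the
#' score `100 * (100 - r) / 99`, so rank 1 scores 100 and rank 100 scores
#' 0; categories absent from every top-`k` score -1.
#'
#' @inheritParams category_presence
#' @return A tibble per (selector, category): `best_rank` (NA when
#'   absent) and `score`.
#' @export
category_score <- function(rankings, layout = feature_layout(), k = 100L) {
  rk_tbl <- rankings_to_tbl(rankings, layout, k)
  base <- tidyr::expand_grid(
    selector = unique(rk_tbl$selector),
    category = unique(layout$category)
  )
  best <- rk_tbl |>
    dplyr::group_by(.data$selector, .data$category) |>
    dplyr::summarise(best_rank = min(.data$rank), .groups = "drop")
  base |>
    dplyr::left_join(best, by = c("selector", "category")) |>
    dplyr::mutate(
      score = ifelse(is.na(.data$best_rank), -1,
                     100 * (100 - .data$best_rank) / 99)
    )
}

# Normalize ranking input (list of oct_ranking or run_cv rankings attr)
# into one tibble with selector, fold key, rank and category.
rankings_to_tbl <- function(rankings, layout, k) {
  if (inherits(rankings, "oct_ranking")) rankings <- list(rankings)
  rows <- lapply(seq_along(rankings), function(i) {
    item <- rankings[[i]]
    if (inherits(item, "oct_ranking")) {
      rk <- item
      selector <- attr(rk, "selector") %||% "selector"
      fold_key <- as.character(i)
    } else {
      rk <- item$ranking
      selector <- item$selector %||% attr(rk, "selector") %||% "selector"
      fold_key <- paste(item$repeat_id %||% i, item$fold %||% i, sep = ".")
    }
    top <- rk[rk$rank <= k, ]
    tibble::tibble(
      selector = selector, fold_key = fold_key,
      rank = top$rank, name = top$name
    )
  })
  out <- dplyr::bind_rows(rows)
  out$category <- layout$category[match(out$name, layout$name)]
  if (anyNA(out$category)) {
    stop("ranking feature names not found in the layout", call. = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
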