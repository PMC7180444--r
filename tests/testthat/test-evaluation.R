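make_cv_table <- function(n = 60, n_feat = 12, seed = 1, label_copy = FALSE) {
  withr::with_seed(seed, {
    y <- rep(c("cystoid", "non_cystoid"), each = n / 2)
    x <- matrix(rnorm(n * n_feat), n, n_feat)
    if (label_copy) x[, 1] <- as.numeric(y == "cystoid")
    colnames(x) <- paste0("f", seq_len(n_feat))
    tbl <- tibble::as_tibble(as.data.frame(x))
    tbl$label <- y
    tbl
  })
}

test_that("run_cv emits the full record grid, stratified and seeded", {
  tbl <- make_cv_table(n = 60, n_feat = 12, seed = 2)
  cfg <- cv_config(n_folds = 3L, n_repeats = 2L, max_features = 4L,
                   selectors = c("trace_ratio", "forest"),
                   classifiers = c("lda", "knn15"), seed = 9L)
  cv <- run_cv(tbl, cfg)
  expect_equal(nrow(cv), 2L * 3L * 2L * 2L * 4L)
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  counts <- dplyr::count(tidy(cv), .data$selector, .data$classifier,
                         .data$subset_size)
  expect_true(all(counts$n == 6L))
  # determinism
  cv2 <- run_cv(tbl, cfg)
  expect_equal(tidy(cv), tidy(cv2))
  # stratification: each fold of each repeat holds both classes
  y <- factor(tbl$label)
  for (r in 1:2) {
    folds <- octcyst:::stratified_folds(y, 3L,
                                        octcyst:::derive_seed(9L, r))
    expect_true(all(table(folds, y) > 0))
  }
})

test_that("a label-copy feature drives accuracy to 1 at every size", {
  tbl <- make_cv_table(n = 40, n_feat = 6, seed = 3, label_copy = TRUE)
  cfg <- cv_config(n_folds = 2L, n_repeats = 1L, max_features = 3L,
                   selectors = "forest", classifiers = "knn15", seed = 1L)
  cv <- run_cv(tbl, cfg)
  expect_true(all(cv$accuracy == 1))
})

test_that("feature selection sees only the training rows", {
  tbl <- make_cv_table(n = 60, n_feat = 10, seed = 4)
  xy <- octcyst:::split_feature_table(tbl)
  folds <- octcyst:::stratified_folds(xy$y, 3L, seed = 11L)
  test_idx <- which(folds == 1L)
  train_idx <- which(folds != 1L)
  rk1 <- trace_ratio_rank(xy$x[train_idx, ], xy$y[train_idx], k = 5)
  # shuffle the held-out labels: the fitted ranking must not move
  y2 <- xy$y
  y2[test_idx] <- withr::with_seed(12, sample(y2[test_idx]))
  rk2 <- trace_ratio_rank(xy$x[train_idx, ], y2[train_idx], k = 5)
  expect_identical(tidy(rk1), tidy(rk2))
  # and the ranking recorded by run_cv equals the train-only ranking
  cfg <- cv_config(n_folds = 3L, n_repeats = 1L, max_features = 5L,
                   selectors = "trace_ratio", classifiers = "lda",
                   seed = 11L)
  cv <- run_cv(tbl, cfg)
  rks <- attr(cv, "rankings")
  fold1 <- Filter(function(r) r$fold == 1L, rks)[[1]]
  folds_cv <- octcyst:::stratified_folds(xy$y, 3L,
                                         octcyst:::derive_seed(11L, 1L))
  rk_direct <- trace_ratio_rank(xy$x[folds_cv != 1L, ],
                                xy$y[folds_cv != 1L], k = 5)
  expect_identical(tidy(fold1$ranking), tidy(rk_direct))
})

test_that("subset prefixes are nested within a fold", {
  tbl <- make_cv_table(n = 40, n_feat = 8, seed = 5)
  cfg <- cv_config(n_folds = 2L, n_repeats = 1L, max_features = 6L,
                   selectors = "forest", classifiers = "lda", seed = 2L)
  cv <- run_cv(tbl, cfg)
  for (r in attr(cv, "rankings")) {
    idx <- r$ranking$index
    for (m in 2:length(idx)) {
      expect_true(all(idx[seq_len(m - 1L)] %in% idx[seq_len(m)]))
    }
  }
})

test_that("accuracy curves aggregate records correctly", {
  toy <- tibble::tibble(
    repeat_id = c(1L, 1L, 2L, 2L),
    fold = c(1L, 2L, 1L, 2L),
    selector = "s", classifier = "c",
    subset_size = c(1L, 1L, 1L, 1L),
    accuracy = c(0.5, 0.7, 0.9, 0.7)
  )
  curves <- accuracy_curves(toy)
  expect_equal(nrow(curves), 1L)
  expect_equal(curves$mean_accuracy, 0.7)
  expect_equal(curves$sd_accuracy, stats::sd(c(0.5, 0.7, 0.9, 0.7)))
  # flat records give a flat curve of max_features points
  flat <- tidyr::expand_grid(repeat_id = 1L, fold = 1:2, selector = "s",
                             classifier = "c", subset_size = 1:5)
  flat$accuracy <- 0.8
  cf <- accuracy_curves(flat)
  expect_equal(nrow(cf), 5L)
  expect_true(all(cf$mean_accuracy == 0.8))
  # missing cells are an error
  expect_error(accuracy_curves(flat[-1, ]), "incomplete")
})

test_that("best_results picks the maximum and its smallest subset size", {
  toy <- tibble::tibble(
    repeat_id = 1L, fold = 1L, selector = "s", classifier = "c",
    subset_size = 1:3, accuracy = c(0.7, 0.9, 0.8)
  )
  br <- best_results(toy)
  expect_equal(br$best_accuracy, 0.9)
  expect_equal(br$best_size, 2L)
  # flat curve: first size attaining the maximum
  toy$accuracy <- 0.75
  expect_equal(best_results(toy)$best_size, 1L)
  # monotone curve: argmax at max_features
  toy$accuracy <- c(0.6, 0.7, 0.8)
  expect_equal(best_results(toy)$best_size, 3L)
})

test_that("pairwise correlation follows the stated conventions", {
  withr::with_seed(6, {
    a <- rnorm(50); b <- rnorm(50); c <- a + rnorm(50, sd = 0.01)
  })
  tbl <- tibble::tibble(x1 = a, x2 = b, x3 = a, x4 = rep(1, 50))
  pc <- pairwise_correlation(tbl)
  expect_equal(pc$matrix["x1", "x3"], 1)
  expect_equal(pc$matrix["x1", "x4"], 0)     # constant feature
  expect_equal(unname(diag(pc$matrix))[1:3], rep(1, 3))
  # hand-computed 3-feature check
  tbl2 <- tibble::tibble(p = c(1, 2, 3, 4), q = c(2, 4, 6, 9),
                         r = c(4, 3, 2, 1))
  pc2 <- pairwise_correlation(tbl2)
  expect_equal(pc2$matrix["p", "q"], abs(stats::cor(tbl2$p, tbl2$q)))
  expect_equal(pc2$matrix["p", "r"], 1)
  # independent noise: small mean absolute correlation
  withr::with_seed(7, {
    noise <- tibble::as_tibble(matrix(rnorm(1000 * 8), 1000, 8),
                               .name_repair = "minimal")
  })
  names(noise) <- paste0("n", 1:8)
  pcn <- pairwise_correlation(noise)
  off <- pcn$matrix[upper.tri(pcn$matrix)]
  expect_lt(mean(off), 0.1)
})

test_that("category presence and score follow the layout arithmetic", {
  layout <- feature_layout()
  # ranking = the first 100 layout indices
  rk <- octcyst:::new_ranking(1:100, seq(100, 1), "toy", layout$name)
  pres <- category_presence(list(rk))
  gibs <- pres[pres$category == "GIBS", ]
  expect_equal(gibs$mean_count, 15)
  expect_equal(gibs$proportional_presence, 1)
  lesh <- pres[pres$category == "LESH", ]   # indices 56..100 of 56..183
  expect_equal(lesh$mean_count, 45)
  expect_equal(lesh$proportional_presence, 45 / 100)
  glrl <- pres[pres$category == "GLRL", ]   # absent from the first 100
  expect_equal(glrl$mean_count, 0)
  sc <- category_score(list(rk))
  expect_equal(sc$score[sc$category == "GIBS"], 100)   # rank 1
  expect_equal(sc$score[sc$category == "GLRL"], -1)    # absent
  # a category whose best marker sits at rank 100 scores 0
  rk2 <- octcyst:::new_ranking(c(1:99, 504L), seq(100, 1), "toy",
                               layout$name)
  sc2 <- category_score(list(rk2))
  expect_equal(sc2$score[sc2$category == "GLRL"], 0)
  # best rank 50 maps to 100 * 50 / 99
  rk3 <- octcyst:::new_ranking(c(1:49, 504L, 50:99), seq(100, 1), "toy",
                               layout$name)
  sc3 <- category_score(list(rk3))
  expect_equal(sc3$score[sc3$category == "GLRL"], 100 * 50 / 99)
  # averaging over two folds
  pres2 <- category_presence(list(rk, rk2))
  expect_equal(pres2$mean_count[pres2$category == "GLRL"], 0.5)
})

test_that("chance-level data stays near one half", {
  tbl <- make_cv_table(n = 80, n_feat = 10, seed = 8)
  tbl$label <- withr::with_seed(9, sample(tbl$label))
  cfg <- cv_config(n_folds = 4L, n_repeats = 1L, max_features = 3L,
                   selectors = "forest", classifiers = "lda", seed = 3L)
  cv <- run_cv(tbl, cfg)
  expect_gte(mean(cv$accuracy), 0.25)
  expect_lte(mean(cv$accuracy), 0.75)
})
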