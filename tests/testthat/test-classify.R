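make_blobs <- function(n = 40, sep = 4, seed = 1, p = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n * p), ncol = p),
               matrix(rnorm(n * p, mean = sep), ncol = p))
  })
  list(x = x, y = rep(c("pos", "neg"), each = n))
}

test_that("kernel_scale follows the sqrt(P) / 4 sqrt(P) rule", {
  expect_equal(kernel_scale(571, "medium"), sqrt(571))
  expect_equal(kernel_scale(571, "coarse"), 4 * sqrt(571))
  expect_equal(kernel_scale(82, "medium"), sqrt(82))
  expect_equal(kernel_scale(82, "coarse"), 4 * sqrt(82))
  expect_equal(kernel_scale(1, "medium"), 1)
  expect_equal(kernel_scale(1, "coarse"), 4)
  expect_error(kernel_scale(0, "medium"), "valid range")
})

test_that("balance_and_split balances, stratifies and is seed-deterministic", {
  wn <- seq(400, 1800, length.out = 20)
  n_big <- 40; n_small <- 12
  m <- matrix(runif(20 * (n_big + n_small)), nrow = 20)
  x <- spectra_from_matrix(m, wn,
                           sample_id = sprintf("s%03d", seq_len(n_big + n_small)),
                           label = rep(c("big", "small"), c(n_big, n_small)))
  sp <- balance_and_split(x, train_frac = 0.8, seed = 5)
  tr_labs <- spectra_labels(sp$train)
  ho_labs <- spectra_labels(sp$holdout)
  expect_equal(as.vector(table(tr_labs)[c("big", "small")]), c(9L, 9L))
  expect_equal(as.vector(table(ho_labs)[c("big", "small")]), c(3L, 3L))
  expect_equal(length(intersect(names(tr_labs), names(ho_labs))), 0)

  sp2 <- balance_and_split(x, train_frac = 0.8, seed = 5)
  expect_identical(sp$train, sp2$train)

  tiny <- spectra_from_matrix(m[, 1:6], wn, sample_id = letters[1:6],
                              label = rep(c("a", "b"), c(4, 2)))
  expect_error(balance_and_split(tiny), "at least 5")
})

test_that("an 80/20 split of 100 + 100 gives 80/20 per class", {
  wn <- 1:10
  m <- matrix(runif(10 * 200), nrow = 10)
  x <- spectra_from_matrix(m, wn, sample_id = sprintf("s%03d", 1:200),
                           label = rep(c("u", "v"), each = 100))
  sp <- balance_and_split(x, train_frac = 0.8, seed = 2)
  expect_equal(as.vector(table(spectra_labels(sp$train))), c(80L, 80L))
  expect_equal(as.vector(table(spectra_labels(sp$holdout))), c(20L, 20L))
})

test_that("well-separated blobs are classified perfectly", {
  b <- make_blobs(n = 40, sep = 4)
  model <- train_svm(b$x, b$y, positive = "pos", kernel = "medium")
  expect_equal(model$kernel_scale, sqrt(2))
  test <- make_blobs(n = 20, sep = 4, seed = 99)
  sc <- predict_scores(model, test$x)
  expect_equal(mean(sc$pred == test$y), 1)
  cv <- cross_validate(b$x, b$y, positive = "pos", kernel = "medium", k = 5,
                       seed = 3)
  expect_equal(cv$accuracy, 100)
})

test_that("permuted labels give chance-level cross-validation accuracy", {
  accs <- vapply(1:20, function(s) {
    b <- make_blobs(n = 20, sep = 4, seed = s)
    y_perm <- withr::with_seed(1000 + s, sample(b$y))
    cross_validate(b$x, y_perm, positive = "pos", k = 5, seed = s)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("train_svm rejects degenerate inputs", {
  b <- make_blobs(n = 10)
  expect_error(train_svm(b$x[1:10, ], b$y[1:10]), "2 classes")
  expect_error(train_svm(b$x, b$y, positive = "nope"), "not in labels")
  xb <- b$x; xb[1, 1] <- NA
  expect_error(train_svm(xb, b$y), "non-finite")
})

test_that("score sign semantics: positive score means positive class", {
  b <- make_blobs(n = 30, sep = 5)
  model <- train_svm(b$x, b$y, positive = "pos")
  sc <- predict_scores(model, b$x)
  expect_true(all(sc$pred[sc$score > 0] == "pos"))
  expect_true(all(sc$pred[sc$score <= 0] == "neg"))
  expect_gt(mean(sc$score[b$y == "pos"]), mean(sc$score[b$y == "neg"]))
  expect_error(predict_scores(model, b$x[, 1, drop = FALSE]),
               "does not match")
})

test_that("cross_validate enforces fold-size preconditions", {
  b <- make_blobs(n = 4)
  expect_error(cross_validate(b$x, b$y, k = 5, seed = 1), "fewer than k")
  expect_error(cross_validate(b$x, b$y, k = 1, seed = 1), "at least 2")
})

test_that("confusion metrics match the hand-computed example", {
  truth <- c(rep("hi", 10), rep("lo", 10))
  pred <- c(rep("hi", 9), "lo", rep("lo", 8), "hi", "hi")
  scores <- ifelse(pred == "hi", 1, -1) + rnorm(20, 0, 0.01)
  ev <- evaluate_predictions(truth, pred, scores, positive = "hi")
  expect_equal(c(ev$tp, ev$fn, ev$tn, ev$fp), c(9, 1, 8, 2))
  expect_equal(ev$sensitivity, 90)
  expect_equal(ev$specificity, 80)
  expect_equal(ev$accuracy, 85)
})

test_that("metric identities hold on random confusion data", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(10:200, 1)
    truth <- sample(c("hi", "lo"), n, replace = TRUE, prob = c(runif(1, 0.2, 0.8), 1))
    if (length(unique(truth)) < 2) next
    scores <- rnorm(n)
    pred <- ifelse(scores > 0, "hi", "lo")
    ev <- evaluate_predictions(truth, pred, scores, positive = "hi")
    expect_equal(ev$accuracy, 100 * (ev$tp + ev$tn) / n)
    if (ev$tp + ev$fn > 0) expect_equal(ev$sensitivity, 100 * ev$tp / (ev$tp + ev$fn))
    if (ev$tn + ev$fp > 0) expect_equal(ev$specificity, 100 * ev$tn / (ev$tn + ev$fp))
    expect_equal(ev$roc$fpr[1], 0); expect_equal(ev$roc$tpr[1], 0)
    expect_equal(ev$roc$fpr[nrow(ev$roc)], 1)
    expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
    expect_true(all(diff(ev$roc$fpr) >= 0))
    expect_gte(ev$auc, 0); expect_lte(ev$auc, 1)
  }
})

test_that("AUC is 1 for perfectly ordered scores and invariant to monotone maps", {
  truth <- rep(c("hi", "lo"), each = 25)
  scores <- c(runif(25, 1, 2), runif(25, -2, -1))
  pred <- ifelse(scores > 0, "hi", "lo")
  ev <- evaluate_predictions(truth, pred, scores, "hi")
  expect_equal(ev$auc, 1)

  set.seed(32)
  scores2 <- rnorm(50)
  pred2 <- ifelse(scores2 > 0, "hi", "lo")
  a1 <- evaluate_predictions(truth, pred2, scores2, "hi")$auc
  a2 <- evaluate_predictions(truth, pred2, exp(3 * scores2) + 5, "hi")$auc
  expect_equal(a1, a2)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  for (k in 1:10) {
    n <- 60
    truth <- sample(c("hi", "lo"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- rnorm(n) + (truth == "hi") * runif(1, 0, 2)
    pred <- ifelse(scores > 0, "hi", "lo")
    mine <- evaluate_predictions(truth, pred, scores, "hi")$auc
    ref <- suppressMessages(pROC::auc(pROC::roc(
      response = truth, predictor = scores, levels = c("lo", "hi"),
      direction = "<")))
    expect_equal(mine, as.numeric(ref))
  }
})

test_that("random scores give chance AUC on large samples", {
  set.seed(34)
  truth <- rep(c("hi", "lo"), each = 500)
  scores <- rnorm(1000)
  pred <- ifelse(scores > 0, "hi", "lo")
  ev <- evaluate_predictions(truth, pred, scores, "hi")
  expect_lt(abs(ev$auc - 0.5), 0.05)
})

test_that("run_experiment populates the full grid with the mask applied", {
  cfg <- toy_synth_config()
  cfg$bands$delta <- ifelse(cfg$bands$target_d > 0, 0.03, 0)
  train <- generate_dataset(cfg, seed = 41)
  pp <- preprocess_spectra(train)
  gs <- group_summaries(pp)
  mask <- double_sd_mask(gs$high_cx43, gs$low_cx43)
  test1 <- preprocess_spectra(generate_dataset(cfg, seed = 42))
  res <- run_experiment(pp, testing = list(testing1 = test1), mask = mask,
                        positive = "high_cx43", folds = 3, seed = 7)
  expect_equal(nrow(res), 2 * 2 * 2)  # kernel x mode x scenario
  expect_setequal(unique(res$scenario), c("training", "testing1"))
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  n_sel <- attr(mask, "n_selected")
  expect_true(all(res$n_features[res$feature_mode == "selected"] == n_sel))
  expect_true(all(res$n_features[res$feature_mode == "all"] == 571))
  expect_error(run_experiment(pp, mask = NULL, positive = "high_cx43"),
               "requires a feature mask")
})

test_that("median test accuracy rises monotonically with programmed contrast", {
  base_cfg <- synth_config(n_per_class = 40, seed = 51)
  levels <- c(0, 1, 2)  # multiples of a modest per-band contrast
  n_seeds <- 20
  acc <- matrix(NA_real_, n_seeds, length(levels))
  for (li in seq_along(levels)) {
    cfg <- base_cfg
    cfg$bands$delta <- levels[[li]] * 0.008 * cfg$bands$target_d
    for (s in seq_len(n_seeds)) {
      pp <- preprocess_spectra(generate_dataset(cfg, seed = 5200 + s))
      sp <- balance_and_split(pp, train_frac = 0.8, seed = 5300 + s)
      model <- train_svm(sp$train, positive = "high_cx43", kernel = "coarse")
      sc <- predict_scores(model, sp$holdout)
      acc[s, li] <- 100 * mean(sc$pred == unname(spectra_labels(sp$holdout)))
    }
  }
  med <- apply(acc, 2, median)
  expect_true(all(diff(med) >= 0),
              label = sprintf("medians %s", paste(round(med, 1), collapse = " <= ")))
})
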