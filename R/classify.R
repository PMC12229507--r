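# Gaussian-kernel SVM classification of high- vs low-Cx43 spectra.

#' Kernel scale for the medium and coarse Gaussian kernels
#'
#' With P predictors, the medium Gaussian kernel uses scale `sqrt(P)` and
#' the coarse kernel `4 * sqrt(P)`. The kernel is
#' `K(u, v) = exp(-||u - v||^2 / s^2)`, i.e. `gamma = 1 / s^2`.
#'
#' @param p Number of predictors (>= 1).
#' @param kind `"medium"` or `"coarse"`.
#' @return Kernel scale `s`.
#' @export
kernel_scale <- function(p, kind = c("medium", "coarse")) {
  kind <- match.arg(kind)
  .assert_scalar_number(p, "p", lower = 1)
  switch(kind, medium = sqrt(p), coarse = 4 * sqrt(p))
}

#' Balance classes and split into training and holdout sets
#'
#' Both classes are subsampled (without replacement, seeded) to the smaller
#' class size, then split stratified so that `train_frac` of each class goes
#' to training and the rest to holdout. Deterministic given `seed`.
#'
#' @param x An `fgrs_spectra` tibble.
#' @param labels The two class labels; defaults to the labels present.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed for the subsample and split.
#' @return List with `train` and `holdout` spectra tibbles.
#' @export
balance_and_split <- function(x, labels = NULL, train_frac = 0.8, seed = 1) {
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must be in (0, 1)")
  x <- as_spectra(x)
  labs <- spectra_labels(x)
  if (is.null(labels)) labels <- unique(labs[!is.na(labs)])
  if (length(labels) != 2) abort("need exactly two class labels")
  ids_by_class <- lapply(labels, function(l) names(labs)[!is.na(labs) & labs == l])
  n_min <- min(lengths(ids_by_class))
  if (n_min < 5) {
    abort(sprintf("class '%s' has %d spectra; need at least 5",
                  labels[which.min(lengths(ids_by_class))], n_min))
  }
  .with_seed(seed, {
    picked <- lapply(ids_by_class, function(ids) {
      if (length(ids) > n_min) sample(ids, n_min) else ids
    })
    n_train <- floor(train_frac * n_min)
    train_ids <- unlist(lapply(picked, function(ids) sample(ids, n_train)))
    holdout_ids <- setdiff(unlist(picked), train_ids)
  })
  list(
    train = as_spectra(x[x$sample_id %in% train_ids, ]),
    holdout = as_spectra(x[x$sample_id %in% holdout_ids, ])
  )
}

# Samples-by-channels feature matrix (optionally mask-restricted).
.spectra_features <- function(x, mask = NULL) {
  m <- spectra_matrix(as_spectra(x))
  wn <- attr(m, "wavenumber")
  feats <- t(unclass(m))
  colnames(feats) <- as.character(wn)
  if (!is.null(mask)) {
    sel_wn <- mask$wavenumber[mask$selected]
    keep <- wn %in% sel_wn
    if (!any(keep)) abort("feature mask selects no channels on this axis")
    feats <- feats[, keep, drop = FALSE]
  }
  attr(feats, "labels") <- unname(attr(m, "labels"))
  feats
}

#' Train a Gaussian-kernel SVM
#'
#' Fits a soft-margin SVM with kernel `exp(-||u - v||^2 / s^2)` where `s`
#' follows the [kernel_scale()] rule for the number of predictors actually
#' used. Features are standardized with center/scale learned on the training
#' data (an SD floor of 1e-8 guards zero-variance channels). The returned
#' score convention is: positive score predicts the positive (high-Cx43)
#' class; ties at exactly zero predict the negative class.
#'
#' @param x Feature matrix (samples x channels) or an `fgrs_spectra` tibble.
#' @param labels Class label per sample (taken from `x` for spectra input).
#' @param positive Label of the positive class (default: first label in
#'   sort order, with a message).
#' @param kernel `"medium"` or `"coarse"`.
#' @param cost Soft-margin box constraint C.
#' @param standardize Center and scale features before the kernel.
#' @param mask Optional [double_sd_mask()] restricting spectra input to the
#'   selected channels.
#' @return An object of class `fgrs_svm`.
#' @export
train_svm <- function(x, labels = NULL, positive = NULL,
                      kernel = c("medium", "coarse"), cost = 1,
                      standardize = TRUE, mask = NULL) {
  kernel <- match.arg(kernel)
  .assert_scalar_number(cost, "cost", lower = 0, strict_lower = TRUE)
  if (is.data.frame(x)) {
    feats <- .spectra_features(x, mask)
    if (is.null(labels)) labels <- attr(feats, "labels")
  } else {
    feats <- as.matrix(x)
    if (!is.null(mask)) abort("`mask` requires spectra input")
  }
  if (is.null(labels) || length(labels) != nrow(feats)) {
    abort("`labels` must provide one class label per sample")
  }
  if (any(!is.finite(feats))) abort("non-finite feature values")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) {
    abort(sprintf("training needs exactly 2 classes, got %d", length(classes)))
  }
  if (is.null(positive)) positive <- classes[[1]]
  if (!positive %in% classes) abort(sprintf("positive class '%s' not in labels", positive))
  negative <- setdiff(classes, positive)
  if (min(table(labels)) < 2) abort("need at least 2 examples per class")

  center <- rep(0, ncol(feats)); scale_ <- rep(1, ncol(feats))
  n_floored <- 0L
  if (standardize) {
    center <- colMeans(feats)
    scale_ <- apply(feats, 2, sd)
    n_floored <- sum(scale_ < 1e-8)
    scale_ <- pmax(scale_, 1e-8)
  }
  z <- sweep(sweep(feats, 2, center, "-"), 2, scale_, "/")
  p <- ncol(z)
  s <- kernel_scale(p, kernel)
  y <- factor(as.character(labels), levels = c(positive, negative))
  fit <- e1071::svm(x = z, y = y, kernel = "radial", gamma = 1 / s^2,
                    cost = cost, scale = FALSE)
  # Orient decision values so that positive score == positive class.
  dv <- attr(predict(fit, z, decision.values = TRUE), "decision.values")[, 1]
  flip <- if (mean(dv[y == positive]) >= mean(dv[y == negative])) 1 else -1

  structure(
    list(fit = fit, center = center, scale = scale_, kernel = kernel,
         kernel_scale = s, gamma = 1 / s^2, cost = cost,
         positive = positive, negative = negative, flip = flip,
         n_features = p, feature_names = colnames(feats),
         standardize = standardize, n_floored = n_floored,
         n_train = nrow(feats)),
    class = "fgrs_svm"
  )
}

#' Decision scores and predicted labels
#'
#' @param model An [train_svm()] fit.
#' @param x Feature matrix or `fgrs_spectra` tibble with the model's
#'   feature count.
#' @param mask Optional mask (must match the one used in training) for
#'   spectra input.
#' @return A tibble with `sample_id` (spectra input), `score` (positive
#'   predicts high-Cx43) and `pred`.
#' @export
predict_scores <- function(model, x, mask = NULL) {
  stopifnot(inherits(model, "fgrs_svm"))
  ids <- NULL
  if (is.data.frame(x)) {
    feats <- .spectra_features(x, mask)
    ids <- rownames(feats)
  } else {
    feats <- as.matrix(x)
  }
  if (nrow(feats) == 0) abort("no samples to predict")
  if (ncol(feats) != model$n_features) {
    abort(sprintf("feature count %d does not match model (%d features)",
                  ncol(feats), model$n_features))
  }
  z <- sweep(sweep(feats, 2, model$center, "-"), 2, model$scale, "/")
  dv <- attr(predict(model$fit, z, decision.values = TRUE),
             "decision.values")[, 1]
  score <- model$flip * dv
  pred <- ifelse(score > 0, model$positive, model$negative)
  tibble(sample_id = ids %||% sprintf("sample_%d", seq_along(score)),
         score = unname(score), pred = unname(pred))
}

#' Stratified k-fold cross-validation accuracy
#'
#' @inheritParams train_svm
#' @param k Number of folds (each class must have at least `k` samples).
#' @param seed Seed for the fold assignment.
#' @return An object of class `fgrs_cv`: list with `accuracy` (percent,
#'   pooled over folds), `predictions` (tibble `truth`, `pred`, `score`,
#'   `fold`) and `k`.
#' @export
cross_validate <- function(x, labels = NULL, positive = NULL,
                           kernel = c("medium", "coarse"), cost = 1,
                           standardize = TRUE, mask = NULL, k = 5, seed = 1) {
  kernel <- match.arg(kernel)
  if (k < 2) abort("`k` must be at least 2")
  if (is.data.frame(x)) {
    feats <- .spectra_features(x, mask)
    if (is.null(labels)) labels <- attr(feats, "labels")
  } else {
    feats <- as.matrix(x)
  }
  labels <- as.character(labels)
  counts <- table(labels)
  if (min(counts) < k) {
    abort(sprintf("class '%s' has %d samples, fewer than k = %d folds",
                  names(counts)[which.min(counts)], min(counts), k))
  }
  if (is.null(positive)) positive <- sort(unique(labels))[[1]]
  folds <- .with_seed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  preds <- purrr::map_dfr(seq_len(k), function(fold) {
    tr <- folds != fold
    model <- train_svm(feats[tr, , drop = FALSE], labels[tr],
                       positive = positive, kernel = kernel, cost = cost,
                       standardize = standardize)
    sc <- predict_scores(model, feats[!tr, , drop = FALSE])
    tibble(truth = labels[!tr], pred = sc$pred, score = sc$score, fold = fold)
  })
  structure(
    list(accuracy = 100 * mean(preds$pred == preds$truth),
         predictions = preds, k = k, positive = positive),
    class = "fgrs_cv"
  )
}

#' @export
print.fgrs_cv <- function(x, ...) {
  cat(sprintf("<%d-fold CV: accuracy %.1f%% (n = %d)>\n",
              x$k, x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' Confusion-matrix metrics, ROC curve and AUC
#'
#' The positive class is the high-Cx43 class. Accuracy, sensitivity
#' (`TP / (TP + FN)`) and specificity (`TN / (TN + FP)`) are percentages.
#' The ROC curve sweeps all decision-score thresholds (tied scores are
#' grouped); AUC is the trapezoidal area, invariant under any strictly
#' increasing transform of the scores.
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @param scores Decision scores (larger favors the positive class).
#' @param positive Positive class label.
#' @return An object of class `fgrs_eval`: confusion counts, metrics, `roc`
#'   tibble (`threshold`, `fpr`, `tpr`) and `auc`.
#' @export
evaluate_predictions <- function(truth, pred, scores, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred) || length(truth) != length(scores)) {
    abort("`truth`, `pred` and `scores` must have equal length")
  }
  if (!positive %in% c(truth, pred)) {
    abort(sprintf("positive class '%s' absent from labels", positive))
  }
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)

  is_pos <- truth == positive
  np <- sum(is_pos); nn <- sum(!is_pos)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]; pos_sorted <- is_pos[ord]
  grp <- cumsum(!duplicated(s_sorted))
  tp_c <- cumsum(pos_sorted); fp_c <- cumsum(!pos_sorted)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- tibble(
    threshold = c(Inf, s_sorted[last]),
    tpr = c(0, tp_c[last] / max(np, 1)),
    fpr = c(0, fp_c[last] / max(nn, 1))
  )
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)

  structure(
    list(tp = tp, fn = fn, tn = tn, fp = fp,
         accuracy = 100 * (tp + tn) / length(truth),
         sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
         auc = auc, roc = roc, positive = positive, n = length(truth)),
    class = "fgrs_eval"
  )
}

#' @export
print.fgrs_eval <- function(x, ...) {
  cat(sprintf(
    "<evaluation vs '%s': accuracy %.1f%%, AUC %.2f, sensitivity %.1f%%, specificity %.1f%% (n = %d)>\n",
    x$positive, x$accuracy, x$auc, x$sensitivity, x$specificity, x$n))
  cat(sprintf("confusion: TP %d, FN %d, TN %d, FP %d\n", x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' @export
tidy.fgrs_eval <- function(x, ...) {
  tibble(
    metric = c("accuracy", "auc", "sensitivity", "specificity",
               "tp", "fn", "tn", "fp"),
    value = c(x$accuracy, x$auc, x$sensitivity, x$specificity,
              x$tp, x$fn, x$tn, x$fp)
  )
}

#' @export
glance.fgrs_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, auc = x$auc, sensitivity = x$sensitivity,
         specificity = x$specificity, n = x$n)
}

#' @export
tidy.fgrs_svm <- function(x, ...) {
  tibble(
    term = c("kernel", "kernel_scale", "gamma", "cost", "n_features",
             "n_support", "n_train"),
    value = c(x$kernel, format(x$kernel_scale), format(x$gamma),
              format(x$cost), x$n_features, x$fit$tot.nSV, x$n_train)
  )
}

#' @export
glance.fgrs_svm <- function(x, ...) {
  tibble(kernel = x$kernel, kernel_scale = x$kernel_scale, gamma = x$gamma,
         cost = x$cost, n_features = x$n_features,
         n_support = x$fit$tot.nSV, n_train = x$n_train,
         positive = x$positive)
}

#' @export
print.fgrs_svm <- function(x, ...) {
  cat(sprintf(
    "<Gaussian-kernel SVM (%s): P = %d, scale = %.3f, C = %g, %d support vectors>\n",
    x$kernel, x$n_features, x$kernel_scale, x$cost, x$fit$tot.nSV))
  cat(sprintf("positive class: '%s'\n", x$positive))
  invisible(x)
}

#' Run the full training/testing experiment grid
#'
#' Reproduces the classification protocol: for each kernel kind and feature
#' mode, the training set is class-balanced and split (80/20 by default),
#' training metrics come from stratified five-fold cross-validation pooled
#' over folds, and each named testing scenario is evaluated with the model
#' trained on the training portion. Testing scenarios with several low-Cx43
#' groups are pooled and subsampled (seeded) to match the high-Cx43 count.
#'
#' @param training An `fgrs_spectra` tibble with both classes.
#' @param testing Named list of labelled `fgrs_spectra` tibbles.
#' @param mask [double_sd_mask()] result; required when `"selected"` is in
#'   `feature_modes`.
#' @param positive Label of the high-Cx43 class (in training and testing
#'   sets alike).
#' @param kernels,feature_modes Grid axes.
#' @param train_frac,folds,cost,seed Protocol parameters.
#' @return A tibble of class `fgrs_experiment`: one row per kernel x
#'   feature mode x scenario with `accuracy`, `auc`, `sensitivity`,
#'   `specificity`, `n`; ROC curves in `attr(, "roc")`, models in
#'   `attr(, "models")`.
#' @export
run_experiment <- function(training, testing = list(), mask = NULL,
                           positive, kernels = c("coarse", "medium"),
                           feature_modes = c("all", "selected"),
                           train_frac = 0.8, folds = 5, cost = 1, seed = 1) {
  if ("selected" %in% feature_modes && is.null(mask)) {
    abort("feature mode 'selected' requires a feature mask")
  }
  training <- as_spectra(training)
  labs <- unique(spectra_labels(training))
  if (!positive %in% labs) abort(sprintf("positive class '%s' not in training data", positive))
  seeds <- .child_seeds(seed, 2 + length(testing))
  split <- balance_and_split(training, train_frac = train_frac, seed = seeds[[1]])

  # balance each testing scenario: pool non-positive groups, subsample to
  # the positive count
  testing_bal <- list()
  if (length(testing) > 0) {
    for (i in seq_along(testing)) {
      ts <- as_spectra(testing[[i]])
      tl <- spectra_labels(ts)
      pos_ids <- names(tl)[tl == positive]
      neg_ids <- names(tl)[tl != positive]
      if (length(pos_ids) == 0 || length(neg_ids) == 0) {
        abort(sprintf("testing scenario '%s' must contain the positive and at least one other class",
                      names(testing)[[i]] %||% i))
      }
      n_eval <- min(length(pos_ids), length(neg_ids))
      picked <- .with_seed(seeds[[2 + i]], {
        c(if (length(pos_ids) > n_eval) sample(pos_ids, n_eval) else pos_ids,
          if (length(neg_ids) > n_eval) sample(neg_ids, n_eval) else neg_ids)
      })
      testing_bal[[i]] <- as_spectra(ts[ts$sample_id %in% picked, ])
    }
    names(testing_bal) <- names(testing)
  }

  rows <- list(); rocs <- list(); models <- list()
  for (fm in feature_modes) {
    use_mask <- if (fm == "selected") mask else NULL
    for (kn in kernels) {
      cv <- cross_validate(split$train, positive = positive, kernel = kn,
                           cost = cost, mask = use_mask, k = folds,
                           seed = seeds[[2]])
      ev_tr <- evaluate_predictions(cv$predictions$truth, cv$predictions$pred,
                                    cv$predictions$score, positive)
      key <- paste(kn, fm, sep = "/")
      model <- train_svm(split$train, positive = positive, kernel = kn,
                         cost = cost, mask = use_mask)
      models[[key]] <- model
      rows[[length(rows) + 1L]] <- tibble(
        kernel = kn, feature_mode = fm, scenario = "training",
        accuracy = ev_tr$accuracy, auc = ev_tr$auc,
        sensitivity = ev_tr$sensitivity, specificity = ev_tr$specificity,
        n = ev_tr$n, n_features = model$n_features
      )
      rocs[[paste(key, "training", sep = "/")]] <- ev_tr$roc
      for (sc_name in names(testing_bal)) {
        ts <- testing_bal[[sc_name]]
        sc <- predict_scores(model, ts, mask = use_mask)
        tl <- spectra_labels(ts)
        truth <- ifelse(unname(tl) == positive, positive, model$negative)
        ev <- evaluate_predictions(truth, sc$pred, sc$score, positive)
        rows[[length(rows) + 1L]] <- tibble(
          kernel = kn, feature_mode = fm, scenario = sc_name,
          accuracy = ev$accuracy, auc = ev$auc,
          sensitivity = ev$sensitivity, specificity = ev$specificity,
          n = ev$n, n_features = model$n_features
        )
        rocs[[paste(key, sc_name, sep = "/")]] <- ev$roc
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "roc") <- rocs
  attr(out, "models") <- models
  attr(out, "seed") <- seed
  class(out) <- unique(c("fgrs_experiment", class(out)))
  out
}
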