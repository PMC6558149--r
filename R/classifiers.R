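# Multivariate classifiers behind a common fit/predict surface, their
# cross-validated evaluation, and sequential forward feature selection.
#
# Configurations follow the study settings: DTC splits on the Gini index and
# stops growing a node holding fewer than 20% of the training trials; SVM
# uses a cubic polynomial kernel with kernel scale 1; KNN uses Euclidean
# distance with 10 neighbours weighted by squared inverse distance; QDA is
# standard, with a diagonal-ridge fallback when a class covariance is
# singular.

#' Classifier configuration
#'
#' @param method One of `"dtc"`, `"svm"`, `"qda"`, `"knn"`.
#' @param ... Method parameters overriding the defaults: `min_node_frac`
#'   (DTC, default 0.2), `degree`/`gamma`/`coef0`/`cost` (SVM, defaults 3, 1,
#'   1, 1), `k` and `standardize` (KNN, defaults 10 and `TRUE`: features are
#'   z-scored on training statistics, since Euclidean distance is otherwise
#'   dominated by the largest-scale features), `ridge` (QDA fallback ridge
#'   fraction, default 1e-6).
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(method = c("dtc", "svm", "qda", "knn"), ...) {
  method <- match.arg(method)
  defaults <- switch(
    method,
    dtc = list(min_node_frac = 0.2),
    svm = list(degree = 3, gamma = 1, coef0 = 1, cost = 1),
    qda = list(ridge = 1e-6),
    knn = list(k = 10, standardize = TRUE)
  )
  structure(utils::modifyList(defaults, list(...)),
            class = "classifier_config", method = method)
}

fit_classifier <- function(config, X, y) {
  stopifnot(inherits(config, "classifier_config"))
  method <- attr(config, "method")
  X <- as.matrix(X)
  y <- factor(y)
  model <- switch(
    method,
    dtc = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = "gini"),
        control = rpart::rpart.control(
          minsplit = ceiling(config$min_node_frac * nrow(X)),
          cp = 0, xval = 0
        )
      )
    },
    svm = e1071::svm(
      x = X, y = y, kernel = "polynomial", degree = config$degree,
      gamma = config$gamma, coef0 = config$coef0, cost = config$cost,
      scale = FALSE
    ),
    qda = fit_qda(X, y, config$ridge),
    knn = {
      if (isTRUE(config$standardize)) {
        ctr <- colMeans(X)
        scl <- apply(X, 2L, sd)
        scl[scl == 0] <- 1
        list(X = scale(X, ctr, scl), y = y, k = config$k, center = ctr,
             scale = scl)
      } else {
        list(X = X, y = y, k = config$k)
      }
    }
  )
  structure(list(model = model, levels = levels(y)),
            class = "ordlag_classifier", method = method)
}

fit_qda <- function(X, y, ridge) {
  tryCatch(
    MASS::qda(X, y),
    error = function(e) {
      message("QDA covariance singular; applying diagonal ridge regularisation.")
      stats <- lapply(levels(y), function(cl) {
        Xc <- X[y == cl, , drop = FALSE]
        S <- stats::cov(Xc)
        lam <- ridge * mean(diag(S)) + 1e-12
        S <- S + diag(lam, ncol(X))
        list(mu = colMeans(Xc), Sinv = solve(S),
             logdet = determinant(S, logarithm = TRUE)$modulus,
             logprior = log(nrow(Xc) / nrow(X)))
      })
      structure(list(stats = stats, levels = levels(y)), class = "ridge_qda")
    }
  )
}

predict_classifier <- function(fit, Xnew) {
  stopifnot(inherits(fit, "ordlag_classifier"))
  Xnew <- as.matrix(Xnew)
  method <- attr(fit, "method")
  m <- fit$model
  out <- switch(
    method,
    dtc = {
      df <- data.frame(Xnew, check.names = FALSE)
      as.character(predict(m, newdata = df, type = "class"))
    },
    svm = as.character(predict(m, Xnew)),
    qda = {
      if (inherits(m, "ridge_qda")) {
        disc <- vapply(m$stats, function(s) {
          D <- sweep(Xnew, 2L, s$mu)
          -0.5 * rowSums((D %*% s$Sinv) * D) - 0.5 * as.numeric(s$logdet) +
            s$logprior
        }, numeric(nrow(Xnew)))
        disc <- matrix(disc, nrow = nrow(Xnew))
        m$levels[max.col(disc, ties.method = "first")]
      } else {
        as.character(predict(m, Xnew)$class)
      }
    },
    knn = predict_wknn(m, Xnew)
  )
  out
}

# Squared-inverse-distance weighted k-nearest-neighbour vote. A zero-distance
# neighbour gets (numerically) unbounded weight and so decides the vote.
predict_wknn <- function(m, Xnew) {
  if (!is.null(m$center)) Xnew <- scale(Xnew, m$center, m$scale)
  k <- min(m$k, nrow(m$X))
  d2 <- outer(rowSums(Xnew^2), rowSums(m$X^2), `+`) - 2 * tcrossprod(Xnew, m$X)
  d2 <- pmax(d2, 1e-24)
  lv <- levels(m$y)
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    w <- 1 / row[nn]
    votes <- vapply(lv, function(cl) sum(w[m$y[nn] == cl]), numeric(1))
    lv[which.max(votes)]
  })
}

#' Cross-validated evaluation of a multivariate classifier
#'
#' Fits the configured classifier on the training folds and scores the
#' held-out fold, for every fold; sensitivity, specificity and accuracy
#' (percent, distress positive) are averaged across folds.
#'
#' @param data Tibble with `group` and numeric feature columns.
#' @param config A [classifier_config()].
#' @param folds Integer fold assignment (default: stratified 10-fold with
#'   `seed`).
#' @param features Feature columns to use (default all).
#' @param positive Positive class.
#' @param k,seed Fold construction when `folds` is `NULL`.
#' @return An `ordlag_cv` report.
#' @export
classifier_cv <- function(data, config, folds = NULL, features = NULL,
                          positive = "distress", k = 10, seed = 1L) {
  features <- features %||% feature_columns(data)
  if (length(features) == 0) abort("No feature columns found.")
  folds <- folds %||% stratified_kfold(data$group, k = k, seed = seed)
  X <- as.matrix(data[, features, drop = FALSE])
  y <- as.character(data$group)
  per_fold <- purrr::map_dfr(seq_len(max(folds)), function(f) {
    tr <- folds != f
    fit <- fit_classifier(config, X[tr, , drop = FALSE], y[tr])
    pred <- predict_classifier(fit, X[!tr, , drop = FALSE])
    rates <- confusion_rates(pred, y[!tr], positive)
    tibble::tibble(fold = f, n_test = sum(!tr), se = rates[["se"]],
                   sp = rates[["sp"]], acc = rates[["acc"]])
  })
  new_cv_report(per_fold, config = list(model = attr(config, "method"),
                                        features = features))
}

# Misclassification rate of `config` on (X, y) under the given inner folds.
inner_cv_error <- function(config, X, y, folds) {
  wrong <- 0L
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    fit <- fit_classifier(config, X[tr, , drop = FALSE], y[tr])
    pred <- predict_classifier(fit, X[!tr, , drop = FALSE])
    wrong <- wrong + sum(pred != y[!tr])
  }
  wrong / length(y)
}

#' Sequential forward feature selection with cross-validated evaluation
#'
#' For each outer fold: starting from the empty set, greedily adds the
#' feature whose inclusion minimises the classifier's misclassification rate
#' under a stratified 10-fold cross-validation nested inside the outer
#' training set, stopping when no candidate strictly improves the criterion
#' or `cap` features are reached (ties go to the earliest column, so a
#' duplicated feature is selected at most once). The classifier is then
#' refitted on the full outer training set with the selected features and
#' scored on the held-out fold. Per-feature selection occurrences across
#' outer folds are reported.
#'
#' @inheritParams classifier_cv
#' @param cap Maximum number of features selected per fold (default 10).
#' @param inner_k Folds of the nested selection CV (default 10, reduced to
#'   the smallest training-class size when a class is smaller than that).
#' @return An `ordlag_cv` report whose `selection` element counts, for every
#'   feature ever chosen, the number of outer folds selecting it;
#'   `per_fold_selection` lists the chosen sets.
#' @export
sfs_select <- function(data, config, folds = NULL, features = NULL,
                       positive = "distress", cap = 10, inner_k = 10,
                       k = 10, seed = 1L) {
  features <- features %||% feature_columns(data)
  if (length(features) == 0) abort("Need at least one candidate feature.")
  folds <- folds %||% stratified_kfold(data$group, k = k, seed = seed)
  X <- as.matrix(data[, features, drop = FALSE])
  y <- as.character(data$group)
  sel_sets <- vector("list", max(folds))
  per_fold <- purrr::map_dfr(seq_len(max(folds)), function(f) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    k_eff <- min(inner_k, min(table(ytr)))
    inner <- stratified_kfold(ytr, k = k_eff, seed = seed + 1000L + f)
    fast_knn <- identical(attr(config, "method"), "knn")
    if (fast_knn) {
      Xs <- if (isTRUE(config$standardize)) {
        scl <- apply(Xtr, 2L, sd)
        scl[scl == 0] <- 1
        scale(Xtr, colMeans(Xtr), scl)
      } else Xtr
      yint <- as.integer(ytr == ytr[order(ytr)][1L])  # first level = 1
    }
    chosen <- integer()
    best_err <- Inf
    repeat {
      if (length(chosen) >= cap) break
      remaining <- setdiff(seq_along(features), chosen)
      errs <- if (fast_knn) {
        .wknn_cv_errors(Xs, chosen - 1L, remaining - 1L, yint, inner,
                        as.integer(min(config$k, length(ytr))))
      } else {
        vapply(remaining, function(j) {
          inner_cv_error(config, Xtr[, c(chosen, j), drop = FALSE], ytr, inner)
        }, numeric(1))
      }
      jbest <- remaining[which.min(errs)]
      if (min(errs) < best_err - 1e-12) {
        chosen <- c(chosen, jbest)
        best_err <- min(errs)
      } else {
        break
      }
    }
    if (length(chosen) == 0) chosen <- 1L  # degenerate: keep first feature
    sel_sets[[f]] <<- features[chosen]
    fit <- fit_classifier(config, Xtr[, chosen, drop = FALSE], ytr)
    pred <- predict_classifier(fit, X[!tr, chosen, drop = FALSE])
    rates <- confusion_rates(pred, y[!tr], positive)
    tibble::tibble(fold = f, n_test = sum(!tr), se = rates[["se"]],
                   sp = rates[["sp"]], acc = rates[["acc"]],
                   n_selected = length(chosen))
  })
  counts <- tibble::as_tibble(table(feature = unlist(sel_sets)))
  names(counts)[2L] <- "count"
  counts <- dplyr::arrange(counts, dplyr::desc(.data$count), .data$feature)
  rep <- new_cv_report(per_fold, selection = counts,
                       config = list(model = attr(config, "method"),
                                     cap = cap, inner_k = inner_k))
  rep$per_fold_selection <- sel_sets
  rep
}
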