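# Statistical testing and cross-validated single-feature classification.
# Class convention throughout: "distress" is the positive class, so
# sensitivity is the distress detection rate and specificity the calmness
# detection rate. All rates are reported in percent.

#' Assign calmness/distress labels from SAM ratings
#'
#' Maps arousal/valence ratings (1-9 scale) to the two study groups:
#' distress when arousal > `distress_arousal` and valence <
#' `distress_valence`; calmness when arousal < `calm_arousal` and valence
#' within `calm_valence` (inclusive); `"excluded"` otherwise. Boundary
#' semantics are strict by default and configurable.
#'
#' @param arousal,valence Numeric vectors in `[1, 9]`.
#' @param distress_arousal,distress_valence Distress thresholds (arousal
#'   strictly above, valence strictly below).
#' @param calm_arousal Calmness arousal threshold (strictly below).
#' @param calm_valence Length-2 inclusive valence window for calmness.
#' @return Character vector: `"distress"`, `"calmness"` or `"excluded"`.
#' @examples
#' sam_group(c(6, 3, 5), c(2, 5, 5))
#' @export
sam_group <- function(arousal, valence, distress_arousal = 5,
                      distress_valence = 3, calm_arousal = 4,
                      calm_valence = c(4, 6)) {
  if (length(arousal) != length(valence)) {
    abort("`arousal` and `valence` must have the same length.")
  }
  if (any(!is.finite(arousal)) || any(!is.finite(valence)) ||
      any(arousal < 1 | arousal > 9) || any(valence < 1 | valence > 9)) {
    abort("Ratings must be finite values in [1, 9].")
  }
  out <- rep("excluded", length(arousal))
  out[arousal > distress_arousal & valence < distress_valence] <- "distress"
  out[arousal < calm_arousal &
        valence >= calm_valence[1] & valence <= calm_valence[2]] <- "calmness"
  out
}

#' Label the rows of a feature/rating table by SAM region
#'
#' Data-frame front end to [sam_group()]: adds (or overwrites) a `group`
#' column and optionally drops excluded rows.
#'
#' @param data Data frame with `arousal` and `valence` columns.
#' @param drop_excluded Drop rows falling in neither region (default `TRUE`).
#' @param ... Passed to [sam_group()].
#' @return A tibble.
#' @export
label_trials <- function(data, drop_excluded = TRUE, ...) {
  data <- tibble::as_tibble(data)
  data$group <- sam_group(data$arousal, data$valence, ...)
  if (drop_excluded) data <- dplyr::filter(data, .data$group != "excluded")
  data
}

feature_columns <- function(data) {
  meta <- c("trial_id", "group", "arousal", "valence", "fold")
  setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
}

# ---- distributional checks --------------------------------------------------

#' Normality and homoscedasticity screening for a feature
#'
#' Shapiro-Wilk per group plus Levene's test (mean-centered) across groups.
#' Advisory only: downstream ANOVA is run regardless, these tests simply
#' document whether the mean/SD summaries are adequate.
#'
#' @param values Numeric vector.
#' @param groups Factor/character vector, same length.
#' @return A tibble with one row per test (`test`, `group`, `statistic`,
#'   `p_value`). Constant-valued groups produce a warning and `NA` rows.
#' @export
normality_homoscedasticity <- function(values, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 3)) abort("Need at least 3 values per group.")
  rows <- list()
  degenerate <- FALSE
  for (g in levels(groups)) {
    v <- values[groups == g]
    if (sd(v) == 0) {
      warn(sprintf("Group '%s' is constant; Shapiro-Wilk skipped.", g))
      degenerate <- TRUE
      rows[[g]] <- tibble::tibble(test = "shapiro_wilk", group = g,
                                  statistic = NA_real_, p_value = NA_real_)
    } else {
      sw <- stats::shapiro.test(v)
      rows[[g]] <- tibble::tibble(test = "shapiro_wilk", group = g,
                                  statistic = unname(sw$statistic),
                                  p_value = sw$p.value)
    }
  }
  lev <- if (degenerate && all(vapply(levels(groups),
                                      function(g) sd(values[groups == g]) == 0,
                                      logical(1)))) {
    tibble::tibble(test = "levene", group = NA_character_,
                   statistic = 0, p_value = NA_real_)
  } else {
    lt <- car::leveneTest(values ~ groups, center = mean)
    tibble::tibble(test = "levene", group = NA_character_,
                   statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"])
  }
  dplyr::bind_rows(c(rows, list(levene = lev)))
}

#' One-way ANOVA per feature column
#'
#' Classic one-way analysis of variance of each feature against the group
#' labels (for two groups, F is exactly the squared pooled-variance t
#' statistic). Raw p-values are reported, mirroring the per-channel testing
#' scheme; Benjamini-Hochberg adjusted values can be added on request.
#'
#' @param data Tibble with a `group` column and numeric feature columns.
#' @param features Character vector of columns to test (default: all numeric
#'   feature columns).
#' @param adjust Add a `p_adjusted` (Benjamini-Hochberg) column (default
#'   `FALSE`).
#' @return A tibble `feature`, `statistic` (F), `p_value`, sorted by
#'   `p_value`.
#' @export
anova_features <- function(data, features = NULL, adjust = FALSE) {
  if (!"group" %in% names(data)) abort("`data` needs a `group` column.")
  features <- features %||% feature_columns(data)
  g <- factor(data$group)
  if (nlevels(g) < 2) abort("Need at least two groups.")
  res <- purrr::map_dfr(features, function(f) {
    v <- data[[f]]
    if (var(v) == 0) {
      return(tibble::tibble(feature = f, statistic = NA_real_, p_value = NA_real_))
    }
    ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
    tibble::tibble(feature = f, statistic = unname(ow$statistic),
                   p_value = ow$p.value)
  })
  if (adjust) res$p_adjusted <- stats::p.adjust(res$p_value, "BH")
  dplyr::arrange(res, .data$p_value)
}

# ---- folds ------------------------------------------------------------------

#' Stratified k-fold assignment
#'
#' Splits trials into `k` folds whose sizes differ by at most one and whose
#' class proportions match the global proportions to within one trial per
#' fold. Within each class, trials are shuffled with the given seed and dealt
#' into folds; each class's remainder trials go to the currently smallest
#' folds. Deterministic given (`labels`, `k`, `seed`).
#'
#' @param labels Class label per trial.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, one per trial.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1L) {
  labels <- as.factor(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("Every class needs at least k = %d members.", k))
  }
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  load <- integer(k)  # running fold sizes
  for (cl in names(sort(tab, decreasing = TRUE))) {
    idx <- sample(which(labels == cl))
    n_cl <- length(idx)
    base <- n_cl %/% k
    rem <- n_cl %% k
    counts <- rep(base, k)
    if (rem > 0) {
      # give the extras to the folds that are currently smallest
      extra <- order(load, seq_len(k))[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    stops <- cumsum(counts)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (f in seq_len(k)) {
      if (counts[f] > 0) fold[idx[starts[f]:stops[f]]] <- f
    }
    load <- load + counts
  }
  fold
}

# ---- ROC threshold model ----------------------------------------------------

confusion_rates <- function(pred, truth, positive = "distress") {
  tp <- sum(pred == positive & truth == positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fp <- sum(pred == positive & truth != positive)
  c(
    se = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    acc = 100 * (tp + tn) / length(truth)
  )
}

#' Fit a single-feature ROC-threshold classifier
#'
#' Scans every candidate cut-point (midpoints between consecutive sorted
#' unique training values, plus the two infinite extremes) and both
#' polarities, and keeps the threshold that maximises training accuracy. Ties
#' are resolved by maximum sensitivity + specificity, then by the smaller
#' threshold, then by the "high values are distress" polarity — a
#' deterministic rule favouring balanced errors.
#'
#' @param values Numeric training feature values.
#' @param labels Training class labels (two classes present).
#' @param positive Positive class (default `"distress"`).
#' @return An object of class `roc_threshold`: `threshold`, `polarity`
#'   (`"high"` if values above threshold are called positive, `"low"`
#'   otherwise, `"majority"` fallback for constant features), `positive`,
#'   `negative`, `train_accuracy` (percent).
#' @export
fit_roc_threshold <- function(values, labels, positive = "distress") {
  labels <- as.character(labels)
  classes <- unique(labels)
  if (!(positive %in% classes) || length(classes) != 2) {
    abort("Training data must contain the positive class and exactly one other.")
  }
  negative <- setdiff(classes, positive)
  if (length(unique(values)) == 1L) {
    warn("Constant feature: falling back to a majority-class predictor.")
    maj <- names(which.max(table(labels)))
    return(structure(
      list(threshold = NA_real_, polarity = "majority", positive = positive,
           negative = negative, majority = maj,
           train_accuracy = 100 * mean(labels == maj)),
      class = "roc_threshold"
    ))
  }
  su <- sort(unique(values))
  u <- length(su)
  # candidate i (i = 0..u) is the cut just above su[i]; i = 0 is -Inf,
  # i = u is +Inf
  cand <- c(-Inf, (su[-1] + su[-u]) / 2, Inf)
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  # counts of positives/negatives at or below each unique value
  vi <- match(values, su)
  pos_le <- c(0, cumsum(tabulate(vi[is_pos], u)))
  neg_le <- c(0, cumsum(tabulate(vi[!is_pos], u)))
  n <- length(values)
  # polarity "high": values above the cut are called positive
  tp_hi <- n_pos - pos_le; tn_hi <- neg_le
  # polarity "low": values below the cut are called positive
  tp_lo <- pos_le; tn_lo <- n_neg - neg_le
  tab <- tibble::tibble(
    threshold = rep(cand, 2L),
    polarity = rep(c("high", "low"), each = u + 1L),
    acc = c(tp_hi + tn_hi, tp_lo + tn_lo) / n,
    youden = c(tp_hi / n_pos + tn_hi / n_neg, tp_lo / n_pos + tn_lo / n_neg)
  )
  tol <- 1e-12
  tab <- tab[tab$acc >= max(tab$acc) - tol, ]
  tab <- tab[tab$youden >= max(tab$youden) - tol, ]
  tab <- tab[tab$threshold == min(tab$threshold), ]
  best <- tab[order(tab$polarity), ][1L, ]  # "high" precedes "low"
  structure(
    list(threshold = best$threshold, polarity = best$polarity,
         positive = positive, negative = negative,
         train_accuracy = 100 * best$acc),
    class = "roc_threshold"
  )
}

#' @export
predict.roc_threshold <- function(object, newdata, ...) {
  values <- if (is.data.frame(newdata)) newdata[[1L]] else newdata
  if (object$polarity == "majority") {
    return(rep(object$majority, length(values)))
  }
  called_pos <- if (object$polarity == "high") {
    values > object$threshold
  } else {
    values < object$threshold
  }
  ifelse(called_pos, object$positive, object$negative)
}

# ---- CV report --------------------------------------------------------------

new_cv_report <- function(per_fold, selection = NULL, config = NULL) {
  means <- dplyr::summarise(
    per_fold,
    se = mean(.data$se, na.rm = TRUE),
    sp = mean(.data$sp, na.rm = TRUE),
    acc = mean(.data$acc, na.rm = TRUE)
  )
  structure(
    list(folds = per_fold, summary = means, selection = selection,
         config = config),
    class = "ordlag_cv"
  )
}

#' @export
print.ordlag_cv <- function(x, ...) {
  cat(sprintf(
    "<ordlag_cv> %d folds | Se %.2f%%  Sp %.2f%%  Acc %.2f%%\n",
    nrow(x$folds), x$summary$se, x$summary$sp, x$summary$acc
  ))
  if (!is.null(x$selection)) {
    top <- head(dplyr::arrange(x$selection, dplyr::desc(.data$count)), 5L)
    cat("  top selected features:",
        paste(sprintf("%s (%d)", top$feature, top$count), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cross-validated evaluation of one feature with a ROC threshold
#'
#' For every fold, fits [fit_roc_threshold()] on the other folds and
#' classifies the held-out trials; sensitivity, specificity and accuracy
#' (percent, distress positive) are computed per fold and averaged. Folds
#' whose test trials contain a single class yield `NA` for the undefined rate
#' and are excluded from that rate's average, with a warning.
#'
#' @param values Numeric feature values, one per trial.
#' @param labels Class labels.
#' @param folds Integer fold assignment from [stratified_kfold()].
#' @param positive Positive class.
#' @return An `ordlag_cv` report.
#' @export
single_feature_cv <- function(values, labels, folds, positive = "distress") {
  labels <- as.character(labels)
  k <- max(folds)
  rows <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- folds != f
    model <- fit_roc_threshold(values[tr], labels[tr], positive)
    pred <- predict(model, values[!tr])
    rates <- confusion_rates(pred, labels[!tr], positive)
    tibble::tibble(fold = f, n_test = sum(!tr), se = rates[["se"]],
                   sp = rates[["sp"]], acc = rates[["acc"]])
  })
  if (anyNA(rows$se) || anyNA(rows$sp)) {
    warn("Some folds contained a single class; undefined rates excluded from the average.")
  }
  new_cv_report(rows, config = list(model = "roc_threshold"))
}

#' Cross-validated accuracy of every feature column
#'
#' Convenience sweep of [single_feature_cv()] over all feature columns of a
#' labelled feature matrix, returning the averaged metrics per feature.
#'
#' @param data Tibble with `group` and feature columns.
#' @param folds Fold assignment (default: stratified 10-fold with `seed`).
#' @param features Columns to evaluate (default all features).
#' @param k,seed Fold construction parameters when `folds` is `NULL`.
#' @return Tibble `feature`, `se`, `sp`, `acc` sorted by decreasing `acc`.
#' @export
sweep_single_features <- function(data, folds = NULL, features = NULL,
                                  k = 10, seed = 1L) {
  features <- features %||% feature_columns(data)
  folds <- folds %||% stratified_kfold(data$group, k = k, seed = seed)
  res <- purrr::map_dfr(features, function(f) {
    rep <- single_feature_cv(data[[f]], data$group, folds)
    dplyr::mutate(rep$summary, feature = f, .before = 1L)
  })
  dplyr::arrange(res, dplyr::desc(.data$acc))
}
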