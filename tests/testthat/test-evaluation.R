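# SAM labelling, statistical tests, folds, ROC-threshold classification.

test_that("SAM regions map to the documented groups", {
  expect_equal(sam_group(6, 2), "distress")
  expect_equal(sam_group(3, 5), "calmness")
  expect_equal(sam_group(5, 5), "excluded")   # boundary: strictly above 5 needed
  expect_equal(sam_group(c(6, 3, 9), c(2, 5, 9)),
               c("distress", "calmness", "excluded"))
  expect_equal(sam_group(4, 4), "excluded")   # calm arousal must be < 4
  expect_error(sam_group(0.5, 5), "\\[1, 9\\]")

  df <- tibble::tibble(arousal = c(6, 3, 5), valence = c(2, 5, 5),
                       f = c(1, 2, 3))
  lab <- label_trials(df)
  expect_equal(nrow(lab), 2L)
  expect_equal(lab$group, c("distress", "calmness"))
})

test_that("normality/homoscedasticity screening behaves on known inputs", {
  set.seed(40)
  ok <- replicate(100, {
    v <- c(rnorm(50), rnorm(50))
    g <- rep(c("a", "b"), each = 50)
    out <- normality_homoscedasticity(v, g)
    all(out$p_value[out$test == "shapiro_wilk"] > 0.05)
  })
  expect_gte(mean(ok), 0.8)

  # inflated variance in one group is caught by Levene
  set.seed(41)
  v <- c(rnorm(100), rnorm(100, sd = sqrt(10)))
  g <- rep(c("a", "b"), each = 100)
  out <- normality_homoscedasticity(v, g)
  expect_lt(out$p_value[out$test == "levene"], 0.05)

  # identical groups: Levene statistic 0
  v0 <- rep(c(1, 2, 3, 4), 2)
  out0 <- normality_homoscedasticity(v0, rep(c("a", "b"), each = 4))
  expect_equal(out0$statistic[out0$test == "levene"], 0, tolerance = 1e-12)

  expect_warning(
    normality_homoscedasticity(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3)),
    "constant"
  )
})

test_that("two-group ANOVA equals the closed form and the squared t test", {
  df <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                       f = c(1, 2, 3, 4, 5, 6))
  out <- anova_features(df)
  expect_equal(out$statistic, 13.5, tolerance = 1e-12)
  expect_equal(out$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:50) {
    v <- rnorm(30)
    g <- rep(c("x", "y"), times = c(13, 17))
    d <- tibble::tibble(group = g, f = v)
    f_stat <- anova_features(d)$statistic
    t_stat <- stats::t.test(v ~ g, var.equal = TRUE)$statistic
    expect_equal(f_stat, unname(t_stat)^2, tolerance = 1e-9)
  }

  # identical groups: F = 0
  d0 <- tibble::tibble(group = rep(c("a", "b"), each = 4),
                       f = rep(c(1, 2, 3, 4), 2))
  expect_equal(anova_features(d0)$statistic, 0)
})

test_that("stratified folds balance size and class composition", {
  # 10 + 10 trials in 10 folds: one of each class per fold
  lab <- rep(c("calmness", "distress"), each = 10)
  f <- stratified_kfold(lab, k = 10, seed = 1)
  for (i in 1:10) {
    expect_equal(sum(f == i), 2L)
    expect_equal(sum(f == i & lab == "distress"), 1L)
  }

  # study-sized: 122 + 137 -> fold sizes 25/26, composition within 1 trial
  lab2 <- rep(c("distress", "calmness"), times = c(122, 137))
  f2 <- stratified_kfold(lab2, k = 10, seed = 7)
  sizes <- table(f2)
  expect_true(all(sizes %in% c(25L, 26L)))
  per_fold_distress <- tapply(lab2 == "distress", f2, sum)
  expect_true(all(abs(per_fold_distress - 12.2) <= 1))

  expect_identical(stratified_kfold(lab2, 10, seed = 3),
                   stratified_kfold(lab2, 10, seed = 3))
  expect_false(identical(stratified_kfold(lab2, 10, seed = 3),
                         stratified_kfold(lab2, 10, seed = 4)))
  expect_error(stratified_kfold(rep(c("a", "b"), times = c(5, 50)), k = 10),
               "at least k")
})

test_that("ROC threshold maximises training accuracy with stated tie rules", {
  # perfect separation
  m <- fit_roc_threshold(c(1, 2, 3, 10, 11, 12),
                         rep(c("calmness", "distress"), each = 3))
  expect_equal(m$train_accuracy, 100)
  expect_equal(predict(m, c(0, 20)), c("calmness", "distress"))

  # interleaved values: brute-force over all cuts and polarities says 75%
  vals <- c(1, 3, 2, 4)
  labs <- c("calmness", "calmness", "distress", "distress")
  brute_best <- max(vapply(
    c(-Inf, sort(vals) + 0.5, Inf),
    function(th) max(mean((vals > th) == (labs == "distress")),
                     mean((vals < th) == (labs == "distress"))),
    numeric(1)
  ))
  expect_equal(brute_best, 0.75)
  m2 <- fit_roc_threshold(vals, labs)
  expect_equal(m2$train_accuracy, 75)

  # label swap flips polarity, keeps the boundary's location quality
  m3 <- fit_roc_threshold(c(1, 2, 3, 10, 11, 12),
                          rep(c("distress", "calmness"), each = 3))
  expect_equal(m3$train_accuracy, 100)
  expect_equal(predict(m3, c(0, 20)), c("distress", "calmness"))

  expect_warning(
    m4 <- fit_roc_threshold(rep(1, 6), rep(c("calmness", "distress"),
                                           times = c(4, 2))),
    "Constant feature"
  )
  expect_equal(unique(predict(m4, c(1, 1))), "calmness")
})

test_that("single-feature CV: perfect separation, chance level, determinism", {
  lab <- rep(c("calmness", "distress"), each = 20)
  vals <- c(rnorm(20, 0), rnorm(20, 10))
  folds <- stratified_kfold(lab, 10, seed = 1)
  rep1 <- single_feature_cv(vals, lab, folds)
  expect_equal(rep1$summary$acc, 100)
  expect_equal(rep1$summary$se, 100)
  expect_equal(nrow(tidy(rep1)), 10L)
  expect_equal(glance(rep1)$acc, 100)

  # label-independent feature stays at chance on average
  set.seed(50)
  accs <- vapply(1:20, function(s) {
    lab <- rep(c("calmness", "distress"), each = 500)
    v <- rnorm(1000)
    f <- stratified_kfold(lab, 10, seed = s)
    single_feature_cv(v, lab, f)$summary$acc
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)

  rep2 <- single_feature_cv(vals, lab, folds)
  expect_identical(tidy(rep1), tidy(rep2))
})

test_that("accuracy identity: reported Acc matches confusion counts per fold", {
  set.seed(52)
  lab <- rep(c("calmness", "distress"), each = 15)
  vals <- rnorm(30) + (lab == "distress") * 1.2
  folds <- stratified_kfold(lab, 5, seed = 2)
  rep <- single_feature_cv(vals, lab, folds)
  for (f in 1:5) {
    tr <- folds != f
    m <- fit_roc_threshold(vals[tr], lab[tr])
    pred <- predict(m, vals[!tr])
    acc <- 100 * mean(pred == lab[!tr])
    expect_equal(rep$folds$acc[rep$folds$fold == f], acc)
  }
})
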