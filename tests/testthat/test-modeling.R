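# Classifiers, model-choice rule, nested LOSO and SDA procedures.

toy_xy <- function(n = 60, seed = 1) {
  with_seed_test(seed, {
    y <- rep(c(0, 1), each = n / 2)
    x <- cbind(f1 = y * 2 + rnorm(n, sd = 0.1),
               f2 = rnorm(n))
    list(x = x, y = y)
  })
}

test_that("linear SVM separates a separable toy set perfectly", {
  d <- toy_xy()
  cell <- data.frame(model = "svm", kernel = "linear", kernel_scale = 1,
                     cost = 1, k = NA, metric = NA, weight = NA)
  p <- fit_predict(cell, d$x, d$y, d$x)
  expect_equal(p, d$y)
  expect_error(fit_predict(cell, d$x, rep(1, nrow(d$x)), d$x), "single class")
})

test_that("1-NN reproduces training labels on the training set", {
  d <- toy_xy(40, seed = 2)
  p <- knn_predict(d$x, d$y, d$x, k = 1)
  expect_equal(p, d$y)
})

test_that("squared-euclidean and euclidean metrics rank neighbours alike", {
  d <- with_seed_test(3, list(tr = matrix(rnorm(200), 50),
                              te = matrix(rnorm(40), 10)))
  y <- rep(c(0, 1), 25)
  for (k in c(1, 5, 15))
    expect_equal(knn_predict(d$tr, y, d$te, k, metric = "euclidean"),
                 knn_predict(d$tr, y, d$te, k, metric = "squared-euclidean"))
})

test_that("cityblock metric and distance weights are honoured", {
  tr <- rbind(c(0, 0), c(3, 0), c(0, 4))
  y <- c(0, 1, 1)
  te <- rbind(c(0.4, 0))
  # cityblock distances: 0.4, 2.6, 4.4 -> k=3 equal weights vote 1 (2 of 3)
  expect_equal(knn_predict(tr, y, te, k = 3, metric = "cityblock",
                           weight = "equal"), 1)
  # inverse-distance weights: w = 1/0.4 > 1/2.6 + 1/4.4 -> vote 0
  expect_equal(knn_predict(tr, y, te, k = 3, metric = "cityblock",
                           weight = "inverse"), 0)
  # zero-distance training point dominates under inverse weighting
  expect_equal(knn_predict(tr, y, rbind(c(3, 0)), k = 3, metric = "cityblock",
                           weight = "squared-inverse"), 1)
})

test_that("model-choice rule follows accuracy+F, F decides disagreements", {
  both <- data.frame(id = c("A", "B"), accuracy = c(0.9, 0.8),
                     f_score = c(0.9, 0.85))
  expect_equal(choose_model(both), "A")
  split <- data.frame(id = c("A", "B"), accuracy = c(0.85, 0.84),
                      f_score = c(0.84, 0.85))
  expect_equal(choose_model(split), "B")
  tie <- data.frame(id = c("B", "A"), accuracy = c(0.8, 0.8),
                    f_score = c(0.8, 0.8))
  expect_equal(choose_model(tie), "A")
})

test_that("grid presets cover the published ranges", {
  g <- fog_grid("full")
  expect_equal(sum(g$model == "svm"), 4 * 5 * 5)
  expect_equal(sum(g$model == "knn"), 6 * 3 * 3)
  expect_setequal(unique(g$kernel[g$model == "svm"]),
                  c("linear", "quadratic", "cubic", "gaussian"))
  expect_true(all(g$kernel_scale[g$model == "svm"] >= 0.1 &
                    g$kernel_scale[g$model == "svm"] <= 100))
  expect_true(all(g$k[g$model == "knn"] >= 1 & g$k[g$model == "knn"] <= 180))
  gc <- fog_grid("compact")
  expect_setequal(unique(gc$model), c("svm", "knn"))
})

test_that("nested LOSO: N outer folds, N-1 inner folds, no leakage", {
  d <- small_cohort_fit_data()
  fit <- suppressWarnings(fog_sia(d$x, d$windows$label,
                                  subjects = d$windows$subject_id,
                                  tasks = d$windows$task_id,
                                  starts = d$windows$start_s))
  n_subj <- length(unique(d$windows$subject_id))
  expect_length(fit$folds, n_subj)
  # each fold validates on at most N-1 subjects (fewer only if a training
  # subject lacks a class)
  for (f in fit$folds) expect_lte(f$n_inner, n_subj - 1)
  expect_true(leakage_audit(fit))
  # every window receives exactly one out-of-fold prediction
  expect_false(any(is.na(fit$predictions)))
})

test_that("an oracle feature drives nested LOSO to perfect accuracy", {
  with_seed_test(50, {
    n_per <- 60
    subjects <- rep(sprintf("S%02d", 1:4), each = n_per)
    y <- as.vector(replicate(4, rep(c(0, 1), each = n_per / 2)))
    x <- cbind(oracle = y + rnorm(length(y), sd = 0.01),
               junk1 = rnorm(length(y)), junk2 = rnorm(length(y)))
    fit <- fog_sia(x, y, subjects)
    expect_equal(fit$metrics$accuracy, 1)
    expect_equal(fit$metrics$f_score, 1)
  })
})

test_that("label permutation within subjects gives chance-level accuracy", {
  d <- small_cohort_fit_data()
  y <- as.numeric(d$windows$label == "FOG")
  subj <- d$windows$subject_id
  perm <- with_seed_test(60, {
    out <- y
    for (s in unique(subj)) {
      ix <- which(subj == s)
      out[ix] <- y[ix][sample.int(length(ix))]
    }
    out
  })
  skip_if(length(unique(perm)) < 2)
  fit <- tryCatch(
    suppressWarnings(fog_sia(d$x, perm, subjects = subj)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # selection finding nothing under permuted labels is itself chance-level
    expect_match(conditionMessage(fit), "no features retained")
  } else {
    maj <- max(mean(perm), 1 - mean(perm))
    se <- sqrt(maj * (1 - maj) / length(perm))
    expect_lt(fit$metrics$accuracy, maj + 4 * se + 0.03)
  }
})

test_that("determinism: identical seeds give identical fits", {
  d <- small_cohort_fit_data()
  f1 <- suppressWarnings(fog_sia(d$x, d$windows$label, d$windows$subject_id))
  f2 <- suppressWarnings(fog_sia(d$x, d$windows$label, d$windows$subject_id))
  expect_identical(f1$predictions, f2$predictions)
  expect_identical(lapply(f1$folds, `[[`, "cell"),
                   lapply(f2$folds, `[[`, "cell"))
})

test_that("SDA: LOTO folds per task, stratified CV folds contain both classes", {
  with_seed_test(70, {
    n_per <- 80
    tasks <- rep(sprintf("T%02d", 1:4), each = n_per)
    y <- as.vector(replicate(4, rep(c(0, 1), each = n_per / 2)))
    x <- cbind(oracle = y + rnorm(length(y), sd = 0.05),
               junk = rnorm(length(y)))
    fit <- fog_sda(x, y, tasks, seed = 5)
    expect_length(fit$folds, 4)
    expect_gte(fit$metrics$f_score, 0.99)
    expect_true(leakage_audit(fit))
  })
  # stratified fold construction keeps both classes whenever feasible
  yy <- rep(c(0, 1), c(60, 30))
  id <- with_seed_test(71, fogmm:::stratified_folds(yy, 10))
  for (fi in 1:10) expect_setequal(unique(yy[id == fi]), c(0, 1))
})

test_that("SDA rejects subjects with FOG in fewer than two tasks", {
  y <- c(rep(0, 50), rep(c(0, 1), 25))
  tasks <- rep(c("T01", "T02"), each = 50)
  x <- cbind(f = rnorm(100))
  expect_error(fog_sda(x, y, tasks), "fewer than 2 tasks")
})

test_that("predict method applies the consensus model to new windows", {
  with_seed_test(80, {
    n_per <- 60
    subjects <- rep(sprintf("S%02d", 1:4), each = n_per)
    y <- as.vector(replicate(4, rep(c(0, 1), each = n_per / 2)))
    x <- cbind(oracle = y + rnorm(length(y), sd = 0.01),
               junk = rnorm(length(y)))
    fit <- fog_sia(x, y, subjects)
    newx <- cbind(oracle = c(0.01, 1.02), junk = rnorm(2))
    expect_equal(predict(fit, newx), c(0, 1))
  })
})
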