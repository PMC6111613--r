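# A small shared dataset keeps the pipeline tests fast: 3 subjects x
# 4 classes x 30 s (6 windows each), 2 units.
small_ds <- simulate_har_data(n_subjects = 3, n_classes = 4, minutes = 0.5,
                              units = 2, seed = 101)

test_that("leave-one-subject-out folds partition the data by subject", {
  subj <- rep(1:8, each = 1140 / 8)  # any per-subject layout
  folds <- l1o_split(subj)
  expect_length(folds, 8L)
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(test_union, seq_along(subj))
  for (f in folds) {
    expect_setequal(unique(subj[f$test]), f$subject)
    expect_identical(sort(c(f$train, f$test)), seq_along(subj))
    expect_length(intersect(f$train, f$test), 0L)
  }
  expect_length(l1o_split(c(1, 1, 2, 2)), 2L)
  expect_error(l1o_split(rep(1, 5)), "two subjects")
})

test_that("feature vectors have the technique-dependent dimension", {
  for (te in c("reference", "norm", "proposed")) {
    fe <- har_features(small_ds, te, seed = 1)
    expect_equal(nrow(fe$X), 3L * 4L * 6L)
    expect_equal(ncol(fe$X), 2L * channels_per_unit(te) * 26L)
    expect_false(anyNA(fe$X))
  }
  # the full-shape arithmetic: 5 units x 9 axes x 26 = 1170 features for
  # the untransformed pipeline, 65 x 26 = 1690 for the proposed one
  expect_equal(5L * channels_per_unit("reference") * 26L, 1170L)
  expect_equal(5L * channels_per_unit("proposed") * 26L, 1690L)
})

test_that("feature extraction is deterministic and permutation-equivariant", {
  fe1 <- har_features(small_ds, "svd", seed = 9)
  fe2 <- har_features(small_ds, "svd", seed = 9)
  expect_identical(fe1$X, fe2$X)
  # permuting segment order permutes feature rows identically
  segs <- orientHAR:::as_har_segments(small_ds)
  perm <- rev(seq_along(segs$segments))
  segs_p <- structure(list(segments = segs$segments[perm],
                           meta = segs$meta[perm, ], rate = segs$rate,
                           units = segs$units), class = "har_segments")
  fe3 <- har_features(segs_p, "svd", seed = 9)
  expect_equal(fe3$X, fe1$X[perm, ])
})

test_that("evaluation aggregates folds, confusion counts and groups", {
  ev <- har_evaluate(small_ds, "reference", classifier_spec("ldc"),
                     seed = 1, stationary_classes = 1:2)
  expect_s3_class(ev, "har_eval")
  expect_length(ev$fold_accuracy, 3L)
  expect_equal(sum(ev$confusion), 3L * 4L * 6L)
  expect_equal(unname(colSums(ev$confusion)), rep(18L, 4L))
  expect_true(all(ev$fold_accuracy >= 0 & ev$fold_accuracy <= 100))
  expect_equal(ev$stationary_accuracy,
               mean(ev$per_class_accuracy[c("1", "2")]))
  expect_equal(ev$nonstationary_accuracy,
               mean(ev$per_class_accuracy[c("3", "4")]))
  # overall accuracy equals total correct over total
  expect_equal(ev$overall_accuracy,
               100 * sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_output(print(ev), "Leave-one-subject-out")
  expect_output(summary(ev), "Confusion matrix")
})

test_that("well-separated synthetic activities are classified perfectly
           and shuffled labels drop to chance", {
  ev <- har_evaluate(small_ds, "reference", classifier_spec("svm"),
                     seed = 2)
  expect_gt(ev$mean_accuracy, 90)
  # shuffled labels: chance level ~ 100/K
  segs <- orientHAR:::as_har_segments(small_ds)
  set.seed(7)
  segs$meta$activity <- sample(segs$meta$activity)
  ev0 <- har_evaluate(segs, "reference", classifier_spec("knn"), seed = 2)
  expect_lt(ev0$mean_accuracy, 100 / 4 + 20)
})

test_that("global-scope PCA and precomputed features are honoured", {
  fe <- har_features(small_ds, "norm", seed = 3)
  ev1 <- har_evaluate(small_ds, "norm", classifier_spec("ldc"), seed = 3,
                      features = fe)
  ev2 <- har_evaluate(small_ds, "norm", classifier_spec("ldc"), seed = 3,
                      features = fe, pca_scope = "global")
  expect_length(ev2$fold_accuracy, 3L)
  expect_false(identical(ev1$confusion, NULL))
})
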