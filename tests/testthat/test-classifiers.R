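test_that("all seven classifiers separate the Gaussian benchmark", {
  tr <- gaussian_blobs(seed = 1)
  te <- gaussian_blobs(seed = 2)
  for (nm in c("svm", "ann", "bdm", "ldc", "knn", "rf", "omp")) {
    m <- har_train(classifier_spec(nm), tr$X, tr$y, seed = 5)
    expect_gte(mean(predict(m, te$X) == te$y), 0.95)
    # training accuracy on separable blobs is essentially perfect
    expect_gte(mean(predict(m, tr$X) == tr$y), 0.95)
  }
})

test_that("the network's hidden width follows the stated formula", {
  expect_identical(ann_hidden_units(19), 21L)
  expect_identical(ann_hidden_units(3),
                   as.integer(round((log2(6) + 5) / 2)))
})

test_that("seeded classifiers give bit-identical repeated predictions", {
  tr <- gaussian_blobs(seed = 4)
  te <- gaussian_blobs(seed = 5)
  for (nm in c("ann", "rf")) {
    m1 <- har_train(classifier_spec(nm), tr$X, tr$y, seed = 11)
    m2 <- har_train(classifier_spec(nm), tr$X, tr$y, seed = 11)
    expect_identical(predict(m1, te$X), predict(m2, te$X))
  }
})

test_that("the linear discriminant coincides with the Gaussian classifier
           under a shared covariance and has hyperplane boundaries", {
  set.seed(6)
  n <- 200; d <- 4
  L <- chol(diag(d) + 0.3)
  X <- rbind(matrix(rnorm(n * d), n, d) %*% L,
             sweep(matrix(rnorm(n * d), n, d) %*% L, 2, c(4, 0, 0, 0), "+"))
  y <- factor(rep(1:2, each = n))
  ldc <- har_train(classifier_spec("ldc"), X, y, seed = 1)
  # force identical class covariances in a Gaussian-classifier fit
  bdm_fit <- orientHAR:::gauss_fit(X, y, pooled = FALSE, ridge = 1e-8)
  bdm_fit$chols <- ldc$fit$chols
  grid <- matrix(rnorm(500 * d), 500, d) * 3
  s_ldc <- orientHAR:::gauss_scores(ldc$fit, grid)
  s_bdm <- orientHAR:::gauss_scores(bdm_fit, grid)
  expect_lt(max(abs((s_ldc[, 1] - s_ldc[, 2]) - (s_bdm[, 1] - s_bdm[, 2]))),
            1e-6)
  # with one shared covariance the score difference is affine in x:
  # residuals of a linear fit vanish
  dd <- s_ldc[, 1] - s_ldc[, 2]
  fit <- lm.fit(cbind(1, grid), dd)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("k-NN honours a unanimous neighbourhood and Gaussian classifiers
           pick the nearer mean", {
  X <- rbind(matrix(0.01 * rnorm(14), 7, 2),
             matrix(5 + 0.01 * rnorm(14), 7, 2))
  y <- factor(rep(c("A", "B"), each = 7))
  m <- har_train(classifier_spec("knn"), X, y, seed = 1)
  expect_equal(as.character(predict(m, matrix(c(0, 0), 1))), "A")
  set.seed(13)
  Xg <- rbind(matrix(rnorm(100), 50, 2),
              sweep(matrix(rnorm(100), 50, 2), 2, c(6, 0), "+"))
  yg <- factor(rep(1:2, each = 50))
  bdm <- har_train(classifier_spec("bdm"), Xg, yg, seed = 1)
  probe <- rbind(c(1, 0), c(5, 0))
  expect_equal(as.character(predict(bdm, probe)), c("1", "2"))
})

test_that("orthogonal matching pursuit recovers supports and residuals", {
  # dictionary with orthogonal columns: exact recovery of a 2-sparse code
  D <- diag(6)[, 1:4]
  x <- 2 * D[, 2] + 0.5 * D[, 4]
  code <- omp_sparse_code(x, D, tol = 1e-9)
  expect_setequal(code$support, c(2L, 4L))
  expect_equal(code$residual_norm, 0, tolerance = 1e-12)
  # membership of the dictionary: immediate termination at zero residual
  tr <- gaussian_blobs(seed = 8)
  m <- har_train(classifier_spec("omp"), tr$X, tr$y, seed = 1)
  expect_equal(as.character(predict(m, tr$X[5, , drop = FALSE])),
               as.character(tr$y[5]))
  # residual norms are non-increasing across iterations
  set.seed(20)
  Dn <- matrix(rnorm(30 * 12), 30, 12)
  Dn <- sweep(Dn, 2, sqrt(colSums(Dn^2)), "/")
  x <- rnorm(30)
  norms <- sapply(1:8, function(k) {
    omp_sparse_code(x, Dn, tol = 0, max_atoms = k)$residual_norm
  })
  expect_true(all(diff(norms) <= 1e-12))
  # brute force over all 2-subsets confirms the greedy pick of an exact
  # combination of two orthogonalised atoms
  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30, 5)))
  xb <- 3 * Q[, 1] - 2 * Q[, 3]
  cb <- omp_sparse_code(xb, Q, tol = 1e-9)
  expect_setequal(cb$support, c(1L, 3L))
})

test_that("specs validate their inputs and models their dimensions", {
  expect_error(classifier_spec("svm", k = 3), "unknown")
  tr <- gaussian_blobs(seed = 3)
  m <- har_train(classifier_spec("ldc"), tr$X, tr$y, seed = 1)
  expect_error(predict(m, tr$X[, 1:3]), "dimension")
  expect_error(har_train(classifier_spec("svm"), tr$X,
                         rep("a", nrow(tr$X))), "two classes")
  g <- svm_grids()
  expect_equal(nrow(g$coarse), 11L * 10L)
  expect_true(all(c(5, 0.1) %in% c(g$fine$cost, g$fine$gamma)))
})
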