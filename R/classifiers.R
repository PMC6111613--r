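#' Classifier specification
#'
#' Names one of the seven supported classifiers together with its
#' hyperparameters. Defaults are the published operating points: SVM with a
#' Gaussian RBF kernel at \code{C = 5}, \code{gamma = 0.1}; 7-nearest
#' neighbours; 100 random-forest trees; OMP residual tolerance \code{1e-3};
#' a three-layer sigmoid network trained by backpropagation with learning
#' rate 0.3, weights initialised uniformly in \code{[0, 0.2]} and training
#' stopped once the epoch-error reduction relative to the mean of the last
#' 10 epochs falls below 0.01.
#'
#' @param name One of \code{"svm"}, \code{"ann"}, \code{"bdm"},
#'   \code{"ldc"}, \code{"knn"}, \code{"rf"}, \code{"omp"}.
#' @param ... Hyperparameter overrides: \code{cost}, \code{gamma} (svm);
#'   \code{k} (knn); \code{ntree} (rf); \code{tol}, \code{residual_mode},
#'   \code{max_atoms} (omp); \code{learning_rate}, \code{init_range},
#'   \code{stop_threshold}, \code{max_epochs} (ann); \code{ridge}
#'   (bdm/ldc).
#' @return A list of class \code{"classifier_spec"}.
#' @export
classifier_spec <- function(name = c("svm", "ann", "bdm", "ldc", "knn",
                                     "rf", "omp"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    svm = list(cost = 5, gamma = 0.1),
    ann = list(learning_rate = 0.3, init_range = c(0, 0.2),
               stop_threshold = 0.01, stop_window = 10L, max_epochs = 1000L),
    bdm = list(ridge = 1e-8),
    ldc = list(ridge = 1e-8),
    knn = list(k = 7L),
    rf = list(ntree = 100L),
    omp = list(tol = 1e-3, residual_mode = c("support", "class_omp"),
               max_atoms = NULL)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    stop("classifier_spec: unknown parameter(s) for ", name, ": ",
         paste(bad, collapse = ", "))
  }
  defaults[names(over)] <- over
  if (name == "omp") {
    defaults$residual_mode <- match.arg(defaults$residual_mode,
                                        c("support", "class_omp"))
  }
  structure(c(list(name = name), defaults), class = "classifier_spec")
}

#' Hidden-layer width of the three-layer network
#'
#' The integer nearest to the average of \code{log2(2K)} (optimistic:
#' separating hyperplanes intersect) and \code{2K - 1} (pessimistic:
#' parallel hyperplanes), for \code{K} classes.
#'
#' @param K Number of classes.
#' @return Integer number of hidden neurons.
#' @export
ann_hidden_units <- function(K) {
  stopifnot(K >= 2)
  as.integer(round((log(2 * K) / log(2) + (2 * K - 1)) / 2))
}

#' SVM hyperparameter search grids
#'
#' The coarse grid spans \code{C} over \code{10^-5 ... 10^15} and
#' \code{gamma} over \code{10^-15 ... 10^3}, both in hundredfold steps; the
#' fine grid is \code{100 P x P} with
#' \code{P = 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 1, 3, 5}. The
#' published optimum \code{(C, gamma) = (5, 0.1)} is the package default.
#'
#' @return List with data frames \code{coarse} and \code{fine} of candidate
#'   \code{(cost, gamma)} pairs.
#' @export
svm_grids <- function() {
  coarse <- expand.grid(cost = 10^seq(-5, 15, by = 2),
                        gamma = 10^seq(-15, 3, by = 2))
  p <- c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 1, 3, 5)
  fine <- data.frame(cost = 100 * p, gamma = p)
  list(coarse = coarse, fine = fine)
}

#' Train a classifier
#'
#' Fits the classifier named by \code{spec} to a numeric feature matrix and
#' a label vector, behind a uniform train/predict contract. Randomised
#' learners (ann initialisation, rf bootstrap, knn tie-breaking) are made
#' deterministic by \code{seed}.
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric matrix (samples x features), all finite.
#' @param y Labels (coerced to factor); at least two classes.
#' @param seed Integer seed.
#' @return An object of class \code{"har_model"}.
#' @export
har_train <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"), is.matrix(X),
            all(is.finite(X)))
  y <- factor(y)
  if (nlevels(y) < 2L) stop("har_train: need at least two classes")
  fit <- with_seed(seed, switch(spec$name,
    svm = e1071::svm(X, y, kernel = "radial", cost = spec$cost,
                     gamma = spec$gamma, scale = FALSE),
    ann = ann_fit(X, y, spec),
    bdm = gauss_fit(X, y, pooled = FALSE, ridge = spec$ridge),
    ldc = gauss_fit(X, y, pooled = TRUE, ridge = spec$ridge),
    knn = list(X = X, y = y, k = spec$k),
    rf = randomForest::randomForest(X, y, ntree = spec$ntree),
    omp = omp_fit(X, y)
  ))
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 dim = ncol(X), seed = seed), class = "har_model")
}

#' @export
print.har_model <- function(x, ...) {
  cat("Trained", x$spec$name, "classifier:", length(x$levels), "classes,",
      x$dim, "features\n")
  invisible(x)
}

#' Predict activity labels
#'
#' @param object A \code{"har_model"} from [har_train()].
#' @param newdata Numeric matrix with the training feature dimension.
#' @param ... Unused.
#' @return Factor of predicted labels (levels = training levels).
#' @export
predict.har_model <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$dim) {
    stop("predict.har_model: feature dimension mismatch (got ",
         ncol(newdata), ", expected ", object$dim, ")")
  }
  spec <- object$spec
  out <- with_seed(object$seed + 1L, switch(spec$name,
    svm = stats::predict(object$fit, newdata),
    ann = ann_predict(object$fit, newdata),
    bdm = gauss_predict(object$fit, newdata),
    ldc = gauss_predict(object$fit, newdata),
    knn = class::knn(object$fit$X, newdata, object$fit$y, k = object$fit$k),
    rf = stats::predict(object$fit, newdata),
    omp = omp_predict(object$fit, newdata, spec)
  ))
  factor(as.character(out), levels = object$levels)
}

# ---- Gaussian classifiers (BDM / LDC) -------------------------------------

# BDM: per-class Gaussian with its own sample covariance; LDC: the same
# except the unweighted average of the class covariances replaces each
# class covariance. MAP rule with training-proportion priors.
gauss_fit <- function(X, y, pooled, ridge) {
  lv <- levels(y)
  means <- list(); covs <- list(); prior <- numeric(length(lv))
  for (i in seq_along(lv)) {
    Xi <- X[y == lv[i], , drop = FALSE]
    if (nrow(Xi) < 2L) stop("gauss_fit: class ", lv[i], " has < 2 samples")
    means[[i]] <- colMeans(Xi)
    covs[[i]] <- stats::cov(Xi)
    prior[i] <- nrow(Xi) / nrow(X)
  }
  if (pooled) {
    avg <- Reduce(`+`, covs) / length(covs)
    covs <- rep(list(avg), length(lv))
  }
  chols <- lapply(covs, function(S) safe_chol(S, ridge))
  list(levels = lv, means = means, chols = chols, log_prior = log(prior))
}

# Cholesky with escalating ridge regularisation for singular covariances.
safe_chol <- function(S, ridge) {
  scale <- mean(diag(S))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  eps <- ridge * scale
  for (i in 1:12) {
    ch <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
    if (!is.null(ch)) {
      if (i > 1L) message("covariance regularized with ridge ", signif(eps, 3))
      return(ch)
    }
    eps <- eps * 100
  }
  stop("safe_chol: covariance could not be regularized")
}

gauss_predict <- function(fit, X) {
  n <- nrow(X)
  scores <- matrix(NA_real_, n, length(fit$levels))
  for (i in seq_along(fit$levels)) {
    ch <- fit$chols[[i]]
    Z <- forwardsolve(t(ch), t(sweep(X, 2L, fit$means[[i]])))
    scores[, i] <- -0.5 * colSums(Z^2) - sum(log(diag(ch))) +
      fit$log_prior[i]
  }
  factor(fit$levels[max.col(scores, ties.method = "first")],
         levels = fit$levels)
}

# Per-class posterior scores; exposed internally for equivalence checks.
gauss_scores <- function(fit, X) {
  scores <- matrix(NA_real_, nrow(X), length(fit$levels))
  for (i in seq_along(fit$levels)) {
    ch <- fit$chols[[i]]
    Z <- forwardsolve(t(ch), t(sweep(X, 2L, fit$means[[i]])))
    scores[, i] <- -0.5 * colSums(Z^2) - sum(log(diag(ch))) +
      fit$log_prior[i]
  }
  colnames(scores) <- fit$levels
  scores
}

# ---- three-layer sigmoid network ------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

# Backpropagation with per-sample (online) updates, shuffled each epoch.
# Epoch error is the sum of squared one-hot errors; training stops when the
# reduction relative to the mean of the previous `stop_window` epochs is
# below `stop_threshold` (or at max_epochs).
ann_fit <- function(X, y, spec) {
  K <- nlevels(y)
  H <- ann_hidden_units(K)
  d <- ncol(X)
  n <- nrow(X)
  lo <- spec$init_range[1]; hi <- spec$init_range[2]
  W1 <- matrix(stats::runif(d * H, lo, hi), d, H)
  b1 <- stats::runif(H, lo, hi)
  W2 <- matrix(stats::runif(H * K, lo, hi), H, K)
  b2 <- stats::runif(K, lo, hi)
  Tmat <- diag(K)[as.integer(y), , drop = FALSE]
  lr <- spec$learning_rate
  errs <- numeric(0)
  for (epoch in seq_len(spec$max_epochs)) {
    ord <- sample.int(n)
    err <- 0
    for (i in ord) {
      x <- X[i, ]
      h <- sigmoid(drop(x %*% W1) + b1)
      o <- sigmoid(drop(h %*% W2) + b2)
      e <- o - Tmat[i, ]
      err <- err + sum(e^2)
      delta_o <- e * o * (1 - o)
      delta_h <- (W2 %*% delta_o) * h * (1 - h)
      W2 <- W2 - lr * tcrossprod(h, delta_o)
      b2 <- b2 - lr * delta_o
      W1 <- W1 - lr * tcrossprod(x, drop(delta_h))
      b1 <- b1 - lr * drop(delta_h)
    }
    errs <- c(errs, err)
    w <- spec$stop_window
    if (length(errs) > w) {
      reduction <- mean(errs[(length(errs) - w):(length(errs) - 1L)]) - err
      if (reduction < spec$stop_threshold) break
    }
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = levels(y),
       epochs = length(errs), final_error = errs[length(errs)])
}

ann_predict <- function(fit, X) {
  Hid <- sigmoid(sweep(X %*% fit$W1, 2L, fit$b1, "+"))
  O <- sigmoid(sweep(Hid %*% fit$W2, 2L, fit$b2, "+"))
  factor(fit$levels[max.col(O, ties.method = "first")], levels = fit$levels)
}

# ---- orthogonal matching pursuit / sparse-representation classifier -------

# dictionary of L2-normalised training vectors (columns)
omp_fit <- function(X, y) {
  D <- t(X)
  norms <- sqrt(colSums(D^2))
  list(D = sweep(D, 2L, pmax(norms, 1e-300), "/"), y = y)
}

#' Greedy sparse coding by orthogonal matching pursuit
#'
#' Iteratively selects the dictionary column most correlated with the
#' current residual (ties toward the lower index), refits the coefficients
#' by least squares on the selected support, and stops once the residual
#' norm is at or below \code{tol} or the support is exhausted.
#'
#' @param x Numeric target vector.
#' @param dictionary Matrix whose columns are L2-normalised atoms.
#' @param tol Residual-norm stopping tolerance (default \code{1e-3}).
#' @param max_atoms Optional cap on the support size.
#' @return List with integer \code{support}, \code{coefficients}, the final
#'   \code{residual} vector and \code{residual_norm}.
#' @export
omp_sparse_code <- function(x, dictionary, tol = 1e-3, max_atoms = NULL) {
  stopifnot(length(x) == nrow(dictionary))
  m <- ncol(dictionary)
  limit <- min(m, nrow(dictionary), if (is.null(max_atoms)) Inf else max_atoms)
  support <- integer(0)
  coef <- numeric(0)
  r <- x
  while (sqrt(sum(r^2)) > tol && length(support) < limit) {
    corr <- abs(crossprod(dictionary, r))
    corr[support] <- -Inf
    j <- which.max(corr)
    support <- c(support, j)
    A <- dictionary[, support, drop = FALSE]
    coef <- qr.coef(qr(A), x)
    coef[is.na(coef)] <- 0
    r <- x - drop(A %*% coef)
  }
  list(support = support, coefficients = coef, residual = r,
       residual_norm = sqrt(sum(r^2)))
}

# Sparse-representation classification: global OMP, then a per-class
# residual. Default mode refits least squares on the global support
# restricted to each class's atoms; mode "class_omp" reruns OMP within each
# class's dictionary. Classes with no usable atoms get residual ||x||.
omp_predict <- function(fit, X, spec) {
  lv <- levels(fit$y)
  max_atoms <- if (is.null(spec$max_atoms)) nrow(fit$D) else spec$max_atoms
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    code <- omp_sparse_code(x, fit$D, tol = spec$tol, max_atoms = max_atoms)
    resid <- rep(sqrt(sum(x^2)), length(lv))
    for (ci in seq_along(lv)) {
      if (spec$residual_mode == "support") {
        sel <- code$support[fit$y[code$support] == lv[ci]]
        if (length(sel)) {
          A <- fit$D[, sel, drop = FALSE]
          cf <- qr.coef(qr(A), x)
          cf[is.na(cf)] <- 0
          resid[ci] <- sqrt(sum((x - drop(A %*% cf))^2))
        }
      } else {
        cols <- which(fit$y == lv[ci])
        sub <- omp_sparse_code(x, fit$D[, cols, drop = FALSE],
                               tol = spec$tol,
                               max_atoms = max(length(code$support), 1L))
        resid[ci] <- sub$residual_norm
      }
    }
    out[i] <- lv[which.min(resid)]
  }
  factor(out, levels = lv)
}
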