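# Full recognition pipeline: segmentation -> (optional random re-orientation)
# -> transform -> per-axis features -> per-subject [0,1] normalisation ->
# PCA -> classifier, evaluated by leave-one-subject-out cross-validation.

# Coerce a dataset to segmented form: list(segments, meta, rate, units).
as_har_segments <- function(dataset, window_s = 5) {
  if (inherits(dataset, "har_segments")) return(dataset)
  stopifnot(inherits(dataset, "har_dataset"))
  segs <- list()
  meta <- list()
  for (i in seq_len(nrow(dataset$meta))) {
    w <- segment_stream(dataset$streams[[i]], window_s, dataset$rate)
    if (!length(w)) next
    segs <- c(segs, w)
    meta[[length(meta) + 1L]] <- data.frame(
      subject = dataset$meta$subject[i],
      activity = dataset$meta$activity[i],
      segment = seq_along(w)
    )
  }
  structure(list(segments = segs, meta = do.call(rbind, meta),
                 rate = dataset$rate, units = dataset$units),
            class = "har_segments")
}

#' Extract per-segment feature vectors for a transform technique
#'
#' Segments the dataset into windows, optionally re-orients every segment of
#' every unit by an independent random rotation (emulating arbitrarily worn
#' units), applies the named transform, and computes the 26 statistical
#' features per channel. Feature-vector length is
#' \code{units * channels_per_unit(technique) * 26}.
#'
#' @param dataset A \code{"har_dataset"} or \code{"har_segments"} object.
#' @param technique One of [har_techniques()].
#' @param seed Seed governing the random re-orientations.
#' @param rotate \code{"none"} or \code{"segment"} (one random rotation per
#'   segment per unit applied to the raw data before the transform).
#' @param config [filter_config()] for the orientation-estimation
#'   techniques.
#' @param window_s Window duration in seconds.
#' @return List with \code{X} (segments x features matrix) and \code{meta}
#'   (subject/activity/segment data frame).
#' @export
har_features <- function(dataset, technique, seed = 1L,
                         rotate = c("none", "segment"),
                         config = filter_config(), window_s = 5) {
  technique <- match.arg(technique, har_techniques())
  rotate <- match.arg(rotate)
  ds <- as_har_segments(dataset, window_s)
  nseg <- length(ds$segments)
  stopifnot(nseg > 0L)
  units <- ds$units
  cpu <- channels_per_unit(technique)
  nchan <- units * cpu
  n <- nrow(ds$segments[[1L]])
  big <- matrix(0, n, nseg * nchan)
  with_seed(seed, {
    for (i in seq_len(nseg)) {
      useg <- segment_matrix_to_units(ds$segments[[i]], units, ds$rate)
      for (u in seq_len(units)) {
        seg <- useg[[u]]
        if (rotate == "segment") {
          P <- random_rotation()
          seg$acc <- seg$acc %*% t(P)
          seg$gyro <- seg$gyro %*% t(P)
          seg$mag <- seg$mag %*% t(P)
        }
        tr <- transform_segment(seg, technique, config = config)
        cols <- (i - 1L) * nchan + (u - 1L) * cpu + seq_len(cpu)
        big[, cols] <- tr$channels
      }
    }
  })
  feats <- features_channels(big, ds$rate)
  X <- matrix(as.vector(t(feats)), nrow = nseg, byrow = TRUE)
  list(X = X, meta = ds$meta)
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is exactly that subject's
#' segments and its training set is everyone else's.
#'
#' @param subject Vector of subject identifiers, one per segment.
#' @return List of folds, each \code{list(subject, train, test)} with
#'   integer row indices.
#' @export
l1o_split <- function(subject) {
  subs <- sort(unique(subject))
  if (length(subs) < 2L) stop("l1o_split: need at least two subjects")
  lapply(subs, function(s) {
    list(subject = s, train = which(subject != s),
         test = which(subject == s))
  })
}

#' Evaluate a transform/classifier combination by leave-one-subject-out
#'
#' Runs the complete pipeline and aggregates per-fold accuracies, the
#' pooled confusion matrix, per-class accuracies, and the mean per-class
#' accuracy within the stationary and non-stationary activity groups.
#'
#' @inheritParams har_features
#' @param spec A [classifier_spec()].
#' @param F Number of principal components retained (default 30).
#' @param pca_scope \code{"fold"} fits PCA on each fold's training subjects
#'   only (leakage-safe default); \code{"global"} fits once on all data.
#' @param stationary_classes Integer ids of the stationary activities
#'   (default \code{1:4}).
#' @param features Optional precomputed result of [har_features()] (the
#'   \code{dataset}/\code{technique}/\code{rotate} arguments are then only
#'   used for labelling).
#' @return Object of class \code{"har_eval"}.
#' @export
har_evaluate <- function(dataset, technique = "proposed",
                         spec = classifier_spec("svm"), seed = 1L,
                         rotate = c("none", "segment"), F = 30L,
                         pca_scope = c("fold", "global"),
                         config = filter_config(), window_s = 5,
                         stationary_classes = 1:4, features = NULL) {
  rotate <- match.arg(rotate)
  pca_scope <- match.arg(pca_scope)
  if (is.null(features)) {
    features <- har_features(dataset, technique, seed, rotate, config,
                             window_s)
  }
  X <- normalize_per_subject(features$X, features$meta$subject)
  meta <- features$meta
  y <- factor(meta$activity)
  folds <- l1o_split(meta$subject)
  if (pca_scope == "global") {
    pca <- fit_pca(X, F)
    Z_all <- apply_pca(pca, X)
  }
  K <- nlevels(y)
  confusion <- matrix(0L, K, K, dimnames = list(predicted = levels(y),
                                                true = levels(y)))
  fold_acc <- numeric(length(folds))
  names(fold_acc) <- vapply(folds, function(f) as.character(f$subject), "")
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    if (pca_scope == "fold") {
      pca <- fit_pca(X[f$train, , drop = FALSE], F)
      Ztr <- apply_pca(pca, X[f$train, , drop = FALSE])
      Zte <- apply_pca(pca, X[f$test, , drop = FALSE])
    } else {
      Ztr <- Z_all[f$train, , drop = FALSE]
      Zte <- Z_all[f$test, , drop = FALSE]
    }
    model <- har_train(spec, Ztr, y[f$train], seed = seed + fi)
    pred <- predict(model, Zte)
    truth <- y[f$test]
    fold_acc[fi] <- 100 * mean(pred == truth)
    confusion <- confusion + table(factor(pred, levels(y)),
                                   factor(truth, levels(y)))
  }
  per_class <- 100 * diag(confusion) / pmax(colSums(confusion), 1L)
  stat <- intersect(as.character(stationary_classes), levels(y))
  nonstat <- setdiff(levels(y), stat)
  structure(list(
    technique = technique, classifier = spec$name, rotate = rotate,
    fold_accuracy = fold_acc,
    mean_accuracy = mean(fold_acc),
    sd_accuracy = stats::sd(fold_acc) * sqrt((length(fold_acc) - 1) /
                                             length(fold_acc)),
    overall_accuracy = 100 * sum(diag(confusion)) / sum(confusion),
    confusion = confusion,
    per_class_accuracy = per_class,
    stationary_accuracy = if (length(stat)) mean(per_class[stat]) else NA,
    nonstationary_accuracy = if (length(nonstat)) {
      mean(per_class[nonstat])
    } else NA,
    n_test = sum(confusion)
  ), class = "har_eval")
}

#' @export
print.har_eval <- function(x, ...) {
  cat("Leave-one-subject-out evaluation\n")
  cat("  technique: ", x$technique, "   classifier: ", x$classifier,
      if (x$rotate == "segment") "   (randomly re-oriented units)" else "",
      "\n", sep = "")
  cat(sprintf("  accuracy: %.1f%% +/- %.1f%% over %d folds (overall %.1f%%)\n",
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracy),
              x$overall_accuracy))
  if (!is.na(x$stationary_accuracy)) {
    cat(sprintf("  stationary: %.1f%%   non-stationary: %.1f%%\n",
                x$stationary_accuracy, x$nonstationary_accuracy))
  }
  invisible(x)
}

#' @export
summary.har_eval <- function(object, ...) {
  print(object)
  cat("\nPer-fold accuracy (%):\n")
  print(round(object$fold_accuracy, 1))
  cat("\nConfusion matrix (rows = predicted, columns = true):\n")
  print(object$confusion)
  invisible(object)
}

#' Run the synthetic orientation-invariance benchmark
#'
#' Simulates a dataset, then evaluates each requested technique under the
#' condition it is meant for: the untransformed baseline on data from
#' nominally oriented units, the \code{"random"} condition with an
#' independent random re-orientation of every segment of every unit, and
#' the orientation-invariant transforms on the re-oriented data.
#'
#' @param seed Integer seed for the dataset and all re-orientations.
#' @param techniques Techniques to evaluate (default all seven).
#' @param spec A [classifier_spec()].
#' @param n_subjects,n_classes,minutes,units Dataset shape passed to
#'   [simulate_har_data()].
#' @param F Retained principal components.
#' @return Named numeric vector of mean leave-one-subject-out accuracies
#'   (%), plus attribute \code{"evals"} holding the full
#'   \code{"har_eval"} objects.
#' @export
har_benchmark <- function(seed = 1L, techniques = har_techniques(),
                          spec = classifier_spec("svm"), n_subjects = 8L,
                          n_classes = 19L, minutes = 0.5, units = 5L,
                          F = 30L) {
  ds <- simulate_har_data(n_subjects, n_classes, minutes, units = units,
                          seed = seed)
  segs <- as_har_segments(ds)
  acc <- numeric(length(techniques))
  names(acc) <- techniques
  evals <- list()
  for (te in techniques) {
    rot <- if (te %in% c("reference", "random")) "none" else "segment"
    ev <- har_evaluate(segs, te, spec, seed = seed, rotate = rot, F = F)
    acc[te] <- ev$mean_accuracy
    evals[[te]] <- ev
  }
  attr(acc, "evals") <- evals
  acc
}
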