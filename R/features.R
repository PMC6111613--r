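#' Split a multi-channel stream into non-overlapping windows
#'
#' Consecutive windows of \code{rate * window_s} samples; a trailing
#' remainder shorter than one window is dropped.
#'
#' @param x Numeric matrix (samples x channels) or vector.
#' @param window_s Window duration in seconds (default 5).
#' @param rate Sampling rate in Hz (default 25).
#' @return List of matrices, each \code{rate * window_s} rows.
#' @export
segment_stream <- function(x, window_s = 5, rate = 25) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n_win <- round(window_s * rate)
  stopifnot(n_win >= 1L)
  k <- nrow(x) %/% n_win
  if (k == 0L) {
    warning("segment_stream: stream shorter than one window")
    return(list())
  }
  lapply(seq_len(k), function(i) {
    x[((i - 1L) * n_win + 1L):(i * n_win), , drop = FALSE]
  })
}

#' Names of the 26 per-axis features, in extraction order
#' @return Character vector of length 26.
#' @export
axis_feature_names <- function() {
  c("min", "max", "mean", "variance", "skewness", "kurtosis",
    paste0("acf_lag", seq(5, 50, by = 5)),
    paste0("dft_peak", 1:5), paste0("dft_freq", 1:5))
}

# Batched extractor: X is samples x M (one column per channel instance);
# returns M x 26. Features per column: min, max, mean, variance (sample),
# skewness, kurtosis (plain m4/m2^2), biased autocorrelation at lags
# 5,10,...,50 normalised by lag 0, then the 5 largest DFT peak magnitudes
# (one-sided spectrum, DC excluded, local maxima with pairwise bin
# separation >= 11) and their frequencies in Hz. Constant columns yield
# zero autocorrelation/skewness/kurtosis, never NaN.
features_channels <- function(X, rate) {
  n <- nrow(X); m <- ncol(X)
  stopifnot(n >= 51L)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  ss <- colSums(Xc^2)
  m2 <- ss / n
  m3 <- colSums(Xc^3) / n
  m4 <- colSums(Xc^4) / n
  const <- m2 < .Machine$double.eps * 100
  skew <- ifelse(const, 0, m3 / m2^1.5)
  kurt <- ifelse(const, 0, m4 / m2^2)
  variance <- ss / (n - 1L)
  lags <- seq(5L, 50L, by = 5L)
  ac <- matrix(0, m, length(lags))
  ss_safe <- ifelse(const, 1, ss)
  for (j in seq_along(lags)) {
    l <- lags[j]
    ac[, j] <- colSums(Xc[1:(n - l), , drop = FALSE] *
                       Xc[(l + 1):n, , drop = FALSE]) / ss_safe
  }
  ac[const, ] <- 0
  # one-sided magnitude spectrum without the DC bin
  sp <- abs(stats::mvfft(X))
  nb <- n %/% 2L
  sp <- sp[2:(nb + 1L), , drop = FALSE]
  pk <- dft_peaks_cpp(sp, 5L, 11L)
  peak_mag <- t(pk[1:5, , drop = FALSE])
  peak_freq <- t(pk[6:10, , drop = FALSE]) * rate / n
  cbind(apply(X, 2L, min), apply(X, 2L, max), mu, variance, skew, kurt,
        ac, peak_mag, peak_freq, deparse.level = 0)
}

#' Statistical features of one axis over a window
#'
#' Computes the fixed 26-feature summary of a single channel: minimum,
#' maximum, mean, variance, skewness, kurtosis, the biased autocorrelation
#' (normalised by lag 0) at lags 5, 10, ..., 50, and the five largest
#' local maxima of the one-sided DFT magnitude spectrum (DC excluded,
#' pairwise bin separation at least 11 samples) followed by their
#' frequencies in Hz. Missing peaks are reported as (0, 0).
#'
#' @param x Numeric vector, length at least 51.
#' @param rate Sampling rate in Hz.
#' @return Named numeric vector of length 26 (see [axis_feature_names()]).
#' @export
extract_axis_features <- function(x, rate = 25) {
  stopifnot(is.numeric(x), length(x) >= 51L, all(is.finite(x)))
  f <- features_channels(matrix(x, ncol = 1L), rate)[1L, ]
  names(f) <- axis_feature_names()
  f
}

#' Min-max normalisation per subject
#'
#' Scales every feature dimension to \code{[0, 1]} independently within
#' each subject's feature vectors; dimensions constant within a subject
#' map to 0.
#'
#' @param X Numeric matrix (segments x features).
#' @param subject Vector of subject identifiers, one per row of \code{X}.
#' @return Matrix of the same shape with all values in \code{[0, 1]}.
#' @export
normalize_per_subject <- function(X, subject) {
  stopifnot(nrow(X) == length(subject))
  for (s in unique(subject)) {
    i <- which(subject == s)
    lo <- apply(X[i, , drop = FALSE], 2L, min)
    hi <- apply(X[i, , drop = FALSE], 2L, max)
    rng <- hi - lo
    rng[rng == 0] <- 1
    X[i, ] <- sweep(sweep(X[i, , drop = FALSE], 2L, lo), 2L, rng, "/")
  }
  X
}

#' Fit a PCA dimensionality-reduction model
#'
#' Eigen-decomposes the covariance matrix of the training vectors and keeps
#' the eigenvectors of the \code{F} largest eigenvalues. When the feature
#' dimension exceeds the sample count, the mathematically equivalent
#' eigendecomposition of the Gram matrix of centred rows is used. If the
#' data rank is below \code{F}, only the rank components are kept, with a
#' warning.
#'
#' @param X Numeric training matrix (segments x features).
#' @param F Number of components to retain (default 30).
#' @return Object of class \code{"pca_model"}: \code{mean}, \code{rotation}
#'   (features x F, orthonormal columns), \code{eigenvalues} (descending),
#'   \code{F}.
#' @export
fit_pca <- function(X, F = 30L) {
  n <- nrow(X); d <- ncol(X)
  stopifnot(n >= 2L)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  if (d <= n) {
    eg <- eigen(crossprod(Xc) / (n - 1L), symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    vecs <- eg$vectors
  } else {
    eg <- eigen(tcrossprod(Xc) / (n - 1L), symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    keep <- vals > max(vals[1], .Machine$double.eps) * 1e-12
    vecs <- crossprod(Xc, eg$vectors[, keep, drop = FALSE])
    vecs <- sweep(vecs, 2L, sqrt((n - 1L) * vals[keep]), "/")
    vals <- vals[keep]
  }
  rank <- sum(vals > max(vals[1], .Machine$double.eps) * 1e-9)
  keepF <- min(F, rank, ncol(vecs))
  if (keepF < F) {
    warning(sprintf("fit_pca: data rank %d below requested F = %d", keepF, F))
  }
  rot <- vecs[, seq_len(keepF), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (k in seq_len(keepF)) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  structure(list(mean = mu, rotation = rot, eigenvalues = vals,
                 F = keepF), class = "pca_model")
}

#' Project feature vectors with a fitted PCA model
#'
#' @param model A \code{"pca_model"} from [fit_pca()].
#' @param X Numeric matrix (segments x features), feature dimension matching
#'   the training data.
#' @return Matrix (segments x F) of projected coordinates.
#' @export
apply_pca <- function(model, X) {
  stopifnot(inherits(model, "pca_model"), ncol(X) == length(model$mean))
  sweep(X, 2L, model$mean) %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", length(x$mean), "features ->", x$F, "components\n")
  ev <- x$eigenvalues[seq_len(min(5, length(x$eigenvalues)))]
  cat("Leading eigenvalues:", paste(signif(ev, 4), collapse = ", "), "\n")
  invisible(x)
}
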