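# Readers/writers for the on-disk dataset layout: one plain-text CSV per
# 5-s segment (125 rows x 45 columns at the default shape), organised as
# <dir>/a01..aNN/p1..pS/s01..sMM.txt. Columns are unit-major; within each
# unit the order is acc x/y/z, gyro x/y/z, mag x/y/z (an overridable dialect
# setting, since the public dataset does not document it).

#' Read one segment file into per-unit segments
#'
#' @param path Path to a comma-separated numeric file with
#'   \code{9 * units} columns.
#' @param units Number of sensor units encoded in the columns (default 5).
#' @param rate Sampling rate in Hz (default 25).
#' @return List of \code{units} [unit_segment()] objects.
#' @export
read_segment_file <- function(path, units = 5L, rate = 25) {
  raw <- tryCatch(
    utils::read.table(path, sep = ",", header = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop("read_segment_file: ", path, ": ",
                             conditionMessage(e))
  )
  X <- as.matrix(raw)
  if (ncol(X) != 9L * units) {
    stop("read_segment_file: ", path, ": expected ", 9L * units,
         " columns, found ", ncol(X))
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1L, ]
    stop("read_segment_file: ", path, ": non-numeric value at row ",
         bad[1L], ", column ", bad[2L])
  }
  segment_matrix_to_units(X, units, rate)
}

segment_matrix_to_units <- function(X, units, rate) {
  lapply(seq_len(units), function(u) {
    cols <- (u - 1L) * 9L
    unit_segment(X[, cols + 1:3, drop = FALSE],
                 X[, cols + 4:6, drop = FALSE],
                 X[, cols + 7:9, drop = FALSE], rate = rate, unit = u)
  })
}

#' Write one segment matrix as a comma-separated file
#'
#' Full double precision, no header, matching [read_segment_file()].
#'
#' @param X Numeric matrix (samples x \code{9 * units}).
#' @param path Output file path.
#' @export
write_segment_file <- function(X, path) {
  utils::write.table(format(X, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset as a directory tree of segment files
#'
#' Splits every recording into non-overlapping 5-s windows and writes each
#' as \code{aXX/pY/sZZ.txt} under \code{dir}.
#'
#' @param dataset A \code{"har_dataset"} from [simulate_har_data()].
#' @param dir Output directory (created if missing).
#' @param window_s Window duration in seconds (default 5).
#' @return Invisibly, the index data frame (see [dataset_index()]).
#' @export
write_har_dataset <- function(dataset, dir, window_s = 5) {
  stopifnot(inherits(dataset, "har_dataset"))
  for (i in seq_len(nrow(dataset$meta))) {
    a <- dataset$meta$activity[i]
    s <- dataset$meta$subject[i]
    sub <- file.path(dir, sprintf("a%02d", a), sprintf("p%d", s))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    segs <- segment_stream(dataset$streams[[i]], window_s, dataset$rate)
    for (j in seq_along(segs)) {
      write_segment_file(segs[[j]], file.path(sub, sprintf("s%02d.txt", j)))
    }
  }
  invisible(dataset_index(dir))
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper around [simulate_har_data()] and
#' [write_har_dataset()].
#'
#' @inheritParams simulate_har_data
#' @param dir Output directory.
#' @return Invisibly, the index data frame of written files.
#' @export
simulate_dataset <- function(dir, n_subjects = 8L, n_classes = 19L,
                             minutes = 5, rate = 25, units = 5L, seed = 1L,
                             noise = c(acc = 0.05, gyro = 0.005,
                                       mag = 0.01)) {
  ds <- simulate_har_data(n_subjects, n_classes, minutes, rate, units,
                          seed, noise)
  write_har_dataset(ds, dir)
}

#' Index a dataset directory
#'
#' @param dir Root of an \code{aXX/pY/sZZ.txt} tree.
#' @return Data frame with \code{activity}, \code{subject},
#'   \code{segment} and \code{path}, sorted.
#' @export
dataset_index <- function(dir) {
  paths <- list.files(dir, pattern = "^s[0-9]+\\.txt$", recursive = TRUE,
                      full.names = TRUE)
  if (!length(paths)) stop("dataset_index: no segment files under ", dir)
  rel <- substring(paths, nchar(dir) + 2L)
  parts <- strsplit(rel, "/", fixed = TRUE)
  df <- data.frame(
    activity = as.integer(sub("^a", "", vapply(parts, `[`, "", 1L))),
    subject = as.integer(sub("^p", "", vapply(parts, `[`, "", 2L))),
    segment = as.integer(sub("^s([0-9]+)\\.txt$", "\\1",
                             vapply(parts, `[`, "", 3L))),
    path = paths
  )
  df[order(df$subject, df$activity, df$segment), ]
}

#' Read a segmented dataset directory
#'
#' Loads every segment file under \code{dir} into memory.
#'
#' @param dir Root of an \code{aXX/pY/sZZ.txt} tree.
#' @param units Number of sensor units per file (default 5).
#' @param rate Sampling rate in Hz (default 25).
#' @return Object of class \code{"har_segments"}: \code{segments} (list of
#'   numeric matrices), \code{meta} (subject/activity/segment data frame),
#'   \code{rate}, \code{units}.
#' @export
read_dataset <- function(dir, units = 5L, rate = 25) {
  idx <- dataset_index(dir)
  segs <- lapply(idx$path, function(p) {
    raw <- as.matrix(utils::read.table(p, sep = ",", header = FALSE,
                                       colClasses = "numeric"))
    if (ncol(raw) != 9L * units) {
      stop("read_dataset: ", p, ": expected ", 9L * units, " columns")
    }
    raw
  })
  structure(list(segments = segs,
                 meta = idx[, c("subject", "activity", "segment")],
                 rate = rate, units = units),
            class = "har_segments")
}
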