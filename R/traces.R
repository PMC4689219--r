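#' Hierarchical clustering of single-cell traces
#'
#' Agglomerative clustering of expression timecourses with Euclidean
#' distance on log-transformed intensities and Ward linkage, cutting the
#' tree at `k` clusters. The log transform makes the distance robust to
#' the multiplicative character of fluorescence noise; intensities are
#' clamped at zero and shifted by one count (`log1p`) so background-level
#' values are well defined. Cluster labels are ordered by descending
#' cluster-mean final value, so cluster 1 is the high-expressing class.
#'
#' @param trace_matrix Numeric matrix, cells in rows, frames in columns;
#'   no missing values (interpolate gaps beforehand).
#' @param k Number of clusters (1 <= k <= number of cells).
#' @return Integer vector of cluster labels, one per cell, with the
#'   `hclust` tree attached as attribute `"tree"`.
#' @examples
#' m <- rbind(matrix(10, 5, 8), matrix(0.1, 5, 8))
#' cluster_traces(m, k = 2)
#' @export
cluster_traces <- function(trace_matrix, k) {
  if (!is.matrix(trace_matrix) || anyNA(trace_matrix))
    stop("'trace_matrix' must be a complete cells x frames matrix",
         call. = FALSE)
  check_number(k, "k", lower = 1)
  if (k > nrow(trace_matrix))
    stop("'k' exceeds the number of cells", call. = FALSE)
  lt <- log1p(pmax(trace_matrix, 0))
  tree <- stats::hclust(stats::dist(lt), method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  finals <- tapply(trace_matrix[, ncol(trace_matrix)], raw, mean)
  relabel <- match(raw, as.integer(names(sort(finals, decreasing = TRUE))))
  structure(relabel, tree = tree)
}

#' Peaks of a smoothed intensity histogram
#'
#' Mimics flow-cytometry peak calling: the 1-D intensity sample is
#' smoothed by a Gaussian kernel density estimate on a 512-point grid
#' spanning the data, and local maxima with prominence of at least
#' `prominence_frac` of the global maximum are reported in increasing
#' position order. The default bandwidth is Silverman's rule of thumb.
#'
#' @param values Numeric intensity sample (>= 10 values).
#' @param bandwidth Kernel bandwidth \[a.u.\]; `NULL` for Silverman's rule.
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   global density maximum.
#' @return An object of class `"peak_set"`: data frame with columns
#'   `position`, `height`, `prominence`, the bandwidth used attached as
#'   attribute `"bandwidth"`.
#' @examples
#' set.seed(1)
#' histogram_peaks(c(rnorm(500), rnorm(500, 5)))
#' @export
histogram_peaks <- function(values, bandwidth = NULL,
                            prominence_frac = 0.05) {
  if (length(values) < 10L)
    stop("at least 10 values are required for peak detection",
         call. = FALSE)
  if (anyNA(values)) stop("'values' must not contain NA", call. = FALSE)
  dens <- stats::density(values, bw = bandwidth %||% "nrd0", n = 512,
                         from = min(values), to = max(values))
  x <- dens$x; y <- dens$y
  n <- length(y)
  # local maxima, treating the grid ends as walls
  is_max <- c(y[1L] > y[2L],
              y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n],
              y[n] > y[n - 1L])
  idx <- which(is_max)
  if (length(idx) == 0L) idx <- which.max(y)
  prominence <- vapply(idx, function(i) {
    peers <- idx[y[idx] > y[i]]
    left <- peers[peers < i]; right <- peers[peers > i]
    low_l <- if (length(left)) min(y[max(left):i]) else min(y[1:i])
    low_r <- if (length(right)) min(y[i:min(right)]) else min(y[i:n])
    y[i] - if (length(left) && length(right)) max(low_l, low_r)
           else if (length(left)) low_l
           else if (length(right)) low_r
           else min(y)
  }, numeric(1L))
  keep <- prominence >= prominence_frac * max(y)
  if (!any(keep)) keep <- which.max(y[idx])
  out <- data.frame(position = x[idx[keep]], height = y[idx[keep]],
                    prominence = prominence[keep])
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, bandwidth = dens$bw,
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peak(s), bandwidth = %.4g\n", nrow(x),
              attr(x, "bandwidth")))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fold-change between the positive and negative histogram peaks
#'
#' Position of the highest-position (positive) peak divided by the
#' position of the lowest-position (negative) peak of a smoothed intensity
#' histogram — the per-sample summary used to compare reporter-positive
#' populations across signaling conditions.
#'
#' @inheritParams histogram_peaks
#' @return The peak-position ratio (> 0).
#' @examples
#' set.seed(1)
#' peak_fold_change(c(rnorm(500, 2, 0.2), rnorm(500, 10, 0.5)))  # ~5
#' @export
peak_fold_change <- function(values, bandwidth = NULL,
                             prominence_frac = 0.05) {
  pk <- histogram_peaks(values, bandwidth, prominence_frac)
  if (nrow(pk) < 2L)
    stop("fold-change undefined: histogram is unimodal", call. = FALSE)
  lo <- min(pk$position); hi <- max(pk$position)
  if (lo <= 0)
    stop("non-positive negative-peak position: fold-change undefined",
         call. = FALSE)
  hi / lo
}

#' Reshape long trace tables to a cells x frames matrix
#'
#' @param traces Long data frame with columns `cell_id`, `time_h`,
#'   `channel`, `intensity` (as written by [write_traces()]), or the
#'   `traces` component of a [simulate_population()] result (columns
#'   `cell`, `time`, `N`, `G`, `G_X`).
#' @param channel Channel to extract (e.g. `"G_X"`).
#' @return Numeric matrix, cells in rows (named by cell id), frames in
#'   columns, with the frame times as attribute `"times"`.
#' @examples
#' pop <- simulate_population(fate_model(), pulse_protocol(),
#'                            dose_distribution("fixed", 0.3), n = 2)
#' dim(trace_matrix(pop$traces, "G_X"))
#' @export
trace_matrix <- function(traces, channel) {
  if (all(c("cell_id", "time_h", "channel", "intensity") %in% names(traces))) {
    traces <- traces[traces$channel == channel, ]
    if (nrow(traces) == 0L)
      stop(sprintf("channel '%s' not present", channel), call. = FALSE)
    cells <- unique(traces$cell_id)
    times <- sort(unique(traces$time_h))
    m <- matrix(NA_real_, length(cells), length(times),
                dimnames = list(cells, NULL))
    m[cbind(match(traces$cell_id, cells), match(traces$time_h, times))] <-
      traces$intensity
  } else if (all(c("cell", "time", channel) %in% names(traces))) {
    cells <- unique(traces$cell)
    times <- sort(unique(traces$time))
    m <- matrix(NA_real_, length(cells), length(times),
                dimnames = list(cells, NULL))
    m[cbind(match(traces$cell, cells), match(traces$time, times))] <-
      traces[[channel]]
  } else stop("unrecognized trace table layout", call. = FALSE)
  if (anyNA(m))
    warning("trace table has gaps; matrix contains NA")
  attr(m, "times") <- times
  m
}
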