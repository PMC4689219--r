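# Coerce fate labels to logical "positive" (GATA/PrE outcome).
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(labels == 1)
  }
  lab <- as.character(labels)
  pos_names <- c("GATA_high", "PrE", "positive", "TRUE", "1")
  neg_names <- c("NANOG_high", "Epi", "negative", "FALSE", "0")
  if (!all(lab %in% c(pos_names, neg_names)))
    stop("unrecognized fate labels: ",
         paste(unique(setdiff(lab, c(pos_names, neg_names))), collapse = ", "),
         call. = FALSE)
  lab %in% pos_names
}

# Fast ROC statistics for one value vector: candidate thresholds are the
# midpoints between consecutive distinct sorted values plus +/-Inf
# sentinels; predict positive iff value >= threshold. Returns everything
# in descending-threshold order (so TPR/FPR are non-decreasing).
roc_core <- function(values, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC undefined: one class is empty", call. = FALSE)
  d <- sort(unique(values), decreasing = TRUE)
  thr <- if (length(d) > 1L)
    c(Inf, (d[-length(d)] + d[-1L]) / 2, -Inf) else c(Inf, -Inf)
  # cumulative class counts over descending distinct-value groups
  grp <- match(values, d)
  tp <- cumsum(tabulate(grp[pos], nbins = length(d)))
  fp <- cumsum(tabulate(grp[!pos], nbins = length(d)))
  TPR <- c(0, tp[-length(tp)] / n1, 1)
  FPR <- c(0, fp[-length(fp)] / n0, 1)
  auc <- trapz(FPR, TPR)
  J <- TPR - FPR
  best <- which.max(J)  # first maximum = largest threshold on ties
  list(thresholds = thr, TPR = TPR, FPR = FPR, auc = auc,
       optimal_threshold = thr[best], J = J[best])
}

#' ROC analysis of a labeled intensity sample
#'
#' Receiver operating characteristic for separating the two fate classes by
#' a single intensity threshold (predict the GATA/PrE outcome when the value
#' is at or above the cutoff). Candidate thresholds are the midpoints
#' between consecutive distinct sorted values plus infinite sentinels; the
#' area under the curve is computed by the trapezoidal rule and equals the
#' Mann-Whitney pair statistic with ties counted one half.
#'
#' @param values Numeric intensities \[a.u.\].
#' @param labels Parallel fate labels; positive = GATA/PrE outcome
#'   (accepts logical, 0/1, or `"GATA_high"`/`"NANOG_high"` style labels).
#' @return An object of class `"roc_frame"`: list with ascending
#'   `thresholds`, aligned `TPR` and `FPR`, `auc`, `optimal_threshold`
#'   (Youden-optimal cutoff, ties resolved toward the largest threshold)
#'   and `J` (the maximized TPR - FPR).
#' @examples
#' rf <- roc_frame(c(1, 3, 2, 4), c(0, 0, 1, 1))
#' rf$auc  # 0.75
#' @export
roc_frame <- function(values, labels) {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length", call. = FALSE)
  if (anyNA(values)) stop("'values' must not contain NA", call. = FALSE)
  pos <- as_positive(labels)
  rc <- roc_core(values, pos)
  k <- length(rc$thresholds)
  structure(list(thresholds = rev(rc$thresholds), TPR = rev(rc$TPR),
                 FPR = rev(rc$FPR), auc = rc$auc,
                 optimal_threshold = rc$optimal_threshold, J = rc$J,
                 n_pos = sum(pos), n_neg = sum(!pos)),
            class = "roc_frame")
}

#' @export
print.roc_frame <- function(x, ...) {
  cat(sprintf(
    "ROC frame: %d positives, %d negatives\n  AUC = %.4f, optimal threshold = %g (J = %.4f)\n",
    x$n_pos, x$n_neg, x$auc, x$optimal_threshold, x$J))
  invisible(x)
}

#' @export
plot.roc_frame <- function(x, ...) {
  graphics::plot(x$FPR, x$TPR, type = "s", xlab = "FPR", ylab = "TPR",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  i <- which(x$thresholds == x$optimal_threshold)[1L]
  graphics::points(x$FPR[i], x$TPR[i], col = "red3", pch = 19)
  invisible(x)
}

#' Youden-optimal classification threshold
#'
#' The cutoff maximizing `TPR - FPR` (Youden's J) among the candidate
#' thresholds of [roc_frame()]; ties are broken toward the largest
#' threshold, i.e. the most conservative call of differentiation.
#'
#' @inheritParams roc_frame
#' @return List with `threshold` and `J`.
#' @examples
#' optimal_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1))  # threshold 2.5, J = 1
#' @export
optimal_threshold <- function(values, labels) {
  rf <- roc_frame(values, labels)
  list(threshold = rf$optimal_threshold, J = rf$J)
}

check_trace_matrix <- function(traces, labels) {
  if (!is.matrix(traces))
    stop("'traces' must be a cells x frames matrix (see trace_matrix())",
         call. = FALSE)
  if (nrow(traces) != length(labels))
    stop("one label per trace row is required", call. = FALSE)
  invisible(traces)
}

#' Per-timepoint ROC analysis with bootstrap uncertainty
#'
#' Runs [roc_frame()] on the instantaneous values of every frame of a set
#' of single-cell traces against their end-point fate labels, and estimates
#' per-frame standard deviations of the AUC and of the optimal threshold by
#' bootstrap resampling of cells (whole traces, since frames within a cell
#' are dependent). Replicates in which one class vanishes are redrawn (up
#' to 100 attempts).
#'
#' @param traces Numeric matrix, cells in rows, frames in columns.
#' @param labels Per-cell fate labels (positive = GATA/PrE outcome).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed for the resampling.
#' @param times Optional frame times \[h\] (defaults to column index).
#' @return An object of class `"roc_timecourse"`: data frame with columns
#'   `time`, `auc`, `auc_sd`, `threshold`, `threshold_sd`, `J`; `n_boot`
#'   is carried as an attribute.
#' @examples
#' toy <- generate_labeled_toy(20, 20, separation = 3, seed = 1)
#' m <- cbind(toy$values, toy$values)   # two identical frames
#' roc_timecourse(m, toy$labels, n_boot = 20, seed = 1)
#' @export
roc_timecourse <- function(traces, labels, n_boot = 1000, seed = NULL,
                           times = NULL) {
  check_trace_matrix(traces, labels)
  check_number(n_boot, "n_boot", lower = 1)
  pos <- as_positive(labels)
  nf <- ncol(traces)
  times <- times %||% attr(traces, "times") %||% seq_len(nf)
  point <- lapply(seq_len(nf), function(j) roc_core(traces[, j], pos))
  boot_auc <- matrix(NA_real_, n_boot, nf)
  boot_thr <- matrix(NA_real_, n_boot, nf)
  n <- nrow(traces)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- NULL
      for (try in 1:100) {
        cand <- sample.int(n, n, replace = TRUE)
        if (any(pos[cand]) && any(!pos[cand])) { idx <- cand; break }
      }
      if (is.null(idx)) next  # flagged: replicate left NA
      for (j in seq_len(nf)) {
        rc <- roc_core(traces[idx, j], pos[idx])
        boot_auc[b, j] <- rc$auc
        boot_thr[b, j] <- rc$optimal_threshold
      }
    }
  })
  finite_sd <- function(col) stats::sd(col[is.finite(col)])
  out <- data.frame(
    time = times,
    auc = vapply(point, `[[`, numeric(1L), "auc"),
    auc_sd = apply(boot_auc, 2L, finite_sd),
    threshold = vapply(point, `[[`, numeric(1L), "optimal_threshold"),
    threshold_sd = apply(boot_thr, 2L, finite_sd),
    J = vapply(point, `[[`, numeric(1L), "J"))
  structure(out, n_boot = n_boot,
            class = c("roc_timecourse", "data.frame"))
}

#' @export
print.roc_timecourse <- function(x, ...) {
  cat(sprintf("ROC timecourse: %d frames, %d bootstrap replicates\n",
              nrow(x), attr(x, "n_boot")))
  print.data.frame(utils::head(as.data.frame(x), 5L), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}

#' @export
plot.roc_timecourse <- function(x, ...) {
  graphics::plot(x$time, x$auc, type = "l", ylim = c(0, 1),
                 xlab = "time [h]", ylab = "AUC", ...)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$auc - x$auc_sd, rev(x$auc + x$auc_sd)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$time, x$auc)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Fate-prediction accuracy at one frame
#'
#' Fraction of cells whose fate is correctly predicted by thresholding
#' their intensity at a given frame (predict the GATA/PrE outcome when the
#' value is at or above the frame's cutoff).
#'
#' @inheritParams roc_timecourse
#' @param thresholds Per-frame cutoffs (e.g. the `threshold` column of a
#'   [roc_timecourse()]), or a single cutoff for `frame`.
#' @param frame Column index of the frame to score.
#' @return Fraction correct, in \[0, 1\].
#' @examples
#' toy <- generate_labeled_toy(10, 10, separation = 5, seed = 1)
#' m <- matrix(toy$values, ncol = 1)
#' th <- optimal_threshold(toy$values, toy$labels)$threshold
#' prediction_accuracy(m, toy$labels, th, frame = 1)
#' @export
prediction_accuracy <- function(traces, labels, thresholds, frame) {
  check_trace_matrix(traces, labels)
  if (frame < 1L || frame > ncol(traces))
    stop("'frame' out of range", call. = FALSE)
  thr <- if (length(thresholds) == 1L) thresholds else thresholds[frame]
  pos <- as_positive(labels)
  mean((traces[, frame] >= thr) == pos)
}

#' Cumulative-exposure value series
#'
#' Running time-integral of each trace (trapezoidal rule), an alternative
#' classifier input summarizing cumulative rather than instantaneous
#' reporter exposure.
#'
#' @param traces Numeric matrix, cells in rows, frames in columns.
#' @param times Frame times \[h\].
#' @return Matrix of the same shape with cumulative integrals.
#' @examples
#' cumulative_exposure(matrix(1, 2, 4), times = 0:3)
#' @export
cumulative_exposure <- function(traces, times = attr(traces, "times")) {
  if (is.null(times)) stop("'times' required", call. = FALSE)
  if (length(times) != ncol(traces))
    stop("'times' must match the number of frames", call. = FALSE)
  dt <- diff(times)
  out <- traces
  out[, 1L] <- 0
  for (j in seq_along(dt))
    out[, j + 1L] <- out[, j] + (traces[, j] + traces[, j + 1L]) / 2 * dt[j]
  attr(out, "times") <- times
  out
}
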