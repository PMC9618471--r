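#' Binary ground-truth labels for ischaemia classification
#'
#' Combines the highly and moderately affected regions into the positive
#' (hypoperfused) class and the unaffected region into the negative class;
#' background and blood-pool voxels are excluded (NA).
#'
#' @param labels a region label map from [build_phantom_labels()].
#' @return integer array of the same shape: 1 positive, 0 negative, NA
#'   excluded. Fails if either class is empty.
#' @export
make_truth_labels <- function(labels) {
  lab <- unclass(labels)
  out <- array(NA_integer_, dim = dim(lab))
  out[lab %in% c("highly", "moderate")] <- 1L
  out[lab == "unaffected"] <- 0L
  if (!any(out == 1L, na.rm = TRUE) || !any(out == 0L, na.rm = TRUE))
    stop_perfusim("need at least one affected and one unaffected voxel")
  out
}

# Midrank (Mann-Whitney) AUC; equals the trapezoidal area with ties
# contributing 1/2. Used for fast bootstrap replicates.
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve of the MTT threshold classifier
#'
#' Sweeps a decision threshold over all unique score values (plus an
#' infinite sentinel); a voxel is called hypoperfused when its score
#' (typically MTT) exceeds the threshold. The AUC is the trapezoidal area,
#' equivalent to the Mann-Whitney concordance with ties counted one half.
#'
#' @param scores numeric scores (higher = more likely positive); NA scores
#'   are excluded and counted in \code{n_excluded}.
#' @param labels binary labels (1 positive, 0 negative), same length; pairs
#'   with NA labels are dropped.
#' @return an object of class \code{perf_roc}: \code{thresholds},
#'   \code{fpr}, \code{tpr} (nondecreasing, endpoints (0,0) and (1,1)),
#'   \code{auc}, \code{n_pos}, \code{n_neg}, \code{n_excluded}.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_perfusim("scores and labels must have equal length")
  keep <- !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n_excluded <- sum(is.na(scores))
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_perfusim("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # collapse ties: cumulative counts at each distinct threshold value
  last_of_value <- c(diff(s) != 0, TRUE)
  tp <- cumsum(l == 1L)[last_of_value]
  fp <- cumsum(l == 0L)[last_of_value]
  thresholds <- c(Inf, s[last_of_value])
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg, n_excluded = n_excluded),
            class = "perf_roc")
}

#' @export
print.perf_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positives, %d negatives%s)\n",
              x$auc, x$n_pos, x$n_neg,
              if (x$n_excluded) sprintf(", %d NA scores excluded",
                                        x$n_excluded) else ""))
  invisible(x)
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Resamples (score, label) pairs with replacement, recomputes the AUC per
#' replicate, and reports percentile bounds. Replicates that lose one class
#' entirely are redrawn so the number of bootstrap replicates stays fixed.
#' Resampling is unstratified.
#'
#' @param scores,labels as in [roc_curve()].
#' @param n_boot number of bootstrap replicates; default 1000.
#' @param percentiles lower/upper percentile bounds; default \code{c(5, 95)}.
#' @param seed RNG seed for reproducible resampling.
#' @return an object of class \code{bootstrap_ci}: \code{point} (full-sample
#'   AUC), \code{lower}, \code{upper}, \code{n_boot}, \code{percentiles},
#'   \code{seed}, \code{stratified = FALSE}, and a \code{coverage_flag} set
#'   when resampling noise places the point estimate outside the interval.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000,
                             percentiles = c(5, 95), seed = NULL) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  if (!any(labels == 1L) || !any(labels == 0L))
    stop_perfusim("both classes must be present")
  if (n_boot < 1L) stop_perfusim("n_boot must be >= 1")
  n <- length(scores)
  point <- auc_rank(scores, labels)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      for (attempt in seq_len(1000L)) {
        idx <- sample.int(n, n, replace = TRUE)
        l <- labels[idx]
        if (any(l == 1L) && any(l == 0L))
          return(auc_rank(scores[idx], l))
      }
      stop_perfusim("degenerate data: bootstrap replicates never contain ",
                    "both classes")
    }, 0)
  })
  qs <- stats::quantile(boots, percentiles / 100, names = FALSE)
  structure(list(point = point, lower = qs[1], upper = qs[2],
                 n_boot = as.integer(n_boot), percentiles = percentiles,
                 seed = seed, stratified = FALSE,
                 coverage_flag = !(qs[1] <= point && point <= qs[2])),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f-%.3f] (%d bootstraps, %g-%g%% percentiles%s)\n",
              x$point, x$lower, x$upper, x$n_boot,
              x$percentiles[1], x$percentiles[2],
              if (x$coverage_flag) ", point outside interval" else ""))
  invisible(x)
}
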