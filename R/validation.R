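#' Normalized root-mean-square error between two signals
#'
#' The RMS of the elementwise difference expressed as a percentage of the
#' signal's maximum possible range:
#' `100 * sqrt(mean((a - b)^2)) / signal_range`. Used to compare
#' motor-command sequences (and any other equal-length signal pair) across
#' runs.
#'
#' @param a,b equal-length numeric signals (vectors or matrices of equal
#'   shape).
#' @param signal_range the maximum possible amplitude range of the signal,
#'   `> 0`.
#' @return the normalized RMSE in percent.
#' @export
normalized_rmse <- function(a, b, signal_range) {
  if (length(a) != length(b))
    stop("signals must have equal length", call. = FALSE)
  if (signal_range <= 0)
    stop("signal_range must be positive", call. = FALSE)
  100 * sqrt(mean((as.numeric(a) - as.numeric(b))^2)) / signal_range
}

#' Segmental signal-to-noise ratio
#'
#' The waveform pair is cut into consecutive frames of `frame_len` samples;
#' each frame's SNR `10 * log10(sum(ref^2) / sum((ref - deg)^2))` is clamped
#' to `clamp` dB, and the clamped values are averaged. Frames with zero
#' reference energy are skipped; a zero-difference frame counts at the clamp
#' ceiling.
#'
#' @param ref reference waveform.
#' @param deg degraded waveform, same length.
#' @param frame_len frame length in samples.
#' @param clamp length-2 dB clamp, default `c(-10, 35)`.
#' @return mean segmental SNR in dB.
#' @export
seg_snr <- function(ref, deg, frame_len, clamp = c(-10, 35)) {
  if (length(ref) != length(deg))
    stop("signals must have equal length", call. = FALSE)
  if (frame_len <= 0) stop("frame_len must be positive", call. = FALSE)
  n_frames <- floor(length(ref) / frame_len)
  if (n_frames == 0) stop("signal shorter than one frame", call. = FALSE)
  vals <- numeric(0)
  for (f in seq_len(n_frames)) {
    idx <- ((f - 1) * frame_len + 1):(f * frame_len)
    es <- sum(ref[idx]^2)
    if (es == 0) next
    en <- sum((ref[idx] - deg[idx])^2)
    snr <- if (en == 0) Inf else 10 * log10(es / en)
    vals <- c(vals, min(max(snr, clamp[1]), clamp[2]))
  }
  if (length(vals) == 0)
    stop("no voiced reference material: all frames had zero reference energy",
         call. = FALSE)
  mean(vals)
}

#' Pooled-variance Cohen's d from group summaries
#'
#' `(m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)`: the standardized mean difference
#' using the root-mean of the two group variances.
#'
#' @param m1,sd1 group 1 mean and sample standard deviation.
#' @param m2,sd2 group 2 mean and sample standard deviation.
#' @return Cohen's d.
#' @export
cohens_d_pooled <- function(m1, sd1, m2, sd2) {
  (m1 - m2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Paired t-test and effect size for a metric
#'
#' Two-sided paired t-test on the index-paired groups (t statistic on the
#' differences with n - 1 degrees of freedom) plus the pooled-variance
#' Cohen's d of the group means. Identical groups report `t = 0, p = 1`.
#'
#' @param group1,group2 equal-length numeric vectors, paired by index,
#'   `n >= 2`.
#' @param metric metric label for the report row.
#' @return a one-row data.frame of class `metric_report` with columns
#'   `metric`, `group1_mean`, `group1_sd`, `group2_mean`, `group2_sd`,
#'   `t_stat`, `p_value`, `cohens_d`, `n_pairs`.
#' @export
paired_stats <- function(group1, group2, metric = "metric") {
  n <- length(group1)
  if (length(group2) != n)
    stop("groups must have equal length (paired by index)", call. = FALSE)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- group1 - group2
  if (sd(d) == 0) {
    t_stat <- 0; p <- 1
  } else {
    tt <- t.test(group1, group2, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  out <- data.frame(metric = metric,
                    group1_mean = mean(group1), group1_sd = sd(group1),
                    group2_mean = mean(group2), group2_sd = sd(group2),
                    t_stat = t_stat, p_value = p,
                    cohens_d = cohens_d_pooled(mean(group1), sd(group1),
                                               mean(group2), sd(group2)),
                    n_pairs = n)
  class(out) <- c("metric_report", class(out))
  out
}
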