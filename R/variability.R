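#' Per-peak mean and coefficient of variation
#'
#' Computes, for every peak, the mean normalized intensity across samples and
#' its coefficient of variation (sample standard deviation with `n - 1`
#' denominator, divided by the mean). Peaks with mean 0 get CV 0 and are
#' excluded from trend fitting downstream.
#'
#' @param m A `CountMatrix` at stage `normalized` with at least 2 samples.
#' @return A `MeanCVTable`: data frame with columns `peak_id`, `mean`, `cv`,
#'   and placeholder columns `expected_cv`, `residual`, `flag` (filled by
#'   [flag_variable_peaks()]).
#' @export
mean_cv <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  if (m$stage != "normalized")
    stop("mean_cv expects a normalized matrix")
  if (ncol(m$values) < 2L)
    stop("at least 2 samples are required to estimate a CV")
  mu <- rowMeans(m$values)
  sd_ <- apply(m$values, 1L, stats::sd)
  cv <- ifelse(mu > 0, sd_ / mu, 0)
  out <- data.frame(peak_id = m$peak_ids, mean = mu, cv = cv,
                    expected_cv = NA_real_, residual = NA_real_,
                    flag = NA, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("MeanCVTable", "data.frame")
  out
}

#' Fit the shot-noise mean-CV trend
#'
#' Least-squares fit of the trend `CV^2 = a / mean + b` on peaks with
#' positive mean, performed as a linear regression of `CV^2` on `1 / mean`.
#' The `a / mean` term is the Poisson counting ("shot") noise contribution;
#' `b` absorbs the multiplicative technical/biological CV floor. Negative
#' coefficient estimates are handled by clipping at 0 and refitting the free
#' coefficient (through-origin slope when the intercept clips; plain mean of
#' `CV^2` when the slope clips).
#'
#' @param t A `MeanCVTable` with at least 20 peaks of positive mean.
#' @return A `CVTrendFit`: list with `a` (shot-noise coefficient), `b`
#'   (asymptotic CV^2 floor), `rss` and `n`.
#' @export
fit_cv_trend <- function(t) {
  stopifnot(inherits(t, "MeanCVTable"))
  keep <- t$mean > 0
  if (sum(keep) < 20L)
    stop("need at least 20 peaks with positive mean to fit the CV trend")
  x <- 1 / t$mean[keep]
  y <- t$cv[keep]^2
  if (stats::var(x) == 0)
    stop("degenerate design: all peak means are equal")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, inv_mean = x), y)
  b <- unname(fit$coefficients[1L])
  a <- unname(fit$coefficients[2L])
  if (a < 0) {                       # no shot-noise slope: flat trend
    a <- 0
    b <- max(0, mean(y))
  } else if (b < 0) {                # no CV floor: through-origin slope
    b <- 0
    a <- max(0, sum(x * y) / sum(x^2))
  }
  res <- y - (a * x + b)
  structure(list(a = a, b = b, rss = sum(res^2), n = sum(keep)),
            class = "CVTrendFit")
}

#' @export
print.CVTrendFit <- function(x, ...) {
  cat(sprintf("CV trend fit: CV^2 = %.4g / mean + %.4g  (n = %d, rss = %.4g)\n",
              x$a, x$b, x$n, x$rss))
  invisible(x)
}

#' Expected CV at a given mean under a fitted trend
#'
#' @param fit A `CVTrendFit`.
#' @param mean Vector of peak means (> 0).
#' @return `sqrt(a / mean + b)`.
#' @export
expected_cv <- function(fit, mean) {
  stopifnot(inherits(fit, "CVTrendFit"))
  sqrt(fit$a / mean + fit$b)
}

#' Flag highly variable peaks against the shot-noise trend
#'
#' A peak is flagged "highly variable" when its mean is at least `min_mean`
#' and its CV exceeds `fold` times the expected CV at that mean. `fold` and
#' `min_mean` are calibration parameters; calibrate the false-positive rate on
#' a pure-Poisson null (see the methods vignette).
#'
#' @param t A `MeanCVTable` from [mean_cv()].
#' @param fit A `CVTrendFit` fitted on the same table.
#' @param fold Flagging threshold as a multiple of the expected CV.
#' @param min_mean Minimum mean intensity for a peak to be eligible.
#' @return The table with `expected_cv`, `residual`
#'   (`log2(cv) - log2(expected_cv)`) and `flag` filled in, plus an attribute
#'   `n_flagged`.
#' @export
flag_variable_peaks <- function(t, fit, fold = 1.5, min_mean = 2) {
  stopifnot(inherits(t, "MeanCVTable"), inherits(fit, "CVTrendFit"))
  if (fold <= 0) stop("fold must be positive")
  ecv <- ifelse(t$mean > 0, expected_cv(fit, t$mean), NA_real_)
  t$expected_cv <- ecv
  t$residual <- ifelse(is.na(ecv) | ecv == 0, NA_real_, log2(t$cv / ecv))
  t$flag <- !is.na(ecv) & t$mean >= min_mean & t$cv > fold * ecv
  attr(t, "n_flagged") <- sum(t$flag)
  t
}

#' Restrict peaks to those near transcription start sites
#'
#' Keeps peaks whose minimal coordinate gap to any TSS on the same chromosome
#' is at most `window_bp` (gap 0 when the TSS falls inside the peak), and
#' reports the nearest TSS per retained peak, ties broken toward the smaller
#' coordinate.
#'
#' @param peaks A `PeakSet`.
#' @param tss A `PeakSet` of width-1 TSS intervals.
#' @param window_bp Maximum gap in bp (default 10000).
#' @return List with `peaks` (retained `PeakSet`) and `nearest` (data frame
#'   `peak_id`, `tss_name`, `gap_bp` for retained peaks).
#' @export
tss_proximal <- function(peaks, tss, window_bp = 10000L) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(tss, "PeakSet"))
  if (nrow(tss) == 0L) stop("empty TSS set")
  if (any(tss$end - tss$start != 1L))
    stop("TSS intervals must have width 1")
  check_shared_chroms(peaks, tss, "peaks", "TSS")
  gap <- rep(Inf, nrow(peaks))
  nearest <- rep(NA_character_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    ti <- which(tss$chrom == ch)
    if (length(ti) == 0L) next
    # tss is sorted; positions ascending (ties possible)
    tpos <- tss$start[ti]
    tname <- tss$name[ti]
    pi <- which(peaks$chrom == ch)
    s <- peaks$start[pi]
    e1 <- peaks$end[pi] - 1L          # last covered base
    # nearest position <= e1, and nearest position >= s
    lo <- findInterval(e1, tpos)      # index of largest tpos <= e1 (0 if none)
    hi <- findInterval(s - 1L, tpos) + 1L  # index of smallest tpos >= s
    for (j in seq_along(pi)) {
      best_gap <- Inf; best_pos <- Inf; best_name <- NA_character_
      cand <- c(if (lo[j] >= 1L) lo[j], if (hi[j] <= length(tpos)) hi[j])
      for (ci in cand) {
        p <- tpos[ci]
        g <- if (p >= s[j] && p <= e1[j]) 0L
             else if (p < s[j]) s[j] - p
             else p - e1[j]
        if (g < best_gap || (g == best_gap && p < best_pos)) {
          best_gap <- g; best_pos <- p; best_name <- tname[ci]
        }
      }
      gap[pi[j]] <- best_gap
      nearest[pi[j]] <- best_name
    }
  }
  keep <- gap <= window_bp
  list(peaks = peaks[keep],
       nearest = data.frame(peak_id = peaks$name[keep],
                            tss_name = nearest[keep],
                            gap_bp = gap[keep],
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Write a MeanCVTable to TSV
#'
#' @param t A `MeanCVTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mean_cv <- function(t, path) {
  stopifnot(inherits(t, "MeanCVTable"))
  utils::write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
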