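#' Count reads in consensus peaks by 5' position
#'
#' A read is assigned to every peak that contains its 5' end: the `start`
#' coordinate for `+`/unstranded reads and `end - 1` for `-` reads (tag-style
#' single-end counting; fragment length plays no role). Reads overlapping no
#' peak are ignored.
#'
#' @param reads A `PeakSet` of read intervals.
#' @param peaks A `PeakSet` of consensus peaks.
#' @return Named integer vector of counts, one per peak, in `peaks` order.
#' @export
count_reads_in_peaks <- function(reads, peaks) {
  stopifnot(inherits(reads, "PeakSet"), inherits(peaks, "PeakSet"))
  if (nrow(reads) > 0L && nrow(peaks) > 0L)
    check_shared_chroms(reads, peaks, "reads", "peaks")
  counts <- integer(nrow(peaks))
  names(counts) <- peaks$name
  if (nrow(reads) == 0L || nrow(peaks) == 0L) return(counts)
  pos <- read_five_prime(reads)
  pos_gr <- GenomicRanges::GRanges(reads$chrom,
                                   IRanges::IRanges(pos + 1L, width = 1L))
  hits <- GenomicRanges::countOverlaps(as_granges(peaks), pos_gr,
                                       ignore.strand = TRUE)
  counts[] <- as.integer(hits)
  counts
}

# 0-based 5' position of each read.
read_five_prime <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1L, reads$start)
}

#' Subtract local background from raw peak counts
#'
#' For each peak, reads falling in flanking windows of `flank_bp / 2` on each
#' side (clipped at coordinate 0 and excluding any base inside any peak) are
#' counted, scaled by `peak width / usable flank width`, and subtracted from
#' the peak count; negative results are clipped to 0 so downstream CV and log
#' transforms stay defined. Peaks whose flanks are entirely unusable get a
#' background contribution of 0 and a warning.
#'
#' @param raw A `CountMatrix` at stage `raw`.
#' @param peaks The `PeakSet` the counts were computed over (same peak ids).
#' @param reads A named list of read `PeakSet`s, one per sample column (a
#'   single `PeakSet` is accepted for a one-sample matrix).
#' @param flank_bp Total flank width in bp (half on each side).
#' @return A `CountMatrix` at stage `corrected`.
#' @export
background_correct <- function(raw, peaks, reads, flank_bp = 1000L) {
  stopifnot(inherits(raw, "CountMatrix"), inherits(peaks, "PeakSet"))
  if (raw$stage != "raw") stop("background_correct expects a raw-stage matrix")
  if (inherits(reads, "PeakSet")) reads <- stats::setNames(
    list(reads), raw$sample_ids[1L])
  if (!all(raw$sample_ids %in% names(reads)))
    stop("reads must be a named list covering every sample column")
  if (!identical(sort(raw$peak_ids), sort(peaks$name)))
    stop("peak ids of matrix and peak set disagree")
  if (flank_bp < 2L) stop("flank_bp must be at least 2")
  half <- as.integer(flank_bp %/% 2L)

  usable <- usable_flanks(peaks, half)
  uw <- usable$width_per_peak                # named by peak
  if (any(uw == 0L))
    warning("flanks entirely unusable for ", sum(uw == 0L),
            " peak(s); background contribution set to 0 (e.g. ",
            names(uw)[which(uw == 0L)[1L]], ")", call. = FALSE)

  vals <- raw$values
  widths <- stats::setNames(peaks$end - peaks$start, peaks$name)[raw$peak_ids]
  for (s in raw$sample_ids) {
    rs <- reads[[s]]
    fl_counts <- stats::setNames(numeric(nrow(peaks)), peaks$name)
    if (nrow(rs) > 0L && length(usable$gr) > 0L) {
      pos <- read_five_prime(rs)
      pos_gr <- GenomicRanges::GRanges(rs$chrom,
                                       IRanges::IRanges(pos + 1L, width = 1L))
      hit <- GenomicRanges::findOverlaps(usable$gr, pos_gr,
                                         ignore.strand = TRUE)
      per_frag <- tabulate(S4Vectors::queryHits(hit), length(usable$gr))
      agg <- tapply(per_frag, usable$peak_of, sum)
      fl_counts[names(agg)] <- as.numeric(agg)
    }
    bg <- ifelse(uw[raw$peak_ids] > 0L,
                 fl_counts[raw$peak_ids] * widths / uw[raw$peak_ids], 0)
    vals[, s] <- pmax(0, vals[, s] - bg)
  }
  out <- raw
  out$values <- vals
  advance_stage(out, "corrected")
}

# Flank fragments (0-based half-open) for each peak, with bases inside any
# peak removed. Returns the fragments as a GRanges plus per-peak usable width.
usable_flanks <- function(peaks, half) {
  n <- nrow(peaks)
  fs <- c(pmax(0L, peaks$start - half), peaks$end)
  fe <- c(peaks$start, peaks$end + half)
  peak_of <- rep(peaks$name, 2L)
  chrom <- rep(peaks$chrom, 2L)
  keep <- fs < fe
  fs <- fs[keep]; fe <- fe[keep]; peak_of <- peak_of[keep]
  chrom <- chrom[keep]

  red <- GenomicRanges::reduce(as_granges(peaks), ignore.strand = TRUE)
  frag <- GenomicRanges::GRanges(chrom, IRanges::IRanges(fs + 1L, fe))
  hit <- GenomicRanges::findOverlaps(frag, red, ignore.strand = TRUE)
  # subtract covered sub-intervals fragment by fragment (few hits each)
  out_chrom <- character(0); out_s <- integer(0); out_e <- integer(0)
  out_peak <- character(0)
  hit_q <- S4Vectors::queryHits(hit); hit_s <- S4Vectors::subjectHits(hit)
  for (i in seq_along(frag)) {
    cov <- hit_s[hit_q == i]
    s <- fs[i]; e <- fe[i]
    if (length(cov) == 0L) {
      out_chrom <- c(out_chrom, chrom[i]); out_s <- c(out_s, s)
      out_e <- c(out_e, e); out_peak <- c(out_peak, peak_of[i])
      next
    }
    cs <- sort(BiocGenerics::start(red[cov])) - 1L   # back to 0-based
    ce <- sort(BiocGenerics::end(red[cov]))
    cur <- s
    for (j in seq_along(cs)) {
      if (cs[j] > cur) {
        out_chrom <- c(out_chrom, chrom[i]); out_s <- c(out_s, cur)
        out_e <- c(out_e, min(cs[j], e)); out_peak <- c(out_peak, peak_of[i])
      }
      cur <- max(cur, ce[j])
      if (cur >= e) break
    }
    if (cur < e) {
      out_chrom <- c(out_chrom, chrom[i]); out_s <- c(out_s, cur)
      out_e <- c(out_e, e); out_peak <- c(out_peak, peak_of[i])
    }
  }
  keep <- out_s < out_e
  out_chrom <- out_chrom[keep]; out_s <- out_s[keep]; out_e <- out_e[keep]
  out_peak <- out_peak[keep]
  gr <- GenomicRanges::GRanges(out_chrom,
                               IRanges::IRanges(out_s + 1L, out_e))
  w <- stats::setNames(integer(n), peaks$name)
  if (length(gr)) {
    agg <- tapply(out_e - out_s, out_peak, sum)
    w[names(agg)] <- as.integer(agg)
  }
  list(gr = gr, peak_of = out_peak, width_per_peak = w)
}

#' Normalize columns to the cross-sample mean total
#'
#' Each sample column is scaled by `(mean of all column totals) / (its own
#' total)`, so every column total equals the cross-sample mean and the grand
#' total of the matrix is conserved.
#'
#' @param m A `CountMatrix` at stage `corrected` (a `raw` matrix is accepted
#'   with a warning).
#' @return A `CountMatrix` at stage `normalized`.
#' @export
normalize_between_samples <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  if (m$stage == "raw")
    warning("normalizing a raw (not background-corrected) matrix",
            call. = FALSE)
  else if (m$stage != "corrected")
    stop("normalize_between_samples expects a raw or corrected matrix")
  tot <- colSums(m$values)
  if (any(tot == 0))
    stop("column total is 0 for sample: ",
         m$sample_ids[which(tot == 0)[1L]])
  scale <- mean(tot) / tot
  out <- m
  out$values <- sweep(m$values, 2L, scale, `*`)
  advance_stage(out, "normalized")
}

#' Drop peaks with insufficient signal in every sample
#'
#' A peak is removed when its maximum normalized intensity across samples is
#' below `min_normalized`; a peak supported by any single cell line is kept,
#' so cell-line-specific peaks that are near zero elsewhere survive the
#' filter.
#'
#' @param m A `CountMatrix` at stage `normalized`.
#' @param min_normalized Threshold (default 2 normalized counts).
#' @return List with `matrix` (filtered `CountMatrix`) and `removed`
#'   (character vector of dropped peak ids).
#' @export
filter_min_signal <- function(m, min_normalized = 2) {
  stopifnot(inherits(m, "CountMatrix"))
  if (m$stage != "normalized")
    stop("filter_min_signal expects a normalized matrix")
  mx <- apply(m$values, 1L, max)
  drop <- mx < min_normalized
  out <- m
  out$values <- m$values[!drop, , drop = FALSE]
  out$peak_ids <- m$peak_ids[!drop]
  list(matrix = out, removed = m$peak_ids[drop])
}

#' Peak presence calls per sample
#'
#' A peak is called present in a sample when its normalized intensity is
#' strictly greater than `min_normalized`; the per-sample fraction of present
#' peaks summarizes how much of the consensus universe each line supports.
#'
#' @param m A `CountMatrix` at stage `normalized`.
#' @param min_normalized Strict threshold (default 4 normalized counts).
#' @return List with `presence` (logical peak x sample matrix) and `fraction`
#'   (named per-sample numeric).
#' @export
presence_matrix <- function(m, min_normalized = 4) {
  stopifnot(inherits(m, "CountMatrix"))
  if (m$stage != "normalized")
    stop("presence_matrix expects a normalized matrix")
  pres <- m$values > min_normalized
  list(presence = pres, fraction = colMeans(pres))
}

#' Scale each peak to its cross-sample mean
#'
#' Divides every row by its own mean so each peak's profile has mean 1 --
#' the display transformation used for heatmaps of relative binding.
#'
#' @param m A `CountMatrix` at stage `normalized`.
#' @return A `CountMatrix` at stage `relative`.
#' @export
relative_intensity <- function(m) {
  stopifnot(inherits(m, "CountMatrix"))
  if (m$stage != "normalized")
    stop("relative_intensity expects a normalized matrix")
  rm_ <- rowMeans(m$values)
  if (any(rm_ == 0))
    stop("zero-mean row for peak: ", m$peak_ids[which(rm_ == 0)[1L]])
  out <- m
  out$values <- m$values / rm_
  advance_stage(out, "relative")
}

#' Quantify reads over peaks for many samples
#'
#' Convenience wrapper: counts reads per peak for each sample and optionally
#' applies [background_correct()].
#'
#' @param peaks Consensus `PeakSet`.
#' @param reads Named list of read `PeakSet`s (names become sample ids).
#' @param flank_bp Total background flank width (bp).
#' @param background Apply background correction?
#' @return A `CountMatrix` at stage `corrected` (or `raw` when
#'   `background = FALSE`).
#' @export
quantify <- function(peaks, reads, flank_bp = 1000L, background = TRUE) {
  stopifnot(inherits(peaks, "PeakSet"), is.list(reads),
            !is.null(names(reads)))
  counts <- vapply(reads, count_reads_in_peaks, numeric(nrow(peaks)),
                   peaks = peaks)
  counts <- matrix(counts, ncol = length(reads),
                   dimnames = list(peaks$name, names(reads)))
  m <- count_matrix(counts, stage = "raw")
  if (background) m <- background_correct(m, peaks, reads, flank_bp = flank_bp)
  m
}
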