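#' Apply a probability floor to a PWM
#'
#' Raises every cell to at least `floor` and renormalizes each row to sum 1,
#' so log-odds scores stay finite at positions where a nucleotide was never
#' observed.
#'
#' @param p A `PWMatrix`.
#' @param floor Minimum per-cell probability, `0 <= floor < 0.25`.
#' @return The floored, renormalized `PWMatrix` (with `floor` recorded).
#' @export
apply_probability_floor <- function(p, floor = 0.01) {
  stopifnot(inherits(p, "PWMatrix"))
  if (floor < 0 || floor >= 0.25)
    stop("floor must be in [0, 0.25): a floor of 0.25 or more would exceed ",
         "the uniform distribution")
  probs <- pmax(p$probs, floor)
  probs <- probs / rowSums(probs)
  pwmatrix(probs, floor = floor, background = p$background)
}

# Per-position log2-odds matrix (positions x ACGT).
log_odds_matrix <- function(p) {
  log2(sweep(p$probs, 2L, p$background, `/`))
}

encode_dna <- function(seq) {
  match(strsplit(seq, "", fixed = TRUE)[[1L]], c("A", "C", "G", "T"))
}

# Scores of all windows of length L (rows of `lom`) along integer-coded
# sequence; windows containing N (NA code) score NA.
window_scores <- function(lom, codes) {
  L <- nrow(lom)
  n <- length(codes)
  n_off <- n - L + 1L
  pos_idx <- outer(seq_len(L) - 1L, seq_len(n_off), `+`)  # L x n_off
  cd <- codes[pos_idx]
  sc <- lom[cbind(rep.int(seq_len(L), n_off), cd)]
  colSums(matrix(sc, nrow = L))
}

#' Best-site log-odds score of a sequence
#'
#' The motif score of a peak: the maximum, over all offsets on both strands,
#' of the summed per-position log2 odds `log2(p[i, base] / background[base])`
#' (bits). Windows containing N are skipped; when every window is skipped the
#' score is `-Inf` with `skipped = TRUE`. Ties prefer the forward strand,
#' then the smaller offset.
#'
#' @param p A floor-applied `PWMatrix`.
#' @param seq DNA string over `{A, C, G, T, N}` at least as long as the motif.
#' @return List with `score` (bits), `position` (1-based offset of the best
#'   window on the forward sequence), `strand` (`"+"` or `"-"`), `skipped`.
#' @export
score_best_site <- function(p, seq) {
  stopifnot(inherits(p, "PWMatrix"))
  seq <- toupper(seq)
  L <- nrow(p$probs)
  n <- nchar(seq)
  if (n < L)
    stop("sequence shorter than motif (", n, " < ", L, ")")
  lom <- log_odds_matrix(p)
  fwd <- window_scores(lom, encode_dna(seq))
  rev_ <- window_scores(lom, encode_dna(revcomp_dna(seq)))
  # map reverse-strand offsets back onto the forward sequence
  n_off <- n - L + 1L
  cand <- data.frame(
    score = c(fwd, rev_[n_off:1L]),
    position = c(seq_len(n_off), seq_len(n_off)),
    strand = rep(c("+", "-"), each = n_off),
    stringsAsFactors = FALSE)
  cand$score[is.na(cand$score)] <- -Inf
  if (all(cand$score == -Inf))
    return(list(score = -Inf, position = NA_integer_, strand = NA_character_,
                skipped = TRUE))
  # order: forward strand first, ascending position (already so); which.max
  # takes the first maximum, implementing the tie-break
  best <- which.max(cand$score)
  list(score = cand$score[best], position = cand$position[best],
       strand = cand$strand[best], skipped = FALSE)
}

#' Score many sequences against a PWM
#'
#' @param p A floor-applied `PWMatrix`.
#' @param seqs Named character vector of DNA sequences.
#' @return A `MotifScoreTable`: data frame with `name`, `score`, `position`,
#'   `strand`, `skipped`.
#' @export
score_sequences <- function(p, seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  rows <- lapply(seqs, function(s) score_best_site(p, s))
  out <- data.frame(
    name = names(seqs),
    score = vapply(rows, `[[`, numeric(1L), "score"),
    position = vapply(rows, `[[`, integer(1L), "position"),
    strand = vapply(rows, `[[`, character(1L), "strand"),
    skipped = vapply(rows, `[[`, logical(1L), "skipped"),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("MotifScoreTable", "data.frame")
  out
}

#' Flanking background regions for motif scoring
#'
#' For each peak, candidate regions of `width_bp` immediately left
#' (`[start - width, start)`) and right (`[end, end + width)`) of the peak; a
#' candidate is kept only when it overlaps no peak in the set and does not
#' run past coordinate 0. Names carry `_bgL` / `_bgR` suffixes.
#'
#' @param peaks A `PeakSet`.
#' @param width_bp Background region width (default 500 bp).
#' @return A `PeakSet` of background regions.
#' @export
make_background_regions <- function(peaks, width_bp = 500L) {
  stopifnot(inherits(peaks, "PeakSet"))
  width_bp <- as.integer(width_bp)
  if (width_bp <= 0L) stop("width_bp must be positive")
  cand <- data.frame(
    chrom = rep(peaks$chrom, 2L),
    start = c(peaks$start - width_bp, peaks$end),
    end = c(peaks$start, peaks$end + width_bp),
    name = c(paste0(peaks$name, "_bgL"), paste0(peaks$name, "_bgR")),
    stringsAsFactors = FALSE)
  cand <- cand[cand$start >= 0L, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(peak_set(character(0), integer(0), integer(0), character(0)))
  cg <- GenomicRanges::GRanges(cand$chrom,
                               IRanges::IRanges(cand$start + 1L, cand$end))
  ov <- GenomicRanges::countOverlaps(cg, as_granges(peaks),
                                     ignore.strand = TRUE)
  cand <- cand[ov == 0L, , drop = FALSE]
  peak_set(cand$chrom, cand$start, cand$end, name = cand$name)
}

#' Motif-binding correlation over averaged sample subsets
#'
#' For every subset of `k` samples (all subsets when `choose(n, k)` is at
#' most `max_combos`, otherwise `max_combos` distinct subsets sampled with
#' `seed`), computes the Pearson correlation between the motif score and the
#' subset-mean binding intensity. Averaging over more lines suppresses
#' per-line noise, so the distribution of r typically shifts upward with `k`.
#'
#' @param scores Numeric vector of motif scores, aligned with the rows of
#'   `m` (or a `MotifScoreTable` whose `name` column matches the peak ids).
#' @param m A `CountMatrix`.
#' @param k Subset size, between 1 and the number of samples.
#' @param max_combos Cap on the number of subsets evaluated.
#' @param seed Seed used only when subsets must be sampled.
#' @return Numeric vector of Pearson r values, one per subset evaluated
#'   (`NA` with a warning for zero-variance subsets); the subsets are
#'   attached as attribute `subsets`.
#' @export
subset_average_correlation <- function(scores, m, k, max_combos = 1000L,
                                       seed = 1L) {
  stopifnot(inherits(m, "CountMatrix"))
  if (inherits(scores, "MotifScoreTable")) {
    idx <- match(m$peak_ids, scores$name)
    if (anyNA(idx)) stop("motif scores missing for some peaks")
    scores <- scores$score[idx]
  }
  if (length(scores) != nrow(m$values))
    stop("scores must align with the matrix rows")
  n <- ncol(m$values)
  if (k < 1L || k > n) stop("k must be between 1 and the number of samples")
  n_comb <- choose(n, k)
  if (n_comb <= max_combos) {
    subs <- utils::combn(n, k, simplify = FALSE)
  } else {
    subs <- with_seed(seed, {
      seen <- new.env(parent = emptyenv())
      out <- vector("list", max_combos)
      got <- 0L
      while (got < max_combos) {
        s <- sort(sample.int(n, k))
        key <- paste(s, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          got <- got + 1L
          out[[got]] <- s
        }
      }
      out
    })
  }
  means <- vapply(subs, function(s)
    rowMeans(m$values[, s, drop = FALSE]), numeric(nrow(m$values)))
  ok_scores <- stats::sd(scores) > 0
  sds <- apply(means, 2L, stats::sd)
  r <- rep(NA_real_, length(subs))
  usable <- ok_scores & sds > 0
  if (any(usable))
    r[usable] <- as.vector(stats::cor(scores, means[, usable, drop = FALSE]))
  if (any(!usable))
    warning(sum(!usable), " subset(s) had a zero-variance vector; r = NA",
            call. = FALSE)
  attr(r, "subsets") <- subs
  r
}

#' Write a MotifScoreTable to TSV
#'
#' @param t A `MotifScoreTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_scores <- function(t, path) {
  stopifnot(inherits(t, "MotifScoreTable"))
  utils::write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
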