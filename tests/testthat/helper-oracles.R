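# Brute-force reference implementations and random-instance builders used
# across the suite. Oracles are deliberately naive (O(n*m) loops) and
# independent of the package's code paths.

# --- random instances ------------------------------------------------------

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  width <- sample(50:800, n, replace = TRUE)
  peak_set(chrom, start, start + width,
           name = sprintf("pk_%04d", seq_len(n)))
}

random_reads <- function(n, chroms = c("chr1", "chr2"), max_pos = 101000L,
                         len = 75L) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  peak_set(chrom, start, start + len,
           name = sprintf("rd_%05d", seq_len(n)), strand = strand)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_pwm <- function(L, floor = 0.01) {
  probs <- matrix(stats::rgamma(L * 4L, shape = 1), L, 4L)
  probs <- probs / rowSums(probs)
  apply_probability_floor(pwmatrix(probs), floor)
}

# --- oracles ---------------------------------------------------------------

# exhaustive 5'-containment read counting
oracle_count_reads <- function(reads, peaks) {
  pos <- ifelse(reads$strand == "-", reads$end - 1L, reads$start)
  counts <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(reads))) {
      if (reads$chrom[j] == peaks$chrom[i] &&
          pos[j] >= peaks$start[i] && pos[j] < peaks$end[i])
        counts[i] <- counts[i] + 1L
    }
  }
  names(counts) <- peaks$name
  counts
}

# all-pairs peak-to-TSS gap; same coordinate arithmetic as the spec examples
oracle_tss_proximal <- function(peaks, tss, window_bp) {
  keep <- logical(nrow(peaks))
  gap <- rep(Inf, nrow(peaks))
  nearest_pos <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(tss))) {
      if (tss$chrom[j] != peaks$chrom[i]) next
      t <- tss$start[j]
      g <- if (t >= peaks$start[i] && t <= peaks$end[i] - 1L) 0L
           else if (t < peaks$start[i]) peaks$start[i] - t
           else t - (peaks$end[i] - 1L)
      if (g < gap[i] || (g == gap[i] && t < nearest_pos[i])) {
        gap[i] <- g
        nearest_pos[i] <- t
      }
    }
    keep[i] <- gap[i] <= window_bp
  }
  list(keep = keep, gap = gap, nearest_pos = nearest_pos)
}

# half-open overlap between two interval rows
oracle_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# exhaustive best-site PWM scan over all offsets and both strands
oracle_best_site <- function(pwm, seq) {
  lom <- log2(sweep(pwm$probs, 2L, pwm$background, `/`))
  L <- nrow(lom)
  score1 <- function(s) {
    codes <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
    best <- -Inf
    for (o in seq_len(nchar(s) - L + 1L)) {
      w <- codes[o:(o + L - 1L)]
      if (anyNA(w)) next
      sc <- sum(lom[cbind(seq_len(L), w)])
      if (sc > best) best <- sc
    }
    best
  }
  rc <- paste(rev(chartr("ACGTN", "TGCAN",
                         strsplit(seq, "")[[1L]])), collapse = "")
  max(score1(toupper(seq)), score1(toupper(rc)))
}

# exhaustive UPGMA; returns merge heights and the partition after each merge
oracle_upgma <- function(d) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(0)
  partitions <- list()
  cluster_of <- seq_len(n)
  dist_fun <- function(a, b) mean(d[cbind(rep(members[[a]],
                                              each = length(members[[b]])),
                                          rep(members[[b]],
                                              length(members[[a]])))])
  while (length(active) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      dd <- dist_fun(active[ii], active[jj])
      if (dd < best_d) { best_d <- dd; best <- c(active[ii], active[jj]) }
    }
    members[[best[1L]]] <- c(members[[best[1L]]], members[[best[2L]]])
    active <- setdiff(active, best[2L])
    heights <- c(heights, best_d)
    cluster_of[members[[best[1L]]]] <- best[1L]
    partitions[[length(partitions) + 1L]] <- match(cluster_of,
                                                   unique(cluster_of))
  }
  list(heights = heights, partitions = partitions)
}

# exact upper-tail hypergeometric by combinatorial enumeration
oracle_hyper_upper <- function(k, K, N, n) {
  js <- max(k, 0L, n - (N - K)):min(n, K)
  if (length(js) == 0L || min(n, K) < k) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# adjusted Rand index against known labels (mclust is suggested, not
# required at runtime, so fall back to a direct computation)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(sum(tab), 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# normalized-stage CountMatrix straight from a numeric matrix
as_norm_matrix <- function(vals, prefix = "pk") {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("%s_%04d", prefix, seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  count_matrix(vals, stage = "normalized")
}
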