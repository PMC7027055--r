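#' Read a FASTA file into a named sequence vector
#'
#' Sequences are uppercased and wrap lines joined. Only the alphabet
#' `{A, C, G, T, N}` is accepted; record names (first whitespace-delimited
#' token of the header) must be unique and sequences non-empty.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of DNA sequences (a `SequenceSet`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  xs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(xs))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate FASTA record name: ", paste(utils::head(dup, 3L),
                                                collapse = ", "))
  seqs <- toupper(as.character(xs))
  names(seqs) <- nm
  empty <- nm[nchar(seqs) == 0L]
  if (length(empty))
    stop("empty sequence for FASTA record: ", empty[1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN character in FASTA record: ", nm[which(bad)[1L]])
  seqs
}

#' Write a named sequence vector to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a position probability matrix
#'
#' Expects a TSV with header `A C G T` and one probability row per motif
#' position. Rows whose sum is within `1e-6` of 1 are renormalized; larger
#' deviations or negative entries are errors. No probability floor is applied
#' yet (see [apply_probability_floor()]).
#'
#' @param path Path to the PWM TSV.
#' @return A [pwmatrix()] with `floor = 0`.
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  need <- c("A", "C", "G", "T")
  if (!all(need %in% colnames(df)))
    stop("PWM file must have header columns A, C, G, T")
  m <- as.matrix(df[, need, drop = FALSE])
  if (nrow(m) == 0L) stop("PWM file has no positions")
  if (any(!is.finite(m))) stop("non-numeric PWM entry")
  if (any(m < 0)) {
    i <- which(apply(m < 0, 1L, any))[1L]
    stop("negative probability at PWM row ", i)
  }
  rs <- rowSums(m)
  off <- abs(rs - 1) > 1e-6
  if (any(off)) {
    i <- which(off)[1L]
    stop("PWM row ", i, " probabilities sum to ", format(rs[i]),
         " (must be 1 within 1e-6)")
  }
  pwmatrix(m / rs)
}

#' Construct a position weight matrix object
#'
#' @param probs Numeric matrix, motif positions in rows and the four
#'   nucleotides A, C, G, T in columns; each row sums to 1.
#' @param floor Minimum per-cell probability already applied (0 if none).
#' @param background Background nucleotide frequencies (default uniform).
#' @return A `PWMatrix` object.
#' @export
pwmatrix <- function(probs, floor = 0, background = rep(0.25, 4L)) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4L) stop("PWM must have 4 columns (A, C, G, T)")
  colnames(probs) <- c("A", "C", "G", "T")
  rownames(probs) <- NULL
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive frequencies")
  structure(list(probs = probs, floor = floor,
                 background = as.numeric(background)),
            class = "PWMatrix")
}

#' @export
print.PWMatrix <- function(x, ...) {
  cat("PWMatrix: ", nrow(x$probs), " positions, floor = ", x$floor, "\n",
      sep = "")
  print(round(x$probs, 4L))
  invisible(x)
}

#' Write a PWMatrix to TSV
#'
#' @param p A `PWMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(p, path) {
  stopifnot(inherits(p, "PWMatrix"))
  utils::write.table(format(p$probs, digits = 15L, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Reverse-complement an ACGTN string.
revcomp_dna <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

# Evaluate an expression under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
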