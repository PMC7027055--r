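#' Construct a PeakSet of genomic intervals
#'
#' A `PeakSet` is an ordered collection of genomic intervals in 0-based
#' half-open (BED) coordinates, sorted by `(chrom, start, end)`, with unique
#' names. It carries peaks, read positions, flanking background regions and
#' transcription start sites throughout the package.
#'
#' @param chrom Character vector of chromosome names (compared as exact text;
#'   no "chr" normalization is attempted).
#' @param start Integer vector of 0-based inclusive start positions (bp).
#' @param end Integer vector of exclusive end positions (bp); `start < end`.
#' @param name Optional character vector of unique interval names; defaults to
#'   `peak_<i>` in input order.
#' @param strand Optional character vector over `{"+", "-", "*"}`; `NA` and
#'   `"."` are treated as unspecified (`"*"`).
#'
#' @return A `PeakSet`: a data frame with columns `chrom`, `start`, `end`,
#'   `name`, `strand`, sorted by position.
#' @examples
#' peak_set("chr1", c(100, 900), c(600, 950), name = c("pkA", "pkB"))
#' @export
peak_set <- function(chrom, start, end, name = NULL, strand = NULL) {
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (is.null(name)) name <- paste0("peak_", seq_len(n))
  if (is.null(strand)) strand <- rep("*", n)
  name <- as.character(name)
  strand <- as.character(strand)
  strand[is.na(strand) | strand == "."] <- "*"
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand values must be '+', '-', '.' or '*'")
  start <- suppressWarnings(as.integer(start))
  end <- suppressWarnings(as.integer(end))
  if (anyNA(start) || anyNA(end)) stop("non-integer interval coordinates")
  if (any(start < 0L)) stop("negative start coordinate")
  bad <- which(start >= end)
  if (length(bad))
    stop("empty or inverted interval (start >= end): ",
         paste(utils::head(name[bad], 3L), collapse = ", "))
  dup <- name[duplicated(name)]
  if (length(dup))
    stop("duplicate interval names: ",
         paste(utils::head(unique(dup), 3L), collapse = ", "))
  new_peak_set(chrom, start, end, name, strand)
}

new_peak_set <- function(chrom, start, end, name, strand) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), name = as.character(name),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' @export
print.PeakSet <- function(x, ...) {
  cat("PeakSet with", nrow(x), "intervals on",
      length(unique(x$chrom)), "chromosome(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more\n")
  invisible(x)
}

#' Subset a PeakSet by row
#'
#' @param x A `PeakSet`.
#' @param i Row index (logical, integer or name-based is not supported).
#' @param ... Ignored.
#' @return A `PeakSet` with the selected intervals (sort order is preserved).
#' @export
`[.PeakSet` <- function(x, i, ...) {
  df <- as.data.frame(x)[i, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' Convert a PeakSet to a GRanges object
#'
#' Coordinates are shifted to the 1-based inclusive convention GRanges uses.
#'
#' @param ps A `PeakSet`.
#' @return A [GenomicRanges::GRanges] with interval names.
#' @export
as_granges <- function(ps) {
  stopifnot(inherits(ps, "PeakSet"))
  gr <- GenomicRanges::GRanges(
    seqnames = ps$chrom,
    ranges = IRanges::IRanges(start = ps$start + 1L, end = ps$end),
    strand = ps$strand)
  names(gr) <- ps$name
  gr
}

# Half-open overlap rule used everywhere: a and b overlap iff
# a$start < b$end and b$start < a$end (and chrom matches).
intervals_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

# Warn once when two inputs share no chromosome names (likely naming mismatch,
# e.g. "chr1" vs "1").
check_shared_chroms <- function(a, b, label_a = "first", label_b = "second") {
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(shared) == 0L)
    warning("no chromosome names shared between ", label_a, " and ", label_b,
            " inputs; check naming conventions (e.g. 'chr1' vs '1')",
            call. = FALSE)
  invisible(length(shared) > 0L)
}

#' Read a BED file into a PeakSet
#'
#' Accepts BED3/BED4/BED6 (tab-separated, 0-based half-open). Lines starting
#' with `#`, `track` or `browser` are skipped. When column 4 is absent, names
#' `peak_<i>` are generated in file order.
#'
#' @param path Path to a BED file.
#' @return A [peak_set()].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no interval lines in BED file: ", path)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[`, character(1L), 1L)
  s_chr <- vapply(fields, `[`, character(1L), 2L)
  e_chr <- vapply(fields, `[`, character(1L), 3L)
  bad <- !grepl("^[0-9]+$", s_chr) | !grepl("^[0-9]+$", e_chr)
  if (any(bad))
    stop("BED parse error at line ", idx[which(bad)[1L]],
         ": non-integer coordinates")
  start <- as.integer(s_chr)
  end <- as.integer(e_chr)
  bad <- start >= end
  if (any(bad))
    stop("BED parse error at line ", idx[which(bad)[1L]],
         ": empty interval (start >= end)")
  name <- if (all(nf >= 4L)) vapply(fields, `[`, character(1L), 4L)
          else paste0("peak_", seq_along(idx))
  strand <- if (all(nf >= 6L)) vapply(fields, `[`, character(1L), 6L) else NULL
  peak_set(chrom, start, end, name = name, strand = strand)
}

#' Write a PeakSet to a BED6 file
#'
#' Coordinates are written exactly as stored (0-based half-open), so
#' `read_bed(write_bed(x))` round-trips bit-exactly.
#'
#' @param ps A `PeakSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ps, path) {
  stopifnot(inherits(ps, "PeakSet"))
  strand <- ifelse(ps$strand == "*", ".", ps$strand)
  writeLines(paste(ps$chrom, ps$start, ps$end, ps$name, 0L, strand,
                   sep = "\t"), path)
  invisible(path)
}
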