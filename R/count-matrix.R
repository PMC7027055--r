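.stages <- c("raw", "corrected", "normalized", "relative")

#' Construct a peak-by-sample CountMatrix
#'
#' Container for the signal matrix that flows through the pipeline. Values are
#' finite and non-negative; a `stage` tag records how far along the processing
#' chain (`raw -> corrected -> normalized -> relative`) the matrix is, and
#' stage transitions are only allowed forward.
#'
#' @param values Numeric matrix, peaks in rows and samples in columns, with
#'   complete `dimnames`.
#' @param stage One of `"raw"`, `"corrected"`, `"normalized"`, `"relative"`.
#' @return A `CountMatrix` (list with `peak_ids`, `sample_ids`, `values`,
#'   `stage`).
#' @export
count_matrix <- function(values, stage = "raw") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  stage <- match.arg(stage, .stages)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have row (peak) and column (sample) names")
  if (anyDuplicated(rownames(values))) stop("duplicate peak ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("values must be finite")
  if (any(values < 0))
    stop("values must be non-negative")
  structure(list(peak_ids = rownames(values), sample_ids = colnames(values),
                 values = values, stage = stage),
            class = "CountMatrix")
}

#' @export
as.matrix.CountMatrix <- function(x, ...) x$values

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix [stage: ", x$stage, "]: ", nrow(x$values), " peaks x ",
      ncol(x$values), " samples\n", sep = "")
  print(utils::head(x$values, 5L))
  if (nrow(x$values) > 5L) cat("...", nrow(x$values) - 5L, "more rows\n")
  invisible(x)
}

# Forward-only stage transitions; `allow_same` permits in-place operations
# (filtering) that do not advance the stage.
advance_stage <- function(m, to) {
  from_i <- match(m$stage, .stages)
  to_i <- match(to, .stages)
  if (is.na(to_i)) stop("unknown stage: ", to)
  if (to_i <= from_i)
    stop("illegal stage transition ", m$stage, " -> ", to)
  m$stage <- to
  m
}

#' Read a TSV count matrix
#'
#' Expects a header row `peak_id<TAB>sample1<TAB>...` and a numeric body. An
#' optional leading comment line `#stage=<stage>` declares the processing
#' stage (default `raw`).
#'
#' @param path Path to the TSV file.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  stage <- "raw"
  if (length(lines) && grepl("^#stage=", lines[1L])) {
    stage <- sub("^#stage=", "", lines[1L])
    lines <- lines[-1L]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty count matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "peak_id")
    stop("count matrix header must start with 'peak_id', got '", header[1L], "'")
  samples <- header[-1L]
  body <- fields[-1L]
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("ragged row at line ", which(nf != length(header))[1L] + 1L,
         ": expected ", length(header), " fields")
  peak_ids <- vapply(body, `[`, character(1L), 1L)
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(length(samples))))
  vals <- matrix(vals, ncol = length(samples), byrow = TRUE,
                 dimnames = list(peak_ids, samples))
  if (anyNA(vals)) {
    ij <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at peak '", peak_ids[ij[1L]], "', sample '",
         samples[ij[2L]], "'")
  }
  if (any(vals < 0)) {
    ij <- which(vals < 0, arr.ind = TRUE)[1L, ]
    stop("negative cell at peak '", peak_ids[ij[1L]], "', sample '",
         samples[ij[2L]], "'")
  }
  count_matrix(vals, stage = stage)
}

#' Write a CountMatrix to TSV
#'
#' The processing stage is stored in a `#stage=` comment line. Values are
#' written with `%.17g` so a write/read round-trip reproduces doubles
#' bit-exactly.
#'
#' @param m A `CountMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "CountMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#stage=", m$stage), con)
  writeLines(paste(c("peak_id", m$sample_ids), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(m$peak_ids, body, sep = "\t"), con)
  invisible(path)
}
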