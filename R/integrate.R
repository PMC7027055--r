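#' Ordinary least squares model of log2 binding signal
#'
#' Regresses per-peak `log2` binding signal on motif score and, when given,
#' chromatin accessibility, reporting coefficients and the fraction of
#' variance explained. With accessibility absent this is the motif-only model.
#' The caller is responsible for the `log2(signal + pseudocount)` transform.
#'
#' @param log2_signal Numeric vector of log2 binding intensities.
#' @param motif_score Numeric vector, aligned with `log2_signal`.
#' @param accessibility Optional aligned numeric vector (e.g. log2 ATAC
#'   signal).
#' @return A `LinearFit`: list with `coefficients`, `r_squared`,
#'   `adj_r_squared`, `n`.
#' @export
fit_binding_model <- function(log2_signal, motif_score, accessibility = NULL) {
  n <- length(log2_signal)
  if (length(motif_score) != n ||
      (!is.null(accessibility) && length(accessibility) != n))
    stop("predictor vectors must align with log2_signal")
  if (n < 10L) stop("need at least 10 observations")
  X <- cbind(`(Intercept)` = 1, motif = motif_score)
  if (!is.null(accessibility))
    X <- cbind(X, accessibility = accessibility)
  if (any(!is.finite(X)) || any(!is.finite(log2_signal)))
    stop("non-finite values in model inputs")
  if (kappa(X, exact = TRUE) > 1e10)
    stop("collinear predictors (condition number above 1e10)")
  fit <- stats::lm.fit(X, log2_signal)
  p <- ncol(X) - 1L
  rss <- sum(fit$residuals^2)
  tss <- sum((log2_signal - mean(log2_signal))^2)
  if (tss == 0) stop("response has zero variance")
  r2 <- 1 - rss / tss
  structure(list(coefficients = fit$coefficients,
                 r_squared = r2,
                 adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1L),
                 n = n),
            class = "LinearFit")
}

#' @export
print.LinearFit <- function(x, ...) {
  cat(sprintf("LinearFit (n = %d): R^2 = %.4f (adj. %.4f)\n",
              x$n, x$r_squared, x$adj_r_squared))
  print(round(x$coefficients, 4L))
  invisible(x)
}

# Pearson r with a two-tailed t-distribution p-value.
pearson_with_p <- function(x, y) {
  n <- length(x)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r, p = max(p, .Machine$double.xmin), n = n)
}

#' Correlate binding changes with accessibility changes between two samples
#'
#' Computes `delta_bind = log2(bind_b + pc) - log2(bind_a + pc)` and the
#' analogous accessibility delta, then the Pearson correlation (with two-
#' tailed t-test p-value) and the `R^2` of regressing the binding delta on
#' the accessibility delta.
#'
#' @param bind_a,bind_b Per-peak binding intensities in the two samples.
#' @param acc_a,acc_b Per-peak accessibility in the two samples.
#' @param pseudocount Added before `log2` (default 1).
#' @return List with `r`, `p`, `n`, `r_squared`.
#' @export
delta_delta_correlation <- function(bind_a, bind_b, acc_a, acc_b,
                                    pseudocount = 1) {
  n <- length(bind_a)
  if (any(c(length(bind_b), length(acc_a), length(acc_b)) != n))
    stop("all four vectors must have equal length")
  db <- log2(bind_b + pseudocount) - log2(bind_a + pseudocount)
  da <- log2(acc_b + pseudocount) - log2(acc_a + pseudocount)
  if (stats::sd(db) == 0) stop("zero variance in binding delta")
  if (stats::sd(da) == 0) stop("zero variance in accessibility delta")
  ct <- pearson_with_p(da, db)
  list(r = ct$r, p = ct$p, n = n, r_squared = ct$r^2)
}

#' Per-peak correlation of binding with expression of the mapped gene
#'
#' For every peak, the Pearson correlation across shared samples between the
#' peak's binding profile and the expression profile of its mapped gene, with
#' two-tailed t-test p-values.
#'
#' @param binding A `CountMatrix`.
#' @param expression Numeric gene x sample matrix with dimnames.
#' @param peak2gene Named character vector mapping peak id to gene id; must
#'   cover every peak in `binding`.
#' @return Data frame with `peak_id`, `gene`, `r`, `p`, `n`.
#' @export
binding_expression_association <- function(binding, expression, peak2gene) {
  stopifnot(inherits(binding, "CountMatrix"), is.matrix(expression))
  shared <- intersect(binding$sample_ids, colnames(expression))
  if (length(shared) < 3L)
    stop("fewer than 3 shared samples between binding and expression")
  if (!all(binding$peak_ids %in% names(peak2gene)))
    stop("peak2gene mapping missing for some peaks")
  genes <- peak2gene[binding$peak_ids]
  if (!all(genes %in% rownames(expression)))
    stop("mapped gene absent from expression matrix: ",
         genes[which(!genes %in% rownames(expression))[1L]])
  B <- binding$values[, shared, drop = FALSE]
  E <- expression[genes, shared, drop = FALSE]
  n <- length(shared)
  r <- vapply(seq_len(nrow(B)), function(i) {
    if (stats::sd(B[i, ]) == 0 || stats::sd(E[i, ]) == 0) NA_real_
    else stats::cor(B[i, ], E[i, ])
  }, numeric(1L))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(peak_id = binding$peak_ids, gene = unname(genes), r = r,
             p = p, n = n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare two distributions of correlation coefficients
#'
#' Two-sided two-sample t-test between the per-peak correlation coefficients
#' of two peak groups (e.g. variable peaks vs canonical targets). Welch's
#' unequal-variance test by default; an optional Fisher z-transform of r is
#' available.
#'
#' @param r_a,r_b Numeric vectors of correlation coefficients (`NA` dropped).
#' @param fisher_z Apply `atanh` before testing?
#' @param var_equal Assume equal variances (classic t-test)?
#' @return List with `t`, `df`, `p`.
#' @export
compare_correlation_groups <- function(r_a, r_b, fisher_z = FALSE,
                                       var_equal = FALSE) {
  r_a <- r_a[!is.na(r_a)]
  r_b <- r_b[!is.na(r_b)]
  if (fisher_z) {
    r_a <- atanh(pmin(pmax(r_a, -1 + 1e-12), 1 - 1e-12))
    r_b <- atanh(pmin(pmax(r_b, -1 + 1e-12), 1 - 1e-12))
  }
  tt <- stats::t.test(r_a, r_b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Hypergeometric over-representation test of a gene set
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing `k` query
#' hits in a term of size `K` when drawing `n` genes from a universe of size
#' `N`, for each term, with multiple-testing correction across terms.
#'
#' @param query Character vector of query gene names (subset of `universe`).
#' @param terms Named list of character vectors (term gene sets; intersected
#'   with the universe before testing).
#' @param universe Character vector, the finite gene universe.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @return An `EnrichmentResult` data frame sorted by p: columns `term`, `k`,
#'   `K`, `n`, `N`, `p`, `p_adj`.
#' @export
hypergeometric_enrichment <- function(query, terms, universe,
                                      correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  if (is.null(names(terms))) stop("terms must be a named list")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(tm) {
    tset <- intersect(unique(terms[[tm]]), universe)
    K <- length(tset)
    k <- length(intersect(query, tset))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = correction)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Five-number summaries of y within bins of x
#'
#' Bins `x` by quantiles (default) or fixed-width intervals and summarizes
#' `y` per bin with count, median, quartiles and Tukey whiskers (most extreme
#' points within 1.5 IQR of the quartiles). Tied quantile breaks collapse
#' bins with a warning.
#'
#' @param x,y Aligned numeric vectors.
#' @param n_bins Number of bins requested.
#' @param scheme `"quantile"` or `"fixed"`.
#' @return Data frame with one row per bin: `bin`, `x_lo`, `x_hi`, `n`,
#'   `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`.
#' @export
bin_summary <- function(x, y, n_bins = 5L, scheme = c("quantile", "fixed")) {
  scheme <- match.arg(scheme)
  n <- length(x)
  if (length(y) != n) stop("x and y must align")
  if (n < n_bins) stop("need at least n_bins observations")
  breaks <- if (scheme == "quantile")
    stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L))
  else
    seq(min(x), max(x), length.out = n_bins + 1L)
  ub <- unique(breaks)
  if (length(ub) < length(breaks))
    warning("tied bin breaks; ", length(breaks) - length(ub),
            " bin(s) merged", call. = FALSE)
  if (length(ub) < 2L) stop("all x values identical; cannot bin")
  g <- cut(x, breaks = ub, include.lowest = TRUE)
  lev <- levels(g)
  out <- lapply(seq_along(lev), function(i) {
    yi <- y[g == lev[i]]
    q <- stats::quantile(yi, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    in_lo <- yi[yi >= q[1L] - 1.5 * iqr]
    in_hi <- yi[yi <= q[3L] + 1.5 * iqr]
    data.frame(bin = i, x_lo = ub[i], x_hi = ub[i + 1L],
               n = length(yi), median = q[2L], q1 = q[1L], q3 = q[3L],
               whisker_lo = if (length(in_lo)) min(in_lo) else NA_real_,
               whisker_hi = if (length(in_hi)) max(in_hi) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
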