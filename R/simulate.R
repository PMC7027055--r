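#' Configuration for the synthetic multi-cell-line simulator
#'
#' Defines the statistical structure the analysis assumes: a consensus peak
#' universe shared by all samples, a small planted fraction of cell-line-
#' specific ("variable") peaks boosted `effect_fold`-fold in their active
#' line(s), log-normal latent binding affinities, Poisson counting noise,
#' per-line multiplicative noise with extra correlation inside lineage pairs,
#' and chromatin accessibility that is elevated wherever a variable peak is
#' active.
#'
#' @param n_peaks Number of consensus peaks.
#' @param n_samples Number of cell lines (default 12).
#' @param frac_variable Planted fraction of cell-line-specific peaks
#'   (default 0.05).
#' @param affinity_sd SD of the log-normal latent affinity (log scale).
#' @param effect_fold Intensity multiplier for a variable peak in its active
#'   line(s) (default 4; must be >= 1).
#' @param n_active_lines Number of lines in which a variable peak is active.
#' @param acc_coupling Exponent tying expected intensity to accessibility
#'   (`expected ~ accessibility^acc_coupling`). Default 0: the active-line
#'   gain is carried entirely by `effect_fold` while accessibility is still
#'   elevated in active lines, so binding and accessibility co-vary without
#'   double-counting the effect size.
#' @param acc_fold Accessibility multiplier in a variable peak's active
#'   line(s).
#' @param acc_sd SD of log-normal accessibility noise.
#' @param lineage_pairs List of sample index pairs sharing correlated
#'   multiplicative noise (tissue-of-origin structure). `NULL` (default)
#'   plants pairs (1,2), (3,4), (5,6), dropping any that exceed `n_samples`.
#' @param lineage_sd SD (log scale) of the noise shared within a lineage
#'   pair.
#' @param sample_sd SD (log scale) of independent per-line noise.
#' @param depth Mean reads per peak per unit affinity.
#' @param background_rate Background reads per flank bp (read-level output).
#' @param read_length Read length (bp) for read-level output.
#' @param peak_width Range (min, max) of simulated peak widths (bp).
#' @param gap_bp Gap between consecutive peaks (>= 2000 bp).
#' @param nb_dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) keeps pure Poisson counts.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A validated `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_peaks = 2000L, n_samples = 12L,
                             frac_variable = 0.05, affinity_sd = 0.8,
                             effect_fold = 4, n_active_lines = 1L,
                             acc_coupling = 0, acc_fold = 4, acc_sd = 0.25,
                             lineage_pairs = NULL,
                             lineage_sd = 0.25, sample_sd = 0.15,
                             depth = 50, background_rate = 0.01,
                             read_length = 75L, peak_width = c(300L, 700L),
                             gap_bp = 2500L, nb_dispersion = NULL,
                             seed = 1L) {
  if (is.null(lineage_pairs))
    lineage_pairs <- Filter(function(p) max(p) <= n_samples,
                            list(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
  cfg <- list(n_peaks = as.integer(n_peaks), n_samples = as.integer(n_samples),
              frac_variable = frac_variable, affinity_sd = affinity_sd,
              effect_fold = effect_fold,
              n_active_lines = as.integer(n_active_lines),
              acc_coupling = acc_coupling, acc_fold = acc_fold,
              acc_sd = acc_sd, lineage_pairs = lineage_pairs,
              lineage_sd = lineage_sd, sample_sd = sample_sd, depth = depth,
              background_rate = background_rate,
              read_length = as.integer(read_length),
              peak_width = as.integer(peak_width),
              gap_bp = as.integer(gap_bp), nb_dispersion = nb_dispersion,
              seed = as.integer(seed))
  if (cfg$n_peaks < 1L || cfg$n_samples < 1L)
    stop("n_peaks and n_samples must be positive")
  if (cfg$frac_variable < 0 || cfg$frac_variable > 1)
    stop("frac_variable must be in [0, 1]")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$effect_fold < 1) stop("effect_fold must be >= 1")
  if (cfg$n_active_lines < 1L || cfg$n_active_lines > cfg$n_samples)
    stop("n_active_lines must be between 1 and n_samples")
  if (cfg$gap_bp < 2000L) stop("gap_bp must be at least 2000")
  if (cfg$background_rate < 0) stop("background_rate must be non-negative")
  if (length(cfg$peak_width) != 2L || any(cfg$peak_width < 50L) ||
      cfg$peak_width[1L] > cfg$peak_width[2L])
    stop("peak_width must be an increasing pair of widths >= 50")
  for (pr in cfg$lineage_pairs)
    if (length(pr) != 2L || any(pr < 1L) || any(pr > cfg$n_samples) ||
        pr[1L] == pr[2L])
      stop("lineage_pairs must be distinct sample index pairs")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Generate planted ground truth and peak coordinates
#'
#' Deterministic given `cfg$seed`. Peaks are placed non-overlapping on a
#' single synthetic chromosome `chrS` with `gap_bp` between them. Expected
#' intensity is
#' `depth * affinity * effect_fold^[active] * accessibility^acc_coupling *
#' exp(lineage + line noise)`.
#'
#' @param cfg A [synthetic_config()].
#' @return A `SyntheticTruth`: list with `config`, `peaks` (a `PeakSet`),
#'   `sample_ids`, `class` (`"shared"`/`"variable"` per peak),
#'   `latent_affinity`, `active_lines` (list of sample indices per peak),
#'   `accessibility` and `expected` (peak x sample matrices).
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  with_seed(cfg$seed, {
    n <- cfg$n_peaks
    S <- cfg$n_samples
    sample_ids <- sprintf("line_%02d", seq_len(S))
    widths <- if (cfg$peak_width[1L] == cfg$peak_width[2L])
      rep(cfg$peak_width[1L], n)
    else
      sample(seq(cfg$peak_width[1L], cfg$peak_width[2L]), n, replace = TRUE)
    starts <- cfg$gap_bp + c(0L, cumsum(widths[-n] + cfg$gap_bp))
    peaks <- peak_set(rep("chrS", n), starts, starts + widths,
                      name = sprintf("peak_%05d", seq_len(n)))

    n_var <- round(cfg$frac_variable * n)
    var_idx <- if (n_var > 0L) sort(sample.int(n, n_var)) else integer(0)
    cls <- rep("shared", n)
    cls[var_idx] <- "variable"
    affinity <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$affinity_sd)
    active <- vector("list", n)
    active[] <- list(integer(0))
    for (i in var_idx)
      active[[i]] <- sort(sample.int(S, cfg$n_active_lines))

    acc <- matrix(stats::rlnorm(n * S, 0, cfg$acc_sd), n, S)
    eff <- matrix(1, n, S)
    for (i in var_idx) {
      acc[i, active[[i]]] <- acc[i, active[[i]]] * cfg$acc_fold
      eff[i, active[[i]]] <- cfg$effect_fold
    }

    lin <- matrix(0, n, S)
    for (pr in cfg$lineage_pairs) {
      z <- stats::rnorm(n, 0, cfg$lineage_sd)
      lin[, pr[1L]] <- lin[, pr[1L]] + z
      lin[, pr[2L]] <- lin[, pr[2L]] + z
    }
    noise <- exp(lin + matrix(stats::rnorm(n * S, 0, cfg$sample_sd), n, S))

    expected <- cfg$depth * affinity * eff * acc^cfg$acc_coupling * noise
    dimnames(acc) <- dimnames(expected) <- list(peaks$name, sample_ids)
    structure(list(config = cfg, peaks = peaks, sample_ids = sample_ids,
                   class = cls, latent_affinity = affinity,
                   active_lines = active, accessibility = acc,
                   expected = expected),
              class = "SyntheticTruth")
  })
}

#' Draw observed counts (and optional read-level BED intervals)
#'
#' Counts are Poisson around the planted expected intensity (negative
#' binomial when `nb_dispersion` is set). With `reads = TRUE`, each counted
#' read is also materialized as a 5'-position interval placed uniformly
#' inside its peak, plus background reads in the peak flanks (never inside a
#' peak), so re-counting the read-level output reproduces the matrix exactly.
#'
#' @param truth A `SyntheticTruth` from [generate_truth()].
#' @param reads Also generate per-sample read intervals?
#' @param flank_bp Flank width receiving background reads (total; half per
#'   side).
#' @return List with `counts` (a raw-stage `CountMatrix`) and, when
#'   requested, `reads` (named list of read `PeakSet`s).
#' @export
generate_counts <- function(truth, reads = FALSE, flank_bp = 1000L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  cfg <- truth$config
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_peaks
    S <- cfg$n_samples
    mu <- truth$expected
    cnt <- if (is.null(cfg$nb_dispersion))
      matrix(stats::rpois(n * S, mu), n, S)
    else
      matrix(stats::rnbinom(n * S, size = cfg$nb_dispersion, mu = mu), n, S)
    dimnames(cnt) <- dimnames(mu)
    m <- count_matrix(cnt * 1.0, stage = "raw")
    if (!reads) return(list(counts = m))

    half <- as.integer(flank_bp %/% 2L)
    pk <- truth$peaks
    read_sets <- lapply(seq_len(S), function(s) {
      pos <- integer(0)
      for (i in seq_len(n)) {
        k <- cnt[i, s]
        if (k > 0L) {
          w <- pk$end[i] - pk$start[i]
          pos <- c(pos, pk$start[i] +
                     as.integer(floor(stats::runif(k) * w)))
        }
      }
      # background reads in flanks only (gap_bp >= 2000 guarantees the
      # half-flanks of adjacent peaks never reach into a peak)
      if (cfg$background_rate > 0) {
        for (i in seq_len(n)) {
          for (side in 1:2) {
            fs <- if (side == 1L) max(0L, pk$start[i] - half) else pk$end[i]
            fe <- if (side == 1L) pk$start[i] else pk$end[i] + half
            wb <- fe - fs
            if (wb <= 0L) next
            kb <- stats::rpois(1L, cfg$background_rate * wb)
            if (kb > 0L)
              pos <- c(pos, fs + as.integer(floor(stats::runif(kb) * wb)))
          }
        }
      }
      pos <- sort(pos)
      peak_set(rep("chrS", length(pos)), pos, pos + cfg$read_length,
               name = sprintf("read_%07d", seq_along(pos)),
               strand = rep("+", length(pos)))
    })
    names(read_sets) <- truth$sample_ids
    list(counts = m, reads = read_sets)
  })
}

#' Generate peak sequences with affinity-coupled motif sites
#'
#' Each peak gets a uniform-random background sequence of its own width with
#' one motif site planted at a random offset. The site is sampled from the
#' PWM sharpened by a per-peak temperature: sampling probabilities are
#' proportional to `p^(1/t)` per position, and `t` interpolates from `t_max`
#' (weak, noisy sites) down to `t_min` (near-consensus sites) with the
#' peak's affinity rank, so best-site scores correlate positively with
#' latent affinity.
#'
#' @param truth A `SyntheticTruth`.
#' @param pwm A floor-applied `PWMatrix`.
#' @param t_min,t_max Temperature range (`t_min > 0`); `t -> 0` plants the
#'   consensus site everywhere.
#' @return Named character vector of sequences, one per peak.
#' @export
generate_sequences <- function(truth, pwm, t_min = 0.25, t_max = 2) {
  stopifnot(inherits(truth, "SyntheticTruth"), inherits(pwm, "PWMatrix"))
  if (t_min <= 0 || t_max < t_min) stop("need 0 < t_min <= t_max")
  cfg <- truth$config
  with_seed(cfg$seed + 2L, {
    n <- cfg$n_peaks
    L <- nrow(pwm$probs)
    bases <- c("A", "C", "G", "T")
    q <- rank(truth$latent_affinity, ties.method = "first") / n
    temp <- t_max - (t_max - t_min) * q
    widths <- truth$peaks$end - truth$peaks$start
    seqs <- vapply(seq_len(n), function(i) {
      w <- widths[i]
      s <- sample(bases, w, replace = TRUE)
      # sharpen in log space so tiny temperatures do not underflow
      lw <- log(pwm$probs) / temp[i]
      lw <- lw - apply(lw, 1L, max)
      pr <- exp(lw)
      pr <- pr / rowSums(pr)
      site <- vapply(seq_len(L), function(j)
        sample(bases, 1L, prob = pr[j, ]), character(1L))
      off <- sample.int(w - L + 1L, 1L)
      s[off:(off + L - 1L)] <- site
      paste(s, collapse = "")
    }, character(1L))
    names(seqs) <- truth$peaks$name
    seqs
  })
}

#' Generate a basal expression matrix coupled to accessibility
#'
#' One gene per peak (`gene_<peak>`): expression is
#' `base * accessibility^gamma * exp(noise)`, so genes at variable peaks
#' co-vary with binding in the peaks' active lines. `gamma = 0` decouples
#' expression from the binding structure entirely.
#'
#' @param truth A `SyntheticTruth`.
#' @param gamma Accessibility coupling exponent.
#' @param expr_sd SD (log scale) of expression noise.
#' @return Numeric gene x sample matrix; the peak-to-gene map is attached as
#'   attribute `peak2gene` (named character vector).
#' @export
generate_expression <- function(truth, gamma = 1, expr_sd = 0.3) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  cfg <- truth$config
  with_seed(cfg$seed + 3L, {
    n <- cfg$n_peaks
    S <- cfg$n_samples
    base <- stats::rlnorm(n, meanlog = 2, sdlog = 1)
    noise <- matrix(stats::rnorm(n * S, 0, expr_sd), n, S)
    expr <- base * truth$accessibility^gamma * exp(noise)
    genes <- paste0("gene_", truth$peaks$name)
    dimnames(expr) <- list(genes, truth$sample_ids)
    attr(expr, "peak2gene") <- stats::setNames(genes, truth$peaks$name)
    expr
  })
}

#' Simulate aligned predictors and response for the binding model
#'
#' Builds `n` peaks with standardized motif and accessibility scores and a
#' log2 binding signal `y = sqrt(r2_motif) * motif + sqrt(r2_acc) * acc +
#' sqrt(1 - r2_motif - r2_acc) * noise`, so the planted population R^2 of
#' the two-predictor model is exactly `r2_motif + r2_acc`.
#'
#' @param n Number of peaks.
#' @param r2_motif,r2_acc Planted variance fractions (sum < 1).
#' @param seed Integer seed.
#' @return List with `log2_signal`, `motif_score`, `accessibility`,
#'   `r2_total`.
#' @export
simulate_binding_model_data <- function(n = 8742L, r2_motif = 0.08,
                                        r2_acc = 0.12, seed = 1L) {
  if (r2_motif < 0 || r2_acc < 0 || r2_motif + r2_acc >= 1)
    stop("planted variance fractions must be non-negative and sum below 1")
  with_seed(seed, {
    motif <- stats::rnorm(n)
    acc <- stats::rnorm(n)
    y <- sqrt(r2_motif) * motif + sqrt(r2_acc) * acc +
      sqrt(1 - r2_motif - r2_acc) * stats::rnorm(n)
    list(log2_signal = y, motif_score = motif, accessibility = acc,
         r2_total = r2_motif + r2_acc)
  })
}

#' Write a complete simulated dataset to disk
#'
#' Writes `peaks.bed`, `reads_<sample>.bed`, `counts.tsv`, `peaks.fa`,
#' `accessibility.tsv`, `expression.tsv`, `tss.bed` (one TSS per gene,
#' placed just downstream of its peak) and `truth.tsv`.
#'
#' @param cfg A [synthetic_config()].
#' @param outdir Output directory (created if needed).
#' @param pwm A `PWMatrix` for sequence generation; default is the bundled
#'   synthetic p53 consensus PWM with a 0.01 floor.
#' @param reads Write read-level BED files?
#' @return Invisibly, the `SyntheticTruth`.
#' @export
simulate_dataset <- function(cfg, outdir, pwm = NULL, reads = TRUE) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(pwm)) {
    pwm_path <- system.file("extdata", "p53_pwm_synthetic.tsv",
                            package = "peakvar")
    pwm <- apply_probability_floor(read_pwm(pwm_path), 0.01)
  }
  truth <- generate_truth(cfg)
  gen <- generate_counts(truth, reads = reads)
  seqs <- generate_sequences(truth, pwm)
  expr <- generate_expression(truth)

  write_bed(truth$peaks, file.path(outdir, "peaks.bed"))
  write_count_matrix(gen$counts, file.path(outdir, "counts.tsv"))
  write_fasta(seqs, file.path(outdir, "peaks.fa"))
  write_matrix_tsv(truth$accessibility, file.path(outdir, "accessibility.tsv"))
  write_matrix_tsv(expr, file.path(outdir, "expression.tsv"),
                   id_col = "gene_id")
  if (reads)
    for (s in names(gen$reads))
      write_bed(gen$reads[[s]], file.path(outdir, paste0("reads_", s, ".bed")))
  tss <- peak_set(truth$peaks$chrom, truth$peaks$end + 100L,
                  truth$peaks$end + 101L,
                  name = paste0("gene_", truth$peaks$name))
  write_bed(tss, file.path(outdir, "tss.bed"))
  truth_df <- data.frame(
    peak_id = truth$peaks$name, class = truth$class,
    latent_affinity = truth$latent_affinity,
    active_lines = vapply(truth$active_lines, paste, character(1L),
                          collapse = ","),
    stringsAsFactors = FALSE)
  utils::write.table(truth_df, file.path(outdir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}

# Plain gene/peak x sample TSV writer used for simulator side matrices.
write_matrix_tsv <- function(x, path, id_col = "peak_id") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}
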