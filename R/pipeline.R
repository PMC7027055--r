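#' Validate pipeline inputs
#'
#' Reporting operation: checks that configured files exist, that matrices
#' agree on sample labels, that BED inputs share chromosome names, and that
#' the PWM is well-formed. Never throws for a failed check; returns one row
#' per check.
#'
#' @param config Named list (or path to a flat JSON file) of pipeline inputs;
#'   recognized keys include `peaks`, `reads` (named list of BED paths),
#'   `counts`, `pwm`, `fasta`, `tss`, `accessibility`, `expression`.
#' @return Data frame with columns `check`, `status` (`"pass"`/`"fail"`),
#'   `detail`.
#' @export
validate_inputs <- function(config) {
  config <- load_config(config)
  checks <- list()
  add <- function(check, ok, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, status = if (ok) "pass" else "fail", detail = detail,
      stringsAsFactors = FALSE)
  }
  file_keys <- c("peaks", "counts", "pwm", "fasta", "tss", "accessibility",
                 "expression")
  for (key in intersect(file_keys, names(config))) {
    ok <- is.character(config[[key]]) && file.exists(config[[key]])
    add(paste0("file_", key), ok,
        if (ok) config[[key]] else paste0("missing file for '", key, "'"))
  }
  if (!is.null(config$reads)) {
    missing <- unlist(config$reads)[!file.exists(unlist(config$reads))]
    add("file_reads", length(missing) == 0L,
        if (length(missing)) paste("missing:", paste(missing, collapse = ", "))
        else paste(length(config$reads), "read files"))
  }
  safely <- function(expr) tryCatch(expr, error = function(e) NULL)
  peaks <- if (!is.null(config$peaks) && file.exists(config$peaks %||% ""))
    safely(read_bed(config$peaks)) else NULL
  if (!is.null(peaks) && !is.null(config$tss) && file.exists(config$tss)) {
    tss <- safely(read_bed(config$tss))
    if (!is.null(tss)) {
      shared <- length(intersect(unique(peaks$chrom), unique(tss$chrom))) > 0L
      add("chrom_overlap_peaks_tss", shared,
          if (shared) "" else "no shared chromosome names (naming mismatch?)")
    }
  }
  cm <- if (!is.null(config$counts) && file.exists(config$counts %||% ""))
    safely(read_count_matrix(config$counts)) else NULL
  if (!is.null(cm) && !is.null(config$expression) &&
      file.exists(config$expression)) {
    expr <- safely(read_matrix_tsv(config$expression))
    if (!is.null(expr)) {
      shared <- intersect(cm$sample_ids, colnames(expr))
      add("sample_ids_binding_expression", length(shared) >= 3L,
          if (length(shared) >= 3L) paste(length(shared), "shared samples")
          else paste0("sample ids disagree between '", config$counts,
                      "' and '", config$expression, "'"))
    }
  }
  if (!is.null(cm) && !is.null(config$accessibility) &&
      file.exists(config$accessibility)) {
    acc <- safely(read_matrix_tsv(config$accessibility))
    if (!is.null(acc)) {
      ok <- all(cm$peak_ids %in% rownames(acc))
      add("peak_ids_binding_accessibility", ok,
          if (ok) "" else "accessibility matrix missing some peaks")
    }
  }
  if (!is.null(config$pwm) && file.exists(config$pwm %||% "")) {
    p <- safely(read_pwm(config$pwm))
    add("pwm_valid", !is.null(p),
        if (is.null(p)) "PWM failed to parse" else "")
  }
  if (length(checks) == 0L)
    return(data.frame(check = character(0), status = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  do.call(rbind, checks)
}

#' Run the full analysis pipeline
#'
#' Executes quantify -> variability -> motif -> integrate -> cluster on the
#' configured inputs, writing every intermediate table plus a reproducibility
#' manifest (parameter values, seed and md5 checksums of all outputs) to
#' `out_dir`. The quantify stage is skipped when a count matrix is supplied
#' directly. The run is a pure function of (inputs, config, seed): identical
#' runs produce identical checksums.
#'
#' @param config Named list or path to a flat JSON config. Keys: `peaks`
#'   (BED), either `reads` (named list of BED paths) or `counts` (TSV),
#'   optional `pwm`, `fasta`, `tss`, `accessibility`, `expression`, plus
#'   parameters `flank_bp`, `min_signal`, `fold`, `min_mean`, `floor`,
#'   `window_bp`, `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main result objects and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  par <- list(flank_bp = config$flank_bp %||% 1000L,
              min_signal = config$min_signal %||% 2,
              fold = config$fold %||% 1.5,
              min_mean = config$min_mean %||% 2,
              floor = config$floor %||% 0.01,
              window_bp = config$window_bp %||% 10000L,
              seed = config$seed %||% 1L)
  if (is.null(config$counts) && (is.null(config$peaks) ||
                                 is.null(config$reads)))
    stop("config must provide either 'counts' or both 'peaks' and 'reads'")
  needed <- c(config$peaks, config$counts, unlist(config$reads),
              config$pwm, config$fasta, config$tss, config$accessibility,
              config$expression)
  missing <- needed[!file.exists(needed)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  log_msg <- function(...) message("[peakvar] ", ...)

  peaks <- if (!is.null(config$peaks)) read_bed(config$peaks) else NULL

  if (!is.null(config$counts)) {
    log_msg("loading count matrix ", config$counts)
    m <- read_count_matrix(config$counts)
  } else {
    log_msg("quantifying ", length(config$reads), " samples over ",
            nrow(peaks), " peaks")
    reads <- lapply(config$reads, read_bed)
    m <- quantify(peaks, reads, flank_bp = par$flank_bp)
  }
  if (m$stage == "raw")
    m <- suppressWarnings(normalize_between_samples(m))
  else if (m$stage == "corrected")
    m <- normalize_between_samples(m)
  flt <- filter_min_signal(m, par$min_signal)
  m <- flt$matrix
  log_msg(length(flt$removed), " peaks removed below ", par$min_signal,
          " normalized counts; ", nrow(m$values), " retained")
  write_count_matrix(m, file.path(out_dir, "normalized.tsv"))
  emit(file.path(out_dir, "normalized.tsv"))

  tab <- mean_cv(m)
  fit <- fit_cv_trend(tab)
  tab <- flag_variable_peaks(tab, fit, fold = par$fold,
                             min_mean = par$min_mean)
  log_msg(attr(tab, "n_flagged"), " highly variable peaks flagged (",
          sprintf("%.2f%%", 100 * attr(tab, "n_flagged") / nrow(tab)), ")")
  write_mean_cv(tab, file.path(out_dir, "meancv.tsv"))
  emit(file.path(out_dir, "meancv.tsv"))

  scores <- NULL
  if (!is.null(config$pwm) && !is.null(config$fasta)) {
    pwm <- apply_probability_floor(read_pwm(config$pwm), par$floor)
    seqs <- read_fasta(config$fasta)
    scores <- score_sequences(pwm, seqs)
    write_motif_scores(scores, file.path(out_dir, "motif_scores.tsv"))
    emit(file.path(out_dir, "motif_scores.tsv"))
  }

  fit_json <- list(cv_trend = list(a = fit$a, b = fit$b, n = fit$n),
                   n_flagged = attr(tab, "n_flagged"),
                   n_peaks = nrow(tab), parameters = par)
  if (!is.null(scores)) {
    sc <- scores$score[match(m$peak_ids, scores$name)]
    ok <- is.finite(sc)
    y <- log2(rowMeans(m$values) + 1)
    acc <- NULL
    if (!is.null(config$accessibility)) {
      accm <- read_matrix_tsv(config$accessibility)
      acc <- log2(rowMeans(accm[m$peak_ids, , drop = FALSE]) + 1)
    }
    lf <- fit_binding_model(y[ok], sc[ok],
                            accessibility = if (is.null(acc)) NULL
                                            else acc[ok])
    fit_json$binding_model <- list(
      r_squared = lf$r_squared, adj_r_squared = lf$adj_r_squared,
      coefficients = as.list(lf$coefficients), n = lf$n)
    motif_only <- fit_binding_model(y[ok], sc[ok])
    fit_json$binding_model_motif_only <- list(
      r_squared = motif_only$r_squared, n = motif_only$n)
  }
  if (!is.null(config$tss) && !is.null(peaks)) {
    tss <- read_bed(config$tss)
    prox <- tss_proximal(peaks, tss, window_bp = par$window_bp)
    keep <- intersect(prox$peaks$name, m$peak_ids)
    fit_json$tss_proximal <- list(n = length(keep),
                                  window_bp = par$window_bp)
    utils::write.table(prox$nearest, file.path(out_dir, "tss_proximal.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "tss_proximal.tsv"))
  }
  jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(file.path(out_dir, "fit.json"))

  dend <- cluster_matrix(m, axis = "samples")
  jsonlite::write_json(
    list(labels = dend$labels, merge = dend$merge, height = dend$height),
    file.path(out_dir, "dendrogram.json"), digits = NA, pretty = TRUE)
  emit(file.path(out_dir, "dendrogram.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("peakvar")),
    parameters = par,
    inputs = as.list(needed),
    checksums = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("wrote ", length(outputs), " outputs + manifest to ", out_dir)
  invisible(list(matrix = m, mean_cv = tab, cv_trend = fit,
                 motif_scores = scores, dendrogram = dend,
                 results = fit_json, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a named list or a JSON path")
  config
}

# Generic id x sample numeric TSV (first column = row ids).
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
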