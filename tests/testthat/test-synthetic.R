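test_that("planted truth respects the configuration and is reproducible", {
  cfg <- synthetic_config(n_peaks = 1000, frac_variable = 0.05, seed = 5)
  truth <- generate_truth(cfg)
  expect_equal(sum(truth$class == "variable"), 50L)
  expect_true(all(lengths(truth$active_lines[truth$class == "variable"]) ==
                    1L))
  expect_true(all(lengths(truth$active_lines[truth$class == "shared"]) ==
                    0L))
  # non-overlapping placement with >= 2 kb gaps on one synthetic chromosome
  expect_true(all(truth$peaks$start[-1] - truth$peaks$end[-1000] >= 2000L))
  expect_identical(unique(truth$peaks$chrom), "chrS")

  truth2 <- generate_truth(cfg)
  expect_identical(truth$expected, truth2$expected)
  expect_identical(truth$class, truth2$class)

  expect_error(synthetic_config(depth = 0), "depth")
  expect_error(synthetic_config(frac_variable = 1.5), "frac_variable")
  expect_error(synthetic_config(effect_fold = 0.5), "effect_fold")
})

test_that("counts are Poisson around the planted intensity", {
  cfg <- synthetic_config(n_peaks = 10000, n_samples = 1, affinity_sd = 0,
                          sample_sd = 0, lineage_pairs = list(),
                          frac_variable = 0, depth = 100, seed = 8)
  truth <- generate_truth(cfg)
  cnt <- generate_counts(truth)$counts$values
  expect_equal(mean(cnt), 100, tolerance = 3 * sqrt(100 / 10000) / 100)
  expect_equal(var(as.vector(cnt)) / mean(cnt), 1, tolerance = 0.06)
})

test_that("read-level output re-counted by quantify equals the matrix", {
  cfg <- synthetic_config(n_peaks = 80, n_samples = 2, depth = 25,
                          background_rate = 0.01, seed = 13)
  truth <- generate_truth(cfg)
  gen <- generate_counts(truth, reads = TRUE)
  for (s in truth$sample_ids) {
    recount <- count_reads_in_peaks(gen$reads[[s]], truth$peaks)
    expect_equal(unname(recount),
                 unname(as.integer(gen$counts$values[, s])))
  }
})

test_that("zero-temperature sites are the PWM consensus everywhere", {
  pwm <- apply_probability_floor(
    read_pwm(system.file("extdata", "p53_pwm_synthetic.tsv",
                         package = "peakvar")), 0.01)
  cfg <- synthetic_config(n_peaks = 30, seed = 17)
  truth <- generate_truth(cfg)
  seqs <- generate_sequences(truth, pwm, t_min = 1e-4, t_max = 1e-4)
  scores <- score_sequences(pwm, seqs)
  max_score <- sum(apply(log2(pwm$probs / 0.25), 1, max))
  expect_equal(scores$score, rep(max_score, 30), tolerance = 1e-9)
})

test_that("motif scores correlate with latent affinity by construction", {
  pwm <- apply_probability_floor(
    read_pwm(system.file("extdata", "p53_pwm_synthetic.tsv",
                         package = "peakvar")), 0.01)
  rs <- vapply(1:3, function(s) {
    cfg <- synthetic_config(n_peaks = 600, peak_width = c(200L, 200L),
                            seed = s)
    truth <- generate_truth(cfg)
    seqs <- generate_sequences(truth, pwm)
    scores <- score_sequences(pwm, seqs)
    cor(scores$score, log(truth$latent_affinity))
  }, numeric(1))
  expect_true(all(rs > 0.3))

  cfg <- synthetic_config(n_peaks = 40, seed = 19)
  truth <- generate_truth(cfg)
  expect_identical(generate_sequences(truth, pwm),
                   generate_sequences(truth, pwm))
})

test_that("expression couples to binding through accessibility", {
  # gamma = 0: per-peak binding-expression correlations center at 0
  cfg <- synthetic_config(n_peaks = 300, seed = 23, acc_sd = 0.4)
  truth <- generate_truth(cfg)
  counts <- generate_counts(truth)$counts
  m <- suppressWarnings(normalize_between_samples(counts))
  expr0 <- generate_expression(truth, gamma = 0)
  assoc0 <- binding_expression_association(m, expr0,
                                           attr(expr0, "peak2gene"))
  expect_lt(abs(mean(assoc0$r, na.rm = TRUE)), 0.12)

  # active-line accessibility elevation: variable peaks' genes correlate
  # with binding through the shared active-line spike; shared peaks do not
  ps <- vapply(1:3, function(s) {
    cfg <- synthetic_config(n_peaks = 600, seed = s, depth = 50)
    truth <- generate_truth(cfg)
    m <- suppressWarnings(
      normalize_between_samples(generate_counts(truth)$counts))
    expr <- generate_expression(truth, gamma = 1, expr_sd = 0.2)
    assoc <- binding_expression_association(m, expr,
                                            attr(expr, "peak2gene"))
    v <- truth$class == "variable"
    compare_correlation_groups(assoc$r[v], assoc$r[!v])$p
  }, numeric(1))
  expect_true(all(ps < 1e-4))

  expect_identical(generate_expression(truth), generate_expression(truth))
})

test_that("effect_fold 1 makes planted 'variable' peaks indistinguishable", {
  cfg <- synthetic_config(n_peaks = 4000, effect_fold = 1, acc_fold = 1,
                          lineage_pairs = list(), sample_sd = 0,
                          depth = 50, seed = 29)
  truth <- generate_truth(cfg)
  m <- suppressWarnings(
    normalize_between_samples(generate_counts(truth)$counts))
  t <- mean_cv(m)
  t <- flag_variable_peaks(t, fit_cv_trend(t))
  v <- truth$class == "variable"
  expect_lt(abs(mean(t$flag[v]) - mean(t$flag[!v])), 0.05)
})
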