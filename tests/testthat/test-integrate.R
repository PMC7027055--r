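test_that("OLS binding model recovers exact linear relationships", {
  withr::local_seed(79)
  motif <- rnorm(200)
  fit <- fit_binding_model(2 * motif, motif)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["motif"]), 2, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0, tolerance = 1e-10)

  # permuted predictor explains (essentially) nothing
  y <- rnorm(5000)
  fit0 <- fit_binding_model(y, sample(y))
  expect_lt(fit0$r_squared, 0.01)

  expect_error(fit_binding_model(y, y, accessibility = 2 * y + 1e-14),
               "collinear")
})

test_that("single-predictor R^2 equals squared Pearson r", {
  withr::local_seed(83)
  for (rep in 1:10) {
    x <- rnorm(300)
    y <- 0.4 * x + rnorm(300)
    fit <- fit_binding_model(y, x)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("adding a predictor never lowers R^2, and adjusted R^2 is reported", {
  withr::local_seed(89)
  for (rep in 1:10) {
    x <- rnorm(100)
    z <- rnorm(100)               # pure noise predictor
    y <- 0.5 * x + rnorm(100)
    f1 <- fit_binding_model(y, x)
    f2 <- fit_binding_model(y, x, accessibility = z)
    expect_gte(f2$r_squared, f1$r_squared - 1e-12)
    expect_lte(f2$adj_r_squared, f2$r_squared)
  }
})

test_that("variance decomposition recovers the planted R^2", {
  r2 <- vapply(1:5, function(s) {
    d <- simulate_binding_model_data(n = 8742, r2_motif = 0.08,
                                     r2_acc = 0.12, seed = s)
    fit_binding_model(d$log2_signal, d$motif_score,
                      accessibility = d$accessibility)$r_squared
  }, numeric(1))
  expect_true(all(abs(r2 - 0.20) <= 0.05))
})

test_that("delta-binding vs delta-accessibility correlation is exact in the noiseless limit", {
  withr::local_seed(97)
  acc_a <- rexp(500) + 0.5
  acc_b <- acc_a * exp(rnorm(500))
  bind_a <- rexp(500) + 1
  bind_b <- bind_a * (acc_b / acc_a)
  out <- delta_delta_correlation(bind_a, bind_b, acc_a, acc_b,
                                 pseudocount = 0)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$r_squared, 1, tolerance = 1e-12)

  expect_error(delta_delta_correlation(bind_a, bind_b, acc_a, acc_a),
               "zero variance in accessibility")
})

test_that("delta-delta r^2 estimates a planted slope-1 model accurately", {
  r2 <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 5000
    da <- rnorm(n, 0, 1)
    db <- da + rnorm(n, 0, sqrt(3))   # true r^2 = 1/4
    bind_a <- 2^rnorm(n, 5, 1)
    acc_a <- 2^rnorm(n, 5, 1)
    delta_delta_correlation(bind_a, bind_a * 2^db, acc_a, acc_a * 2^da,
                            pseudocount = 0)$r_squared
  }, numeric(1))
  expect_true(all(abs(r2 - 0.25) <= 0.04))
})

test_that("binding-expression association and group test behave at the fixtures", {
  vals <- matrix(c(1, 5, 2, 7, 3, 9, 4, 11), 2, 4,
                 dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
  m <- count_matrix(vals, stage = "normalized")
  expr <- vals
  rownames(expr) <- c("g1", "g2")
  map <- c(p1 = "g1", p2 = "g2")
  out <- binding_expression_association(m, expr, map)
  expect_equal(out$r, c(1, 1), tolerance = 1e-12)

  r <- c(0.1, 0.3, 0.5, 0.2)
  gt <- compare_correlation_groups(r, r)
  expect_equal(gt$t, 0)
  expect_equal(gt$p, 1)

  expect_error(binding_expression_association(
    count_matrix(vals[, 1:2], stage = "normalized"), expr[, 1:2], map),
    "fewer than 3 shared samples")
})

test_that("separated correlation groups are detected by the t-test", {
  p <- vapply(1:5, function(s) {
    set.seed(s)
    r_a <- tanh(rnorm(200, 0.6, 0.3))    # correlated group
    r_b <- tanh(rnorm(200, 0.0, 0.3))    # null group
    compare_correlation_groups(r_a, r_b)$p
  }, numeric(1))
  expect_true(all(p < 1e-6))
})

test_that("hypergeometric enrichment is exact", {
  uni <- paste0("g", 1:20)
  terms <- list(T1 = paste0("g", 1:5))
  q <- paste0("g", c(1:5, 11:15))
  out <- hypergeometric_enrichment(q, terms, uni)
  expect_equal(out$p, 3003 / 184756, tolerance = 1e-12)
  expect_equal(out$p_adj, out$p)   # single term: both corrections identity
  out_b <- hypergeometric_enrichment(q, terms, uni,
                                     correction = "bonferroni")
  expect_equal(out_b$p_adj, out_b$p)

  # k = 0 has upper-tail probability 1
  out0 <- hypergeometric_enrichment(paste0("g", 11:15),
                                    list(T1 = paste0("g", 1:5)), uni)
  expect_equal(out0$k, 0L)
  expect_equal(out0$p, 1)

  expect_error(hypergeometric_enrichment(character(0), terms, uni), "empty")
  expect_error(hypergeometric_enrichment("zz", terms, uni), "subset")
})

test_that("hypergeometric p matches enumeration for every universe up to 12", {
  for (N in 2:12) {
    for (K in 0:N) {
      for (n in 1:N) {
        uni <- paste0("g", seq_len(N))
        term <- list(T = utils::head(uni, K))
        for (k_target in 0:min(n, K)) {
          q <- c(utils::head(uni, k_target),
                 utils::head(setdiff(uni, term$T), n - k_target))
          if (length(q) != n) next
          p <- hypergeometric_enrichment(q, term, uni)$p
          expect_equal(p, oracle_hyper_upper(k_target, K, N, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH adjustment is monotone in p-rank and bounded by 1", {
  withr::local_seed(101)
  uni <- paste0("g", 1:60)
  terms <- lapply(1:15, function(i) sample(uni, sample(5:25, 1)))
  names(terms) <- paste0("T", 1:15)
  out <- hypergeometric_enrichment(sample(uni, 20), terms, uni)
  expect_true(all(diff(out$p_adj) >= -1e-12))   # sorted by p
  expect_true(all(out$p_adj <= 1))
  expect_true(all(out$p_adj >= out$p))
})

test_that("bin summaries respect monotone structure and bin counts", {
  withr::local_seed(103)
  x <- rnorm(500)
  b <- bin_summary(x, x, n_bins = 5)
  expect_true(all(diff(b$median) > 0))
  expect_equal(sum(b$n), 500)

  # independent y: bin medians show no trend
  rho <- cor(bin_summary(x, sample(x), n_bins = 5)$median, 1:5,
             method = "spearman")
  expect_lt(abs(rho), 1)

  xq <- c(1, 2, 3, 4, 5)
  b1 <- bin_summary(xq, xq * 10, n_bins = 5)
  expect_equal(b1$n, rep(1L, 5))
  expect_equal(b1$median, xq * 10)

  expect_warning(bin_summary(c(rep(1, 50), 2, 3), rnorm(52), n_bins = 5),
                 "merged")
})
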