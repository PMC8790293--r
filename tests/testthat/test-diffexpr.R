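make_cm <- function(mat, labels) {
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  count_matrix(mat, labels)
}

test_that("libsize factors are proportional to column sums, centered", {
  cm <- make_cm(matrix(c(10, 20, 30,
                         10, 20, 30), ncol = 2), c("tumor", "normal"))
  f <- normalize_factors(cm, "libsize")
  expect_equal(unname(f), c(1, 1))

  # one library doubled at identical composition
  cm2 <- make_cm(matrix(c(10, 20, 30,
                          20, 40, 60), ncol = 2), c("tumor", "normal"))
  f2 <- normalize_factors(cm2, "libsize")
  expect_equal(unname(f2[2] / f2[1]), 2)
  expect_equal(exp(mean(log(f2))), 1)

  cm0 <- make_cm(matrix(0L, 3, 2), c("tumor", "normal"))
  expect_error(normalize_factors(cm0), "all-zero")
})

test_that("TMM factor equals a directly recomputed trimmed mean of M values", {
  set.seed(42)
  n <- 500
  ref <- rpois(n, 100)
  obs <- rpois(n, 100)
  shifted <- which(seq_len(n) <= 50)
  obs[shifted] <- obs[shifted] * 6         # composition bias in 10% of genes
  cm <- make_cm(cbind(obs, ref), c("tumor", "normal"))
  f <- normalize_factors(cm, "tmm")

  # brute-force oracle: recompute the doubly trimmed mean of gene-wise M
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  m <- log2((obs[keep] / n_obs) / (ref[keep] / n_ref))
  a <- 0.5 * log2((obs[keep] / n_obs) * (ref[keep] / n_ref))
  inside <- m >= quantile(m, 0.3) & m <= quantile(m, 0.7) &
    a >= quantile(a, 0.05) & a <= quantile(a, 0.95)
  expected_nf <- 2^mean(m[inside])

  nf <- attr(f, "norm_factor")
  expect_equal(unname(nf[1] / nf[2]), expected_nf, tolerance = 1e-10)
})

test_that("dispersion estimation recovers the simulation truth", {
  sim <- simulate_counts(2000, 25, 25, frac_de = 0, dispersion = 0, seed = 21,
                         baseline_meanlog = log(80), baseline_sdlog = 0.6)
  est <- estimate_dispersion(sim$counts)
  expect_lt(est$common, 0.05)

  sim4 <- simulate_counts(2000, 25, 25, frac_de = 0, dispersion = 0.4,
                          seed = 22, baseline_meanlog = log(80),
                          baseline_sdlog = 0.6)
  est4 <- estimate_dispersion(sim4$counts)
  expect_gt(est4$common, 0.3)
  expect_lt(est4$common, 0.5)
})

test_that("constant genes clamp to zero and single-sample groups warn", {
  mat <- matrix(rpois(40, 50), nrow = 4)
  mat[1, ] <- 50L                          # constant gene, zero variance
  cm <- make_cm(mat, rep(c("tumor", "normal"), each = 5))
  est <- estimate_dispersion(cm, size_factors = setNames(rep(1, 10),
                                                         colnames(cm$counts)),
                             prior_weight = 0)
  expect_identical(unname(est$tagwise[1]), 0)

  cm1 <- make_cm(matrix(rpois(30, 50), nrow = 3),
                 c(rep("tumor", 9), "normal"))
  expect_warning(estimate_dispersion(cm1), "single sample")
})

test_that("exact test matches brute-force enumeration and its Poisson limit", {
  cases <- expand.grid(ya = c(0, 3, 10, 18), yb = c(0, 2, 12),
                       phi = c(0, 0.1, 0.7))
  for (i in seq_len(nrow(cases))) {
    ya <- cases$ya[i]; yb <- cases$yb[i]; phi <- cases$phi[i]
    p <- exact_test(c(ya, 0, 0), c(yb, 0), dispersion = phi)
    expect_equal(p, oracle_exact_p(ya, yb, 3, 2, phi), tolerance = 1e-10,
                 info = sprintf("ya=%d yb=%d phi=%g", ya, yb, phi))
  }
  # phi = 0 equals the conditional-binomial exact test
  p0 <- exact_test(c(4, 3), c(9, 10), dispersion = 0)
  pr <- dbinom(0:26, 26, 0.5)
  expect_equal(p0, sum(pr[pr <= pr[8] * (1 + 1e-12)]), tolerance = 1e-12)
})

test_that("exact test symmetry, monotonicity and degenerate inputs", {
  expect_identical(exact_test(integer(3), integer(3), 0.2), 1)
  # equal group totals with equal group sizes sit at the mode
  expect_equal(exact_test(c(7, 7), c(7, 7), 0.3), 1)
  # label swap leaves the two-sided p unchanged
  p_ab <- exact_test(c(20, 21), c(5, 6), 0.15)
  p_ba <- exact_test(c(5, 6), c(20, 21), 0.15)
  expect_equal(p_ab, p_ba, tolerance = 1e-12)
  # growing imbalance at fixed total never increases p
  t <- 40
  p_seq <- vapply(20:36, function(ya) {
    exact_test(c(ya, 0), c(t - ya, 0), 0.2)
  }, numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("DEG filter thresholds are strict, as stated", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d"),
    FC = c(2.5, 2.0, 0.4, 0.45),
    PValue = c(0.01, 0.001, 0.2, 0.01)
  )
  res <- call_degs(tab)
  expect_setequal(res$degs$gene, c("a", "d"))
  expect_identical(res$degs$direction[res$degs$gene == "a"], "up")
  expect_identical(res$degs$direction[res$degs$gene == "d"], "down")
  expect_identical(res$n_up, 1L)
  expect_identical(res$n_down, 1L)
  # FC exactly at the bound is excluded; p failure excludes regardless of FC
  expect_false("b" %in% res$degs$gene)
  expect_false("c" %in% res$degs$gene)
})

test_that("planted DEGs are recovered and null false positives stay low", {
  sim <- simulate_counts(1000, 50, 50, frac_de = 0.2, lfc_magnitude = 2,
                         dispersion = 0.1, seed = 77)
  det <- de_table(sim$counts)
  called <- call_degs(det)$degs$gene
  planted <- sim$truth$de_genes
  nulls <- setdiff(det$gene, planted)
  expect_gte(mean(planted %in% called), 0.90)
  expect_lte(mean(nulls %in% called), 0.07)
})
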