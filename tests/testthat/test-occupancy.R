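make_cov_table <- function(cov, mark = "MIRA", condition = "WT") {
  # coverage_table built from explicit tracks so the full path is used
  n <- length(cov)
  genes <- gene_models(
    gene_id = sprintf("G%02d", seq_len(n)), symbol = sprintf("S%02d", seq_len(n)),
    chrom = "chr1", strand = "+",
    tx_start = seq_len(n) * 100000L, tx_end = seq_len(n) * 100000L + 1000L,
    exon_starts = as.list(seq_len(n) * 100000L),
    exon_ends = as.list(seq_len(n) * 100000L + 1000L)
  )
  # 10 probes per gene body; requested fraction realised by floor
  probes <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (is.na(cov[i])) return(NULL)
    k <- floor(cov[i] * 10)
    data.frame(chrom = "chr1", start = genes$tx_start[i] + 0:9 * 100L,
               end = genes$tx_start[i] + 0:9 * 100L + 50L,
               value = c(rep(2, k), rep(0, 10 - k)))
  }))
  tr <- signal_track(probes, mark, condition)
  coverage_table(genes, list(tr))
}

test_that("gene classification is inclusive at the coverage threshold", {
  tab <- make_cov_table(c(0.20, 0.199, NA, 0.5, 0.1))
  m <- classify_marked_genes(tab, "MIRA")
  expect_equal(unname(m), c(TRUE, FALSE, FALSE, TRUE, FALSE),
               ignore_attr = TRUE)
  expect_equal(unname(attr(m, "excluded")), c(FALSE, FALSE, TRUE, FALSE,
                                              FALSE))
  expect_error(classify_marked_genes(tab, "NOSUCH"), "not present")
})

test_that("coverage 0.199 stays below threshold after exact realisation", {
  # realised via 10 probes, so 0.199 -> 2/10 = 0.2; build a finer case
  genes <- make_gene(0L, 100000L)
  probes <- data.frame(chrom = "chr1", start = 0:999 * 100L,
                       end = 0:999 * 100L + 50L,
                       value = c(rep(2, 199), rep(0, 801)))
  tab <- coverage_table(genes, list(signal_track(probes, "M", "C")))
  expect_false(unname(classify_marked_genes(tab, "M")))
})

test_that("co-occupancy counts partition the shared universe", {
  a <- c(G1 = TRUE, G2 = TRUE, G3 = FALSE)
  b <- c(G1 = FALSE, G2 = TRUE, G3 = TRUE)
  cc <- cooccupancy_counts(a, b)
  expect_equal(cc$only_a, 1); expect_equal(cc$only_b, 1)
  expect_equal(cc$both, 1); expect_equal(cc$neither, 0)
  expect_equal(cc$only_a + cc$only_b + cc$both + cc$neither, cc$n_universe)
  expect_equal(sum(cc$table), cc$n_universe)

  ident <- cooccupancy_counts(a, a)
  expect_equal(ident$only_a + ident$only_b, 0)
  disj <- cooccupancy_counts(c(G1 = TRUE, G2 = FALSE),
                             c(G1 = FALSE, G2 = TRUE))
  expect_equal(disj$both, 0)
  expect_error(cooccupancy_counts(a, b[1:2]), "universes differ")
})

test_that("excluded genes drop out of both classification vectors", {
  a <- structure(c(G1 = TRUE, G2 = FALSE, G3 = TRUE),
                 excluded = c(FALSE, TRUE, FALSE))
  b <- c(G1 = TRUE, G2 = TRUE, G3 = FALSE)
  cc <- cooccupancy_counts(a, b)
  expect_equal(cc$n_universe, 2)
  set.seed(3)
  for (k in 1:30) {
    n <- sample(4:40, 1)
    nm <- sprintf("g%02d", 1:n)
    a <- stats::setNames(sample(c(TRUE, FALSE), n, TRUE), nm)
    b <- stats::setNames(sample(c(TRUE, FALSE), n, TRUE), nm)
    attr(a, "excluded") <- sample(c(TRUE, FALSE), n, TRUE, prob = c(.2, .8))
    cc <- cooccupancy_counts(a, b)
    expect_equal(cc$only_a + cc$only_b + cc$both + cc$neither,
                 cc$n_universe)
  }
})

test_that("chi-square matches the closed-form Pearson statistic", {
  t1 <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  r1 <- chi_square_test(t1)
  expect_equal(r1$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r1$df, 1)
  t2 <- matrix(c(12, 12, 12, 12), 2)
  r2 <- chi_square_test(t2)
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p, 1)
  expect_message(r3 <- chi_square_test(matrix(c(5, 0, 0, 5), 2)), "Fisher")
  expect_equal(r3$statistic, 10, tolerance = 1e-9)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
  # r x c table against the oracle
  set.seed(8)
  for (k in 1:40) {
    t <- matrix(sample(1:30, 6, TRUE), 2, 3)
    got <- chi_square_test(t)
    expect_equal(got$statistic, oracle_chisq_stat(t), tolerance = 1e-9)
    expect_equal(got$df, 2)
    expect_equal(got$p, pchisq(oracle_chisq_stat(t), 2, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact_test(matrix(3, 2, 2))$p_two_tailed, 1)
  p <- fisher_exact_test(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))$p_two_tailed
  expect_equal(p, 2 / 252, tolerance = 1e-7)
  expect_equal(fisher_exact_test(matrix(c(13, 0, 13, 0), 2,
                                        byrow = TRUE))$p_two_tailed, 1)
  expect_error(fisher_exact_test(matrix(1, 3, 3)), "2x2")
  set.seed(13)
  for (k in 1:60) {
    t <- matrix(sample(0:12, 4, TRUE), 2)
    if (sum(t) == 0) next
    expect_equal(fisher_exact_test(t)$p_two_tailed, oracle_fisher_p(t),
                 tolerance = 1e-7)
  }
})

test_that("pearson_correlation handles exact and derived cases", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_correlation(x, x)$R, 1)
  expect_equal(pearson_correlation(x, -x)$R, -1)
  r <- pearson_correlation(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$R, 3 / sqrt(2 * 42 / 9), tolerance = 1e-9)
  expect_equal(r$n, 3)
  expect_error(pearson_correlation(x, rep(2, 5)), "constant")
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "fewer than 3")
  # missing pairs dropped
  expect_equal(pearson_correlation(c(x, NA), c(x, 7))$n, 5)
})

test_that("pearson_correlation is affine-invariant and sign-flips", {
  set.seed(21)
  for (k in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    r0 <- pearson_correlation(x, y)$R
    expect_equal(pearson_correlation(3.2 * x + 7, y)$R, r0,
                 tolerance = 1e-12)
    expect_equal(pearson_correlation(x, 0.1 * y - 2)$R, r0,
                 tolerance = 1e-12)
    expect_equal(pearson_correlation(-x, y)$R, -r0, tolerance = 1e-12)
  }
})

test_that("group comparison runs all pairs with Bonferroni correction", {
  set.seed(31)
  g <- list(a = rnorm(50), b = rnorm(50) + 3, c = rnorm(50) - 3)
  res <- group_signal_comparison(g)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 3))
  expect_true(all(res$p_bonferroni < 0.001))
  # identical groups: corrected p near 1
  x <- rnorm(60)
  expect_gte(group_signal_comparison(list(a = x, b = x))$p_bonferroni[1],
             0.9)
  expect_error(group_signal_comparison(list(a = 1, b = rnorm(5))),
               ">= 2 values")
  expect_error(group_signal_comparison(list(a = rnorm(5))), "2 groups")
})
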