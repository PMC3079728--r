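test_that("expression strata pick the top and bottom quantiles", {
  set.seed(71)
  x <- sample(seq(1, 10, length.out = 100))  # 100 distinct intensities
  s <- select_expression_extremes(x)
  expect_equal(sum(s == "high"), 15)
  expect_equal(sum(s == "low"), 15)
  expect_true(all(x[s == "high"] > max(x[s == "mid"])))
  expect_true(all(x[s == "low"] < min(x[s == "mid"])))

  x20 <- rnorm(20)
  s20 <- select_expression_extremes(x20)
  expect_equal(sum(s20 == "high"), 3)
  expect_equal(sum(s20 == "low"), 3)

  expect_warning(sd <- select_expression_extremes(rep(1, 50)),
                 "degenerate")
  expect_true(all(is.na(sd)))
  expect_true(attr(sd, "degenerate"))
  expect_error(select_expression_extremes(rnorm(3)), "too few")
})

test_that("strata sizes and disjointness hold under ties", {
  set.seed(73)
  for (k in 1:40) {
    n <- sample(20:200, 1)
    x <- sample(round(rnorm(n), sample(0:2, 1)))  # induces ties
    s <- suppressWarnings(select_expression_extremes(x))
    if (isTRUE(attr(s, "degenerate"))) next
    q <- 0.15
    expect_gte(sum(s == "high"), floor(q * n))
    expect_gte(sum(s == "low"), floor(q * n))
    expect_equal(sum(s == "high" & s == "low"), 0)
  }
})

test_that("exon/intron summary is strand-aware and tiles the gene", {
  tr <- make_track(seq(0L, 400L, by = 20L), rep(1, 21), width = 10L)
  g <- make_gene(0L, 300L, "+", exon_starts = c(0L, 200L),
                 exon_ends = c(100L, 300L))
  s <- exon_intron_summary(g[1, ], tr)
  expect_equal(s$role[s$feature == "exon"], c("first_exon", "last_exon"))
  expect_equal(s$start[s$role == "first_exon"], 0L)
  intr <- s[s$feature == "intron", ]
  expect_equal(c(intr$start, intr$end), c(100L, 200L))

  gm <- make_gene(0L, 300L, "-", exon_starts = c(0L, 200L),
                  exon_ends = c(100L, 300L))
  sm <- exon_intron_summary(gm[1, ], tr)
  expect_equal(sm$start[sm$role == "first_exon"], 200L)

  g1 <- make_gene(0L, 300L, "+")
  s1 <- exon_intron_summary(g1[1, ], tr)
  expect_true(attr(s1, "single_exon"))
  expect_equal(sum(s1$feature == "intron"), 0)
  expect_equal(s1$role, "internal")
})

test_that("exons plus derived introns exactly tile the transcript", {
  set.seed(81)
  for (k in 1:60) {
    cfg <- NULL
    n_ex <- sample(2:8, 1)
    bounds <- sort(sample(1:998, 2 * n_ex - 2)) * 10L
    es <- c(0L, bounds[seq(2, length(bounds), by = 2)])
    ee <- c(bounds[seq(1, length(bounds), by = 2)], 10000L)
    g <- make_gene(0L, 10000L, sample(c("+", "-"), 1),
                   exon_starts = es, exon_ends = ee)
    ex <- genebodymarks:::exon_intervals(g[1, ])
    intr <- genebodymarks:::intron_intervals(g[1, ])
    segs <- rbind(ex[, c("start", "end")], intr[, c("start", "end")])
    segs <- segs[order(segs$start), ]
    expect_equal(segs$start[1], 0L)
    expect_equal(segs$end[nrow(segs)], 10000L)
    expect_true(all(segs$start[-1] == segs$end[-nrow(segs)]))
  }
})

test_that("coding exon summary intersects exons with the CDS", {
  tr <- make_track(seq(0L, 600L, by = 20L), rep(1, 31), width = 10L)
  # 5' UTR-only first exon: CDS begins in exon 2
  g <- make_gene(0L, 500L, "+", exon_starts = c(0L, 200L, 400L),
                 exon_ends = c(100L, 300L, 500L),
                 cds_start = 250L, cds_end = 450L)
  cs <- coding_exon_summary(g[1, ], tr)
  expect_equal(cs$start[cs$role == "first_coding_exon"], 250L)
  expect_equal(cs$end[cs$role == "first_coding_exon"], 300L)
  expect_equal(cs$ordinal[cs$role == "first_coding_exon"], 2L)
  expect_equal(cs$end[cs$role == "last_coding_exon"], 450L)

  # CDS within a single exon -> excluded
  g1 <- make_gene(0L, 500L, "+", exon_starts = c(0L, 200L),
                  exon_ends = c(100L, 500L),
                  cds_start = 250L, cds_end = 450L)
  expect_equal(nrow(coding_exon_summary(g1[1, ], tr)), 0)
  # non-coding gene -> excluded
  g2 <- make_gene(0L, 500L, "+", exon_starts = c(0L, 200L),
                  exon_ends = c(100L, 500L))
  expect_equal(nrow(coding_exon_summary(g2[1, ], tr)), 0)
  # CDS boundaries equal exon boundaries -> coding exons equal exons
  g3 <- make_gene(0L, 500L, "+", exon_starts = c(0L, 200L),
                  exon_ends = c(100L, 500L), cds_start = 0L,
                  cds_end = 500L)
  cs3 <- coding_exon_summary(g3[1, ], tr)
  expect_equal(cs3$start, c(0L, 200L))
  expect_equal(cs3$end, c(100L, 500L))
})

test_that("differential classification uses inclusive thresholds", {
  expr <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                     WT = c(5, 5, 5, 5, NA),
                     KO = c(5.5, 5.49, 4.5, 5.0, 6))
  d <- classify_differential(expr, "WT", "KO")
  expect_equal(d$status, c("up", "unchanged", "down", "unchanged", NA))
  expect_equal(d$delta[1], 0.5)
  expect_error(classify_differential(expr, "WT", "NOPE"), "condition")
})

test_that("expression-change vs CpG correlation behaves at the limits", {
  set.seed(91)
  n <- 2000
  cpg <- stats::setNames(runif(n, 1, 60), sprintf("g%04d", 1:n))
  delta0 <- stats::setNames(rnorm(n), names(cpg))
  r0 <- expression_change_vs_cpg(delta0, cpg)
  expect_lt(abs(r0$R), 0.05)  # null: |R| below ~1.96/sqrt(n)
  delta1 <- stats::setNames(-0.01 * cpg + rnorm(n, 0, 1e-6), names(cpg))
  r1 <- expression_change_vs_cpg(delta1, cpg)
  expect_lt(r1$R, -0.999)
  expect_error(expression_change_vs_cpg(delta0, cpg * 0 + 5), "constant")
  znf <- stats::setNames(rep(c(TRUE, FALSE), n / 2), names(cpg))
  expect_equal(sum(expression_change_vs_cpg(delta0, cpg, znf)$scatter$znf),
               n / 2)
})

test_that("boxplot export carries the five-number summary", {
  b <- boxplot_stats(c(1, 2, 3, 4, 100, NA))
  expect_equal(b$min, 1); expect_equal(b$max, 100); expect_equal(b$n, 5)
  expect_equal(b$median, 3)
  expect_equal(boxplot_stats(numeric(0))$n, 0)
})
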