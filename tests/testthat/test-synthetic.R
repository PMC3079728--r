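small_cfg <- function(n = 40, seed = 5, ...) {
  synthetic_config(n_genes = n, seed = seed, ...)
}

test_that("annotation simulation is fully deterministic", {
  g1 <- simulate_annotation(small_cfg())
  g2 <- simulate_annotation(small_cfg())
  expect_identical(g1, g2)
  g3 <- simulate_annotation(small_cfg(seed = 6))
  expect_false(identical(g1$tx_start, g3$tx_start))
})

test_that("class assignment follows the configured multinomial", {
  cfg <- synthetic_config(n_genes = 1000, seed = 17)
  g <- simulate_annotation(cfg)
  props <- vapply(cfg$classes, `[[`, 0, "proportion")
  counts <- table(factor(g$class, levels = names(props)))
  for (cl in names(props)) {
    expected <- 1000 * props[[cl]]
    sd3 <- 3 * sqrt(1000 * props[[cl]] * (1 - props[[cl]]))
    expect_lt(abs(counts[[cl]] - expected), sd3)
  }
})

test_that("ZNF-like genes satisfy the symbol labeling rule", {
  g <- simulate_annotation(small_cfg(n = 120))
  znf_cls <- g$class == "ZNF_LIKE"
  expect_true(all(grepl("^ZNF", g$symbol[znf_cls])))
  expect_false(any(grepl("^ZNF", g$symbol[!znf_cls])))
  expect_equal(is_znf(g), znf_cls)
  # structural sanity: genes ordered, non-overlapping, 2-12 exons
  expect_true(all(diff(g$tx_start) > 0))
  expect_true(all(g$tx_start[-1] >= g$tx_end[-nrow(g)]))
  expect_true(all(lengths(g$exon_starts) >= 2 &
                    lengths(g$exon_starts) <= 12))
})

test_that("simulated sequence realizes class CpG density targets", {
  cfg <- small_cfg(n = 50, seed = 23)
  g <- simulate_annotation(cfg)
  sq <- simulate_sequence(g, cfg)
  measured <- gene_body_cpg_density(g, sq$genome)
  # realized density within +/-15% of the drawn target (rounding only),
  # with an absolute floor for near-zero targets
  tol <- pmax(sq$targets$target * 0.15, 1)
  expect_true(all(abs(measured - sq$targets$target) <= tol))
  expect_equal(measured, sq$targets$realized, tolerance = 1e-9)
  # fixed seed -> identical FASTA
  sq2 <- simulate_sequence(g, cfg)
  expect_identical(as.character(sq$genome), as.character(sq2$genome))
})

test_that("a zero CpG target yields a CG-free gene body", {
  classes <- default_gene_classes()
  classes$ZNF_LIKE$body_cpg_per_kb <- c(0, 0)
  cfg <- small_cfg(n = 30, seed = 29, classes = classes)
  g <- simulate_annotation(cfg)
  sq <- simulate_sequence(g, cfg)
  znf <- which(g$class == "ZNF_LIKE")
  expect_true(length(znf) > 0)
  expect_true(all(gene_body_cpg_density(g, sq$genome)[znf] == 0))
})

test_that("noise-free tracks sit exactly at class target amplitudes", {
  cfg <- small_cfg(n = 30, seed = 31, noise_sd = 0)
  g <- simulate_annotation(cfg)
  trk <- simulate_tracks(g, cfg, "WT")
  i <- which(g$class == "METH_ACTIVE")[1]
  # interior body region avoiding the TSS-proximal promoter feature
  tss_off <- if (g$strand[i] == "+") 600L else 0L
  core <- region(g$chrom[i], g$tx_start[i] + tss_off,
                 g$tx_end[i] - (600L - tss_off), g$strand[i], "gene_body")
  expect_equal(unique(assign_probes(trk$MIRA, core)$value), 2)
  # upstream promoter window carries the promoter amplitude
  tss <- if (g$strand[i] == "+") g$tx_start[i] else g$tx_end[i]
  prom_up <- if (g$strand[i] == "+") {
    region(g$chrom[i], tss - 500L, tss, "+", "promoter")
  } else {
    region(g$chrom[i], tss, tss + 500L, "-", "promoter")
  }
  expect_equal(unique(assign_probes(trk$MIRA, prom_up)$value), -0.5)
  # ZNF-like gene bodies planted positive for both H3K9me3 and H3K36me3
  j <- which(g$class == "ZNF_LIKE")[1]
  tss_off <- if (g$strand[j] == "+") 600L else 0L
  corej <- region(g$chrom[j], g$tx_start[j] + tss_off,
                  g$tx_end[j] - (600L - tss_off), g$strand[j], "gene_body")
  expect_true(all(assign_probes(trk$H3K9me3, corej)$value > 1))
  expect_true(all(assign_probes(trk$H3K36me3, corej)$value > 1))
})

test_that("knockout condition applies the configured deltas", {
  cfg <- small_cfg(n = 40, seed = 37, noise_sd = 0)
  g <- simulate_annotation(cfg)
  wt <- simulate_tracks(g, cfg, "WT")
  ko <- simulate_tracks(g, cfg, "DKO")
  j <- which(g$class == "ZNF_LIKE")[1]
  tss_off <- if (g$strand[j] == "+") 600L else 0L
  core <- region(g$chrom[j], g$tx_start[j] + tss_off,
                 g$tx_end[j] - (600L - tss_off), g$strand[j], "gene_body")
  tss <- if (g$strand[j] == "+") g$tx_start[j] else g$tx_end[j]
  prom <- if (g$strand[j] == "+") {
    region(g$chrom[j], tss - 500L, tss, "+", "promoter")
  } else {
    region(g$chrom[j], tss, tss + 500L, "-", "promoter")
  }
  # body MIRA scaled x0.4; promoter MIRA set to baseline
  expect_equal(unique(assign_probes(ko$MIRA, core)$value),
               0.4 * unique(assign_probes(wt$MIRA, core)$value))
  expect_equal(unique(assign_probes(wt$MIRA, prom)$value), 1.5)
  expect_equal(unique(assign_probes(ko$MIRA, prom)$value), 0)
  # H3K9me3 amplitude x 0.3
  expect_equal(unique(assign_probes(ko$H3K9me3, core)$value),
               0.3 * unique(assign_probes(wt$H3K9me3, core)$value))
  expect_error(simulate_tracks(g, cfg, "NOPE"), "unknown condition")
})

test_that("expression simulation applies knockout deltas and is seeded", {
  cfg <- small_cfg(n = 200, seed = 41)
  g <- simulate_annotation(cfg)
  e1 <- simulate_expression(g, cfg)
  e2 <- simulate_expression(g, cfg)
  expect_identical(e1, e2)
  d <- classify_differential(e1$gene, "WT", "DKO")
  znf <- g$class == "ZNF_LIKE"
  # planted +0.8 with sd 0.1*sqrt(2): >= 95% recovered at delta 0.5
  expect_gte(mean(d$status[znf] == "up"), 0.95)
  # inert classes: false-positive rate near the Gaussian tail bound
  expect_lte(mean(d$status[!znf] != "unchanged"), 0.05)
  # exon rows consistent with gene models
  expect_equal(nrow(e1$exon), sum(lengths(g$exon_starts)))
})

test_that("planted promoter UMC/MIRA anticorrelation is recovered", {
  cfg <- small_cfg(n = 80, seed = 43)
  g <- simulate_annotation(cfg)
  trk <- simulate_tracks(g, cfg, "WT")
  prom <- coverage_table(g, trk[c("MIRA", "UMC")], region_role = "promoter")
  mira <- table_column(prom, "MIRA", "WT", "mean")
  umc <- table_column(prom, "UMC", "WT", "mean")
  r <- pearson_correlation(mira, umc)
  expect_lt(r$R, 0)
})

test_that("correlated body-mean generator recovers the planted rho", {
  d <- simulate_correlated_body_means(n = 800, rho = 0.4, seed = 99)
  r <- pearson_correlation(d$mira, d$h3k36me3)
  expect_lt(abs(r$R - 0.4), 0.1)
  d2 <- simulate_correlated_body_means(n = 800, rho = 0.4, seed = 99)
  expect_identical(d, d2)
})

test_that("bundle round-trips byte-identically through its own readers", {
  cfg <- small_cfg(n = 15, seed = 47)
  b <- simulate_bundle(cfg, sequence = TRUE)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(b, d1)
  write_fixture_bundle(b, d2)
  # determinism: identical config+seed => byte-identical files
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_true(validate_fixture_bundle(d1))
  rb <- read_fixture_bundle(d1)
  expect_equal(rb$genes$tx_start, b$genes$tx_start)
  expect_equal(rb$genes$exon_starts, b$genes$exon_starts)
  expect_equal(rb$genes$class, b$genes$class)
  expect_equal(rb$tracks$WT$MIRA$probes$value, b$tracks$WT$MIRA$probes$value)
  expect_equal(rb$expression$gene$WT, b$expression$gene$WT)
  # manifest records the seed
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, cfg$seed)
  # deleting a track invalidates the bundle
  unlink(file.path(d1, "MIRA_WT.bedgraph"))
  expect_error(validate_fixture_bundle(d1), "missing file")
})
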