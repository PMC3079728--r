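#!/usr/bin/env Rscript
# Gene-body coverage classification and mark co-occupancy on the
# flagship bundle: positive probes (log2 ratio > 1), marked genes
# (>= 20% positive coverage), pairwise co-occupancy contingency tables
# with chi-square tests, and the ZNF share of H3K9me3+H3K36me3
# dual-occupied genes. Run analysis/01_simulate.R first.

library(genebodymarks)

bundle <- read_fixture_bundle("scratch/bundle")
genes <- bundle$genes
params <- analysis_params()
tab <- coverage_table(genes, bundle$tracks$WT, params)
write.table(tab$summary, "results/02_coverage_WT.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

pairs <- list(c("MIRA", "H3K36me3"), c("H3K9me3", "H3K36me3"),
              c("MIRA", "H3K27me3"))
rows <- lapply(pairs, function(p) {
  a <- classify_marked_genes(tab, p[1], "WT")
  b <- classify_marked_genes(tab, p[2], "WT")
  cc <- cooccupancy_counts(a, b)
  ct <- suppressMessages(chi_square_test(cc$table))
  znf <- mean(is_znf(genes)[match(cc$genes_both, genes$gene_id)])
  message(sprintf(
    "%s ~ %s: both=%d only_%s=%d only_%s=%d neither=%d  chi2=%.1f (p=%.3g)  ZNF among dual: %.0f%%",
    p[1], p[2], cc$both, p[1], cc$only_a, p[2], cc$only_b, cc$neither,
    ct$statistic, ct$p, 100 * znf))
  data.frame(mark_a = p[1], mark_b = p[2], both = cc$both,
             only_a = cc$only_a, only_b = cc$only_b,
             neither = cc$neither, chi_square = ct$statistic,
             p = ct$p, dual_znf_fraction = znf)
})
write.table(do.call(rbind, rows), "results/02_cooccupancy.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

# gene-body and promoter signal correlations across genes
prom <- coverage_table(genes, bundle$tracks$WT[c("MIRA", "UMC")], params,
                       "promoter")
col <- function(t, mk, what) {
  s <- t$summary
  v <- s[[what]][s$mark == mk]
  v[s$n_probes[s$mark == mk] < params$min_probes_cor] <- NA_real_
  v
}
cors <- rbind(
  data.frame(pair = "body MIRA ~ H3K36me3",
             as.data.frame(pearson_correlation(col(tab, "MIRA", "mean"),
                                               col(tab, "H3K36me3", "mean")))),
  data.frame(pair = "body UMC ~ H3K36me3",
             as.data.frame(pearson_correlation(col(tab, "UMC", "mean"),
                                               col(tab, "H3K36me3", "mean")))),
  data.frame(pair = "promoter UMC ~ MIRA",
             as.data.frame(pearson_correlation(col(prom, "UMC", "mean"),
                                               col(prom, "MIRA", "mean"))))
)
write.table(cors, "results/02_correlations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("correlations:")
print(cors, row.names = FALSE)
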