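#!/usr/bin/env Rscript
# Expression analyses: wild-type vs DNMT double-knockout differential
# classification (|delta log2| >= 0.5), its association with gene-body
# CpG density, ZNF reactivation, and exon-level H3K36me3 stratified by
# expression (top/bottom 15% exons). Run analysis/01_simulate.R first.

library(genebodymarks)

bundle <- read_fixture_bundle("scratch/bundle")
genes <- bundle$genes
params <- analysis_params()

diff <- classify_differential(bundle$expression$gene, "WT", "DKO", params)
write.table(diff, "results/04_differential.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
znf <- is_znf(genes)
message(sprintf("up: %d, down: %d, unchanged: %d",
                sum(diff$status == "up"), sum(diff$status == "down"),
                sum(diff$status == "unchanged")))
message(sprintf("ZNF genes reactivated in DKO: %.1f%% (%d/%d)",
                100 * mean(diff$status[znf] == "up"),
                sum(diff$status[znf] == "up"), sum(znf)))

cpg <- gene_body_cpg_density(genes, bundle$genome, params)
assoc <- expression_change_vs_cpg(
  stats::setNames(diff$delta, diff$gene_id),
  stats::setNames(cpg, genes$gene_id),
  stats::setNames(znf, genes$gene_id))
write.table(assoc$scatter, "results/04_delta_vs_cpg.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
up <- diff$status == "up"
mw <- wilcox.test(cpg[up], cpg[!up], alternative = "less")
message(sprintf(
  "expression change vs body CpG density: R = %.3f (p = %.3g, n = %d)",
  assoc$R, assoc$p, assoc$n))
message(sprintf(
  "up-regulated genes sit at lower CpG density: one-sided MW p = %.3g",
  mw$p.value))

# exon-level H3K36me3 by expression stratum
ex <- bundle$expression$exon
ex$stratum <- select_expression_extremes(ex$WT, params)
sel <- ex[ex$stratum %in% c("high", "low"), ]
sig <- exon_mark_signal(genes, sel, bundle$tracks$WT$H3K36me3, params)
box <- do.call(rbind, lapply(c("high", "low"), function(s) {
  data.frame(stratum = s,
             as.data.frame(boxplot_stats(sig$mark_mean[sig$stratum == s])))
}))
write.table(box, "results/04_exon_k36_by_stratum.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("exon H3K36me3 by expression stratum:")
print(box, row.names = FALSE)
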