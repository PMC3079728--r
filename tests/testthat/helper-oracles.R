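# Independent brute-force oracles and small fixture builders shared
# across the suite. Oracles deliberately avoid the package's code paths.

# count CpG dinucleotides by scanning every index position
oracle_cpg_count <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 2) return(0L)
  sum(vapply(seq_len(n - 1L),
             function(i) substr(s, i, i + 1L) == "CG", logical(1)))
}

# O(n) probe-in-region scan by midpoint
oracle_assign <- function(probes, start, end) {
  mid <- (probes$start + probes$end) %/% 2L
  which(mid >= start & mid < end)
}

# closed-form Pearson chi-square statistic
oracle_chisq_stat <- function(t) {
  E <- outer(rowSums(t), colSums(t)) / sum(t)
  sum((t - E)^2 / E)
}

# two-tailed Fisher exact p by full hypergeometric enumeration with
# explicit log-factorials (probability-mass rule)
oracle_fisher_p <- function(t) {
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- sum(t)
  lp <- function(x) {
    # log P(table with [1,1]=x | margins), via multinomial counting
    lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(c2 - r1 + x)
  }
  xs <- max(0L, r1 - c2):min(r1, c1)
  probs <- exp(vapply(xs, lp, numeric(1)))
  obs <- probs[match(a, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# per-base bin slot for a probe midpoint, by direct closed-form offset
# arithmetic over the genomic windows (left-remainder layout, full
# reversal for minus strand) — independent of gene_bins()
oracle_slot <- function(mid, tx_start, tx_end, strand,
                        n_body = 20L, n_flank = 10L, flank = 5000L) {
  seg_bin <- function(off, len, n) {
    w <- len %/% n; r <- len %% n
    ifelse(off < r * (w + 1L), off %/% (w + 1L),
           r + (off - r * (w + 1L)) %/% max(w, 1L))
  }
  L <- tx_end - tx_start
  slot <- rep(NA_integer_, length(mid))
  in_up <- mid >= tx_start - flank & mid < tx_start
  in_body <- mid >= tx_start & mid < tx_end
  in_down <- mid >= tx_end & mid < tx_end + flank
  slot[in_up] <- seg_bin(mid[in_up] - (tx_start - flank), flank, n_flank)
  slot[in_body] <- n_flank + seg_bin(mid[in_body] - tx_start, L, n_body)
  slot[in_down] <- n_flank + n_body +
    seg_bin(mid[in_down] - tx_end, flank, n_flank)
  total <- n_body + 2L * n_flank
  if (strand == "-") slot <- ifelse(is.na(slot), NA_integer_,
                                    total - 1L - slot)
  slot + 1L  # 1-based slots
}

# implementation-side slot lookup through gene_bins(): locate the row
# whose [start, end) contains the midpoint
impl_slot <- function(mid, gene, params = analysis_params()) {
  bins <- gene_bins(gene, params)
  g <- bins[order(bins$start), ]
  i <- findInterval(mid, g$start)
  slot <- rep(NA_integer_, length(mid))
  ok <- i >= 1 & i <= nrow(g)
  ok[ok] <- mid[ok] < g$end[i[ok]]
  slot[ok] <- g$slot[i[ok]]
  slot
}

# quick single-gene constructor
make_gene <- function(tx_start = 10000L, tx_end = 20000L, strand = "+",
                      chrom = "chr1", gene_id = "G1", symbol = gene_id,
                      exon_starts = NULL, exon_ends = NULL,
                      cds_start = NA_integer_, cds_end = NA_integer_) {
  if (is.null(exon_starts)) {
    exon_starts <- tx_start
    exon_ends <- tx_end
  }
  gene_models(gene_id = gene_id, symbol = symbol, chrom = chrom,
              strand = strand, tx_start = tx_start, tx_end = tx_end,
              cds_start = cds_start, cds_end = cds_end,
              exon_starts = list(exon_starts), exon_ends = list(exon_ends))
}

# track from explicit probe starts/values (fixed 50 bp probes)
make_track <- function(starts, values, chrom = "chr1", width = 50L,
                       mark = "MIRA", condition = "WT") {
  signal_track(data.frame(chrom = chrom, start = starts,
                          end = starts + width, value = values),
               mark = mark, condition = condition)
}
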