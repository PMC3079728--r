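#' Read an expression table
#'
#' Tab-delimited with a header row of condition names. Gene-level tables
#' have an id column `gene_id`; exon-level tables additionally carry
#' `exon_id`, `gene_id` and `exon_ordinal` (1-based, transcriptional
#' order).
#'
#' @param path File path.
#' @param level "gene" or "exon".
#' @return Data frame of log2 intensities with id columns first.
#' @export
read_expression_table <- function(path, level = c("gene", "exon")) {
  level <- match.arg(level)
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- if (level == "gene") "gene_id" else
    c("exon_id", "gene_id", "exon_ordinal")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  }
  value_cols <- setdiff(names(df), need)
  if (!length(value_cols)) stop(sprintf("%s: no condition columns", path))
  for (cc in value_cols) {
    if (!is.numeric(df[[cc]])) {
      stop(sprintf("%s: non-numeric intensities in column '%s'", path, cc))
    }
  }
  df
}

#' Assign high/low expression strata to exons
#'
#' The top and bottom `exon_quantile` (default 15%) of the log2
#' intensity distribution, by order statistics: with k =
#' ceiling(q * n), the low stratum is intensity <= k-th smallest and the
#' high stratum intensity >= k-th largest, ties at a threshold included
#' on the extreme side; everything else is "mid". When the two
#' thresholds collide (e.g. all intensities equal) the distribution is
#' degenerate and no strata are assigned.
#'
#' @param intensity Numeric vector of log2 intensities (one condition).
#' @param params [analysis_params].
#' @return Character vector ("high"/"low"/"mid", or NA when degenerate)
#'   with attribute `degenerate`.
#' @export
select_expression_extremes <- function(intensity,
                                       params = analysis_params()) {
  params <- as_params(params)
  q <- params$exon_quantile
  n <- sum(is.finite(intensity))
  if (n < ceiling(1 / q)) {
    stop(sprintf("too few exons (%d) for quantile %g", n, q))
  }
  k <- ceiling(q * n)
  s <- sort(intensity[is.finite(intensity)])
  lo_thr <- s[k]
  hi_thr <- s[n - k + 1L]
  if (lo_thr >= hi_thr) {
    warning("degenerate intensity distribution: strata not assigned")
    out <- rep(NA_character_, length(intensity))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- rep("mid", length(intensity))
  out[!is.finite(intensity)] <- NA_character_
  out[is.finite(intensity) & intensity <= lo_thr] <- "low"
  out[is.finite(intensity) & intensity >= hi_thr] <- "high"
  attr(out, "degenerate") <- FALSE
  out
}

# exon/intron coordinate helpers -------------------------------------------

# Exons of one gene in transcriptional order with ordinals; introns are
# the gaps between consecutive exons.
exon_intervals <- function(gene) {
  g <- as.list(gene)
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  df <- data.frame(start = es, end = ee)
  if (g$strand == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  df$ordinal <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

intron_intervals <- function(gene) {
  g <- as.list(gene)
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  if (length(es) < 2) {
    return(data.frame(start = integer(0), end = integer(0),
                      ordinal = integer(0)))
  }
  df <- data.frame(start = ee[-length(ee)], end = es[-1])
  df <- df[df$end > df$start, , drop = FALSE]
  if (g$strand == "-") df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  df$ordinal <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

feature_mean <- function(track, gene, start, end, params) {
  r <- region(as.list(gene)$chrom, start, end, as.list(gene)$strand, "exon")
  v <- assign_probes(track, r, params)$value
  list(n = length(v), mean = if (length(v)) mean(v) else NA_real_)
}

#' Exon and intron mark summary for one gene
#'
#' Mean probe signal (midpoint membership) in each exon and intron.
#' "First"/"last" are transcriptional: the first exon of a minus-strand
#' gene is the rightmost. Single-exon genes yield only one exon row
#' (role "internal", `single_exon` attribute set) and no introns.
#'
#' @param gene One gene-model row.
#' @param track [signal_track].
#' @param params [analysis_params].
#' @return Data frame: gene_id, feature, ordinal, role, start, end,
#'   n_probes, mean.
#' @export
exon_intron_summary <- function(gene, track, params = analysis_params()) {
  params <- as_params(params)
  g <- as.list(gene)
  ex <- exon_intervals(gene)
  multi <- nrow(ex) >= 2
  rows <- lapply(seq_len(nrow(ex)), function(i) {
    fm <- feature_mean(track, gene, ex$start[i], ex$end[i], params)
    role <- if (!multi) "internal"
      else if (i == 1) "first_exon"
      else if (i == nrow(ex)) "last_exon"
      else "internal"
    data.frame(gene_id = g$gene_id, feature = "exon", ordinal = ex$ordinal[i],
               role = role, start = ex$start[i], end = ex$end[i],
               n_probes = fm$n, mean = fm$mean, stringsAsFactors = FALSE)
  })
  intr <- intron_intervals(gene)
  rows <- c(rows, lapply(seq_len(nrow(intr)), function(i) {
    fm <- feature_mean(track, gene, intr$start[i], intr$end[i], params)
    data.frame(gene_id = g$gene_id, feature = "intron",
               ordinal = intr$ordinal[i], role = "intron",
               start = intr$start[i], end = intr$end[i],
               n_probes = fm$n, mean = fm$mean, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "single_exon") <- !multi
  out
}

#' First and last coding exon mark summary
#'
#' Coding exons are the exons intersected with the CDS interval; genes
#' without a CDS or with fewer than two CDS-overlapping exons are
#' skipped (empty result). First/last are transcriptional.
#'
#' @inheritParams exon_intron_summary
#' @return Data frame with rows for first_coding_exon and
#'   last_coding_exon (possibly empty).
#' @export
coding_exon_summary <- function(gene, track, params = analysis_params()) {
  params <- as_params(params)
  g <- as.list(gene)
  empty <- data.frame(gene_id = character(0), feature = character(0),
                      ordinal = integer(0), role = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), mean = numeric(0))
  if (is.na(g$cds_start)) return(empty)
  ex <- exon_intervals(gene)
  cs <- pmax(ex$start, g$cds_start)
  ce <- pmin(ex$end, g$cds_end)
  keep <- ce > cs
  if (sum(keep) < 2) return(empty)
  cod <- data.frame(start = cs[keep], end = ce[keep],
                    ordinal = ex$ordinal[keep])
  pick <- c(1L, nrow(cod))
  roles <- c("first_coding_exon", "last_coding_exon")
  out <- do.call(rbind, lapply(seq_along(pick), function(j) {
    i <- pick[j]
    fm <- feature_mean(track, gene, cod$start[i], cod$end[i], params)
    data.frame(gene_id = g$gene_id, feature = "coding_exon",
               ordinal = cod$ordinal[i], role = roles[j],
               start = cod$start[i], end = cod$end[i],
               n_probes = fm$n, mean = fm$mean, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean mark signal per exon from an exon expression table
#'
#' Joins exon rows (gene_id + exon_ordinal, transcriptional order) to
#' their genomic intervals and computes each exon's mean probe signal.
#'
#' @param genes [gene_models].
#' @param exon_table Data frame with `gene_id` and `exon_ordinal`.
#' @param track [signal_track].
#' @param params [analysis_params].
#' @return `exon_table` with `n_probes` and `mark_mean` columns added.
#' @export
exon_mark_signal <- function(genes, exon_table, track,
                             params = analysis_params()) {
  params <- as_params(params)
  gi <- match(exon_table$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("exon table references unknown gene_id")
  n <- integer(nrow(exon_table)); mu <- rep(NA_real_, nrow(exon_table))
  for (k in seq_len(nrow(exon_table))) {
    ex <- exon_intervals(genes[gi[k], ])
    o <- exon_table$exon_ordinal[k]
    if (o > nrow(ex)) stop(sprintf("gene '%s': exon ordinal %d out of range",
                                   exon_table$gene_id[k], o))
    fm <- feature_mean(track, genes[gi[k], ], ex$start[o], ex$end[o], params)
    n[k] <- fm$n; mu[k] <- fm$mean
  }
  exon_table$n_probes <- n
  exon_table$mark_mean <- mu
  exon_table
}

#' Classify differential expression between two conditions
#'
#' Delta = log2(condition b) - log2(condition a); "up" when delta >=
#' `diff_log2` (inclusive), "down" when delta <= -`diff_log2`, else
#' "unchanged". Genes missing either value get NA status.
#'
#' @param expr Gene-level expression data frame ([read_expression_table]).
#' @param cond_a,cond_b Column names (reference and comparison).
#' @param params [analysis_params].
#' @return Data frame: gene_id, delta, status.
#' @export
classify_differential <- function(expr, cond_a, cond_b,
                                  params = analysis_params()) {
  params <- as_params(params)
  for (cc in c(cond_a, cond_b)) {
    if (!cc %in% names(expr)) stop(sprintf("condition '%s' not in table", cc))
  }
  delta <- expr[[cond_b]] - expr[[cond_a]]
  status <- ifelse(!is.finite(delta), NA_character_,
                   ifelse(delta >= params$diff_log2, "up",
                          ifelse(delta <= -params$diff_log2, "down",
                                 "unchanged")))
  data.frame(gene_id = expr$gene_id, delta = delta, status = status,
             stringsAsFactors = FALSE)
}

#' Expression change versus gene-body CpG density
#'
#' Pearson correlation between per-gene expression deltas and body CpG
#' density, with a scatter table flagging ZNF-labeled genes.
#'
#' @param delta Named (gene_id) numeric vector of expression deltas.
#' @param cpg Named numeric vector of body CpG densities per kb.
#' @param znf Optional named logical vector of ZNF labels.
#' @return List with `R`, `p`, `n`, and `scatter` (gene_id, delta, cpg,
#'   znf).
#' @export
expression_change_vs_cpg <- function(delta, cpg, znf = NULL) {
  ids <- intersect(names(delta), names(cpg))
  if (!length(ids)) stop("no shared gene ids between delta and cpg")
  d <- delta[ids]; cd <- cpg[ids]
  ct <- pearson_correlation(cd, d)
  scatter <- data.frame(gene_id = ids, delta = unname(d), cpg = unname(cd),
                        znf = if (is.null(znf)) FALSE else
                          unname(znf[ids]) %in% TRUE,
                        stringsAsFactors = FALSE)
  list(R = ct$R, p = ct$p, n = ct$n, scatter = scatter)
}

#' Five-number boxplot statistics
#' @param values Numeric vector (NA dropped).
#' @return List: min, q1, median, q3, max, n.
#' @export
boxplot_stats <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v)) return(list(min = NA_real_, q1 = NA_real_,
                              median = NA_real_, q3 = NA_real_,
                              max = NA_real_, n = 0L))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
       n = length(v))
}
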