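#' Build the genes x marks coverage table
#'
#' For each gene and each supplied track, summarises the probes assigned
#' to one analysis region (gene body by default): probe count, mean log2
#' ratio, and positive-probe coverage fraction (probes with log2 ratio
#' strictly greater than `theta_pos`). Genes without probes for a mark
#' carry NA summaries and are excluded from that mark's classification
#' denominator downstream.
#'
#' @param genes A [gene_models] data frame.
#' @param tracks List of [signal_track] objects.
#' @param params [analysis_params].
#' @param region_role Which derived region to summarise: "gene_body",
#'   "promoter", "upstream_flank" or "downstream_flank".
#' @return A `mark_coverage_table`: list with `summary` (long data frame:
#'   gene_id, mark, condition, n_probes, mean, coverage) and `genes`
#'   (per-gene metadata).
#' @export
coverage_table <- function(genes, tracks, params = analysis_params(),
                           region_role = "gene_body") {
  params <- as_params(params)
  regs <- lapply(seq_len(nrow(genes)), function(i) {
    suppressWarnings(derive_regions(genes[i, ], params))[[region_role]]
  })
  summ <- do.call(rbind, lapply(tracks, function(tr) {
    n <- integer(nrow(genes)); mu <- numeric(nrow(genes))
    cov <- numeric(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      v <- assign_probes(tr, regs[[i]], params)$value
      n[i] <- length(v)
      mu[i] <- if (length(v) >= params$min_probes) mean(v) else NA_real_
      cov[i] <- if (length(v)) mean(v > params$theta_pos) else NA_real_
    }
    data.frame(gene_id = genes$gene_id, mark = tr$mark,
               condition = tr$condition, n_probes = n, mean = mu,
               coverage = cov, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  meta <- data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
                     chrom = genes$chrom, strand = genes$strand,
                     length = genes$tx_end - genes$tx_start,
                     znf = is_znf(genes), stringsAsFactors = FALSE)
  structure(list(summary = summ, genes = meta, region_role = region_role,
                 params = params),
            class = "mark_coverage_table")
}

#' @export
print.mark_coverage_table <- function(x, ...) {
  cat(sprintf("mark_coverage_table: %d genes x %d track(s) over %s\n",
              nrow(x$genes),
              nrow(unique(x$summary[, c("mark", "condition")])),
              x$region_role))
  invisible(x)
}

# Extract one (mark, condition) column as a named vector.
table_column <- function(table, mark, condition, what) {
  s <- table$summary
  sel <- s$mark == mark
  if (!is.null(condition)) sel <- sel & s$condition == condition
  if (!any(sel)) {
    stop(sprintf("mark '%s'%s not present in coverage table", mark,
                 if (is.null(condition)) "" else
                   sprintf(" (condition '%s')", condition)))
  }
  stats::setNames(s[[what]][sel], s$gene_id[sel])
}

#' Classify genes as marked
#'
#' A gene is marked when its positive-probe coverage is at or above
#' `theta_cov` (inclusive, default 20%). Genes with missing coverage
#' (no probes) are unmarked and flagged excluded via the `excluded`
#' attribute; callers drop them from classification denominators.
#'
#' @param table A [coverage_table] result.
#' @param mark Mark name; must be present in the table.
#' @param condition Optional condition filter (needed when the table
#'   holds several conditions of the same mark).
#' @param params [analysis_params].
#' @return Named logical vector over genes with attribute `excluded`.
#' @export
classify_marked_genes <- function(table, mark, condition = NULL,
                                  params = NULL) {
  params <- if (is.null(params)) table$params else as_params(params)
  cov <- table_column(table, mark, condition, "coverage")
  excluded <- is.na(cov)
  marked <- !excluded & cov >= params$theta_cov
  attr(marked, "excluded") <- excluded
  marked
}

#' Co-occupancy counts for two marks
#'
#' Counts genes marked by only A, only B, both, or neither, over the
#' shared universe (genes excluded for either mark are dropped from
#' both), and builds the 2x2 contingency table (rows = mark A status,
#' columns = mark B status).
#'
#' @param marked_a,marked_b Named logical vectors from
#'   [classify_marked_genes] over the same gene universe.
#' @return List with `only_a`, `only_b`, `both`, `neither`, `n_universe`,
#'   `table` (2x2 matrix) and `genes_both` (ids of dual-marked genes).
#' @export
cooccupancy_counts <- function(marked_a, marked_b) {
  if (length(marked_a) != length(marked_b) ||
      !identical(names(marked_a), names(marked_b))) {
    stop("cooccupancy_counts: gene universes differ")
  }
  drop <- attr_or(marked_a, "excluded") | attr_or(marked_b, "excluded")
  a <- marked_a[!drop]; b <- marked_b[!drop]
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(mark_a = c("marked", "unmarked"),
                                mark_b = c("marked", "unmarked")))
  list(only_a = sum(a & !b), only_b = sum(!a & b), both = sum(a & b),
       neither = sum(!a & !b), n_universe = length(a), table = tab,
       genes_both = names(a)[a & b])
}

attr_or <- function(x, which) {
  a <- attr(x, which)
  if (is.null(a)) rep(FALSE, length(x)) else a
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction, df = (r-1)(c-1), p
#' from the upper tail of the chi-square distribution. Tables with a
#' zero row or column margin are rejected with a pointer to the Fisher
#' exact test; when any expected cell is below 5 a recommendation to use
#' the exact test is attached.
#'
#' @param t Matrix of non-negative integer counts.
#' @return List with `statistic`, `df`, `p`, `expected` and
#'   `recommend_fisher`.
#' @export
chi_square_test <- function(t) {
  t <- as.matrix(t)
  if (any(t < 0) || sum(t) < 1) stop("counts must be non-negative, total >= 1")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("zero row/column margin: use fisher_exact_test")
  }
  res <- suppressWarnings(stats::chisq.test(t, correct = FALSE))
  rec <- any(res$expected < 5)
  if (rec) message("expected cell < 5: Fisher exact test recommended")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected, recommend_fisher = rec)
}

#' Fisher exact test (2x2, two-tailed)
#'
#' Two-tailed p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within
#' relative tolerance 1e-7). Other two-sided conventions can differ in
#' the third decimal.
#'
#' @param t 2x2 matrix of non-negative integer counts.
#' @return List with `p_two_tailed`.
#' @export
fisher_exact_test <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2))) stop("fisher_exact_test requires a 2x2 table")
  if (any(t < 0) || sum(t) < 1) stop("counts must be non-negative, total >= 1")
  list(p_two_tailed = stats::fisher.test(t)$p.value)
}

#' Pearson correlation with t-test p-value
#'
#' Pairs with a missing value in either vector are dropped; requires at
#' least 3 complete pairs and non-constant vectors. p is two-sided from
#' the t distribution with n-2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors (e.g. per-gene mean signals).
#' @return List with `R`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Pairwise group comparison with multiplicity correction
#'
#' All pairwise two-sided Mann-Whitney U (Wilcoxon rank-sum) tests
#' between the supplied groups, Bonferroni-corrected over the number of
#' pairs.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 finite values).
#' @return Data frame: group_a, group_b, n_a, n_b, statistic, p_raw,
#'   p_bonferroni.
#' @export
group_signal_comparison <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
  nm <- names(groups)
  if (is.null(nm) || any(!nzchar(nm))) nm <- paste0("group", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    wt <- suppressWarnings(stats::wilcox.test(groups[[i]], groups[[j]],
                                              alternative = "two.sided"))
    data.frame(group_a = nm[i], group_b = nm[j],
               n_a = length(groups[[i]]), n_b = length(groups[[j]]),
               statistic = unname(wt$statistic), p_raw = wt$p.value,
               stringsAsFactors = FALSE)
  }))
  out$p_bonferroni <- pmin(1, out$p_raw * ncol(pairs))
  out
}
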