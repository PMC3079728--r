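#' Bin boundaries for one gene
#'
#' Partitions the gene body into `n_body_bins` near-equal bins and each
#' flank window (`flank_bp` 5' of the TSS and 3' of the transcript end)
#' into `n_flank_bins` bins. Bins are laid out in genomic space, left to
#' right, with any remainder bases distributed one per bin from the
#' leftmost bin; for minus-strand genes the complete row order is then
#' reversed so that row 1 is always the 5'-most bin. Computing in
#' genomic space and reversing makes strand reversal flip the profile
#' vector exactly. Flank bins extending past chromosome position 0 are
#' clipped (possibly to empty).
#'
#' @param gene One gene-model row.
#' @param params [analysis_params].
#' @return Data frame with columns `slot` (1..total bins), `section`
#'   (upstream/body/downstream), `start`, `end` (genomic, clipped).
#' @export
gene_bins <- function(gene, params = analysis_params()) {
  params <- as_params(params)
  g <- as.list(gene)
  L <- g$tx_end - g$tx_start
  if (L < params$n_body_bins) {
    stop(sprintf("gene '%s': length %d shorter than %d body bins",
                 g$gene_id, L, params$n_body_bins))
  }
  # genomic-space layout, remainder bases one-per-bin from the left
  lay <- function(win_lo, win_hi, n) {
    len <- win_hi - win_lo
    w <- rep(len %/% n, n)
    r <- len %% n
    if (r > 0) w[seq_len(r)] <- w[seq_len(r)] + 1L
    ends <- win_lo + cumsum(w)
    data.frame(start = ends - w, end = ends)
  }
  F <- params$flank_bp
  bins <- rbind(lay(g$tx_start - F, g$tx_start, params$n_flank_bins),
                lay(g$tx_start, g$tx_end, params$n_body_bins),
                lay(g$tx_end, g$tx_end + F, params$n_flank_bins))
  bins$section <- rep(c("left_flank", "body", "right_flank"),
                      c(params$n_flank_bins, params$n_body_bins,
                        params$n_flank_bins))
  if (g$strand == "-") bins <- bins[rev(seq_len(nrow(bins))), , drop = FALSE]
  bins$section <- c(left_flank = "upstream", body = "body",
                    right_flank = "downstream")[bins$section]
  if (g$strand == "-") {
    bins$section[bins$section == "upstream"] <- "tmp"
    bins$section[bins$section == "downstream"] <- "upstream"
    bins$section[bins$section == "tmp"] <- "downstream"
  }
  bins$slot <- seq_len(nrow(bins))
  rownames(bins) <- NULL
  # clip at chromosome origin
  bins$start <- pmax(0L, bins$start)
  bins$end <- pmax(bins$start, bins$end)
  bins[, c("slot", "section", "start", "end")]
}

#' Strand-oriented binned profile of one gene
#'
#' Mean probe log2 ratio per bin (probe membership by midpoint,
#' length-unweighted mean), over the 10 + 20 + 10 default bin layout.
#' Index 1 is always the 5'-most bin; minus-strand genes are therefore
#' reported reversed relative to genomic order. Bins without probes are
#' NA, never 0.
#'
#' @param gene One gene-model row.
#' @param track [signal_track].
#' @param params [analysis_params].
#' @return A `bin_profile` list: gene_id, mark, condition, bins (numeric
#'   vector), n_probes (integer vector), layout (the [gene_bins] frame).
#' @export
bin_gene_profile <- function(gene, track, params = analysis_params()) {
  params <- as_params(params)
  g <- as.list(gene)
  bins <- gene_bins(gene, params)
  vals <- rep(NA_real_, nrow(bins))
  n <- integer(nrow(bins))
  for (i in seq_len(nrow(bins))) {
    rows <- probe_rows_in(track, g$chrom, bins$start[i], bins$end[i])
    n[i] <- length(rows)
    if (length(rows)) vals[i] <- mean(track$probes$value[rows])
  }
  structure(list(gene_id = g$gene_id, mark = track$mark,
                 condition = track$condition, bins = vals, n_probes = n,
                 layout = bins),
            class = "bin_profile")
}

#' Binned profiles for many genes as a matrix
#'
#' @param genes [gene_models].
#' @param track [signal_track].
#' @param params [analysis_params].
#' @return List with `values` (genes x bins matrix, NA for empty bins),
#'   `n` (probe counts), rownames = gene_id.
#' @export
bin_profile_matrix <- function(genes, track, params = analysis_params()) {
  params <- as_params(params)
  nb <- params$n_body_bins + 2L * params$n_flank_bins
  values <- matrix(NA_real_, nrow(genes), nb,
                   dimnames = list(genes$gene_id, NULL))
  n <- matrix(0L, nrow(genes), nb, dimnames = list(genes$gene_id, NULL))
  for (i in seq_len(nrow(genes))) {
    bp <- bin_gene_profile(genes[i, ], track, params)
    values[i, ] <- bp$bins
    n[i, ] <- bp$n_probes
  }
  list(values = values, n = n, mark = track$mark, condition = track$condition)
}

#' Composite (metagene) profile of a gene group
#'
#' Per-bin mean over genes with a defined value in that bin; bins a gene
#' is missing are excluded from both numerator and denominator. Reports
#' per-bin contributing gene counts and standard errors.
#'
#' @param profiles Either a list of `bin_profile` objects (same mark,
#'   condition and layout) or the result of [bin_profile_matrix].
#' @param group Optional character vector of gene_ids to average over
#'   (default: all genes present).
#' @return A `composite_profile` data frame: slot, mean, n, se.
#' @export
composite_profile <- function(profiles, group = NULL) {
  if (is.list(profiles) && !is.null(profiles$values)) {
    mat <- profiles$values
  } else {
    if (!length(profiles)) stop("empty profile list")
    marks <- unique(vapply(profiles, `[[`, "", "mark"))
    conds <- unique(vapply(profiles, `[[`, "", "condition"))
    if (length(marks) > 1 || length(conds) > 1) {
      stop("profiles mix marks or conditions")
    }
    mat <- do.call(rbind, lapply(profiles, `[[`, "bins"))
    rownames(mat) <- vapply(profiles, `[[`, "", "gene_id")
  }
  if (!is.null(group)) {
    keep <- rownames(mat) %in% group
    if (!any(keep)) stop("empty group: no profiled gene matches")
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) == 0) stop("empty group")
  n <- colSums(!is.na(mat))
  mu <- ifelse(n > 0, colMeans(mat, na.rm = TRUE), NA_real_)
  sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
  se <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
  out <- data.frame(slot = seq_len(ncol(mat)), mean = mu, n = n, se = se)
  class(out) <- c("composite_profile", "data.frame")
  out
}

#' Clustered multi-mark profile matrix
#'
#' Concatenates per-mark bin matrices column-wise, imputes missing bins
#' with the column mean for distance computation only, and orders genes
#' by average-linkage hierarchical clustering on Euclidean distance.
#' Rows are pre-sorted by gene_id so leaf order is deterministic under
#' input permutation. Genes missing every bin are dropped with a
#' warning. Returned values are the original (non-imputed) bins.
#'
#' @param mats List of [bin_profile_matrix] results (same genes).
#' @return List with `values` (reordered genes x concatenated bins),
#'   `order` (gene_ids in leaf order), `hclust` (the tree).
#' @export
cluster_profile_matrix <- function(mats) {
  mat <- do.call(cbind, lapply(mats, function(m) {
    v <- m$values
    colnames(v) <- paste0(m$mark, ".", seq_len(ncol(v)))
    v
  }))
  if (nrow(mat) < 2) stop("need at least 2 genes to cluster")
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  all_na <- rowSums(!is.na(mat)) == 0
  if (any(all_na)) {
    warning(sprintf("%d gene(s) with all-missing profiles dropped",
                    sum(all_na)))
    mat <- mat[!all_na, , drop = FALSE]
  }
  imp <- mat
  cm <- colMeans(imp, na.rm = TRUE)
  cm[!is.finite(cm)] <- 0
  for (j in seq_len(ncol(imp))) {
    nas <- is.na(imp[, j])
    if (any(nas)) imp[nas, j] <- cm[j]
  }
  hc <- stats::hclust(stats::dist(imp, method = "euclidean"),
                      method = "average")
  ord <- hc$order
  list(values = mat[ord, , drop = FALSE], order = rownames(mat)[ord],
       hclust = hc)
}

#' Center and saturate a profile matrix for display
#'
#' Heatmap scaling: per-mark centering at a reference level (typically
#' the chromosome-wide mean probe signal of that mark's track) with
#' symmetric saturation. Display-only; never feeds statistics.
#'
#' @param mat Genes x bins matrix for one mark.
#' @param center Reference level to subtract (default: chromosome-wide
#'   mean is supplied by the caller; fallback is the matrix mean).
#' @param saturate Clip at +/- this value on the log2 scale.
#' @return Centered, clipped matrix.
#' @export
scale_profile_display <- function(mat, center = NULL, saturate = 2) {
  if (is.null(center)) center <- mean(mat, na.rm = TRUE)
  pmin(pmax(mat - center, -saturate), saturate)
}
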