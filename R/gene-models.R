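#' Gene model tables
#'
#' Gene models are held in a data frame with one row per transcript and
#' columns `gene_id`, `symbol`, `chrom`, `strand`, `tx_start`, `tx_end`,
#' `cds_start`, `cds_end` (NA for non-coding records), plus list-columns
#' `exon_starts`, `exon_ends` (sorted integer vectors) and `labels`
#' (character vectors, e.g. "ZNF"). All coordinates are 0-based,
#' half-open (BED convention); refFlat input already uses this convention
#' and BED12 block offsets are resolved on read. Transcripts are kept
#' per-record (RefSeq style), not collapsed by symbol.
#'
#' @param gene_id,symbol,chrom Character vectors.
#' @param strand "+" or "-".
#' @param tx_start,tx_end Transcript span.
#' @param cds_start,cds_end CDS span or NA.
#' @param exon_starts,exon_ends Lists of integer vectors.
#' @param labels List of character vectors (default: empty).
#' @return A `gene_models` data frame.
#' @export
gene_models <- function(gene_id, symbol, chrom, strand, tx_start, tx_end,
                        cds_start = NA_integer_, cds_end = NA_integer_,
                        exon_starts, exon_ends, labels = NULL) {
  n <- length(gene_id)
  if (is.null(labels)) labels <- rep(list(character(0)), n)
  gm <- data.frame(
    gene_id = as.character(gene_id),
    symbol = as.character(symbol),
    chrom = as.character(chrom),
    strand = as.character(strand),
    tx_start = as.integer(tx_start),
    tx_end = as.integer(tx_end),
    cds_start = as.integer(rep_len(cds_start, n)),
    cds_end = as.integer(rep_len(cds_end, n)),
    stringsAsFactors = FALSE
  )
  gm$exon_starts <- lapply(exon_starts, as.integer)
  gm$exon_ends <- lapply(exon_ends, as.integer)
  gm$labels <- labels
  class(gm) <- c("gene_models", "data.frame")
  validate_gene_models(gm)
  gm
}

validate_gene_models <- function(gm) {
  if (!all(gm$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  bad <- which(gm$tx_start >= gm$tx_end)
  if (length(bad)) {
    stop(sprintf("transcript '%s': tx_start >= tx_end", gm$gene_id[bad[1]]))
  }
  for (i in seq_len(nrow(gm))) {
    es <- gm$exon_starts[[i]]; ee <- gm$exon_ends[[i]]
    if (length(es) != length(ee) || length(es) == 0L) {
      stop(sprintf("transcript '%s': exon start/end lists malformed",
                   gm$gene_id[i]))
    }
    if (any(es >= ee)) {
      stop(sprintf("transcript '%s': empty or inverted exon", gm$gene_id[i]))
    }
    if (is.unsorted(es, strictly = TRUE) && length(es) > 1L) {
      stop(sprintf("transcript '%s': exons not sorted", gm$gene_id[i]))
    }
    if (length(es) > 1L && any(es[-1] < ee[-length(ee)])) {
      stop(sprintf("transcript '%s': overlapping exons", gm$gene_id[i]))
    }
    if (es[1] < gm$tx_start[i] || ee[length(ee)] > gm$tx_end[i]) {
      stop(sprintf("transcript '%s': exon outside transcript span",
                   gm$gene_id[i]))
    }
    cs <- gm$cds_start[i]; ce <- gm$cds_end[i]
    if (!is.na(cs) && (cs < gm$tx_start[i] || ce > gm$tx_end[i] || cs >= ce)) {
      stop(sprintf("transcript '%s': CDS outside transcript span",
                   gm$gene_id[i]))
    }
  }
  invisible(gm)
}

#' Read gene models from BED12 or refFlat
#'
#' BED12 blocks become exons (offsets resolved to absolute coordinates);
#' `thickStart == thickEnd` and refFlat `cdsStart == cdsEnd` both denote a
#' non-coding record (CDS absent). Malformed lines abort with the
#' offending line number.
#'
#' @param path Path to the annotation file (tab-delimited, no header).
#' @param format "bed12" or "refflat".
#' @return A [gene_models] data frame, one row per transcript.
#' @export
read_gene_models <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("no records in %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- if (format == "bed12") 12L else 11L
  recs <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < nfield) {
      stop(sprintf("%s line %d: expected %d fields, found %d",
                   format, i, nfield, length(f)))
    }
    recs[[i]] <- parse_gene_record(f, format, i)
  }
  gm <- gene_models(
    gene_id = vapply(recs, `[[`, "", "gene_id"),
    symbol = vapply(recs, `[[`, "", "symbol"),
    chrom = vapply(recs, `[[`, "", "chrom"),
    strand = vapply(recs, `[[`, "", "strand"),
    tx_start = vapply(recs, `[[`, 0L, "tx_start"),
    tx_end = vapply(recs, `[[`, 0L, "tx_end"),
    cds_start = vapply(recs, `[[`, NA_integer_, "cds_start"),
    cds_end = vapply(recs, `[[`, NA_integer_, "cds_end"),
    exon_starts = lapply(recs, `[[`, "exon_starts"),
    exon_ends = lapply(recs, `[[`, "exon_ends")
  )
  gm
}

parse_gene_record <- function(f, format, lineno) {
  int_or_fail <- function(x, what) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) {
      stop(sprintf("%s line %d: non-integer %s ('%s')",
                   format, lineno, what, paste(x[is.na(v)], collapse = ",")))
    }
    v
  }
  if (format == "bed12") {
    start <- int_or_fail(f[2], "chromStart")
    end <- int_or_fail(f[3], "chromEnd")
    strand <- f[6]
    thick_s <- int_or_fail(f[7], "thickStart")
    thick_e <- int_or_fail(f[8], "thickEnd")
    n_blk <- int_or_fail(f[10], "blockCount")
    sizes <- int_or_fail(strsplit(f[11], ",")[[1]][seq_len(n_blk)], "blockSizes")
    offs <- int_or_fail(strsplit(f[12], ",")[[1]][seq_len(n_blk)], "blockStarts")
    es <- start + offs
    list(gene_id = f[4], symbol = f[4], chrom = f[1], strand = strand,
         tx_start = start, tx_end = end,
         cds_start = if (thick_s == thick_e) NA_integer_ else thick_s,
         cds_end = if (thick_s == thick_e) NA_integer_ else thick_e,
         exon_starts = es, exon_ends = es + sizes)
  } else {
    # refFlat: geneName name chrom strand txStart txEnd cdsStart cdsEnd
    #          exonCount exonStarts exonEnds
    tx_s <- int_or_fail(f[5], "txStart")
    tx_e <- int_or_fail(f[6], "txEnd")
    cds_s <- int_or_fail(f[7], "cdsStart")
    cds_e <- int_or_fail(f[8], "cdsEnd")
    n_ex <- int_or_fail(f[9], "exonCount")
    es <- int_or_fail(strsplit(f[10], ",")[[1]][seq_len(n_ex)], "exonStarts")
    ee <- int_or_fail(strsplit(f[11], ",")[[1]][seq_len(n_ex)], "exonEnds")
    list(gene_id = f[2], symbol = f[1], chrom = f[3], strand = f[4],
         tx_start = tx_s, tx_end = tx_e,
         cds_start = if (cds_s == cds_e) NA_integer_ else cds_s,
         cds_end = if (cds_s == cds_e) NA_integer_ else cds_e,
         exon_starts = es, exon_ends = ee)
  }
}

#' Label zinc-finger (ZNF) genes
#'
#' A gene receives the "ZNF" label when its symbol matches
#' `znf_pattern` (default: starts with "ZNF", case-sensitive) or appears
#' in `override`. Existing labels are preserved.
#'
#' @param genes A [gene_models] data frame.
#' @param znf_pattern Regular expression applied to `symbol`.
#' @param override Optional character vector of symbols to label
#'   regardless of the pattern.
#' @return `genes` with the `labels` list-column updated.
#' @export
label_gene_class <- function(genes, znf_pattern = "^ZNF", override = NULL) {
  stopifnot(all(nzchar(genes$symbol)))
  hit <- grepl(znf_pattern, genes$symbol) | genes$symbol %in% override
  genes$labels <- mapply(function(lab, h) {
    if (h) union(lab, "ZNF") else lab
  }, genes$labels, hit, SIMPLIFY = FALSE)
  genes
}

#' @rdname label_gene_class
#' @export
is_znf <- function(genes) {
  vapply(genes$labels, function(l) "ZNF" %in% l, logical(1))
}
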