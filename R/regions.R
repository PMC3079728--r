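#' Genomic analysis regions
#'
#' A region is a 0-based half-open interval with a strand and a role. The
#' constructor permits empty regions (start == end) so clipped flanks can
#' be represented; all other code treats an empty region as "no probes".
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates, start <= end.
#' @param strand "+" or "-".
#' @param role One of promoter, gene_body, upstream_flank,
#'   downstream_flank, exon, intron.
#' @return A `region` list.
#' @export
region <- function(chrom, start, end, strand = "+",
                   role = c("gene_body", "promoter", "upstream_flank",
                            "downstream_flank", "exon", "intron")) {
  role <- match.arg(role)
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(start <= end, strand %in% c("+", "-"))
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand, role = role),
            class = "region")
}

region_length <- function(r) r$end - r$start

#' Derive analysis regions for one gene
#'
#' The gene body is the full transcribed span (TSS to transcript end).
#' The promoter extends `promoter_up` bp upstream and `promoter_down` bp
#' downstream of the TSS in transcriptional orientation; for minus-strand
#' genes the TSS is `tx_end` and all orientations mirror. Flanks cover
#' `flank_bp` immediately 5' of the TSS and 3' of the transcript end.
#' Regions are clipped at chromosome position 0; a flank fully clipped
#' away is returned empty with a warning.
#'
#' @param gene One row of a [gene_models] data frame (data frame or list).
#' @param params [analysis_params].
#' @return Named list of [region] objects: gene_body, promoter,
#'   upstream_flank, downstream_flank.
#' @export
derive_regions <- function(gene, params = analysis_params()) {
  params <- as_params(params)
  g <- as.list(gene)
  s <- g$tx_start; e <- g$tx_end
  clip <- function(lo, hi, role) {
    lo2 <- max(0L, lo); hi2 <- max(lo2, hi)
    if (hi2 <= lo2 && hi > lo) {
      warning(sprintf("gene '%s': %s clipped to empty region", g$gene_id, role))
    }
    region(g$chrom, lo2, hi2, g$strand, role)
  }
  if (g$strand == "+") {
    list(
      gene_body = region(g$chrom, s, e, "+", "gene_body"),
      promoter = clip(s - params$promoter_up, s + params$promoter_down,
                      "promoter"),
      upstream_flank = clip(s - params$flank_bp, s, "upstream_flank"),
      downstream_flank = clip(e, e + params$flank_bp, "downstream_flank")
    )
  } else {
    list(
      gene_body = region(g$chrom, s, e, "-", "gene_body"),
      promoter = clip(e - params$promoter_down, e + params$promoter_up,
                      "promoter"),
      upstream_flank = clip(e, e + params$flank_bp, "upstream_flank"),
      downstream_flank = clip(s - params$flank_bp, s, "downstream_flank")
    )
  }
}

#' CpG density of a region
#'
#' Counts CpG dinucleotides in `sequence` and scales to counts per
#' `cpg_scale` bp (default 1 kb). CpG is self-complementary, so the
#' density is strand-independent. Case-insensitive; overlapping matches
#' cannot occur for a dinucleotide.
#'
#' @param sequence DNA string (character or Biostrings::DNAString) for
#'   the region.
#' @param region Optional [region]; when given, its length must equal
#'   `nchar(sequence)`.
#' @param params [analysis_params] (uses `cpg_scale`).
#' @return CpG count per `cpg_scale` bp.
#' @export
cpg_density <- function(sequence, region = NULL, params = analysis_params()) {
  params <- as_params(params)
  seq_chr <- toupper(as.character(sequence))
  len <- nchar(seq_chr)
  if (len == 0L) stop("cpg_density: zero-length sequence")
  if (!is.null(region) && region_length(region) != len) {
    stop(sprintf("cpg_density: sequence length %d != region length %d",
                 len, region_length(region)))
  }
  if (grepl("[^ACGTN]", seq_chr)) stop("cpg_density: non-ACGTN character")
  n_cpg <- Biostrings::countPattern("CG", Biostrings::DNAString(seq_chr))
  n_cpg / len * params$cpg_scale
}

#' Gene-body CpG density for a set of genes
#'
#' @param genes A [gene_models] data frame.
#' @param genome A named Biostrings::DNAStringSet or path to a FASTA file.
#' @param params [analysis_params].
#' @return Numeric vector of per-gene body CpG densities (per
#'   `cpg_scale` bp), in `genes` order.
#' @export
gene_body_cpg_density <- function(genes, genome, params = analysis_params()) {
  params <- as_params(params)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(genes$chrom), names(genome))
  if (length(missing_chr)) {
    stop(sprintf("chromosome(s) absent from genome: %s",
                 paste(missing_chr, collapse = ", ")))
  }
  vapply(seq_len(nrow(genes)), function(i) {
    body <- Biostrings::subseq(genome[[genes$chrom[i]]],
                               start = genes$tx_start[i] + 1L,
                               end = genes$tx_end[i])
    n_cpg <- Biostrings::countPattern("CG", body)
    n_cpg / length(body) * params$cpg_scale
  }, numeric(1))
}

#' Write per-gene regions as BED6
#'
#' One line per (gene, role); the BED name field is `<gene_id>|<role>`.
#'
#' @param genes [gene_models].
#' @param path Output file.
#' @param params [analysis_params].
#' @return Invisibly, the path.
#' @export
write_region_bed <- function(genes, path, params = analysis_params()) {
  params <- as_params(params)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    regs <- suppressWarnings(derive_regions(genes[i, ], params))
    do.call(rbind, lapply(regs, function(r) {
      data.frame(chrom = r$chrom, start = r$start, end = r$end,
                 name = paste0(genes$gene_id[i], "|", r$role),
                 score = 0L, strand = r$strand)
    }))
  })
  bed <- do.call(rbind, rows)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
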