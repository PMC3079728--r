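#' Write gene models as refFlat
#' @param genes [gene_models].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_refflat <- function(genes, path) {
  cds_s <- ifelse(is.na(genes$cds_start), genes$tx_end, genes$cds_start)
  cds_e <- ifelse(is.na(genes$cds_end), genes$tx_end, genes$cds_end)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$symbol[i], genes$gene_id[i], genes$chrom[i],
          genes$strand[i], genes$tx_start[i], genes$tx_end[i],
          cds_s[i], cds_e[i], length(genes$exon_starts[[i]]),
          paste0(paste(genes$exon_starts[[i]], collapse = ","), ","),
          paste0(paste(genes$exon_ends[[i]], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as BED12
#' @inheritParams write_refflat
#' @return Invisibly, the path.
#' @export
write_bed12 <- function(genes, path) {
  thick_s <- ifelse(is.na(genes$cds_start), genes$tx_start, genes$cds_start)
  thick_e <- ifelse(is.na(genes$cds_end), genes$tx_start, genes$cds_end)
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    paste(genes$chrom[i], genes$tx_start[i], genes$tx_end[i],
          genes$gene_id[i], 0L, genes$strand[i], thick_s[i], thick_e[i],
          "0", length(es),
          paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_fasta_indexed <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(genome, path, width = width)
  # .fai: name, length, byte offset of first base, bases/line, bytes/line
  offsets <- cumsum(c(0L, utils::head(
    nchar(names(genome)) + 2L +  # ">name\n"
      Biostrings::width(genome) +
      ceiling(Biostrings::width(genome) / width), -1)))
  fai <- data.frame(name = names(genome),
                    len = Biostrings::width(genome),
                    offset = offsets + nchar(names(genome)) + 2L,
                    linebases = width, linewidth = width + 1L)
  data.table::fwrite(fai, paste0(path, ".fai"), sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write a synthetic bundle to disk
#'
#' Emits the generated chromosome as standard files: FASTA (+ .fai),
#' refFlat and BED12 annotation, one bedGraph per (mark, condition),
#' gene- and exon-level expression TSVs, and a JSON manifest recording
#' the configuration, the seed and every emitted file.
#'
#' @param bundle Result of [simulate_bundle].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_fixture_bundle <- function(bundle, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2) != 0) {
    stop(sprintf("cannot write to directory: %s", outdir))
  }
  files <- list(annotation_refflat = "genes.refflat",
                annotation_bed12 = "genes.bed")
  write_refflat(bundle$genes, file.path(outdir, "genes.refflat"))
  write_bed12(bundle$genes, file.path(outdir, "genes.bed"))
  if (!is.null(bundle$genome)) {
    write_fasta_indexed(bundle$genome, file.path(outdir, "genome.fa"))
    files$genome <- "genome.fa"
  }
  classes <- file.path(outdir, "gene_classes.tsv")
  data.table::fwrite(data.frame(gene_id = bundle$genes$gene_id,
                                class = bundle$genes$class),
                     classes, sep = "\t")
  files$gene_classes <- "gene_classes.tsv"
  files$tracks <- list()
  for (cond in names(bundle$tracks)) {
    for (mk in names(bundle$tracks[[cond]])) {
      fn <- sprintf("%s_%s.bedgraph", mk, cond)
      write_signal_track(bundle$tracks[[cond]][[mk]],
                         file.path(outdir, fn))
      files$tracks[[mk]][[cond]] <- fn
    }
  }
  data.table::fwrite(bundle$expression$gene,
                     file.path(outdir, "expression_gene.tsv"), sep = "\t")
  data.table::fwrite(bundle$expression$exon,
                     file.path(outdir, "expression_exon.tsv"), sep = "\t")
  files$expression_gene <- "expression_gene.tsv"
  files$expression_exon <- "expression_exon.tsv"
  cfg <- bundle$config
  cfg$classes <- lapply(cfg$classes, unclass)
  manifest <- list(seed = bundle$config$seed, config = unclass(cfg),
                   files = files)
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

manifest_files <- function(manifest) {
  f <- manifest$files
  unlist(c(f[setdiff(names(f), "tracks")],
           unlist(f$tracks, use.names = FALSE)), use.names = FALSE)
}

#' Validate a bundle directory against its manifest
#'
#' @param dir Bundle directory containing `manifest.json`.
#' @return TRUE invisibly; errors if the manifest or any listed file is
#'   missing.
#' @export
validate_fixture_bundle <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::read_json(mpath)
  missing <- Filter(function(f) !file.exists(file.path(dir, f)),
                    manifest_files(manifest))
  if (length(missing)) {
    stop(sprintf("bundle %s: missing file(s): %s", dir,
                 paste(unlist(missing), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a bundle back through the standard readers
#'
#' @param dir Bundle directory.
#' @return List: genes (with `class` column), tracks (condition -> mark
#'   -> [signal_track]), expression (gene/exon), genome path (if
#'   present), manifest.
#' @export
read_fixture_bundle <- function(dir) {
  validate_fixture_bundle(dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  genes <- read_gene_models(file.path(dir, manifest$files$annotation_refflat),
                            "refflat")
  cls <- data.table::fread(file.path(dir, manifest$files$gene_classes),
                           data.table = FALSE)
  genes$class <- cls$class[match(genes$gene_id, cls$gene_id)]
  genes <- label_gene_class(genes)
  tracks <- list()
  for (mk in names(manifest$files$tracks)) {
    for (cond in names(manifest$files$tracks[[mk]])) {
      tracks[[cond]][[mk]] <- read_signal_track(
        file.path(dir, manifest$files$tracks[[mk]][[cond]]),
        "bedgraph", mark = mk, condition = cond)
    }
  }
  expr <- list(
    gene = read_expression_table(
      file.path(dir, manifest$files$expression_gene), "gene"),
    exon = read_expression_table(
      file.path(dir, manifest$files$expression_exon), "exon")
  )
  genome <- if (!is.null(manifest$files$genome)) {
    file.path(dir, manifest$files$genome)
  }
  list(genes = genes, tracks = tracks, expression = expr,
       genome = genome, manifest = manifest)
}
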