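#' Analysis run configuration
#'
#' @param annotation Path to the gene-model file.
#' @param annotation_format "refflat" or "bed12".
#' @param tracks Nested named list: mark -> condition -> bedGraph path.
#' @param genome Optional FASTA path (enables CpG-density analyses).
#' @param expression Optional list(gene = path, exon = path).
#' @param condition_pair Optional c(reference, comparison) for
#'   differential analysis (defaults to the first two conditions).
#' @param cooccupancy_pairs List of mark pairs to cross-tabulate
#'   (default: MIRA~H3K36me3 and H3K9me3~H3K36me3 where present).
#' @param params [analysis_params] (NULL for defaults).
#' @param outdir Output directory; NULL suppresses file output.
#' @param znf_override Optional symbols to force-label as ZNF.
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, annotation_format = "refflat",
                       tracks = list(), genome = NULL, expression = NULL,
                       condition_pair = NULL,
                       cooccupancy_pairs = NULL, params = NULL,
                       outdir = NULL, znf_override = NULL) {
  structure(list(annotation = annotation,
                 annotation_format = annotation_format,
                 tracks = tracks, genome = genome,
                 expression = expression,
                 condition_pair = condition_pair,
                 cooccupancy_pairs = cooccupancy_pairs,
                 params = params, outdir = outdir,
                 znf_override = znf_override),
            class = "run_config")
}

#' @rdname run_config
#' @param dir A bundle directory written by [write_fixture_bundle].
#' @param ... Passed on to [run_config].
#' @export
run_config_from_bundle <- function(dir, ...) {
  validate_fixture_bundle(dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  tracks <- lapply(manifest$files$tracks, function(conds) {
    lapply(conds, function(f) file.path(dir, f))
  })
  run_config(
    annotation = file.path(dir, manifest$files$annotation_refflat),
    annotation_format = "refflat",
    tracks = tracks,
    genome = if (!is.null(manifest$files$genome)) {
      file.path(dir, manifest$files$genome)
    },
    expression = list(
      gene = file.path(dir, manifest$files$expression_gene),
      exon = file.path(dir, manifest$files$expression_exon)
    ),
    ...
  )
}

#' Validate a run configuration
#'
#' Checks file existence, parameter ranges and a light format sniff of
#' every referenced file; all problems are collected and returned at
#' once rather than failing on the first.
#'
#' @param config [run_config].
#' @return Character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  chk_file <- function(path, what) {
    if (is.null(path)) return(FALSE)
    if (!is.character(path) || !file.exists(path)) {
      add(sprintf("%s: file not found: %s", what, as.character(path)))
      return(FALSE)
    }
    TRUE
  }
  if (chk_file(config$annotation, "annotation")) {
    if (!config$annotation_format %in% c("refflat", "bed12")) {
      add(sprintf("unknown annotation format '%s'",
                  config$annotation_format))
    }
  }
  if (!length(config$tracks)) add("no signal tracks configured")
  for (mk in names(config$tracks)) {
    for (cond in names(config$tracks[[mk]])) {
      path <- config$tracks[[mk]][[cond]]
      if (chk_file(path, sprintf("track %s/%s", mk, cond))) {
        ln <- readLines(path, n = 50)
        ln <- ln[!grepl("^(#|track|browser)", ln) & nzchar(ln)]
        if (length(ln)) {
          f <- strsplit(ln[1], "\t")[[1]]
          if (length(f) < 4 ||
              is.na(suppressWarnings(as.numeric(f[4])))) {
            add(sprintf("track %s/%s: %s line 1: not 4-column numeric bedGraph",
                        mk, cond, path))
          }
        }
      }
    }
  }
  chk_file(config$genome, "genome")
  if (!is.null(config$expression)) {
    chk_file(config$expression$gene, "gene expression")
    chk_file(config$expression$exon, "exon expression")
  }
  if (!is.null(config$params)) {
    perr <- tryCatch({ as_params(config$params); NULL },
                     error = function(e) conditionMessage(e))
    if (!is.null(perr)) add(sprintf("params: %s", perr))
  }
  errs
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis
#'
#' Orchestrates: annotation parsing and ZNF labeling; CpG density (when
#' a genome is supplied); per-condition gene-body and promoter coverage
#' tables; mark classification and co-occupancy with chi-square tests;
#' gene-body and promoter signal correlations; composite profiles of
#' co-occupied groups; differential expression between the condition
#' pair, its association with body CpG density, and exon-level
#' expression strata. Stage errors abort naming the stage. Results are
#' written under `outdir` (TSV + report.json) when configured and
#' returned invisibly.
#'
#' @param config [run_config].
#' @return An `analysis_report` list.
#' @export
run_full_analysis <- function(config) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop(paste(c("invalid configuration:", errs), collapse = "\n  "))
  }
  params <- as_params(config$params)
  log_msg <- function(...) message(sprintf(...))

  genes <- stage("annotations", {
    g <- read_gene_models(config$annotation, config$annotation_format)
    label_gene_class(g, override = config$znf_override)
  })
  log_msg("annotations: %d transcripts, %d ZNF-labeled",
          nrow(genes), sum(is_znf(genes)))

  cpg <- NULL
  if (!is.null(config$genome)) {
    cpg <- stage("cpg_density", {
      stats::setNames(gene_body_cpg_density(genes, config$genome, params),
                      genes$gene_id)
    })
  }

  tracks <- stage("signal_io", {
    lapply(config$tracks, function(conds) {
      out <- lapply(names(conds), function(cond) {
        read_signal_track(conds[[cond]], "bedgraph",
                          mark = NA, condition = cond)
      })
      stats::setNames(out, names(conds))
    })
  })
  for (mk in names(tracks)) {
    for (cond in names(tracks[[mk]])) tracks[[mk]][[cond]]$mark <- mk
  }
  conditions <- unique(unlist(lapply(tracks, names)))
  marks <- names(tracks)

  by_cond <- function(cond) {
    Filter(Negate(is.null), lapply(tracks, function(t) t[[cond]]))
  }

  cov_tables <- stage("occupancy", {
    out <- lapply(conditions, function(cond) {
      coverage_table(genes, by_cond(cond), params, "gene_body")
    })
    stats::setNames(out, conditions)
  })
  prom_tables <- stage("occupancy_promoter", {
    out <- lapply(conditions, function(cond) {
      coverage_table(genes, by_cond(cond), params, "promoter")
    })
    stats::setNames(out, conditions)
  })

  ref_cond <- conditions[1]
  pairs <- config$cooccupancy_pairs
  if (is.null(pairs)) {
    pairs <- Filter(function(p) all(p %in% marks),
                    list(c("MIRA", "H3K36me3"), c("H3K9me3", "H3K36me3"),
                         c("MIRA", "H3K27me3")))
  }
  cooc <- stage("cooccupancy", lapply(pairs, function(p) {
    ma <- classify_marked_genes(cov_tables[[ref_cond]], p[1], ref_cond)
    mb <- classify_marked_genes(cov_tables[[ref_cond]], p[2], ref_cond)
    cc <- cooccupancy_counts(ma, mb)
    test <- tryCatch(chi_square_test(cc$table), error = function(e) NULL)
    znf <- is_znf(genes)[match(cc$genes_both, genes$gene_id)]
    list(mark_a = p[1], mark_b = p[2], counts = cc, chi_square = test,
         both_znf_fraction = if (length(znf)) mean(znf) else NA_real_)
  }))
  for (cc in cooc) {
    log_msg("cooccupancy %s~%s: universe %d, both %d (ZNF %.0f%%)",
            cc$mark_a, cc$mark_b, cc$counts$n_universe, cc$counts$both,
            100 * cc$both_znf_fraction)
  }

  body_mean <- function(mark) {
    m <- table_column(cov_tables[[ref_cond]], mark, ref_cond, "mean")
    n <- table_column(cov_tables[[ref_cond]], mark, ref_cond, "n_probes")
    m[n < params$min_probes_cor] <- NA_real_
    m
  }
  prom_mean <- function(mark) {
    m <- table_column(prom_tables[[ref_cond]], mark, ref_cond, "mean")
    n <- table_column(prom_tables[[ref_cond]], mark, ref_cond, "n_probes")
    m[n < params$min_probes_cor] <- NA_real_
    m
  }
  correlations <- stage("correlations", {
    out <- list()
    try_cor <- function(x, y) tryCatch(pearson_correlation(x, y),
                                       error = function(e) NULL)
    if (all(c("MIRA", "H3K36me3") %in% marks)) {
      out$body_mira_vs_h3k36me3 <- try_cor(body_mean("MIRA"),
                                           body_mean("H3K36me3"))
    }
    if (all(c("UMC", "H3K36me3") %in% marks)) {
      out$body_umc_vs_h3k36me3 <- try_cor(body_mean("UMC"),
                                          body_mean("H3K36me3"))
    }
    if (all(c("UMC", "MIRA") %in% marks)) {
      out$promoter_umc_vs_mira <- try_cor(prom_mean("UMC"),
                                          prom_mean("MIRA"))
    }
    out
  })

  profiles <- stage("profiles", {
    mats <- lapply(marks, function(mk) {
      bin_profile_matrix(genes, tracks[[mk]][[ref_cond]], params)
    })
    names(mats) <- marks
    composites <- lapply(cooc, function(cc) {
      grp <- cc$counts$genes_both
      if (!length(grp)) return(NULL)
      out <- lapply(mats, composite_profile, group = grp)
      names(out) <- marks
      list(group = sprintf("%s+%s", cc$mark_a, cc$mark_b),
           n_genes = length(grp), profiles = out)
    })
    clustered <- if (nrow(genes) >= 2) cluster_profile_matrix(mats)
    list(matrices = mats, composites = Filter(Negate(is.null), composites),
         clustered = clustered)
  })

  differential <- NULL
  exon_strata <- NULL
  if (!is.null(config$expression)) {
    expr_gene <- stage("expression_io", {
      read_expression_table(config$expression$gene, "gene")
    })
    cp <- config$condition_pair
    if (is.null(cp)) {
      vc <- setdiff(names(expr_gene), "gene_id")
      if (length(vc) >= 2) cp <- vc[1:2]
    }
    if (!is.null(cp)) {
      differential <- stage("differential", {
        d <- classify_differential(expr_gene, cp[1], cp[2], params)
        res <- list(conditions = cp, table = d,
                    n_up = sum(d$status == "up", na.rm = TRUE),
                    n_down = sum(d$status == "down", na.rm = TRUE))
        if (!is.null(cpg)) {
          delta <- stats::setNames(d$delta, d$gene_id)
          res$delta_vs_cpg <- tryCatch(
            expression_change_vs_cpg(delta, cpg,
                                     stats::setNames(is_znf(genes),
                                                     genes$gene_id)),
            error = function(e) NULL)
        }
        res
      })
      log_msg("differential %s -> %s: %d up, %d down",
              cp[1], cp[2], differential$n_up, differential$n_down)
    }
    if (!is.null(config$expression$exon)) {
      exon_strata <- stage("exon_strata", {
        ex <- read_expression_table(config$expression$exon, "exon")
        strata <- select_expression_extremes(ex[[ref_cond]], params)
        ex$stratum <- strata
        summary_marks <- intersect(c("H3K36me3", "MIRA", "H3K9me3"), marks)
        sig <- lapply(summary_marks, function(mk) {
          s <- exon_mark_signal(genes, ex, tracks[[mk]][[ref_cond]], params)
          list(mark = mk,
               high = boxplot_stats(s$mark_mean[s$stratum %in% "high"]),
               low = boxplot_stats(s$mark_mean[s$stratum %in% "low"]),
               mean_high = mean(s$mark_mean[s$stratum %in% "high"],
                                na.rm = TRUE),
               mean_low = mean(s$mark_mean[s$stratum %in% "low"],
                               na.rm = TRUE))
        })
        list(table = ex, signals = stats::setNames(sig, summary_marks))
      })
    }
  }

  report <- structure(
    list(genes = genes, cpg = cpg, coverage = cov_tables,
         promoter_coverage = prom_tables, cooccupancy = cooc,
         correlations = correlations, profiles = profiles,
         differential = differential, exon_strata = exon_strata,
         provenance = list(
           package_version = as.character(utils::packageVersion("genebodymarks")),
           config_hash = config_hash(config),
           reference_condition = ref_cond,
           n_genes = nrow(genes))),
    class = "analysis_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  invisible(report)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveable <- config
  saveable$params <- if (is.null(config$params)) NULL else
    unclass(config$params)
  jsonlite::write_json(unclass(saveable), tmp, auto_unbox = TRUE,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Write an analysis report to disk
#'
#' TSV tables for coverage, correlations, composites, differential calls
#' and exon strata, plus a JSON summary (`report.json`) of the numeric
#' results and provenance.
#'
#' @param report [run_full_analysis] result.
#' @param outdir Directory (created if needed).
#' @return Invisibly, the report.json path.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (cond in names(report$coverage)) {
    data.table::fwrite(report$coverage[[cond]]$summary,
                       file.path(outdir, sprintf("coverage_%s.tsv", cond)),
                       sep = "\t")
  }
  if (!is.null(report$cpg)) {
    data.table::fwrite(data.frame(gene_id = names(report$cpg),
                                  cpg_per_kb = unname(report$cpg)),
                       file.path(outdir, "cpg_density.tsv"), sep = "\t")
  }
  for (comp in report$profiles$composites) {
    for (mk in names(comp$profiles)) {
      data.table::fwrite(comp$profiles[[mk]],
                         file.path(outdir, sprintf("composite_%s_%s.tsv",
                                                   gsub("[^A-Za-z0-9]+", "_",
                                                        comp$group), mk)),
                         sep = "\t")
    }
  }
  if (!is.null(report$differential)) {
    data.table::fwrite(report$differential$table,
                       file.path(outdir, "differential.tsv"), sep = "\t")
    if (!is.null(report$differential$delta_vs_cpg)) {
      data.table::fwrite(report$differential$delta_vs_cpg$scatter,
                         file.path(outdir, "delta_vs_cpg.tsv"), sep = "\t")
    }
  }
  if (!is.null(report$exon_strata)) {
    data.table::fwrite(report$exon_strata$table,
                       file.path(outdir, "exon_strata.tsv"), sep = "\t")
  }
  summary <- list(
    provenance = report$provenance,
    cooccupancy = lapply(report$cooccupancy, function(cc) {
      list(mark_a = cc$mark_a, mark_b = cc$mark_b,
           only_a = cc$counts$only_a, only_b = cc$counts$only_b,
           both = cc$counts$both, neither = cc$counts$neither,
           chi_square_p = if (!is.null(cc$chi_square)) cc$chi_square$p,
           both_znf_fraction = cc$both_znf_fraction)
    }),
    correlations = lapply(report$correlations, function(x) {
      x[c("R", "p", "n")]
    }),
    differential = if (!is.null(report$differential)) {
      list(conditions = report$differential$conditions,
           n_up = report$differential$n_up,
           n_down = report$differential$n_down,
           delta_vs_cpg = if (!is.null(report$differential$delta_vs_cpg)) {
             report$differential$delta_vs_cpg[c("R", "p", "n")]
           })
    },
    exon_signals = if (!is.null(report$exon_strata)) {
      lapply(report$exon_strata$signals, function(s) {
        s[c("mark", "mean_high", "mean_low")]
      })
    }
  )
  path <- file.path(outdir, "report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report: %d genes, %d condition(s), %d mark(s)\n",
              x$provenance$n_genes, length(x$coverage),
              length(x$profiles$matrices)))
  for (cc in x$cooccupancy) {
    cat(sprintf("  %s~%s: both=%d only_a=%d only_b=%d neither=%d\n",
                cc$mark_a, cc$mark_b, cc$counts$both, cc$counts$only_a,
                cc$counts$only_b, cc$counts$neither))
  }
  invisible(x)
}
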