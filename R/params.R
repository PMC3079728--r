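#' Analysis parameters
#'
#' Bundles the thresholds and geometry constants used throughout the
#' pipeline. Defaults follow the operational definitions used for
#' chromosome-scale tiling-array analysis of intragenic marks: a probe is
#' "positive" when its log2 enrichment ratio exceeds 1; a gene carries a
#' mark when at least 20% of its gene-body probes are positive; composite
#' profiles use 20 gene-body bins flanked by 10 bins over 5 kb on each
#' side; the promoter is the transcription start site +/- 500 bp; CpG
#' density is reported per kilobase; exon expression strata take the top
#' and bottom 15%; differential expression uses |delta log2| >= 0.5.
#'
#' @param theta_pos Positivity threshold on the probe log2 ratio
#'   (strictly greater-than).
#' @param theta_cov Coverage fraction at or above which a gene counts as
#'   marked (inclusive).
#' @param n_body_bins Number of equal-sized bins partitioning the gene body.
#' @param n_flank_bins Number of bins for each 5' and 3' flank.
#' @param flank_bp Flank width in bp on each side of the transcript.
#' @param promoter_up,promoter_down Promoter extent upstream/downstream of
#'   the TSS, in bp (transcriptional orientation).
#' @param cpg_scale Length scale for CpG density (bp per reported unit).
#' @param exon_quantile Fraction defining the high/low exon expression
#'   strata.
#' @param diff_log2 Absolute log2 expression change at or above which a
#'   gene is called up/down regulated.
#' @param min_probes Minimum probes per region for a signal summary to be
#'   defined.
#' @param min_probes_cor Minimum probes per region for a gene to enter
#'   correlation analyses.
#' @param probe_assign Probe-to-region membership rule: "midpoint"
#'   (default) or "any_overlap".
#'
#' @return An object of class `analysis_params` (a validated list).
#' @export
analysis_params <- function(theta_pos = 1.0,
                            theta_cov = 0.20,
                            n_body_bins = 20L,
                            n_flank_bins = 10L,
                            flank_bp = 5000L,
                            promoter_up = 500L,
                            promoter_down = 500L,
                            cpg_scale = 1000L,
                            exon_quantile = 0.15,
                            diff_log2 = 0.5,
                            min_probes = 1L,
                            min_probes_cor = 5L,
                            probe_assign = c("midpoint", "any_overlap")) {
  probe_assign <- match.arg(probe_assign)
  p <- list(
    theta_pos = as.numeric(theta_pos),
    theta_cov = as.numeric(theta_cov),
    n_body_bins = as.integer(n_body_bins),
    n_flank_bins = as.integer(n_flank_bins),
    flank_bp = as.integer(flank_bp),
    promoter_up = as.integer(promoter_up),
    promoter_down = as.integer(promoter_down),
    cpg_scale = as.integer(cpg_scale),
    exon_quantile = as.numeric(exon_quantile),
    diff_log2 = as.numeric(diff_log2),
    min_probes = as.integer(min_probes),
    min_probes_cor = as.integer(min_probes_cor),
    probe_assign = probe_assign
  )
  stopifnot(
    is.finite(p$theta_pos),
    is.finite(p$theta_cov), p$theta_cov > 0, p$theta_cov <= 1,
    p$n_body_bins >= 1L, p$n_flank_bins >= 1L,
    p$flank_bp >= 0L, p$promoter_up >= 0L, p$promoter_down >= 0L,
    p$cpg_scale >= 1L,
    p$exon_quantile > 0, p$exon_quantile < 0.5,
    is.finite(p$diff_log2), p$diff_log2 >= 0,
    p$min_probes >= 1L, p$min_probes_cor >= 1L
  )
  structure(p, class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("Analysis parameters:\n")
  cat(sprintf("  positive probe: log2 ratio > %g\n", x$theta_pos))
  cat(sprintf("  marked gene: coverage >= %g\n", x$theta_cov))
  cat(sprintf("  bins: %d flank + %d body + %d flank (flank %d bp)\n",
              x$n_flank_bins, x$n_body_bins, x$n_flank_bins, x$flank_bp))
  cat(sprintf("  promoter: TSS -%d/+%d bp; CpG density per %d bp\n",
              x$promoter_up, x$promoter_down, x$cpg_scale))
  cat(sprintf("  exon strata: top/bottom %g; |dlog2| >= %g\n",
              x$exon_quantile, x$diff_log2))
  invisible(x)
}

# coerce defaults when callers pass NULL
as_params <- function(params) {
  if (is.null(params)) return(analysis_params())
  if (!inherits(params, "analysis_params")) {
    stop("`params` must be created by analysis_params()")
  }
  params
}
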