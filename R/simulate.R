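#' Gene-class specification for the synthetic generator
#'
#' A planted gene class: its share of the gene population, gene-body CpG
#' density distribution, per-mark target amplitudes over the promoter
#' and the two gene-body halves (flanks sit at the chromosome baseline),
#' expression level, and the deltas a DNMT-knockout condition applies.
#'
#' @param name Class name.
#' @param proportion Fraction of genes.
#' @param body_cpg_per_kb c(mean, sd) of the gene-body CpG density.
#' @param promoter_cpg_island Whether the upstream promoter half gets
#'   CpG-island-like density.
#' @param marks Named list: mark -> list(promoter=, body_5p=, body_3p=)
#'   target log2 amplitudes; omitted entries default to 0 (baseline).
#' @param expression_log2 c(mean, sd) of the gene-level log2 intensity
#'   baseline.
#' @param knockout List with optional `promoter_set` (named numeric:
#'   mark -> absolute promoter amplitude), `body_scale` (named numeric:
#'   mark -> multiplicative factor on body amplitude) and
#'   `expression_delta` (additive log2 shift).
#' @return A `gene_class_spec` list.
#' @export
gene_class_spec <- function(name, proportion, body_cpg_per_kb,
                            promoter_cpg_island = FALSE, marks = list(),
                            expression_log2 = c(4, 1),
                            knockout = list()) {
  stopifnot(nzchar(name), proportion > 0, proportion <= 1,
            length(body_cpg_per_kb) == 2, body_cpg_per_kb[2] >= 0,
            length(expression_log2) == 2, expression_log2[2] >= 0)
  structure(list(name = name, proportion = proportion,
                 body_cpg_per_kb = as.numeric(body_cpg_per_kb),
                 promoter_cpg_island = isTRUE(promoter_cpg_island),
                 marks = marks,
                 expression_log2 = as.numeric(expression_log2),
                 knockout = knockout),
            class = "gene_class_spec")
}

#' Default planted gene classes
#'
#' Four classes emulating the co-occupancy structure seen on a
#' gene-dense human chromosome:
#' \itemize{
#'   \item METH_ACTIVE (55%): high-CpG gene bodies carrying DNA
#'     methylation (MIRA) and H3K36me3, CpG-island promoters that are
#'     unmethylated (high UMC, low MIRA) and H3-acetylated; highly
#'     expressed. Knockout halves-and-more body methylation
#'     (MIRA x 0.4).
#'   \item ZNF_LIKE (20%): low-CpG bodies dual-occupied by H3K9me3 and
#'     H3K36me3 (plus H4K20me3 and body methylation), methylated
#'     promoters, modest expression. Knockout demethylates the promoter
#'     (MIRA to baseline), scales body MIRA x 0.4 and H3K9me3 x 0.3, and
#'     activates transcription (+0.8 log2).
#'   \item POLYCOMB (15%): H3K27me3-covered, partially methylated
#'     bodies, low expression.
#'   \item INERT (10%): no body marks, methylated promoter, low
#'     expression.
#' }
#' Amplitudes are target probe log2 ratios; 2.0 against a 0 baseline
#' with the default noise sd 0.5 puts planted marks ~4 noise sd above
#' the positivity threshold of 1.
#'
#' @return Named list of [gene_class_spec] objects.
#' @export
default_gene_classes <- function() {
  list(
    METH_ACTIVE = gene_class_spec(
      "METH_ACTIVE", 0.55, body_cpg_per_kb = c(40, 8),
      promoter_cpg_island = TRUE,
      marks = list(
        MIRA = list(promoter = -0.5, body_5p = 2, body_3p = 2),
        UMC = list(promoter = 2, body_5p = -0.5, body_3p = -0.5),
        H3K36me3 = list(body_5p = 2, body_3p = 2),
        H3ac = list(promoter = 2)
      ),
      expression_log2 = c(8, 1),
      knockout = list(body_scale = c(MIRA = 0.4), expression_delta = 0)
    ),
    ZNF_LIKE = gene_class_spec(
      "ZNF_LIKE", 0.20, body_cpg_per_kb = c(8, 2),
      promoter_cpg_island = TRUE,
      marks = list(
        MIRA = list(promoter = 1.5, body_5p = 2, body_3p = 2),
        UMC = list(promoter = -0.5, body_5p = -0.5, body_3p = -0.5),
        H3K9me3 = list(body_5p = 2, body_3p = 2),
        H3K36me3 = list(body_5p = 2, body_3p = 2),
        H4K20me3 = list(body_5p = 2, body_3p = 2),
        H3ac = list(promoter = 2)
      ),
      expression_log2 = c(5, 1),
      knockout = list(promoter_set = c(MIRA = 0, UMC = 2),
                      body_scale = c(MIRA = 0.4, H3K9me3 = 0.3),
                      expression_delta = 0.8)
    ),
    POLYCOMB = gene_class_spec(
      "POLYCOMB", 0.15, body_cpg_per_kb = c(25, 5),
      marks = list(
        # partial methylation: both methylated- and unmethylated-DNA
        # enrichment co-occur over Polycomb gene bodies
        MIRA = list(promoter = 1.5, body_5p = 2, body_3p = 2),
        UMC = list(promoter = -0.5, body_5p = 2, body_3p = 2),
        H3K27me3 = list(promoter = 1.5, body_5p = 2, body_3p = 2)
      ),
      expression_log2 = c(4, 1),
      knockout = list(body_scale = c(MIRA = 0.4), expression_delta = 0)
    ),
    INERT = gene_class_spec(
      "INERT", 0.10, body_cpg_per_kb = c(15, 4),
      marks = list(
        MIRA = list(promoter = 1.5),
        UMC = list(promoter = -0.5)
      ),
      expression_log2 = c(4, 1),
      knockout = list(expression_delta = 0)
    )
  )
}

#' Synthetic chromosome configuration
#'
#' All randomness downstream of the generator is a pure function of
#' `seed`; identical configs yield byte-identical bundles.
#'
#' @param n_genes Number of genes.
#' @param gene_length c(min, max) transcript length in bp.
#' @param intergenic_gap c(min, max) gap between consecutive genes.
#' @param probe_spacing,probe_length Probe grid geometry in bp.
#' @param noise_sd Gaussian probe noise, log2 units.
#' @param expr_noise_sd Per-condition gene expression noise, log2 units.
#' @param exon_noise_sd Exon-level scatter around the gene value.
#' @param classes Named list of [gene_class_spec]; proportions must sum
#'   to 1.
#' @param seed Integer seed (< 2^31 - 1e6).
#' @param conditions Condition names; `knockout_condition` names the one
#'   receiving the knockout deltas.
#' @param knockout_condition See above.
#' @param chrom Chromosome name.
#' @param origin Leftmost gene start (leaves room for upstream flanks).
#' @param background_cpg_per_kb Intergenic CpG density.
#' @param island_cpg_per_kb CpG-island promoter density.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 1000L,
                             gene_length = c(2000L, 10000L),
                             intergenic_gap = c(1000L, 3000L),
                             probe_spacing = 100L, probe_length = 50L,
                             noise_sd = 0.5, expr_noise_sd = 0.1,
                             exon_noise_sd = 0.3,
                             classes = default_gene_classes(),
                             seed = 42L,
                             conditions = c("WT", "DKO"),
                             knockout_condition = "DKO",
                             chrom = "chrS", origin = 10000L,
                             background_cpg_per_kb = 10,
                             island_cpg_per_kb = 80) {
  props <- vapply(classes, `[[`, 0, "proportion")
  if (abs(sum(props) - 1) > 1e-8) stop("class proportions must sum to 1")
  stopifnot(n_genes >= 1, probe_spacing > 0, probe_length > 0,
            gene_length[1] <= gene_length[2], gene_length[1] >= 200,
            intergenic_gap[1] <= intergenic_gap[2],
            noise_sd >= 0, seed == as.integer(seed), seed < 2^31 - 1e6)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 intergenic_gap = as.integer(intergenic_gap),
                 probe_spacing = as.integer(probe_spacing),
                 probe_length = as.integer(probe_length),
                 noise_sd = noise_sd, expr_noise_sd = expr_noise_sd,
                 exon_noise_sd = exon_noise_sd, classes = classes,
                 seed = as.integer(seed), conditions = conditions,
                 knockout_condition = knockout_condition, chrom = chrom,
                 origin = as.integer(origin),
                 background_cpg_per_kb = background_cpg_per_kb,
                 island_cpg_per_kb = island_cpg_per_kb),
            class = "synthetic_config")
}

# deterministic sub-seeds so generator stages are order-independent
sim_seed <- function(config, offset) as.integer(config$seed + offset)

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

#' Simulate gene annotation with planted classes
#'
#' Genes are placed left to right with random intergenic gaps, random
#' strands and 2-12 exons; class membership is multinomial with the
#' configured proportions. ZNF_LIKE genes get symbols beginning with
#' "ZNF" so the symbol-based labeling rule recovers them.
#'
#' @param config [synthetic_config].
#' @return A [gene_models] data frame with an extra `class` column.
#' @export
simulate_annotation <- function(config) {
  set.seed(sim_seed(config, 0L))
  n <- config$n_genes
  cls_names <- names(config$classes)
  props <- vapply(config$classes, `[[`, 0, "proportion")
  cls <- sample(cls_names, n, replace = TRUE, prob = props)
  lens <- runif_int(n, config$gene_length[1], config$gene_length[2])
  gaps <- runif_int(n, config$intergenic_gap[1], config$intergenic_gap[2])
  strands <- sample(c("+", "-"), n, replace = TRUE)
  starts <- config$origin + cumsum(c(0L, (lens + gaps)[-n]))
  ends <- starts + lens
  n_ex <- runif_int(n, 2L, 12L)
  coding <- stats::runif(n) > 0.1
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  cds_start <- rep(NA_integer_, n); cds_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    k <- n_ex[i]
    nseg <- 2L * k - 1L
    # segment weights -> widths summing to gene length, each >= 20 bp
    w <- stats::rexp(nseg) + 0.2
    widths <- pmax(20L, as.integer(round(lens[i] * w / sum(w))))
    widths[nseg] <- widths[nseg] + (lens[i] - sum(widths))
    if (widths[nseg] < 20L) {  # rebalance from the largest segment
      j <- which.max(widths[-nseg])
      widths[j] <- widths[j] + widths[nseg] - 20L
      widths[nseg] <- 20L
    }
    bounds <- starts[i] + cumsum(c(0L, widths))
    es <- bounds[seq(1L, nseg, by = 2L)]
    ee <- bounds[seq(2L, nseg + 1L, by = 2L)]
    exon_starts[[i]] <- es; exon_ends[[i]] <- ee
    if (coding[i]) {
      cds_start[i] <- es[1] + min(50L, (ee[1] - es[1]) %/% 2L)
      cds_end[i] <- ee[k] - min(50L, (ee[k] - es[k]) %/% 2L)
    }
  }
  idx_in_class <- stats::ave(seq_len(n), cls, FUN = seq_along)
  symbol <- ifelse(cls == "ZNF_LIKE",
                   sprintf("ZNF%03d", idx_in_class),
                   sprintf("%s%04d", substr(cls, 1, 1), idx_in_class))
  gm <- gene_models(
    gene_id = sprintf("SYNT%04d", seq_len(n)), symbol = symbol,
    chrom = config$chrom, strand = strands,
    tx_start = starts, tx_end = ends,
    cds_start = cds_start, cds_end = cds_end,
    exon_starts = exon_starts, exon_ends = exon_ends
  )
  gm$class <- cls
  gm <- label_gene_class(gm)
  attr(gm, "chrom_length") <- as.integer(ends[n] + 5000L + 1000L)
  gm
}

# target amplitude of `mark` for a gene of class `cls` at a region role,
# with knockout deltas applied when requested
mark_amplitude <- function(cls, mark, role, knockout = FALSE) {
  mspec <- cls$marks[[mark]]
  amp <- if (is.null(mspec) || is.null(mspec[[role]])) 0 else mspec[[role]]
  if (knockout) {
    ko <- cls$knockout
    if (role %in% c("body_5p", "body_3p") &&
        !is.null(ko$body_scale) && mark %in% names(ko$body_scale)) {
      amp <- amp * ko$body_scale[[mark]]
    }
    if (role == "promoter" &&
        !is.null(ko$promoter_set) && mark %in% names(ko$promoter_set)) {
      amp <- ko$promoter_set[[mark]]
    }
  }
  amp
}

#' Marks planted in each class's gene body
#'
#' @param config [synthetic_config].
#' @param theta Amplitude above which a body mark counts as planted
#'   (default: the positivity threshold 1).
#' @return Named list: class -> character vector of marks.
#' @export
planted_mark_sets <- function(config, theta = 1) {
  all_marks <- simulated_marks(config)
  lapply(config$classes, function(cls) {
    all_marks[vapply(all_marks, function(m) {
      max(mark_amplitude(cls, m, "body_5p"),
          mark_amplitude(cls, m, "body_3p")) > theta
    }, logical(1))]
  })
}

#' @rdname planted_mark_sets
#' @export
simulated_marks <- function(config) {
  sort(unique(unlist(lapply(config$classes, function(c) names(c$marks)))))
}

#' Simulate probe-level signal tracks for one condition
#'
#' Probes sit on a regular grid across the chromosome. Each probe's
#' target is the class amplitude for the region role its midpoint falls
#' in, plus Gaussian noise. The promoter feature spans 500 bp upstream
#' of the TSS plus the first gene-body bin (1/20 of the body) downstream
#' and overrides the body there — TSS-proximal features thereby occupy
#' exactly the two composite-profile bins flanking the TSS while
#' contributing only ~5% of body probes, so gene-body coverage
#' classification reflects the planted body marks. The body is split
#' into 5' and 3' halves; everything else is baseline 0. UMC is
#' anticorrelated with MIRA at promoters by construction of the class
#' amplitudes. The knockout condition applies each class's knockout
#' deltas.
#'
#' @param genes Result of [simulate_annotation].
#' @param config [synthetic_config].
#' @param condition Condition name (one of `config$conditions`).
#' @return Named list of [signal_track] objects, one per mark.
#' @export
simulate_tracks <- function(genes, config, condition = "WT") {
  if (!condition %in% config$conditions) {
    stop(sprintf("unknown condition '%s'", condition))
  }
  ko <- identical(condition, config$knockout_condition)
  chrom_len <- attr(genes, "chrom_length")
  if (is.null(chrom_len)) chrom_len <- max(genes$tx_end) + 6000L
  starts <- seq.int(0L, chrom_len - config$probe_length,
                    by = config$probe_spacing)
  mids <- starts + config$probe_length %/% 2L
  all_marks <- simulated_marks(config)
  targets <- matrix(0, length(starts), length(all_marks),
                    dimnames = list(NULL, all_marks))
  prng <- function(lo, hi) {  # probe rows with lo <= mid < hi
    i1 <- findInterval(lo - 0.5, mids) + 1L
    i2 <- findInterval(hi - 0.5, mids)
    if (i2 < i1) integer(0) else i1:i2
  }
  up <- 500L  # upstream promoter extent, matches the analysis default
  for (i in seq_len(nrow(genes))) {
    cls <- config$classes[[genes$class[i]]]
    s <- genes$tx_start[i]; e <- genes$tx_end[i]
    m <- s + (e - s) %/% 2L
    bw <- (e - s) %/% 20L  # first body bin: downstream promoter extent
    i5 <- if (genes$strand[i] == "+") prng(s, m) else prng(m, e)
    i3 <- if (genes$strand[i] == "+") prng(m, e) else prng(s, m)
    ip <- if (genes$strand[i] == "+") prng(s - up, s + bw)
          else prng(e - bw, e + up)
    for (mk in all_marks) {
      a5 <- mark_amplitude(cls, mk, "body_5p", ko)
      a3 <- mark_amplitude(cls, mk, "body_3p", ko)
      ap <- mark_amplitude(cls, mk, "promoter", ko)
      if (a5 != 0) targets[i5, mk] <- a5
      if (a3 != 0) targets[i3, mk] <- a3
      targets[ip, mk] <- ap  # promoter overrides body
    }
  }
  cond_i <- match(condition, config$conditions)
  out <- lapply(seq_along(all_marks), function(j) {
    set.seed(sim_seed(config, 1000L + 97L * j + 13L * cond_i))
    val <- targets[, j] + stats::rnorm(length(starts), 0, config$noise_sd)
    signal_track(data.frame(chrom = config$chrom, start = starts,
                            end = starts + config$probe_length,
                            value = val),
                 mark = all_marks[j], condition = condition)
  })
  stats::setNames(out, all_marks)
}

#' Simulate gene- and exon-level expression
#'
#' A per-gene baseline is drawn once from the class distribution and
#' shared across conditions; each condition adds its knockout delta (if
#' any) and independent Gaussian noise (`expr_noise_sd`). Exon
#' intensities scatter around the gene value with sd `exon_noise_sd`.
#'
#' @param genes Result of [simulate_annotation].
#' @param config [synthetic_config].
#' @return List with `gene` (gene_id + one column per condition) and
#'   `exon` (exon_id, gene_id, exon_ordinal + condition columns).
#' @export
simulate_expression <- function(genes, config) {
  n <- nrow(genes)
  cls <- config$classes[genes$class]
  mu <- vapply(cls, function(c) c$expression_log2[1], 0)
  sdv <- vapply(cls, function(c) c$expression_log2[2], 0)
  set.seed(sim_seed(config, 2000L))
  baseline <- stats::rnorm(n, mu, sdv)
  gene_tab <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  n_ex <- lengths(genes$exon_starts)
  exon_tab <- data.frame(
    exon_id = unlist(mapply(function(id, k) sprintf("%s.E%02d", id, 1:k),
                            genes$gene_id, n_ex, SIMPLIFY = FALSE)),
    gene_id = rep(genes$gene_id, n_ex),
    exon_ordinal = unlist(lapply(n_ex, seq_len)),
    stringsAsFactors = FALSE
  )
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    ko <- identical(cond, config$knockout_condition)
    delta <- vapply(cls, function(c) {
      d <- c$knockout$expression_delta
      if (ko && !is.null(d)) d else 0
    }, 0)
    set.seed(sim_seed(config, 3000L + 7L * ci))
    gv <- baseline + delta + stats::rnorm(n, 0, config$expr_noise_sd)
    gene_tab[[cond]] <- gv
    set.seed(sim_seed(config, 4000L + 7L * ci))
    exon_tab[[cond]] <- rep(gv, n_ex) +
      stats::rnorm(nrow(exon_tab), 0, config$exon_noise_sd)
  }
  list(gene = gene_tab, exon = exon_tab)
}

#' Simulate the chromosome sequence with controlled CpG density
#'
#' The chromosome is first drawn CpG-free, then CpG dinucleotides are
#' planted at sampled even offsets: each gene body receives a count
#' matching a density drawn from its class (truncated at 0), CpG-island
#' promoters get `island_cpg_per_kb` over the 500 bp upstream of the
#' TSS, and the remaining sequence gets the background density.
#' Planting at disjoint positions never creates extra CpGs, so realized
#' densities match their targets up to rounding.
#'
#' @param genes Result of [simulate_annotation].
#' @param config [synthetic_config].
#' @return List: `genome` (named DNAStringSet), `targets` (per-gene
#'   data frame: gene_id, class, target, realized density per kb).
#' @export
simulate_sequence <- function(genes, config) {
  chrom_len <- attr(genes, "chrom_length")
  set.seed(sim_seed(config, 5000L))
  base <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  # remove every CpG: one vectorized pass suffices (the replacement 'A'
  # cannot form a new CG with either neighbour)
  cg <- which(base[-chrom_len] == "C" & base[-1] == "G")
  if (length(cg)) base[cg + 1L] <- "A"

  plant <- function(lo, hi, density) {  # [lo, hi) 0-based, per-kb density
    len <- hi - lo
    count <- min(round(density * len / 1000), len %/% 2L)
    if (count <= 0) return(invisible(0L))
    cand <- seq.int(lo + 1L, hi - 1L, by = 2L)  # 1-based, step 2: disjoint
    pos <- if (length(cand) == 1L) cand else sample(cand, count)
    base[pos] <<- "C"; base[pos + 1L] <<- "G"
    invisible(as.integer(count))
  }
  cls <- config$classes[genes$class]
  target <- pmax(0, stats::rnorm(nrow(genes),
                                 vapply(cls, function(c) c$body_cpg_per_kb[1], 0),
                                 vapply(cls, function(c) c$body_cpg_per_kb[2], 0)))
  if (any(target > 500)) stop("infeasible CpG density target > 500/kb")
  # background outside gene bodies and island promoters
  gaps_lo <- c(0L, genes$tx_end)
  gaps_hi <- c(genes$tx_start, chrom_len)
  for (k in seq_along(gaps_lo)) {
    if (gaps_hi[k] - gaps_lo[k] >= 4L) {
      plant(gaps_lo[k], gaps_hi[k], config$background_cpg_per_kb)
    }
  }
  realized <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- genes$tx_start[i]; e <- genes$tx_end[i]
    cnt <- plant(s, e, target[i])
    realized[i] <- cnt / (e - s) * 1000
    if (cls[[i]]$promoter_cpg_island) {
      tss <- if (genes$strand[i] == "+") s else e
      up_lo <- if (genes$strand[i] == "+") max(0L, tss - 500L) else tss
      up_hi <- if (genes$strand[i] == "+") tss else tss + 500L
      # island planted in the upstream promoter half only, so the body
      # density stays at its target
      plant(up_lo, up_hi, config$island_cpg_per_kb)
    }
  }
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- config$chrom
  list(genome = genome,
       targets = data.frame(gene_id = genes$gene_id, class = genes$class,
                            target = target, realized = realized,
                            stringsAsFactors = FALSE))
}

#' Bivariate-normal per-gene body signals for two marks
#'
#' Plants a latent per-gene (MIRA, H3K36me3) gene-body mean with
#' correlation `rho`, plus independent measurement noise on each
#' coordinate — the generator behind correlation-recovery checks.
#'
#' @param n Number of genes.
#' @param rho Latent correlation.
#' @param mean,sd Latent mean and sd (both marks).
#' @param noise_sd Measurement noise sd per coordinate.
#' @param seed Integer seed.
#' @return Data frame with columns `mira` and `h3k36me3`.
#' @export
simulate_correlated_body_means <- function(n, rho = 0.4, mean = 1.5,
                                           sd = 0.5, noise_sd = 0.07,
                                           seed = 1L) {
  stopifnot(n >= 3, abs(rho) <= 1)
  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(
    mira = mean + sd * z1 + stats::rnorm(n, 0, noise_sd),
    h3k36me3 = mean + sd * z2 + stats::rnorm(n, 0, noise_sd)
  )
}

#' Run the full generator
#'
#' @param config [synthetic_config].
#' @param sequence Also simulate the chromosome sequence (slower for
#'   large chromosomes).
#' @return List: config, genes, tracks (condition -> mark ->
#'   [signal_track]), expression, and optionally genome + cpg_targets.
#' @export
simulate_bundle <- function(config, sequence = TRUE) {
  genes <- simulate_annotation(config)
  tracks <- lapply(config$conditions, function(cond) {
    simulate_tracks(genes, config, cond)
  })
  names(tracks) <- config$conditions
  expr <- simulate_expression(genes, config)
  out <- list(config = config, genes = genes, tracks = tracks,
              expression = expr)
  if (sequence) {
    sq <- simulate_sequence(genes, config)
    out$genome <- sq$genome
    out$cpg_targets <- sq$targets
  }
  out
}
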