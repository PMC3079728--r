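# Flagship fixture shared across acceptance blocks: 1000 genes with the
# default 55/20/15/10 class mix, amplitude 2.0, noise sd 0.5, fixed
# seed. Built lazily once per test run.
.flagship <- new.env(parent = emptyenv())

flagship_config <- function() synthetic_config(n_genes = 1000L, seed = 2024L)

flagship <- function(sequence = FALSE) {
  key <- if (sequence) "with_seq" else "no_seq"
  if (is.null(.flagship[[key]])) {
    cfg <- flagship_config()
    if (sequence && !is.null(.flagship$no_seq)) {
      b <- .flagship$no_seq
      sq <- simulate_sequence(b$genes, cfg)
      b$genome <- sq$genome
      b$cpg_targets <- sq$targets
      .flagship[[key]] <- b
    } else {
      .flagship[[key]] <- simulate_bundle(cfg, sequence = sequence)
    }
  }
  .flagship[[key]]
}

# per-gene mark sets under the log2>1 / >=20% rules for a given track set
mark_sets_from_tracks <- function(genes, tracks, condition,
                                  params = analysis_params()) {
  tab <- coverage_table(genes, tracks, params)
  marks <- names(tracks)
  marked <- vapply(marks, function(mk) {
    classify_marked_genes(tab, mk, condition)
  }, logical(nrow(genes)))
  apply(marked, 1, function(row) sort(marks[row]), simplify = FALSE)
}

# recovered per-gene mark sets from the noisy fixture tracks
recovered_mark_sets <- function(bundle, condition = "WT",
                                params = analysis_params()) {
  mark_sets_from_tracks(bundle$genes, bundle$tracks[[condition]],
                        condition, params)
}

# planted per-gene truth: classification of the noise-free signal, i.e.
# exactly what the generator deposited for each gene (class amplitudes
# plus promoter/body geometry), before measurement noise
planted_mark_sets_by_gene <- function(bundle, condition = "WT",
                                      params = analysis_params()) {
  cfg0 <- bundle$config
  cfg0$noise_sd <- 0
  tracks0 <- simulate_tracks(bundle$genes, cfg0, condition)
  mark_sets_from_tracks(bundle$genes, tracks0, condition, params)
}
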