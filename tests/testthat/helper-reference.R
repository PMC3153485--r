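# The reference superfamily run is expensive (about a minute), so it is
# built once per test session and shared.

ref_env <- new.env(parent = emptyenv())

ref_simulation <- function() {
  if (is.null(ref_env$sim)) {
    ref_env$sim <- simulate_superfamily(reference_config(seed = 42))
  }
  ref_env$sim
}

# seed alignments: a deterministic 12-row subset of each true domain
# alignment, standing in for the curated starting alignments a survey
# would begin from
ref_seed_alns <- function(n = 12, seed = 7) {
  lapply(ref_simulation()$truth$domain_alns, function(aln) {
    set.seed(seed)
    alignment(unclass(aln)[sample(nrow(aln), min(n, nrow(aln))), ,
                           drop = FALSE])
  })
}

ref_classification <- function() {
  if (is.null(ref_env$res)) {
    sim <- ref_simulation()
    ref_env$res <- iterative_classify(sim$proteomes, ref_seed_alns(),
                                      pipeline_config(seed = 1))
  }
  ref_env$res
}

# majority mapping from emitted subgroup names to true subgroup names,
# and per-protein correctness under that mapping
ref_label_accuracy <- function() {
  res <- ref_classification()
  truth <- ref_simulation()$truth$proteins
  lab <- res$labels
  lab$true_sg <- truth$subgroup[match(lab$seq_id, truth$seq_id)]
  lab$is_decoy <- truth$is_decoy[match(lab$seq_id, truth$seq_id)]
  lab$is_fragment <- truth$is_fragment[match(lab$seq_id, truth$seq_id)]
  fam <- lab[!lab$is_decoy & !lab$is_fragment, , drop = FALSE]
  map <- vapply(split(fam$true_sg, fam$subgroup), function(x) {
    names(sort(table(x), decreasing = TRUE))[[1]]
  }, character(1))
  fam$correct <- map[fam$subgroup] == fam$true_sg
  list(labels = lab, family = fam, map = map,
       accuracy = mean(fam$correct))
}
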