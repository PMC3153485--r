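#!/usr/bin/env Rscript
# Build the reference synthetic RSH superfamily: 20 genomes, 6 subgroups
# (3 long bifunctional RSHs of which one carries a degraded hydrolase
# domain, 2 SYNTH-only SAS analogues, 1 HD-only SAH analogue), decoy
# proteins and short fragments, with full truth (labels, architectures,
# true alignments, true tree). Everything downstream starts from these
# files.

suppressPackageStartupMessages(library(rshkit))

out_dir <- "results/simulation"
cfg <- reference_config(seed = 42)
sim <- simulate_superfamily(cfg, out_dir = out_dir)

truth <- sim$truth$proteins
cat("Simulated superfamily written to", out_dir, "\n")
cat(sprintf("  genomes: %d, proteins: %d (%d family, %d decoys, %d fragments)\n",
            length(sim$proteomes), nrow(truth),
            sum(!truth$is_decoy & !truth$is_fragment),
            sum(truth$is_decoy), sum(truth$is_fragment)))
print(table(subgroup = truth$subgroup[!truth$is_fragment], useNA = "ifany"))
cat("Domain truth alignments:",
    paste(sprintf("%s (%d cols)", names(sim$truth$domain_alns),
                  vapply(sim$truth$domain_alns, ncol, integer(1))),
          collapse = ", "), "\n")
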