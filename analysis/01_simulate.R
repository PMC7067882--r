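#!/usr/bin/env Rscript
# Step 1: state the synthetic world. Simulates the 7-taxon cheetah-like
# coding-region alignment (outgroup cherry at 4.92 My; cheetah splits at
# 138.9 / 72.2 / 24 / 10 ky; historical-sample missing-data masks) and a
# numt-chimera fixture for the mismatch screen. Large FASTA goes to scratch/,
# small truth tables to results/.
library(mitodate)

dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

scenario <- default_cheetah_scenario(seed = 1L, length = 15000L)
sim <- simulate_alignment(scenario)
write_fasta(sim$alignment, "scratch/sim/alignment.fasta")
ape::write.tree(sim$time_tree, "scratch/sim/time_tree.nwk")
jsonlite::write_json(sim$truth[c("root_age", "ne_split", "india_se_split",
                                 "se_splits", "mutation_rate", "seed")],
                     "results/sim_truth.json", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE)
called <- vapply(sim$alignment$seqs, function(s) {
  sum(strsplit(s, "")[[1]] != "N")
}, 0L)
message("simulated ", sim$alignment$length, " sites x ",
        length(sim$alignment$taxa), " taxa; called sites per taxon:")
print(stats::setNames(called, sim$alignment$taxa))

# numt fixture: a clean reference and a query carrying a 1 kb segment at 5%
# divergence (plus 0.5% background noise across the whole query)
set.seed(2L)
ref <- sim$alignment$seqs[sim$alignment$taxa == "SEAfrica_ref"]
noisy <- make_numt_chimera(ref, c(0L, 15000L), divergence = 0.005, seed = 3L)
chim <- make_numt_chimera(noisy$sequence, c(8000L, 9000L), divergence = 0.05,
                          seed = 4L)
write_fasta(c(reference = ref, query = chim$sequence),
            "scratch/sim/numt_pair.fasta")
jsonlite::write_json(list(segment = c(8000L, 9000L),
                          implant_mutations = chim$n_mutated,
                          background_mutations = noisy$n_mutated),
                     "results/numt_truth.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("numt fixture: ", chim$n_mutated, " implant mutations on [8000,9000)")
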