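#!/usr/bin/env Rscript
# Stage 1: generate the synthetic SNAP-array experiment.
#
# Produces the genomic regions (FASTA + BED), the probe library
# (genomic tiling at 6 bp, monomer mismatch permutations, the dimer
# spacing series), triplicate raw intensities, and the ground-truth
# table used by later stages to score recovery.

suppressMessages(library(snapspec))

dir.create("results", showWarnings = FALSE)
cfg <- simulator_config(seed = 20260930L)
sim <- simulate_snap_experiment(cfg)

write_fasta(setNames(sim$regions$sequence, sim$regions$region_id),
            "results/regions.fa")
write_bed(tibble::tibble(chrom = sim$regions$chrom,
                         start = sim$regions$start,
                         end = sim$regions$end,
                         name = sim$regions$region_id),
          "results/regions.bed")
write_probe_table(sim$probes, "results/probes.tsv")
write_intensity_table(sim$probes, sim$raw, "results/raw_intensities.tsv")
tr <- sim$truth
tr$mismatch_positions <- vapply(tr$mismatch_positions, paste,
                                character(1), collapse = ",")
write.table(as.data.frame(tr), "results/ground_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Simulated %d regions (%d with a planted motif) -> %d probes:\n",
            nrow(sim$regions), sum(sim$truth$planted), nrow(sim$probes)))
print(table(sim$probes$probe_class))
cat(sprintf("True classes: %d direct, %d indirect\n",
            sum(sim$truth$true_class == "direct"),
            sum(sim$truth$true_class == "indirect")))
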