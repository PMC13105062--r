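#!/usr/bin/env Rscript
# Stage 3: motif and mismatch specificity.
#
# Ranks genomic probes, exports the top bins for external de novo motif
# discovery, checks that the consensus octamer dominates the top
# binders, quantifies flanking-base preferences around perfect sites,
# and builds the Sequence Specificity Landscape (with the flattened
# one-mismatch ring).

suppressMessages(library(snapspec))

probes <- read_probe_table("results/probes.tsv")
norm <- read.delim("results/normalized_intensities.tsv")
probes$intensity <- norm$normalized[match(probes$probe_id, norm$probe_id)]
gen <- probes[probes$probe_class == "genomic", ]

# --- top-probe ranking and motif-discovery export ------------------------
top <- rank_top_probes(gen, n = 1200, bin_size = 300)
export_ranked_fasta(top, "results/motif_bins")
tk <- top_enriched_kmer(top$sequence, 8)
cat(sprintf("Top-enriched 8-mer among the 1200 top binders: %s (%d/%d probes)\n",
            tk$kmer[1], tk$count[1], nrow(top)))
write.table(as.data.frame(tk[1:20, ]), "results/top_kmers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# --- flanking-base preferences -------------------------------------------
eligible <- filter_flank_eligible(gen)
cat(sprintf("%d genomic probes eligible for flank analysis\n", nrow(eligible)))
flank <- quartile_enrichment(eligible)
write.table(as.data.frame(flank), "results/flank_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- flank[flank$significant & flank$ratio > 1, c("position", "base", "ratio", "p")]
cat("Significantly enriched flank bases (top vs bottom quartile):\n")
print(as.data.frame(sig), row.names = FALSE)

# --- Sequence Specificity Landscape --------------------------------------
mono <- probes[probes$probe_class == "monomer_mismatch", ]
lay <- layout_rings(tibble::tibble(sequence = mono$sequence,
                                   ring = mono$n_mismatch,
                                   intensity = mono$intensity))
write.table(as.data.frame(lay), "results/ssl_layout.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
rs <- ring_summary(lay)
cat("Mean intensity per mismatch ring:\n")
print(as.data.frame(rs), row.names = FALSE)

fl <- flatten_one_mismatch_ring(lay)
write.table(as.data.frame(fl$entries), "results/ssl_ring1_flat.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
sec <- tapply(fl$entries$intensity, fl$entries$mismatch_position, mean)
cat("Mean ring-1 intensity by mismatch position (lowest = most constrained):\n")
print(round(sort(sec), 3))
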