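#!/usr/bin/env Rscript
# Stage 6: infer intron loss, lateral gain and transposition events from
# homologue families and the species tree, and score the recovery against
# the simulator's ground truth.

suppressPackageStartupMessages(library(cobintron))

recs <- read_gene_records("results/simulation/genes.fa", "fasta-pair")
tree <- read_species_tree("results/simulation/species_tree.nwk")
cat1 <- extract_all_introns(new_catalogue(recs))
cat2 <- assign_positions(cat1, reference = sort(names(cat1$records))[1])

pairs <- pairwise_homology(cat2$introns)
fam <- build_families(cat2$introns, pairs, cat2$assignments)

# ground truth from stage 1
truth_events <- read.table("results/simulation/events_truth.tsv",
                           sep = "\t", header = TRUE)
truth_fams <- read.table("results/simulation/families_truth.tsv",
                         sep = "\t", header = TRUE)
intr <- cat2$introns
truth_fams$sequence <- intr$sequence[match(
  paste(truth_fams$species_id, truth_fams$insertion_point),
  paste(intr$species_id, intr$insertion_point))]
truth <- list(events = truth_events, complements = truth_fams)

ev <- recover_events(cat2, tree, fam, truth = truth)

write.table(ev$losses, "results/events_losses.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ev$lateral_gains, "results/events_lateral.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ev$transpositions, "results/events_transpositions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(kind = rownames(ev$recovery),
                  as.data.frame(ev$recovery)),
            "results/recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("inferred: %d origins, %d losses, %d lateral-gain pairs, %d transpositions\n",
            nrow(ev$origins), nrow(ev$losses), nrow(ev$lateral_gains),
            nrow(ev$transpositions)))
cat("recovery against simulation truth:\n")
print(round(ev$recovery, 3))
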