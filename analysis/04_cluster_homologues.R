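#!/usr/bin/env Rscript
# Stage 4: pairwise intron homology by tiled local-alignment statistics
# (reciprocal coverage > 30%, tiled mean identity > 80%) and homologue
# families as connected components.

suppressPackageStartupMessages(library(cobintron))

recs <- read_gene_records("results/simulation/genes.fa", "fasta-pair")
cat1 <- extract_all_introns(new_catalogue(recs))
cat2 <- assign_positions(cat1, reference = sort(names(cat1$records))[1])

pairs <- pairwise_homology(cat2$introns)
fam <- build_families(cat2$introns, pairs, cat2$assignments)

write.table(pairs, "results/pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(fam, "results/families.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

shared <- unique(fam$family_id[fam$n_members >= 2])
cat(sprintf("%d intron pairs evaluated; %d homologous\n",
            nrow(pairs), sum(pairs$homologous)))
cat(sprintf("%d families, of which %d have >= 2 members (singletons: %d)\n",
            length(unique(fam$family_id)), length(shared),
            sum(fam$n_members == 1)))
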