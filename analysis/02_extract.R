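#!/usr/bin/env Rscript
# Stage 2: decompose each genomic sequence into exons and introns by
# comparison with its spliced coding sequence, and check the group I
# splice consensus (intron ends in G, preceded by an exonic T).

suppressPackageStartupMessages(library(cobintron))

out_dir <- "results"
recs <- read_gene_records("results/simulation/genes.fa", "fasta-pair")
cat1 <- extract_all_introns(new_catalogue(recs))
intr <- cat1$introns

cons <- vapply(seq_len(nrow(intr)), function(i)
  unlist(validate_splice_consensus(intr[i, ])), logical(2))
write.table(intr[, setdiff(names(intr), "sequence")],
            file.path(out_dir, "introns.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
con <- file(file.path(out_dir, "introns.fa"), "w")
writeLines(paste0(">", intr$intron_id, "\n", intr$sequence), con)
close(con)

cat(sprintf("extracted %d introns from %d genes (%d intron-free)\n",
            nrow(intr), length(recs),
            sum(!names(cat1$records) %in% intr$species_id)))
cat(sprintf("splice consensus: %.0f%% end in G, %.0f%% preceded by T\n",
            100 * mean(cons[1, ]), 100 * mean(cons[2, ])))
cat(sprintf("length conservation holds for all genes: %s\n",
            all(vapply(cat1$records, function(r) {
              nchar(r$gdna) - nchar(r$cdna) ==
                sum(intr$length[intr$species_id == r$species_id])
            }, logical(1)))))
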