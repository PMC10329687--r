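#!/usr/bin/env Rscript
# Per-gene dN/dS by Nei-Gojobori counting, and the membrane-vs-organelle
# contrast of the ratios. Genes are screened for variation, framed on a
# bacterial start codon, and stripped of trailing stop codons before
# counting. Requires 01 to have run.

suppressMessages(library(geophylo))

alignments <- read_gene_alignments("results/dataset/genes")
ann <- read_annotations("results/dataset/annotations.tsv")
groups <- assign_groups(names(alignments), ann)

tab <- dnds_table(alignments)
write.table(tab, "results/dnds.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

ok <- tab[tab$status == "ok", ]
cat("dN/dS computed for", nrow(ok), "of", nrow(tab), "genes\n")
cat("  excluded:", paste(names(table(tab$reason[tab$reason != ""])),
                         table(tab$reason[tab$reason != ""]),
                         collapse = ", "), "\n")
cat("  median ratio by group:\n")
print(round(tapply(ok$ratio, groups[ok$gene_id], median, na.rm = TRUE), 3))

cmp <- dnds_group_contrast(tab, groups)
print(cmp)
write.table(cmp$pairwise, "results/dnds_group_comparison.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
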