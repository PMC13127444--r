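#!/usr/bin/env Rscript
# Step 3 — candidate screening with Storey q-value FDR control.
#
# CLR-transforms the pseudo-count-imputed family table and keeps the
# families whose CLR abundance differs between presence and absence of
# at least one pore-fluid constituent at q < 0.05.

library(redoxtaxa)

fam <- read_community(file.path("results", "family", "counts.tsv"),
                      file.path("results", "family", "taxonomy.tsv"),
                      file.path("results", "family", "metadata.tsv"))
chem <- read.delim(file.path("results", "sample_chemistry.tsv"))
class(chem) <- c("sample_chemistry", "data.frame")

clrm <- clr(zero_impute_counts(t(fam$counts)))
rownames(clrm) <- colnames(fam$counts)

scr <- screen_taxa(clrm, chem)
write.table(scr$table, file.path("results", "screening.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(scr$candidates, file.path("results", "candidates.txt"))

per_con <- tapply(scr$table$selected, scr$table$constituent, sum)
cat(sprintf("significant families per constituent: %s\n",
            paste(names(per_con), per_con, sep = "=", collapse = ", ")))
cat(sprintf("union candidate set: %d of %d families\n",
            length(scr$candidates), nrow(fam$counts)))
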