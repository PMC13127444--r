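#!/usr/bin/env Rscript
# Step 2 — family binning, chemistry interpolation, anoxia assignment.
#
# Bins the count table to family level, linearly interpolates each
# core's pore-fluid profile onto the microbial sampling depths (no
# extrapolation), and assigns 0 uM oxygen to samples without an oxygen
# measurement whose ammonium is >= 10 uM with manganese present.

library(redoxtaxa)

data_dir <- file.path("results", "data")
community <- read_community(file.path(data_dir, "counts.tsv"),
                            file.path(data_dir, "taxonomy.tsv"),
                            file.path(data_dir, "metadata.tsv"))
profiles <- read_pore_fluid(file.path(data_dir, "pore_fluid.csv"))

fam <- bin_to_family(community)
write_community(fam, file.path("results", "family"))

chem <- suppressWarnings(interpolate_chemistry(profiles, fam$metadata))
chem <- impute_anoxia(chem)
write.table(chem, file.path("results", "sample_chemistry.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("binned %d taxa into %d families (per-sample totals conserved)\n",
            nrow(community$counts), nrow(fam$counts)))
for (con in c("O2", "NO3", "NH4", "Mn"))
  cat(sprintf("  %-3s: %s\n", con,
              paste(names(table(chem[[paste0(con, "_flag")]])),
                    table(chem[[paste0(con, "_flag")]]),
                    sep = "=", collapse = ", ")))
cat(sprintf("%d samples assigned anoxic (O2 := 0) by the NH4/Mn rule\n",
            sum(chem$O2_flag == "imputed_anoxic")))
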