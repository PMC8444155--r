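#!/usr/bin/env Rscript
# Stage 3: lncRNA secondary-structure accessibility.
#
# Computes base-pair probabilities with the uniform-weight partition
# function, masks positions whose maximal pair probability reaches 0.1,
# and reports how accessible the planted triplex-forming tract remains.

suppressPackageStartupMessages(library(triplexmeth))

rna <- read_fasta("results/data/lncrna.fa")[[1L]]
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

acc <- accessibility_profile(rna)
write.table(acc$profile, "results/accessibility_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fasta(c(lncRNA_masked = acc$masked_rna), "results/lncrna_masked.fa")

tr <- truth$planted_tfo_interval
in_tract <- acc$profile$position >= tr[1L] & acc$profile$position < tr[2L]
cat("Masked", sum(acc$profile$masked), "of", nrow(acc$profile),
    "positions (", round(100 * mean(acc$profile$masked), 1), "% )\n")
cat("Planted TFO tract [", tr[1L], ",", tr[2L], "):",
    round(100 * mean(!acc$profile$masked[in_tract]), 1),
    "% of positions unpaired at cutoff 0.1\n")
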