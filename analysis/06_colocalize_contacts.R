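#!/usr/bin/env Rscript
# Stage 6: validation against RNA-chromatin contacts.
#
# Filters contacts to those whose RNA anchor overlaps the lncRNA locus,
# expands triplex-positive windows by +-3 kb, confirms contacts whose DNA
# anchor intersects an expanded window, and compares methylation deltas at
# validated versus other sites.

suppressPackageStartupMessages(library(triplexmeth))

contacts <- read_intervals("results/data/contacts.bedpe", "BEDPE")
windows <- read_intervals("results/windows.bed", "BED")
names(windows)[names(windows) == "name"] <- "probe_id"
windows$triplex_positive <- windows$score == 1
cls <- read.table("results/classification.tsv", header = TRUE, sep = "\t")
genome <- read_fasta("results/data/genome.fa")
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

lnc_len <- nchar(read_fasta("results/data/lncrna.fa")[[1L]])
params <- coloc_params(flank = 3000L,
                       rna_locus = list(chrom = names(genome)[1L],
                                        start = 100L,
                                        end = 100L + lnc_len))
kept <- filter_rna_contacts(contacts, params)
v <- validate_triplexes(windows, kept, params,
                        setNames(nchar(genome), names(genome)))
write_bedpe(v$confirmed_contacts, "results/confirmed_contacts.bedpe")

cat("Contacts at the lncRNA locus:", nrow(kept), "\n")
cat("Confirmed contacts:", nrow(v$confirmed_contacts),
    "( true:", sum(grepl("^true_", v$confirmed_contacts$id)),
    "/ decoy:", sum(grepl("^decoy_", v$confirmed_contacts$id)), ")\n")
cat("All planted true contacts confirmed:",
    setequal(v$confirmed_contacts$id, truth$true_contact_ids), "\n")

others <- windows[!(windows$probe_id %in% v$validated_windows$probe_id), ]
pr <- protection_at_validated_sites(cls, v$validated_windows, others)
cat("Delta at validated vs other sites: ",
    signif(pr$mean_delta_validated, 3), " vs ",
    signif(pr$mean_delta_other, 3),
    " (rank-sum p = ", signif(pr$p_value, 3), ")\n", sep = "")
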