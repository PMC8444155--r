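#!/usr/bin/env Rscript
# Stage 5: hypermethylation protection and binding-domain enrichment.
#
# Crosses HM/NHM classes with triplex status (Fisher's exact test; an odds
# ratio < 1 means triplex-capable loci avoid hypermethylation), clusters
# TFOs into DNA binding domains, and scores each domain against 100
# resamples of a genomic background pool.

suppressPackageStartupMessages(library(triplexmeth))
seed <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

cls <- read.table("results/classification.tsv", header = TRUE, sep = "\t")
windows <- read_intervals("results/windows.bed", "BED")
names(windows)[names(windows) == "name"] <- "probe_id"
windows$triplex_positive <- windows$score == 1
genome <- read_fasta("results/data/genome.fa")
masked <- read_fasta("results/lncrna_masked.fa")[[1L]]
hits <- read.table("results/triplex_hits.tsv", header = TRUE, sep = "\t")

pt <- hm_protection_table(cls, windows)
cat("Protection table (HM/NHM x triplex +/-):\n")
print(pt$table)
cat("Fisher: OR =", signif(pt$fisher$odds_ratio, 3),
    ", p =", signif(pt$fisher$p_value, 3), "\n")

set.seed(seed)
cl <- setNames(nchar(genome), names(genome))
neg <- windows[!windows$triplex_positive, ]
bg <- sample_background_windows(cl, 500L, 100L, neg)
bg <- extract_window_sequences(bg, genome)
bg_hits <- find_triplexes(masked, bg, triplex_params())
target_hits <- hits[hits$window_id %in%
                      windows$probe_id[windows$triplex_positive], ]
dbds <- cluster_dbds(target_hits, enrichment_params(seed = seed))
dbds <- dbd_enrichment(dbds, target_hits, bg_hits, bg$name,
                       sum(windows$triplex_positive),
                       enrichment_params(seed = seed))
write.table(dbds, "results/dbds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(nrow(dbds), "DNA binding domain(s);",
    sum(dbds$empirical_p <= 0.05), "significant at empirical p <= 0.05\n")
print(dbds)
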