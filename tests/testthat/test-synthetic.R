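test_that("synthetic config validates fractions, sizes, and tract layout", {
  expect_error(synthetic_config(frac_hyper = 1.2), "fractions")
  expect_error(synthetic_config(n_mut_samples = 1, n_wt_samples = 2))
  expect_error(synthetic_config(tfo_tract = list(start = 550, end = 700,
                                                 composition = "GGGGA"),
                                lnc_length = 600))
  expect_error(synthetic_config(frac_hyper = 0.6, frac_protected = 0.5))
})

test_that("genome generation is deterministic and handles the empty case", {
  cfg <- synthetic_config(n_probes = 0L, seed = 9)
  g <- generate_genome(cfg)
  expect_identical(nrow(g$probes), 0L)
  expect_identical(length(g$genome), 2L)
  expect_identical(nchar(g$genome[[1L]]), 150000L)

  cfg <- synthetic_config(n_probes = 40L, seed = 9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(generate_genome(cfg)$genome, f1)
  write_fasta(generate_genome(cfg)$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("chromosomes too short for the probe load are a sizing error", {
  expect_error(generate_genome(synthetic_config(chrom_length = 1000L,
                                                n_probes = 100L)),
               "sizing")
})

test_that("every probe sits on CG and planted tract counts are exact", {
  cfg <- synthetic_config(n_probes = 50L, frac_protected = 0.4, seed = 3)
  g <- generate_genome(cfg)
  for (i in seq_len(nrow(g$probes))) {
    di <- substr(g$genome[[g$probes$chrom[i]]], g$probes$pos[i] + 1L,
                 g$probes$pos[i] + 2L)
    expect_identical(di, "CG")
  }
  wins <- extract_window_sequences(
    build_windows(g$probes, setNames(nchar(g$genome), names(g$genome))),
    g$genome)
  # exhaustive scan: a >=10-nt tract with guanine fraction >= 0.7?
  scan <- vapply(wins$seq, function(s) {
    gc <- cumsum(c(0L, strsplit(s, "")[[1L]] == "G"))
    L <- nchar(s)
    for (len in 10:L) {
      cnt <- gc[(len + 1L):(L + 1L)] - gc[1L:(L - len + 1L)]
      if (any(cnt >= 0.7 * len - 1e-9)) return(TRUE)
    }
    FALSE
  }, logical(1))
  expect_identical(sum(scan), 20L)
  expect_setequal(wins$probe_id[scan], g$protected_probe_ids)
  expect_true(all(g$probes$pos >= 0 &
                    g$probes$pos < nchar(g$genome[g$probes$chrom])))
})

test_that("methylation cohort reproduces group sizes and planted labels", {
  cfg <- synthetic_config(n_probes = 1000L, chrom_length = 200000L,
                          frac_hyper = 0.3, seed = 7)
  g <- generate_genome(cfg)
  m <- generate_methylation(cfg, g$probes, g$protected_probe_ids)
  expect_identical(length(m$truth$hyper_probe_ids), 300L)
  expect_identical(sum(m$beta$group == "mut"), 13L)
  expect_identical(sum(m$beta$group == "wt"), 173L)
  expect_true(all(m$beta$values >= 0 & m$beta$values <= 1))
  # protection excluded from the hyper draw when linked
  expect_length(intersect(m$truth$hyper_probe_ids,
                          g$protected_probe_ids), 0L)

  cfg0 <- synthetic_config(n_probes = 200L, effect_delta = 0, seed = 7)
  g0 <- generate_genome(cfg0)
  m0 <- generate_methylation(cfg0, g0$probes, g0$protected_probe_ids)
  expect_length(m0$truth$hyper_probe_ids, 0L)
  d <- rowMeans(m0$beta$values[, m0$beta$group == "mut"]) -
    rowMeans(m0$beta$values[, m0$beta$group == "wt"])
  expect_lt(max(abs(d)), 0.1)
})

test_that("a saturating baseline plus effect warns about clipping", {
  cfg <- synthetic_config(n_probes = 40L, effect_delta = 0.5,
                          baseline_range = c(0.7, 0.9), seed = 2)
  g <- generate_genome(cfg)
  expect_warning(generate_methylation(cfg, g$probes), "clipping")
})

test_that("lncRNA layout plants hairpins clear of the accessible tract", {
  cfg <- synthetic_config(seed = 3)
  lnc <- generate_lncrna(cfg)
  expect_identical(nchar(lnc$rna), 600L)
  tr <- lnc$truth$planted_tfo_interval
  expect_identical(tr, c(400L, 500L))
  hp <- lnc$truth$hairpins
  expect_identical(nrow(hp), 3L)
  expect_true(all(hp$end <= tr[1L]))
  # tract is the purine tiling, so it cannot self-pair
  tract <- substr(lnc$rna, tr[1L] + 1L, tr[2L])
  expect_false(grepl("[CU]", tract))
  # stems are exact reverse complements
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (k in seq_len(nrow(hp))) {
    arm1 <- strsplit(substr(lnc$rna, hp$start[k] + 1L,
                            hp$start[k] + 8L), "")[[1L]]
    arm2 <- strsplit(substr(lnc$rna, hp$start[k] + 13L,
                            hp$start[k] + 20L), "")[[1L]]
    expect_identical(arm2, rev(unname(comp[arm1])))
  }
  expect_error(generate_lncrna(synthetic_config(
    lnc_length = 200L, n_hairpins = 5L,
    tfo_tract = list(start = 60L, end = 160L, composition = "GGGGA"))),
    "layout")
  # no hairpins requested: no planted stems
  lnc0 <- generate_lncrna(synthetic_config(n_hairpins = 0L, seed = 4))
  expect_identical(nrow(lnc0$truth$hairpins), 0L)
})

test_that("under the structure model the tract is accessible and stems are
           pairing-enriched", {
  cfg <- synthetic_config(seed = 3)
  lnc <- generate_lncrna(cfg)
  prof <- unpaired_profile(pair_probabilities(lnc$rna))
  tr <- lnc$truth$planted_tfo_interval
  in_tract <- prof$position >= tr[1L] & prof$position < tr[2L]
  # the planted tract mirrors the accessible 3' region of the real
  # transcript: >= 95% of its positions unpaired at cutoff 0.1
  expect_gte(mean(prof$p_paired[in_tract] < 0.1), 0.95)
  hp <- lnc$truth$hairpins
  stem_pos <- unlist(lapply(seq_len(nrow(hp)), function(k)
    c(hp$start[k]:(hp$start[k] + 7L),
      (hp$start[k] + 12L):(hp$start[k] + 19L))))
  in_stem <- prof$position %in% stem_pos
  bg <- !in_stem & !in_tract
  # uniform-weight ensembles spread pairing probability; planted stems do
  # not dominate outright but sit above the background average and well
  # above the purine tract
  expect_gt(mean(prof$p_paired[in_stem]), mean(prof$p_paired[bg]))
  expect_gt(mean(prof$p_paired[in_stem]),
            2 * mean(prof$p_paired[in_tract]))
})

test_that("contacts: counts, anchoring near positive windows, decoy distance", {
  cfg <- synthetic_config(seed = 5)
  g <- generate_genome(cfg)
  cl <- setNames(nchar(g$genome), names(g$genome))
  pw <- build_windows(g$probes[g$probes$probe_id %in%
                                 g$protected_probe_ids, ], cl)
  locus <- list(chrom = "chr1", start = 100L, end = 700L)
  con <- generate_contacts(cfg, locus, pw, cl)
  expect_identical(nrow(con$contacts), 157L)
  expect_length(con$truth$true_contact_ids, 29L)
  # expanded positive windows at flank 3000 catch every true contact and
  # no decoy
  ex <- data.frame(chrom = pw$chrom, start = pmax(pw$start - 3000L, 0L),
                   end = pw$end + 3000L)
  anchors <- data.frame(chrom = con$contacts$dna_chrom,
                        start = con$contacts$dna_start,
                        end = con$contacts$dna_end)
  hit <- brute_any_overlap(anchors, ex)
  expect_true(all(hit[grepl("^true_", con$contacts$id)]))
  expect_false(any(hit[grepl("^decoy_", con$contacts$id)]))
  # RNA anchors inside the locus
  expect_true(all(con$contacts$rna_chrom == "chr1" &
                    con$contacts$rna_start >= locus$start &
                    con$contacts$rna_end <= locus$end))

  empty <- generate_contacts(
    synthetic_config(n_true_contacts = 0L, n_decoy_contacts = 0L),
    locus, pw, cl)
  expect_identical(nrow(empty$contacts), 0L)
})
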