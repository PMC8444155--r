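make_contacts <- function(dna_chrom, dna_start, dna_end,
                          rna_chrom = "chr1", rna_start = 100L,
                          rna_end = 200L, ids = NULL) {
  n <- length(dna_start)
  data.frame(rna_chrom = rna_chrom, rna_start = rna_start,
             rna_end = rna_end, dna_chrom = dna_chrom,
             dna_start = as.integer(dna_start),
             dna_end = as.integer(dna_end),
             id = if (is.null(ids)) sprintf("c%02d", seq_len(n)) else ids,
             stringsAsFactors = FALSE)
}

test_that("contacts are filtered by RNA-anchor overlap with the locus", {
  p <- coloc_params(rna_locus = list(chrom = "chr1", start = 150L,
                                     end = 400L))
  con <- make_contacts("chr2", c(10L, 20L, 30L), c(200L, 220L, 230L),
                       rna_chrom = c("chr1", "chr1", "chr5"),
                       rna_start = c(200L, 0L, 200L),
                       rna_end = c(300L, 150L, 300L))
  kept <- filter_rna_contacts(con, p)
  # inside kept; abutting half-open [0,150) vs [150,400) dropped; other
  # chromosome dropped
  expect_identical(kept$id, "c01")
  expect_error(filter_rna_contacts(con, coloc_params()), "rna_locus")
})

test_that("window expansion arithmetic and half-open boundary semantics", {
  w <- data.frame(chrom = "chr1", start = 5000L, end = 5100L,
                  probe_id = "p1", triplex_positive = TRUE)
  # expanded interval is [2000, 8100)
  con <- make_contacts("chr1", c(1900L, 1950L, 8100L, 8050L),
                       c(2000L, 2050L, 8200L, 8150L))
  v <- validate_triplexes(w, con, coloc_params(flank = 3000L))
  # abutting at both edges excluded, 1-bp-in included
  expect_setequal(v$confirmed_contacts$id, c("c02", "c04"))

  # flank 0: contact exactly abutting the window end is not confirmed
  con <- make_contacts("chr1", c(5100L, 5099L), c(5200L, 5200L))
  v <- validate_triplexes(w, con, coloc_params(flank = 0L))
  expect_identical(v$confirmed_contacts$id, "c02")
})

test_that("confirmation grows monotonically with the flank", {
  set.seed(23)
  w <- data.frame(chrom = "chr1", start = sample.int(50000L, 20L),
                  probe_id = sprintf("p%02d", 1:20),
                  triplex_positive = rep(c(TRUE, FALSE), 10L))
  w$end <- w$start + 100L
  con <- make_contacts("chr1", s <- sample.int(60000L, 40L), s + 150L)
  prev <- -1L
  for (f in c(0L, 500L, 2000L, 5000L)) {
    v <- validate_triplexes(w, con, coloc_params(flank = f))
    expect_gte(nrow(v$confirmed_contacts), prev)
    prev <- nrow(v$confirmed_contacts)
  }
})

test_that("expanding windows is equivalent to expanding contacts, and
           overlap matches a quadratic scan", {
  set.seed(24)
  for (rep in 1:10) {
    f <- sample.int(2000L, 1)
    w <- data.frame(chrom = sample(c("chr1", "chr2"), 15, TRUE),
                    start = sample.int(40000L, 15) + 2500L,
                    probe_id = sprintf("p%02d", 1:15),
                    triplex_positive = sample(c(TRUE, FALSE), 15, TRUE))
    w$end <- w$start + 100L
    s <- sample.int(45000L, 25)
    con <- make_contacts(sample(c("chr1", "chr2"), 25, TRUE), s, s + 200L)
    a <- validate_triplexes(w, con, coloc_params(flank = f))
    con2 <- con
    con2$dna_start <- pmax(con$dna_start - f, 0L)
    con2$dna_end <- con$dna_end + f
    b <- validate_triplexes(w, con2, coloc_params(flank = 0L))
    expect_identical(a$confirmed_contacts$id, b$confirmed_contacts$id)
    expect_identical(a$contacted, b$contacted)
    # quadratic oracle for the contacted flag
    ex <- data.frame(chrom = w$chrom, start = pmax(w$start - f, 0L),
                     end = w$end + f)
    anchors <- data.frame(chrom = con$dna_chrom, start = con$dna_start,
                          end = con$dna_end)
    expect_identical(a$contacted, brute_any_overlap(ex, anchors))
  }
})

test_that("a planted fixture confirms every true contact, no decoys, with a
           decisive Fisher test", {
  # module-level fixture: positive windows contacted, negative windows and
  # decoys kept far apart, so the window-by-contact association is extreme
  set.seed(25)
  w <- data.frame(chrom = "chr1",
                  start = seq(10000L, by = 20000L, length.out = 40L),
                  probe_id = sprintf("p%02d", 1:40),
                  triplex_positive = rep(c(TRUE, FALSE), each = 20L))
  w$end <- w$start + 100L
  pos <- w[w$triplex_positive, ]
  true_s <- pos$start + sample(c(-2500L, 2500L), 20L, TRUE)
  con <- rbind(
    make_contacts("chr1", true_s, true_s + 200L,
                  ids = sprintf("true_%02d", 1:20)),
    make_contacts("chr2", seq(5000L, by = 10000L, length.out = 30L),
                  seq(5200L, by = 10000L, length.out = 30L),
                  ids = sprintf("decoy_%02d", 1:30)))
  v <- validate_triplexes(w, con, coloc_params(flank = 3000L))
  expect_setequal(v$confirmed_contacts$id, sprintf("true_%02d", 1:20))
  expect_identical(v$table["positive", "contacted"], 20L)
  expect_identical(v$table["negative", "contacted"], 0L)
  expect_lt(v$fisher$p_value, 0.001)
  expect_warning(validate_triplexes(w, con[0, ], coloc_params()),
                 "degenerate")
})

test_that("protection at validated sites detects planted delta shifts and
           is calibrated under exchange", {
  set.seed(26)
  cls <- data.frame(probe_id = sprintf("p%03d", 1:120),
                    delta = c(rnorm(40, -0.15, 0.05), rnorm(80, 0, 0.05)))
  vw <- data.frame(probe_id = sprintf("p%03d", 1:40))
  ow <- data.frame(probe_id = sprintf("p%03d", 41:120))
  r <- protection_at_validated_sites(cls, vw, ow)
  expect_lt(r$p_value, 1e-3)
  expect_true(r$protective)

  # identical groups: exact p = 1
  cls2 <- data.frame(probe_id = c("a", "b", "c", "d"),
                     delta = c(0.1, 0.2, 0.1, 0.2))
  r <- protection_at_validated_sites(cls2,
                                     data.frame(probe_id = c("a", "b")),
                                     data.frame(probe_id = c("c", "d")))
  expect_identical(r$p_value, 1)

  # null: p-values roughly uniform across reshuffled group labels
  ps <- vapply(1:200, function(i) {
    deltas <- rnorm(60, 0, 0.05)
    ids <- sample(60)
    cls0 <- data.frame(probe_id = sprintf("q%02d", 1:60), delta = deltas)
    protection_at_validated_sites(
      cls0, data.frame(probe_id = sprintf("q%02d", ids[1:25])),
      data.frame(probe_id = sprintf("q%02d", ids[26:60])))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_error(protection_at_validated_sites(
    cls2, data.frame(probe_id = character(0)),
    data.frame(probe_id = "c")), "delta")
})
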