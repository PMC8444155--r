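#' Parameters for RNA-chromatin colocalization validation
#'
#' @param flank Symmetric expansion (bp) applied to CpG target windows
#'   before intersecting with contact DNA anchors (default 3000).
#' @param rna_locus List with `chrom`, `start`, `end`: the genomic source
#'   interval of the lncRNA (0-based half-open).
#' @return List of class `coloc_params`.
#' @export
coloc_params <- function(flank = 3000L, rna_locus = NULL) {
  stopifnot(flank >= 0L)
  if (!is.null(rna_locus))
    stopifnot(all(c("chrom", "start", "end") %in% names(rna_locus)),
              rna_locus$end > rna_locus$start)
  structure(list(flank = as.integer(flank), rna_locus = rna_locus),
            class = "coloc_params")
}

#' Keep contacts whose RNA anchor overlaps the lncRNA locus
#'
#' @param contacts Contact table (see [read_intervals()] with
#'   `dialect = "BEDPE"`).
#' @param params A [coloc_params()] with a non-`NULL` `rna_locus`.
#' @return Subset of `contacts` with RNA-anchor overlap of at least 1 bp.
#' @export
filter_rna_contacts <- function(contacts, params) {
  loc <- params$rna_locus
  if (is.null(loc)) stop("params$rna_locus is required")
  keep <- contacts$rna_chrom == loc$chrom &
    contacts$rna_start < loc$end & contacts$rna_end > loc$start
  out <- contacts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L,
                                                 end = end))
}

#' Validate predicted triplex windows against chromatin contacts
#'
#' Each window is expanded by `flank` on both sides (clipped at 0 and, when
#' chromosome lengths are supplied, at the chromosome end). A contact is
#' confirmed when its DNA anchor intersects at least one expanded
#' triplex-positive window; a window is contacted when its expanded
#' interval intersects at least one DNA anchor. The attached 2x2 table
#' cross-classifies windows (triplex-positive / negative) by contact status
#' (contacted / not), with a two-sided Fisher test.
#'
#' @param windows Windows data frame carrying `probe_id` and
#'   `triplex_positive`.
#' @param contacts Contact table (DNA anchors used).
#' @param params A [coloc_params()].
#' @param chrom_lengths Optional named vector for clipping expansions.
#' @return List with `validated_windows` (triplex-positive and contacted),
#'   `confirmed_contacts`, `contacted` (logical per window), `table`,
#'   `fisher`.
#' @export
validate_triplexes <- function(windows, contacts, params = coloc_params(),
                               chrom_lengths = NULL) {
  stopifnot("triplex_positive" %in% names(windows))
  if (nrow(contacts) == 0L)
    warning("no contacts supplied: degenerate contingency table")
  f <- params$flank
  ex_start <- pmax(windows$start - f, 0L)
  ex_end <- windows$end + f
  if (!is.null(chrom_lengths))
    ex_end <- pmin(ex_end, as.integer(chrom_lengths[windows$chrom]))
  wg <- granges0(windows$chrom, ex_start, ex_end)
  cg <- granges0(contacts$dna_chrom, contacts$dna_start, contacts$dna_end)
  ov <- GenomicRanges::findOverlaps(wg, cg)
  contacted <- seq_len(nrow(windows)) %in% S4Vectors::queryHits(ov)
  pos_hits <- windows$triplex_positive[S4Vectors::queryHits(ov)]
  confirmed_ix <- sort(unique(S4Vectors::subjectHits(ov)[pos_hits]))
  a <- sum(windows$triplex_positive & contacted)
  b <- sum(windows$triplex_positive & !contacted)
  c <- sum(!windows$triplex_positive & contacted)
  d <- sum(!windows$triplex_positive & !contacted)
  tab <- matrix(c(a, c, b, d), 2L, 2L,
                dimnames = list(triplex = c("positive", "negative"),
                                contact = c("contacted", "not_contacted")))
  list(validated_windows = windows[windows$triplex_positive & contacted, ,
                                   drop = FALSE],
       confirmed_contacts = contacts[confirmed_ix, , drop = FALSE],
       contacted = contacted,
       table = tab,
       fisher = fisher_exact_2x2(a, b, c, d))
}

#' Methylation protection at experimentally validated binding sites
#'
#' Compares the methylation delta values of validated windows against the
#' remaining windows with a Mann-Whitney rank-sum test; validated sites
#' shifting toward lower deltas indicates protection from
#' hypermethylation.
#'
#' @param classifications Data frame from [classify_cpgs()].
#' @param validated_windows,other_windows Windows data frames (each with
#'   `probe_id`); both groups must be nonempty.
#' @return List with `U`, `p_value`, `method`, `mean_delta_validated`,
#'   `mean_delta_other`, `protective` (`TRUE` when validated deltas are
#'   lower on average).
#' @export
protection_at_validated_sites <- function(classifications,
                                          validated_windows,
                                          other_windows) {
  dv <- classifications$delta[match(validated_windows$probe_id,
                                    classifications$probe_id)]
  do_ <- classifications$delta[match(other_windows$probe_id,
                                     classifications$probe_id)]
  dv <- dv[!is.na(dv)]; do_ <- do_[!is.na(do_)]
  if (length(dv) == 0L || length(do_) == 0L)
    stop("both window groups must have delta values")
  rs <- rank_sum_test(dv, do_)
  list(U = rs$U, p_value = rs$p_value, method = rs$method,
       mean_delta_validated = mean(dv), mean_delta_other = mean(do_),
       protective = mean(dv) < mean(do_))
}
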