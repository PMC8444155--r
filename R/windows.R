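#' Build fixed-width DNA target windows centered on CpG probes
#'
#' A window of width `width` (default 100 nt) is placed around each probe:
#' `start = pos - width / 2`, `end = start + width`, so the C of the CpG is
#' the `width / 2`-th 0-based position of the window. Windows overhanging a
#' chromosome end are clipped and flagged; probes off-chromosome are
#' skipped with a message.
#'
#' @param probes Data frame with `probe_id`, `chrom`, `pos` (0-based
#'   position of the C of the CpG) and optionally `klass` (carried over).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param width Window width in nt (default 100).
#' @return Data frame with `chrom`, `start`, `end`, `probe_id`, `clipped`,
#'   and `klass` when supplied.
#' @export
build_windows <- function(probes, chrom_lengths, width = 100L) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(probes)),
            !is.null(names(chrom_lengths)))
  len <- chrom_lengths[probes$chrom]
  ok <- !is.na(len) & probes$pos >= 0L & probes$pos < len
  if (any(!ok)) {
    message("skipping ", sum(!ok), " probe(s) outside genome bounds")
    probes <- probes[ok, , drop = FALSE]
    len <- len[ok]
  }
  start <- pmax(probes$pos - width %/% 2L, 0L)
  end <- pmin(probes$pos - width %/% 2L + width, as.integer(len))
  out <- data.frame(chrom = probes$chrom, start = as.integer(start),
                    end = as.integer(end), probe_id = probes$probe_id,
                    clipped = (end - start) < width,
                    stringsAsFactors = FALSE)
  if ("klass" %in% names(probes)) out$klass <- probes$klass
  rownames(out) <- NULL
  out
}

#' Extract reference-strand sequences for target windows
#'
#' @param windows Data frame from [build_windows()].
#' @param genome Named character vector of chromosome sequences (e.g. from
#'   [read_fasta()]).
#' @return `windows` with an uppercase `seq` column of length
#'   `end - start`.
#' @export
extract_window_sequences <- function(windows, genome) {
  missing_chr <- setdiff(unique(windows$chrom), names(genome))
  if (length(missing_chr) > 0L)
    stop("chromosome(s) missing from genome: ",
         paste(missing_chr, collapse = ", "))
  windows$seq <- toupper(substring(genome[windows$chrom],
                                   windows$start + 1L, windows$end))
  stopifnot(nchar(windows$seq) == windows$end - windows$start)
  windows
}

#' Annotate each window with its nearest gene
#'
#' Distance is measured from the window midpoint to the gene span: 0 when
#' the midpoint falls inside the gene, otherwise signed (positive when the
#' gene lies downstream of the midpoint, negative upstream). Ties are
#' broken by smaller gene start, then lexicographic gene name. Chromosomes
#' without genes get an infinite distance and an empty gene name.
#'
#' @param windows Data frame with `chrom`, `start`, `end`, `probe_id`.
#' @param genes Data frame with `chrom`, `start`, `end`, `name` (0-based
#'   half-open).
#' @return `windows` with `gene` and `gene_distance` columns.
#' @export
annotate_nearest_gene <- function(windows, genes) {
  mid <- windows$start + (windows$end - windows$start) %/% 2L
  gene <- character(nrow(windows))
  dist <- rep(Inf, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    g <- genes[genes$chrom == windows$chrom[w], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- ifelse(mid[w] < g$start, g$start - mid[w],
                ifelse(mid[w] >= g$end, (g$end - 1L) - mid[w], 0L))
    o <- order(abs(d), g$start, g$name)
    gene[w] <- g$name[o[1L]]
    dist[w] <- d[o[1L]]
  }
  windows$gene <- gene
  windows$gene_distance <- dist
  windows
}
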