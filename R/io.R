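#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' conventions used throughout the package: record names are truncated at the
#' first whitespace, sequences are uppercased, and duplicate names are an
#' error.
#'
#' @param path Path to a FASTA file (possibly multi-record, wrapped lines).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  nm <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name: ", nm[duplicated(nm)][1L])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- nm
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read genomic intervals from BED, BEDPE, or 1-based TSV dialects
#'
#' All coordinates are represented internally as 0-based half-open intervals
#' (the BED convention). The `TSV` dialect is read as 1-based inclusive (the
#' genome-browser convention) and converted on ingest.
#'
#' @param path Input path.
#' @param dialect One of `"BED"`, `"BEDPE"`, `"TSV"`.
#' @return For `BED`/`TSV`: data frame with columns `chrom`, `start`, `end`,
#'   and `name`/`score`/`strand` when present. For `BEDPE`: a contact table
#'   with columns `rna_chrom`, `rna_start`, `rna_end`, `dna_chrom`,
#'   `dna_start`, `dna_end`, `id` (anchor 1 is the RNA anchor).
#' @export
read_intervals <- function(path, dialect = c("BED", "BEDPE", "TSV")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("interval file not found: ", path)
  header <- dialect == "TSV"
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  offset <- if (header) 1L else 0L
  bad_line <- function(i, what) {
    stop("parse error at line ", i + offset + (if (header) 1L else 0L),
         " of ", path, ": ", what)
  }
  if (dialect == "BEDPE") {
    if (ncol(tab) < 6L) stop("BEDPE needs >= 6 columns: ", path)
    out <- data.frame(
      rna_chrom = as.character(tab[[1L]]),
      rna_start = as.integer(tab[[2L]]), rna_end = as.integer(tab[[3L]]),
      dna_chrom = as.character(tab[[4L]]),
      dna_start = as.integer(tab[[5L]]), dna_end = as.integer(tab[[6L]]),
      id = if (ncol(tab) >= 7L) as.character(tab[[7L]]) else
        paste0("contact_", seq_len(nrow(tab))),
      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(out))) {
      if (is.na(out$rna_start[i]) || is.na(out$rna_end[i]) ||
          is.na(out$dna_start[i]) || is.na(out$dna_end[i]))
        bad_line(i, "non-numeric coordinate")
      if (out$rna_end[i] <= out$rna_start[i] ||
          out$dna_end[i] <= out$dna_start[i])
        bad_line(i, "interval end <= start")
    }
    return(out)
  }
  if (ncol(tab) < 3L) stop(dialect, " needs >= 3 columns: ", path)
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]),
                    end = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (dialect == "TSV") out$start <- out$start - 1L  # 1-based inclusive in
  if (ncol(tab) >= 4L) out$name <- as.character(tab[[4L]])
  if (ncol(tab) >= 5L) out$score <- tab[[5L]]
  if (ncol(tab) >= 6L) out$strand <- as.character(tab[[6L]])
  for (i in seq_len(nrow(out))) {
    if (is.na(out$start[i]) || is.na(out$end[i]))
      bad_line(i, "non-numeric coordinate")
    if (out$end[i] <= out$start[i]) bad_line(i, "interval end <= start")
  }
  out
}

#' Write intervals as BED
#'
#' @param df Data frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns (0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  opt <- intersect(c("name", "score", "strand"), names(df))
  # BED columns are positional: stop at the first absent optional column
  for (cn in c("name", "score", "strand")) {
    if (cn %in% opt) cols <- c(cols, cn) else break
  }
  utils::write.table(df[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write contact records as BEDPE
#'
#' @param contacts Contact table as returned by
#'   [read_intervals()] with `dialect = "BEDPE"`.
#' @param path Output path.
#' @export
write_bedpe <- function(contacts, path) {
  cols <- c("rna_chrom", "rna_start", "rna_end",
            "dna_chrom", "dna_start", "dna_end", "id")
  utils::write.table(contacts[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an RNAplfold-style unpaired-probability track
#'
#' Parses the `_lunp` dialect: comment header lines starting with `#`, then
#' one row per nucleotide with a 1-based position in column 1 followed by
#' unpaired probabilities for window spans 1, 2, ... Positions are converted
#' to the package's 0-based convention on ingest.
#'
#' @param path Path to a `_lunp` file.
#' @param span Which window-span column to use (default 1, the
#'   single-nucleotide unpaired probability).
#' @return Data frame with columns `position` (0-based), `p_unpaired`,
#'   `p_paired` (taken as `1 - p_unpaired` for this ingest path).
#' @export
read_lunp <- function(path, span = 1L) {
  if (!file.exists(path)) stop("_lunp file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  if (length(rows) == 0L) stop("no data rows in _lunp file: ", path)
  pos <- numeric(length(rows))
  pu <- numeric(length(rows))
  for (k in seq_along(rows)) {
    fields <- strsplit(trimws(lines[rows[k]]), "\\s+")[[1L]]
    if (length(fields) < span + 1L)
      stop("parse error at line ", rows[k], " of ", path,
           ": fewer than ", span + 1L, " columns")
    v <- suppressWarnings(as.numeric(fields[c(1L, span + 1L)]))
    if (is.na(v[1L]) || v[1L] != round(v[1L]) || v[1L] < 1)
      stop("parse error at line ", rows[k], " of ", path,
           ": bad position field '", fields[1L], "'")
    if (is.na(v[2L]) && fields[span + 1L] != "NA")
      stop("parse error at line ", rows[k], " of ", path,
           ": bad probability field '", fields[span + 1L], "'")
    pos[k] <- v[1L]
    pu[k] <- v[2L]
  }
  if (any(!is.na(pu) & (pu < 0 | pu > 1)))
    stop("unpaired probability outside [0,1] in ", path)
  data.frame(position = as.integer(pos) - 1L, p_unpaired = pu,
             p_paired = 1 - pu)
}

#' Write an unpaired-probability profile in the `_lunp` dialect
#'
#' @param profile Data frame with `position` (0-based) and `p_unpaired`.
#' @param path Output path.
#' @export
write_lunp <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#unpaired probabilities", con)
  writeLines(" #i$\tl=1", con)
  writeLines(sprintf("%d\t%.8g", profile$position + 1L, profile$p_unpaired),
             con)
  invisible(path)
}

#' Read a beta-value matrix and sample groups from TSV
#'
#' @param beta_path TSV with probes as rows (first column `probe_id`) and
#'   samples as columns.
#' @param groups_path Two-column TSV (`sample_id`, `group`) with groups
#'   `mut`/`wt`.
#' @return A [beta_matrix()] object.
#' @export
read_beta_matrix <- function(beta_path, groups_path) {
  tab <- utils::read.table(beta_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab[[1L]]
  g <- utils::read.table(groups_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  group <- g[[2L]]
  names(group) <- g[[1L]]
  beta_matrix(values, group[colnames(values)])
}

#' Write a beta matrix and its sample groups to TSV
#'
#' @param beta A [beta_matrix()] object.
#' @param beta_path Output TSV for values.
#' @param groups_path Output TSV for sample groups.
#' @export
write_beta_matrix <- function(beta, beta_path, groups_path) {
  tab <- data.frame(probe_id = rownames(beta$values), beta$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, beta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- data.frame(sample_id = colnames(beta$values),
                  group = as.character(beta$group))
  utils::write.table(g, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(beta_path)
}
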