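#' Triplex search parameters
#'
#' Defaults follow the standard optimisation for lncRNA triplex screens:
#' minimum length 10 nt, error rate 20%, guanine rate 70%, repeat filtering
#' off. The guanine rate is the fraction of G on the purine strand of the
#' triplex target site. `max_consecutive_errors` bounds runs of mismatched
#' (or masked) positions inside a hit.
#'
#' @param min_length Minimum hit length in nt (default 10, must be >= 5).
#' @param max_error_rate Maximum `n_errors / length` (default 0.20).
#' @param min_guanine_rate Minimum G fraction of the TTS purine strand
#'   (default 0.70).
#' @param max_consecutive_errors Maximum run of consecutive error positions
#'   (default 1).
#' @param motifs Subset of `c("Y", "R", "GT")` (default all): pyrimidine
#'   motif (T.A:T, C.G:C; parallel), purine motif (G.G:C, A.A:T;
#'   antiparallel), mixed GT motif (G.G:C, T.A:T; both orientations).
#' @param filter_repeats Reserved flag (default `FALSE`); low-complexity
#'   masking is not applied by this engine.
#' @return List of class `triplex_params`.
#' @export
triplex_params <- function(min_length = 10L, max_error_rate = 0.20,
                           min_guanine_rate = 0.70,
                           max_consecutive_errors = 1L,
                           motifs = c("Y", "R", "GT"),
                           filter_repeats = FALSE) {
  stopifnot(min_length >= 5L, max_error_rate >= 0, max_error_rate <= 1,
            min_guanine_rate >= 0, min_guanine_rate <= 1,
            max_consecutive_errors >= 0,
            all(motifs %in% c("Y", "R", "GT")), length(motifs) >= 1L)
  structure(list(min_length = as.integer(min_length),
                 max_error_rate = max_error_rate,
                 min_guanine_rate = min_guanine_rate,
                 max_consecutive_errors = as.integer(max_consecutive_errors),
                 motifs = motifs, filter_repeats = isTRUE(filter_repeats)),
            class = "triplex_params")
}

# motif/orientation combinations searched, in fixed order
motif_combos <- function(motifs) {
  combos <- list(c("Y", "parallel"), c("R", "antiparallel"),
                 c("GT", "parallel"), c("GT", "antiparallel"))
  Filter(function(cmb) cmb[1L] %in% motifs, combos)
}

# canonical (TFO base, purine-strand base) matches per motif
triplet_table <- function(motif) {
  switch(motif,
         Y = c(T = "A", C = "G"),
         R = c(G = "G", A = "A"),
         GT = c(G = "G", T = "A"),
         stop("unknown motif ", motif))
}

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rev_string <- function(s) {
  paste(rev(strsplit(s, "")[[1L]]), collapse = "")
}

normalize_tfo <- function(rna) {
  s <- toupper(rna)
  if (grepl("[^ACGUTN]", s)) stop("invalid RNA alphabet in TFO sequence")
  chartr("U", "T", s)
}

empty_hits <- function() {
  data.frame(rna_start = integer(0), rna_end = integer(0),
             tts_chrom = character(0), tts_start = integer(0),
             tts_end = integer(0), motif = character(0),
             orientation = character(0), strand = character(0),
             n_errors = integer(0), guanine_rate = numeric(0),
             length = integer(0), window_id = character(0),
             stringsAsFactors = FALSE)
}

order_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$tts_chrom, hits$tts_start, hits$tts_end, hits$rna_start,
             hits$motif, hits$orientation, hits$strand)
  out <- hits[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate triplex-target tracts in a DNA window
#'
#' Reports, for each duplex strand, the maximal intervals of length at
#' least `min_length` that contain no run of more than
#' `max_consecutive_errors` consecutive non-purine positions. Every
#' position matched by any Hoogsteen triplet carries a purine (A or G) on
#' the purine strand, and errors cannot run longer than the consecutive
#' cap, so every legal triplex target site is contained in one of these
#' tracts; they are candidate regions, not hits.
#'
#' @param dna_window Character scalar over \{A,C,G,T,N\}.
#' @param params A [triplex_params()].
#' @return Data frame with `start`, `end` (0-based half-open, reference
#'   coordinates of the window) and `strand` (`+` purine tract on the given
#'   sequence, `-` on its reverse complement).
#' @export
find_tts_tracts <- function(dna_window, params = triplex_params()) {
  s <- toupper(dna_window)
  if (grepl("[^ACGTN]", s)) stop("invalid DNA alphabet")
  W <- nchar(s)
  res <- data.frame(start = integer(0), end = integer(0),
                    strand = character(0), stringsAsFactors = FALSE)
  for (strand in c("+", "-")) {
    seq_s <- if (strand == "+") s else revcomp_dna(s)
    bad <- !(strsplit(seq_s, "")[[1L]] %in% c("A", "G"))
    iv <- segments_without_runs(bad, params$max_consecutive_errors,
                                params$min_length)
    if (nrow(iv) > 0L) {
      if (strand == "-") {
        ref <- data.frame(start = W - iv$end, end = W - iv$start)
        iv <- ref[order(ref$start), , drop = FALSE]
      }
      res <- rbind(res, data.frame(start = iv$start, end = iv$end,
                                   strand = strand,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(res) <- NULL
  res
}

# maximal 0-based half-open intervals avoiding any full run of
# (max_run + 1) TRUE values, of length >= min_len
segments_without_runs <- function(bad, max_run, min_len) {
  L <- length(bad)
  run <- 0L
  ends <- integer(0)   # positions where a violating run (max_run+1) ends
  for (b in seq_len(L)) {
    run <- if (bad[b]) run + 1L else 0L
    if (run >= max_run + 1L) ends <- c(ends, b - 1L)  # 0-based end position
  }
  if (length(ends) == 0L) {
    iv <- data.frame(start = 0L, end = L)
  } else {
    starts <- c(0L, ends - max_run + 1L)
    stops <- c(ends, L)  # half-open ends: violating run end is excluded
    iv <- unique(data.frame(start = starts, end = stops))
  }
  iv <- iv[iv$end - iv$start >= min_len, , drop = FALSE]
  # drop intervals contained in another (possible when runs overlap)
  if (nrow(iv) > 1L) {
    o <- order(iv$start, -iv$end)
    iv <- iv[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(iv))
    maxend <- -1L
    for (k in seq_len(nrow(iv))) {
      if (iv$end[k] <= maxend) keep[k] <- FALSE else maxend <- iv$end[k]
    }
    iv <- iv[keep, , drop = FALSE]
  }
  rownames(iv) <- NULL
  iv
}

# scan one (rna, window, motif, orientation, strand) combination using the
# compiled diagonal scanner; returns hit rows in reference coordinates
scan_combo <- function(rna, win_seq, win_chrom, win_start, win_id,
                       motif, orientation, strand, params) {
  R <- nchar(rna)
  W <- nchar(win_seq)
  tfo <- if (orientation == "parallel") rna else rev_string(rna)
  pur <- if (strand == "+") win_seq else revcomp_dna(win_seq)
  motif_code <- match(motif, c("Y", "R", "GT")) - 1L
  m <- .triplex_scan_cpp(tfo, pur, motif_code, params$min_length,
                         params$max_error_rate, params$min_guanine_rate,
                         params$max_consecutive_errors)
  if (nrow(m) == 0L) return(empty_hits())
  len <- m[, "len"]
  rna_start <- if (orientation == "parallel") m[, "tfo_start"] else
    R - m[, "tfo_start"] - len
  tts_start <- if (strand == "+") win_start + m[, "pur_start"] else
    win_start + W - m[, "pur_start"] - len
  data.frame(rna_start = rna_start, rna_end = rna_start + len,
             tts_chrom = win_chrom, tts_start = tts_start,
             tts_end = tts_start + len, motif = motif,
             orientation = orientation, strand = strand,
             n_errors = m[, "n_err"], guanine_rate = m[, "n_g"] / len,
             length = len, window_id = win_id, stringsAsFactors = FALSE)
}

#' Predict RNA:DNA triplexes between a (masked) RNA and DNA windows
#'
#' For every window and every motif/orientation/strand combination, finds
#' all maximal gap-free aligned matches between the RNA (the
#' triplex-forming oligonucleotide, TFO) and the purine strand of the
#' duplex (the triplex target site, TTS) under the canonical Hoogsteen
#' triplet rules, subject to the length, error-rate, consecutive-error and
#' guanine-rate constraints in `params`. `'N'` on either side counts as an
#' error position, so hits may span isolated masked bases within the error
#' budget. A hit is maximal when no valid hit on the same alignment
#' diagonal strictly contains it.
#'
#' @param rna_masked Character scalar: the RNA sequence, typically after
#'   [mask_paired()]. U and T are synonymous.
#' @param windows Data frame with columns `chrom`, `start`, `end`, `seq`
#'   (reference-strand window sequence) and a window identifier column
#'   `probe_id` (or `name`).
#' @param params A [triplex_params()].
#' @return Data frame of hits ordered by (chrom, tts_start, tts_end,
#'   rna_start, motif): columns `rna_start`, `rna_end`, `tts_chrom`,
#'   `tts_start`, `tts_end`, `motif`, `orientation`, `strand`, `n_errors`,
#'   `guanine_rate`, `length`, `window_id`. Coordinates are 0-based
#'   half-open; `strand` is the duplex purine strand.
#' @export
find_triplexes <- function(rna_masked, windows, params = triplex_params()) {
  rna <- normalize_tfo(rna_masked)
  if (nchar(gsub("N", "", rna)) == 0L) {
    warning("RNA is empty (or fully masked); no triplexes searched")
    return(empty_hits())
  }
  id_col <- if ("probe_id" %in% names(windows)) "probe_id" else "name"
  stopifnot(all(c("chrom", "start", "end", "seq") %in% names(windows)),
            id_col %in% names(windows))
  combos <- motif_combos(params$motifs)
  out <- vector("list", nrow(windows) * length(combos))
  k <- 0L
  for (wi in seq_len(nrow(windows))) {
    wseq <- toupper(windows$seq[wi])
    for (cmb in combos) {
      for (strand in c("+", "-")) {
        k <- k + 1L
        out[[k]] <- scan_combo(rna, wseq, windows$chrom[wi],
                               windows$start[wi], windows[[id_col]][wi],
                               cmb[1L], cmb[2L], strand, params)
      }
    }
  }
  order_hits(do.call(rbind, out[seq_len(k)]))
}

#' Brute-force triplex search (verification oracle)
#'
#' Enumerates every equal-length (RNA substring, DNA substring) pair of
#' length at least `min_length` for every motif, orientation, and duplex
#' strand, checks the Hoogsteen triplet rules position by position, applies
#' the error-rate, consecutive-error, and guanine-rate filters, and reduces
#' to maximal hits per alignment diagonal. Independent of the compiled
#' scanner; guarded to small inputs.
#'
#' @param rna Character scalar, at most 30 nt.
#' @param dna Character scalar (one window, reference strand), at most
#'   60 nt.
#' @param params A [triplex_params()].
#' @param chrom,win_start,win_id Coordinates assigned to the window
#'   (defaults `"win"`, 0, `"win"`).
#' @return Hits data frame with the same columns and ordering as
#'   [find_triplexes()].
#' @export
brute_force_triplexes <- function(rna, dna, params = triplex_params(),
                                  chrom = "win", win_start = 0L,
                                  win_id = "win") {
  if (nchar(rna) > 30L || nchar(dna) > 60L)
    stop("brute-force oracle limited to |rna| <= 30, |dna| <= 60")
  rna <- normalize_tfo(rna)
  dna <- toupper(dna)
  R <- nchar(rna)
  W <- nchar(dna)
  rows <- list()
  for (cmb in motif_combos(params$motifs)) {
    motif <- cmb[1L]; orientation <- cmb[2L]
    rules <- triplet_table(motif)
    for (strand in c("+", "-")) {
      tfo <- strsplit(if (orientation == "parallel") rna else rev_string(rna),
                      "")[[1L]]
      pur <- strsplit(if (strand == "+") dna else revcomp_dna(dna), "")[[1L]]
      cand <- list()  # per diagonal: valid aligned intervals
      for (i0 in seq_len(R)) for (j0 in seq_len(W)) {
        maxL <- min(R - i0 + 1L, W - j0 + 1L)
        for (L in seq_len(maxL)) {
          if (L < params$min_length) next
          rr <- tfo[i0:(i0 + L - 1L)]
          dd <- pur[j0:(j0 + L - 1L)]
          err <- !(rr %in% names(rules)) | dd != unname(rules[rr])
          err[is.na(err)] <- TRUE
          ne <- sum(err)
          if (ne > params$max_error_rate * L + 1e-9) next
          if (max_run_length(err) > params$max_consecutive_errors) next
          ng <- sum(dd == "G")
          if (ng < params$min_guanine_rate * L - 1e-9) next
          key <- as.character(i0 - j0)
          cand[[key]] <- rbind(cand[[key]],
                               c(i0 - 1L, j0 - 1L, L, ne, ng))
        }
      }
      for (key in names(cand)) {
        iv <- cand[[key]]
        keep <- rep(TRUE, nrow(iv))
        for (a in seq_len(nrow(iv))) for (b in seq_len(nrow(iv))) {
          if (a == b) next
          inside <- iv[b, 1L] <= iv[a, 1L] &&
            iv[b, 1L] + iv[b, 3L] >= iv[a, 1L] + iv[a, 3L] &&
            iv[b, 3L] > iv[a, 3L]
          if (inside) keep[a] <- FALSE
        }
        iv <- iv[keep, , drop = FALSE]
        for (a in seq_len(nrow(iv))) {
          ts <- iv[a, 1L]; ps <- iv[a, 2L]; L <- iv[a, 3L]
          rna_start <- if (orientation == "parallel") ts else R - ts - L
          tts_start <- if (strand == "+") win_start + ps else
            win_start + W - ps - L
          rows[[length(rows) + 1L]] <- data.frame(
            rna_start = rna_start, rna_end = rna_start + L,
            tts_chrom = chrom, tts_start = tts_start,
            tts_end = tts_start + L, motif = motif,
            orientation = orientation, strand = strand,
            n_errors = iv[a, 4L], guanine_rate = iv[a, 5L] / L,
            length = L, window_id = win_id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  order_hits(do.call(rbind, rows))
}

max_run_length <- function(flags) {
  if (!any(flags)) return(0L)
  r <- rle(flags)
  max(r$lengths[r$values])
}

#' Flag windows with at least one triplex hit
#'
#' @param windows Windows data frame (with `probe_id` or `name` id column).
#' @param hits Hits from [find_triplexes()].
#' @return `windows` with a logical `triplex_positive` column.
#' @export
triplex_positive <- function(windows, hits) {
  id_col <- if ("probe_id" %in% names(windows)) "probe_id" else "name"
  windows$triplex_positive <- windows[[id_col]] %in% hits$window_id
  windows
}
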