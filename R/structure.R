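#' Parameters for the RNA secondary-structure accessibility model
#'
#' The package scores pseudoknot-free secondary structures with a uniform
#' Boltzmann factor per base pair (`pair_weight`) rather than a full
#' nearest-neighbor energy model; the partition function over that ensemble
#' is exact and directly checkable against brute-force structure
#' enumeration. Users wanting thermodynamic-quality profiles can ingest an
#' RNAplfold track via [read_lunp()] instead.
#'
#' @param pairing_cutoff Positions whose maximal per-pair probability
#'   reaches this cutoff are masked before triplex search (default 0.1).
#' @param min_loop Minimum hairpin loop length in nt (default 3): a pair
#'   (i, j) requires `j - i > min_loop`.
#' @param pair_weight Boltzmann factor per allowed pair (default `exp(1)`).
#' @return List of class `structure_params`.
#' @export
structure_params <- function(pairing_cutoff = 0.1, min_loop = 3L,
                             pair_weight = exp(1)) {
  stopifnot(pairing_cutoff > 0, pairing_cutoff < 1, min_loop >= 0,
            pair_weight > 0)
  structure(list(pairing_cutoff = pairing_cutoff,
                 min_loop = as.integer(min_loop),
                 pair_weight = pair_weight),
            class = "structure_params")
}

check_rna_alphabet <- function(rna) {
  stopifnot(is.character(rna), length(rna) == 1L)
  s <- toupper(rna)
  if (grepl("[^ACGUT]", s))
    stop("invalid RNA alphabet: characters outside {A,C,G,U,T}")
  s
}

#' Base-pair probability matrix from the uniform-weight partition function
#'
#' Computes P(i, j), the equilibrium probability that positions i and j are
#' paired, over all pseudoknot-free structures with pairs drawn from
#' \{AU, UA, GC, CG, GU, UG\}, each structure weighted
#' `pair_weight ^ npairs`, and the minimum-loop constraint respected.
#' U and T are synonymous. Implemented as an inside-outside dynamic program
#' in C++ with adaptive rescaling for long sequences.
#'
#' @param rna Character scalar over \{A,C,G,U,T\}.
#' @param params A [structure_params()].
#' @return Symmetric numeric matrix P with `P[i, j] = 0` whenever
#'   `j - i <= min_loop` or the pair is disallowed.
#' @export
pair_probabilities <- function(rna, params = structure_params()) {
  s <- check_rna_alphabet(rna)
  .pair_prob_cpp(s, params$min_loop, params$pair_weight)
}

#' Brute-force pair probabilities by exhaustive structure enumeration
#'
#' Verification oracle for [pair_probabilities()]: recursively enumerates
#' every pseudoknot-free structure (each generated exactly once via an
#' unambiguous decomposition), accumulates `pair_weight ^ npairs` weights,
#' and forms the per-pair marginals directly. Guarded to short sequences.
#'
#' @param rna Character scalar over \{A,C,G,U,T\}, at most `max_len` nt.
#' @param params A [structure_params()].
#' @param max_len Length guard (default 18).
#' @param max_structures Abort beyond this many structures (default 5e5).
#' @return List with `P` (marginal matrix), `Z` (total weight),
#'   `n_structures`.
#' @export
enumerate_pair_probabilities <- function(rna, params = structure_params(),
                                         max_len = 18L,
                                         max_structures = 5e5) {
  s <- check_rna_alphabet(rna)
  n <- nchar(s)
  if (n > max_len) stop("enumeration oracle limited to ", max_len, " nt")
  chars <- chartr("T", "U", strsplit(s, "")[[1L]])
  ok_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  ml <- params$min_loop
  # structures over [i, j] as lists of pair matrices (2 columns, 1-based)
  structures <- function(i, j) {
    if (j < i) return(list(matrix(integer(0), ncol = 2L)))
    out <- structures(i, j - 1L)               # j unpaired
    ks <- seq_len(max(0L, j - ml - 1L - i + 1L)) + i - 1L
    for (k in ks) {
      if (!ok_pair(chars[k], chars[j])) next
      left <- structures(i, k - 1L)
      inner <- structures(k + 1L, j - 1L)
      for (a in left) for (b in inner) {
        out[[length(out) + 1L]] <- rbind(a, b, c(k, j))
      }
      if (length(out) > max_structures)
        stop("structure count exceeds max_structures")
    }
    out
  }
  all_s <- structures(1L, n)
  w <- params$pair_weight
  P <- matrix(0, n, n)
  Z <- 0
  for (st in all_s) {
    wt <- w^nrow(st)
    Z <- Z + wt
    if (nrow(st) > 0L) {
      P[st] <- P[st] + wt
      P[st[, 2:1, drop = FALSE]] <- P[st[, 2:1, drop = FALSE]] + wt
    }
  }
  list(P = P / Z, Z = Z, n_structures = length(all_s))
}

#' Per-position pairing profile from a pair-probability matrix
#'
#' @param P Symmetric pair-probability matrix.
#' @return Data frame with `position` (0-based), `p_unpaired`
#'   (`1 - sum_j P(i, j)`), and `p_paired` (`max_j P(i, j)`).
#' @export
unpaired_profile <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  n <- nrow(P)
  if (n == 0L)
    return(data.frame(position = integer(0), p_unpaired = numeric(0),
                      p_paired = numeric(0)))
  pu <- pmin(pmax(1 - rowSums(P), 0), 1)
  pp <- if (n == 1L) 0 else apply(P, 1L, max)
  data.frame(position = 0:(n - 1L), p_unpaired = pu, p_paired = pp)
}

#' Mask paired nucleotides with 'N' before triplex search
#'
#' Position i is replaced by `'N'` when its pairing evidence reaches
#' `pairing_cutoff`; all other characters are left untouched. Two modes
#' mirror the two ways an accessibility track can be thresholded:
#' `"per_pair"` uses `p_paired` (the maximal single-pair probability, the
#' semantics of RNAplfold's `-c` cutoff on printed pairs) and `"unpaired"`
#' uses `1 - p_unpaired` (total pairedness, the only information a `_lunp`
#' track carries).
#'
#' @param rna Character scalar, same length as the profile.
#' @param profile Data frame from [unpaired_profile()] or [read_lunp()].
#' @param params A [structure_params()].
#' @param mode `"per_pair"` or `"unpaired"`; defaults to `"per_pair"` when
#'   the profile has a genuine `p_paired` column.
#' @return Masked sequence (same length, characters upper-cased only at
#'   masked positions being replaced by `N`).
#' @export
mask_paired <- function(rna, profile, params = structure_params(),
                        mode = c("per_pair", "unpaired")) {
  mode <- match.arg(mode)
  stopifnot(is.character(rna), length(rna) == 1L)
  if (nchar(rna) != nrow(profile))
    stop("sequence length (", nchar(rna), ") != profile length (",
         nrow(profile), ")")
  score <- if (mode == "per_pair") profile$p_paired else 1 - profile$p_unpaired
  if (is.null(score)) stop("profile lacks the column required by mode ", mode)
  chars <- strsplit(rna, "")[[1L]]
  chars[!is.na(score) & score >= params$pairing_cutoff] <- "N"
  paste(chars, collapse = "")
}

#' Full accessibility profile of an RNA: probabilities plus mask flags
#'
#' Convenience wrapper chaining [pair_probabilities()],
#' [unpaired_profile()], and the masking rule.
#'
#' @inheritParams pair_probabilities
#' @return List with `profile` (data frame adding a `masked` flag) and
#'   `masked_rna`.
#' @export
accessibility_profile <- function(rna, params = structure_params()) {
  P <- pair_probabilities(rna, params)
  prof <- unpaired_profile(P)
  prof$masked <- prof$p_paired >= params$pairing_cutoff
  list(profile = prof, masked_rna = mask_paired(rna, prof, params))
}
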