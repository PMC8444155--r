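# shared brute-force oracles and fixture builders for the suite

# exhaustive enumeration of the Fisher two-sided p over all tables with the
# observed margins, using explicit binomial-coefficient arithmetic
enum_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- vapply(ks, function(k)
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1)),
    numeric(1))
  sum(pr[pr <= pr[ks == a] * (1 + 1e-7)])
}

# quadratic interval-overlap scan: which of the query intervals overlap any
# subject interval (all data frames with chrom/start/end, half-open)
brute_any_overlap <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    any(subject$chrom == query$chrom[i] &
          subject$start < query$end[i] &
          subject$end > query$start[i])
  }, logical(1))
}

# union-merge of 0-based half-open intervals with a gap tolerance, by
# direct sweep (oracle for cluster_dbds)
brute_merge_intervals <- function(starts, ends, gap = 0L) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  out <- NULL
  for (k in seq_along(starts)[-1L]) {
    if (starts[k] - me <= gap) {
      me <- max(me, ends[k])
    } else {
      out <- rbind(out, c(ms, me))
      ms <- starts[k]; me <- ends[k]
    }
  }
  rbind(out, c(ms, me))
}

# brute-force nearest gene by full scan (oracle for annotate_nearest_gene)
brute_nearest_gene <- function(mid, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(list(gene = "", distance = Inf))
  best <- NULL
  for (k in seq_len(nrow(g))) {
    d <- if (mid < g$start[k]) g$start[k] - mid
    else if (mid >= g$end[k]) (g$end[k] - 1L) - mid
    else 0L
    cand <- list(gene = g$name[k], distance = d, start = g$start[k])
    if (is.null(best) || abs(d) < abs(best$distance) ||
        (abs(d) == abs(best$distance) &&
         (cand$start < best$start ||
          (cand$start == best$start && cand$gene < best$gene))))
      best <- cand
  }
  best[c("gene", "distance")]
}

random_rna <- function(n, alpha = c("A", "C", "G", "U")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

random_dna <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# one-window data frame for find_triplexes
one_window <- function(seq, start = 0L, chrom = "win", id = "w1") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + nchar(seq)), seq = seq,
             probe_id = id, stringsAsFactors = FALSE)
}
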