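#' Construct a beta-value matrix with sample group labels
#'
#' Container for methylation-array beta values (methylation fractions in
#' \[0,1\]) for a two-group cohort, e.g. mutation carriers versus wild type.
#'
#' @param values Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param group Character or factor vector of per-sample labels, levels
#'   `mut` and `wt`, aligned with `colnames(values)`.
#' @return An object of class `beta_matrix`: a list with `values` and
#'   `group`.
#' @export
beta_matrix <- function(values, group) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (length(group) != ncol(values))
    stop("need one group label per sample")
  group <- factor(as.character(group), levels = c("mut", "wt"))
  if (anyNA(group)) stop("groups must be 'mut' or 'wt'")
  rng <- range(values, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("beta values must lie in [0,1]")
  if (any(table(group) < 2L)) stop("need >= 2 samples per group")
  structure(list(values = values, group = group), class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples (", sum(x$group == "mut"), "mut /", sum(x$group == "wt"),
      "wt )\n")
  invisible(x)
}

#' Classifier thresholds for hypermethylation calls
#'
#' @param fdr_threshold FDR cutoff for hypermethylation (default 0.05).
#' @param delta_threshold Minimum beta-scale group difference (default 0.1).
#' @param test_variant `"welch"` (unequal variances, the default — robust to
#'   the strong group-size imbalance typical of mutation cohorts) or
#'   `"student"` (pooled variance).
#' @return List of class `classifier_params`.
#' @export
classifier_params <- function(fdr_threshold = 0.05, delta_threshold = 0.1,
                              test_variant = c("welch", "student")) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            delta_threshold > 0, delta_threshold < 1)
  structure(list(fdr_threshold = fdr_threshold,
                 delta_threshold = delta_threshold,
                 test_variant = match.arg(test_variant)),
            class = "classifier_params")
}

#' Two-sample t test (Welch or Student), scalar interface
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom, two-sided. Degenerate inputs follow explicit conventions: zero
#' variance in both groups with equal means gives `t = 0, p = 1`; zero
#' pooled standard error with unequal means gives `p = 0` with a
#' `degenerate` flag.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param variant `"welch"` or `"student"`.
#' @return List with `t`, `df`, `p_value`, `degenerate`.
#' @export
welch_t_test <- function(x, y, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  r <- t_rows(matrix(c(x, y), nrow = 1L),
              rep(c("mut", "wt"), c(length(x), length(y))), variant)
  list(t = r$t[1L], df = r$df[1L], p_value = r$p[1L],
       degenerate = r$degenerate[1L])
}

# Row-wise two-sample t tests, vectorised over probes. group aligns with
# columns of mat; returns delta = mean(mut) - mean(wt).
t_rows <- function(mat, group, variant = "welch") {
  g <- as.character(group)
  m <- mat[, g == "mut", drop = FALSE]
  w <- mat[, g == "wt", drop = FALSE]
  n1 <- ncol(m); n2 <- ncol(w)
  m1 <- rowMeans(m); m2 <- rowMeans(w)
  v1 <- rowSums((m - m1)^2) / (n1 - 1)
  v2 <- rowSums((w - m2)^2) / (n2 - 1)
  delta <- m1 - m2
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(delta))
  }
  degenerate <- se2 == 0
  t <- ifelse(degenerate, ifelse(delta == 0, 0, sign(delta) * Inf),
              delta / sqrt(se2))
  p <- ifelse(degenerate, ifelse(delta == 0, 1, 0),
              2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p, delta = delta, degenerate = degenerate)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return Vector of BH-adjusted q-values (via [stats::p.adjust()]).
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Classify CpG probes as hypermethylated, non-hypermethylated, or other
#'
#' Per-probe two-group comparison on a beta matrix. A probe is
#' hypermethylated (`HM`) when its BH q-value is at most `fdr_threshold`
#' and its delta (mean mut minus mean wt) is at least `delta_threshold`;
#' non-hypermethylated (`NHM`) when q exceeds the threshold and |delta| is
#' below the delta threshold; everything else is `OTHER`. Probes with any
#' missing beta value are dropped with a message.
#'
#' @param beta A [beta_matrix()].
#' @param params A [classifier_params()].
#' @param probes Optional data frame (`probe_id`, `chrom`, `pos`) supplying
#'   coordinates; probes absent from it get `NA` coordinates.
#' @return Data frame with columns `probe_id`, `chrom`, `pos`, `delta`,
#'   `p_value`, `q_value`, `klass`.
#' @export
classify_cpgs <- function(beta, params = classifier_params(), probes = NULL) {
  stopifnot(inherits(beta, "beta_matrix"))
  vals <- beta$values
  complete <- rowSums(is.na(vals)) == 0L
  if (any(!complete)) {
    message("dropping ", sum(!complete), " probe(s) with missing values")
    vals <- vals[complete, , drop = FALSE]
  }
  r <- t_rows(vals, beta$group, params$test_variant)
  q <- bh_fdr(r$p)
  klass <- ifelse(q <= params$fdr_threshold & r$delta >= params$delta_threshold,
                  "HM",
           ifelse(q > params$fdr_threshold & abs(r$delta) < params$delta_threshold,
                  "NHM", "OTHER"))
  out <- data.frame(probe_id = rownames(vals), chrom = NA_character_,
                    pos = NA_integer_, delta = r$delta, p_value = r$p,
                    q_value = q, klass = klass,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(probes)) {
    i <- match(out$probe_id, probes$probe_id)
    out$chrom <- probes$chrom[i]
    out$pos <- probes$pos[i]
  }
  out
}
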