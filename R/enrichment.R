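#' Parameters for DNA-binding-domain enrichment
#'
#' @param n_resamples Number of background resamples (default 100).
#' @param gap_tolerance Maximum gap (nt) between TFO intervals merged into
#'   one DNA binding domain (default 0: overlapping or abutting intervals
#'   merge).
#' @param seed Seed for the resampling draws.
#' @return List of class `enrichment_params`.
#' @export
enrichment_params <- function(n_resamples = 100L, gap_tolerance = 0L,
                              seed = 1L) {
  stopifnot(n_resamples >= 1L, gap_tolerance >= 0L)
  structure(list(n_resamples = as.integer(n_resamples),
                 gap_tolerance = as.integer(gap_tolerance),
                 seed = as.integer(seed)),
            class = "enrichment_params")
}

#' Fisher's exact test for a 2x2 table, from the hypergeometric law
#'
#' Two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (up to a
#' small relative tolerance for floating-point ties). The odds ratio is the
#' sample odds ratio `(a d) / (b c)`.
#'
#' @param a,b,c,d Nonnegative counts: rows are the first classification
#'   (e.g. HM / NHM), columns the second (e.g. triplex-positive /
#'   negative), so `a` = row 1 column 1.
#' @return List with `odds_ratio` (`NA` when a margin is empty, `Inf` when
#'   only the denominator is 0), `p_value`, and `table`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  tab <- matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE,
                dimnames = list(NULL, NULL))
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab))
  odds <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  # support of the (1,1) cell given the margins
  k <- max(0, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  list(odds_ratio = odds, p_value = min(p, 1), table = tab)
}

#' Hypermethylation-protection contingency table and Fisher test
#'
#' Cross-classifies windows by methylation class (HM / NHM; OTHER is
#' excluded) and triplex status (positive / negative), and attaches the
#' two-sided Fisher result. An odds ratio below 1 means hypermethylated
#' windows are depleted of triplex targets, i.e. triplex-capable loci are
#' protected from hypermethylation.
#'
#' @param classifications Data frame from [classify_cpgs()].
#' @param windows Windows data frame carrying `probe_id` and
#'   `triplex_positive` (see [triplex_positive()]).
#' @return List with `table` (2x2 matrix, rows HM/NHM, columns
#'   positive/negative), `fisher` (from [fisher_exact_2x2()]), and `n_other`
#'   (excluded probes).
#' @export
hm_protection_table <- function(classifications, windows) {
  i <- match(windows$probe_id, classifications$probe_id)
  klass <- classifications$klass[i]
  keep <- !is.na(klass) & klass %in% c("HM", "NHM")
  klass <- klass[keep]
  pos <- windows$triplex_positive[keep]
  a <- sum(klass == "HM" & pos); b <- sum(klass == "HM" & !pos)
  c <- sum(klass == "NHM" & pos); d <- sum(klass == "NHM" & !pos)
  if (a + b == 0L || c + d == 0L)
    warning("degenerate contingency table: an entire class is empty")
  fisher <- fisher_exact_2x2(a, b, c, d)
  tab <- matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE,
                dimnames = list(klass = c("HM", "NHM"),
                                triplex = c("positive", "negative")))
  list(table = tab, fisher = fisher, n_other = sum(!keep))
}

#' Cluster TFO intervals into DNA binding domains
#'
#' Merges the RNA-side (TFO) intervals of triplex hits whose gaps are at
#' most `gap_tolerance` nt into maximal domains, counting member TFOs and
#' distinct target regions per domain.
#'
#' @param hits Hits data frame from [find_triplexes()].
#' @param params An [enrichment_params()].
#' @return Data frame with `rna_start`, `rna_end` (0-based half-open),
#'   `n_tfos`, `n_target_regions_hit`, ordered by `rna_start`.
#' @export
cluster_dbds <- function(hits, params = enrichment_params()) {
  if (nrow(hits) == 0L)
    return(data.frame(rna_start = integer(0), rna_end = integer(0),
                      n_tfos = integer(0),
                      n_target_regions_hit = integer(0)))
  ir <- IRanges::IRanges(start = hits$rna_start + 1L, end = hits$rna_end)
  red <- IRanges::reduce(ir, min.gapwidth = params$gap_tolerance + 1L,
                         with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  data.frame(
    rna_start = IRanges::start(red) - 1L,
    rna_end = IRanges::end(red),
    n_tfos = lengths(revmap),
    n_target_regions_hit = vapply(revmap, function(ix)
      length(unique(hits$window_id[ix])), integer(1)))
}

#' Background-resampled enrichment of DNA binding domains
#'
#' For each domain, the observed statistic is the number of target regions
#' carrying at least one hit whose TFO overlaps the domain. The null draws
#' `n_resamples` samples of `n_targets` regions (without replacement) from
#' the background pool and counts, per draw, how many sampled regions the
#' domain hits. Reported per domain: background mean and sd, the z-score
#' `(observed - mean) / sd` (`NA` when sd is 0), the one-sided add-one
#' empirical p-value `(1 + #{resample >= observed}) / (n_resamples + 1)`,
#' and a BH-adjusted q across domains.
#'
#' @param dbds Data frame from [cluster_dbds()] (computed on target hits).
#' @param target_hits Hits of the RNA against the target regions.
#' @param background_hits Hits of the same RNA against the background pool.
#' @param background_ids Character vector: all region ids in the background
#'   pool (hit or not).
#' @param n_targets Number of target regions (sample size per draw).
#' @param params An [enrichment_params()]; `params$seed` fixes the draws.
#' @return `dbds` with columns `background_mean`, `background_sd`,
#'   `z_score`, `empirical_p`, `q_value`.
#' @export
dbd_enrichment <- function(dbds, target_hits, background_hits,
                           background_ids, n_targets,
                           params = enrichment_params()) {
  if (nrow(dbds) == 0L) {
    dbds$background_mean <- numeric(0); dbds$background_sd <- numeric(0)
    dbds$z_score <- numeric(0); dbds$empirical_p <- numeric(0)
    dbds$q_value <- numeric(0)
    return(dbds)
  }
  if (length(background_ids) < n_targets)
    stop("background pool (", length(background_ids),
         ") smaller than the number of target regions (", n_targets, ")")
  overlaps_dbd <- function(hits, s, e) {
    hits$rna_start < e & hits$rna_end > s
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)
  draws <- replicate(params$n_resamples,
                     sample(background_ids, n_targets, replace = FALSE),
                     simplify = FALSE)
  res <- lapply(seq_len(nrow(dbds)), function(k) {
    s <- dbds$rna_start[k]; e <- dbds$rna_end[k]
    obs <- length(unique(
      target_hits$window_id[overlaps_dbd(target_hits, s, e)]))
    bg_hit_ids <- unique(
      background_hits$window_id[overlaps_dbd(background_hits, s, e)])
    counts <- vapply(draws, function(d) sum(d %in% bg_hit_ids), integer(1))
    mu <- mean(counts); sdv <- stats::sd(counts)
    c(obs = obs, mean = mu, sd = sdv,
      z = if (sdv == 0) NA_real_ else (obs - mu) / sdv,
      p = (1 + sum(counts >= obs)) / (params$n_resamples + 1))
  })
  res <- do.call(rbind, res)
  dbds$n_target_regions_hit <- as.integer(res[, "obs"])
  dbds$background_mean <- res[, "mean"]
  dbds$background_sd <- res[, "sd"]
  dbds$z_score <- res[, "z"]
  dbds$empirical_p <- res[, "p"]
  dbds$q_value <- bh_fdr(dbds$empirical_p)
  dbds
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mann-Whitney rank-sum test on two delta samples
#'
#' Exact mode (default for pooled n <= 12 and automatic there) enumerates
#' all assignments of the pooled values to the two groups and reports the
#' two-sided permutation p-value of the U statistic; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' All values tied gives p = 1.
#'
#' @param x,y Numeric vectors, each nonempty.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) mode;
#'   `NULL` (default) selects exact when `length(x) + length(y) <= 12`.
#' @return List with `U` (number of (x, y) pairs with x > y, ties counted
#'   1/2), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- N <= 12L
  mu <- n1 * n2 / 2
  if (exact) {
    if (length(unique(pooled)) == 1L)
      return(list(U = U, p_value = 1, method = "exact"))
    sel <- utils::combn(N, n1)
    us <- apply(sel, 2L, function(ix)
      sum(rk[ix]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p_value = p, method = "exact"))
  }
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-max(z, 0))),
       method = "normal")
}
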