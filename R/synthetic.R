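#' Configuration for the synthetic cohort and genome generator
#'
#' The generator emulates the statistical structure of the real study
#' design at desk scale: a two-group methylation-array cohort (13 mutation
#' carriers vs 173 wild type by default), a genome with CpG probes of which
#' a planted fraction sits inside guanine-rich purine tracts complementary
#' to the lncRNA's triplex-forming tract, a structured lncRNA with planted
#' hairpins plus an unpaired purine-rich TFO tract, and true/decoy
#' RNA-chromatin contacts.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length (bp) of each chromosome.
#' @param gc_fraction Background GC fraction of the genome.
#' @param n_probes Number of CpG probes.
#' @param n_mut_samples,n_wt_samples Cohort group sizes.
#' @param frac_hyper Fraction of probes planted as hypermethylated (the
#'   effect is applied only when `effect_delta > 0`).
#' @param effect_delta Beta-scale shift added to hyperprobes in the mut
#'   group.
#' @param beta_noise_sd Gaussian noise sd on the beta scale.
#' @param frac_protected Fraction of probes placed inside planted purine
#'   tracts (the triplex-protected set).
#' @param baseline_range Range of per-probe baseline methylation (uniform).
#' @param link_protection When `TRUE` (default) hyperprobes are drawn from
#'   unprotected probes only, planting the protection association; when
#'   `FALSE` hypermethylation is assigned independently of protection (the
#'   null for calibration studies).
#' @param lnc_length lncRNA length (nt).
#' @param n_hairpins Number of planted hairpins (stem 8 bp, loop 4 nt).
#' @param tfo_tract List `(start, end, composition)`: the planted
#'   triplex-forming tract on the RNA (0-based half-open) and the purine
#'   repeat unit tiled across it (default `"GGGGA"`, 80% G).
#' @param n_true_contacts,n_decoy_contacts Planted contact counts (defaults
#'   29 true and 128 decoys, 157 records total).
#' @param contact_flank Distance scale for contact placement: true-contact
#'   DNA anchors land within this distance of a protected window, decoys at
#'   least twice this distance from every protected window.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chrom = 2L, chrom_length = 150000L,
                             gc_fraction = 0.41, n_probes = 200L,
                             n_mut_samples = 13L, n_wt_samples = 173L,
                             frac_hyper = 0.2, effect_delta = 0.2,
                             beta_noise_sd = 0.05, frac_protected = 0.15,
                             baseline_range = c(0.2, 0.6),
                             link_protection = TRUE,
                             lnc_length = 600L, n_hairpins = 3L,
                             tfo_tract = list(start = 400L, end = 500L,
                                              composition = "GGGGA"),
                             n_true_contacts = 29L,
                             n_decoy_contacts = 128L,
                             contact_flank = 3000L, seed = 1L) {
  fr <- c(gc_fraction = gc_fraction, frac_hyper = frac_hyper,
          beta_noise_sd = beta_noise_sd, frac_protected = frac_protected)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0,1]: ",
         paste(names(fr)[fr < 0 | fr > 1], collapse = ", "))
  stopifnot(n_mut_samples + n_wt_samples >= 4L,
            n_mut_samples >= 2L, n_wt_samples >= 2L,
            tfo_tract$start >= 0L, tfo_tract$end <= lnc_length,
            tfo_tract$end > tfo_tract$start,
            frac_hyper + frac_protected <= 1,
            effect_delta >= 0, baseline_range[1L] >= 0,
            baseline_range[2L] <= 1, lnc_length >= 100L)
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 gc_fraction = gc_fraction, n_probes = as.integer(n_probes),
                 n_mut_samples = as.integer(n_mut_samples),
                 n_wt_samples = as.integer(n_wt_samples),
                 frac_hyper = frac_hyper, effect_delta = effect_delta,
                 beta_noise_sd = beta_noise_sd,
                 frac_protected = frac_protected,
                 baseline_range = baseline_range,
                 link_protection = isTRUE(link_protection),
                 lnc_length = as.integer(lnc_length),
                 n_hairpins = as.integer(n_hairpins),
                 tfo_tract = tfo_tract,
                 n_true_contacts = as.integer(n_true_contacts),
                 n_decoy_contacts = as.integer(n_decoy_contacts),
                 contact_flank = as.integer(contact_flank),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# the planted TFO tract sequence: composition unit tiled across the tract
tfo_tract_seq <- function(cfg) {
  tr <- cfg$tfo_tract
  len <- tr$end - tr$start
  unit <- toupper(tr$composition)
  substr(paste(rep(unit, ceiling(len / nchar(unit))), collapse = ""), 1L, len)
}

# TRUE when a window sequence contains a >= min_len interval with G
# fraction >= min_frac (the criterion used both by the planting repair and
# by the recovery checks)
has_g_tract <- function(seq, min_len = 10L, min_frac = 0.7) {
  g <- cumsum(c(0L, strsplit(toupper(seq), "")[[1L]] == "G"))
  L <- length(g) - 1L
  for (len in min_len:L) {
    cnt <- g[(len + 1L):(L + 1L)] - g[1L:(L - len + 1L)]
    if (any(cnt >= min_frac * len - 1e-9)) return(TRUE)
  }
  FALSE
}

# locate one offending `base` inside the first >= min_len interval whose
# `base` fraction reaches min_frac; returns its 1-based index, or 0L.
# base "G" finds plus-strand purine tracts, base "C" their minus-strand
# counterparts (a C tract is a guanine tract on the reverse complement).
first_g_tract_g <- function(seq, min_len = 10L, min_frac = 0.7,
                            forbidden = integer(0), base = "G") {
  ch <- strsplit(toupper(seq), "")[[1L]]
  g <- cumsum(c(0L, ch == base))
  L <- length(ch)
  for (len in min_len:L) {
    cnt <- g[(len + 1L):(L + 1L)] - g[1L:(L - len + 1L)]
    hit <- which(cnt >= min_frac * len - 1e-9)
    if (length(hit) > 0L) {
      a <- hit[1L]
      gpos <- setdiff(which(ch[a:(a + len - 1L)] == base) + a - 1L,
                      forbidden)
      if (length(gpos) > 0L) {
        mid <- a + len / 2
        return(gpos[which.min(abs(gpos - mid))])
      }
    }
  }
  0L
}

#' Generate a synthetic genome with planted CpG probes and purine tracts
#'
#' Every probe sits on a planted `CG` dinucleotide (the probe position is
#' the C). A fraction `frac_protected` of probes additionally gets a
#' guanine-rich purine tract (a reversed segment of the planted RNA TFO
#' tract, placed immediately downstream of the CpG) inside its 100-nt
#' window; the windows of all remaining probes are scrubbed of incidental
#' guanine-rich tracts so that tract presence is a clean planted label.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `genome` (named character vector), `probes`
#'   (`probe_id`, `chrom`, `pos`, 0-based), `protected_probe_ids`.
#' @export
generate_genome <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  spacing <- 160L
  margin <- 60L
  per_chrom_cap <- max(0L, (cfg$chrom_length - 2L * margin) %/% spacing)
  if (cfg$chrom_length < 200L)
    stop("sizing error: chrom_length must be >= 200")
  if (per_chrom_cap * cfg$n_chrom < cfg$n_probes)
    stop("sizing error: chromosomes too short to host ", cfg$n_probes,
         " probes at ", spacing, " bp spacing")
  probs <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
             G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
  genome <- vapply(seq_len(cfg$n_chrom), function(i)
    paste(sample(names(probs), cfg$chrom_length, replace = TRUE,
                 prob = probs), collapse = ""), character(1))
  names(genome) <- paste0("chr", seq_len(cfg$n_chrom))
  if (cfg$n_probes == 0L)
    return(list(genome = genome,
                probes = data.frame(probe_id = character(0),
                                    chrom = character(0),
                                    pos = integer(0),
                                    stringsAsFactors = FALSE),
                protected_probe_ids = character(0)))
  # spread probes over chromosomes, spaced positions per chromosome
  chrom_of <- rep(names(genome), length.out = cfg$n_probes)
  chrom_of <- sort(chrom_of)
  pos <- integer(cfg$n_probes)
  for (cn in unique(chrom_of)) {
    k <- sum(chrom_of == cn)
    slots <- sort(sample.int(per_chrom_cap, k))
    base <- margin + (slots - 1L) * spacing
    jitter <- sample.int(spacing - 120L, k, replace = TRUE) - 1L
    pos[chrom_of == cn] <- base + jitter
  }
  probes <- data.frame(probe_id = sprintf("cg%05d", seq_len(cfg$n_probes)),
                       chrom = chrom_of, pos = pos,
                       stringsAsFactors = FALSE)
  n_prot <- round(cfg$frac_protected * cfg$n_probes)
  protected <- sort(sample(probes$probe_id, n_prot))
  tfo_seq <- tfo_tract_seq(cfg)
  chars <- lapply(genome, function(s) strsplit(s, "")[[1L]])
  for (i in seq_len(nrow(probes))) {
    cc <- probes$chrom[i]; p <- probes$pos[i]
    chars[[cc]][p + 1L] <- "C"
    chars[[cc]][p + 2L] <- "G"
    if (probes$probe_id[i] %in% protected) {
      tract_len <- sample(25:35, 1L)
      a <- sample.int(nchar(tfo_seq) - tract_len + 1L, 1L)
      tract <- rev(strsplit(substr(tfo_seq, a, a + tract_len - 1L),
                            "")[[1L]])
      chars[[cc]][(p + 3L):(p + 2L + tract_len)] <- tract
    }
  }
  # scrub incidental guanine tracts from unprotected probe windows
  half <- 50L
  for (i in which(!(probes$probe_id %in% protected))) {
    cc <- probes$chrom[i]; p <- probes$pos[i]
    a <- max(0L, p - half); b <- min(cfg$chrom_length, p - half + 2L * half)
    cpg_local <- c(p, p + 1L) - a + 1L
    for (iter in 1:200) {
      win <- paste(chars[[cc]][(a + 1L):b], collapse = "")
      gi <- first_g_tract_g(win, forbidden = cpg_local, base = "G")
      if (gi > 0L) {
        chars[[cc]][a + gi] <- "T"
        next
      }
      ci <- first_g_tract_g(win, forbidden = cpg_local, base = "C")
      if (ci == 0L) break
      chars[[cc]][a + ci] <- "A"
    }
  }
  genome <- vapply(chars, paste, character(1), collapse = "")
  list(genome = genome, probes = probes,
       protected_probe_ids = protected)
}

#' Generate a two-group beta matrix with planted hypermethylation
#'
#' Wild-type betas are per-probe baselines plus Gaussian noise clipped to
#' \[0,1\]; planted hyperprobes additionally receive `effect_delta` in the
#' mutation group. When `link_protection` is `TRUE`, hyperprobes are drawn
#' from unprotected probes only, so protection and hypermethylation are
#' mutually exclusive by construction; with `FALSE` they are independent.
#'
#' @param cfg A [synthetic_config()].
#' @param probes Probe table from [generate_genome()].
#' @param protected_probe_ids Planted protected set (may be empty).
#' @return List with `beta` (a [beta_matrix()]) and `truth` (list with
#'   `hyper_probe_ids`, `protected_probe_ids`).
#' @export
generate_methylation <- function(cfg, probes,
                                 protected_probe_ids = character(0)) {
  stopifnot(nrow(probes) > 0L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)
  n <- nrow(probes)
  n_hyper <- if (cfg$effect_delta > 0) round(cfg$frac_hyper * n) else 0L
  pool <- if (cfg$link_protection)
    setdiff(probes$probe_id, protected_probe_ids) else probes$probe_id
  if (n_hyper > length(pool))
    stop("frac_hyper too large for the unprotected probe pool")
  hyper <- sort(sample(pool, n_hyper))
  baseline <- stats::runif(n, cfg$baseline_range[1L], cfg$baseline_range[2L])
  names(baseline) <- probes$probe_id
  if (n_hyper > 0L && max(baseline[hyper]) + cfg$effect_delta > 1)
    warning("baseline + effect_delta exceeds 1 for some probes; ",
            "clipping weakens the planted effect")
  n_s <- cfg$n_mut_samples + cfg$n_wt_samples
  group <- rep(c("mut", "wt"), c(cfg$n_mut_samples, cfg$n_wt_samples))
  vals <- matrix(stats::rnorm(n * n_s, mean = baseline,
                              sd = cfg$beta_noise_sd), nrow = n)
  shift <- matrix(0, n, n_s)
  shift[probes$probe_id %in% hyper, group == "mut"] <- cfg$effect_delta
  vals <- pmin(pmax(vals + shift, 0), 1)
  rownames(vals) <- probes$probe_id
  colnames(vals) <- c(sprintf("mut_%03d", seq_len(cfg$n_mut_samples)),
                      sprintf("wt_%03d", seq_len(cfg$n_wt_samples)))
  list(beta = beta_matrix(vals, group),
       truth = list(hyper_probe_ids = hyper,
                    protected_probe_ids = protected_probe_ids))
}

#' Generate a synthetic lncRNA with planted hairpins and a TFO tract
#'
#' Hairpins (stem 8 bp of exact reverse complements, loop 4 nt) are placed
#' upstream of the TFO tract; the tract itself is tiled from the purine
#' composition unit, which cannot base-pair with itself, keeping it
#' accessible. A layout that cannot fit the hairpins outside the tract is
#' an error.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `rna` (character, U alphabet), `truth` (list with
#'   `planted_tfo_interval`, `hairpins` data frame of stem coordinates).
#' @export
generate_lncrna <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 2L)
  n <- cfg$lnc_length
  tr <- cfg$tfo_tract
  stem <- 8L; loop <- 4L
  unit <- 2L * stem + loop
  chars <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  region_end <- tr$start - 4L  # hairpins end before the tract
  if (cfg$n_hairpins > 0L && cfg$n_hairpins * (unit + 4L) > region_end)
    stop("layout error: hairpins do not fit upstream of the TFO tract")
  hp <- data.frame(start = integer(0), end = integer(0))
  if (cfg$n_hairpins > 0L) {
    slot_w <- region_end %/% cfg$n_hairpins
    starts <- (seq_len(cfg$n_hairpins) - 1L) * slot_w +
      vapply(seq_len(cfg$n_hairpins), function(i)
        sample.int(slot_w - unit, 1L), integer(1))
    comp <- c(A = "U", C = "G", G = "C", U = "A")
    for (s in starts) {
      arm <- sample(c("A", "C", "G", "U"), stem, replace = TRUE)
      chars[(s + 1L):(s + stem)] <- arm
      chars[(s + stem + loop + 1L):(s + unit)] <- rev(unname(comp[arm]))
    }
    hp <- data.frame(start = starts, end = starts + unit)
  }
  tract <- strsplit(chartr("T", "U", tfo_tract_seq(cfg)), "")[[1L]]
  chars[(tr$start + 1L):tr$end] <- tract
  list(rna = paste(chars, collapse = ""),
       truth = list(planted_tfo_interval = c(tr$start, tr$end),
                    hairpins = hp))
}

#' Generate true and decoy RNA-chromatin contacts
#'
#' True contacts get DNA anchors within `contact_flank` of a
#' triplex-positive window; decoys are placed at least `2 * contact_flank`
#' away from every triplex-positive window, so at validation flank equal to
#' `contact_flank` every true contact intersects an expanded positive
#' window and no decoy does. RNA anchors are random subintervals of the
#' lncRNA source locus.
#'
#' @param cfg A [synthetic_config()].
#' @param rna_locus List with `chrom`, `start`, `end`: genomic source of
#'   the lncRNA.
#' @param positive_windows Data frame (`chrom`, `start`, `end`) of
#'   triplex-positive windows; must be nonempty when `n_true_contacts > 0`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return List with `contacts` (BEDPE-style data frame) and `truth` (list
#'   with `true_contact_ids`).
#' @export
generate_contacts <- function(cfg, rna_locus, positive_windows,
                              chrom_lengths) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 3L)
  if (cfg$n_true_contacts > 0L && nrow(positive_windows) == 0L)
    stop("no triplex-positive windows to anchor true contacts")
  anchor_w <- 200L
  rna_w <- 100L
  flank <- cfg$contact_flank
  mk_rna_anchor <- function() {
    s <- rna_locus$start +
      sample.int(max(1L, rna_locus$end - rna_locus$start - rna_w), 1L) - 1L
    c(s, s + rna_w)
  }
  rows <- list()
  for (k in seq_len(cfg$n_true_contacts)) {
    w <- positive_windows[sample.int(nrow(positive_windows), 1L), ]
    gap <- sample.int(max(1L, floor(0.8 * flank)), 1L) - 1L
    side <- sample(c(-1L, 1L), 1L)
    ds <- if (side > 0L) w$end + gap else w$start - gap - anchor_w
    ds <- max(0L, min(ds, chrom_lengths[[w$chrom]] - anchor_w))
    ra <- mk_rna_anchor()
    rows[[length(rows) + 1L]] <- data.frame(
      rna_chrom = rna_locus$chrom, rna_start = ra[1L], rna_end = ra[2L],
      dna_chrom = w$chrom, dna_start = as.integer(ds),
      dna_end = as.integer(ds + anchor_w),
      id = sprintf("true_%03d", k), stringsAsFactors = FALSE)
  }
  # decoys: rejection-sample positions far from every positive window
  far_enough <- function(cn, s, e) {
    pw <- positive_windows[positive_windows$chrom == cn, , drop = FALSE]
    if (nrow(pw) == 0L) return(TRUE)
    gap <- pmax(pw$start - e, s - pw$end)
    all(gap >= 2L * flank)
  }
  tries <- 0L
  k <- 0L
  max_tries <- 10000L * max(1L, cfg$n_decoy_contacts)
  while (k < cfg$n_decoy_contacts) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("sizing error: insufficient genome space for decoy contacts")
    cn <- sample(names(chrom_lengths), 1L)
    s <- sample.int(chrom_lengths[[cn]] - anchor_w, 1L) - 1L
    if (!far_enough(cn, s, s + anchor_w)) next
    k <- k + 1L
    ra <- mk_rna_anchor()
    rows[[length(rows) + 1L]] <- data.frame(
      rna_chrom = rna_locus$chrom, rna_start = ra[1L], rna_end = ra[2L],
      dna_chrom = cn, dna_start = as.integer(s),
      dna_end = as.integer(s + anchor_w),
      id = sprintf("decoy_%03d", k), stringsAsFactors = FALSE)
  }
  contacts <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(rna_chrom = character(0), rna_start = integer(0),
               rna_end = integer(0), dna_chrom = character(0),
               dna_start = integer(0), dna_end = integer(0),
               id = character(0), stringsAsFactors = FALSE)
  list(contacts = contacts,
       truth = list(true_contact_ids =
                      grep("^true_", contacts$id, value = TRUE)))
}
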