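#' Assemble a pipeline configuration
#'
#' Collects input paths, per-stage parameter objects, and the seed into a
#' single validated configuration. Every default equals the study's stated
#' parameter where one exists (FDR 0.05, delta 0.1, pairing cutoff 0.1,
#' triplex length 10 / error 20% / guanine 70%, 100-nt windows, 100
#' resamples, 3000-bp flank).
#'
#' @param genome_fasta,probes_bed,beta_tsv,groups_tsv,lnc_fasta,contacts_bedpe
#'   Input paths. `contacts_bedpe` may be `NULL` to skip colocalization.
#' @param lunp Optional RNAplfold `_lunp` track; when given it replaces the
#'   internal structure model for masking.
#' @param rna_locus List (`chrom`, `start`, `end`): genomic source locus of
#'   the lncRNA (needed when contacts are supplied).
#' @param out_dir Output directory for artifacts and the JSON report.
#' @param classifier,structure,triplex,enrichment,coloc Stage parameter
#'   objects (see the corresponding `_params` constructors).
#' @param window_width Target-window width (default 100).
#' @param n_background Background pool size for domain enrichment.
#' @param seed Integer seed driving every random draw in the run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, probes_bed, beta_tsv, groups_tsv,
                            lnc_fasta, contacts_bedpe = NULL, lunp = NULL,
                            rna_locus = NULL, out_dir = tempfile("run_"),
                            classifier = classifier_params(),
                            structure = structure_params(),
                            triplex = triplex_params(),
                            enrichment = enrichment_params(),
                            coloc = coloc_params(),
                            window_width = 100L, n_background = 500L,
                            seed = 1L) {
  paths <- list(genome_fasta = genome_fasta, probes_bed = probes_bed,
                beta_tsv = beta_tsv, groups_tsv = groups_tsv,
                lnc_fasta = lnc_fasta)
  if (!is.null(contacts_bedpe)) paths$contacts_bedpe <- contacts_bedpe
  if (!is.null(lunp)) paths$lunp <- lunp
  for (field in names(paths)) {
    if (!file.exists(paths[[field]]))
      stop("input path for '", field, "' does not exist: ", paths[[field]])
  }
  structure(c(paths,
              list(rna_locus = rna_locus, out_dir = out_dir,
                   classifier = classifier, structure = structure,
                   triplex = triplex, enrichment = enrichment,
                   coloc = coloc, window_width = as.integer(window_width),
                   n_background = as.integer(n_background),
                   seed = as.integer(seed))),
            class = "pipeline_config")
}

#' Generate a full set of synthetic inputs on disk
#'
#' Runs all four generators and writes genome FASTA, probe BED, beta and
#' group TSVs, lncRNA FASTA, contact BEDPE, and the ground-truth JSON.
#' Contacts are anchored to the windows of the planted protected probes
#' (the by-construction triplex-positive set).
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return List with all file paths, the in-memory objects, and `truth`.
#' @export
simulate_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_genome(cfg)
  meth <- generate_methylation(cfg, gen$probes, gen$protected_probe_ids)
  lnc <- generate_lncrna(cfg)
  chrom_lengths <- stats::setNames(nchar(gen$genome), names(gen$genome))
  rna_locus <- list(chrom = names(gen$genome)[1L], start = 100L,
                    end = 100L + cfg$lnc_length)
  prot_windows <- build_windows(
    gen$probes[gen$probes$probe_id %in% gen$protected_probe_ids, ,
               drop = FALSE],
    chrom_lengths, width = 100L)
  con <- generate_contacts(cfg, rna_locus, prot_windows, chrom_lengths)
  paths <- list(
    genome_fasta = file.path(dir, "genome.fa"),
    probes_bed = file.path(dir, "probes.bed"),
    beta_tsv = file.path(dir, "beta.tsv"),
    groups_tsv = file.path(dir, "groups.tsv"),
    lnc_fasta = file.path(dir, "lncrna.fa"),
    contacts_bedpe = file.path(dir, "contacts.bedpe"),
    truth_json = file.path(dir, "truth.json"))
  write_fasta(gen$genome, paths$genome_fasta)
  write_bed(data.frame(chrom = gen$probes$chrom, start = gen$probes$pos,
                       end = gen$probes$pos + 2L,
                       name = gen$probes$probe_id), paths$probes_bed)
  write_beta_matrix(meth$beta, paths$beta_tsv, paths$groups_tsv)
  write_fasta(stats::setNames(lnc$rna, "lncRNA"), paths$lnc_fasta)
  write_bedpe(con$contacts, paths$contacts_bedpe)
  truth <- list(hyper_probe_ids = meth$truth$hyper_probe_ids,
                protected_probe_ids = gen$protected_probe_ids,
                planted_tfo_interval = lnc$truth$planted_tfo_interval,
                true_contact_ids = con$truth$true_contact_ids)
  jsonlite::write_json(truth, paths$truth_json, auto_unbox = FALSE)
  c(paths, list(genome = gen$genome, probes = gen$probes,
                beta = meth$beta, rna = lnc$rna,
                contacts = con$contacts, rna_locus = rna_locus,
                chrom_lengths = chrom_lengths, truth = truth))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: classify CpGs from the beta matrix; fold the lncRNA
#' (or ingest a `_lunp` track) and mask paired positions; build CpG target
#' windows and extract sequences; predict triplexes; test hypermethylation
#' protection and domain enrichment against a resampled background;
#' validate against RNA-chromatin contacts when supplied. All artifacts
#' are written under `config$out_dir`; the JSON report collects every
#' count and test statistic. Fully deterministic under `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return The report, invisibly also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  genome <- run_stage("read_inputs", read_fasta(config$genome_fasta))
  probes_bed <- run_stage("read_inputs",
                          read_intervals(config$probes_bed, "BED"))
  probes <- data.frame(probe_id = probes_bed$name, chrom = probes_bed$chrom,
                       pos = probes_bed$start, stringsAsFactors = FALSE)
  beta <- run_stage("read_inputs",
                    read_beta_matrix(config$beta_tsv, config$groups_tsv))
  rna <- run_stage("read_inputs", read_fasta(config$lnc_fasta))[[1L]]
  chrom_lengths <- stats::setNames(nchar(genome), names(genome))

  cls <- run_stage("classify",
                   classify_cpgs(beta, config$classifier, probes))
  utils::write.table(cls, file.path(config$out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  masked <- run_stage("structure", {
    if (!is.null(config$lunp)) {
      prof <- read_lunp(config$lunp)
      mask_paired(rna, prof, config$structure, mode = "unpaired")
    } else {
      acc <- accessibility_profile(rna, config$structure)
      utils::write.table(acc$profile,
                         file.path(config$out_dir, "profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      acc$masked_rna
    }
  })
  write_fasta(stats::setNames(masked, "lncRNA_masked"),
              file.path(config$out_dir, "masked.fa"))

  windows <- run_stage("windows", {
    w <- build_windows(merge(probes, cls[, c("probe_id", "klass")],
                             by = "probe_id", sort = TRUE),
                       chrom_lengths, config$window_width)
    extract_window_sequences(w, genome)
  })

  hits <- run_stage("triplex", find_triplexes(masked, windows,
                                              config$triplex))
  utils::write.table(hits, file.path(config$out_dir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  windows <- triplex_positive(windows, hits)
  write_bed(data.frame(chrom = windows$chrom, start = windows$start,
                       end = windows$end, name = windows$probe_id,
                       score = as.integer(windows$triplex_positive)),
            file.path(config$out_dir, "windows.bed"))

  protection <- run_stage("enrichment", hm_protection_table(cls, windows))

  enr <- run_stage("enrichment", {
    # background pool: random windows away from the triplex-negative loci
    # (the analog of masking zero-triplex loci out of the genomic
    # background before resampling)
    neg <- windows[!windows$triplex_positive, , drop = FALSE]
    n_bg <- max(config$n_background,
                2L * sum(windows$triplex_positive))
    bg <- sample_background_windows(chrom_lengths, n_bg,
                                    config$window_width, neg)
    bg <- extract_window_sequences(bg, genome)
    bg_hits <- find_triplexes(masked, bg, config$triplex)
    target_hits <- hits[hits$window_id %in%
                          windows$probe_id[windows$triplex_positive], ,
                        drop = FALSE]
    dbds <- cluster_dbds(target_hits, config$enrichment)
    dbds <- dbd_enrichment(dbds, target_hits, bg_hits, bg$name,
                           sum(windows$triplex_positive),
                           config$enrichment)
    utils::write.table(dbds, file.path(config$out_dir, "dbds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dbds
  })

  coloc <- NULL
  if (!is.null(config$contacts_bedpe)) {
    coloc <- run_stage("colocalization", {
      contacts <- read_intervals(config$contacts_bedpe, "BEDPE")
      cp <- config$coloc
      if (!is.null(config$rna_locus)) cp$rna_locus <- config$rna_locus
      kept <- if (!is.null(cp$rna_locus))
        filter_rna_contacts(contacts, cp) else contacts
      val <- validate_triplexes(windows, kept, cp, chrom_lengths)
      write_bed(val$validated_windows[, c("chrom", "start", "end",
                                          "probe_id")],
                file.path(config$out_dir, "validated_windows.bed"))
      write_bedpe(val$confirmed_contacts,
                  file.path(config$out_dir, "confirmed_contacts.bedpe"))
      prot <- if (nrow(val$validated_windows) > 0L &&
                  nrow(val$validated_windows) < nrow(windows)) {
        others <- windows[!(windows$probe_id %in%
                              val$validated_windows$probe_id), ,
                          drop = FALSE]
        protection_at_validated_sites(cls, val$validated_windows, others)
      } else NULL
      list(n_contacts_in = nrow(contacts), n_contacts_locus = nrow(kept),
           n_confirmed = nrow(val$confirmed_contacts),
           confirmed_ids = val$confirmed_contacts$id,
           table = val$table, fisher = val$fisher,
           protection_rank_sum = prot)
    })
  }

  report <- list(
    parameters = list(classifier = unclass(config$classifier),
                      structure = unclass(config$structure),
                      triplex = unclass(config$triplex),
                      enrichment = unclass(config$enrichment),
                      coloc_flank = config$coloc$flank,
                      window_width = config$window_width,
                      n_background = config$n_background,
                      seed = config$seed),
    counts = list(
      n_probes = nrow(cls),
      n_hm = sum(cls$klass == "HM"),
      n_nhm = sum(cls$klass == "NHM"),
      n_other = sum(cls$klass == "OTHER"),
      n_windows = nrow(windows),
      n_triplex_positive = sum(windows$triplex_positive),
      n_triplex_negative = sum(!windows$triplex_positive),
      n_hits = nrow(hits),
      n_dbds = nrow(enr),
      n_significant_dbds = sum(enr$empirical_p <= 0.05),
      rna_masked_fraction =
        mean(strsplit(masked, "")[[1L]] == "N")),
    protection = list(table = as.vector(protection$table),
                      odds_ratio = protection$fisher$odds_ratio,
                      p_value = protection$fisher$p_value),
    dbds = enr,
    colocalization = coloc)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  report
}

#' Sample random background windows away from excluded loci
#'
#' Draws `n` fixed-width windows uniformly over the genome, rejecting any
#' that overlap the intervals in `exclude` — the analog of masking
#' zero-triplex loci out of the genomic background before enrichment
#' resampling. Draws come from the current RNG stream.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param n Number of windows.
#' @param width Window width (bp).
#' @param exclude Data frame with `chrom`, `start`, `end` to avoid.
#' @return Data frame with `chrom`, `start`, `end`, `name`.
#' @export
sample_background_windows <- function(chrom_lengths, n, width, exclude) {
  picks <- vector("list", n)
  k <- 0L
  tries <- 0L
  while (k < n) {
    tries <- tries + 1L
    if (tries > 200L * n)
      stop("could not place background windows away from excluded loci")
    cn <- sample(names(chrom_lengths), 1L)
    s <- sample.int(chrom_lengths[[cn]] - width, 1L) - 1L
    ex <- exclude[exclude$chrom == cn, , drop = FALSE]
    if (nrow(ex) > 0L && any(ex$start < s + width & ex$end > s)) next
    k <- k + 1L
    picks[[k]] <- data.frame(chrom = cn, start = s, end = s + width,
                             name = sprintf("bg_%05d", k),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, picks)
}
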