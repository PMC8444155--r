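---
title: "Methods: triplex-mediated protection from CpG hypermethylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplex-mediated protection from CpG hypermethylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline asks

Some long non-coding RNAs bind duplex DNA in the major groove as a third
strand, forming an RNA:DNA triple helix. A bound triplex can sterically
shield the underlying CpG dinucleotides from DNA methyltransferases, so
loci capable of forming triplexes with an abundant lncRNA should be
under-represented among loci that become hypermethylated when that lncRNA
is lost. `triplexmeth` implements the full chain of evidence for this
hypothesis on a two-group methylation cohort:

1. classify CpG probes into hypermethylated (HM) and non-hypermethylated
   (NHM) sets from a beta-value matrix;
2. compute the lncRNA's secondary-structure accessibility and mask paired
   nucleotides, because only unpaired RNA can engage a duplex;
3. predict triplex-forming oligonucleotide (TFO) / triplex target site
   (TTS) matches between the masked RNA and 100-nt windows centered on
   each CpG;
4. test whether triplex-positive windows avoid hypermethylation (Fisher's
   exact test), cluster TFOs into DNA binding domains (DBDs), and score
   each domain against a resampled genomic background;
5. validate predictions against RNA-chromatin contact data (iMARGI-style
   paired anchors) and compare methylation deltas at validated sites.

Every stage is driven by the numbered scripts under `analysis/` and unit
tested against independent oracles; a synthetic-data generator supplies
inputs with planted ground truth so the whole chain is checkable without
any external download.

## Differential methylation

For each probe the mutation-group mean minus the wild-type mean (delta)
and a two-sample t test are computed, with Benjamini-Hochberg adjustment
across probes. A probe is `HM` when q ≤ 0.05 and delta ≥ 0.1, `NHM` when
q > 0.05 and |delta| < 0.1, and `OTHER` otherwise; the three classes
partition the tested probes. Probes with missing values are dropped, not
imputed.

The test variant was a genuinely open choice: with 13 cases against 173
controls, pooled-variance t statistics are fragile to variance
differences, so Welch's unequal-variance test with Satterthwaite degrees
of freedom is the default (`test_variant = "student"` is available for
comparison). Nonparametric comparisons of delta distributions — the
natural reading of a "non parametric" group comparison at validated
binding sites — are kept separate, as the Mann-Whitney rank-sum test used
in the colocalization stage. The row-wise implementation is vectorised
over probes and agrees with `stats::t.test` to 1e-12 in the tests.

Under the global null the HM rate is controlled far below the FDR
threshold (BH controls the expected false-discovery proportion, and with
no true positives significant q-values are rare); the suite verifies the
rate over 200 seeded null cohorts.

## RNA accessibility model

Full nearest-neighbor thermodynamics are deliberately not reimplemented.
The package scores every pseudoknot-free structure `S` with weight
`pair_weight^|S|` (default `exp(1)`) over the allowed pairs
{AU, UA, GC, CG, GU, UG} with a minimum hairpin loop of 3 nt, and
computes exact base-pair probabilities `P(i, j)` by an inside-outside
dynamic program (C++, with adaptive per-nucleotide rescaling so
multi-kilobase transcripts stay inside double range). The payoff is
testability: for sequences up to 18 nt the matrix is reproduced to 1e-9
by brute-force enumeration of every structure, so the model is exact by
construction rather than approximately calibrated. Users who want
thermodynamic-quality profiles can compute them externally with RNAplfold
and feed the `_lunp` track in via `read_lunp()`; the pipeline then masks
from that profile instead.

Masking replaces position `i` with `N` when its pairing evidence reaches
`pairing_cutoff` (default 0.1). Two thresholding modes exist because an
accessibility track can carry two different quantities: `per_pair` uses
`max_j P(i, j)`, matching the semantics of a printed-pair cutoff;
`unpaired` uses `1 - p_unpaired(i)`, the only information a `_lunp` file
carries. The internal model defaults to `per_pair`.

A known limitation, discussed because it shapes what the tests can claim:
a uniform-weight ensemble has no stacking cooperativity, so pairing
probability spreads diffusely over many alternative partners. Planted
8-bp hairpin stems in a 600-nt synthetic transcript reach maximal pair
probabilities of only ~0.05-0.15 — enriched over background but not
dominant, at any pair weight. The tests therefore assert enrichment of
planted stems and, more importantly, the property the downstream stages
actually rely on: the planted purine tract stays ≥ 95% unpaired at the
0.1 cutoff, mirroring the highly accessible 3' region reported for the
real transcript. Conclusions about real structured RNAs should come from
a thermodynamic folder via the `_lunp` path.

## Triplex engine

Matches are scored under the canonical Hoogsteen triplet chemistries:
pyrimidine motif (T·A:T, C·G:C; TFO parallel to the purine strand),
purine motif (G·G:C, A·A:T; antiparallel), and the mixed GT motif
(G·G:C, T·A:T; both orientations). Both duplex strands are scanned as
potential purine strands. A hit is a gap-free aligned interval satisfying
four constraints (defaults follow the established optimisation for lncRNA
screens): length ≥ 10 nt, error rate ≤ 20%, guanine rate ≥ 70%, and at
most 1 consecutive error. `N` on either side is always an error, so hits
may bridge isolated masked bases within the error budget. The published
parameter "G-C content = 70%" is ambiguous between guanine fraction of
the TTS, of the TFO, or combined G+C; it is implemented as the guanine
fraction of the TTS purine strand, the interpretation under which the
parameter controls triplex stability via G·G:C triplets, and it is
configurable.

Maximality is declarative: a hit is reported iff no valid hit on the same
alignment diagonal (same motif, orientation, strand, and RNA/DNA offset)
strictly contains it. This makes the production scanner and the
brute-force oracle — which enumerates every equal-length substring pair
and filters — provably comparable, and the suite asserts exact hit-set
equality on hundreds of fuzzed instances, including fuzzed parameter
settings. Relaxing any threshold can only grow the set of
triplex-positive windows (verified as a property), and
reverse-complementing a window yields the mirrored hit set with strands
flipped.

`find_tts_tracts()` reports candidate purine tracts per strand — maximal
intervals free of disqualifying pyrimidine runs — and every reported
hit's TTS provably falls inside one; they are candidates for inspection,
not hits.

## Protection and domain enrichment

The protection test crosses HM/NHM status with triplex status in an
explicit 2x2 table (OTHER excluded) and applies a two-sided Fisher exact
test implemented from the hypergeometric law with the probability-mass
criterion; the odds ratio is the sample odds ratio, so OR < 1 reads
"triplex-capable loci are depleted among hypermethylated loci". The
implementation is checked against full enumeration of all tables with the
observed margins (to 1e-12) and against `stats::fisher.test`.

TFO intervals within `gap_tolerance` (default 0: overlapping or abutting)
merge into DBDs. Each domain's observed statistic is the number of target
regions it hits; the null resamples `n_resamples = 100` same-size region
sets from a background pool of random genomic windows excluding the
triplex-negative loci (the analog of masking zero-triplex loci out of the
genomic background), and reports the z-score and the one-sided add-one
empirical p `(1 + #{resample ≥ observed}) / (n_resamples + 1)`, plus a BH
q across domains since several domains are tested. With 100 resamples the
smallest attainable p is ~0.0099; stronger resolution costs linearly more
resampling.

Calibration is asserted the way an exact conditional test permits:
Fisher's p-values are discrete and conservative, so rather than strict
uniformity under the null the tests bound the rejection rate by the
nominal level (plus Monte-Carlo error) at several thresholds, on both
table-level nulls and independence-planted synthetic cohorts.

## Colocalization validation

Contacts whose RNA anchor overlaps the lncRNA's source locus by ≥ 1 bp
are retained; triplex-positive windows are expanded by ±3 kb (clipped at
chromosome bounds) and a contact is confirmed when its DNA anchor
intersects an expanded window. The ±3 kb expansion is applied to the CpG
windows (not to anchors), though the tests verify the two are equivalent;
all intervals are 0-based half-open, so an anchor exactly abutting an
expanded window does not count. The attached 2x2 table crosses window
triplex status with contact status. Methylation deltas at validated
versus other windows are compared by the Mann-Whitney test (exact
enumeration for pooled n ≤ 12, tie- and continuity-corrected normal
approximation otherwise).

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical skeleton of the study at desk
scale, with defaults chosen once as the packaged study conditions:

| quantity | default | rationale |
|---|---|---|
| cohort | 13 mut / 173 wt | the real cohort's imbalance |
| probes | 200 (1000 in classifier studies) | smallest sizes with stable rates |
| genome | 2 x 150 kb | hosts 200 spaced windows plus decoy space |
| planted hyper fraction | 0.2, delta +0.2, noise sd 0.05 | recoverable but not trivial at 13 vs 173 |
| protected fraction | 0.15 | enough positives for a decisive 2x2 |
| lncRNA | 600 nt, 3 hairpins, purine tract at [400, 500) | scaled-down analog of a 4.8-kb transcript with an accessible 3' tract |
| contacts | 29 true + 128 decoys | the validation counts reported for the real interactome |

Protected probes get a 25-35 nt reversed segment of the RNA's TFO tract
planted next to their CpG (a perfect antiparallel purine-motif target);
all other probe windows are scrubbed of incidental guanine tracts on
both strands, so "triplex-positive" is a clean planted label and
planted-truth recovery is exact rather than statistical. Hypermethylation
is drawn from unprotected probes (`link_protection = TRUE`), planting the
protection association; `link_protection = FALSE` breaks the link for
null calibration. True contact anchors land within 0.8x the flank of a
protected window; decoys are rejection-sampled at least twice the flank
away from every protected window, making the confirmed/decoy split
deterministic by construction rather than probabilistic.

Betas are clipped Gaussians around per-probe baselines (uniform on
[0.2, 0.6]) — transparent to reason about, but not beta-distributed, with
no probe cross-hybridisation, batch structure, or normalisation
artifacts. The baseline distribution of protected versus unprotected
loci is not pinned by any external source, so it is a parameter rather
than a constant. Decoy contacts are placed by distance, not by a contact
frequency model. Passing tests therefore demonstrate that the chain of
inference is implemented correctly and recovers planted structure; they
do not demonstrate power or error rates on real 450K arrays or real
interactome data.

## Numerical and reproducibility choices

* All coordinates are 0-based half-open internally; the `TSV` interval
  dialect (1-based inclusive) is converted on ingest, and locus strings
  like `chr19:33298573-33303358` are treated as 1-based inclusive.
* Window centering with even width puts the CpG's C at 0-based offset
  `width/2`; windows overhanging chromosome ends are clipped and flagged.
* Nearest-gene ties break by smaller gene start, then name; zero-variance
  t tests and empty-margin Fisher tables follow explicit conventions
  (`p = 1` with sentinel odds ratio) rather than erroring mid-pipeline.
* Every stochastic step (cohort generation, background sampling,
  enrichment resampling) is seeded; two runs of `run_pipeline()` with the
  same seed produce byte-identical JSON reports, and the generators are
  byte-deterministic per seed.
* Problem sizes in the shipped tests and analysis scripts (200-1000
  probes, 600-nt RNA, 500-window background, 100-200 fuzz instances per
  oracle) were chosen as the smallest sizes at which the asserted rates
  and recoveries are stable.

## Known limitations

Triplexator's internal heuristics (q-gram filtering, duplicate merging,
low-complexity masks) are not replicated — correctness here is defined by
the declarative rule set plus the brute-force oracle, so hit sets need
not be bitwise identical to that tool's. The structure model trades
thermodynamic realism for exactness, as discussed above. Coordinate
liftover between assemblies is out of scope: all inputs must share one
assembly. GO enrichment and plotting are likewise outside the package.
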