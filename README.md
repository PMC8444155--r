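# triplexmeth

Do RNA:DNA triple helices protect CpG loci from hypermethylation?
`triplexmeth` is an R implementation of the full analysis chain behind
that question, for epigenomics researchers studying lncRNA-guided DNA
methylation: from differential-methylation classification on a two-group
beta-value cohort, through structure-masked triplex prediction and
DNA-binding-domain enrichment, to validation against RNA-chromatin
contact data. A synthetic-data generator with planted ground truth makes
every stage testable offline.

## The model in brief

For probe *i* with beta values in two groups (`mut`, `wt`):

* Δᵢ = mean(mutᵢ) − mean(wtᵢ); Welch t test, BH adjustment across probes;
  **HM** iff q ≤ 0.05 ∧ Δ ≥ 0.1, **NHM** iff q > 0.05 ∧ |Δ| < 0.1.
* RNA accessibility: base-pair probabilities P(i,j) from an exact
  partition function over pseudoknot-free structures weighted
  w^(#pairs) (w = e by default, min loop 3); position i is masked to `N`
  when maxⱼ P(i,j) ≥ 0.1. RNAplfold `_lunp` tracks can be ingested
  instead.
* Triplex search in 100-nt CpG-centered windows under Hoogsteen motifs —
  Y (T·A:T, C·G:C, parallel), R (G·G:C, A·A:T, antiparallel), GT (G·G:C,
  T·A:T, both) — on both duplex strands, with min length 10, error rate
  ≤ 20%, guanine rate ≥ 70% on the purine strand, ≤ 1 consecutive error;
  maximal hits per alignment diagonal, verified against a brute-force
  oracle.
* Protection: Fisher's exact test (from the hypergeometric law) on the
  HM/NHM × triplex-positive/negative table; OR < 1 = protection.
* DBDs: TFO intervals merged (gap 0), each scored as
  z = (obs − mean)/sd and empirical p = (1 + #{resample ≥ obs})/101 over
  100 same-size draws from a background pool excluding triplex-negative
  loci.
* Validation: contacts whose RNA anchor overlaps the lncRNA locus are
  confirmed when their DNA anchor intersects a triplex-positive window
  expanded by ±3 kb; methylation deltas at validated vs other sites are
  compared by Mann-Whitney.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
inputs (seed via `ANALYSIS_SEED`, default 1), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_methylation.R
Rscript analysis/03_fold_and_mask.R
Rscript analysis/04_predict_triplexes.R
Rscript analysis/05_test_protection.R
Rscript analysis/06_colocalize_contacts.R
```

Output of stages 2-6 on the default seed:

```
Classified 200 probes: 40 HM, 154 NHM, 6 OTHER
Planted-HM recovery: sensitivity 1 | empirical FDR 0

Masked 112 of 600 positions ( 18.7 % )
Planted TFO tract [ 400 , 500 ): 99 % of positions unpaired at cutoff 0.1

Predicted 3086 triplex hits; 30 of 200 windows triplex-positive
Planted protected set recovered exactly: TRUE

Protection table (HM/NHM x triplex +/-):
     triplex
klass positive negative
  HM         0       40
  NHM       27      127
Fisher: OR = 0 , p = 0.00164
1 DNA binding domain(s); 1 significant at empirical p <= 0.05

Contacts at the lncRNA locus: 157
Confirmed contacts: 29 ( true: 29 / decoy: 0 )
All planted true contacts confirmed: TRUE
```

Reading: none of the 40 hypermethylated windows can form a triplex while
27 of the 154 non-hypermethylated ones can (odds ratio 0, Fisher
p ≈ 2 × 10⁻³) — the planted protection signal; the lncRNA's planted
purine tract survives structure masking, is recovered as the single
enriched DNA binding domain (z ≈ 32), and all 29 planted true chromatin
contacts — and none of the 128 decoys — are confirmed at the ±3 kb flank.

The same pipeline runs on real data by pointing `pipeline_config()` at a
genome FASTA, probe BED, beta/group TSVs, lncRNA FASTA, and a BEDPE
contact table sharing one assembly; `run_pipeline()` writes all artifacts
plus a machine-readable `report.json`.

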