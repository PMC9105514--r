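# lncm6a

Integrative analysis of N6-methyladenosine (m6A) methylation on long
noncoding RNAs (lncRNAs) between oxidative (soleus, SOL) and glycolytic
(extensor digitorum longus, EDL) skeletal muscle, from paired MeRIP-seq
IP/Input libraries (two tissues x three replicates). The package is aimed
at epitranscriptomics analysts who want each stage of such a study as a
tested, replaceable function, exercised end-to-end on synthetic data with
planted ground truth.

## What it computes

- **Novel-lncRNA discovery**: the filter cascade
  class code ∈ {i, j, o, u, x} → length ≥ 200 nt → CNCI/FEElnc/CPC2 all
  noncoding → no Swiss-Prot/Pfam/Rfam hit → FPKM ≥ 0.5 in ≥ 1 sample
  (≥ 2.0 if single-exon), with per-stage attrition reporting, positional
  classes (intronic / exonic / antisense / lincRNA) and ORF statistics.
- **Differential expression**: FPKM = counts·10⁹/(library·length); an NB
  Wald test on median-of-ratios normalized counts; BH adjustment;
  DE iff padj < 0.05 and |log2FC| ≥ 1.
- **m6A peaks and enrichment**: window Fisher peak calling over spliced
  transcripts; MFPKM = mean over replicates of FPKM_IP/FPKM_Input and
  m6A level = log2(MFPKM); metagene/last-exon summit profiles; RRACH
  consensus enrichment vs dinucleotide-preserving shuffles.
- **Association**: L/M/H sets (m6A peaks in neither / one / both
  tissues), expression divergence |log2(a+1) − log2(b+1)| with
  Low/Median/High quartile groups, Mann–Kendall trend tests, and the
  Pearson correlation between m6A-level and expression log2 fold changes.
- **Conjoint analysis**: per-lncRNA differential methylation (two-sided
  Fisher on pooled IP/Input counts, BH) joined with the DE table into the
  quadrants Hyper-Up / Hypo-Up / Hyper-Down / Hypo-Down (dme-lncRNAs).
- **Genomic context**: dme-lncRNA × QTL interval intersection with trait
  category proportions; cis potential target genes within 100 kb.
- **Network**: PPI graph (combined score > 0.4), MCODE clustering (degree
  cutoff 2, node score cutoff 0.3, k-core 2, max depth 100),
  hypergeometric term enrichment.
- **Synthetic data**: `simulation_spec()` / `simulate_study()` generate a
  full study — annotation, paired counts, peaks, QTLs, PPI — with planted
  truths (cascade violations, fold-change copula, quadrant memberships,
  last-exon peak bias) emitted as sidecar tables for testing.

## Worked example

The numbered scripts under `analysis/` run the whole study on the two
synthetic scenarios (a copula-coupling scenario for the association
analysis, a quadrant scenario for the conjoint analysis) and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_discover.R
...
Rscript analysis/08_network.R
```

`analysis/02_discover.R` prints the cascade attrition on 2,540 candidates
(30 planted violators per stage category):

```
 stage            n_in n_out n_removed
 class_code       2540  2340       200
 length           2340  2260        80
 coding_potential 2260  2140       120
 db_hit           2140  2080        60
 fpkm             2080  2000        80

novel lncRNAs: 2000 | annotated: 420 | expressed universe: 2420
```

Every removal is a planted violation, so the 2,000 survivors are exactly
the pass-all candidates. `analysis/05_association.R` then reports, on the
copula scenario (planted coupling 0.72):

```
L/M/H set sizes: L=1643, M=229, H=548
divergence groups: Low=605, Median=1210, High=605
m6A-expression fold-change correlation (H set): r = 0.728, p = 1.8e-91, n = 548
median expression by set:  H=947, L=433.1, M=694.4
```

i.e. lncRNAs methylated in both tissues are the most expressed and the
correlation between methylation change and expression change recovers the
planted value. `analysis/06_conjoint.R` recovers the planted quadrant
design exactly:

```
dme-lncRNAs: 305 of 349 DE lncRNAs
quadrants: Hyper-Up=43, Hypo-Up=109, Hyper-Down=16, Hypo-Down=137, total=305
```

and `analysis/08_network.R` shows MCODE pulling the planted 8-clique out
of the score-filtered PPI graph as its top cluster (score 8.0), with the
module's synthetic term enriched at p = 2.6e-12.

## Layout

```
R/                 package code (io, simulate, discovery, expression,
                   peaks, association, conjoint, context, network, pipeline)
analysis/          numbered narrative drivers writing results/ tables
tests/testthat/    unit, property and acceptance suites
scripts/           acceptance.R
vignettes/         methods vignette (model, generator, design choices)
```
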