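# smMIPseq

Targeted quantification of gene expression with single-molecule molecular
inversion probes (cDNA smMIPs).

smMIPs are single-stranded oligos whose two targeting arms (16–24 nt each,
40 nt combined) hybridize around a ~100-nt region of a cDNA molecule; gap
fill and ligation circularize the probe, capturing the target together with
a random 9-nt unique molecular identifier (UMI). Because every captured
molecule carries its own UMI, sequencing reads can be collapsed back to
*molecule counts*, making expression quantification robust to PCR
amplification at a fraction of the cost of whole-transcriptome RNA-seq —
the regime of interest being tens to hundreds of genes across hundreds of
samples.

The package implements the complete desk side of such an experiment:

* **Panel design** — spliced transcript models from FASTA + GFF3/BED,
  exhaustive candidate enumeration under arm/target-length constraints,
  exon–exon junction probes, arm copy-number filtering, and SNP probe
  pairs with non-overlapping arms for independent allelic estimates.
* **Molecule counting** — alignment-free assignment of read pairs to probes
  by arm matching (≤2 mismatches per arm), extension–ligation dimer
  removal, and per-probe UMI collapsing with a sequencing-error threshold:
  the largest R such that UMIs with read coverage ≥ R still account for
  ≥95% of the probe's reads (at 0.2% per-base error, 1 − 0.998⁹ ≈ 1.8% of
  reads carry a corrupted UMI).
* **Expression model** — a Bayesian hierarchical negative-binomial model
  per condition,

  ```
  y[p,r] ~ NB(mean = m[p,r], dispersion = phi[experiment(r)])
  log m[p,r] = log N[r] + mu[p] + lambda[class(r)] * x[p]
  ```

  with depth normalization (molecules per million), a condition-independent
  probe-bias covariate `x` estimated from replicate-class differences, and
  per-experiment dispersion. MCMC (JAGS) yields 1,000 posterior samples per
  condition; differential expression is the paired cross-condition contrast
  of `mu`, aggregated to gene level by sample-wise averaging over probes.
* **Allele-specific expression** — per-(probe, UMI) majority vote over the
  base at a targeted SNP, with molecules from different probes kept
  independent; Clopper–Pearson intervals on allelic ratios; dilution-series
  analysis via consecutive-step ratios of ratios.
* **Simulator** — a ground-truth generator (abundances over orders of
  magnitude, fold-change groups 0.5/0.67/1/4, per-probe capture
  efficiencies, class bias, heavy-tailed PCR duplication, substitution
  errors) against which every component is tested.

See `vignettes/smmip-quantification.Rmd` for the models, assumptions, and
design decisions.

## Worked example

Simulate a small two-condition experiment (8 transcripts in the four
fold-change groups, 3 probes each, 20,000 molecules per replicate, four
technical replicates per condition in two input classes), count molecules
from the FASTQ, fit both conditions and estimate gene-level differential
expression:

```r
library(smMIPseq)

cfg <- simConfig(seed = 7, n_transcripts = 8L, probes_per_transcript = c(3L, 3L),
                 tx_length_range = c(300L, 500L), n_molecules = 20000)
sim <- simulateExpressionExperiment(cfg)

mc <- countSamples(sim$sample_sheet, sim$panel)
mc
#> class: MoleculeCounts
#> dim: 24 8
#> assays(4): molecules rawUmis thresholdR totalReads
#> colnames(8): cond1_rep1 cond1_rep2 ... cond2_rep3 cond2_rep4

bias <- estimateBias(mc)
f1 <- fitCondition(mc, "cond1", bias, mcmcConfig(seed = 7))
f2 <- fitCondition(mc, "cond2", bias, mcmcConfig(seed = 7))
de <- geneSummary(differentialExpression(f1, f2), sim$panel)
tab <- deTable(de)
tab$true_ratio <- sim$truth$fold_group[match(tab$unit, rownames(sim$truth$abundance))]
tab
#>    unit   mean    sd    lower  upper true_ratio
#> 1 tx001  0.058 0.031  0.00094  0.120       1.00
#> 2 tx002 -0.608 0.061 -0.73150 -0.496       0.67
#> 3 tx003 -0.986 0.108 -1.20043 -0.780       0.50
#> 4 tx004  1.413 0.202  1.04738  1.823       4.00
#> 5 tx005 -0.996 0.036 -1.06538 -0.927       0.50
#> 6 tx006 -0.550 0.031 -0.60906 -0.487       0.67
#> 7 tx007  2.051 0.035  1.97878  2.119       4.00
#> 8 tx008 -0.321 0.151 -0.59419 -0.015       1.00
```

`mean` is the posterior mean log2 fold change (condition 1 vs condition 2)
with a central 95% credible interval; the true simulated ratios are 0.5
(log2 = −1), 0.67 (−0.58), 1 (0) and 4 (+2). Well-expressed genes land on
their group values (tx005, tx006, tx007); the two lowest-expression genes
(tx004, tx008 — a handful of molecules per probe at this depth) are
correspondingly noisy, which is why benchmark summaries exclude genes below
an expression floor. At realistic panel sizes and depths (see the
vignette's benchmark section) group fold changes are recovered within a few
hundredths of a log2 unit.

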