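---
title: "Quantifying gene expression with cDNA smMIPs: models and methods"
author: "smMIPseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene expression with cDNA smMIPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smMIPseq)
```

# The measurement

A single-molecule molecular inversion probe (smMIP) is a single-stranded
oligo whose two terminal targeting arms hybridize on either side of a
~100-nt target region of a cDNA molecule. Polymerase extension across the
gap and ligation circularize the probe, capturing a copy of the target
together with a random 9-nt unique molecular identifier (UMI) carried by the
probe. After amplification and paired-end sequencing, reads carrying the
same (probe, UMI) combination derive from one original cDNA molecule, so
expression can be quantified in *molecules* rather than PCR-amplified reads.

This package covers the full desk side of such an experiment: panel design
against spliced transcript models, conversion of raw paired reads into
error-corrected molecule counts, a Bayesian hierarchical model for
normalized and differential expression, allele-specific counting by
per-molecule majority vote, and a ground-truth simulator that every analysis
component is tested against.

# Probe anatomy and panel design

An assembled oligo is, 5'&rarr;3': ligation arm, the 30-nt universal
backbone (`smmipBackbone()`), a UMI placeholder of `N` &times; 9, and the
extension arm, with the UMI sitting between the extension arm and the
amplification primer. Arms are each 16-24 nt and sum to 40 nt, so the
standard oligo is 40 + 9 + 30 = 79 nt. The gap-fill (target) length is a
design constraint, not a constant: 112 nt for expression panels and 100 nt
for SNP panels by default (`designConstraints()`).

`enumerateCandidates()` exhaustively enumerates placements and arm-length
splits around an anchor: a transcript segment (long targets are divided into
non-overlapping 200-nt segments by `segmentTargets()`, with trailing
remainders flagged partial rather than dropped) or a SNP offset (the SNP
must fall inside the gap-fill, never under an arm, since an allele under an
arm would bias hybridization). Candidates whose span straddles an exon-exon
boundary of the spliced transcript model are flagged `junction_crossing`;
they are legitimate designs (cDNA is spliced) and useful for isoform-aware
panels.

Arm uniqueness is enforced with `armCopyNumber()`: exact occurrence counts
of each arm and its reverse complement over the supplied reference
sequences, keeping candidates whose arms occur exactly once. Exact matching
is deterministic and dependency-free; for &ge;16-nt arms it agrees with
read-mapper copy estimates at desk scale, and externally computed copy
numbers can be passed to `filterCandidates()` instead. Candidate performance
scores (e.g. from external MIP-design software) are treated as an optional
input column and filtered on, never computed internally.

For allele-specific panels, `designSnpPair()` selects two probes per SNP
whose extension arms do not overlap and whose ligation arms do not overlap,
so the two probes give statistically independent estimates of the same
allelic ratio; within the feasible set the pair with the highest summed
score wins, with ties broken toward candidates valid in more transcripts and
then lexicographically.

Coordinates: exons follow the Bioconductor convention (1-based closed
`IRanges`); transcript offsets and panel target coordinates are 0-based
half-open; VCF positions are 1-based and converted at the boundary only.

# From reads to molecules

The documented read layout (`readLayout()`) is: mate 1 begins with the
ligation arm followed by the gap-fill in transcript orientation; mate 2
begins with the 9-nt UMI, then the reverse complement of the extension arm
and of the gap-fill. Every element is configurable, since instrument and
protocol versions differ in where the UMI lands.

Assignment is alignment-free: each pair is compared against every panel
probe's expected arm prefixes under Hamming distance, allowing up to 2
mismatches per arm, and assigned to the probe with the minimal total
mismatch count. Reads are never aligned to a reference first, which avoids
mapping bias against unannotated exons or variant-carrying targets. Exact
ties are discarded as `ambiguous` (the correct probe cannot be determined);
pairs shorter than any probe's arms are `short`. Likely extension-ligation
dimers -- capture artifacts with no genuine insert -- are detected as pairs
where the extension arm follows the ligation arm within `min_insert`
(default 20 nt, far below the 100-112-nt designed gap-fills and far above
read-start noise) and are excluded from molecule counting.

## Sequencing-error correction of UMIs

At a per-base error rate of 0.2%, a 9-nt UMI is corrupted with probability
1 - 0.998^9 = 1.8%, so phantom UMIs accumulate with depth and would inflate
molecule counts indefinitely. The correction is a read-coverage threshold:
for each probe, the threshold R is the largest integer such that UMIs with
coverage &ge; R still account for at least 95% of the probe's reads; only
those UMIs count as molecules (`errorCorrectedCount()`). Retained reads are
therefore &ge; 95% of the total by construction. The &ge; reading of the
threshold is implemented as the default because it is the only reading that
always retains the stated read fraction; a strictly-greater variant is
available behind `strict = TRUE`.

Two properties of this heuristic matter in practice. With deep, tight PCR
duplication the discarded tail is almost entirely phantom UMIs and counts
are nearly exact. With heavy-tailed duplication the rule still discards up
to 5% of reads, which then includes genuinely low-coverage molecules -- a
systematic undercount of up to roughly 5% that is shared across probes and
conditions and therefore cancels in fold changes. UMI matching is
exact-sequence; the coverage threshold is the sole error-correction device,
and UMIs containing `N` are dropped by default.

# The expression model

Error-corrected molecule counts $y_{pr}$ for probe $p$ in replicate $r$ of
one condition are modelled as negative binomial:

$$y_{pr} \sim \mathrm{NB}(m_{pr}, \phi_{e(r)}), \qquad
\log m_{pr} = \log N_r + \mu_p + \lambda_{k(r)} x_p,$$

with $N_r$ the replicate's total molecule count (depth), $\mu_p$ the probe's
log mean normalized expression in the condition, $\phi$ a dispersion shared
by all probes of an experiment ($\mathrm{Var} = m + m^2/\phi$, so larger
$\phi$ means closer to Poisson; dispersion is per-experiment because some
experiments are visibly noisier than others), $x_p$ a probe-bias covariate
and $\lambda_k$ a per-replicate-class loading.

The bias covariate captures a reproducible phenomenon: a probe's normalized
count can deviate between replicate classes (for example, different cDNA
input amounts) *in the same direction in every condition*. `estimateBias()`
computes, per probe, half the difference in mean $\log(1+\mathrm{mpm})$
(mpm = molecules per million) between the first two replicate classes,
averaged over conditions and centered to mean zero; it is computed once from
the full data set and passed to every per-condition fit. In the model the
first replicate class is the reference with $\lambda = 0$: with a free
loading for every class, $\mu_p + \lambda_k x_p$ is invariant under
$(\mu + c\,x, \lambda - c)$ and the posterior has an unidentified ridge, so
anchoring one class is required, exactly as in standard covariate coding.

Priors are weakly informative and scale-free on the composition simplex:
$\mu_p \sim \mathcal{N}(\log(1/P), 5^2)$ with $P$ the probe count,
$\lambda \sim \mathcal{N}(0, 1)$, $\phi \sim \mathrm{HalfCauchy}(0, 5)$.
All are exposed in `mcmcConfig()`. Inference is MCMC (JAGS via rjags) with
the negative binomial likelihood expressed directly (continuous dispersion);
defaults are 4 chains, 1,000 warmup iterations, 250 kept draws per chain at
thin 2, giving 1,000 posterior samples, with a fixed, logged seed.
Convergence is checked with split-chain scale-reduction factors; any value
above 1.05 raises a warning (in practice the worst-mixing parameters are
$\mu$ of probes with all-zero counts, whose posteriors are prior-dominated
and wide -- such probes are also the ones a low-expression filter excludes
from benchmark summaries). Zero counts are retained; $\log(1+\cdot)$ appears
only in the bias covariate and in relative-expression reporting.

Each condition is fit independently. `differentialExpression()` pairs the
$s$-th posterior draw of each fit (valid by independence) to form per-probe
log2 fold-change samples $(\mu_A - \mu_B)/\ln 2$; `geneSummary()` averages
the probe-level samples of a gene's probes sample-wise, which empirically
tightens gene-level intervals relative to single probes.
`relativeExpression()` reports gene-level $\log_2(1+\mathrm{mpm})$; these
values are comparable to external measures such as $\log_2(1+\mathrm{RPKM})$
only up to an affine transform.

## What is identifiable

Capture data are compositional: only the *relative* weights
(abundance &times; capture efficiency &times; class bias) of the panel's
probes are observable, and depth normalization fixes their scale within each
condition. Consequently every log fold change carries a common additive
constant $\log(T_2/T_1)$, the ratio of the two conditions' total capture
weights, which no depth-normalized method can estimate from the data. Real
two-mix spike-in designs neutralize this by construction: the two mixes
contain the same total amount of material. The simulator emulates exactly
that property (below), which is what makes the nominal group ratios the
estimand in the recovery benchmarks.

# Allele-specific expression

For allelic ratios the UMI is first moved out of the read into the read
identifier (`rewriteUmiToHeader()`), so that the pair can be mapped without
the random tag affecting alignment. Molecule-level allele calls use a
majority vote: reads are grouped per (probe, UMI); the base observed at the
SNP -- located by offset arithmetic inside the designed gap-fill
(alignment-free default) or by reference coordinate from a SAM/BAM file --
is classified ref/alt/other, and each group contributes one molecule to the
strictly winning allele. Exact ties are excluded as `tied_molecules`
(tie behaviour is not externally defined; a seeded random-resolution mode
exists for sensitivity checks), and groups with the same UMI under
*different* probes are deliberately counted as independent molecules. Base
qualities are ignored: the vote is a pure majority. Both counting backends
share the identical vote code and agree exactly on error-free data.

Allelic ratios ref/(ref+alt) carry central Clopper-Pearson intervals on the
molecule counts. In a two-genotype serial dilution where each step retains
rate $\rho$ of the previous mix, the *ratio of allelic ratios* between
consecutive steps is expected to equal $\rho$ regardless of the genes'
(unknown and gene-specific) expression difference between the two genotypes;
the absolute ratio of the first step is therefore not predictable and only
consecutive-step ratios are evaluated (`dilutionRatioOfRatios()`).

# The simulator and what passing tests mean

`simConfig()` defines the study conditions; the defaults are the benchmark
design exercised by the test suite:

* two mixes of 40 transcripts in four equal fold-change groups at ratios
  0.5, 0.67, 1.0 and 4.0 between conditions;
* log-uniform abundances spanning 4 orders of magnitude;
* 5-9 probes per transcript with log-normal capture efficiencies
  (sd(log) = 0.7, i.e. a many-fold spread between probes of one transcript,
  matching the strong inter-probe variability seen in capture data);
* a log-normal per-probe class bias (sd(log) = 0.25) applied to one
  replicate class in both conditions -- the phenomenon the bias covariate
  corrects;
* PCR duplication as shifted negative binomial reads-per-molecule
  (mean 4, size 0.8: the heavy-tailed coverage the 95% threshold exists
  for);
* i.i.d. substitution errors at 0.2% per base; no indels, because arm
  matching and UMI thresholding -- the components under test -- are
  substitution-driven;
* uniform random 9-nt UMIs, with collisions allowed; collisions merge
  molecules and give the small downward count bias real UMIs also have.

Group assignment is stratified (each fold-change group spans the full
abundance range) and the highest-ratio group is rescaled in both mixes --
preserving its exact ratio -- so that the two mixes have equal totals, molar
in `makeTranscriptome()` and capture-weighted in
`simulateExpressionExperiment()`. Without this two-mix balance the
compositional constant above would shift all estimated fold changes by a
seed-dependent offset of order 0.1 log2 units and absolute recovery would be
ill-posed.

The fold-change benchmark (`foldChangeBenchmark()`) runs the entire chain --
read simulation, counting, bias estimation, per-condition fits, DE, gene
aggregation -- on 8 replicates (4 per condition, two replicate classes) of
1e5 molecules each, excludes genes below 3 molecules per probe per replicate
in either condition (published fold-change comparisons likewise exclude
transcripts below an expression floor, which are unquantifiable at any given
depth), and summarises each group by a precision-weighted mean of its
gene-level estimates (weights = inverse posterior variance, the standard
fixed-effect summary of estimates with known uncertainties). The
dilution benchmark (`dilutionBenchmark()`) simulates 32 SNPs &times; 2
probes over an 8-step 0.75-rate series at ~2,000 molecules per SNP per step
and summarises the consecutive-step ratio of ratios and the between-probe
concordance.

What the simulator does **not** emulate: sequence-dependent (GC) capture
efficiency, ribosomal or off-target background, indels and mapping
artifacts, library-prep batch structure beyond the single class-bias factor,
and cell-type-dependent input requirements. Passing tests therefore
demonstrate correctness of the counting and inference machinery under the
stated generative assumptions, not performance on any particular real
library.

# Numerical choices and degenerate inputs

* Threshold search iterates over observed coverage values (or those minus
  one in strict mode); empty coverage sets give zero molecules and an
  undefined threshold.
* Probe-assignment ties at equal total mismatches are discarded rather than
  arbitrarily resolved.
* Zero-depth replicates are excluded from normalization and fitting with a
  warning.
* Pool-concentration arithmetic conserves total moles to floating-point
  accuracy; volumes are microlitres, concentrations micromolar, masses
  nanograms, with no unit auto-conversion.
* Trailing partial transcript segments are emitted flagged, not dropped.
* All simulator outputs are reproducible from the seed; every pipeline run
  writes its resolved configuration, seeds and input/output checksums to a
  JSON manifest.

# Known limitations

* With heavy-tailed duplication the coverage threshold discards up to ~5%
  of true molecules (shared across conditions; cancels in fold changes but
  not in absolute molecule yields).
* Absolute fold changes are identifiable only up to the two-mix total
  ratio; the simulator's balanced design makes the benchmark well-posed,
  but real experiments without balanced spike-ins should interpret global
  shifts cautiously.
* The SAM-backed allele counter assumes ungapped alignments (a leading
  soft-clip is honoured); indel-containing alignments are out of scope.
* Single-cell-scale inputs, isoform deconvolution, probe-pool rebalancing
  and external normalization factors are out of scope.
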