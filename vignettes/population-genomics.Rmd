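---
title: "Population-genomic statistics from pooled metagenome variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic statistics from pooled metagenome variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolpg)
```

## The setting

Shotgun metagenome reads from an environmental sample that map to one
reference genome are a pooled draw from the local population of that
organism: each read is (approximately) one independently sampled
chromosome at the positions it covers. Mapping several samples and calling
variants jointly in pooled mode yields, per sample and per variant locus,
a vector of allele *counts*. `poolpg` consumes those counts and computes
within-sample diversity, between-sample differentiation, codon-aware
selection statistics, and a permutation test for gene-level
differentiation. Read mapping, variant calling, and coverage-based sample
admission are upstream concerns and are deliberately out of scope.

## Data model

All statistics run off a single long table with one row per
(locus, allele, sample) carrying the read count, produced by `read_loci()`
from a VCF. Per-sample counts are taken from `AD` fields, or `RO`/`AO`
(Freebayes pooled-continuous) as a fallback; a sample with missing data at
a record gets zero counts there, so the minimum-count filter excludes it
rather than imputing. Haplotype-style records (equal-length multi-base
REF/ALT) are decomposed column-wise into single-nucleotide loci, with
counts inherited from the parent record; indel alleles are skipped and
tallied, never fatal. When two records decompose to the same position
their allele lists are unioned; alternate counts are summed while the
reference count is taken as the *maximum* across records, because the
reference-supporting reads are the same physical reads reported once per
record — summing would double-count depth. Multi-allelic loci are kept
whole; every estimator below is defined over the full allele-frequency
vector.

## Filtering and subsampling

Three parameters govern inclusion, applied in a fixed order:

1. `min_count` (default 10 reads): a sample is included at a locus only
   if its depth there reaches this value.
2. `subsample` (default 10): included counts deeper than the target are
   downsampled to exactly the target. Reads are physical units, so the
   draw is without replacement — multivariate hypergeometric over the
   allele classes. Counts already at the target pass through.
3. `min_found` (default 1): loci qualifying in fewer samples than this
   are removed entirely. Setting it to the number of samples restricts
   every statistic to one shared locus set, which is preferable when
   comparing π between samples.

Qualification precedes subsampling, so subsampling can never change
qualification status and the pipeline is idempotent when
`subsample == min_count` (the configuration also enforces
`subsample <= min_count`). Excluded sample–locus combinations are masked
out, not zeroed, so per-sample denominators (numbers of included loci)
stay well defined. A single seeded generator drives the hypergeometric
draws, vectorized allele-rank-major over (locus, sample) groups in
(locus, sample-order) order; a run is bit-reproducible given the seed and
input order.

## Diversity

Locus diversity is the probability that two reads drawn *without
replacement* differ:

$$\pi_\ell = 1 - \frac{\sum_i c_i (c_i - 1)}{n (n - 1)}.$$

This form is unbiased for the population heterozygosity at any depth,
unlike the plug-in $1 - \sum_i \hat f_i^2$, which is biased low by the
factor $(n-1)/n$. Genome-wide π for a sample is the sum of $\pi_\ell$
over that sample's included loci divided by the genome size; monomorphic
and excluded positions contribute zero. Gene-wise π divides by gene
length in bp (including trailing partial-codon bases). Because under
`min_found = 1` samples can include different locus subsets, a
*normalized* value is also reported: the mean per-included-locus π
rescaled by the overall SNV density (variant loci / genome size). Both
are emitted and labelled; tables serialize π at six decimals, rounding
only at serialization.

## Differentiation

For a sample pair at one locus, with allele frequencies $f^a, f^b$
computed from the (post-subsampling) counts:

- $H_a = 1 - \sum_i (f^a_i)^2$, likewise $H_b$; $H_S = (H_a + H_b)/2$;
- $\bar f = (f^a + f^b)/2$ (equal sample weight — subsampling has already
  equalized depths); $H_T = 1 - \sum_i \bar f_i^2$.

The default estimator aggregates as a ratio of sums over the loci where
both samples qualify, $F_{ST} = (\sum H_T - \sum H_S) / \sum H_T$ — the
standard multi-locus form, far more stable than averaging per-locus
ratios at low-$H_T$ loci. It is bounded to $[0, 1]$: 0 for identical
frequencies, 1 for fixed differences. A pair with no pooled polymorphism
($\sum H_T = 0$) is reported missing, with per-pair locus counts emitted
so downstream users can drop unstable pairs.

The alternative `"hudson"` estimator is
$1 - \sum \pi_{within} / \sum \pi_{between}$ with within-sample diversity
in the without-replacement form and
$\pi_{between} = 1 - \sum_i f^a_i f^b_i$. It is unbiased at finite depth
but can go negative for undifferentiated pairs.

**Finite-depth behaviour, and which estimator to validate against.** The
two estimators answer slightly different questions. Under a two-population
Balding–Nichols model with parameter $F$, interior ancestral frequency
$p$ and per-population heterozygosity $h = 2p(1-p)$, the expectations are
$E[H_S] = h(1-F)$ and $E[H_T] = h(1 - F/2)$, so the Nei-style ratio
converges to $(F/2)/(1 - F/2)$, not $F$ — the familiar two-deme
compression of $G_{ST}$ — and plug-in frequencies at depth $n$ shrink
$H_S$ by $(n-1)/n$, moving the ratio to approximately
$(\tfrac{1}{2n} + (1-\tfrac{1}{n})\tfrac{F}{2})\,/\,(1 - \tfrac{1}{2n} -
(1-\tfrac{1}{n})\tfrac{F}{2})$ (at $n = 10$:
$(0.05 + 0.45F)/(0.95 - 0.45F)$). The Hudson-style ratio is unbiased for
$F$ itself. The validation suite therefore checks *parameter recovery*
with the Hudson estimator and checks the Nei estimator against its
analytic finite-depth expectation; both checks run at $10^4$ loci and
depth 10. For ranking pairs or genes within one data set the two
estimators are effectively interchangeable (they are monotonically
related at equal depths), which is why the bounded Nei form remains the
default for reporting.

## Codon-aware statistics

With gene models and the genome sequence available, each included locus
inside a CDS is mapped to its codon index and within-codon position,
honouring strand and phase: on the minus strand, alleles are complemented
and codons are read from the 3'-most genomic coordinate of the CDS. Each
variant allele is substituted into the *reference* codon with the other
two positions held at reference state; co-occurring variants within one
codon are evaluated independently, because a VCF carries no read-level
phasing. Loci in the phase-trimmed leader or a trailing partial codon are
excluded and counted. Translation uses genetic code table 11
(bacteria/archaea) by default, configurable to any table Biostrings
knows.

Amino-acid frequencies per variant codon position are the summed
frequencies of the nucleotide alleles translating to each residue;
synonymous alleles collapse. Amino-acid-level π and F<sub>ST</sub> apply
the nucleotide estimators to these collapsed state counts, so
synonymous-only positions contribute zero diversity and zero
heterozygosity.

**pN/pS.** Sites are counted per gene in the Nei–Gojobori manner: for
every complete reference codon, each of the nine single-base mutants is
classified, accumulating the per-position synonymous fraction into $S$
and the rest into $N$ (so $N + S = 3$ per counted codon). Stop-gain
mutants count as non-synonymous; reference stop codons are excluded, with
a warning when internal. Polymorphism is weighted by the same
without-replacement read-pair probabilities as π: at each variant
position the probability that two reads differ splits into a
non-synonymous part (different residues — algebraically equal to the
amino-acid-level locus π) and a synonymous part (same residue, different
base — the nucleotide-level minus the amino-acid-level π). These parts
are summed over the gene and divided by $N$ and $S$ respectively;
`pnps = pn/ps`, reported `NA` when `ps` is zero. This frequency-weighted
definition keeps pN/pS depth-consistent with π; a count-based alternative
(each segregating site weighted once) was considered and rejected because
it reintroduces depth dependence that subsampling was meant to remove.

Proteome charge summaries average the frequency of acidic (D, E) and
alkaline (K, R, H) residues over a sample's variant codon positions; the
residue sets are a documented choice (histidine is included among the
alkaline residues despite its marginal pKa).

## The permutation test

Gene-level differentiation is judged against the genome's own background:
for a focal sample pair (typically the two samples at the extremes of an
environmental gradient, `select_extreme_pair()`), the genome-wide pool of
pair-qualifying variant loci is randomly permuted and each gene receives
as many loci as it originally contained, allele counts travelling with
their loci. One global shuffle re-scores *all* genes per replicate, which
both matches the sampling design (genome-level differentiation is held
constant) and makes 10,000 replicates cheap: per-locus numerator and
denominator contributions are precomputed once, so each replicate costs
one permutation plus segment sums. The p-value is

$$p = \frac{1 + \#\{F_{ST}^{perm} \ge F_{ST}^{actual}\}}{n_{perm}},$$

capped at 1 (the +1 makes the smallest attainable value
$1/n_{perm}$, never 0). Ties count as exceedances, compared with a
$10^{-12}$ tolerance so that re-summing identical terms in permuted order
still ties. A permuted locus set with no pooled polymorphism yields an
undefined value, counted as an exceedance only when the actual value is
$\le 0$ — the conservative direction. Benjamini–Hochberg adjustment runs
across the genome's genes. The pool is restricted to loci where both
focal samples qualify, since F<sub>ST</sub> is computable only there; the
alternative (shuffling all loci and discarding unusable draws) would only
dilute the permutation distribution with missing values.

## The synthetic generator

`simulate_genome()` builds a contig with equally spaced, non-overlapping
CDS genes on both strands, each a uniform draw over the 61 sense codons —
hence stop-free by construction. `simulate_allele_counts()` places
variant sites, draws an ancestral frequency $p \sim U(0.05, 0.95)$ per
site, per-population frequencies from the Balding–Nichols distribution
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, and per-sample alternate counts
$\mathrm{Binomial}(depth, f_{pop})$. Genic sites are placed as synonymous
(third positions of 4-fold degenerate codons) or amino-acid-changing, in
a controllable ratio, so pN/pS ground truth is constructable; designated
signal genes instead receive sites fixed for opposite alleles in the two
populations (gene-wise F<sub>ST</sub> of 1). Sites at which no sample
observes an alternate read are flagged and withheld, mirroring the fact
that a variant caller cannot emit an unobserved variant; validation
comparisons account for this by comparing against all simulated sites,
to which unobserved sites contribute zero on both sides.

Defaults describe a modest, realistic experiment: depth 20 (matching a
20× downsampled coverage convention), SNV density 0.005–0.01 per bp
(mid-range for an abundant bacterioplankton population), two populations.
The generator emulates count noise and differentiation structure only: no
sequencing error model, no read-level linkage, no coverage variation
along the genome, no strain mixtures with structured haplotypes.
Passing tests therefore demonstrate correctness of the estimators under
the sampling model, not robustness to mapping artefacts or reference
bias in real data.

## Validation design and problem sizes

The test suite pins every estimator to an independent oracle: explicit
read-pair enumeration for π (exhaustively, all count vectors to depth 30
and four alleles), hand-accumulated heterozygosity sums for multi-locus
F<sub>ST</sub>, exhaustive nine-mutant enumeration for all 61 sense
codons, and translation via Biostrings for the codon mapping on both
strands. Stochastic properties run at fixed seeds and sizes chosen to
keep the whole suite under a couple of minutes: parameter recovery at
$10^4$ loci and depth 10 for $F \in \{0.05, 0.2, 0.5\}$ (tolerance
±0.03); null calibration of the permutation p-values at 200 genes × 1000
permutations (Kolmogorov–Smirnov against uniform at the 1% critical
value); depth-robustness across 55 sample pairs comparing subsampling
depths 10 and 40 (Pearson correlation ≥ 0.8, which in practice comes out
near 1 under the generator's conditions).

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive everywhere a user sees them (VCF and
  GFF conventions); 0-based arithmetic is internal only.
- π and F<sub>ST</sub> of an empty region are 0 and `NA` respectively;
  a sample with no included loci reports `NA` diversity rather than 0.
- Output tables are fixed-point with six decimals and literal `NA`,
  making reruns byte-comparable.
- Ties in the permutation test compare with a $10^{-12}$ absolute
  tolerance; all other comparisons are exact.
- Genes whose spans overlap so heavily that they jointly hold more loci
  than the genome-wide pool fall back to independent per-gene draws
  within a replicate (contiguous-block assignment is used otherwise).

## Limitations

- No read-level linkage: haplotype structure within codons (and beyond)
  is invisible to a VCF, so double mutants in one codon are scored as two
  independent single substitutions.
- No genotype-likelihood handling; callers must report allelic depths or
  observation counts.
- The Nei-style default compresses the absolute differentiation scale at
  two demes (see above); cross-study comparisons of absolute values
  should use the Hudson estimator or matched settings.
- Normalized genome-wide π is one reasonable cross-sample correction
  among several; it is labelled distinctly in all outputs so users can
  choose the raw value instead.
- Watterson's θ, Tajima's D, linkage statistics, Weir–Cockerham
  variance-components F<sub>ST</sub>, and ordination/regression of the
  resulting matrices are out of scope; the TSV outputs are designed as
  inputs to such downstream analyses.
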