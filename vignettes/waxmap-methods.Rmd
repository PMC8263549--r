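---
title: "waxmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{waxmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waxmap)
```

## The problem

Lowland switchgrass (*Panicum virgatum*) ecotypes carry a glaucous,
heavily waxed abaxial leaf surface that upland ecotypes lack. Mapping the
loci behind such an ecotype-differentiating trait in an obligate
outcrosser requires an F1 x F1 intercross design: two heterozygous
founders (one lowland, one upland) are crossed, and two F1 progeny are
intercrossed to give an F2 population that segregates for founder
alleles. Genotyping-by-sequencing (GBS) then yields shallow,
missingness-prone allele read counts at tens of thousands of sites, and
everything downstream -- map construction, QTL scans, candidate-gene
work, duplication structure, presence/absence screens -- has to cope with
that data shape.

`waxmap` implements the full chain as testable, seed-reproducible
components, together with a synthetic-data generator that produces every
input the pipeline consumes with planted, recoverable truth.

## Genotype scoring

Read counts at a biallelic site are converted to the five-letter score
alphabet used for outbred GBS populations: `A` (homozygous parent 1),
`B` (homozygous parent 2), `H` (heterozygous), plus the ambiguous codes
`D` ("A or H") and `C` ("B or H"). The rules, in order:

* depth < 8 reads: missing (`-`);
* minor-allele read fraction `f >= 0.2`: `H`;
* `f <= 0.05`: homozygous for the major allele;
* `0.05 < f < 0.2`: the ambiguous code on the major allele's side.

The 8x missing-data rule, the site filters (biallelic, QD >= 10, pooled
alt-allele frequency within [0.10, 0.90]), the 1,000-bp consolidation
window and the 30% missing-marker cutoff are the conventional values for
this assay and are the package defaults; the minor-fraction thresholds
that trigger the homozygous/ambiguous/heterozygous calls are a concrete
operationalization of the alphabet's semantics (the alphabet itself does
not pin them down) and are exposed in `genotyping_config()`.

Ambiguity is treated algebraically throughout: every score denotes a
*set* of compatible genotypes (`D` = {A, H}, `C` = {B, H}, missing =
{A, B, H}), consolidation intersects the member sets, and the empty
intersection (a concrete conflict such as A vs B) maps back to missing.
This single semantics also drives cosegregation compatibility, so the
consolidation and grouping rules cannot drift apart.

Site filters are applied in a fixed order (allele count, QD, frequency)
and each removed site is tallied against the first rule it fails, so
filter reports partition the input deterministically.

### Cosegregation

Markers that segregate identically map to the same position, so only one
representative per cosegregation group is kept. Two markers cosegregate
when they share at least 20 progeny scored in both (a floor that stops
missing-data-driven spurious merges), every shared progeny is
score-compatible, and both markers have the same segregation category.
Grouping is seeded-greedy in order of increasing
(missing + ambiguous) count, which makes the representative -- the seed --
the cleanest marker of its group by construction.

## Segregation datasets

Markers are classified from the two F1 parents' scores: heterozygous in
both (`HH`, F2 intercross segregation 1:2:1), homozygous in parent 1 and
heterozygous in parent 2 (`AH`, paternal, 1:1), and the reverse (`HA`,
maternal). In the AH/HA datasets `B` scores are recoded to `A` (and `C`
to `D`), turning them into backcross-coded data. Chi-square tests
(1:2:1 with df = 2, or 1:1 with df = 1, no continuity correction) drop
highly distorted markers at p <= 1e-10. Ambiguous scores are excluded
from the test counts rather than fractionally allocated: exclusion is
conservative and deterministic. Markers homozygous in both parents are
unclassifiable under this scheme and are dropped rather than remapped as
dominant markers.

## Map construction and QTL scanning

Marker order is taken from reference physical coordinates (a
user-supplied order hook exists). This is deliberate: in switchgrass the
concordance between de-novo marker orders and the assembly is near
total, and re-deriving order adds an enormous amount of machinery for no
downstream gain here. Adjacent-pair recombination fractions come from
direct recombinant counts (backcross coding) or an EM maximum-likelihood
fit on the 3x3 genotype table (F2; initialized at 0.25, tolerance 1e-8,
at most 200 iterations), and cM positions are cumulative Haldane
distances (`d = -50 ln(1 - 2r)`; Kosambi is available by flag). Pairs
with too few doubly-informative progeny yield an undefined fraction; the
marker inherits the last anchored position and is flagged as a gap.

Scans use Haley-Knott regression on expected genotype dosages rather
than full-EM interval mapping: at each 0.5-cM step the phenotype is
regressed on the expected additive dosage (and a dominance indicator for
F2 "SF2" scans; backcross-coded "B2" scans fit a single effect), with
`LOD = (n/2) log10(RSS0/RSS1)`. Haley-Knott is the standard fast
approximation, is numerically transparent, and -- unlike a closed
binary -- can be tested against enumeration oracles. Genotype
probabilities at off-marker positions condition on the nearest flanking
*concrete* markers through no-interference transition probabilities,
with ambiguous or missing flanks falling back outward and the Mendelian
prior used when no informative flank exists.

Composite interval mapping adds background cofactor markers chosen by
forward stepwise regression (entry p < 0.01, at most 5 cofactors),
dropping any cofactor within 10 cM of the test position. These are the
conventional CIM defaults; with zero cofactors CIM reduces exactly to
interval mapping, which the tests assert bit-for-bit. Significance comes
from permutation: the phenotype is shuffled, the genome rescanned, and
the threshold is the empirical 95th percentile of the per-permutation
genome-wide maximum LOD. Cofactors are held at the observed-data
selection during permutation, which keeps the null scans comparable and
the cost linear. R^2 is reported from the single-position model at the
peak. QTL support intervals are delimited by a 1-LOD drop; this is a
convention (support-interval rules are not standardized) and the peak
and flanking markers are reported alongside.

## Candidate genes

A cM support interval is projected to physical coordinates by linear
interpolation between bp-anchored markers (ends clamp to the chromosome
bounds). Genes inside the interval are flagged on four independent
evidence axes:

* **DE**: adjusted p < 0.01 and |log2FC| > 1, i.e. strictly more than
  twofold;
* **impact**: at least one HIGH or MODERATE variant with the two
  founders homozygous for different alleles -- the configuration a
  fixed ecotype-differentiating trait requires;
* **GO**: case-insensitive substring match of the term name against a
  keyword list (defaults: "fatty acid biosynthetic process", "lipid
  metabolic process"); named-term matching, not ontology traversal,
  because the shortlist step is a keyword filter, not an enrichment
  statistic;
* **absence**: mean CDS coverage < 1x in one founder and >= 5x in the
  other -- a reproducible stand-in for visual read-alignment inspection
  of presence/absence.

Genes are ranked by descending evidence count, then ascending adjusted
p, then id, which makes the ranking a total order independent of input
row order. DE direction is recorded but never gates candidacy. A
feature-scope switch restricts impact evidence to CDS rows when the
effect table distinguishes features.

## Duplication structure

Protein hits between the two homoeologous chromosomes are chained into
collinear blocks by dynamic programming over gene ranks with the
standard collinearity parameters: match score 50 per pair, minimum 3
pairs per block, gap penalty 1 per skipped rank, maximum gap 25 ranks on
either side, tandem duplicates collapsed within a 5-rank window, hits
above e-value 1e-5 ignored. This is a deliberate simplification of the
full MCScanX pipeline -- downstream classification needs block
*membership*, not MCScanX's exact scores -- and exact numeric parity
with MCScanX is not claimed. Genes in a block pair are homoeologs.

A gene's paralog is its top remaining hit (self hits excluded; ties
broken by e-value, then similarity, then subject id) iff e-value
<= 1e-5, alignment length >= 70% of the query length, similarity
>= 80%, and the pair is not in a collinear block. Similarity is read
from the hit table's positives column, falling back to identity when
absent. Per-200-kb windows report the percentage of genes with a
homoeolog and with a paralog; windows without genes are `NA`, never 0.

## Presence/absence hotspots

Panel genotypes are pre-filtered to drop NPs missing in more than 50% of
all accessions, then binned into fixed half-open 10-kb windows anchored
at coordinate 0 (a fixed grid, not a sliding window, so the statistic is
reproducible). Within each ecotype an NP counts as *absent* when it is
missing in at least 50% of that ecotype's accessions; a window whose
absent-NP percentage reaches 50% is a deletion hotspot for that ecotype.
"Missing" means no genotype call -- heterozygous calls are present --
since an uncalled site is the footprint a hemizygous deletion leaves in
short-read genotyping. The coding-variant summary restricts to one
ecotype's accessions, computes minor allele frequency on non-missing
calls only (the standard convention), applies MAF >= 0.05 and <= 30%
missingness, and tallies effect classes per gene.

## The synthetic-data generator

The generator is first-class, tested code; its defaults define the
conditions under which the pipeline is validated.

* **Cross**: disomic inheritance (switchgrass tetraploids pair
  disomically); crossovers per gamete are Poisson(length in Morgans)
  with independent uniform placement -- the Haldane, no-interference
  model, matching the mapping function used downstream. A zero map
  length is the no-recombination limit; negative lengths are rejected.
  Physical coordinates follow a fixed 1 cM = 1 Mb scale by default,
  with an optional suppressed-recombination region that inflates
  physical spacing to emulate a proximal low-recombination arm.
* **Reads**: per sample-site depth is negative binomial (mean 20,
  dispersion 5) with binomial allele sampling at a 0.005 per-read
  miscall rate. The depth distribution of real GBS libraries is not
  published in a fittable form; negative binomial is the standard
  overdispersed stand-in. Site QD is a saturating deterministic
  function of mean depth plus Gaussian noise, since only its threshold
  behaviour matters.
* **Phenotype**: `y = mu + a x + d z + N(0, sigma^2)` with
  `x = +1/0/-1` and `z = 1[H]` at the site nearest the planted QTL;
  `sigma_for_r2()` solves the 1:2:1 variance algebra
  (`var(x) = 1/2`, `var(z) = 1/4`, x and z uncorrelated) so
  simulations can target a heritability.
* **Panel**: 95 lowland and 65 upland accessions by default; deletion
  blocks assign carriers per accession at a configurable frequency and
  raise the per-NP missing probability for carriers inside the block.
* **Evidence and hits**: planted candidate genes carry all four
  evidence lines; planted collinear pairs appear as strong reciprocal
  hits, planted paralogs with configured similarity/coverage, and
  optional noise hits sit above the e-value cut.

What the generator does *not* emulate: restriction-site biasing of GBS
loci, linked selection or segregation distortion gradients, tetrasomic
exchanges, reference bias in read mapping, and correlated missingness
outside planted deletions. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical model, not
robustness to every artefact of real libraries.

## Problem sizes and numerical choices

The test and validation workloads use deliberately modest sizes that
keep every statistical check well-powered: genotype accuracy on a
200-progeny x 500-site matrix over 3 seeds; QTL recovery on 20
replicates of a 300-progeny, 200-marker, 100-cM chromosome with a
planted 30%-R^2 additive QTL and 200-permutation thresholds; null
calibration over 100 datasets of a 2 x 50 cM genome; duplication and
hotspot checks on planted layouts of a few hundred genes or NPs. EM
stops at 1e-8 or 200 iterations; recombination fractions are clamped to
[0, 0.4999] so map distances stay finite; LOD is clamped at 0 and RSS1
at RSS0 to absorb floating-point rank noise; rank-deficient designs fall
back through QR with coefficient NA handling; permutation thresholds use
the empirical quantile of the permutation maxima.

## Known limitations

De-novo linkage grouping and ordering, multi-QTL and epistatic models,
imputation, dominant markers, variant calling and effect prediction,
and GO enrichment are out of scope. The AH/HA "B2" scan treats
backcross-coded data with a single-effect model, so dominance at
maternal/paternal QTL is not separately estimable. Exact MCScanX parity
is not claimed. The worked-example tables bundled under `inst/extdata/`
are demonstration summaries for the arithmetic helpers, not raw data.
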