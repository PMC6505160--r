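---
title: "RADseq population genomics with radpop: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RADseq population genomics with radpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpop)
```

radpop implements the computational pipeline of a restriction
site-associated DNA (RAD) population-genomics study design: in-silico
restriction digestion and sequencing-unit construction for a
methylation-sensitive enzyme such as PstI, SNP filtering and
within-unit redundancy pruning, diversity and differentiation
statistics, and linkage-disequilibrium (LD) analysis from unphased
genotypes. The motivating application is a wild-tomato
(*Solanum pimpinellifolium*) diversity panel of roughly a hundred
accessions genotyped at tens of thousands of SNPs, but nothing in the
package is tomato-specific. This vignette explains the statistical
models, the conventions chosen where the field's tools differ, and what
the bundled synthetic-data generators do and do not emulate.

## The data model

A `genotype_matrix` stores biallelic SNPs as alt-allele dosages 0/1/2
with `NA` for missing calls, plus marker metadata (chromosome, 1-based
position, ref/alt alleles, and the sequencing unit assigned by
`build_units()`). Missingness is a first-class state, never conflated
with the reference genotype: real RAD panels routinely miss 1–16% of
calls per accession and several statistics must condition on the called
subset. Phase in VCF input is read and ignored; all statistics are
defined on unphased dosages, and two-locus analyses recover haplotype
structure with an EM algorithm rather than assuming phase. Coordinates
are 1-based inclusive throughout (the VCF/GFF convention); BED input is
converted on read, and BED output converted on write.

## RAD marker design

`digest_genome()` scans the forward strand for exact occurrences of the
recognition motif (default CTGCAG). Because PstI's motif is its own
reverse complement, a forward scan is complete; the scan is exhaustive,
so overlapping occurrences of self-overlapping motifs are all reported,
and IUPAC ambiguity codes never match. The cut-site anchor is the first
motif base, not the staggered cut position; the 5 bp offset is
immaterial at the kb scales of every downstream use.

A *sequencing unit* is the region captured by single-end reads anchored
at one cut site: `motif_start ± read_span`, 186 bp at the default
`read_span = 93` (100 bp reads less barcode and overhang), kept only
when it contains at least one SNP. Each SNP joins the nearest
containing cut site, ties resolved to the lower coordinate. Units are
the grain of two analyses: redundancy pruning and the local LD profile.

Sites are euchromatic or heterochromatic by point containment of the
motif start in the heterochromatin track; sites on chromosomes the
annotation does not cover (e.g. an unanchored "chromosome 0") default
to euchromatin with a warning. Genes count as "sequenced" at a single
bp of overlap with a unit, since no minimum-overlap rule is better
motivated; `overlap_report()` tabulates SNPs, sequenced genes, genes
with SNPs and genic SNPs per chromosome.

## Filtering

`filter_markers()` applies, in order, a presence filter (call fraction
at least 75/99 by default, generalising the "present in at least 75 of
99 populations-of-one" design) and a minor-allele-frequency filter.
Both boundaries are inclusive: MAF exactly 0.05 survives the default.
The exclusion rule ("MAF below 0.05 is removed") is taken as operative
because a strict-greater reading would silently drop boundary markers;
the threshold is configurable. A removal log records the stage and
reason per dropped marker, and stage counts are kept so a run on real
data can be audited against a published 67,804 → 24,330 → 19,993-style
narrative.

`prune_redundant()` then removes, within each sequencing unit only,
SNPs in complete LD (r² = 1 within 1e-9) with an already-retained SNP,
scanning in ascending position. The scan is greedy, which matches the
"only the first SNP is kept" rule; with missing data, r² = 1 is not
transitive, so greedy retention against the kept set is the only
order-independent reading. Identical SNPs in *different* units are
never compared — the rule exists to collapse read-level duplication
inside a unit, not genome-wide LD structure.

## Diversity and differentiation

Observed heterozygosity is the per-locus heterozygote fraction among
called individuals, averaged over loci. Gene diversity uses the
Nei–Chesser unbiased estimator,
$H_s = \frac{n}{n-1}\left(1 - p^2 - q^2 - \frac{H_o}{2n}\right)$,
skipping loci with fewer than two calls. For the whole-collection row
the package reports both conventions a reader might intend — the pooled
collection treated as one population and the unweighted mean over
subpopulations — labelled `Total_pooled` and `Total_mean`; the
diversity table uses the pooled value, which is the convention under
which a structured collection shows the Wahlund excess
($H_s > H_o$).

Pairwise $F_{st}$ is Weir & Cockerham's θ with the variance components
a, b, c computed per locus and θ formed as a ratio of sums over loci,
never an average of per-locus ratios. Loci with fewer than two called
individuals in either population are excluded from both sums. Note one
finite-sample property that surprises at first sight: for two literally
identical samples θ is slightly *negative*, because the estimator
subtracts the sampling variance expected under panmixia; θ is unbiased
around zero over panmictic replicates, which is what the tests assert.
Bootstrap CIs resample loci with a fixed seed.

AMOVA is the one-level distance-based decomposition. The distance is
the missing-scaled squared Euclidean on dosage vectors:
$\delta^2_{ij} = \sum_{l \in \text{shared}} (d_{il}-d_{jl})^2 \cdot L/L_{ij}$,
which rescales each pair's sum to the full locus count so unevenly
missing pairs are comparable. Published AMOVA tools do not print their
distance convention, so numeric parity with any particular published
percent-among figure is a tolerance target rather than a bit-exact one.
Significance permutes individuals among groups with sizes fixed, using
the add-one rule so p is never zero; p-values are exact in distribution
only as permutation counts grow.

PCA mean-imputes missing dosages per marker, centres columns without
variance scaling, and takes scores from the SVD; percent variance per
component is the squared singular value over the total. Mean imputation
is declared and deterministic; it shrinks missing individuals toward
the centroid, which slightly attenuates structure but never invents it.

The Mantel isolation-by-distance test correlates the strictly-lower
triangles of a genetic distance matrix (default: one minus mean allele
sharing, `allele_sharing_distance()`) and great-circle distances
(haversine, Earth radius 6371 km), permuting accession order of the
genetic matrix, one-sided.

## Linkage disequilibrium

Two-locus haplotype frequencies come from EM over the
double-heterozygote ambiguity on pairwise-complete observations — the
convention of the standard unphased-genotype LD tool chain. Allele
frequencies are fixed by the genotype counts, so EM moves a single
degree of freedom; initialisation is at linkage equilibrium, the
degenerate double-heterozygote split (both phase products zero)
resolves to half/half, and iteration stops when no frequency moves by
1e-10. The observed-data log-likelihood is non-decreasing across
iterations, which the tests assert step by step, and the result agrees
with a one-dimensional likelihood-grid maximisation to better than
1e-6. $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, clipped to [0, 1]; a
composite-LD alternative is deliberately not the default.

`windowed_ld()` evaluates all intra-chromosome pairs within 1 Mb.
`fit_decay()` fits the Hill–Weir drift-recombination expectation
$$E(r^2) = \frac{10+C}{(2+C)(11+C)}
\left(1 + \frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right), \quad C=\rho d,$$
by one-parameter least squares in ρ (grid-seeded golden-section on
log₁₀ρ — a one-dimensional search is more robust than a generic
nonlinear optimiser here and exactly reproducible). Sample size n is
fixed before fitting at twice the median pairwise-complete count
(`ld_sample_size()`), keeping the regression one-parameter; the fit is
to raw pairs by default, with distance-binned means available for
plotting parity. The decay distance is where the fitted curve crosses
the baseline (r² = 0.1 by default), found by bisection to 1 bp — decay
is reported in kb, so 1 bp is far below reporting precision. The curve
has the analytic anchors $E(r^2)(0) \to 5/11$ as $n \to \infty$ and
$E(r^2) \to 1/n$ as $d \to \infty$; a baseline above $E(r^2)(0)$ yields
decay distance zero, and a curve that never reaches the baseline within
ten times the observed range reports "not reached" rather than an
extrapolated number.

`local_ld_profile()` averages r² over all cross-unit SNP pairs for each
pair of *consecutive* sequencing units on a chromosome, records the
mean at the left unit's cut position, and tallies means at or above vs
below the baseline per chromosome — the local recombination landscape
summary, where roughly two-thirds of flanking unit pairs in a
rapid-decay population fall below r² = 0.1.

## What the synthetic data emulate

`simulate_structured_population()` draws ancestral frequencies uniform
on (0.05, 0.95), population frequencies from the Balding–Nichols Beta
with differentiation F, Dirichlet ancestry per individual, binomial
genotypes on the admixed frequency, and an independent missing mask.
Balding–Nichols was chosen over coalescent simulation because F is a
closed-form truth the Fst estimator should recover, with no external
simulator. Defaults emulate the motivating panel: K = 3 ancestral
populations, 33 accessions each (99 total), both near-pure and admixed
ancestry (Dirichlet 0.3 biased toward a home population), F = 0.4
(matching a ~40% AMOVA among-population share), 5.7% missingness,
1,000 loci over 12 chromosomes. Estimator-recovery runs use K = 2,
F = 0.15, 50 accessions per population and 1,000 loci, with 50
replicates — sizes at which the estimator's sampling error is well
inside the ±0.02 band being checked.

`simulate_ld_genotypes()` uses a founder-mosaic (haplotype-pool) model:
M = 10 founder haplotypes, gametes copying from founders and switching
between adjacent markers with probability $1-e^{-c\,\Delta}$. LD decays
with distance because founder identity is lost; the defaults
(c = 3e-6 per bp, 2 kb mean spacing, 300 markers) put the fitted decay
distance in the 15–25 kb band, the tens-of-kb regime of the emulated
population. The model is phenomenological: fitted ρ is not analytically
tied to c, so LD checks are monotonicity and self-consistency
(recovering ρ from curve-sampled pairs), not equality to c.

`simulate_genome_fixture()` builds random chromosomes with motif
occurrences planted at recorded positions, a central heterochromatin
block, and genes placed with four-fold euchromatic enrichment (the
gene-dense-arms layout of a plant genome). Ground truth comes from a
construction-time plain-text scan of the final sequence, independent of
the Biostrings digestion path, so recovery is checked exactly.
`simulate_coordinates()` places population centroids on a north–south
transect with optional divergence-proportional spacing and Gaussian
jitter, giving isolation by distance by construction.

What the generators do *not* emulate: methylation-dependent site
dropout (the biological reason PstI RAD favours euchromatin — here
gene/heterochromatin layout is planted directly), linked selection,
realistic chromosome-scale recombination maps, genotyping error
correlated with depth, and ascertainment of SNP panels. Passing tests
therefore demonstrate correctness of the estimators under their
assumed models and faithful bookkeeping of the pipeline — not that any
particular biological dataset will match published values.

## Reproducibility and scale

Every stochastic operation takes an explicit seed (simulators refuse to
run without one); permutation defaults are 999 and bootstraps 1,000,
reduced in tests and the acceptance script to keep runs fast at the
problem sizes stated above. Pipelines rerun with the same inputs and
seed are byte-identical, including permutation p-values and bootstrap
intervals. The full published-scale reproduction (a 24,330-SNP × 98
accession matrix) is supported by the same functions via
`import_supplementary_genotypes()` but requires the externally
distributed genotype matrix; the package ships no data that size.

## Known limitations

- AMOVA is single-level (among/within populations); nested designs are
  out of scope.
- The Fst estimator is the two-population Weir–Cockerham form applied
  pairwise; a global multi-population θ is not reported.
- r² is EM-based; with extreme missingness the pairwise-complete subset
  can be small, and pairs monomorphic in that subset are undefined and
  skipped (counted, never imputed).
- The in-silico digest knows nothing about methylation: on a real
  genome it enumerates all sites, and the observed/sequenced contrast
  must come from the user's data.
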