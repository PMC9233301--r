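---
title: "Haplotype sharing, coancestry painting and recent demography: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype sharing, coancestry painting and recent demography: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hapsharing` analyses fine-scale population structure and recent demographic
history from phased diploid genotypes, using haplotypes rather than single
markers as the unit of information. This vignette describes the models each
stage implements, the parameters that matter, and the design decisions taken
where more than one reasonable choice existed. Companion driver scripts under
`analysis/` run the whole workflow on simulated cohorts, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.

## Overview of the pipeline

1. **Chunk painting** (`paint_panel`): every recipient haplotype is tiled
   into chunks attributed to donor haplotypes, giving N x N *chunkcount* and
   *chunklength* coancestry matrices.
2. **Coancestry network and clustering** (`build_graph`,
   `leiden_recursive`): individuals are nodes, symmetrized chunkcounts are
   edge weights; recursive Leiden community detection yields a cluster tree.
3. **Cluster relationships** (`copying_vectors`, `nnls_profile`, `tvd`,
   `hudson_fst`): mixture-style sharing profiles and distances between
   clusters.
4. **IBD segments** (`detect_ibd`, `merge_ibd`, `sharing_summary`):
   pairwise identity-by-descent segments, gap-merged, summarized within
   clusters.
5. **Recent effective size** (`segment_spectrum`, `fit_ne`): a diploid Ne
   trajectory fitted to the IBD segment-length spectrum with bootstrap
   bands.
6. **Inbreeding** (`detect_roh`, `f_roh`, `f_snp`): runs of homozygosity
   and the F_ROH / F_SNP coefficients.
7. **Simulator** (`sim_config`, `simulate_panel`): a forward pedigree and
   recombination simulator with ground-truth IBD, used as the truth set for
   every stage.

## Chunk painting

A haplotype panel stores 0/1 alleles for H haplotypes at S sites with bp and
cM coordinates (two haplotypes per individual, cM non-decreasing within a
chromosome). Painting attributes every site of a recipient haplotype to the
donor haplotype carrying the *longest identical interval covering that
site*; maximal runs of sites attributed to the same donor form chunks. This
longest-covering-set-maximal-match rule is the deterministic core of
PBWT-style painting: it is exactly checkable against a site-by-site
brute-force oracle, which the test suite does on dozens of random panels.
Set-maximal matches themselves are exposed via `maximal_matches`, and the
long-match machinery used for IBD detection is a positional Burrows-Wheeler
transform (prefix and divergence arrays) implemented in C++.

Donor choices and conventions:

* Both haplotypes of the recipient's own individual are excluded as donors;
  copying is between individuals only. Whether within-individual copying
  should be allowed is genuinely ambiguous in the wider literature; the
  between-individual convention matches standard coancestry usage and makes
  the matrix diagonal exactly zero.
* When several donors tie for the longest covering match the site is
  attributed by a deterministic seeded hash over (seed, recipient, site,
  donor) — unbiased across donors in expectation, exactly reproducible in
  both the compiled implementation and the R oracle, with an optional
  `"split-equally"` mode that shares the site's length among tied donors.
  Sites where no donor matches (possible only on tiny panels) are attributed
  by the same hash over all eligible donors, so every site is always
  assigned.
* Site lengths are adjacent-midpoint cM weights, so each recipient's
  chunklength row sums *exactly* to 2 x the total map length — a conserved
  quantity asserted for every painted panel in the tests.
* `chunks_per_region` (default 100) is carried as metadata for
  compatibility; chunk counts are not rescaled by it, because the PCA of the
  coancestry matrix normalizes rows explicitly.

PCA of the coancestry matrix (`coancestry_pca`) row-normalizes to
proportions, centers columns, and takes the SVD; component signs are fixed
by making each component's largest-magnitude loading positive.

## Coancestry network and recursive Leiden clustering

The network has one node per individual and edge weight equal to the
arithmetic mean of the two directed chunkcounts (the direction convention of
the painting is not meaningful for community detection). Edges are kept only
when `low < w < high`, with both bounds strict. The lower bound removes the
diffuse background of deep coancestry every pair shares; the upper bound
removes close relatives from the last few generations, whose enormous
weights would otherwise dominate modularity and pull out family cliques
instead of populations. The defaults (2 and 25) are the bounds used at
biobank scale; on desk-scale simulated panels the same two regimes sit at
different absolute counts, so the analysis scripts use a scale-free analogue
— keep positive weights below 5 x the mean positive weight — which removes
the same relative-pair regime.

Clustering applies igraph's Leiden implementation (weighted modularity,
resolution 1 by default) to the full graph, then recursively to each
community's induced subgraph, to `max_depth` (default 4). A community is not
subdivided when:

* it has fewer than `min_size` members (default 100; desk-scale runs use
  20), or
* the candidate subdivision is a single community, or
* the candidate subdivision's modularity falls below `min_modularity`
  (default 0.2).

The modularity gate is this package's addition. Modularity optimizers find
spurious communities in unstructured graphs, with modularity values well
below what genuinely planted block structure attains; without a gate,
recursion subdivides homogeneous clusters indefinitely and the planted
partitions the test suite constructs could not be recovered at the leaves.
The default of 0.2 was fixed once, from a dense Erdős–Rényi null
calibration that separates the two regimes, and is exposed as a parameter.
On simulated multi-subpopulation panels the first partition tier recovers
the subpopulations, while deeper tiers resolve genuine family-level
structure — the same behaviour that produces many fine-scale clusters on
real biobank data. Recovery of planted labels is
therefore evaluated at the tree tier matching the labels' granularity
(`cut_tree`): the first tier for subpopulation labels, the leaves for flat
planted partitions.

## Sharing profiles, TVD and Fst

A cluster's *copying vector* is the mean of its members' chunklength rows,
summed by donor cluster and normalized to 1. The *nnls sharing profile* of a
target cluster treats every other cluster as a potential source and solves

    min || xbar - t(Y) beta ||^2   subject to beta >= 0,

where `xbar` is the target's mean chunklength received from each source and
`Y[k, l]` is the mean chunklength cluster k receives from cluster l (source
rows and columns only; the diagonal — a source's own within-cluster copying
— is retained, since removing it would misrepresent the sources' profiles).
The non-negative fit uses the Lawson–Hanson solver; the fitted coefficients
are renormalized to sum to 1 and read as proportions of the target's
haplotype sharing best represented by each source. On simulated admixture
(one population drawing fathers from two sources in 70/30 proportion every
generation) the profile recovers the mixture within the tolerance of
ancestry drift; because a single 150-diploid cohort's realized ancestry
drifts appreciably around the nominal mixture, the recovery checks average
the profile over three replicate simulations.

Total variation distance between copying vectors is `0.5 * sum(|a - b|)` —
a metric on the simplex, property-tested for symmetry and the triangle
inequality. Differentiation is quantified by Hudson's Fst with the
ratio-of-averages estimator: per-site numerator
`(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` over denominator
`p1(1-p2) + p2(1-p1)`, summed separately before dividing, which is less
biased than averaging per-site ratios. Sites monomorphic in both groups are
skipped; each group needs at least two allele copies per site.

## IBD segments

`detect_ibd` reports every maximal pairwise identical haplotype interval of
genetic length at least `min_cM` (default 1 cM), using PBWT long matches
with the site-count threshold derived conservatively from the densest
possible window spanning `min_cM`. On error-free data these are exactly the
maximal allele-identity runs (verified against a brute-force oracle).
Within-individual matches are excluded; segment length is `cM(last site) -
cM(first site)` of the run.

Genotyping and phase-switch errors fragment true segments. `merge_ibd`
rejoins adjacent segments of the same haplotype pair when the gap is
shorter than 0.6 cM *and* contains at most one discordant site (a site
where the two haplotypes differ), applied transitively left to right. The
discordance count is at haplotype level: the external utilities this rule
mirrors count genotype discordances, an intentional and documented
divergence since this module works on phased haplotypes throughout. Under
0.2% genotype error the merge step measurably improves length-weighted
recall of long truth segments.

Within-cluster sharing (`sharing_summary`) gives each individual the mean
total IBD length and mean segment count over all same-cluster partners,
counting partners with no sharing as zeros; singleton clusters are flagged
as missing. Group contrasts use the Mann–Whitney U test (`rank_test`),
exact for small samples without ties.

## Recent effective population size

For a pair of haplotype lineages under a diploid trajectory Ne(g), the
probability of first coalescence g generations ago is

    P(g) = 1/(2 Ne(g)) * prod_{h<g} (1 - 1/(2 Ne(h))).

Under the Haldane model a segment from a coalescence at g has
exponentially distributed length with rate 2g per Morgan, giving the
textbook expectation `sum_g P(g) * 2 g L * exp(-2 g u)` for segments of
length at least u Morgans per haplotype pair. Two refinements apply when
chromosome lengths are supplied:

* **Finite chromosomes**: per chromosome of length Lc the expectation
  becomes `exp(-lam u) * (lam (Lc - u) + 1)`, accounting for segments
  truncated by chromosome ends.
* **Merge thinning**: observed maximal shared segments are excursions of
  the coalescence-time process below the horizon, not single coalescence
  episodes — a recombination breakpoint ends a segment only when the
  detached lineage fails to re-coalesce within the horizon. Termination is
  therefore thinned to `lam = 2 g (1 - cbar)`, with `cbar = sum_g P(g)` the
  total coalescence mass. Without this correction the model systematically
  under-predicts mid-length bins of ground-truth spectra; with it, binned
  truth spectra from the simulator pass a chi-square goodness-of-fit test
  at the scales the suite exercises.

`fit_ne` minimizes the Poisson deviance between observed per-bin counts
(segments above 4 cM by default, between-individual pairs only) and the
model expectation over a piecewise-constant log10-Ne trajectory with knots
every 5 generations, an L-BFGS-B fit bounded to Ne in [10, 1e8], plus a
smoothness penalty `smoothing * sum(diff(theta)^2)` on adjacent knots
(default 0.02 on the deviance normalized per observed segment, which makes
the point estimate exactly invariant to rescaling counts and pair numbers
together). Generations with little data are pulled toward their neighbours
rather than diverging.

Confidence bands come from a bootstrap. A replicate, by default, resamples
*both* individuals (with replacement, reweighting segments by the product
of their carriers' multiplicities and recomputing the pair count) *and*
10 cM genomic blocks. Individual resampling alone captures sampling noise
but not the realized-genealogy noise — the cohort's single pedigree makes
segment counts fluctuate coherently across all pairs, a component that
varies *along the genome* and is therefore visible to block resampling.
With individual-only resampling the 95% bands are too narrow to cover the
simulated truth; the joint scheme restores coverage at the scales the
suite exercises. `bootstrap_unit = "individuals"` remains available. The summary
table reports generations 5, 15 and 30 by default, configurable because
reporting conventions differ.

## Runs of homozygosity and inbreeding coefficients

`detect_roh` re-implements the standard sliding-window scan: 50-SNP windows
pass with at most 1 heterozygote and 5 missing calls; a SNP is a run
candidate when at least 5% of the windows containing it pass; maximal
candidate runs — split at inter-SNP gaps over 1000 kb — are reported when
they contain at least 50 SNPs, span at least 1500 kb and average at least
one SNP per 50 kb. All parameters are exposed in `roh_params`. The scan is
verified against a literal brute-force evaluation of every rule. No LD
pruning is applied to the ROH input.

`f_roh` is the fraction of the genome in ROH strictly longer than 1.5 Mb;
the default denominator is the autosomal length used at biobank scale
(2,879,248,291 bp), and simulated analyses pass their simulated genome
length. `f_snp` is the excess-homozygosity coefficient
`(O_HOM - E_HOM)/(N - E_HOM)` with `E_HOM = sum_i (1 - 2 p_i (1 - p_i)
n_i/(n_i - 1))` over the group's polymorphic sites; frequencies are
computed within user-supplied cluster groups, so that drift shared by a
group is absorbed and F_SNP isolates current-generation mating structure:
near zero under random mating *and* after a pure bottleneck (which elevates
F_ROH instead), positive under ongoing consanguinity. This contrast is the
diagnostic the inbreeding analyses are built around.

One caveat surfaced by the simulations: with a 30% first-cousin union rate
the theoretical F_SNP expectation is `c/16 * (1 + 3 F)`, just under 0.02,
and realized cohort means scatter on either side of that value — so
contrasts against the random-mating control (F_ROH and F_SNP both
elevated) are the robust readout rather than any fixed F_SNP cutoff.

## The simulator

`simulate_panel` runs a forward-in-time pedigree with per-generation
subpopulation sizes (time-varying, enabling bottlenecks), per-generation
migration matrices (time-varying, enabling admixture pulses or sustained
gene flow), consanguinity, and genotype/phase error:

* **Mating** is organized into monogamous couples with balanced sexes:
  every female may mother one couple; fathers are drawn from the
  subpopulation given by the migration row, without replacement; children
  are assigned to couples uniformly at random, producing full-sib
  families. Fully independent per-child parent draws were rejected because
  they make almost all siblings half-siblings, leaving "first cousins" with
  kinship 1/32 instead of 1/16 and halving every consanguinity signal.
* **Consanguinity**: with probability `cousin_mating_rate` the father is
  drawn from the mother's first cousins — children of a full sibling of a
  parent (sharing a grandparental couple, no shared parent). Cousin unions
  are not blocked by prior couple membership, mirroring how endogamous
  communities re-use families; when no cousin exists the couple falls back
  to random choice and the fallback is counted.
* **Transmission** is Haldane: crossover counts Poisson(length_cM/100) per
  chromosome, positions uniform in cM, no interference — deliberately
  matching the exponential segment-length assumptions of the Ne model.
  Founder haplotypes carry unique labels, so ground-truth IBD (including
  within-individual autozygosity) is exact interval algebra on the ancestry
  mosaics.
* **Genotyping**: sites are placed uniformly at random in cM (bp = cM x
  1 Mb by default), founder alleles are drawn per site from `maf_law`
  (uniform MAF 0.02–0.5 by default), and errors are applied as phase
  switches then allele flips.

What the simulator does *not* emulate: linkage disequilibrium among founder
haplotypes (founders are unrelated by construction, so there is no deep
coalescent structure beyond generation G), crossover interference, gene
conversion, genotyping error that clusters along the genome, and real
marker ascertainment. Passing tests therefore demonstrate correctness of
the algorithms under the stated generative model, and qualitative
reproduction of the real-data signatures (sharing gradients, bottleneck vs
endogamy contrasts); they do not calibrate absolute biobank-scale numbers,
which additionally depend on data the simulator does not model.

## Study conditions and problem sizes

The suite and the acceptance script use desk-scale cohorts chosen to keep a
full run within minutes while leaving each signal measurable: a constant
population of 500 diploids over 50 generations with 2 x 100 cM chromosomes
at 50 sites/cM (200 sampled) for IBD and Ne recovery; four subpopulations
of 150 diploids exchanging 0.1% of couples per generation for cluster
recovery; three 150-diploid populations with sustained 70/30 paternal gene
flow for profile recovery; 200-diploid cohorts over 25 generations with
3 x 100 cM genomes for the inbreeding regimes; and goodness-of-fit checks
on 20-chromosome truth spectra restricted to disjoint individual pairs so
that Poisson sampling noise, not shared-pedigree correlation, sets the test
scale.

## Numerical choices and degenerate inputs

* Coordinates: bp are 1-based as in VCF; site intervals are half-open in
  site index; cM segment lengths are differences of site positions.
* Chromosomes with fewer than 2 sites are skipped (with a warning) by
  painting; zero-length chromosomes produce single-interval mosaics.
* Chunklength row sums are exact by construction (midpoint weights), not
  approximate.
* Ties: painting donor ties use the seeded hash above; LD pruning removes
  the later site of a violating pair; Leiden recursion is seeded per node.
* Degenerate nnls systems (rank-deficient source matrices) and empty
  segment spectra are errors, not silent results; singleton clusters yield
  missing sharing summaries; `f_snp` is flagged missing when `N == E_HOM`.

## Known limitations

* Painting is the deterministic longest-match attribution, not the
  Li–Stephens probabilistic model; no donor-panel (supervised) mode.
* IBD detection is exact matching on phased haplotypes — suited to
  simulated or well-phased data; robustness to error comes only from the
  merge rule, not from within-segment mismatch tolerance.
* The Ne estimator is a spectrum-matching fit with an explicit, printable
  model; it is not a re-implementation of any external tool's iterative
  algorithm, and its absolute trajectories on real data should be read
  with the same caution as any IBD-based estimator (phasing and detection
  biases propagate).
* F_SNP depends on the grouping used for allele frequencies; pooling
  differentiated clusters into one group adds a Wahlund component by
  construction.
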