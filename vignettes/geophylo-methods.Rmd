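---
title: "Methods: quantifying geographic structure in within-species phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying geographic structure in within-species phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Bacterial genomes assembled from environmental samples collected around the
world carry a genealogical signal: if a species disperses freely, the gene
trees of its local variants interleave samples from different continents;
if dispersal is restricted or local selection acts, samples from the same
region cluster together. `geophylo` measures that clustering, asks whether
it differs between gene functional classes — the hypothesis being that
surface-exposed (membrane) proteins experience region-specific selection
pressures that core machinery (ribosomal and other organelle-class
proteins) does not — and provides a simulator in which the answer is known
by construction.

## Geographic clustering: PERMANOVA on tree distances

The unit of analysis is a phylogeny with tips annotated by region. We
convert it to patristic distances (sum of branch lengths along tip-to-tip
paths) and run a one-factor permutational MANOVA. With squared distances
$d_{ij}^2$, Gower centering $G = J(-\tfrac12 D \circ D)J$,
$J = I - \tfrac1n \mathbf{1}\mathbf{1}^\top$, and $H$ the projection onto
the region-indicator design,

$$SS_{total} = \mathrm{tr}(G), \qquad SS_{model} = \mathrm{tr}(HGH), \qquad
R^2 = \frac{SS_{model}}{SS_{total}},$$

$$F = \frac{SS_{model}/(k-1)}{SS_{resid}/(n-k)}.$$

$R^2$ is the fraction of distance variation explained by region — the
headline statistic. On a Euclidean-embeddable matrix it equals classical
one-way ANOVA on the embedded coordinates and lies in $[0,1]$; on
non-embeddable matrices (negative eigenvalues of $G$, which short
low-variance genes can produce) it can be negative, meaning the regional
model fits worse than a flat baseline. The permutation null shuffles
region labels; with the add-one correction
$p = (1 + \#\{F_\pi \ge F_{obs}\})/(1+P)$ a p-value is never exactly zero.
The default is $P = 999$ unrestricted permutations with a caller-supplied
seed; permutations are unrestricted because geography is the only factor.

Before testing, two filters mirror how redundant assemblies must be
handled: among tips sharing a city only the best dedup-scored genome is
kept (ties broken by smallest tip id, for determinism), and a tip left as
its region's sole representative is dropped. A tree retaining fewer than
two regions is reported `untestable` rather than silently discarded, so
whole-run summaries account for every input. p-values are BH-corrected
across the species trees of a run; gene-tree p-values are left raw because
downstream group comparisons consume the $R^2$ values, not the p-values.

## Gene groups and bias diagnostics

Genes are stratified by top-level cellular-component labels: `membrane`,
`organelle`, and everything else — including the typically large
unannotated fraction — pooled as `metabolic`. A gene labeled both membrane
and organelle goes to membrane, since surface exposure drives the
hypothesis; conflicts are counted and reported. Group differences in
$R^2$ (or dN/dS) are tested with a Kruskal-Wallis screen followed by
pairwise two-sided Wilcoxon rank-sum tests, the pairwise stage gated on
the screen clearing $\alpha = 0.05$ after BH correction. Wilcoxon tests
are exact when both groups have $\le 25$ members and no ties, otherwise
normal approximation with tie and continuity correction.

Because $R^2$ could be driven by gene properties rather than biology, the
package computes Pearson correlations of per-gene $R^2$ against four
covariates: number of tips after filtering, mean pairwise difference
fraction (mean pi), alignment length, and the Shannon entropy (nats) of
the tips' regional composition. A species where any covariate correlates
significantly after BH is flagged — never auto-dropped; that judgement is
left to the analyst.

## dN/dS: Nei-Gojobori counting

Likelihood dN/dS machinery is deliberately replaced by the Nei-Gojobori
(1986) unweighted counting method with Jukes-Cantor correction: it is
dependency-free, exactly testable against brute-force enumeration, and
adequate for rank-based group contrasts, which is all the downstream
analysis consumes. This is the package's single deliberate methodological
substitution. Synonymous site fractions enumerate the three single-base
mutations per codon position under bacterial translation table 11, with
mutations to stop codons excluded from the denominator (so S + N = 3 per
codon); pairwise differences average over all shortest substitution
pathways, excluding pathways through stops. Genes enter the calculation
only if they vary at the nucleotide level (gap-versus-base columns do not
count), start on a consensus ATG/TTG/GTG (the consensus-first-codon
reading of the framing rule), and have trailing stop codons trimmed.
Gapped or ambiguous codons are skipped pair by pair rather than
column-wise, preserving pairs in patchy alignments. A ratio is undefined
when $dS = 0$ or a proportion saturates ($p \ge 3/4$); such genes are
reported but excluded from group tests.

## Abundance normalization

For presence filtering, the expected coverage of a genome of length $g$
receiving $r$ reads of length $l$ is $c = 1 - (1 - l/g)^r$; cells whose
observed covered fraction falls below half the expectation are zeroed
(the ratio direction is exposed as a flag because the source protocol's
wording is ambiguous). Counts are rarefied to a common depth by a single
seeded draw without replacement per sample (multivariate hypergeometric),
then converted to TPM; the rarefaction depth is always a parameter, never
hard-coded. Shannon diversity is computed in nats from TPM (it is
scale-invariant, so raw proportions give the same value), and composition
profiles are compared with the two-sample Kolmogorov-Smirnov test.

## The simulator: what it emulates and what it does not

The generator emulates the data regime the analysis is designed for:
multi-region sampling of one bacterial species, per-gene alignments whose
variation is either genealogy-only or regionally selected, duplicate
genomes from the same city, and functional labels tied to the truth.

**Genealogy.** A backward-time Gillespie implementation of the island
model: within each region, lineage pairs coalesce at rate `1/pop_scale`;
each lineage migrates at rate $m$ to a uniformly chosen other region.
Branch lengths are coalescent units. `pop_scale = 1` is the canonical
coalescent convention. The defaults — 3 regions × 8 samples, $m = 0.1$ —
produce genealogies whose regional structure varies widely across seeds
(species-tree $R^2$ roughly 0.2 to 1.0), bracketing the intermediate
clustering regime real data show.

**Sequences.** The root is an ATG start plus random sense codons; branches
accumulate Poisson($\mu \cdot \ell \cdot L$) substitutions (uniform site,
uniform alternative base), resampling any mutation that would create an
in-frame stop. The start codon itself never mutates — real start codons
are under strong purifying selection, and the dN/dS framing rules key on
them. $\mu = 0.05$ per site per coalescent unit with 300-codon genes
yields within-region similarity and deep between-region divergence.

**Selection.** Regional selection is modeled as character-state
convergence, not fitness-based forward simulation: it creates exactly the
signal the statistic measures, with interpretable knobs. In a selected
gene, `selection_fraction` of the alignment's sites (default 10%, i.e. 90
of 900) are constrained; they sit at first and second codon positions, so
the regional signal is amino-acid changing — which is what lets the dN/dS
contrast between selected and neutral gene groups recover the expected
direction. Each region receives a preferred base at each constrained
site, *distinct between regions* — independent draws would coincide a
quarter of the time, which models global purifying constraint rather than
regional differentiation — and every tip's state is overwritten with
probability `selection_strength` (default 0.8) by its region's
preference, skipped in the rare backgrounds where it would create a stop.

**Gene trees.** Gene trees are deliberately rebuilt by neighbor joining
from each simulated alignment rather than reusing the true genealogy, so
tree-estimation noise is part of every recovery test. NJ uses
Jukes-Cantor-corrected distances: NJ assumes additive distances, and
uncorrected p-distances saturate at deep between-region divergence,
compressing exactly the structure being measured. Saturated pairs
($p \ge 3/4$) are capped at 5 substitutions/site so the reconstruction
stays finite.

**What passing tests do not show.** The simulator has no recombination,
HGT, indels, rate heterogeneity, or realistic demography; all genes share
one genealogy, whereas real within-species data mix histories; selection
is a direct overwrite rather than a fitness process. Recovery of the
membrane-versus-organelle contrast here demonstrates that the statistical
pipeline detects region-correlated sequence variation when present and
stays quiet when absent — not that real membrane genes are under regional
selection.

## Numerical choices and degenerate inputs

- City-dedup ties break by lexicographic tip id; missing newick branch
  lengths parse as 0 with a warning; negative NJ branch estimates clamp
  to 0.
- Gap/N handling is pairwise deletion throughout (p-distances, mean pi,
  dN/dS), preserving information in patchy alignments.
- A distance matrix of identical points has $SS_{total} = 0$ and is
  flagged untestable rather than divided by zero; an all-equal value
  vector gives a Kruskal-Wallis H of 0 and p of 1 by convention.
- Every stochastic step (permutations, rarefaction, simulation) takes an
  explicit seed and restores the caller's RNG state.

## Problem sizes

The validation suite runs at desk scale: oracle equivalences on 6-10
point configurations; type-I calibration over 200 label shuffles of a
24-tip genealogy (199 permutations each); mechanism-recovery panels of 20
seeds at the default generator conditions (60 genes × 24 + 3 tips per
seed, 199 permutations per tree); coalescent closed forms over 2000
two-lineage runs and 800 high-migration runs. These sizes make every
result reproducible in minutes on one CPU while keeping the Monte-Carlo
standard errors well inside the asserted tolerances.
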