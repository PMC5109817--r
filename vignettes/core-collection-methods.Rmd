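---
title: "Constructing and evaluating germplasm core collections with germCore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and evaluating germplasm core collections with germCore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A genebank holding thousands of accessions of a crop and its wild relatives
is hard to use: most accessions are redundant with respect to the variation
the collection actually carries, and phenotyping or sequencing everything is
impractical. A *core collection* is a small subset chosen so that every
allele, trait category and trait-range class observed in the entire
collection is still present — maximum diversity, minimum redundancy.

germCore implements the complete workflow for building such a core from a
small genome-wide SNP panel (tens of markers) plus qualitative and
quantitative morphological traits: accession-level quality control,
diversity statistics, distance-based clustering, class construction, greedy
maximum-coverage selection under five sampling strategies, and a
representativeness evaluation framework with hold-out marker validation.
Because genebank genotype tables are rarely redistributable, the package
also ships a generative simulator that reproduces the statistical structure
such collections exhibit, so the whole pipeline is testable end to end.

```{r, eval = FALSE}
library(germCore)
sim <- simulateCollection(defaultPaperLikeConfig(seed = 1))
res <- runPipeline(list(seed = 1, output_dir = "run",
                        simulation = list(paper_like = TRUE)))
```

## Quality control

Crop germplasm of predominantly selfing species is expected to be highly
homozygous. Two accession-level filters are applied before any analysis:

* **F1-hybrid filter.** Accessions whose observed heterozygosity
  $H_O$ (heterozygous calls over non-missing calls) strictly exceeds 0.3
  are flagged as planted F1 hybrids — a cross between two inbred parents is
  heterozygous wherever the parents differ, which in a structured selfing
  collection puts it far above the bulk of the $H_O$ distribution.
* **Missingness filter.** Accessions with strictly more than 7 missing
  calls (of a 48-marker panel) are excluded.

Both inequalities are strict — an accession exactly at a threshold is
retained — and the $H_O$ denominator excludes missing calls so that
missingness is not penalized twice (it has its own filter). Both choices
are assumptions where the filtering rules could be read either way; they
are documented here and in `applyQC()`.

## Diversity statistics

All statistics define their own denominators over non-missing data; nothing
is ever imputed.

* Expected heterozygosity (gene diversity) $H_E = 1 - \sum_i p_i^2$ on
  allele frequencies, **without** small-sample correction — the plain
  textbook form, stated so results are reproducible.
* Observed heterozygosity $H_O$ per marker: het calls / non-missing calls.
* Polymorphic information content in the Botstein form
  $\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2 \le H_E$.
* Shannon's information index $I = -\sum_c f_c \ln f_c$ with the natural
  logarithm throughout, $I_{max} = \ln(\text{classes})$ and Pielou evenness
  $J' = I / I_{max}$. The natural log is forced by the published worked
  values this package reproduces ($\ln 9 = 2.20$, $\ln 16 = 2.77$ at two
  decimals). For SNP markers the Shannon classes are observed *genotype
  patterns* (`A/A`, `A/B`, `B/B`); allele-level classes are used only in
  core selection, where a heterozygote carries both alleles.
* Per-cluster differentiation is the Wright-style proxy
  $F_{ST,k} = \mathrm{mean}_m (H_T - H_{S,k})/H_T$ over polymorphic
  markers, with $H_T$ from pooled frequencies. Negative estimates are
  reported, never clipped. Note this estimator is a proxy: model-based
  clustering programs report a differently defined per-cluster $F$, and the
  two are not numerically interchangeable. With $K$ pooled clusters the
  proxy is also mildly downward-biased (the pooled $H_T$ already contains
  some between-cluster variance), on the order of the factor
  $(1 - 1/K)/(1 - F/K)$.
* Distance-based AMOVA decomposes $\sum_{i<j} d_{ij}^2/N$ into among- and
  within-cluster components via the standard expected-mean-square
  equations, with $\Phi_{ST}$ and a label-permutation test
  ($p = (1 + \#\{\Phi^\ast \ge \Phi\})/(B+1)$, seeded, default $B = 999$;
  the pipeline uses 199 to keep runs fast).

## Distances, trees and ordination

Genotypes are encoded as per-allele dosages; a marker contributes
$\sum_a |x_{ia} - x_{ja}|/4 \in [0,1]$ to the pair $(i,j)$ (for a biallelic
marker this is half the minor-allele dosage difference), and the pairwise
dissimilarity is the mean over markers at which both accessions are
non-missing (*pairwise deletion*). This keeps values in $[0,1]$ under
missingness, at a price worth stating: because each pair has its own
denominator, the triangle inequality can fail between accessions with very
different missingness patterns. The matrix of co-non-missing counts is
returned alongside the distances so users can see where the support is
thin; the property is exact (triangle inequality holds) on complete data.

Trees are classic Saitou–Nei neighbor joining (negative branch lengths
clamped to zero, count reported) and UPGMA (average linkage). Cluster
labels for stratified selection come from cutting the UPGMA tree at a
chosen $k$; NJ trees are unrooted and cannot be cut, which `cutTree()`
enforces. External cluster labels (e.g. from a model-based structure
analysis run outside this package) can be supplied anywhere a cluster
vector is accepted. Principal coordinate analysis is classical metric
scaling on $-D^2/2$, keeping positive-eigenvalue axes.

## Class construction and the advanced M strategy

Selection operates on a *classification table*: each variable contributes
classes, each accession carries the classes it exhibits.

* Markers: one class per observed allele (a 48-SNP biallelic panel gives
  96 classes); a heterozygote carries two.
* Qualitative traits: observed categories (typically 3–12 per trait).
* Quantitative traits: Sturges bins, $k = \lceil 1 + \log_2 n \rceil$
  equal-width bins over the observed range; values on an internal edge go
  to the lower bin. A constant trait degenerates to a single class with a
  warning.

The selector is a deterministic greedy maximum-coverage heuristic in the
spirit of the advanced M (maximization) strategy: repeatedly pick the
accession carrying the most still-uncovered classes, breaking ties first
toward accessions carrying *rarer* classes (larger $\sum 1/\text{carrier
count}$ over their uncovered classes), then by lexicographically smallest
id; finish with a backward redundancy pass that drops any selected
accession whose removal leaves all classes covered. The published
heuristic softwares in this area do not document their internals in
reproducible detail, so this package defines its own deterministic
procedure and validates it against an exhaustive minimum-set-cover oracle
on small instances (full coverage always; size within +1 of the optimum on
all tested instances up to 12 accessions x 10 classes). Full coverage is
enforced unconditionally — the selector never trades coverage for size.

Five strategies are exposed: `Gcc` (genotype classes, whole collection),
`Ggcc` (genotype, selected within each cluster), `Pcc` (phenotype only),
`G+Pcc` (both, whole collection) and `Gg+Pcc` (both, within clusters).
For the stratified strategies Sturges bins are recomputed within each
cluster — selection there sees cluster data only — and coverage is
accounted against exactly the classes targeted (allele/category classes
deduplicated globally, bins counted per cluster), every one of which the
returned union verifiably covers.

## Evaluating a core

For quantitative traits, with $M$, $V$, $R$, $CV$ the mean, sample
variance, range and coefficient of variation and subscripts $e$/$c$ for
entire/core:

$$MD\% = \frac{100}{m}\sum_j \frac{|M_{ej} - M_{cj}|}{|M_{ej}|},\quad
  VD\% = \frac{100}{m}\sum_j \frac{|V_{ej} - V_{cj}|}{V_{ej}},\quad
  CR\% = \frac{100}{m}\sum_j \frac{R_{cj}}{R_{ej}},\quad
  VR\% = \frac{100}{m}\sum_j \frac{CV_{cj}}{CV_{ej}}$$

A core is flagged *representative* when $MD\% < 20$ and $CR\% > 80$.
The relative-difference forms above are the default because the published
comparison values this framework mirrors are not multiples of $100/m$ for
any plausible trait count, which rules out the alternative
"percent-of-significant-tests" convention; that count form (Welch t-test /
F-test at 0.05) remains available via `form = "count"` for comparability
with other literature. Variances use the $n-1$ denominator; traits whose
entire-collection denominator is zero are skipped with a warning.

For categorical variables (markers as genotype patterns + qualitative
traits), $I$, $I_{max}$ and $J'$ are compared between core and entire
collection. By default $I_{max}$ uses the *entire-collection* class count
for both sides (a fixed denominator, so core and entire evenness are
directly comparable); hold-out validation instead uses each column's own
observed pattern count, the convention of published hold-out tables. Both
conventions are implemented and labeled. Hold-out validation runs on
multi-allelic markers that took no part in selection (enforced by id
disjointness) — the honest way to test a core, since selection variables
are covered by construction.

## The simulator

`simulateCollection()` generates collections with the structure the
analysis assumes, plus a truth record for parameter-recovery testing:

* **Markers.** Ancestral frequency $p_m \sim U(0.1, 0.9)$; cluster $k$'s
  frequency is a Balding–Nichols draw
  $\mathrm{Beta}(p(1-F_k)/F_k,\ (1-p)(1-F_k)/F_k)$, the minimal standard
  F-model with $E[F_{ST}] = F_k$ tunable per cluster.
* **Genotypes.** Inbreeding-adjusted proportions
  $P(\text{het}) = 2pq(1-F_{IS})$, $P(\text{hom}) = p^2 + pqF_{IS}$, with
  $F_{IS}$ settable per species — selfing crop species are simulated with
  high $F_{IS}$ (excess homozygosity), wild outcrossers with low.
* **Species.** A species plan assigns counts and cluster-mixture weights;
  admixture is species-level (each accession still belongs to one latent
  cluster). Per-accession admixture proportions are deliberately out of
  scope.
* **Hybrids.** Planted F1s replace a configurable fraction of accessions
  and are literal first-generation crosses: one gamete from each of two
  random non-hybrid parents from different clusters.
* **Traits.** Quantitative traits get positive baselines
  ($U(10,100)$ with 15% relative dispersion, emulating measured lengths,
  weights and dates — this keeps the relative MD% denominator away from
  zero, as for real crop traits); cluster effects and noise scale with
  that dispersion. Qualitative traits are cluster-specific multinomials
  over 3–12 classes. Hold-out markers draw 9–16 alleles from
  cluster-specific Dirichlet frequencies with the same divergence scaling.
* **Missingness** is i.i.d. per call. Everything is deterministic given
  the config (including its seed).

`defaultPaperLikeConfig()` is a desk-scale stand-in for a multi-thousand
accession genebank: 1,000 accessions, 11 species of very unequal size (the
dominant crop species holds 88% and spans seven of $K = 10$ clusters),
divergences 0.1–0.7, $F_{IS} = 0.8$ in the crop species, 10% planted F1s,
2% missing calls, 17 quantitative + 15 qualitative traits, 3 hold-out
markers. One thousand accessions keeps a full five-strategy pipeline run
in the tens of seconds while preserving every qualitative feature of the
larger problem; the parameter-recovery checks in the test suite use 200 to
800 accessions for the same reason.

What the simulator does *not* emulate — and hence what passing tests do
not certify about real data: linkage between markers, genuine trait
genetic architecture (traits are cluster-linked only), non-random
missingness (real genotyping failures concentrate in poor-quality DNA),
clonal duplicates, and per-accession admixture. Results on real
collections should be read with those gaps in mind.

## Numerical conventions and degenerate inputs

* Report tables round half-up to 2 decimals (display only; internal values
  keep full precision).
* Shannon uses $0 \ln 0 := 0$; $J'$ is undefined below 2 classes and such
  variables are skipped in averages.
* Markers with no data in a subset are flagged absent and excluded from
  that subset's means; a pair of accessions sharing no marker is an error
  naming the pair.
* UPGMA ties follow the platform agglomeration order of `hclust`
  (deterministic for fixed input); NJ negative branch lengths are clamped
  to zero with a count kept on the tree.
* `cutTree(k)` partitions refine `cutTree(k-1)` by construction.
* An empty retained set after QC is allowed (with a warning); an empty
  core is an error.

## Design choices that were genuinely open

* **Missing-data policy in distances**: pairwise deletion (normalize by
  co-non-missing markers) was chosen over fixed-denominator scoring so the
  dissimilarity stays in $[0,1]$ regardless of missingness; the caveat on
  the triangle inequality is above.
* **Cluster source for stratification**: UPGMA tree cutting, because it is
  reproducible from the package's own distance matrix; model-based
  admixture clustering is an external tool whose labels can be plugged in.
* **"Unweighted" neighbor joining** is read as classic Saitou–Nei with the
  unweighted distance update.
* **Multi-allelic markers in distances** use per-allele dosage components
  (contribution $\sum_a |\Delta_a|/4$), keeping every marker's range
  $[0,1]$ regardless of allele count.
* **Coverage accounting for stratified cores** counts cluster-qualified
  quantitative bins (see above), since per-stratum binning makes global
  bins ill-defined.

## Known limitations

* The greedy selector is validated against the optimum only on small
  instances; like all greedy set-cover heuristics it has no global
  optimality guarantee.
* The per-cluster $F_{ST}$ proxy is biased downward relative to the
  divergence parameter by the pooled-$H_T$ factor noted above; the bias is
  small for moderate $K$ and divergence.
* Qualitative-trait class counts outside 3–12 only warn; enforcing them as
  errors would reject legitimate descriptors.
* The pipeline's AMOVA step is skipped (with a warning) when a tree cut
  produces a singleton cluster, since variance components need at least
  two members per group.
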