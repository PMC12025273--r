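---
title: "Driver-induced modular screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Driver-induced modular screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dims)
```

## The screening strategy

`dims` implements a multi-stage screen for the mechanism of a drug
*combination*, built around four ideas:

1. **Treatment-specific co-expression modules.** For each treated group a
   weighted gene co-expression network is built from the expression profiles
   of that group alone, and modules are detected on the topological overlap
   dendrogram. Modules are the unit of analysis: a coordinated
   transcriptional programme, not a single gene.
2. **Drug-responsive and synergy modules by preservation.** A module
   detected under a treatment is compared against a comparator dataset with
   a permutation Zsummary statistic. Modules whose density and connectivity
   *fail* to reproduce in the untreated comparator (Zsummary < 0, "On"
   modules) are the treatment's transcriptional footprint; modules that
   reproduce (Zsummary ≥ 2) are conserved housekeeping structure. A
   combination-treatment module that is On versus the untreated group *and*
   non-preserved versus at least one single drug is a synergy (Sy) module —
   structure the combination creates that neither single drug explains.
3. **Network separation of the single drugs' footprints.** On an
   interaction network, the separation score
   $S_{AB} = d_{AB} - (d_{AA} + d_{BB})/2$ under the "closest" distance
   measures whether the two single drugs' gene sets occupy overlapping
   ($S_{AB} < 0$) or isolated ($S_{AB} > 0$) neighborhoods. Overlapping,
   complementary neighborhoods are the established network signature of a
   useful combination.
4. **Driver genes by proximity and flow.** Candidate genes are ranked by
   (a) total shortest distance to the members of the two footprints
   (ascending) and (b) flow centrality — the summed fraction of A-to-B
   shortest paths through the candidate (descending). The union of the two
   top-k lists (k = 10 by default) is the driver set; genes on both lists
   are "common" drivers, so $|drivers| = 2k - |common|$ holds by
   construction.

## The expression model

Each module m is a one-factor Gaussian: gene j in module m, sample s of
group g,

$$x_{js} = \mu + \sigma\left(r_{m,g}\, e_{m,g}(s) +
\sqrt{1 - r_{m,g}^2}\,\varepsilon_{js}\right) + \delta_{g}(j),$$

with $e$ and $\varepsilon$ independent standard normals. Consequences used
throughout the tests:

* the within-module correlation is exactly $r^2$ in expectation, so a
  loading of 0.9 yields the 0.81 correlation a strongly coherent microarray
  module shows;
* disrupting a module in one group (replacing $r$ with 0) destroys its
  co-expression there while leaving means, variances and the module's
  *label* intact — preservation statistics respond, differential expression
  does not;
* planted effects $\delta$ are additive on the log2 scale, so a
  $\delta = \log_2 1.5$ plants exactly a 1.5-fold change.

Defaults of the stated world (`sim_config()`): 200 genes, 20 samples per
group, five modules of 30 genes at loading 0.9, residual sd
$\sigma = 0.3$ on the log2 scale, baseline log2 expression 8. Twenty
samples per group and a log2-scale residual sd of ~0.3 are typical of a
well-powered rodent microarray experiment; 0.9 loadings represent strong,
clearly-present modules (the regime in which module screening is
meaningful at this sample size). `synergy_config()` arranges the stated
synergy world: two always-intact modules, one module co-expressed only
under drug A, one only under drug B, and one only under the combination —
the unique planted Sy module.

### What the generator does *not* emulate

Probe-level effects, batch effects, heteroskedastic intensity-dependent
noise, correlated noise between modules, signed (anti-correlated) module
structure, and any relationship between expression level and network
degree. A green end-to-end test therefore establishes that the pipeline's
logic recovers planted structure of realistic strength — not that it would
reproduce any particular published module count on real arrays.

## Co-expression networks and module detection

Unsigned adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ and the
topological overlap matrix
$TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$ with
$L_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj}$. The unsigned form is the
field's default and matches the unsigned use of the preservation
statistics. Soft powers are chosen by the scale-free fit criterion
(smallest $\beta$ with fit index ≥ 0.8; the best-fitting power with a
warning otherwise), and published powers can be passed as explicit
overrides, bypassing selection.

Module detection clusters 1 − TOM with average linkage. Because the
reference dynamic tree-cut implementation is not available as a
dependency, the cut is a fixed-height cut whose height is chosen
**adaptively**: candidate heights are the midpoints between consecutive
merge heights near the top of the dendrogram plus coarser quantile-based
candidates below (this always samples the gap between within-module and
between-module merges); each candidate partition keeps clusters of at
least `min_size` (3, following the screen's published setting) and is
scored by the size-weighted mean cluster silhouette on the 1 − TOM scale,
*discounted by the assigned fraction of genes*. The discount stops a
partition from buying tight clusters by dumping most genes into the grey
pool; contrasting each cluster only against *other clusters* (not the grey
pool) stops a fragmented module from scoring well against its own stray
members.

Two further numerical choices:

* **Branch-quality floor.** Surviving clusters must reach a mean
  silhouette of `min_silhouette` (0.1). Clusters of ≥ 10 genes face a
  third of that bar: a chance aggregate of ten mutually correlated noise
  genes is essentially impossible at these sample sizes, while small
  chance triplets — the clusters the floor exists to remove — are common.
  Without this floor, spurious three-gene modules leak into the
  preservation stage, where an unstructured gene set is systematically
  classified drug-responsive (its observed statistics sit below a null
  that contains genuinely structured random sets).
* **Tie handling.** Modules are renumbered by decreasing size; colors are
  cosmetic aliases with grey reserved for the unassigned label 0.

## Preservation: the permutation Zsummary

For a module defined in the `ref` (treatment) dataset, seven statistics are
evaluated: four density-side statistics in the `test` dataset (mean
within-module correlation, mean adjacency at the test power, proportion of
variance explained by the module eigengene, mean eigengene membership kME)
and three connectivity-side ref-versus-test correlations (intramodular
connectivity kIM, kME, and the within-module correlation matrix itself).
Each is standardized against `n_perm` random gene sets of the same size
drawn without replacement from the full universe, and

$$Z_{summary} = \tfrac{1}{2}\left[\mathrm{median}(Z_{meanCor}, Z_{meanAdj},
Z_{propVarExpl}, Z_{meanKME}) + \mathrm{median}(Z_{cor.kIM}, Z_{cor.kME},
Z_{cor.cor})\right].$$

Classification: On below 0, conserved at or above 2 (the boundary is
inclusive), indeterminate in the band between — indeterminate modules
belong to neither set.

Design choices on points the method's published description leaves open:

* **Direction.** Modules are detected in the treatment dataset and their
  preservation is evaluated in the comparator. The direction is part of
  the function signature (`ref` = where modules live, `test` = where
  preservation is measured); swapping the arguments is a different
  analysis and is never done silently.
* **Null scheme and count.** Random gene sets (not label rotations), seed
  mandatory, `n_perm` defaulting to 200. Zero-spread nulls set the
  affected Z to 0 with a warning rather than produce infinities.
* **Sy rule.** $Sy = (On_{vs\,A} \cup On_{vs\,B}) \cap On_{vs\,sham}$,
  which reproduces the published worked example
  ({8} ∪ {1,7,10}) ∩ {6,7,8,10} = {7,8,10}.

## Differential expression

A plain Welch t-test per gene on log2 values, with
$FC = 2^{|\Delta\text{mean}|}$ and the screen gate FC > 1.2 and p < 0.05;
the Bonferroni-adjusted p is always reported and can be made the gating
p-value by a flag. A variance-moderation option (empirical-Bayes squeezing
of gene variances toward the common value) is available behind
`shrink_var = TRUE`; the default stays the plain, fully specified test so
that the screen's behavior is transparent. Overlap percentages between DEG
sets are reported under both plausible denominators (pair union and total
distinct genes), since published overlap percentages rarely state theirs.

## Network measures

All distances are unweighted BFS hop counts; by default queries are
restricted to the largest connected component (flagged), and disconnected
pairs are skipped *and counted* rather than given a pseudo-distance, so
means stay interpretable. Flow centrality is computed by shortest-path
counting (per-source BFS path counts; $\sigma_{ab}(v) =
\sigma_{a\to v}\,\sigma_{v\to b}$ when v lies on a shortest path), never
by path enumeration — but the test suite checks it against an exhaustive
path-enumeration oracle on hundreds of small random graphs, alongside a
hand-rolled Floyd–Warshall oracle for the distance-based measures. Both
the normalized flow centrality (the printed $1/|A||B|$ form) and the raw
pair-sum are reported; ranking uses the raw sum by default, matching the
magnitudes with which driver tables are published. The per-gene "shortest
distance" driver score is implemented as the total distance from the gene
to all members of $A \cup B$ — a reconstruction, clearly labeled, of a
published per-gene column whose exact target set is not stated.

The driver candidate pool defaults to *all* network nodes: bridge-like
drivers need not belong to either footprint, and several published drivers
lie outside the module gene lists. Ties in either ranking break by score
and then lexicographically, making rankings deterministic.

## Known limitations

* The fixed-height-plus-quality-floor cut is a deliberate simplification
  of dynamic hybrid tree cutting; on real data with nested module
  structure it will merge adjacent branches a deep-split cut would
  separate.
* The scale-free criterion can select degenerate powers when the true
  structure is a few equal-size modules covering most genes (connectivity
  is then nearly constant and the log-log regression is uninformative);
  explicit overrides are the remedy, as in the published analyses.
* Preservation Z-scores depend on the composition of the permutation
  universe: a universe with no intact structure at all shrinks the
  contrast between disrupted modules and the null.
* Separation and flow centrality are topology-only: no edge confidences,
  no degree-preserving null for the significance of $S_{AB}$.
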