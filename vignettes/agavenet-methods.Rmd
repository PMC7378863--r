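---
title: "Methods: from abundance tables to interaction networks"
author: "agavenet"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Methods: from abundance tables to interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agavenet)
```

# Scope

`agavenet` re-implements, as one tested pipeline, the computational chain
that turns genus-level amplicon count tables from a paired
rhizosphere/bulk-soil survey into directed, signed microbial interaction
networks, and then asks which structural features of those networks are
distinguishable from random graphs. Because the raw sequencing data of such
surveys are not needed to exercise the chain, the package ships a
generalized Lotka-Volterra (gLV) community simulator whose ground truth
makes every downstream stage testable.

# The community model

Dynamics follow the discrete multiplicative (Ricker) form of the gLV model:

$$x_i(t+1) = x_i(t)\,\exp\!\Big(r_i + \sum_j a_{ij}\, x_j(t) + \varepsilon_i(t)\Big),
\qquad \varepsilon_i(t) \sim \mathcal N(0, \sigma^2).$$

* The Ricker map was chosen over an Euler discretization of the continuous
  gLV because it keeps abundances non-negative for any parameter values and
  is the standard discrete-time stand-in for logistic-type dynamics.
* Process noise enters on the log scale (multiplicative). Abundance
  fluctuations of microbial taxa are heavy-tailed and
  magnitude-proportional; additive noise would let abundances go negative
  and would misrepresent the error structure of compositional data.
* `a_{ii} < 0` always (self-limitation); `a_{ij}` is the per-unit effect of
  taxon *j* on taxon *i*, and the network edge `j -> i` follows the same
  convention.

Default parameter ranges (`sample_glv_parameters()`): growth rates
`r ~ U(0.2, 0.6)` per step, self-limitation `|a_ii| ~ U(0.15, 0.3)` per
unit abundance, so isolated taxa equilibrate near 1--3 abundance units;
interactions have random sign and magnitude
`~ interaction_scale * U(0.5, 1.5)`. The default `interaction_scale` keeps
the community inside the stability regime suggested by the random-matrix
(May) criterion $\sqrt{nC}\,\sigma \lesssim d$: 0.08 for the 10-taxon
recovery experiments and 0.04 for the 40-genus survey generator give the
same stability margin at their respective sizes. Parameter draws that still
diverge are rejected and redrawn — a surveyed community is persistent by
construction, so conditioning the generator on persistence emulates the
observational design rather than biasing it.

# What the synthetic study emulates

`simulate_study()` reproduces a balanced survey: 2 soil compartments
(rhizosphere, bulk) x 2 seasons (dry, rainy) x 4 sites x 3 replicates = 48
libraries. Within each soil compartment one noisy trajectory is simulated,
the dry block preceding the rainy block, and the 12 samples per
season are successive trajectory states two steps apart; a
(season, site, replicate) ordering of the samples is therefore a genuine
time course, mirroring the time-series reading that interaction inference
imposes on survey data. Condition effects relocate a fraction of the
interactions (soil effect, `effect_size`; season effect, 40% of that) and
shift growth rates upward in the rainy season, so the per-condition ground
truths genuinely differ.

Sequencing is modelled as a multinomial draw at a library size uniform in
50,000--150,000 reads — bracketing typical 16S depths around
10^5 — and each genus is observed as 1--3 OTUs with fixed random split
weights. Taxonomic bootstrap confidences are high (0.85--1) for ~90% of
OTUs and low (0.5--0.79) for the rest, so the 80% confidence filter has
work to do.

The generator does **not** emulate: read-level errors, chimeras or PCR
bias; phylogenetic correlation between interaction strengths; true
compositional closure effects beyond the multinomial (no spike-ins);
environmental covariates driving the dynamics. Passing tests therefore
demonstrate that the pipeline recovers what its own model class generates —
they do not certify recovery of interactions from real soil surveys, where
identifiability is far weaker (see Limitations).

# Count-table processing

* **Rarefaction** subsamples every library without replacement to the
  smallest library by default, the depth-bias correction used with classic
  alpha-diversity estimators (hypergeometric draw via `vegan::rrarefy`).
* **Bootstrap filter**: taxa keep their genus assignment when the
  classifier's bootstrap confidence is `>= 0.80`, inclusive. Where a
  source describes the rule both as "greater than" and "greater or equal",
  the inclusive reading was adopted (both thresholds, 0.80 and the 1%
  below).
* **Genus aggregation** sums OTU counts per genus label; unlabelled taxa
  land in an explicit `unclassified` bucket so per-sample totals are
  conserved.
* **Abundance filter**: a genus is kept when its relative abundance reaches
  1% in at least one sample (inclusive; `scope = "mean"` is available
  because the any-sample and mean readings are both defensible). Remaining
  rows are *not* renormalized: the network regression receives proportions
  of the original community, and renormalizing would distort the gLV
  design matrix.
* **Alpha diversity**: observed richness; bias-corrected Chao1
  `S_obs + F1(F1-1)/(2(F2+1))`, which stays defined when doubletons are
  absent — the common situation after rarefaction; Shannon entropy in nats
  (values near 6--7 for soil communities are consistent with the natural
  log); Gini-Simpson `1 - sum p_i^2`.

# Two-way ANOVA from cell summaries

Published condition tables often report only `mean ± SD` per cell. For a
balanced two-factor design with equal cell size *n*, the error mean square
is the pooled within-cell variance (the mean of the cell variances) and all
factor sums of squares are functions of the cell means alone, so the
printed F statistics can be reconstructed exactly up to rounding of the
summaries. `anova2_from_summaries()` implements that reconstruction;
`anova2_raw()` (a front-end to `stats::aov` restricted to balanced complete
designs) is its oracle — the two agree to 1e-9 on exact summaries, which
the test suite verifies on a thousand simulated tables. Only balanced
designs are supported; the survey is balanced (12 observations per cell)
and unbalanced ANOVA would reintroduce the sum-of-squares ambiguities the
summary reconstruction cannot resolve. No transformation is applied by
default; a log flag exists in `compare_guilds()` because some analytes in
such tables are evidently analysed on a transformed scale.

Functional-guild profiles sum the relative abundances of the genera
annotated with each category (a genus may carry several categories), and
`compare_guilds()` runs the balanced ANOVA per category with
Benjamini-Hochberg adjustment across categories — a concrete multiplicity
rule had to be chosen, and BH is the field default.

# Network inference

For an ordered series of proportion vectors the Ricker update linearizes
exactly on log-ratios:

$$y_i(t) = \log x_i(t+1) - \log x_i(t) = r_i + \sum_j a_{ij} x_j(t) + \varepsilon_i(t),$$

one ordinary linear regression per target taxon with the predecessor
abundances as shared predictors. Zeros are replaced by a pseudocount (half
the smallest nonzero proportion by default) before logs. Sparsity comes
from forward selection under BIC — start at the intercept, greedily add the
predictor that most lowers BIC (ties to the lowest column index), stop at
no improvement or `max_parents` — followed by a backward pass dropping
predictors whose removal lowers BIC. The backward pass matters: on exact
(noiseless) data greedy forward steps occasionally admit a correlated
predecessor before the true one, and pruning restores exact recovery. An
exact fit is handled by flooring the residual sum of squares at 1e-300, so
model-size penalties still order the candidates.

**Orderings and consensus.** Survey samples are not a literal time series;
the canonical (season, site, replicate) ordering, dry before rainy, is the
time-series reading. `infer_network()` can refit under `B` random
within-season permutations of that ordering and keep only edges selected
with a consistent sign in at least a fraction `f` of orderings (edge weight
= support fraction, coefficient = median over supporting fits). The default
is `B = 1`, the canonical ordering alone, for a measured reason: with 12-24
samples and ~40 candidate predictors, sparse selection is unstable under
*any* reordering — even permuting replicates within a single site visit
leaves per-ordering edge sets nearly disjoint — so a majority consensus
empties every network at survey scale. Multi-ordering consensus is
therefore exposed as a *selection-stability analysis* (raising `f` can only
shrink the edge set, which the suite tests as a monotonicity property)
rather than as the default estimator.

Self-effects (`a_ii`) are estimated like any other coefficient but reported
separately; the analytics operate on the simple directed graph of
between-taxon edges.

**What the recovery tests show.** With the ground truth in hand the suite
measures sign-recovery F1 (correct-sign edges against the true nonzero
pattern) at 10 taxa, connectance 0.15, 30 transitions split over six
restarted segments — restarts keep the design matrix informative instead of
collapsing onto the equilibrium. Noiseless recovery exceeds F1 = 0.9;
adding log-scale process noise of SD 0.05 lowers it to ~0.6-0.7. At the
full survey scale (24 compositional samples, ~38 genera) the inverse
problem is underdetermined and the inferred networks must be read as sparse
association structures under the gLV reading of the data, not as validated
causal interactions.

# Network analytics

All analytics run on the inferred directed graph; quantities defined for
undirected graphs (clustering, diameter, radius, minimum cuts, independent
sets, communities) use the undirected projection, with antiparallel pairs
collapsed to one edge, and distances/cuts refer to its largest connected
component (inferred networks are frequently disconnected). Conventions
worth stating:

* Density is `m / (n(n-1))`; mean degree is reported as the directed
  `m / n` and as the total-degree mean `2m / n`, because published
  network-measure tables mix the two conventions and only `m / n`
  reconciles a 61-node network of density 0.017 with mean degree 1.017.
* Clustering is the average local coefficient with nodes of degree < 2
  counting zero.
* Cycles are summarized via strongly connected components of size >= 2;
  exhaustive simple-cycle enumeration is exponential and deliberately
  avoided.
* The maximal independent set is greedy (ascending degree, lexicographic
  tie-break): deterministic and maximal, not maximum.
* Communities come from an agglomerative greedy modularity search
  (Clauset-Newman-Moore style) written in the package so that ties merge
  the lexicographically smallest pair — fully deterministic; the reported
  modularity always equals the direct Newman formula on the returned
  partition, and the suite cross-checks it against `igraph::modularity`.
* Hubs are the argmax sets of total, in- and out-degree, ties included —
  the degree-based keystone-candidate definition; no betweenness or
  eigenvector ranking is attempted.
* The total-degree distribution is fitted as a discrete power law with
  `xmin = 1` by maximum likelihood (zeta normalization via `pracma::zeta`),
  with the Kolmogorov-Smirnov distance over the observed support as the
  fit diagnostic; all-equal degree vectors are flagged degenerate.

The 3-node motif census counts the 13 connected directed triad classes
(`igraph::triad_census` order) and compares them to degree-preserving
edge-switch randomizations (10 switches per edge per replicate, 100
replicates by default); z-scores with zero null spread are reported as
missing rather than inflated.

# Random-network null model

Structural features are judged against an ensemble of (by default) one
hundred directed Erdős–Rényi G(n, m) graphs matched on order and size — the
minimal null for "is this feature surprising given how many nodes and
edges there are?". For every scalar property the summary reports the
ensemble mean and SD and an add-one empirical p-value, two-sided via
`p = min(1, 2 min(p_low, p_high))` with
`p_low = (1 + #{null <= obs})/(N + 1)`: the add-one form cannot return
zero at finite N, and the doubling flags deficits (e.g. fewer modules than
random) and excesses symmetrically. Matched properties (order, size,
density) are non-significant by construction, which doubles as a self-test.
Calibration is verified empirically: when the "observed" network is itself
drawn from the null, each property's flag fires at a rate no higher than
alpha plus three Monte-Carlo standard errors (500 repetitions at order 24,
size 48, N = 60 per repetition — sizes chosen to keep the check thorough
but cheap).

# Pipeline and reproducibility

`run_pipeline()` chains simulate (or read) -> rarefy -> alpha diversity ->
bootstrap filter -> genus aggregation -> 1% filter -> guild ANOVA -> eight
condition networks (both soils/rhizosphere/bulk x dry/rainy/pooled seasons,
bulk not pooled — the eight-column scheme of the motivating survey) ->
property report, hub table and null summary per network, and writes every
artifact as TSV/GraphML/JSON under the output directory. All randomness
descends from one master seed through independent substreams; a rerun with
the same configuration is byte-identical, and the consolidated report
records the configuration's MD5 hash.

Problem sizes used by the test suite (chosen to keep the default run in
minutes on one CPU): recovery experiments at 10 taxa; oracle comparisons on
all 64 three-node digraphs plus seeded random samples of 4- and 5-node
digraphs; ANOVA equivalence on 1,000 simulated tables; null calibration as
above; motif calibration on 50 random graphs. The exhaustive 5-node graph
space (2^20 graphs) is sampled, not enumerated.

# Limitations

* Interaction recovery from real cross-sectional surveys is close to
  unidentifiable; everything downstream of inference (hubs, modules, motif
  z-scores) inherits that uncertainty. The package quantifies what *is*
  checkable — recovery on its own model class, internal consistency, and
  null-model calibration.
* Proportions are used directly; no compositionality correction
  (SparCC/SPIEC-EASI-style) is implemented. The log-ratio response removes
  the common scale only when totals change slowly.
* Only balanced 2x2 designs are supported in the ANOVA layer.
* The G(n, m) null matches order and size but not the degree sequence;
  degree-matched nulls are used only in the motif census.
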