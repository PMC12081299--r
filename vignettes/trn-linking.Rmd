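---
title: "Metacell enhancer-promoter linking and state-specific regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metacell enhancer-promoter linking and state-specific regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnlink)
```

# The problem

Tumors such as neuroblastoma contain neoplastic cells in distinct
transcriptional states (adrenergic, mesenchymal, intermediate), and therapy
shifts their proportions. Understanding which transcription factors (TFs)
maintain each state requires connecting three measurements that no single
assay provides: which distal chromatin regions behave as enhancers of which
genes, which TF motifs occupy those enhancers, and which genes and motifs
characterize each state. `trnlink` implements that chain for paired
single-nucleus RNA and ATAC data: metacell aggregation, per-gene
enhancer-promoter (E-P) regression, chromVAR-style motif deviations,
one-vs-rest differential testing, and rule-based network assembly — plus the
supporting cohort, signature and spatial statistics such a study reports.

# The model, stage by stage

## Metacells

Single-nucleus counts are too sparse for per-cell regression. Within each
sample, every cell (in input order) seeds a candidate metacell: its `k = 25`
nearest neighbours in the supplied co-embedding, Euclidean distance, the seed
counting among its own neighbours, distance ties broken by cell index. A
candidate is accepted greedily when it shares at most `max_shared = 3`
members with every previously accepted metacell; groups with fewer than
`min_cells = 100` cells yield no metacells. Accepted metacells are retained
when they contain between 5 and 15 RNA cells — with a roughly balanced
RNA/ATAC co-embedding this keeps metacells that genuinely mix both
modalities. Metacell profiles are arithmetic means of the members'
log-normalized values, RNA cells contributing expression and ATAC cells
accessibility.

Two details are deliberate determinism choices, since the aggregation rule we
follow does not print its iteration order: seeds are visited in input cell
order, and ties are index-broken. Given the same embedding the map is
reproducible to the byte.

## Enhancer-promoter regression

For gene $g$ with TSS $t_g$, candidate peaks are those whose midpoint lies
within $\pm 500$ kb of $t_g$ on the same chromosome (boundary inclusive,
strand-agnostic; the promoter is treated as the TSS point). Candidates
non-zero in fewer than `min_peak_frac = 0.05` of metacells are dropped —
regressing on a peak observed in a handful of metacells is meaningless and
the degenerate case is otherwise undefined. The model is ordinary least
squares with intercept,

$$ y_g = \beta_0 + \sum_p \beta_p x_p + \varepsilon, $$

with $y_g$ and each $x_p$ z-scored by default so that the significance
threshold on $\beta_p$ is scale-free. Per-coefficient two-sided $t$-tests use
$n - p - 1$ degrees of freedom. Genes with more surviving candidates than
metacells minus two are skipped with a warning rather than regularized: the
contract is plain linear regression, and a silent ridge fallback would change
the meaning of the coefficient threshold. A link is significant when
$\beta_p > 0.2$ (strict) and its Benjamini-Hochberg adjusted p-value is
below 0.01 (strict).

Two genuinely open choices, and what we chose:

* **Scaling of the 0.2 cutoff.** The source recipe applies 0.2 to
  normalized data without stating the scaling of predictors or response. We
  z-score both by default (`standardize = TRUE`), making the cutoff a
  partial-correlation-like quantity that is comparable across genes and
  sequencing depths. The flag restores raw-scale fits.
* **BH family.** Pooling all gene-peak p-values into one family (default) is
  more conservative and reproducible than per-gene adjustment, and matches
  how a single links track is thresholded; `bh_scope = "per_gene"` is
  available.

## Motif deviations

For motif $m$ and cell $i$, with $o_{mi}$ the summed counts in motif peaks
and $e_{mi}$ = (cell total) × (motif peaks' share of the grand total), the
raw deviation is $d_{mi} = o_{mi}/e_{mi} - 1$. The z-score standardizes
$d_{mi}$ against `n_background = 50` random peak sets matched to the motif's
peaks by mean-accessibility bin (20 equal-frequency bins). Differences from
the reference deviation method are deliberate and documented: backgrounds are
matched on accessibility only (the synthetic peaks carry no sequence, so
GC-matching is undefined here), and a zero-variance background maps the
z-score to 0 with a warning. Because the expectation's peak shares are
weighted by observed totals, deviations are exactly invariant to a common
rescaling of all counts, and a cell whose composition equals the pooled
profile deviates by zero; rescaling one cell alone perturbs the shared
expectation by that cell's weight, as in the reference method. Per-state
motif activity is the mean z inside the state minus the mean outside;
differential activity is a two-sided rank-sum test on per-cell z, BH-adjusted
within state.

## Differential expression and accessibility

`de_genes()` re-expresses the marker-finding recipe as a one-vs-rest
two-sided Wilcoxon rank-sum test on normalized values with the stated
filters: both groups subsampled to at most 500 cells (seeded), genes tested
only when expressed in at least 5% of either group and when the detection
fractions differ by at least 0.05; log fold-change is the difference of group
means on the natural-log normalized scale; BH per state. This is a documented
non-equivalence with the original toolkit's default test; the filters are
reproduced literally.

One consequence worth stating plainly: the detection-difference filter
selects genes on a statistic correlated with the rank-sum statistic, so
among *tested* genes the null p-values are anticonservative (about 0.09 at
the 0.05 level in our null experiments, and the inflation propagates through
BH). This is a property of the published filter-then-test recipe itself, not
of the implementation; the package's calibration checks therefore assess the
machinery with the selection filter disabled, and the filters are verified
separately as deterministic rules.

`da_peaks_pseudobulk()` sums counts to sample-by-state pseudo-bulks and
tests state versus rest with edgeR's TMM normalization and quasi-likelihood
negative-binomial framework, requiring at least two replicates per side.
The source analysis itself used edgeR on pseudo-bulk, so delegation is the
faithful choice; exact replication of its dispersion estimates on real data
is not claimed. "Accessible" always means a non-zero count, and the
sparse-state rule passes peaks accessible in strictly more than 20% of the
state's cells.

## Network assembly

For each state the rules are applied in order: (1) significant links are
kept when the enhancer peak is differentially accessible for the state
(q < 0.05), or, in `sparse_state_mode` (intended for states with too few
differential peaks), when the peak is accessible in > 20% of the state's
cells; (2) a TF is included when it is differentially expressed or
differentially motif-active (q < 0.05) for the state and is expressed in at
least 20% of the state's cells (inclusive); (3) targets are restricted to
the state's differentially expressed genes; (4) an edge (TF, target, peak)
requires the TF's motif at the link's enhancer. Edge weight is the
regression coefficient times the enhancer's accessible fraction in the
state.

The key interpretive choice is **direction**: all three differential gates
are applied on the state-positive side (target log fold-change > 0, enhancer
more accessible in the state, motif activity difference > 0). The recipe's
wording ("differentially expressed", "differentially accessible") does not
state a direction, but an undirected reading would place every
state-characteristic gene in every *other* state's network as well — a gene
up in state A is "differential" for B — which contradicts the purpose of a
per-state network built from positive-coefficient (activating) links. The
q < 0.05 cutoffs for the three gates are our choice; the recipe states the
criteria but not the levels.

`validate_trn()` checks the structural invariants of every network: edge
endpoints exist as nodes, every edge's (target, peak) is a significant link,
the motif is present at the edge peak, and weights are exact products.

## Signatures and stratification

`module_score()` scores cells as the mean normalized expression of the
signature genes minus the mean over a control pool: non-signature genes are
binned by average expression into 24 equal-frequency bins, and each
signature gene draws 100 controls (with replacement, seeded) from the bin
nearest its own average. Excluding signature genes from the control
candidates is our choice — with them included, a coherently elevated
signature would partly cancel itself. The score is invariant to adding a
constant to every gene. Stratification rules are literal: median
dichotomization sends values strictly above the median to "high" (ties at
the median are "low"); maximum-score state assignment breaks exact ties by
column order with a warning; `survival_inputs()` emits the design table
(exposure plus MYCN status, sex, age, with a configurable baseline state as
the reference level) for a delegated Cox fit in the survival package — the
fit is intentionally not re-derived here.

## Spatial statistics

The "window" of the windowed marker density is a closed Euclidean disc of
radius 40 µm centred on the index cell; the index cell's own marker value is
excluded, and index cells with no neighbours are omitted (scoring them 0
would bias density comparisons) and counted in an attribute.
`nearest_distance()` is the plain nearest-neighbour distance per sample.
CLR normalization is per cell across features with pseudocount 1 on raw
intensities, so each cell's transformed markers sum to zero. The
ligand-receptor colocalization score — the fraction of receptor-positive
cells with a ligand-positive cell within the radius, against a null that
permutes ligand flags with positions fixed — is a documented provisional
definition: the source study's exact statistic is described only in
supplementary material that the recipe does not print. All implementations
are direct all-pairs computations, exact by construction at the table sizes
of this workflow (a few thousand cells per sample).

## Cohort statistics

`paired_signed_rank()` tests PTX minus DX differences, dropping zero
differences (the standard convention; the recipe is silent), with the exact
distribution for up to 12 tie-free differences and the tie/continuity
corrected normal approximation otherwise. The direction of a one-sided test
is a required explicit argument — panel captions state "one-sided" without
the direction, so no default is safe. `proportion_test()` is the
continuity-corrected two-sample proportion test; `shift_table()` applies the
signed-rank test per cell type and BH-adjusts across types.

# The synthetic generator

`generate_multiome()` plants a known architecture so every downstream stage
has an oracle: one synthetic chromosome with evenly spaced TSSs; a block of
candidate peaks in each gene's ±500 kb window; per gene one designated
"high" state and two true enhancers open with probability 0.65 in that state
and 0.08 elsewhere; peak accessibility following a logistic model with a
per-state baseline (logit ~ N(-1, 1) for non-enhancer peaks) plus a smooth
gradient (scale 1.75) along the embedding jitter, so embedding neighbours
have similar accessibility; ATAC counts Bernoulli(π) × (1 + Poisson(0.5));
RNA counts negative binomial (dispersion 0.3) with log-mean equal to a gene
baseline (median 2 counts — the sparse single-nucleus regime, and the regime
in which detection-fraction DE filters can see level shifts) plus
`link_effect` times the *z-scored* accessibility probability of each true
enhancer. Defining the planted effect on the standardized scale makes
`link_effect` the standardized effect the regression estimates, so the fixed
0.2 threshold is meaningful; with `link_effect = 0.5` the recovered
coefficients centre near 0.5. Motif hits are Bernoulli background
(density 0.05) on non-enhancer peaks, while each planted enhancer carries
exactly its designated regulator's motif — a random extra motif at a true
enhancer would be indistinguishable from the planted regulator, and the
generator's contract is that the planted truth is realizable. Each TF is
itself one of the genes, peaking in its assigned state; a random 10% of
genes get a +0.5 log-fold PTX shift for the timepoint-direction utilities.

What the generator deliberately does **not** emulate: doublets and ambient
RNA, batch effects beyond patient labels, read-level noise, sequence content
(hence no GC-matched motif backgrounds), multi-chromosome structure, and
integration artefacts — the embedding is generated directly from state
centroids because dimension reduction is outside the package's scope.
Passing recovery tests on these simulations therefore demonstrates that the
statistical machinery is implemented correctly and is well calibrated, not
that the pipeline is robust to the technical artefacts of real data.

`generate_spatial()` produces a homogeneous Poisson background of typed
cells on a 1 mm square with optional planted pairs (partner cells placed
uniformly within 20 µm of index cells, marker elevated additively on
neighbours of index cells); `generate_paired_cohort()` produces per-patient
DX/PTX Dirichlet compositions (22 patients by default) with a +0.1
proportion shift planted on one cell type.

# Numerical choices and problem sizes

All generators and stochastic stages are pure functions of their integer
seeds (`withr::with_seed`), and the pipeline manifest hashes the full
configuration, so reruns are byte-identical. The test suite exercises the
full-size recovery experiment at the study conditions the generator defaults
encode — 200 genes, 2,000 peaks, three states, four patients, two modalities
of 3,000 cells, ~200-300 retained metacells — and the calibration
experiments at 200 null replicates each; oracle comparisons (normal
equations, step-up enumeration, sign-flip enumeration, brute-force geometry)
run at sizes where the naive algorithms are exact and fast (50 metacells,
up to 10 predictors; 2,000-cell spatial tables; n ≤ 10 sign enumerations).
These sizes are the package's reference experiment; scaling them up changes
runtimes, not conclusions.

Degenerate inputs have defined behaviour throughout: zero-total cells, all-zero
Gini vectors, all-zero motif hit columns, empty flag sets and single-state
labelings are errors that name the offender; zero-variance predictors are
dropped with a reason; constant slices in 0-1 rescaling and zero-variance
deviation backgrounds map to zero with a warning.

# Known limitations

* The E-P model is linear and activating-only on the significant side
  (β > 0.2); repressive regulation is invisible by construction.
* Metacell greedy acceptance depends on seed order; the original
  aggregation tool's internal order is unprinted, so cross-tool metacell
  identity is not expected (the rules it prints — k, overlap cap, size
  retention — are enforced exactly).
* edgeR replaces a from-scratch negative-binomial test; calibration is
  verified, exact dispersion equality with any other pipeline is not claimed.
* The ligand-receptor colocalization statistic is provisional, as described
  above.
* Survival modelling is delegated: this package prepares inputs and applies
  the stated stratification rules only.
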