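---
title: "Community flux balance modeling of gut microbiota capabilities"
author: "gutflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community flux balance modeling of gut microbiota capabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutflux)
```

## The modeling question

16S amplicon surveys tell us *who* is in a gut community but say little
about what the community can *do*. Constraint-based community modeling
bridges that gap: each taxon is represented by a genome-scale metabolic
network, the networks are stitched together around a shared gut lumen
with dietary inflow and fecal outflow, relative 16S abundances weight
each taxon's contribution, and linear programming asks what the whole
consortium could maximally produce. The per-sample answer — the **net
maximal production capability (NMPC)** of each exchanged metabolite, in
mmol/day — is a functional fingerprint that can be clustered and screened
for association with host phenotype (here, gouty arthritis versus
healthy).

`gutflux` implements this pipeline end to end: pan-taxon model merging,
community LP assembly, flux variability analysis (FVA), NMPC matrices,
per-taxon exchange attribution and crossfeeding detection, and the
statistical layer (k-means++ clustering, silhouette model selection,
Fisher's exact association, Wilcoxon rank-sum screening with
Benjamini–Hochberg FDR, and the proportionality coefficient for
compositional correlation). Because the curated genome-scale
reconstructions that such studies rely on are a large external database,
the package ships a first-class synthetic-community generator whose toy
taxa are small, hand-auditable, mass-balanced networks; every stage of
the pipeline is exercised and tested on those.

## The community model

For one sample, let $i = 1, \dots, T$ index the modeled taxa with
normalized abundances $a_i$ ($\sum_i a_i = 1$; taxa at zero abundance are
omitted). The LP has one flux variable per reaction:

* **taxon-internal reactions** from the taxon's (pan-)model, carried in a
  private compartment per taxon;
* **IEX reactions** `met[taxon] <-> met[u]` connecting each taxon to the
  shared lumen `[u]`; flux $> 0$ is secretion, $< 0$ uptake, and uptake
  is only open for the taxon's uptake preferences;
* **diet transports** `met[d] -> met[u]` and boundary exchanges
  `EX_met_d` (written `met -> \emptyset`, bounded in $[-d_{\text{met}},
  0]$ where $d_{\text{met}}$ is the diet's maximum uptake rate in
  mmol/day);
* **fecal transports** `met[u] -> met[fe]` and outflow exchanges
  `EX_met_fe` in $[0, 10^4]$;
* a per-taxon biomass reaction producing a biomass pseudo-metabolite
  from precursors (e.g. 0.1 glucose per unit), and one **community
  biomass reaction** consuming $a_i$ units of each taxon's biomass
  metabolite, constrained to the window $[0.4, 1.0]$ mmol/day.

Steady state $S v = 0$ holds over all compartments. **Coupling
constraints** $|v_j| \le 400 \, v_{\text{biomass},i}$ tie every internal
and IEX flux of taxon $i$ to that taxon's biomass flux, which by
construction equals $a_i b$ with $b$ the community biomass flux. They
serve two purposes: a taxon at zero abundance can carry no flux, and a
taxon's catalytic capacity scales with its abundance — which is exactly
the mechanism that makes the capability fingerprint reflect community
composition. The factor 400 and the window 0.4–1.0 mmol/day are the
conventional values for this pipeline family; both are arguments of
`build_community_model()`.

### NMPC

For a metabolite $m$, two LPs are solved under the biomass window:
maximal fecal secretion $v^{fe,\max}_m \ge 0$ and maximal dietary uptake
$v^{d,\min}_m \le 0$ (minimal signed flux of the diet exchange). Then

$$\mathrm{NMPC}_m = \left| v^{fe,\max}_m + v^{d,\min}_m \right|.$$

A metabolite that can only pass through unchanged cancels exactly to
zero; positive values measure net community production beyond what the
diet supplies. Each NMPC is computed independently; simultaneous
maximal production of several metabolites is *not* implied. The two
complementary LPs (minimal secretion, maximal diet inflow) are available
behind `compute_nmpc(..., full = TRUE)`.

## The linear-programming engine

No LP solver is available as an R dependency in this package's dependency
footprint, and the LP is the pipeline's innermost loop, so `gutflux`
carries its own: a dense bounded-variable two-phase primal simplex in
C++ (`src/simplex.cpp`). Design points that matter for correctness and
speed:

* variable bounds are handled implicitly (no bound rows), with
  bound-flip pivots;
* a singleton-column crash basis keeps most coupling rows out of
  phase 1;
* the tableau is periodically **refactorized by LU decomposition against
  the original constraint data** — dense tableaus drift over long
  degenerate pivot sequences, and an accepted optimum must satisfy the
  original system to $10^{-8}$ (verified inside the solver; violations
  trigger refactorization or a warm restart that keeps the nonbasic
  pattern);
* an instance persists across objectives (`lp_instance()` /
  `lp_optimize()`), so the 2·(number of metabolites) FVA solves per
  sample all warm-start from the previous optimal basis, and
  `lp_set_bound()` supports the FVA idioms "relax the biomass floor,
  prove feasibility, re-impose the window" and "pin the objective at its
  optimum" without losing the basis.

The solver is validated in the test suite against exhaustive
vertex-enumeration oracles on small LPs and against an independent
simplex implementation. LP tolerances: feasibility/optimality $10^{-9}$;
NMPC values below $10^{-6}$ are snapped to zero so the "cannot produce"
class is exact for the differential screen.

## Resolving taxa at a production optimum

FVA optima are typically degenerate: many flux patterns achieve the same
maximal production. `maximize_and_attribute()` therefore fixes the
objective at its optimum and minimizes the total absolute flux
(a parsimonious secondary objective) before reading per-taxon secretion
and uptake off the IEX reactions. This is a documented selection rule —
the alternative (reporting an arbitrary optimal vertex) would make
taxa-level attributions solver-dependent and irreproducible. Crossfeeding
edges are then pairs (donor secretes $\ge \tau$, a *different* receiver
takes up $\ge \tau$) with $\tau = 5$ mmol/day by default, focusing on the
largest contributors.

Lumen steady state guarantees, and the tests assert, that for every
metabolite: taxa secretion + diet inflow = taxa uptake + fecal outflow.

## The synthetic community

The generator (`default_taxon_specs()`, `gen_taxon_model()`,
`gen_abundance_table()`, `gen_diet()`) emulates the *structure* of the
study system, not its scale:

* **~25 metabolites** with integer elemental formulas (hexose, a
  10-hexose fiber polymer, SCFAs, D/L-lactate and -alanine, sulfur amino
  acids, BCAAs and their acids, H2, H2S, CO2, NH3, sulfate, water).
  Every internal reaction template is elementally balanced and the
  balance is tested; exchange and biomass reactions are the only
  exceptions.
* **Ten genus/family-level taxa**: a *Bacteroides*-like generalist
  (fiber degradation, acetogenesis, succinate/lactate/formate
  fermentation, cysteine desulfhydration to H2S, alanine and serine
  synthesis), butyrate producers (*Faecalibacterium*-, *Roseburia*-,
  *Coprococcus*-, *Subdoligranulum*-like and a *Lachnospiraceae* family
  bin), a *Prevotella*-like fiber fermenter, *Escherichia*/*Shigella*
  mixed-acid enterics (also BCAA fermenters), and a *Desulfovibrio*-like
  sulfate reducer. The *Faecalibacterium*-like taxon synthesizes
  butyrate **only** through an acetate-consuming route
  (hexose + 2 acetate → 2 butyrate + 2 CO2 + 2 H2O), making acetate
  crossfeeding a designed, strictly testable enhancement.
* **Three community archetypes** mirroring the study's capability
  clusters: *Bacteroides*-dominated (mean fraction 0.75; gout
  probability 22/26), *Faecalibacterium*-elevated (0.15; 11/44) and
  *Prevotella*-elevated (0.45; 6/8), sampled 26/44/8 by default through
  a Dirichlet-multinomial read model.
* **Diet presets**: an EU-average structure (EUD), a high-protein
  variant (amino-acid bounds ×2.5) and a high-fiber variant (fiber ×3,
  L-cysteine ×1.84 — the published relative difference). The absolute
  bounds are package choices: they were set once so that
  substrate-allowed pathway fluxes exceed the $400 a_i$ coupling caps of
  minor pathway carriers, because that is the regime in which community
  composition shapes capability (the phenomenon the pipeline exists to
  measure). With the defaults, the three archetypes separate cleanly:
  alanine, H2, formate and BCAA fermentation acids track *Bacteroides*
  and the enterics (high-gout profile), while butyrate, L-lactate,
  L-cysteine, L-methionine and H2S track the butyrate producers and
  sulfate reducers (low-gout profile).
* The **Dirichlet concentration** defaults to 150. Capability is close
  to piecewise-linear in abundances through the coupling caps, so
  compositional scatter propagates almost linearly into NMPC scatter;
  150 keeps within-archetype scatter below between-archetype separation,
  emulating the robust clustering reported for the real cohort. It is a
  parameter, not a constant.
* The per-sample **modeled fraction** (share of reads covered by modeled
  taxa) is drawn uniformly from [0.94, 1], giving the study's ~97% mean
  coverage; samples below 0.90 are dropped by `prepare_abundances()`
  (inclusive at the threshold), which also splits combined
  `Escherichia/Shigella` read columns equally and absorbs unmodelable
  genera into configurable family bins.

What the generator does **not** emulate: genome-scale network size
(thousands of reactions; here tens), strain-level metabolic variation
beyond random reaction deletions (`gen_strain_variants()`), transport
thermodynamics and pH effects, and the hundreds of exchanged metabolites
of curated reconstructions. Passing tests therefore demonstrate the
pipeline's correctness and the qualitative phenomenology (composition →
capability → phenotype association; crossfeeding enhancement), not
quantitative agreement with any real cohort.

`gen_nmpc_matrix()` complements the LP route with a direct capability
matrix: archetype-specific mean NMPCs with multiplicative log-normal
noise ($\sigma = 0.2$) and ten metabolites planted as differential
between the high- and low-gout archetypes at effect sizes that pass the
screen's filters, plus nulls, a below-floor metabolite and all-zero
columns. Because its ground truth is exact, it is the test-bed for the
screen's sensitivity and false-discovery behavior across many seeds,
independent of LP compute cost.

## The statistical layer

* **Clustering**: `kmeans_cluster()` runs Lloyd iterations (squared
  Euclidean distance, via `stats::kmeans`) from k-means++ seedings, best
  of 1000 replicates by total within-cluster sum of squares; cluster ids
  are relabeled by descending size so labels are reproducible.
  `select_k()` scores candidate k by mean silhouette width under the L1
  (sum of absolute differences) distance, 100 replicates, ties to the
  smallest k.
* **Association**: `fisher_exact_2x2()` (two-sided exact test). The
  printed "cluster versus the entire sample set" comparisons are
  reproduced by the superset construction (the cluster's own samples
  included in the reference margin); the complement variant is also
  available (`cluster_phenotype_association(..., reference =
  "complement")`) but does not match the printed values.
* **Differential production**: per metabolite, a two-sided rank-sum test
  between the high- and low-gout clusters (exact enumeration for small
  tie-free samples, normal approximation with tie and continuity
  corrections otherwise), BH-FDR over all tested metabolites, and two
  magnitude filters: mean NMPC > 10 mmol/day in at least one cluster and
  relative mean difference ≥ 10%. The relative difference uses the
  *larger* mean as denominator — the source convention names no
  denominator, so this conservative choice is explicit and configurable.
  All-zero metabolites are reported untested rather than tested-at-p=1,
  keeping the BH family honest.
* **High/low gout clusters**: among clusters with ≥ 10 samples, highest
  and lowest gouty fraction; the small third cluster is excluded from the
  screen, matching the study design.
* **Compositional correlation**: the proportionality coefficient
  $\rho_p = 2\,\mathrm{cov}(\log x, \log y) / (\mathrm{var}\log x +
  \mathrm{var}\log y)$, with zeros replaced by half the smallest nonzero
  value (documented pseudocount rule).
* **Diet comparison**: cluster-membership concordance between diets is
  the Rand index over sample pairs, and matched high-gout (or low-gout)
  clusters of two diets are screened per metabolite by rank-sum + BH.

## Numerical and design notes

* **Degenerate inputs**: zero-margin contingency tables return p = 1
  with a `degenerate` flag; identical constant samples give rank-sum
  p = 1; all-identical capability matrices are rejected by `select_k()`;
  infeasible community models fail at build time with a diagnostic that
  reports which relaxation (biomass floor, diet bounds) restores
  feasibility.
* **Futile cycles**: merging strain models can create thermodynamically
  impossible loops. `build_pan_model()` closes all exchanges, finds
  internal reactions that can still carry flux, and makes reversible
  loop members irreversible one at a time (preferring a direction some
  strain's default bounds carried) until closed-exchange FVA is silent.
  Every bound change is logged in the model's provenance attribute. The
  original pipeline's exact rule is not published beyond "making certain
  reactions irreversible"; this is a documented stand-in.
* **Diet scaling**: because the biomass window forces a constant
  substrate overhead, maximal secretion is slightly *superlinear* in a
  uniform diet scaling (by $2 \times 0.1\, b_{lo} (\lambda - 1)$ on the
  worked toy); exact positive homogeneity holds once the window is
  relaxed to zero, and the tests assert exactly that plus monotone
  growth under the standard window.
* **"Uptake from the lumen"** in the NMPC definition is bound to the
  diet boundary exchange `EX_met_d` (not an internal lumen transport);
  the alternative reading would double-count taxon uptake already
  constrained through the IEX reactions.
* **Biomass units**: the community biomass flux window 0.4–1.0 is
  carried in mmol/day like every other flux; it is best read as a
  dimensionless LP constraint anchoring production to a fixed growth
  demand.

## Problem sizes

The default synthetic study uses 78 samples (26/44/8), ten taxa,
~25 metabolites and community LPs of roughly 260 reactions, 190
metabolite balances and 300 coupling rows; a full pipeline run
(78 models, ~45 FVA solves each, clustering with 1000 k-means++
replicates, the differential screen) completes in about two minutes on
one core, and the planted-effect recovery study spans 20 generator
seeds. These sizes were chosen to keep a complete, reproducible analysis
interactive while leaving every mechanism of the full-scale pipeline in
place.

## Limitations

NMPCs are capability bounds, not predicted rates: they assume the
community can steer all flux toward one product at a time. Coupling with
a single factor for all reactions is a coarse proxy for enzyme capacity.
The synthetic taxa are metabolic cartoons; conclusions about real gout
cohorts require the curated reconstructions and the original abundance
data, which this package deliberately does not bundle. Within those
limits, every computational claim in this vignette is recomputed by the
test suite or by `scripts/acceptance.R`.
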