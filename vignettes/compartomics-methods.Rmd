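---
title: "Methods: enrichment, reporter metabolites, flux estimation and metabolic regulation analysis"
author: "compartomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enrichment, reporter metabolites, flux estimation and metabolic regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartomics)
```

This vignette is the package's own account of the statistics and models it
implements, the assumptions behind them, the tunable parameters, and the
numerical and design choices that were genuinely open. The running example
is a yeast culture profiled by RNA-seq on two carbon sources — condition A
a fermentable sugar (glucose), condition B a pentose (xylose) — but nothing
in the machinery is organism-specific.

## Bootstrap-calibrated gene-set enrichment

The input is one q-value per gene (a multiple-testing-corrected p-value
from a differential-expression caller). Each q-value is mapped to a
standard-normal deviate

$$ z_g = -\Phi^{-1}(q_g), $$

so that $q = 0.5$ gives $z = 0$ and smaller q-values give larger positive
deviates regardless of the direction of regulation (direction is carried
separately as the counts of significant up- and down-regulated members,
which also drive the colour/brightness attributes emitted for rendering).
Under a true null with uniformly distributed q-values, $z$ is exactly
standard normal; this is the property every calibration below rests on.

A gene set with members $G$ is scored by its total deviate, centred and
scaled by the moments of random sets of the same size $k = |G|$:

$$ S = \frac{\sum_{g \in G} z_g - \mu_k}{\sigma_k}, $$

where $\mu_k$ and $\sigma_k$ are estimated from `nBoot` (default 1000)
random size-$k$ subsets of a stated gene universe. Sampling is **without
replacement**: a gene set cannot contain a gene twice, and the exhaustive
enumeration oracle used in the tests fixes this convention. Sets with
$S \ge 1.64$ (the deviate of $p = 0.05$) are flagged; there is no
generally agreed multiple-testing correction across sets at this step, and
none is applied.

Parameters and defaults:

* `nBoot = 1000` random sets per size — the background standard error of
  $\mu_k$ is $\sigma_k/\sqrt{1000}$, small against the effects of interest;
* `cutoff = 1.64` (dimensionless score);
* q-values are clamped to $[10^{-12}, 1-10^{-12}]$ before inversion, since
  callers floor q at small values and an exact 0 or 1 would map to an
  infinite deviate;
* the universe for ontology/pathway enrichment defaults to *all genes with
  a q-value*; reporter metabolites use the enzyme universe (below).

Backgrounds are computed at every distinct observed set size (no
interpolation) — collections number at most a few thousand sets, and each
size costs $O(k \cdot nBoot)$ draws. Per-size RNG streams are derived from
the run seed and the size, so results do not depend on the order in which
sets are evaluated.

Gene sets for ontology terms are the **descendant closure**: a term
collects the genes annotated to it and to every more specific term
reachable against the `is_a` child-to-parent direction. This is what makes
specific annotations count towards the broad terms of a slim ontology;
parent sets therefore always contain child sets, a property the tests
assert.

## Reporter metabolites

A metabolite's gene set is the union of the gene associations of all
reactions that consume or produce it (a set, not a multiset — genes shared
by several of the metabolite's reactions count once). The score is the same
$S$ statistic, but the background samples **enzyme-encoding genes only**
(genes mapped to at least one reaction). Metabolic genes are collectively
more differentially regulated than the genome at large, so an all-genes
background would hand every metabolite a free score boost; the tests check
directly that the enzyme-only background deflates scores when enzymes "run
hot".

Currency metabolites (ATP, NAD(H), protons, water) are **not** excluded by
default — redox cofactors are often exactly the interesting reporters in a
carbon-source shift — but an opt-in exclusion list is supported.
Compartment-tagged metabolite instances are scored separately by default,
with `mergeCompartments = TRUE` pooling neighbourhoods by base compound.
Thresholds: 1.64 for "enriched", 3.0 for the focused reporter–enzyme
network, q < 0.05 for the enzyme partners.

## Network projections

*Pathway overlap.* Edge weight between two pathways is
$|M_a \cap M_b| / \min(|M_a|, |M_b|)$ over their metabolite sets, computed
after stripping compartment tags (reference pathway databases are
compartment-naive; without stripping, cytosolic and mitochondrial instances
of one compound never match). Default inclusion threshold 0.3 — the choice
is presentational, not inferential, and is exposed as a parameter. Pathways
with no retained edge attach to a `Self` sink so they stay visible.

*Molecular similarity.* Molecules are compared by plain Levenshtein edit
distance on their SMILES strings, normalised by the longer string:
$1 - d/\max(|s_1|, |s_2|)$. The comparison is deliberately string-level (no
canonicalisation, no fingerprints); it is a cheap structural grouping, not
chemistry. Each molecule links only to its single closest match when that
similarity reaches 0.4, else to `Self`. Ties break lexicographically by
partner id, and reciprocal closest pairs collapse to one undirected edge —
the tie rule is a convention of this package, chosen for determinism.

## Reaction-level expression summaries and compartment views

For pathway maps each reaction is summarised over all genes mapped to it
(isozymes from paralogs or multifunctional proteins): transcript abundances
are **summed** per condition, which makes the summary robust to annotation
errors in minor paralogs — a lowly expressed isozyme cannot dominate the
reaction's fold change. The representative fold change for colouring is the
member gene's log2 fold change of largest magnitude, sign preserved (a map
colour should reflect the strongest change, including a downturn). A
reaction's expression change counts as significant when **at least one**
member gene is significant. Classes:

* `up` / `down`: significant genes all on one side;
* `isozyme_switching`: significant genes on both sides — the pattern where
  a condition shift swaps which isozyme carries a function, often across
  compartments;
* `constitutive`: members present, none significant;
* `no_gene`: no member gene in the table.

A reaction with one significant gene among constitutive paralogs takes the
significant gene's direction; switching requires both directions.

Compartment views re-run the same summary restricted to the genes assigned
to one compartment via GO cellular_component annotations. A gene annotated
to several compartments appears in every one of them (including the
membrane term, which is folded into the plasma-membrane label); a gene with
no cellular_component annotation is `unknown`, and terms outside the
shipped map collapse to `other`. This is how an apparently
isozyme-switching reaction resolves into a clean `up` in the cytosol and
`down` in the mitochondrion.

## Flux balance analysis

Condition fluxes solve

$$ \max_v \; v_{\text{biomass}} \quad \text{s.t.} \quad S v = 0,\;
   v_j \ge 0 \text{ for irreversible } j,\;
   v_e = r_e \text{ for measured exchanges } e, $$

with measured uptake and secretion rates as **equality** constraints
(uptake negative under the boundary convention; a `soft` mode relaxes them
to ±5% bands for jointly infeasible measurement sets). After the optimum is
found, a parsimonious second stage minimises total absolute flux at the
fixed optimum, so reported fluxes are reproducible in the presence of
alternate optima — the underlying study question (which fluxes changed)
is meaningless if the reported solution is an arbitrary vertex.

The LP itself is solved by a two-phase dense primal simplex with Bland's
anti-cycling rule written for this package. Metabolic LPs of this size
(tens of reactions) are heavily degenerate — many zero fluxes at the
optimum — and Bland's rule guarantees termination; the solver is validated
in the tests against brute-force vertex enumeration on random small models.
Reversible reactions are split into forward/reverse parts, and the
parsimonious stage minimises the sum of the split variables, which also
eliminates spurious forward-plus-reverse overlap.

Numerical choices: fluxes with magnitude below `1e-6` (consistent rate
units) count as zero when classifying — the solver's noise floor — and
mass-balance residuals are checked against `1e-6 · max|S|`.

## Differential flux and metabolic regulation analysis

Between conditions, a reaction with both fluxes nonzero and same-signed is
`constitutive` when $|J_b - J_a| / \max(|J_a|, |J_b|) < 0.10$; otherwise
`up`/`down` by magnitude. Opposite signs give `reversed`; a flux present in
exactly one condition `appeared`/`disappeared`. The classification is
antisymmetric under swapping conditions.

MRA splits a quantifiable flux change into a hierarchical coefficient

$$ \rho_h = \frac{\Delta \ln e}{\Delta \ln J}, \qquad \rho_m = 1 - \rho_h, $$

with the enzyme level $e$ proxied by the reaction's summed transcript
abundance — an approximation that ignores translation and post-translational
control, adequate for an estimated decomposition. The identity
$\rho_m = 1 - \rho_h$ is how $\rho_m$ is obtained; the elasticity-based
decomposition of $\rho_m$ into per-metabolite terms is out of scope. When
no member gene is significant, $\Delta \ln e$ is set to zero rather than
dropping the reaction: constitutive expression means the flux change is
carried entirely by the metabolic level. Edge cases:

* **disappeared** flux → `purely_metabolic` ($\rho_h = 0$), whatever the
  transcripts did: when a product is absent in condition B the flux is
  forced off, and no finite expression ratio can express an infinite flux
  ratio;
* **appeared** flux → `not_applicable`: the symmetric infinity, but here an
  accompanying expression change *could* be causal, so the package declines
  to attribute it rather than forcing either label;
* **constitutive** flux → `not_applicable` (the denominator
  $\Delta \ln J \approx 0$; with changed expression the diagnostic notes
  the near-zero division);
* **reversed** or zero-in-both → `not_applicable`.

## The synthetic-study generator

`simulateStudy()` emulates, from one seed, the statistical structure every
stage assumes:

* **DE table**: 4953 genes. Null genes draw $q \sim U(0,1)$ — exactly the
  assumption under which $z$ is standard normal — with small symmetric fold
  changes; planted genes draw q from an exponential tail below 0.05 with
  effect sizes $|log_2 FC| \sim N(2.5, 1)$ truncated at 0.5, and abundances
  are reconstructed as $(b, b \cdot 2^{FC})$ from a log-normal baseline.
  The planted fractions (214 up, 136 down) are calibrated so that the
  q < 0.05 rule recovers about 329 up- and 251 down-regulated genes in
  expectation *including* the ~2.5% of null genes that land below 0.05 on
  each side. The alternative — planting 329/251 directly — would overshoot
  the observed totals by the false-positive mass, because a uniform null
  (needed for score calibration) has far heavier q-tails than the
  BH-adjusted q-values of real callers, whose nulls concentrate near 1.
* **Model**: a substrate→biomass backbone chain (12 metabolites, half
  cytosolic, half mitochondrial) with a secreted-product branch that is
  active in condition A (rate 2.0) and shut off in B — producing
  disappeared fluxes and the purely-metabolic MRA class; an
  isozyme-switching reaction on that branch (one significant gene up, one
  down, in different compartments); a reporter hub metabolite whose five
  neighbour genes are strongly up-regulated, hanging off the backbone
  through a gene-less link and dead-end satellites so it can never carry
  or shortcut steady-state flux; and thirty null-expressed decoy enzyme
  genes on dead-end reactions, so the enzyme universe is dominated by
  unregulated enzymes as in a real metabolic complement. Exchange rates
  (uptake 9.4 in A, 5.0 in B) keep FBA feasible by construction and are
  verified by solving at generation time.
* **Planted MRA truth**: backbone transcript totals scale as the flux
  ratio to the power $\rho_h = 0.7$, so recovery is exact in the
  noise-free setting.
* **SMILES** strings are syntactic tokens over a small alphabet — adequate
  for edit-distance behaviour, with one planted near-duplicate pair — and
  claim no chemical validity.

What passing tests on this generator do *not* show: robustness to
correlated q-values, to the non-uniform null of real BH-adjusted data, to
annotation errors, or to genome-scale models with thousands of reactions.
The generator is a correctness harness, not a realism claim.

A bundled synthetic central-carbon model
(`inst/extdata/central_carbon_synthetic_model.json`: glycolysis, both
pentose-phosphate branches, fermentation, a lumped TCA/respiration block
and a biomass reaction with standard yeast anabolic precursor demands,
including ~10 mmol NADPH per gram biomass) illustrates the flux modules at
realistic operating points: under glucose uptake 9.4 with ethanol 2.7 and
acetate 2.0 secreted versus xylose uptake 5.0 with no products, the
oxidative pentose-phosphate flux classifies constitutive (the biomass NADPH
sink shrinks while the xylose-reductase NADPH sink appears, nearly
cancelling), glucose-6-phosphate isomerase reverses, and the fermentation
fluxes vanish.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: 500 random sets
at 1000 bootstrap iterations for null calibration, exhaustive enumeration
on ≤10-gene universes, 1000 random string pairs against a dynamic-
programming edit-distance oracle, vertex enumeration on ≤8-reaction models,
and genome-scale (4953-gene) synthetic studies for the count and recovery
checks. Every stochastic step is seeded; per-size bootstrap streams and the
generator make whole runs bit-reproducible from `(config, seed)`.

## Known limitations

* Enrichment Z-scores are non-directional; a set with strong but opposed
  regulation scores as high as a unidirectional one and must be read
  together with its direction summary.
* The simplex solver targets small dense models; genome-scale
  reconstructions need a sparse industrial LP code.
* Transcript totals proxy enzyme levels in MRA; the decomposition is an
  estimate, not a measurement.
* SMILES similarity is textual; isomorphic molecules with different string
  encodings will not match.
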