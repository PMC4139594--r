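---
title: "Knowledge-based discovery of ventricular-zone gene networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based discovery of ventricular-zone gene networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vznet)
```

## The discovery procedure

Neurons of the mammalian neocortex arise from progenitors proliferating in
the ventricular zone (VZ), with intermediate progenitors in the
subventricular zone (SVZ). Genes that control this process tend to share a
distinctive spatio-temporal signature: high expression in the proliferative
zones at the peak of neurogenesis, and high expression early in
development relative to later stages. `vznet` turns that observation into
a reproducible screening pipeline over structure-by-age expression
matrices:

1. **Spatial co-expression network (mouse-atlas style).** Genes expressed
   in the region of interest and at least `fold_min`-fold enriched in the
   target zone are correlated pairwise over their spatial profile at the
   target age; edges with Pearson `r > r_threshold` define the VZ network.
2. **Dual differential screens (human-atlas style).** A zone contrast
   (VZ+SVZ versus the rest of the structure panel) and a stage contrast
   (earliest bin versus all later stages), each with a linear six-fold
   filter followed by Holm-Bonferroni family-wise control at
   `alpha = 1e-9` on the fold-passing family.
3. **Cross-species intersection.** The two human hit lists are
   intersected; the mouse network is ortholog-mapped (symbol case-restyle
   fallback when no table entry exists) and intersected with the
   candidates, yielding the cross-species core.
4. **Network extension.** The query list is extended by `k_extend`
   associated genes via label propagation over a uniform-weight
   combination of typed association networks (co-expression,
   co-localization, physical, predicted, shared domains).
5. **Over-representation.** Hypergeometric upper-tail enrichment of the
   candidate list against flat gene-set annotations, BH FDR across sets,
   reported in the `C / O / E / R / rawP / adjP` layout.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r_threshold` | 0.7 | strict Pearson cutoff for spatial network edges |
| `fold_min` | 6 | linear fold filter for screens and the zone prefilter |
| `alpha` | 1e-9 | family-wise level on Holm-adjusted p-values |
| `k_extend` | 50 | associated genes added during extension |
| `propagation_alpha` | 0.85 | diffusion strength of the Gaussian-field propagation |

The edge rule is strictly `r > 0.7` rather than `r >= 0.7`; the choice is
configurable because descriptions of such networks use both phrasings.
Correlation is computed over the spatial profile at the target age only
(the age at which the network is defined), not across ages.

Two prefilters operationalize "expressed in the region" and "highly
expressed in the zone", for which no published numeric convention exists:
the expression floor defaults to the 20th percentile of gene means over the
included samples, and the zone-enrichment prefilter reuses `fold_min`. Both
are exposed as arguments. The network membership rule is likewise open —
nothing forces the final gene set to be mutually correlated rather than
correlated to one seed — so three rules are provided:
`top-enriched-component` (default), `all-components`, and `seed-gene`.

The screens' test is Welch's unequal-variance t on `log2(x + 1)`,
vectorised over genes; the choice is recorded in the screen output
(`attr(, "test")`). Holm is applied to the fold-passing family only,
mirroring a filter-then-correct workflow; the family size is reported per
row so the correction is auditable. Note the ordering guarantee that makes
the Holm step conservative relative to alternatives: Bonferroni rejections
are a subset of Holm rejections, which are a subset of BH rejections at the
same level.

For enrichment, the reference universe defaults to all genes carrying at
least one annotation; an explicit (genome-style) universe can be passed
instead, and the choice is recorded in the result attributes. Annotations
are consumed flat (pre-propagated GMTs); ontology-graph propagation is out
of scope.

## The synthetic data model

No public atlas ships with this package; instead, seeded generators
emulate the *statistical structure* the pipeline assumes, with known
ground truth:

* **Template + multiplicative noise.** Expression is non-negative and
  right-skewed, so values are log-normal around a spatial/temporal
  template: planted genes sit at `baseline * planted_fold` (default 10) in
  their target samples and at `baseline` elsewhere; measurement noise is
  log-normal with `sigma = 0.3` (natural-log scale, roughly 1.35-fold
  typical scatter — a realistic magnitude for ISH expression energy or
  array intensity).
* **Module correlation.** Planted genes share a module-level noise
  component giving log-scale correlation `module_cor = 0.9` beyond the
  template, so that co-expression recovery is a genuine statistical task
  rather than an artifact of identical profiles.
* **Bounded decoy profiles.** Decoy genes get independent per-structure
  profile effects drawn log-uniformly within `±log(2)`. The bound caps any
  decoy's zone-enrichment ratio at 4, below the six-fold filter; in the
  noise-free limit (`sigma = 0`) planted-set recovery is therefore exact
  by construction — zero false positives and zero false negatives — which
  the test suite asserts for every screen.
* **Replicate counts were fixed by a power analysis, a priori.** At
  `sigma = 0.3` a single target sample gives each planted gene a ~6%
  chance of missing the six-fold prefilter, and module-shared noise makes
  those misses hit the whole module at once. The mouse atlas therefore
  uses 2 replicate samples per structure/stage (84 conditions, 168
  samples), and the human panels use 160 samples each (20 structures × 4
  ages × 2, and 10 stage bins × 16). With 16 target-group samples the
  Welch statistic at fold 10 sits near t ≈ 29 at ~17 degrees of freedom
  (p ≈ 1e-15), clearing Holm at 1e-9 with a wide margin, while the
  module-wide prefilter miss rate drops to the order of 1-2% — compatible
  with recovering the full planted module in the large majority of seeds.
* **Cross-species wiring.** The human spatial module carries the
  human-styled images of 7 mouse module genes (preferring the canonical
  seven-gene core so output reads naturally); the temporal module shares
  52 of the spatial module's 60 genes, so the candidate intersection and
  the seven-gene core have known expected values.
* **Association compendium.** Five evidence channels with edge
  probability 0.6 within the query module, 0.35 between the module and a
  designated 50-gene associated tier, and 0.02 elsewhere; weights uniform
  on (0.4, 1). The background rate keeps decoys connected so that
  extension ranks against genuine competition.
* **Annotations.** Ten "enriched" sets draw 30% of their members from the
  planted list (capped at the list size) with sizes echoing a
  cell-cycle-dominated pathway panel (318, 261, 242, 158, 99, 141, 307,
  118, 109, 121); ten background sets are uniform draws.

What the generators do **not** emulate: voxel-level image structure,
realistic covariance between anatomical structures, probe-level
redundancy, or cross-dataset batch effects. Passing tests demonstrate that
the pipeline's statistics behave correctly under the assumed model — not
that any particular biological gene list would be recovered from the real
atlases, which would require the external data services these analyses
originally ran against.

## Numerical choices and degenerate inputs

* Fold changes and zone enrichments use a pseudocount (`1e-9`) on both
  means, so all-zero profiles yield 1, not `NaN`.
* Constant spatial profiles have undefined correlation; `pearson_r`
  raises, and the network builder drops such genes with a recorded count.
* Welch on two zero-variance groups: p = 1 when the means agree, the
  smallest representable double when they differ (a 0-adjacent sentinel,
  counted in the screen diagnostics).
* Propagation solves a dense linear system; with `alpha < 1` the Neumann
  series guarantees non-negative scores, and isolated non-query nodes
  score exactly 0. Extension ties are broken lexicographically by symbol
  so outputs are reproducible; when fewer than `k_extend` genes have
  positive scores, all of them are returned with a warning.
* The exact service algorithm behind published network extensions
  (query-adaptive evidence weighting) is deliberately not reproduced;
  uniform weighting plus Gaussian-field propagation is the declared,
  simpler model, and duplicating an evidence channel (with weight
  renormalization) provably leaves scores unchanged.
* Probe-level inputs are collapsed to gene level by keeping the row with
  the smallest raw p per gene — a declared convention, since published
  probe-to-gene counts rarely state one.

## Problem sizes used in the checks

The bundled tests and the acceptance script run at desk scale on one CPU:
the full 2104-gene mouse atlas for network recovery (20 seeds, seconds),
300-500-gene universes for property suites, 100 replicates for the
pure-null screen calibration, and 3000/2000-gene human panels for the
end-to-end run. Full-scale human universes (tens of thousands of genes)
are reachable through the generator arguments; nothing in the
implementation is specific to the scaled-down sizes.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1L)
inputs <- simulate_inputs(cfg)
run <- run_pipeline(inputs, cfg, out_dir = "results/run")
print(run)
```

The report lists the recovered 13-gene mouse network, both screens' family
sizes and hit counts, the 52-gene candidate list, the seven-gene
cross-species core, the 63-node extended network and the flagged
annotation sets; `results/run/` holds every intermediate artifact
(GraphML/SIF networks, TSV screen tables, gene lists, config echo, JSON +
text report).

## Known limitations

* Symbol-level ortholog matching (with case-restyling as fallback) stands
  in for a real homology resource; every fallback is counted so a real
  table can replace it without code changes.
* Enrichment assumes flat, pre-propagated annotation sets.
* The extension step models the *contract* of association-network
  services (k associated genes from typed evidence), not any specific
  service's ranking; parity with a particular database snapshot is out of
  scope.
* Holm correction after the fold filter matches a filter-then-correct
  reading of the screening procedure; correcting over the full family
  first would be more conservative, and the per-row `family_size` makes
  the difference explicit.
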