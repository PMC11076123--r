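---
title: "Modelling the alate transmission bottleneck of gut protist communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the alate transmission bottleneck of gut protist communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protrans)
```

## The biological setting

In lower termites the hindgut houses an obligate, multi-species community
of flagellate protists. The community can only move between host
generations inside dispersing alates, and alates carry roughly an order of
magnitude fewer protist cells than workers (~5,000–9,000 vs ~79,000). The
question this package quantifies: given the species-group proportions of a
source community, how many cells must an alate receive for the *whole*
community — every species group — to make it through?

Counts are taken at the resolution of ten microscopy-distinguishable
species groups (`default_species_groups()`): sixteen morphological species
pooled into ten categories, because several *Dinenympha* species cannot be
told apart live. The two large parabasalids, *Trichonympha agilis* and
*Teranympha mirabilis*, are also the two rarest groups in workers, which
is what makes the bottleneck interesting: rare species are the ones a
small propagule is likely to miss.

## The transmission model

Transmission of $N$ cells is modelled as sampling with replacement from
the source community $p = (p_1, \dots, p_k)$, i.e. one multinomial draw
$(X_1,\dots,X_k) \sim \mathrm{Multinomial}(N, p)$. The model assumes cells
are transmitted independently with probabilities given by the source
composition — no aggregation, no species-specific retention during the
moult, no spatial structure in the gut. Transmission *efficiency* at $N$
is the probability that every group is represented,
$P(\min_i X_i > 0)$, estimated two ways:

* **Monte-Carlo** (`transmission_model(..., mode = "monte_carlo")`):
  the fraction of `iterations` simulated alates with all groups present.
  This mirrors how such simulations are usually reported and exposes the
  grid/seed/iteration dependence of the "minimum cells for 100%
  efficiency" statistic.
* **Analytic** (`mode = "analytic"`, `prob_full_transmission()`): exact
  inclusion–exclusion over subsets of groups,
  $P(N) = \sum_{S} (-1)^{|S|} (1-\sum_{i \in S} p_i)^N$.
  Enumeration is $2^k$ terms and is refused above $k = 25$; at the
  panel's $k = 10$ it is 1,024 terms and effectively free.

For a rare group with proportion $q$, $P(\text{miss}) \approx e^{-qN}$,
so the minimum $N$ scales like $-\log(\alpha)/q$: halving the rarest
proportion doubles the required propagule. This is the quantitative core
of the worker-vs-nymph comparison below.

### The minimum propagule size and its pitfalls

`min_cells(fit, threshold = 1.0)` returns the smallest grid $N$ with
$E(N) \ge$ threshold. With the Monte-Carlo curve and threshold 1.0 this
means "all `iterations` simulated alates succeeded", which is a
seed-dependent event: at $I = 5000$ it occurs with appreciable probability
once the per-alate failure probability drops below about $1/I$. The
package therefore always pairs it with the analytic minimum at threshold
$1 - 1/(2I)$ (`summary()` and the pipeline report both). The minimum is
resolved only to the grid step (500 cells by default); in analytic mode
`min_cells(..., refine = TRUE)` bisects to the exact integer boundary, off
by default to keep reported values grid-comparable.

Threshold comparisons use `efficiency >= threshold - 1e-12` so that an
analytic probability sitting numerically at the threshold is not rejected
for floating-point reasons; ties on the grid resolve to the smallest
qualifying $N$.

### Handling of zero-proportion groups

"All species groups" is interpreted strictly by default: a group with
$p_i = 0$ can never be transmitted, so its presence in the panel forces
efficiency 0 at every $N$. This is deliberate — the empirical source
communities contain no zeros, so a zero almost certainly indicates a data
problem (a missing species column, a mislabelled group), and silently
excluding it would mask the error. `require_all = FALSE` restricts the
criterion to groups with positive proportion when partial panels are
genuinely intended.

## The count-data layer

Haemocytometer observations are scaled to whole-gut population estimates
as $\lfloor \text{raw} \times \text{suspension}/\text{counted} \rfloor$,
rounding down to the nearest integer. Defaults follow the counting
protocol: large groups are counted over 3.2 µl, the rest over 0.8 µl;
worker guts are suspended in 150 µl, nymph and alate guts in 30 µl; both
volumes can be overridden per row. A tolerance of 1e-9 is added before
the floor so that decimal volumes represented inexactly in binary (e.g.
0.8) do not knock an exact ratio such as $10 \times 150 / 0.8 = 1875$
down to 1874.

Source communities are built by `average_composition()`. Two averaging
rules are provided because "the average of the empirical data" is
genuinely ambiguous:

* `method = "individual"` (default): average the per-individual
  proportion vectors, weighting each termite equally. Chosen as default
  because the analysis is about what an *individual* alate receives, and
  because it stops high-count individuals from dominating the composition.
* `method = "pooled"`: sum counts across individuals first, weighting by
  abundance.

Both renormalise to sum exactly 1, and the provenance string on the
returned composition records the filter and rule used.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_grid` | 500–10,000 step 500 | cells | the propagule range actually spanned by alate gut counts, at the grid resolution minima are reported on |
| `iterations` | 5,000 | simulated alates | standard reporting resolution; Monte-Carlo s.e. at $E=0.5$ is 0.007 |
| `threshold` | 1.0 | — | "every simulated alate got everything"; pair with the analytic $1 - 1/(2I)$ reference |
| `kappa` | 200 | — | Dirichlet concentration of individual compositions; gives realistic individual spread (rare-group percentages varying severalfold between termites) |
| `colony_effect_sd` | 0.1 | log scale | small multiplicative colony effect on composition: colonies differ detectably but much less than castes |
| `n_reference` | 20 | individuals | group size assumed when converting published s.e. to sd (sd = s.e.·√n) |

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws, per individual: a log-normal total abundance
moment-matched to the published caste mean and s.e.-derived sd (log-normal
rather than normal so worker-scale dispersion cannot produce negative
totals), rounded to an integer, with freshly moulted workers fixed at
exactly 0; a Dirichlet composition with concentration `kappa` around the
caste base composition, perturbed multiplicatively per colony and
renormalised; and one multinomial count vector of that total over that
composition. Sexes are assigned at an even ratio and have no effect on
composition, matching the empirical finding of no sex effect.

The caste calibration places *Tr. agilis* at 0.48% of the worker
community vs 2.93% in nymphs and *Te. mirabilis* at 0.14% vs 0.27% — the
published percentage summaries. The remaining eight group proportions are
**not** published as a table in the main text; the generator uses a fixed,
documented background split of common oxymonads and minor groups
(`default_compositions()`), a stated modelling default. Consequently:

* properties that depend only on the *rarest* groups (fold enrichment,
  the ordering and approximate location of the minimum propagule sizes)
  are calibrated to the study system;
* properties that depend on the full composition (exact Bray–Curtis
  distances, detection ratios of mid-abundance groups) are internally
  consistent but not reproductions of the field data.

Passing tests on synthetic data therefore demonstrate correctness of the
machinery and of the rare-species arithmetic, not agreement with the
deposited per-individual counts. A0 alates (day of eclosion) have no
published count summary and borrow the nymph calibration, with zero
individuals generated by default.

## Reproducibility and seeding

All Monte-Carlo fits take one master seed. Per-grid-point substreams are
derived deterministically from it (`derive_seeds()`), so the curve does
not depend on internal batching and any single grid point can be
recomputed in isolation. The pipeline (`run_pipeline()`) threads one
master seed through generation and both scenario fits and records it,
with the derived scenario seeds, in `manifest.json`; identical
configuration and seed give byte-identical output files. Plotting is
optional and a plotting failure never fails a run.

## Problem sizes used in the test suite

The suite exercises the exact-vs-simulation agreement on 200 random
communities of 2–10 groups at $I = 5000$; monotonicity and limits on 100
random communities (bounded away from zero proportions, as in the
empirical panel, so the $N = 10^6$ limit check is meaningful); generator
recovery of caste means over 100 seeds at 20 individuals per caste; and
the two-scenario minimum comparison over 20 master seeds at the full
default grid. Tiny enumerable cases ($k \le 3$, $n \le 6$) are checked
against a brute-force enumeration of all $k^n$ outcomes, an oracle
independent of the inclusion–exclusion code.

## Known limitations

* The model treats transmission as a single multinomial draw: no
  biparental founding, no serial bottlenecks over multiple generations,
  no differential survival of species during the moult.
* The Monte-Carlo minimum at threshold 1.0 is an artefact-prone statistic
  (grid-, seed- and $I$-dependent); use the analytic reference for
  anything quantitative.
* The background composition of the eight non-focal groups is a modelling
  default; analyses sensitive to it should substitute measured
  compositions via `average_composition()` on real data files.
* Inference (mixed models, PERMANOVA, ordination) is out of scope; the
  package computes the descriptive statistics and hands off to standard
  tools.
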