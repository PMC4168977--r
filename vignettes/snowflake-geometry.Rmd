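---
title: "Cluster geometry, apoptosis and the demography of snowflake yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster geometry, apoptosis and the demography of snowflake yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowflaker)
```

## The system and the model

Snowflake yeast are experimentally evolved *Saccharomyces cerevisiae* in
which daughter cells stay attached to their mothers after budding. A cluster
is therefore a *lineage tree*: nodes are cells, edges are mother–daughter
attachments, and the founding cell (Node 0) is the root. Because the tree is
acyclic, severing any single attachment splits the cluster into exactly two
connected pieces — cluster-level reproduction. Programmed cell death
(apoptosis) is the severance mechanism modelled here: when a cell dies, one
of its attachments breaks and the cluster divides.

`snowflaker` implements this model stack end to end:

* a lineage-tree data structure with synchronized, constraint-gated growth
  (`new_founder()`, `grow_step()`, `branch_partition()`, `diameter()`);
* closed-form and recursive analytics for branch sizes and the
  concentric-shell volume constraint (`branch_series()`, `total_size()`,
  `shell_occupancy()`, `first_overflow()`);
* exact enumeration of expected offspring-size asymmetry under
  death-triggered severance (`expected_smaller_fraction()`);
* an agent-based population simulator with death, severance, degree caps,
  volume limits and death delays (`simulate_population()`,
  `strategy_sweep()`);
* a dynamic-programming model of optimal cluster division under settling
  selection (`dp_model()`, `solve_policy()`);
* a mutation–selection transfer simulation in which the per-cell death
  probability is a heritable, evolvable trait (`simulate_evolution()`).

## Growth rules

Time advances in discrete generations. At the start of a generation every
cell buds one daughter provided it (1) is alive, (2) has not reached the
degree cap, and (3) has room in the shell where the daughter would reside.
Eligibility is evaluated against the pre-step state, so all births in a
generation are synchronous. A daughter's shell index is its mother's plus
one; shells are counted from the current root of the cluster.

**Degree caps.** A cap `d` bounds a cell's physical attachments (parent link
included). The root has no parent, so it accumulates `d` daughters over
generations `1..d`; every other cell buds in the `d - 1` generations after
its birth. Branch sizes then follow order-`(d-1)` generalized Fibonacci
recursions: a cap of 3 gives ordinary Fibonacci growth
(`branch_series(3, 6)` = `r paste(branch_series(3, 6), collapse = ", ")`), a
cap of 4 tribonacci growth, and caps of 2 give filaments. Once the root is
saturated the whole tree is exactly twice its oldest branch
(`total_size()`), e.g. `total_size(3, 19)` =
`r format(total_size(3, 19), big.mark = ",")` cells.

**Volume constraint.** Cells are identical spheres of radius `r` with
effectively zero edge length, so the cells within `k` links of the root must
fit inside a sphere of radius `(2k + 1) r`: at most `(2k + 1)^3` cell
volumes, ignoring sphere-packing corrections (the capacity is deliberately
an upper bound, as the model aims to show that growth is limited *even*
under generous packing). A birth into shell `s` consumes room in the volume
enclosed by every shell `k >= s`, so the room check is the minimum slack
over those shells. `first_overflow()` scans the unconstrained trajectory for
the first generation at which some shell exceeds its capacity:

```{r overflow}
first_overflow(NULL)[c("generation", "shells")] # uncapped
first_overflow(4)[c("generation", "shells")]
first_overflow(3)[c("generation", "shells")]
```

Uncapped trees overflow shells 4–6 at round 12 (11 limit-free rounds);
degree-cap-4 trees complete 14 limit-free generations before hitting shells
8–11; cap-3 trees last until round 20 (shells 14–15). Filaments (cap 2)
never overflow. The analytic overflow calculation is kept separate from the
simulator, where growth is actually blocked; the two are cross-checked by
growing trees and tallying shells.

When shell room suffices for only some of a generation's would-be births,
the simulator and the reference grower both grant room to inner shells
first and, within a shell, to older cells (smaller id). The tie-break is
arbitrary but deterministic, which keeps the two implementations exactly
comparable; no result in the package depends on it.

## Death, severance and offspring asymmetry

A death severs one of the victim's attachments. Which cell dies and which
link breaks together determine the sizes of the two offspring clusters:

* *uniform random death* mostly kills peripheral, recently born cells, so
  one offspring is usually tiny;
* *oldest-cell death* (Node 0) severs a root branch; with links chosen
  uniformly the expected smaller-offspring fraction after `t` rounds is
  `(2^t - 1) / (t 2^t)`, which decays to zero;
* *oldest-cell death with branch-size-biased severance* (bigger branches
  strain their attachment more and break more easily) gives
  `(4^t - 1) / (3 (2^t - 1) 2^t)`, which approaches **1/3** — much closer
  to experimentally observed offspring ratios.

`expected_smaller_fraction()` computes these values by exact enumeration of
every (victim, link) outcome on the deterministic unconstrained tree; no
sampling is involved, and the closed forms above are verified against the
enumeration in the test suite. Degree-capped trees produce more equal
offspring than uncapped trees under every mode.

Two modelling choices matter here and in the simulator:

* **Severance frees the attachment sites it breaks.** When a link is
  severed, both endpoint cells get the attachment site back, so a
  degree-saturated survivor can bud again and found a new branch. This is
  the mechanism by which cell death lets degree-capped populations keep
  growing; with permanent "bud scars" instead, death is a pure cost and the
  death-benefit results below disappear.
* **Fragments are re-rooted.** The severed piece is re-rooted at the
  severed cell; its shells are recomputed from the new root, so a fragment
  regains fresh volume. This is how fragmentation lets lineages escape the
  volume constraint.

## The population simulator

`simulate_population()` grows a population from a single founder for 21
generations (the default horizon throughout): synchronized reproduction,
then death, then severance, cluster by cluster. Dead cells remain attached,
occupy shell space and never reproduce. Cells enter the death lottery the
generation *after* their birth — death is implemented over the cells that
started the time step — and a configurable `death_delay` additionally
protects any cell that reproduced within the last `delay` generations. A
per-generation record of births, deaths, living cells and cluster counts is
returned together with the final cluster size/diameter table and every
split event.

With these rules the model's central, paradoxical results emerge (all are
asserted by the test suite at 100 replicates on the default death-rate grid
0.005/0.02/0.05/0.1):

* for degree cap 3 with volume limits, mean living cells at generation 21
  *rise* with the death probability: dying cells free attachment sites and
  their clusters fragment into re-rooted pieces with fresh volume;
* removing the volume constraint for cap 4 flips the ordering: the highest
  death rate no longer produces the most cells;
* large cluster-size thresholds reward clusters that never divide, so the
  lowest death probability maximizes the number of clusters above
  threshold, while small thresholds favor high death rates.

The death-rate grid is a package default: the study design it emulates used
four probabilities whose exact values are not recoverable, so all
grid-relative claims are made on the configured grid. `strategy_sweep()`
crosses degree caps, death probabilities and delays at 100 replicates per
strategy with deterministically derived per-replicate seeds
(`seed + 7919 * strategy + replicate`), so sweeps are reproducible and
order-independent.

## Optimal cluster division

Settling selection rewards large clusters. `dp_model()` asks how a cluster
should split if survival of settling is a non-decreasing function `s(n)` of
size, clusters double each step (`g(n) = 2n`), and `V(n, t)` counts expected
surviving clusters (or cells) at horizon `T`:

`V(n, t) = max over a in {0, 1, ..., floor(n/2)} of V(g(a), t+1) + V(g(n-a), t+1)`

with `a = 0` meaning "do not divide". Ties break toward the smallest part,
so no-division wins over an equivalent split. The solved policy reproduces
the analytic regimes: with strictly concave `s` and cluster-count fitness
the optimum is to halve (odd sizes split as evenly as possible); with
cell-count fitness it is optimal never to split even for concave `s`; and
survival functions with a convex region (steep Hill functions) mix no-split
and halving regimes across sizes and times. The table is exact; for short
horizons it equals brute-force enumeration over all division trees. Sizes
are tabulated to `n_max` (default 256) with growth clipped there — a
boundary artifact, so conclusions are read well below the boundary.

## The transfer (evolution) simulation

`simulate_evolution()` emulates serial settling selection: grow (with
per-cell heritable death probabilities and per-cell-per-generation mutation,
redrawn uniformly on `mutation_range`), then retain clusters by
diameter-weighted sampling without replacement until 10% of living cells
are kept, and repeat. The growth phase ends when `growth_budget` new cells
have been added (default `2^15`, a desk-scale stand-in for liquid-culture
scales of order `2^21`; the budget, fraction, weighting and mutation
parameters are all configurable). The generation clock runs continuously
across transfers, so carried-over clusters keep their geometry and ages.

Two controls behave as expected: with mutation off the population mean
death probability never moves, and with selection off it performs neutral
drift (slopes centred on zero when started from the stationary midpoint of
the mutation range; started from a boundary, mutation alone relaxes the
mean toward the midpoint, which is a mutational-pressure trend rather than
selection).

A known limitation, measured rather than assumed: under diameter-weighted
retention of a fixed fraction of cells, the simulated transfer regime
*favors low death probabilities* at every scale we can run on a desktop.
High-death lineages out-produce cells during growth but spread them across
many small-diameter fragments, while low-death lineages concentrate cells
in a few long-lived, large-diameter clusters that dominate any
diameter-weighted retention quota. The acceptance suite states the expected
upward trend as a one-sided test and documents its failure; users exploring
this regime should treat the direction of death-rate evolution under
settling selection as sensitive to how settling selection is implemented
(weighting, retention quota, growth-phase length), not as a robust
prediction of the model as configured here.

## Numerical and design notes

* **Determinism.** Every stochastic routine consumes R's RNG only, so
  `set.seed()` (or the `seed` fields of the config objects) reproduces runs
  bit for bit. The C++ engine draws from the same RNG stream.
* **Desk-scale test sizes.** The test suite runs simulations at the study's
  21-generation horizon; replicated stochastic checks use 100 replicates
  for population orderings, 10–20 for evolution trends, and small growth
  budgets (`2^7`–`2^17`) for the transfer regime. These sizes were chosen
  as the smallest at which the tested effects are unambiguous.
* **Degenerate inputs.** A single-cell cluster dies without severance; a
  cap of 2 grows a two-armed filament (the parentless root carries two
  attachments); extinction (no living cells) terminates a transfer run with
  a flagged trajectory.
* **What the simulator does not model.** Spatial mechanics and physical
  strain, nutrient and waste gradients, sphere-packing corrections,
  multi-way splits ("multiple births"), and asynchronous or
  continuous-time growth. Shell capacities are generous upper bounds by
  construction.

## Serialization

Clusters round-trip losslessly through JSON (`cluster_to_json()`), and
export to Newick with unit branch lengths and dead cells tagged in node
labels (`export_cluster()`), so lineage trees can be inspected with
standard phylogenetics tooling. Configuration objects round-trip through
YAML (`config_to_yaml()`), and every file written by the command-line
interface is accompanied by a manifest (command, configuration, seed,
package version, timestamp) sufficient to regenerate it.
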