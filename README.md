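# snowflaker

Geometry, fragmentation and evolution of snowflake yeast clusters.

Snowflake yeast are experimentally evolved *Saccharomyces cerevisiae* whose
daughter cells stay attached to their mothers after budding. Each cluster is
a lineage tree — cells are nodes, mother–daughter attachments are edges,
the founding cell (Node 0) is the root — and severing any single attachment
splits the cluster into exactly two, which is how clusters reproduce.
Shortly after clusters evolved, the yeast also evolved *higher* rates of
programmed cell death, an apparent paradox since settling selection rewards
large, fast-sinking clusters and death makes clusters divide and shrink.
`snowflaker` implements the modelling stack used to resolve that paradox
through cluster geometry: packages of cells run out of attachment sites
(degree caps) and of interior space (concentric-shell volume limits), and
dying cells relieve both constraints.

The package is aimed at researchers in the evolution of multicellularity
and life-history theory who want to reproduce, perturb or extend the model.

## What is in the box

* **Lineage trees** — `new_founder()`, `grow_step()`, `branch_partition()`,
  `diameter()`: synchronized budding gated by degree caps and shell volume.
* **Geometry analytics** — shell `k` encloses at most `(2k+1)^3` cells;
  `first_overflow()` finds the first generation any shell overflows;
  `branch_series()`/`total_size()` give the generalized-Fibonacci branch
  sizes (cap 3 → Fibonacci, cap 4 → tribonacci; the tree is twice its
  oldest branch).
* **Division analytics** — `expected_smaller_fraction()` enumerates the
  expected smaller-offspring fraction exactly for every combination of
  victim rule (uniform or oldest cell) and link rule (uniform or
  branch-size-biased). Under oldest-cell death with biased severance it
  approaches 1/3.
* **Population simulator** — `simulate_population()` /
  `strategy_sweep()`: an agent-based generational model (Rcpp core) of
  growth, death, link severance and fragmentation from a single founder.
* **Optimal division** — `dp_model()` / `solve_policy()`: backward
  recursion for the division policy maximizing surviving clusters (or
  cells) under a settling-survival function `s(n)`.
* **Evolution** — `simulate_evolution()`: mutation–selection transfers in
  which per-cell death probabilities mutate and clusters are retained by
  diameter-weighted settling selection.
* **Interchange** — JSON and Newick export of clusters, YAML configs, run
  manifests, and a thin command line (`exec/snowflaker`).

## Worked example

```r
library(snowflaker)

# When does a degree-cap-3 tree run out of space?
first_overflow(3)[c("generation", "shells")]
#> $generation
#> [1] 20
#> $shells
#> [1] 14 15

# Offspring symmetry under oldest-cell death with branch-biased severance
asymptotic_biased_fraction(20)
#> [1] 0.3333337

# Grow a population for 21 generations at a 5% per-cell death rate
r <- simulate_population(sim_config(degree_cap = 3, p_death = 0.05,
                                    generations = 21, seed = 42))
r
#> <population_result> 21 generations: 67342 living cells, 5246 dead, 5247 clusters
```

A cap-3 tree exceeds the volume of shells 14–15 on its 20th round of
division; without death it would hold 57,312 cells at generation 21. At a
5% death rate the population instead reaches **67,342 living cells in
5,247 clusters** — every death severed a link, freed two attachment sites
and spawned a re-rooted fragment with fresh interior space, so dying
*faster* left *more* living cells. The split log shows the offspring
asymmetry:

```r
f <- pmin(r$splits$fragment_kept, r$splits$fragment_severed) / r$splits$parent_size
round(mean(f), 3)
#> [1] 0.153   # mean smaller-offspring fraction across 5,246 severances
```

And the optimal-division model says how clusters *should* split when
survival is concave in size and fitness counts surviving clusters — as
evenly as possible:

```r
pol <- solve_policy(dp_model(function(n) sqrt(n / 1024), T = 5, n_max = 256))
pol$split[10:14, "t0"]
#> [1] 5 5 6 6 7   # optimal smaller part for sizes 10..14: floor(n/2)
```

The methods vignette (`vignettes/snowflake-geometry.Rmd`) describes the
model, its parameters and defaults, the design decisions and the known
limitations, including a measured negative result for the direction of
death-rate evolution under diameter-weighted settling selection.

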