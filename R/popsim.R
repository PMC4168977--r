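#' Configuration for a population simulation
#'
#' Parameters of the agent-based generational simulation: a population grows
#' from a single founder cell; each generation every cell that is alive,
#' below the degree cap and has shell room buds one child, then each
#' susceptible living cell dies with probability `p_death`, severing one of
#' its links and splitting its cluster.
#'
#' @param degree_cap Integer `>= 2` or `NULL` for no cap.
#' @param p_death Per-cell per-generation death probability in `[0, 1]`.
#' @param death_delay Generations a cell must have gone without reproducing
#'   before it becomes susceptible to death (0 = all living cells
#'   susceptible).
#' @param volume_limited Enforce shell-volume capacities?
#' @param generations Number of reproduction+death rounds (default 21).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param severance Link-severance rule applied at each death.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(degree_cap = 3, p_death = 0.02, death_delay = 0,
                       volume_limited = TRUE, generations = 21, seed = NULL,
                       severance = c("branch_size_biased", "uniform_link")) {
  severance <- match.arg(severance)
  stopifnot(p_death >= 0, p_death <= 1, generations >= 1,
            death_delay >= 0)
  if (!is.null(degree_cap) && degree_cap < 2) stop("`degree_cap` must be >= 2 or NULL")
  structure(list(degree_cap = if (is.null(degree_cap)) NULL else as.integer(degree_cap),
                 p_death = p_death, death_delay = as.integer(death_delay),
                 volume_limited = isTRUE(volume_limited),
                 generations = as.integer(generations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 severance = severance),
            class = "sim_config")
}

# engine-facing state for a founder cell with the given death probability
.founder_state <- function(p_death = 0, gen0 = 0L) {
  list(parent = 0L, birth_gen = as.integer(gen0),
       last_repro_gen = as.integer(gen0), shell = 0L, links_used = 0L,
       cluster = 1L, alive = TRUE, p_death = p_death)
}

#' Simulate a population of clusters from a single founder
#'
#' Runs the generational engine for `config$generations` rounds. Each round:
#' (i) synchronized reproduction gated by life state, degree cap and
#' per-cluster shell room; (ii) each susceptible living cell dies
#' independently with `p_death`; (iii) each death severs one link of the
#' dead cell (branch-size-biased by default), splitting its cluster. Dead
#' cells remain attached, occupy shell space and never reproduce.
#'
#' @param config A [sim_config()].
#' @return An object of class `population_result`: `per_generation` (data
#'   frame with `gen`, `births`, `deaths`, `living`, `dead`, `clusters`),
#'   `clusters` (per-cluster `living`, `total`, `diameter`), `splits`
#'   (one row per severance: generation, parent size, fragment sizes),
#'   the final engine `state`, and the `config`.
#' @examples
#' r <- simulate_population(sim_config(degree_cap = NULL, p_death = 0,
#'   volume_limited = FALSE, generations = 5))
#' tail(r$per_generation$living, 1) # 32: pure doubling
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .engine_run(.founder_state(config$p_death),
                     generations = config$generations, budget = -1,
                     degree_cap = if (is.null(config$degree_cap)) -1L else config$degree_cap,
                     volume_limited = config$volume_limited,
                     death_delay = config$death_delay,
                     biased_severance = config$severance == "branch_size_biased",
                     mutation_prob = 0, p_min = 0, p_max = 0, gen0 = 0L)
  structure(list(per_generation = res$stats,
                 clusters = .engine_cluster_stats(res$state),
                 splits = res$splits,
                 state = res$state,
                 extinct = res$extinct,
                 config = config),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  last <- x$per_generation[nrow(x$per_generation), ]
  cat(sprintf(
    "<population_result> %d generations: %d living cells, %d dead, %d clusters\n",
    last$gen, as.integer(last$living), as.integer(last$dead),
    as.integer(last$clusters)))
  invisible(x)
}

#' Susceptibility of cells to death
#'
#' Cells enter the death lottery the generation after their birth (death is
#' implemented over the cells that started the time step). A living cell is
#' then susceptible once at least `delay` generations have passed since its
#' last reproductive event; with `delay = 0` every living cell born in an
#' earlier generation is susceptible. Vectorized over the rows of a cells
#' table.
#'
#' @param cells Data frame with `alive`, `birth_gen` and `last_repro_gen`
#'   columns (e.g. `cluster$cells` or an engine state converted with
#'   `as.data.frame`).
#' @param gen Current generation.
#' @param delay Death delay in generations.
#' @return Logical vector, `TRUE` where the cell can die this generation.
#' @export
susceptible <- function(cells, gen, delay) {
  cells$alive & cells$birth_gen < gen & (gen - cells$last_repro_gen >= delay)
}

#' Clusters (or their cells) above a size threshold
#'
#' Cluster size is measured in living cells, matching the settling-selection
#' regime that rewards clusters above a size threshold.
#'
#' @param result A [simulate_population()] result.
#' @param theta Integer threshold `>= 1`.
#' @param measure Count `"clusters"` with `>= theta` living cells, or the
#'   total living `"cells"` inside those clusters.
#' @return A single count.
#' @export
clusters_above_threshold <- function(result, theta,
                                     measure = c("clusters", "cells")) {
  measure <- match.arg(measure)
  stopifnot(theta >= 1)
  sizes <- result$clusters$living
  keep <- sizes >= theta
  if (measure == "clusters") sum(keep) else sum(sizes[keep])
}

#' Sweep over life-history strategies
#'
#' Replicated simulations over a grid of (degree cap, death probability,
#' death delay) strategies, summarized as the mean and variance of the
#' number of clusters (and of living cells in clusters) above each size
#' threshold, plus the mean offspring-to-parent smaller fraction across all
#' severance events. Per-replicate seeds are derived deterministically from
#' the master seed (`seed + 7919 * strategy_index + replicate`), so results
#' do not depend on evaluation order.
#'
#' @param caps List of degree caps (integers or `NULL`).
#' @param p_deaths Numeric vector of death probabilities.
#' @param delays Integer vector of death delays.
#' @param thetas Integer vector of size thresholds.
#' @param replicates Replicates per strategy (the study design uses 100).
#' @param seed Master seed.
#' @param generations Rounds per simulation (default 21).
#' @param volume_limited Enforce shell capacities?
#' @param severance Link rule for every strategy.
#' @return A data frame with one row per strategy x threshold:
#'   `degree_cap`, `p_death`, `death_delay`, `theta`, `mean_clusters`,
#'   `var_clusters`, `mean_cells`, `var_cells`, `mean_living`,
#'   `mean_offspring_fraction`.
#' @export
strategy_sweep <- function(caps, p_deaths, delays, thetas, replicates = 100,
                           seed = 1, generations = 21, volume_limited = TRUE,
                           severance = "branch_size_biased") {
  stopifnot(replicates >= 1)
  if (!is.list(caps)) caps <- as.list(caps)
  grid <- expand.grid(cap_i = seq_along(caps), p_death = p_deaths,
                      delay = delays, KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", nrow(grid) * length(thetas))
  row <- 0L
  for (j in seq_len(nrow(grid))) {
    cap <- caps[[grid$cap_i[j]]]
    above_cl <- matrix(0, replicates, length(thetas))
    above_ce <- matrix(0, replicates, length(thetas))
    living <- numeric(replicates)
    frac_sum <- 0; frac_n <- 0
    for (r in seq_len(replicates)) {
      cfg <- sim_config(degree_cap = cap, p_death = grid$p_death[j],
                        death_delay = grid$delay[j],
                        volume_limited = volume_limited,
                        generations = generations,
                        seed = (seed + 7919L * j + r) %% .Machine$integer.max,
                        severance = severance)
      res <- simulate_population(cfg)
      living[r] <- sum(res$clusters$living)
      for (k in seq_along(thetas)) {
        above_cl[r, k] <- clusters_above_threshold(res, thetas[k], "clusters")
        above_ce[r, k] <- clusters_above_threshold(res, thetas[k], "cells")
      }
      if (nrow(res$splits)) {
        fr <- pmin(res$splits$fragment_kept, res$splits$fragment_severed) /
          res$splits$parent_size
        frac_sum <- frac_sum + sum(fr); frac_n <- frac_n + length(fr)
      }
    }
    for (k in seq_along(thetas)) {
      row <- row + 1L
      out[[row]] <- data.frame(
        degree_cap = if (is.null(cap)) NA_integer_ else cap,
        p_death = grid$p_death[j], death_delay = grid$delay[j],
        theta = thetas[k],
        mean_clusters = mean(above_cl[, k]), var_clusters = stats::var(above_cl[, k]),
        mean_cells = mean(above_ce[, k]), var_cells = stats::var(above_ce[, k]),
        mean_living = mean(living),
        mean_offspring_fraction = if (frac_n) frac_sum / frac_n else NA_real_)
    }
  }
  do.call(rbind, out[seq_len(row)])
}

#' Extract one cluster of a population result as a lineage tree
#'
#' @param result A [simulate_population()] result (or any engine state list
#'   wrapped in one).
#' @param cluster_id Cluster id as reported in `result$clusters`.
#' @return A `snowflake_cluster`.
#' @export
population_cluster <- function(result, cluster_id) {
  st <- result$state
  rows <- which(st$cluster == cluster_id)
  if (!length(rows)) stop("no such cluster: ", cluster_id)
  cells <- data.frame(id = rows,
                      parent = ifelse(st$parent[rows] == 0L, NA_integer_,
                                      st$parent[rows]),
                      birth_gen = st$birth_gen[rows],
                      last_repro_gen = st$last_repro_gen[rows],
                      alive = st$alive[rows],
                      shell = st$shell[rows],
                      links_used = st$links_used[rows])
  root <- cells$id[is.na(cells$parent)]
  structure(list(cells = cells, root_id = root,
                 founding_gen = cells$birth_gen[cells$id == root]),
            class = "snowflake_cluster")
}
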