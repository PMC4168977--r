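#' Configuration for the mutation-selection transfer simulation
#'
#' Emulates the serial-transfer regime of the settling-selection experiment:
#' clusters alternate between growth phases (generational growth, death and
#' fragmentation, with the per-cell death probability a heritable, mutable
#' trait) and selective phases in which clusters are sampled by diameter --
#' a proxy for settling speed -- until a fixed fraction of the living cells
#' is retained.
#'
#' @param initial_p_death Death probability of the founding cell (low, e.g.
#'   0.005).
#' @param mutation_prob Per-cell per-generation probability that the death
#'   probability is redrawn.
#' @param mutation_range Bounds `c(p_min, p_max)` of the uniform redraw.
#' @param growth_budget New cells added per growth phase before selection is
#'   applied. Default `2^15`, a desk-scale stand-in for liquid-culture
#'   populations of order `2^21`.
#' @param selection_fraction Proportion of living cells retained at each
#'   transfer (default 0.10); 1 disables selection.
#' @param transfers Number of growth+selection cycles (default 100).
#' @param degree_cap,volume_limited,death_delay,severance Growth rules, as
#'   in [sim_config()]; the experimental lineage is uncapped and
#'   volume-limited.
#' @param weighting Selection weight: linear in `"diameter"` (default),
#'   `"diameter2"` (squared) or `"rank"` (diameter rank).
#' @param max_gens_per_transfer Safety cap on growth-phase generations.
#' @param seed Integer RNG seed, or `NULL`.
#' @return An object of class `evo_config`.
#' @export
evo_config <- function(initial_p_death = 0.005, mutation_prob = 1e-4,
                       mutation_range = c(0, 0.3), growth_budget = 2^15,
                       selection_fraction = 0.10, transfers = 100,
                       degree_cap = NULL, volume_limited = TRUE,
                       death_delay = 0,
                       severance = c("branch_size_biased", "uniform_link"),
                       weighting = c("diameter", "diameter2", "rank"),
                       max_gens_per_transfer = 500, seed = NULL) {
  severance <- match.arg(severance)
  weighting <- match.arg(weighting)
  stopifnot(initial_p_death >= 0, initial_p_death <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            length(mutation_range) == 2, mutation_range[1] < mutation_range[2],
            mutation_range[1] >= 0, mutation_range[2] <= 1,
            growth_budget >= 1, selection_fraction > 0, selection_fraction <= 1,
            transfers >= 1)
  structure(list(initial_p_death = initial_p_death,
                 mutation_prob = mutation_prob,
                 mutation_range = mutation_range,
                 growth_budget = growth_budget,
                 selection_fraction = selection_fraction,
                 transfers = as.integer(transfers),
                 degree_cap = if (is.null(degree_cap)) NULL else as.integer(degree_cap),
                 volume_limited = isTRUE(volume_limited),
                 death_delay = as.integer(death_delay),
                 severance = severance, weighting = weighting,
                 max_gens_per_transfer = as.integer(max_gens_per_transfer),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "evo_config")
}

#' Settling selection by diameter-weighted sampling
#'
#' Samples clusters without replacement with probability proportional to
#' their selection weight (linear in diameter by default), stopping once the
#' retained clusters hold at least `fraction` of the total living cells.
#' Clusters with zero weight (single cells have diameter 0) are only drawn,
#' uniformly, after every positive-weight cluster.
#'
#' @param diameters Integer vector of cluster diameters.
#' @param living Living-cell count per cluster.
#' @param fraction Proportion of living cells to retain, in (0, 1].
#' @param weighting `"diameter"`, `"diameter2"` or `"rank"`.
#' @return Integer indices of the retained clusters.
#' @export
settle_select <- function(diameters, living, fraction,
                          weighting = c("diameter", "diameter2", "rank")) {
  weighting <- match.arg(weighting)
  stopifnot(length(diameters) == length(living), fraction > 0, fraction <= 1)
  n <- length(diameters)
  if (fraction >= 1 || n == 1L) return(seq_len(n))
  w <- switch(weighting,
    diameter = as.numeric(diameters),
    diameter2 = as.numeric(diameters)^2,
    rank = rank(diameters, ties.method = "average"))
  pos <- which(w > 0); zer <- which(w <= 0)
  order_pos <- if (length(pos) > 1) pos[sample.int(length(pos), prob = w[pos])]
               else pos
  order_all <- c(order_pos, if (length(zer) > 1) zer[sample.int(length(zer))] else zer)
  target <- fraction * sum(living)
  keep_n <- which(cumsum(living[order_all]) >= target)[1]
  if (is.na(keep_n)) keep_n <- length(order_all)
  sort(order_all[seq_len(keep_n)])
}

# subset an engine state to the given cluster ids, compacting indices
.subset_state <- function(state, cluster_ids) {
  rows <- which(state$cluster %in% cluster_ids)
  remap <- integer(length(state$parent))
  remap[rows] <- seq_along(rows)
  cl_map <- integer(max(state$cluster))
  cl_map[sort(unique(state$cluster[rows]))] <- seq_along(cluster_ids)
  p <- state$parent[rows]
  new_parent <- integer(length(p)) # roots keep parent 0
  nz <- p != 0L
  new_parent[nz] <- remap[p[nz]]
  list(parent = new_parent,
       birth_gen = state$birth_gen[rows],
       last_repro_gen = state$last_repro_gen[rows],
       shell = state$shell[rows],
       links_used = state$links_used[rows],
       cluster = cl_map[state$cluster[rows]],
       alive = state$alive[rows],
       p_death = state$p_death[rows])
}

#' Simulate evolution of the death probability across transfers
#'
#' Starting from a single founder with a low, heritable death probability,
#' each transfer grows the population (with per-generation mutation of the
#' death probability) until the growth budget of new cells is met, then
#' applies [settle_select()] and discards the unselected clusters. The
#' generation clock runs continuously across transfers.
#'
#' @param config An [evo_config()].
#' @return An object of class `evo_trajectory`: a data frame `trajectory`
#'   with one row per completed transfer (`transfer`, `mean_p_death`
#'   cell-weighted over living cells, `clusters`, `living_cells`,
#'   `generations` used in the growth phase), plus `extinct` and `config`.
#' @examples
#' cfg <- evo_config(transfers = 3, growth_budget = 2^8, seed = 1)
#' simulate_evolution(cfg)$trajectory$mean_p_death
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "evo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- .founder_state(config$initial_p_death)
  gen0 <- 0L
  traj <- vector("list", config$transfers)
  extinct <- FALSE
  for (tr in seq_len(config$transfers)) {
    res <- .engine_run(state,
                       generations = config$max_gens_per_transfer,
                       budget = config$growth_budget,
                       degree_cap = if (is.null(config$degree_cap)) -1L else config$degree_cap,
                       volume_limited = config$volume_limited,
                       death_delay = config$death_delay,
                       biased_severance = config$severance == "branch_size_biased",
                       mutation_prob = config$mutation_prob,
                       p_min = config$mutation_range[1],
                       p_max = config$mutation_range[2],
                       gen0 = gen0)
    gens_used <- nrow(res$stats)
    gen0 <- gen0 + gens_used
    if (res$extinct) {
      traj[[tr]] <- data.frame(transfer = tr, mean_p_death = NA_real_,
                               clusters = 0L, living_cells = 0,
                               generations = gens_used)
      extinct <- TRUE
      break
    }
    cs <- .engine_cluster_stats(res$state)
    keep <- settle_select(cs$diameter, cs$living, config$selection_fraction,
                          config$weighting)
    state <- .subset_state(res$state, cs$cluster[keep])
    live <- state$alive
    traj[[tr]] <- data.frame(
      transfer = tr,
      mean_p_death = stats::weighted.mean(state$p_death, live),
      clusters = length(keep),
      living_cells = sum(live),
      generations = gens_used)
    if (sum(live) == 0) { extinct <- TRUE; break }
  }
  structure(list(trajectory = do.call(rbind, traj[!vapply(traj, is.null, TRUE)]),
                 final_state = state, extinct = extinct, config = config),
            class = "evo_trajectory")
}

#' @export
print.evo_trajectory <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("<evo_trajectory> %d transfers%s; mean p_death %.4f -> %.4f\n",
              n, if (x$extinct) " (extinct)" else "",
              x$trajectory$mean_p_death[1], x$trajectory$mean_p_death[n]))
  invisible(x)
}
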