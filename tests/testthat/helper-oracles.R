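# Independent oracles used across the suite. These deliberately avoid the
# package's own data structures and algorithms wherever possible: distances
# come from root-paths, sizes from direct counting, and optima from naive
# exhaustive recursion.

# path of ids from a cell up to the root
.path_to_root <- function(cells, id) {
  path <- id
  repeat {
    p <- cells$parent[match(id, cells$id)]
    if (is.na(p)) return(path)
    path <- c(path, p)
    id <- p
  }
}

# tree diameter by brute force over all pairs of cells (small trees only)
brute_diameter <- function(cluster) {
  cells <- cluster$cells
  n <- nrow(cells)
  if (n == 1) return(0L)
  paths <- lapply(cells$id, .path_to_root, cells = cells)
  best <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      common <- max(match(paths[[i]], paths[[j]], nomatch = 0L))
      # distance = steps from i to LCA + steps from j to LCA
      lca <- paths[[j]][common]
      d <- (match(lca, paths[[i]]) - 1L) + (common - 1L)
      best <- max(best, d)
    }
  }
  best
}

# count cells on the far side of each of a cell's links, by direct set
# splitting (no subtree-size bookkeeping)
brute_branch_sizes <- function(cluster, id) {
  cells <- cluster$cells
  kids <- cells$id[!is.na(cells$parent) & cells$parent == id]
  desc <- function(r) { # r plus all descendants, by repeated scans
    got <- r
    repeat {
      more <- cells$id[!is.na(cells$parent) & cells$parent %in% got &
                         !cells$id %in% got]
      if (!length(more)) return(got)
      got <- c(got, more)
    }
  }
  sizes <- vapply(kids, function(k) length(desc(k)), integer(1))
  p <- cells$parent[match(id, cells$id)]
  if (!is.na(p)) sizes <- c(parent = nrow(cells) - length(desc(id)), sizes)
  sizes
}

# naive exhaustive optimum of the division recursion: no memoization, every
# division tree enumerated
brute_dp_value <- function(n, t, T, s, g, n_max, fitness = "clusters") {
  if (t == T) return(if (fitness == "clusters") s(n) else n * s(n))
  gc <- function(m) min(g(m), n_max)
  best <- -Inf
  for (a in 0:(n %/% 2)) {
    v <- if (a == 0) {
      brute_dp_value(gc(n), t + 1, T, s, g, n_max, fitness)
    } else {
      brute_dp_value(gc(a), t + 1, T, s, g, n_max, fitness) +
        brute_dp_value(gc(n - a), t + 1, T, s, g, n_max, fitness)
    }
    best <- max(best, v)
  }
  best
}

# shell tally of a cluster, padded to length k_max + 1
shell_tally <- function(cluster, k_max) {
  tabulate(cluster$cells$shell + 1L, nbins = k_max + 1L)
}

# engine state -> per-cluster living-cell counts (direct tabulation)
state_living_by_cluster <- function(state) {
  as.vector(rowsum(as.numeric(state$alive), state$cluster))
}
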