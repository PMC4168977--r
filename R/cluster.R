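#' Growth constraints for a snowflake cluster
#'
#' Bundles the two geometric limits on cell reproduction: the degree cap
#' (maximum number of physical attachments a cell can carry, the parent link
#' included) and the shell-volume constraint (a new cell can only be born if
#' there is room inside the volume enclosed by every shell from its own
#' outward). Severing a link frees the attachment site on both of its
#' endpoints (see [sever()]).
#'
#' @param degree_cap Positive integer `>= 2`, or `NULL` for unlimited
#'   attachments.
#' @param volume_limited Logical; enforce shell capacities?
#' @param shell_capacity_fn Function mapping shell index `k` to the maximum
#'   cumulative number of cells in shells `0..k`. Defaults to
#'   [shell_capacity()].
#' @return An object of class `growth_constraints`.
#' @export
growth_constraints <- function(degree_cap = NULL, volume_limited = FALSE,
                               shell_capacity_fn = shell_capacity) {
  if (!is.null(degree_cap)) {
    degree_cap <- as.integer(degree_cap)
    if (degree_cap < 2) stop("`degree_cap` must be >= 2 or NULL")
  }
  structure(list(degree_cap = degree_cap,
                 volume_limited = isTRUE(volume_limited),
                 shell_capacity_fn = shell_capacity_fn),
            class = "growth_constraints")
}

#' Found a new cluster from a single cell
#'
#' Creates a cluster containing one living cell, the founder (Node 0), in
#' shell 0 at the given generation.
#'
#' @param gen0 Integer founding generation (usually 0).
#' @return An object of class `snowflake_cluster`: a list with a `cells`
#'   data frame (columns `id`, `parent`, `birth_gen`, `last_repro_gen`,
#'   `alive`, `shell`, `links_used`), the `root_id` and the `founding_gen`.
#' @examples
#' cl <- new_founder(0)
#' n_cells(cl) # 1
#' @export
new_founder <- function(gen0 = 0L) {
  cells <- data.frame(id = 1L, parent = NA_integer_,
                      birth_gen = as.integer(gen0),
                      last_repro_gen = as.integer(gen0),
                      alive = TRUE, shell = 0L, links_used = 0L)
  structure(list(cells = cells, root_id = 1L, founding_gen = as.integer(gen0)),
            class = "snowflake_cluster")
}

#' @export
print.snowflake_cluster <- function(x, ...) {
  cat(sprintf("<snowflake_cluster> %d cells (%d living), root %d, founded gen %d\n",
              nrow(x$cells), sum(x$cells$alive), x$root_id, x$founding_gen))
  invisible(x)
}

#' Number of cells in a cluster
#'
#' @param cluster A `snowflake_cluster`.
#' @param living_only Count only living cells?
#' @return Integer cell count.
#' @export
n_cells <- function(cluster, living_only = FALSE) {
  if (living_only) sum(cluster$cells$alive) else nrow(cluster$cells)
}

# index of each cell's row, id-keyed lookups
.row_of <- function(cluster, ids) match(ids, cluster$cells$id)

#' One synchronized round of cell reproduction
#'
#' Every cell that (1) is alive, (2) has not reached the degree cap and
#' (3) has room in the next shell gains exactly one new living child with
#' `birth_gen = gen`. Eligibility is evaluated against the pre-step state
#' (all cells bud simultaneously). When the volume constraint leaves room
#' for only some of the would-be births into a shell, older cells (smaller
#' id) take priority; blocked cells stay alive and simply do not reproduce.
#'
#' @param cluster A `snowflake_cluster`.
#' @param constraints A [growth_constraints()] object.
#' @param gen Integer generation of this step; must exceed every `birth_gen`
#'   already in the cluster.
#' @return The updated cluster.
#' @examples
#' cl <- new_founder(0)
#' for (g in 1:3) cl <- grow_step(cl, gen = g)
#' n_cells(cl) # 8: the unconstrained tree doubles every round
#' @export
grow_step <- function(cluster, constraints = growth_constraints(), gen) {
  cells <- cluster$cells
  gen <- as.integer(gen)
  if (gen <= max(cells$birth_gen)) {
    stop("`gen` must be greater than every birth generation in the cluster")
  }
  cap <- constraints$degree_cap
  eligible <- cells$alive
  if (!is.null(cap)) eligible <- eligible & cells$links_used < cap

  if (constraints$volume_limited && any(eligible)) {
    # cumulative occupancy per shell, including room already consumed by
    # this round's births into the same or interior shells
    max_shell <- max(cells$shell) + 1L
    occ_by_shell <- tabulate(cells$shell + 1L, nbins = max_shell + 1L)
    slack <- pmax(constraints$shell_capacity_fn(0:max_shell) - cumsum(occ_by_shell), 0)
    # a birth into shell s consumes one unit of slack at every shell k >= s
    granted <- logical(nrow(cells))
    idx <- which(eligible)
    idx <- idx[order(cells$shell[idx], cells$id[idx])] # inner shells, older cells first
    for (i in idx) {
      s <- cells$shell[i] + 1L
      if (min(slack[(s + 1L):(max_shell + 1L)]) >= 1) {
        granted[i] <- TRUE
        slack[(s + 1L):(max_shell + 1L)] <- slack[(s + 1L):(max_shell + 1L)] - 1
      }
    }
    eligible <- granted
  }

  parents <- which(eligible)
  if (length(parents)) {
    new_ids <- max(cells$id) + seq_along(parents)
    kids <- data.frame(id = as.integer(new_ids),
                       parent = cells$id[parents],
                       birth_gen = gen, last_repro_gen = gen,
                       alive = TRUE, shell = cells$shell[parents] + 1L,
                       links_used = 1L)
    cells$links_used[parents] <- cells$links_used[parents] + 1L
    cells$last_repro_gen[parents] <- gen
    cells <- rbind(cells, kids)
  }
  cluster$cells <- cells
  cluster
}

#' Grow a cluster for several rounds
#'
#' Convenience wrapper: applies [grow_step()] for generations
#' `founding_gen + 1, ..., founding_gen + t`.
#'
#' @param cluster A `snowflake_cluster` (default a fresh founder).
#' @param t Number of rounds of reproduction.
#' @param constraints A [growth_constraints()] object.
#' @return The grown cluster.
#' @export
grow <- function(cluster = new_founder(0), t, constraints = growth_constraints()) {
  g0 <- max(cluster$cells$birth_gen)
  for (g in seq_len(t)) cluster <- grow_step(cluster, constraints, gen = g0 + g)
  cluster
}

#' Sizes of the subtree hanging under every cell
#'
#' Internal: vector of subtree sizes (cell itself plus all descendants),
#' aligned with the rows of `cluster$cells`. Computed in one pass from the
#' deepest shell inward, so it costs O(n) regardless of tree shape.
#'
#' @noRd
subtree_sizes <- function(cluster) {
  cells <- cluster$cells
  size <- rep(1L, nrow(cells))
  if (nrow(cells) > 1) {
    parent_row <- .row_of(cluster, cells$parent)
    for (d in sort(unique(cells$shell), decreasing = TRUE)) {
      at <- which(cells$shell == d & !is.na(parent_row))
      if (length(at)) {
        add <- rowsum(size[at], parent_row[at])
        rows <- as.integer(rownames(add))
        size[rows] <- size[rows] + as.integer(add)
      }
    }
  }
  size
}

#' Branch sizes around a cell
#'
#' For each link incident to a cell (its parent link, if any, and one link
#' per child), returns the number of cells on the far side of that link.
#' The sizes always sum to `n_cells(cluster) - 1`. For the root of a tree
#' these are the sizes of its branches; the oldest branch of an uncapped
#' tree is exactly half of the whole tree.
#'
#' @param cluster A `snowflake_cluster`.
#' @param cell_id Id of the focal cell.
#' @return A data frame with one row per incident link: `neighbor` (the id
#'   across the link), `is_parent_link`, and `branch_size`.
#' @examples
#' cl <- grow(t = 3)
#' branch_partition(cl, cl$root_id)$branch_size # 4 2 1
#' @export
branch_partition <- function(cluster, cell_id) {
  row <- .row_of(cluster, cell_id)
  if (is.na(row)) stop("unknown cell id: ", cell_id)
  cells <- cluster$cells
  n <- nrow(cells)
  size <- subtree_sizes(cluster)
  kid_rows <- which(!is.na(cells$parent) & cells$parent == cell_id)
  out <- data.frame(neighbor = cells$id[kid_rows],
                    is_parent_link = rep(FALSE, length(kid_rows)),
                    branch_size = size[kid_rows])
  if (!is.na(cells$parent[row])) {
    out <- rbind(data.frame(neighbor = cells$parent[row],
                            is_parent_link = TRUE,
                            branch_size = n - size[row]),
                 out)
  }
  out
}

#' Diameter of a cluster
#'
#' Number of edges on the longest path between any two cells. Dead cells
#' remain attached and count. Used as the settling-speed proxy in the
#' evolutionary simulation. The unconstrained tree after `t` rounds has
#' diameter `2t - 1` for `t >= 1`: only the lineage of first-born daughters
#' reaches depth `t`, and the deepest cell in any other branch of the root
#' sits at depth `t - 1`.
#'
#' @param cluster A `snowflake_cluster`.
#' @return Integer diameter (0 for a single cell).
#' @examples
#' diameter(grow(t = 3)) # 5
#' @export
diameter <- function(cluster) {
  cells <- cluster$cells
  n <- nrow(cells)
  if (n == 1) return(0L)
  parent_row <- .row_of(cluster, cells$parent)
  # height below each cell, and the two tallest child-heights through it
  best1 <- integer(n) # tallest downward path (edges) from each cell
  best2 <- integer(n) # second tallest via a different child
  for (d in sort(unique(cells$shell), decreasing = TRUE)) {
    at <- which(cells$shell == d & !is.na(parent_row))
    for (i in at) {
      p <- parent_row[i]
      h <- best1[i] + 1L
      if (h > best1[p]) { best2[p] <- best1[p]; best1[p] <- h }
      else if (h > best2[p]) best2[p] <- h
    }
  }
  max(best1 + best2)
}

#' Validate the structural invariants of a cluster
#'
#' Checks that the parent/child relation forms a single connected tree
#' (exactly one root, `n - 1` edges, every cell reachable from the root),
#' that child shells are parent shell + 1 with the root in shell 0, and that
#' `links_used` never exceeds the degree cap if one is supplied.
#'
#' @param cluster A `snowflake_cluster`.
#' @param degree_cap Optional cap to check `links_used` against.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_cluster <- function(cluster, degree_cap = NULL) {
  cells <- cluster$cells
  roots <- which(is.na(cells$parent))
  if (length(roots) != 1) stop("cluster must have exactly one root")
  if (cells$id[roots] != cluster$root_id) stop("root_id does not match the parentless cell")
  if (cells$shell[roots] != 0) stop("root must be in shell 0")
  parent_row <- .row_of(cluster, cells$parent)
  if (any(is.na(parent_row[-roots]))) stop("dangling parent reference")
  if (any(cells$shell[-roots] != cells$shell[parent_row[-roots]] + 1L)) {
    stop("child shell must equal parent shell + 1")
  }
  # shell = depth from root plus acyclicity implies connectedness for n-1 edges
  if (anyDuplicated(cells$id)) stop("duplicated cell ids")
  if (!is.null(degree_cap) && any(cells$links_used > degree_cap)) {
    stop("links_used exceeds the degree cap")
  }
  invisible(TRUE)
}
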