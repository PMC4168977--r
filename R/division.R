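#' Severance mode for death-triggered cluster division
#'
#' When a cell dies, one of its physical attachments is severed and the
#' cluster splits in two. The mode combines the rule for picking which cell
#' dies with the rule for picking which of its links breaks.
#'
#' @param victim_rule `"uniform_random_cell"` (every living cell equally
#'   likely) or `"oldest_cell"` (the cell with the smallest birth generation,
#'   i.e. Node 0 while it lives).
#' @param link_rule `"uniform_link"` (each incident link equally likely) or
#'   `"branch_size_biased"` (probability proportional to the number of cells
#'   on the far side of the link: bigger branches put more strain on their
#'   attachment and break more easily).
#' @return An object of class `severance_mode`.
#' @export
severance_mode <- function(victim_rule = c("uniform_random_cell", "oldest_cell"),
                           link_rule = c("branch_size_biased", "uniform_link")) {
  structure(list(victim_rule = match.arg(victim_rule),
                 link_rule = match.arg(link_rule)),
            class = "severance_mode")
}

#' Sever one link of a cluster
#'
#' Breaking any single mother-daughter attachment splits the lineage tree
#' into exactly two connected clusters. The fragment on the child side is
#' re-rooted at the severed child: its parent becomes none and all shells in
#' the fragment are recomputed relative to the new root. Dead cells travel
#' with whichever fragment contains them. Breaking the link frees the
#' attachment site on both endpoints, so a degree-saturated survivor can bud
#' again and start a new branch -- the mechanism by which cell death lets
#' degree-capped populations keep growing.
#'
#' @param cluster A `snowflake_cluster`.
#' @param link Length-2 vector `c(parent_id, child_id)` naming an existing
#'   edge.
#' @return A list of class `split_result`: `fragment_a` (the piece keeping
#'   the original root), `fragment_b` (re-rooted at the severed child),
#'   `severed_link`, and `smaller_fraction` = min size / parent size.
#' @examples
#' cl <- grow(t = 3)
#' sp <- sever(cl, c(cl$root_id, 2L)) # cut the oldest branch: 4 + 4 cells
#' sp$smaller_fraction # 0.5
#' @export
sever <- function(cluster, link) {
  parent_id <- link[[1]]; child_id <- link[[2]]
  cells <- cluster$cells
  crow <- .row_of(cluster, child_id)
  if (is.na(crow) || is.na(cells$parent[crow]) || cells$parent[crow] != parent_id) {
    stop(sprintf("no link (%s -> %s) in cluster", parent_id, child_id))
  }
  # collect the severed subtree by walking shells outward from the child
  in_b <- logical(nrow(cells))
  in_b[crow] <- TRUE
  ids_b <- cells$id[crow]
  frontier <- cells$id[crow]
  repeat {
    nxt <- which(!is.na(cells$parent) & cells$parent %in% frontier & !in_b)
    if (!length(nxt)) break
    in_b[nxt] <- TRUE
    frontier <- cells$id[nxt]
  }
  # breaking the link frees the attachment site on both endpoints, so a
  # saturated survivor can bud again and start a new branch
  cells$links_used[.row_of(cluster, parent_id)] <-
    cells$links_used[.row_of(cluster, parent_id)] - 1L
  cells$links_used[crow] <- cells$links_used[crow] - 1L
  cells_b <- cells[in_b, , drop = FALSE]
  cells_b$shell <- cells_b$shell - cells$shell[crow]
  cells_b$parent[cells_b$id == child_id] <- NA_integer_
  cells_a <- cells[!in_b, , drop = FALSE]

  frag_a <- structure(list(cells = cells_a, root_id = cluster$root_id,
                           founding_gen = cluster$founding_gen),
                      class = "snowflake_cluster")
  frag_b <- structure(list(cells = cells_b, root_id = child_id,
                           founding_gen = cells$birth_gen[crow]),
                      class = "snowflake_cluster")
  n <- nrow(cells)
  structure(list(fragment_a = frag_a, fragment_b = frag_b,
                 severed_link = c(parent_id = parent_id, child_id = child_id),
                 smaller_fraction = min(nrow(cells_a), nrow(cells_b)) / n),
            class = "split_result")
}

#' Kill one cell and sever one of its links
#'
#' Implements apoptosis-driven cluster division: a victim is chosen among
#' the living cells by the mode's victim rule, marked dead (it stays
#' attached, occupies shell space and never reproduces again), and one of
#' its incident links is severed by the mode's link rule. A newborn leaf
#' victim necessarily yields a one-dead-cell fragment through its one and
#' only link.
#'
#' @param cluster A `snowflake_cluster` with at least one living cell.
#' @param mode A [severance_mode()].
#' @return A `split_result` as in [sever()], with the victim id attached as
#'   `victim`. For a single-cell cluster the result is degenerate: the cell
#'   dies, nothing is severed, and `fragment_b` is `NULL`.
#' @export
death_and_sever <- function(cluster, mode = severance_mode()) {
  cells <- cluster$cells
  living <- which(cells$alive)
  if (!length(living)) stop("cluster has no living cells")
  victim_row <- switch(mode$victim_rule,
    uniform_random_cell = living[sample.int(length(living), 1L)],
    oldest_cell = living[which.min(cells$birth_gen[living])])
  victim_id <- cells$id[victim_row]
  cluster$cells$alive[victim_row] <- FALSE
  if (nrow(cells) == 1L) {
    return(structure(list(fragment_a = cluster, fragment_b = NULL,
                          severed_link = NULL, smaller_fraction = NA_real_,
                          victim = victim_id),
                     class = "split_result"))
  }
  links <- branch_partition(cluster, victim_id)
  w <- switch(mode$link_rule,
    uniform_link = rep(1, nrow(links)),
    branch_size_biased = links$branch_size)
  pick <- sample.int(nrow(links), 1L, prob = w)
  link <- if (links$is_parent_link[pick]) c(links$neighbor[pick], victim_id)
          else c(victim_id, links$neighbor[pick])
  out <- sever(cluster, link)
  out$victim <- victim_id
  out
}

# deterministic unconstrained tree at generation t (degree cap optional),
# grown without volume limits; memoless helper for the enumeration oracle
.analytic_tree <- function(t, degree_cap = NULL) {
  cons <- growth_constraints(degree_cap = degree_cap, volume_limited = FALSE)
  grow(new_founder(0), t, cons)
}

#' Expected smaller-offspring fraction under one death
#'
#' Exact enumeration, on the deterministic unconstrained tree after `t`
#' rounds of reproduction, of E[min(s, n - s)] / n where `s` is the size of
#' the severed branch: every (victim, link) outcome is weighted by its
#' probability under the mode. No sampling is involved.
#'
#' @param t Rounds of reproduction (`>= 1`).
#' @param degree_cap Integer cap `>= 2` or `NULL` for the uncapped tree.
#' @param mode A [severance_mode()].
#' @return The expected size of the smaller offspring as a fraction of the
#'   parent cluster, a value in (0, 1/2].
#' @examples
#' expected_smaller_fraction(3, NULL,
#'   severance_mode("oldest_cell", "uniform_link")) # 7/24
#' @export
expected_smaller_fraction <- function(t, degree_cap = NULL, mode = severance_mode()) {
  stopifnot(t >= 1)
  if (mode$victim_rule == "oldest_cell") {
    # only the root's branches matter; sizes come from the branch series
    f <- branch_series(degree_cap, t)
    ages <- (t - 1):0
    ages <- ages[seq_len(if (is.null(degree_cap)) t else min(degree_cap, t))]
    sizes <- f[ages + 1]
    n <- 1 + sum(sizes)
    w <- switch(mode$link_rule,
      uniform_link = rep(1, length(sizes)),
      branch_size_biased = sizes)
    return(sum(w * pmin(sizes, n - sizes)) / (sum(w) * n))
  }
  # uniform random victim: enumerate every cell's incident links
  cl <- .analytic_tree(t, degree_cap)
  cells <- cl$cells
  n <- nrow(cells)
  size <- subtree_sizes(cl)
  parent_row <- .row_of(cl, cells$parent)
  edge_child <- which(!is.na(parent_row)) # one edge per non-root cell
  s_child <- size[edge_child]             # branch size seen from the parent
  m_edge <- pmin(s_child, n - s_child)    # min split, same from both ends
  if (mode$link_rule == "uniform_link") {
    num <- numeric(n); den <- numeric(n)  # per-victim sum of mins, link count
    add <- rowsum(cbind(m_edge, 1), parent_row[edge_child])
    rows <- as.integer(rownames(add))
    num[rows] <- add[, 1]; den[rows] <- add[, 2]
    num[edge_child] <- num[edge_child] + m_edge
    den[edge_child] <- den[edge_child] + 1
    mean(num / den) / n
  } else {
    # weight of an edge from a given victim = its branch size from that side
    num <- numeric(n); den <- numeric(n)
    add <- rowsum(cbind(s_child * m_edge, s_child), parent_row[edge_child])
    rows <- as.integer(rownames(add))
    num[rows] <- add[, 1]; den[rows] <- add[, 2]
    num[edge_child] <- num[edge_child] + (n - s_child) * m_edge
    den[edge_child] <- den[edge_child] + (n - s_child)
    mean(num / den) / n
  }
}

#' Limit of the biased smaller-offspring fraction
#'
#' For the uncapped tree under oldest-cell death with branch-size-biased
#' severance, the expected smaller-offspring fraction at generation `t` has
#' the closed form `(4^t - 1) / (3 (2^t - 1) 2^t)`, which approaches 1/3 as
#' `t` grows. Its uniform-link analogue `(2^t - 1) / (t 2^t)` decays to 0.
#'
#' @param t Optional generation; if supplied the closed-form value at `t`
#'   is returned, otherwise the limit 1/3.
#' @param link_rule `"branch_size_biased"` (default) or `"uniform_link"`.
#' @return The closed-form expected fraction (or its limit).
#' @examples
#' asymptotic_biased_fraction()      # 1/3
#' asymptotic_biased_fraction(3)     # 0.375
#' @export
asymptotic_biased_fraction <- function(t = NULL,
                                       link_rule = c("branch_size_biased", "uniform_link")) {
  link_rule <- match.arg(link_rule)
  if (is.null(t)) {
    return(if (link_rule == "branch_size_biased") 1 / 3 else 0)
  }
  stopifnot(t >= 1)
  if (link_rule == "branch_size_biased") {
    (4^t - 1) / (3 * (2^t - 1) * 2^t)
  } else {
    (2^t - 1) / (t * 2^t)
  }
}

#' Enumerated severance outcome distribution
#'
#' Full outcome table for one death on the deterministic unconstrained tree:
#' every (victim, link) pair with its probability and the resulting smaller
#' fragment size. Probabilities sum to one; mainly useful for checking the
#' enumeration underlying [expected_smaller_fraction()].
#'
#' @param t Rounds of reproduction.
#' @param degree_cap Integer cap or `NULL`.
#' @param mode A [severance_mode()].
#' @return Data frame with columns `victim`, `neighbor`, `prob`,
#'   `smaller_size`.
#' @export
severance_outcomes <- function(t, degree_cap = NULL, mode = severance_mode()) {
  cl <- .analytic_tree(t, degree_cap)
  cells <- cl$cells
  n <- nrow(cells)
  victims <- switch(mode$victim_rule,
    uniform_random_cell = cells$id,
    oldest_cell = cells$id[which.min(cells$birth_gen)])
  p_victim <- rep(1 / length(victims), length(victims))
  out <- lapply(seq_along(victims), function(i) {
    links <- branch_partition(cl, victims[i])
    w <- switch(mode$link_rule,
      uniform_link = rep(1, nrow(links)),
      branch_size_biased = links$branch_size)
    data.frame(victim = victims[i], neighbor = links$neighbor,
               prob = p_victim[i] * w / sum(w),
               smaller_size = pmin(links$branch_size, n - links$branch_size))
  })
  do.call(rbind, out)
}
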