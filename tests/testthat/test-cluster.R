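test_that("a founder is a single living root cell and unconstrained growth doubles", {
  cl <- new_founder(0)
  expect_equal(n_cells(cl), 1)
  expect_equal(sum(!is.na(cl$cells$parent)), 0) # 0 edges
  expect_true(cl$cells$alive)
  expect_equal(cl$cells$shell, 0L)

  for (t in 1:6) {
    cl <- grow_step(cl, gen = t)
    expect_equal(n_cells(cl), 2^t)
    expect_equal(sum(!is.na(cl$cells$parent)), 2^t - 1) # tree: n - 1 edges
    validate_cluster(cl)
  }
})

test_that("uncapped shell counts are binomial coefficients", {
  for (t in c(3, 5, 6)) {
    cl <- grow(t = t)
    expect_equal(shell_tally(cl, t), choose(t, 0:t))
  }
})

test_that("degree cap 3: root buds in generations 1-3, others in the 2 after birth", {
  cl <- grow(t = 6, constraints = growth_constraints(3))
  cells <- cl$cells
  root_kids <- cells$birth_gen[!is.na(cells$parent) & cells$parent == cl$root_id]
  expect_equal(sort(root_kids), 1:3)
  # every non-root cell's children arrive in the 2 generations after birth
  for (id in cells$id[cells$id != cl$root_id]) {
    b <- cells$birth_gen[match(id, cells$id)]
    kid_gens <- cells$birth_gen[!is.na(cells$parent) & cells$parent == id]
    expect_true(all(kid_gens %in% (b + 1:2)))
  }
  expect_true(all(cells$links_used <= 3))
  validate_cluster(cl, degree_cap = 3)
})

test_that("degree-capped growth never exceeds the cap and matches the size series", {
  for (d in c(2, 3, 4, 5)) {
    cl <- grow(t = 7, constraints = growth_constraints(d))
    expect_true(all(cl$cells$links_used <= d))
    expect_equal(n_cells(cl), total_size(d, 7))
  }
})

test_that("degree cap 2 grows a filament", {
  cl <- grow(t = 8, constraints = growth_constraints(2))
  expect_true(all(cl$cells$links_used <= 2))
  expect_equal(diameter(cl), n_cells(cl) - 1L) # a path
})

test_that("dead cells never gain children", {
  cl <- grow(t = 2)
  victim <- cl$cells$id[2]
  cl$cells$alive[2] <- FALSE
  n_kids_before <- sum(!is.na(cl$cells$parent) & cl$cells$parent == victim)
  cl <- grow_step(cl, gen = 3)
  n_kids_after <- sum(!is.na(cl$cells$parent) & cl$cells$parent == victim)
  expect_equal(n_kids_after, n_kids_before)
})

test_that("branch_partition returns far-side counts that sum to n - 1", {
  cl <- grow(t = 3)
  bp <- branch_partition(cl, cl$root_id)
  expect_equal(sort(bp$branch_size, decreasing = TRUE), c(4, 2, 1))
  expect_equal(sum(bp$branch_size), n_cells(cl) - 1)

  # a leaf: single entry of size n - 1 through the parent link
  leaf <- cl$cells$id[which.max(cl$cells$id)]
  bp_leaf <- branch_partition(cl, leaf)
  expect_equal(nrow(bp_leaf), 1)
  expect_true(bp_leaf$is_parent_link)
  expect_equal(bp_leaf$branch_size, n_cells(cl) - 1)

  expect_error(branch_partition(cl, 999L), "unknown cell")
})

test_that("branch_partition agrees with brute-force set splitting", {
  cl <- grow(t = 5, constraints = growth_constraints(4))
  for (id in sample(cl$cells$id, 8)) {
    bp <- branch_partition(cl, id)
    expect_equal(sort(bp$branch_size), sort(unname(brute_branch_sizes(cl, id))))
  }
})

test_that("the oldest branch of an uncapped tree is half the tree, the next a fourth", {
  for (t in 3:7) {
    cl <- grow(t = t)
    bp <- branch_partition(cl, cl$root_id)
    sizes <- sort(bp$branch_size, decreasing = TRUE)
    n <- n_cells(cl)
    expect_equal(sizes[1], n / 2)
    expect_equal(sizes[2], n / 4)
  }
})

test_that("diameter matches the all-pairs brute force", {
  expect_equal(diameter(new_founder(0)), 0L)
  for (cons in list(growth_constraints(), growth_constraints(3),
                    growth_constraints(2))) {
    for (t in c(2, 4, 5)) {
      cl <- grow(t = t, constraints = cons)
      expect_equal(diameter(cl), brute_diameter(cl))
    }
  }
  # one cell reaches depth t, no other root branch passes depth t - 1
  expect_equal(diameter(grow(t = 5)), 9L)
})

test_that("volume-limited growth respects shell capacities and blocks politely", {
  cons <- growth_constraints(volume_limited = TRUE)
  cl <- grow(t = 13, constraints = cons)
  occ <- cumsum(shell_tally(cl, 13))
  expect_true(all(occ <= shell_capacity(0:13)))
  expect_lt(n_cells(cl), 2^13) # growth was actually blocked
  # unconstrained totals up to generation 11 are untouched
  cl11 <- grow(t = 11, constraints = cons)
  expect_equal(n_cells(cl11), 2^11)
})

test_that("grow_step refuses a stale generation counter", {
  cl <- grow(t = 2)
  expect_error(grow_step(cl, gen = 2), "greater than")
})
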