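m_ou <- severance_mode("oldest_cell", "uniform_link")
m_ob <- severance_mode("oldest_cell", "branch_size_biased")
m_ru <- severance_mode("uniform_random_cell", "uniform_link")
m_rb <- severance_mode("uniform_random_cell", "branch_size_biased")

test_that("sever splits a cluster into two connected re-rooted fragments", {
  # 2-cell cluster through its only link
  cl2 <- grow(t = 1)
  sp <- sever(cl2, c(1L, 2L))
  expect_equal(n_cells(sp$fragment_a), 1)
  expect_equal(n_cells(sp$fragment_b), 1)
  expect_equal(sp$smaller_fraction, 0.5)

  cl <- grow(t = 3)
  # the root's oldest branch is half of the tree
  sp <- sever(cl, c(cl$root_id, 2L))
  expect_equal(n_cells(sp$fragment_a), 4)
  expect_equal(n_cells(sp$fragment_b), 4)
  validate_cluster(sp$fragment_a)
  validate_cluster(sp$fragment_b)
  expect_true(is.na(sp$fragment_b$cells$parent[sp$fragment_b$cells$id == 2L]))
  expect_equal(min(sp$fragment_b$cells$shell), 0) # re-rooted shells

  # a leaf link strips a single cell
  leaf <- cl$cells$id[which.max(cl$cells$id)]
  sp_leaf <- sever(cl, c(cl$cells$parent[match(leaf, cl$cells$id)], leaf))
  expect_equal(sort(c(n_cells(sp_leaf$fragment_a), n_cells(sp_leaf$fragment_b))),
               c(1, 7))
  expect_error(sever(cl, c(2L, 3L)), "no link")
})

test_that("severed fragments conserve cells and keep their dead", {
  set.seed(11)
  cl <- grow(t = 5, constraints = growth_constraints(4))
  cl$cells$alive[sample(n_cells(cl), 10)] <- FALSE
  n_dead <- sum(!cl$cells$alive)
  bp <- branch_partition(cl, cl$root_id)
  sp <- sever(cl, c(cl$root_id, bp$neighbor[1]))
  expect_equal(n_cells(sp$fragment_a) + n_cells(sp$fragment_b), n_cells(cl))
  expect_equal(sum(!sp$fragment_a$cells$alive) + sum(!sp$fragment_b$cells$alive),
               n_dead)
})

test_that("death_and_sever follows the victim and link rules", {
  set.seed(2)
  # the oldest-cell rule always kills the root while it lives
  sp <- death_and_sever(grow(t = 3), m_ou)
  expect_equal(sp$victim, 1L)
  frag_with_victim <- if (1L %in% sp$fragment_a$cells$id) sp$fragment_a else sp$fragment_b
  expect_false(frag_with_victim$cells$alive[frag_with_victim$cells$id == 1L])

  # outcomes always partition the cluster; victims always die
  for (mode in list(m_ou, m_ob, m_ru, m_rb)) {
    for (rep in 1:5) {
      cl <- grow(t = 3)
      sp <- death_and_sever(cl, mode)
      expect_equal(n_cells(sp$fragment_a) + n_cells(sp$fragment_b), 8)
      expect_lte(sp$smaller_fraction, 0.5)
    }
  }

  # a lone cell dies without severance
  sp1 <- death_and_sever(new_founder(0), m_ru)
  expect_null(sp1$fragment_b)
  expect_false(sp1$fragment_a$cells$alive)
})

test_that("a newborn leaf victim yields a one-dead-cell fragment", {
  cl <- grow(t = 2)
  # force the victim by killing everything except one newborn leaf
  newborn <- cl$cells$id[cl$cells$birth_gen == 2][1]
  cl$cells$alive[cl$cells$id != newborn] <- FALSE
  set.seed(5)
  sp <- death_and_sever(cl, m_ru) # only living cell must be picked
  expect_equal(sp$victim, newborn)
  small <- if (n_cells(sp$fragment_a) == 1) sp$fragment_a else sp$fragment_b
  expect_equal(n_cells(small), 1)
  expect_false(small$cells$alive)
})

test_that("enumerated outcome probabilities sum to one", {
  for (mode in list(m_ou, m_ob, m_ru, m_rb)) {
    so <- severance_outcomes(4, NULL, mode)
    expect_equal(sum(so$prob), 1)
    so3 <- severance_outcomes(5, 3L, mode)
    expect_equal(sum(so3$prob), 1)
  }
})

test_that("expected smaller fractions reproduce the exact enumerations", {
  expect_equal(expected_smaller_fraction(3, NULL, m_ou), 7 / 24)
  expect_equal(expected_smaller_fraction(3, NULL, m_ob), 21 / 56)
  expect_equal(expected_smaller_fraction(2, NULL, m_ru), 0.3125)
  # the outcome-table route agrees with the closed computation
  for (mode in list(m_ou, m_ob, m_ru, m_rb)) {
    so <- severance_outcomes(4, NULL, mode)
    expect_equal(sum(so$prob * so$smaller_size) / 16,
                 expected_smaller_fraction(4, NULL, mode))
  }
})

test_that("closed forms for oldest-cell death match enumeration at every t", {
  for (t in 1:12) {
    expect_equal(expected_smaller_fraction(t, NULL, m_ob),
                 asymptotic_biased_fraction(t))
    expect_equal(expected_smaller_fraction(t, NULL, m_ou),
                 asymptotic_biased_fraction(t, "uniform_link"))
  }
  expect_equal(asymptotic_biased_fraction(1), 0.5) # a single branch halves
})

test_that("the biased fraction approaches 1/3 and the uniform fraction decays", {
  expect_equal(asymptotic_biased_fraction(), 1 / 3)
  expect_lt(abs(expected_smaller_fraction(20, NULL, m_ob) - 1 / 3), 1e-5)
  expect_lt(expected_smaller_fraction(20, NULL, m_ou), 0.05)
})

test_that("central, biased death gives more symmetric offspring", {
  for (t in 4:8) {
    f_r <- expected_smaller_fraction(t, NULL, m_ru)
    f_u <- expected_smaller_fraction(t, NULL, m_ou)
    f_b <- expected_smaller_fraction(t, NULL, m_ob)
    expect_lt(f_r, f_u)
    expect_lt(f_u, f_b)
    expect_lte(f_b, 0.5)
  }
})

test_that("degree caps give more equal offspring than uncapped trees", {
  for (t in 6:10) {
    f_none <- expected_smaller_fraction(t, NULL, m_ou)
    expect_gt(expected_smaller_fraction(t, 3L, m_ou), f_none)
    expect_gt(expected_smaller_fraction(t, 4L, m_ou), f_none)
  }
})
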