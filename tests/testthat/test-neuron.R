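test_that("branch condition detection follows threshold arithmetic", {
  b <- new_branch(1:3, c(0.4, 0.4, 0.3), threshold = 1.0)
  r <- detect_condition(b, c(1L, 2L, 3L), step = 1)
  expect_true(r$detected)
  expect_equal(r$active_weight, 1.1)

  # no active sources never detects, whatever the threshold
  r2 <- detect_condition(b, integer(0), step = 2)
  expect_false(r2$detected)

  # the boundary uses >=: a sum equal to the threshold detects
  b3 <- new_branch(1:5, rep(0.2, 5), threshold = 1.0)
  expect_true(detect_condition(b3, 1:5, step = 1)$detected)
})

test_that("bookkeeping: last_active always recorded, contributions only on detection", {
  b <- new_branch(1:4, c(0.3, 0.3, 0.2, 0.2), threshold = 1.0)
  r <- detect_condition(b, c(1L, 2L), step = 5)   # 0.6 < 1: no detection
  expect_false(r$detected)
  expect_equal(r$branch$last_active[1:2], c(5, 5))
  expect_true(all(is.na(r$branch$last_active[3:4])))
  expect_equal(r$branch$contrib, rep(0L, 4))

  r2 <- detect_condition(r$branch, 1:4, step = 6)  # 1.0 >= 1: detection
  expect_true(r2$detected)
  expect_equal(r2$branch$contrib, rep(1L, 4))
  expect_equal(r2$branch$last_active, rep(6, 4))
})

test_that("tree detection counts detecting branches against the tree threshold", {
  # 100 one-synapse branches; sources 1..100, weight 1 each
  branches <- lapply(1:100, function(i) new_branch(i, 1.0, threshold = 1.0))
  tree <- new_tree(branches, threshold = 3L, role = "basal")
  r <- detect_field(tree, c(7L, 33L, 90L), step = 1)
  expect_true(r$detected)
  expect_equal(r$detecting_branch_count, 3L)

  r2 <- detect_field(tree, c(7L, 33L), step = 2)
  expect_false(r2$detected)
  expect_equal(r2$detecting_branch_count, 2L)
})

test_that("incremental detection equals stateless brute-force on random small trees", {
  set.seed(42)
  for (i in 1:1000) {
    case <- random_tree_case()
    r <- detect_field(case$tree, case$active, step = i)
    o <- oracle_tree(case$specs, case$active, case$tree$threshold)
    expect_identical(r$detected, o$detected)
    expect_identical(r$detecting_branch_count, o$count)
    # re-evaluation after bookkeeping must not change the outcome
    r2 <- detect_field(r$tree, case$active, step = i + 1)
    expect_identical(r2$detected, o$detected)
  }
})

test_that("adding weight to an active synapse never loses a detection", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    w <- stats::runif(n, 0, 0.8)
    th <- stats::runif(1, 0.2, 1.5)
    b <- new_branch(seq_len(n), w, threshold = th, w_max = 2)
    act <- sample(seq_len(n), sample(1:n, 1))
    before <- detect_condition(b, act, step = 1)$detected
    j <- act[1]
    w2 <- w
    w2[j] <- w2[j] + stats::runif(1, 0, 0.5)
    b2 <- new_branch(seq_len(n), w2, threshold = th, w_max = 2)
    after <- detect_condition(b2, act, step = 1)$detected
    if (before) expect_true(after)
  }
})

test_that("somatic integration lets only one compartment contribute", {
  u <- new_unit(10L, new_tree(list(new_branch(1L, 1)), 1L, "basal"),
                apical = new_tree(list(new_branch(2L, 1)), 1L, "apical"))
  # sensory context present: apical contribution blocked
  u1 <- integrate_unit(u, TRUE, TRUE, TRUE, step = 1)
  expect_equal(u1$fire_mode, "basal")
  # indirect activation: basal-driven firing absent by construction
  u2 <- integrate_unit(u, FALSE, TRUE, FALSE, step = 2)
  expect_equal(u2$fire_mode, "apical")
  u3 <- integrate_unit(u, FALSE, FALSE, TRUE, step = 3)
  expect_equal(u3$fire_mode, "none")
  expect_false(u3$fired)
  # exhaustive: no flag combination yields a dual contribution
  for (bd in c(TRUE, FALSE)) for (ad in c(TRUE, FALSE))
    for (ctx in c(TRUE, FALSE)) {
      m <- integrate_unit(u, bd, ad, ctx, step = 4)$fire_mode
      expect_true(m %in% c("none", "basal", "apical"))
      if (m == "basal") expect_true(ctx)
      if (m == "apical") expect_false(ctx)
    }
})

test_that("manager synapse participates in detection like any weight by default", {
  b <- new_branch(1:2, c(0.3, 0.3), threshold = 1.0,
                  manager_source = 99L, manager_weight = 1.0)
  # manager alone reaches threshold (default convention)
  expect_true(detect_condition(b, 99L, step = 1)$detected)
  # configurable: manager alone does not count
  expect_false(detect_condition(b, 99L, step = 2,
                                manager_counts_alone = FALSE)$detected)
  # manager plus regular synapses still detects
  expect_true(detect_condition(b, c(1L, 99L), step = 3,
                               manager_counts_alone = FALSE)$detected)
})
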