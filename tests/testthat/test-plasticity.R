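cfg_default <- plasticity_config()   # delta_w 0.15, recent_window 3

test_that("gated expansion records a new condition on the branch", {
  # eight weak synapses that cannot reach threshold on their own, plus a
  # strong hippocampal-drive synapse
  b <- new_branch(1:8, rep(0.1, 8), threshold = 1.0,
                  manager_source = 99L, manager_weight = 1.0)
  expect_false(detect_condition(b, 1:8, step = 1)$detected)  # 0.8 < 1

  # manager drive active, five regular synapses recently active
  r <- detect_condition(b, c(1:5, 99L), step = 2)
  expect_true(r$detected)   # 0.5 + 1.0 over threshold
  ex <- expand_branch(r$branch, manager_active = TRUE,
                      neuron_fired_within_window = TRUE, step = 2,
                      cfg = cfg_default)
  expect_setequal(ex$report$source, 1:5)
  expect_equal(ex$report$delta, rep(0.15, 5))
  reg <- !ex$branch$is_manager
  expect_equal(ex$branch$weights[reg], c(rep(0.25, 5), rep(0.1, 3)))

  # the recently active subset now detects independent of the manager
  r2 <- detect_condition(ex$branch, 1:5, step = 3)
  expect_true(r2$detected)
  expect_equal(r2$active_weight, 1.25, tolerance = 1e-12)
})

test_that("expansion requires manager drive and the Hebbian firing gate", {
  b <- new_branch(1:8, rep(0.1, 8), threshold = 1.0,
                  manager_source = 99L, manager_weight = 1.0)
  b <- detect_condition(b, c(1:5, 99L), step = 2)$branch
  ex1 <- expand_branch(b, manager_active = FALSE,
                       neuron_fired_within_window = TRUE, step = 2,
                       cfg = cfg_default)
  expect_equal(nrow(ex1$report), 0L)
  ex2 <- expand_branch(b, manager_active = TRUE,
                       neuron_fired_within_window = FALSE, step = 2,
                       cfg = cfg_default)
  expect_equal(nrow(ex2$report), 0L)
})

test_that("frozen plasticity refuses expansion with a dedicated signal", {
  b <- new_branch(1:3, rep(0.1, 3), threshold = 1.0,
                  manager_source = 99L, manager_weight = 1.0)
  frozen <- plasticity_config(expansion_enabled = FALSE)
  expect_error(expand_branch(b, TRUE, TRUE, 1, frozen),
               class = "hcm_plasticity_frozen")
})

test_that("weights never exceed their ceiling under random operation sequences", {
  set.seed(11)
  for (i in 1:50) {
    wmax <- stats::runif(1, 0.3, 1)
    n <- sample(3:8, 1)
    b <- new_branch(seq_len(n), stats::runif(n, 0, wmax / 2),
                    threshold = 0.5, manager_source = 99L,
                    manager_weight = 1.0, w_max = wmax)
    cfg <- plasticity_config(delta_w = stats::runif(1, 0.05, 0.6))
    for (s in 1:10) {
      act <- c(sample(seq_len(n), sample(1:n, 1)), 99L)
      b <- detect_condition(b, act, step = s)$branch
      b <- expand_branch(b, TRUE, TRUE, s, cfg)$branch
      expect_true(all(b$weights[!b$is_manager] <= wmax + 1e-12))
    }
  }
})

test_that("expansion is local to the invoked branch", {
  tree <- new_tree(list(
    new_branch(1:4, rep(0.1, 4), threshold = 1.0,
               manager_source = 99L, manager_weight = 1.0),
    new_branch(5:8, rep(0.1, 4), threshold = 1.0,
               manager_source = 99L, manager_weight = 1.0)),
    threshold = 1L, role = "basal")
  r <- detect_field(tree, c(1:8, 99L), step = 1)
  ex <- expand_branch(r$tree$branches[[1]], TRUE, TRUE, 1, cfg_default)
  other <- r$tree$branches[[2]]
  expect_equal(other$weights[!other$is_manager], rep(0.1, 4))
  expect_equal(ex$branch$weights[!ex$branch$is_manager], rep(0.25, 4))
})

test_that("overdetection raises the tree threshold, capped at the branch count", {
  u <- new_unit(1L, new_tree(lapply(1:4, function(i)
    new_branch(i, 1.0)), threshold = 2L, role = "basal"))
  cfg <- plasticity_config(overdetection_rate = 0.5, threshold_step = 1)
  u2 <- raise_threshold(u, detection_rate = 0.9, cfg)
  expect_equal(u2$basal$threshold, 3L)
  u3 <- raise_threshold(u2, detection_rate = 0.2, cfg)
  expect_equal(u3$basal$threshold, 3L)
  u4 <- raise_threshold(u3, 0.9, cfg)
  u5 <- raise_threshold(u4, 0.9, cfg)
  expect_equal(u5$basal$threshold, 4L)   # capped at branch count
})

test_that("never-contributing synapses are eliminated after the window", {
  cfg <- plasticity_config(prune_window = 5L)
  b <- new_branch(1:3, c(0.6, 0.6, 0.1), threshold = 1.0,
                  manager_source = 99L, manager_weight = 0.4)
  u <- new_unit(1L, new_tree(list(b), 1L, "basal"))
  # synapses 1 and 2 contribute on every presentation; 3 never active
  for (s in 1:6) {
    u$basal$branches[[1]] <-
      detect_condition(u$basal$branches[[1]], c(1L, 2L), step = s)$branch
  }
  r <- prune_synapses(u, current_presentation = 6, cfg)
  expect_equal(r$removed$source, 3L)
  kept <- r$unit$basal$branches[[1]]
  expect_setequal(kept$sources, c(1L, 2L, 99L))   # manager exempt

  # a freshly created synapse is within its grace period
  b2 <- new_branch(4:5, c(0.5, 0.5), threshold = 2.0, birth = 5L)
  u2 <- new_unit(2L, new_tree(list(b2), 1L, "basal"))
  r2 <- prune_synapses(u2, current_presentation = 6, cfg)
  expect_equal(nrow(r2$removed), 0L)
})

test_that("optional manager-weight decay shrinks only manager synapses", {
  b <- new_branch(1:2, c(0.3, 0.3), threshold = 1.0,
                  manager_source = 99L, manager_weight = 0.8)
  u <- new_unit(1L, new_tree(list(b), 1L, "basal"))
  cfg <- plasticity_config(manager_decay = 0.5)
  u2 <- decay_manager_weights(u, cfg)
  b2 <- u2$basal$branches[[1]]
  expect_equal(b2$weights[b2$is_manager], 0.4)
  expect_equal(b2$weights[!b2$is_manager], c(0.3, 0.3))
})
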