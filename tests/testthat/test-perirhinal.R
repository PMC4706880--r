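# minimal hand-built perirhinal column: 3 intermediate units reading fake
# member II/III ids, 1 trained P1, 2 P2 ids, 4 P3 units reading fake deep
# ids 61..69 (ids: intermediates 71..73, P1 74, P2 75..76, P3 81..84)
make_toy_pcol <- function(p1_trained = TRUE, p3_delays = c(1L, 2L)) {
  inter <- lapply(1:3, function(i)
    new_unit(70L + i, new_tree(list(new_branch(50L + i, 1.0)), 1L,
                               "basal"), kind = "intermediate"))
  p1_w <- if (p1_trained) 0.375 else 0.1875
  P1 <- list(new_unit(74L,
                      new_tree(list(new_branch(71:73, rep(p1_w, 3),
                                               manager_source = 75L,
                                               manager_weight = 0.5)),
                               1L, "basal"), kind = "P1"))
  P3 <- lapply(1:4, function(i) {
    basal <- new_tree(list(
      new_branch(61:69, rep(0.0625, 9), threshold = 0.625,
                 manager_source = 75L, manager_weight = 0.5,
                 w_max = 0.5)), 1L, "basal")
    apical <- new_tree(list(new_branch(75:76, c(1, 1))), 1L, "apical")
    new_unit(80L + i, basal, apical = apical, kind = "P3",
             delay = p3_delays[((i - 1L) %% length(p3_delays)) + 1L])
  })
  new_perirhinal_column(1L, 1:3, inter, P1, 75:76, 0.1, P3,
                        k_winners = 2L, refractory = 6L)
}

test_that("the P1 gate blocks P2 when the column field is detected", {
  pcol <- make_toy_pcol()
  active <- logical(100)
  active[51:53] <- TRUE   # all member II/III proxies active
  r <- step_perirhinal(pcol, step = 1, entorhinal_drive = 5, active)
  expect_true(r$rec$p1_active)
  expect_false(r$rec$p2_fired)

  # weak intermediate activity, strong drive: P2 fires
  active2 <- logical(100)
  active2[51L] <- TRUE
  active2[61:66] <- TRUE  # member deep activity for P3 eligibility
  r2 <- step_perirhinal(make_toy_pcol(), step = 2,
                        entorhinal_drive = 5, active2)
  expect_false(r2$rec$p1_active)
  expect_true(r2$rec$p2_fired)
  expect_gt(length(r2$rec$p3_fired), 0)

  # no drive: everything silent
  r3 <- step_perirhinal(make_toy_pcol(), step = 3,
                        entorhinal_drive = 0, logical(100))
  expect_false(r3$rec$p2_fired)
  expect_length(r3$rec$p3_fired, 0)
})

test_that("P2 and P1 never fire together in a perirhinal column", {
  set.seed(31)
  for (i in 1:50) {
    pcol <- make_toy_pcol()
    active <- logical(100)
    active[sample(50:70, sample(0:12, 1))] <- TRUE
    r <- step_perirhinal(pcol, step = i, stats::runif(1, 0, 2), active)
    expect_false(r$rec$p1_active && r$rec$p2_fired)
  }
})

test_that("recruited P3 units emit with their configured delay", {
  pcol <- make_toy_pcol()
  active <- logical(100)
  active[61:69] <- TRUE
  r <- step_perirhinal(pcol, step = 10, entorhinal_drive = 5, active)
  expect_gt(length(r$rec$p3_fired), 0)
  for (j in seq_along(r$rec$p3_fired)) {
    id <- r$rec$p3_fired[j]
    u <- Filter(function(x) x$id == id, r$pcol$P3)[[1]]
    expect_equal(r$rec$p3_emit_step[j], 10L + u$delay)
    expect_equal(u$fire_mode, "apical")  # attributed to the P2 drive
  }
  # refractory: an immediate re-presentation recruits different units
  r2 <- step_perirhinal(r$pcol, step = 11, entorhinal_drive = 5, active)
  expect_length(intersect(r2$rec$p3_fired, r$rec$p3_fired), 0)
})

test_that("episodic recording is refused outside an expansion period", {
  pcol <- make_toy_pcol()
  pcol$p2$fired <- FALSE
  expect_error(record_episode(pcol, list(), 1, plasticity_config(),
                              active = logical(100)),
               class = "hcm_not_expansion_period")
  expect_error(expansion_drive(pcol, list(), 1, plasticity_config(),
                               active = logical(100)),
               class = "hcm_not_expansion_period")
})

test_that("repeated encoding compounds increments but clips at the ceiling", {
  cfg <- plasticity_config(delta_w = 0.4375, recent_window = 1L)
  b <- new_branch(61:69, rep(0.0625, 9), threshold = 0.625,
                  manager_source = 75L, manager_weight = 0.5,
                  w_max = 0.5)
  # one pass
  b1 <- detect_condition(b, c(61:64, 75L), step = 1)$branch
  b1 <- expand_branch(b1, TRUE, TRUE, 1, cfg)$branch
  # second pass over the same pattern
  b2 <- detect_condition(b1, c(61:64, 75L), step = 2)$branch
  b2 <- expand_branch(b2, TRUE, TRUE, 2, cfg)$branch
  reg <- !b2$is_manager
  trained <- b2$sources %in% 61:64 & reg
  expect_equal(unique(b2$weights[trained]),
               min(0.0625 + 2 * 0.4375, 0.5))
  expect_equal(unique(b2$weights[reg & !trained]), 0.0625)
})

test_that("retrieval with a never-encoded cue stays within the cue", {
  cfg <- small_config()
  net <- build_network(cfg, seed = 8)
  net <- familiarize(net, 4)$net
  cue <- unlist(net$deep_ids)[1:10]
  ret <- retrieve(net, cue, max_steps = 6)
  for (t in seq_along(ret$timeline)) {
    expect_true(all(ret$timeline[[t]] %in% cue))
  }
  expect_identical(ret$purity, 0)
})

test_that("an empty retrieval cue warns and returns an empty timeline", {
  net <- build_network(small_config(), seed = 8)
  expect_warning(ret <- retrieve(net, integer(0)), "empty")
  expect_length(ret$timeline, 0)
})
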