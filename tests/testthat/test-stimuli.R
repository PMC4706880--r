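test_that("streams are deterministic given the seed", {
  w <- make_world(world_config(rng_seed = 5))
  sched <- list(list(context = 1, novelty_fraction = 0.3,
                     n_presentations = 4))
  s1 <- generate_stream(w, sched, seed = 9)
  s2 <- generate_stream(w, sched, seed = 9)
  expect_identical(s1, s2)
  s3 <- generate_stream(w, sched, seed = 10)
  expect_false(identical(s1, s3))
})

test_that("novelty labels match the construction", {
  w <- make_world(world_config(rng_seed = 3))
  pat <- w$contexts[[1]]
  s0 <- generate_stream(w, list(list(context = 1, novelty_fraction = 0,
                                     n_presentations = 2)))
  for (s in s0) expect_true(all(s$features %in% pat))

  s1 <- generate_stream(w, list(list(context = 1, novelty_fraction = 1,
                                     n_presentations = 2)))
  for (s in s1) expect_length(intersect(s$features, pat), 0)

  sf <- generate_stream(w, list(list(context = 1, novelty_fraction = 0.4,
                                     n_presentations = 5)))
  for (s in sf) {
    measured <- mean(!s$features %in% w$pool)  # fraction never in a context
    expect_equal(measured, round(0.4 * length(pat)) / length(pat),
                 tolerance = 1e-12)
    expect_length(s$features, length(pat))
  }
})

test_that("novelty reservoir exhaustion is signaled", {
  w <- make_world(world_config(n_features = 32L, pattern_density = 0.6,
                               reservoir_fraction = 0.1, rng_seed = 1))
  expect_error(generate_stream(w, list(list(context = 1,
                                            novelty_fraction = 1,
                                            n_presentations = 1))),
               "exhausted")
})

test_that("events are ordered, overlapping, and carry genuine novelty", {
  w <- make_world(world_config(rng_seed = 7))
  ev <- generate_event(w, event_length = 3, event_id = 4L, seed = 21)
  expect_length(ev, 3)
  expect_equal(vapply(ev, function(m) m$moment_index, 0L), 0:2)
  expect_true(all(vapply(ev, function(m) m$event_id, 0L) == 4L))
  m <- w$pattern_size
  k_new <- round(w$cfg$event_novelty * m)
  k_keep <- round(w$cfg$event_overlap * (m - k_new))
  for (k in 1:2) {
    shared <- intersect(ev[[k]]$features, ev[[k + 1]]$features)
    expect_gte(length(shared), k_keep)
  }
  for (mom in ev) {
    expect_length(mom$features, m)
    expect_equal(sum(mom$features %in% w$reservoir), k_new)
  }
  expect_false(identical(ev[[1]]$features, ev[[2]]$features))

  w0 <- make_world(world_config(event_novelty = 0, rng_seed = 7))
  expect_error(generate_event(w0), "novelty")
})

test_that("stimulus streams round-trip through line-oriented JSON", {
  w <- make_world(world_config(rng_seed = 2))
  stim <- c(generate_stream(w, list(list(context = 1,
                                         novelty_fraction = 0.25,
                                         n_presentations = 3))),
            generate_event(w, event_length = 2, event_id = 9L))
  path <- tempfile(fileext = ".jsonl")
  write_stream(stim, path)
  back <- read_stream(path)
  expect_equal(length(back), length(stim))
  for (i in seq_along(stim)) {
    expect_identical(back[[i]]$features, stim[[i]]$features)
    expect_equal(back[[i]]$novelty_label, stim[[i]]$novelty_label)
    expect_equal(back[[i]]$moment_index, stim[[i]]$moment_index)
  }
  unlink(path)
})
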