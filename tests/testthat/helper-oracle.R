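# Stateless brute-force oracles, independent of the package's incremental
# bookkeeping: detection is recomputed from raw weight/source vectors by
# explicit enumeration.

oracle_branch <- function(sources, weights, active_set, threshold) {
  total <- 0
  for (i in seq_along(sources)) {
    hit <- FALSE
    for (a in active_set) if (a == sources[i]) hit <- TRUE
    if (hit) total <- total + weights[i]
  }
  length(active_set) > 0 && total >= threshold
}

oracle_tree <- function(branch_specs, active_set, tree_threshold) {
  n_det <- 0L
  for (b in branch_specs) {
    if (oracle_branch(b$sources, b$weights, active_set, b$threshold)) {
      n_det <- n_det + 1L
    }
  }
  list(detected = n_det >= tree_threshold, count = n_det)
}

# random small tree plus the package objects mirroring it
random_tree_case <- function() {
  n_branches <- sample(1:8, 1)
  specs <- lapply(seq_len(n_branches), function(i) {
    n_syn <- sample(1:6, 1)
    list(sources = sample(1:20, n_syn),
         weights = round(stats::runif(n_syn, 0, 1), 3),
         threshold = round(stats::runif(1, 0.2, 1.5), 3))
  })
  branches <- lapply(specs, function(s)
    new_branch(s$sources, s$weights, threshold = s$threshold))
  tree <- new_tree(branches, threshold = sample(1:n_branches, 1),
                   role = "basal")
  active <- sample(1:20, sample(0:12, 1))
  list(specs = specs, tree = tree, active = active)
}

# compact network configuration for engine-level unit tests
small_config <- function(...) {
  network_config(n_areas = 2L, columns_per_area = 6L, n_p3 = 12L, ...)
}
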