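#' @title Prediction experiments: the circuit's activity claims as assertions
#'
#' @description
#' Each experiment runs a fixed schedule over several seeds and evaluates
#' one falsifiable activity property of the circuit: the zero-novelty
#' null (a fully familiar block drives no CA3 activity and no weight
#' change), the monotone relation between novelty and equilibrium CA3
#' activity, the targeting of expansion drive at candidate columns,
#' episodic pattern completion and moment-order recall from a partial
#' cue, retrieval purity (zero weight change), the basal/apical exclusive-
#' contribution rule, and the elevated burst-population (P2) activity
#' during novel relative to familiarized experience.
#'
#' @name experiments
NULL

.fresh_net <- function(seed, cfg) {
  cfg$world$rng_seed <- as.integer(seed)
  build_network(cfg, seed = as.integer(seed))
}

.experiment_names <- c("zero_novelty_null", "novelty_monotonicity",
                       "candidacy_targeting", "recall_completion",
                       "recall_order", "retrieval_purity", "gating_xor",
                       "novelty_p2")

#' Run a named prediction experiment
#'
#' @param name one of `"zero_novelty_null"`, `"novelty_monotonicity"`,
#'   `"candidacy_targeting"`, `"recall_completion"`, `"recall_order"`,
#'   `"retrieval_purity"`, `"gating_xor"`, `"novelty_p2"`.
#' @param seeds integer vector of seeds (each seed builds a fresh world
#'   and network).
#' @param cfg an `hcm_network_config`.
#' @param recall_target recall fraction an episode retrieval must reach
#'   to count as completed.
#' @return a list with `name`, `pass` (logical), `metrics` (per-seed data
#'   frame), and `summary` (named numerics).
#' @export
run_experiment <- function(name, seeds = 1:10, cfg = network_config(),
                           recall_target = 0.8) {
  if (!name %in% .experiment_names) {
    stop("unknown experiment '", name, "'; available: ",
         paste(.experiment_names, collapse = ", "))
  }
  switch(name,
    zero_novelty_null = .exp_zero_novelty(seeds, cfg),
    novelty_monotonicity = .exp_novelty_mono(seeds, cfg),
    candidacy_targeting = .exp_candidacy(seeds, cfg),
    recall_completion = .exp_recall(seeds, cfg, recall_target, "completion"),
    recall_order = .exp_recall(seeds, cfg, recall_target, "order"),
    retrieval_purity = .exp_recall(seeds, cfg, recall_target, "purity"),
    gating_xor = .exp_gating_xor(seeds, cfg),
    novelty_p2 = .exp_novelty_p2(seeds, cfg))
}

.exp_zero_novelty <- function(seeds, cfg, n_block = 50L) {
  rows <- lapply(seeds, function(sd) {
    net <- .fresh_net(sd, cfg)
    f <- familiarize(net, 5L)
    net <- f$net
    nw0 <- nrow(weight_log(net))
    b <- present_block(net, novelty_fraction = 0,
                       n_presentations = n_block, mode = "familiarize")
    net <- b$net
    data.frame(seed = sd,
               max_ca3 = max(b$reports$total_ca3),
               weight_change_rows = nrow(weight_log(net)) - nw0,
               all_converged = all(b$reports$converged))
  })
  metrics <- do.call(rbind, rows)
  pass <- all(metrics$max_ca3 == 0) && all(metrics$weight_change_rows == 0)
  list(name = "zero_novelty_null", pass = pass, metrics = metrics,
       summary = c(max_ca3 = max(metrics$max_ca3),
                   weight_change_rows = sum(metrics$weight_change_rows)))
}

.exp_novelty_mono <- function(seeds, cfg,
                              grid = c(0.25, 0.5, 0.75, 1.0),
                              n_block = 6L) {
  rows <- lapply(seeds, function(sd) {
    net <- .fresh_net(sd, cfg)
    net <- familiarize(net, 5L)$net
    ca3 <- vapply(grid, function(f) {
      b <- present_block(net, novelty_fraction = f,
                         n_presentations = n_block, mode = "probe",
                         stream_seed = sd * 1000L + round(f * 100))
      mean(b$reports$total_ca3)
    }, 0)
    data.frame(seed = sd, novelty = grid, total_ca3 = ca3)
  })
  metrics <- do.call(rbind, rows)
  means <- tapply(metrics$total_ca3, metrics$novelty, mean)
  means <- means[order(as.numeric(names(means)))]
  pass <- all(diff(means) > 0)
  list(name = "novelty_monotonicity", pass = pass, metrics = metrics,
       summary = stats::setNames(as.numeric(means),
                                 paste0("ca3_", names(means))))
}

.exp_candidacy <- function(seeds, cfg, n_block = 4L) {
  rows <- lapply(seeds, function(sd) {
    net <- .fresh_net(sd, cfg)
    net <- familiarize(net, 5L)$net
    net$logs$driven <- list()
    for (f in c(0.25, 0.5)) {
      net <- present_block(net, novelty_fraction = f,
                           n_presentations = n_block,
                           mode = "familiarize",
                           stream_seed = sd * 100L + round(f * 100))$net
    }
    drv <- if (length(net$logs$driven)) do.call(rbind, net$logs$driven)
           else data.frame(candidate = logical(0))
    data.frame(seed = sd, n_driven = nrow(drv),
               n_candidate = sum(drv$candidate))
  })
  metrics <- do.call(rbind, rows)
  precision <- sum(metrics$n_candidate) / max(1, sum(metrics$n_driven))
  pass <- sum(metrics$n_driven) > 0 && precision >= 0.9
  list(name = "candidacy_targeting", pass = pass, metrics = metrics,
       summary = c(precision = precision,
                   n_driven = sum(metrics$n_driven)))
}

.exp_recall <- function(seeds, cfg, recall_target, which) {
  rows <- lapply(seeds, function(sd) {
    net <- .fresh_net(sd, cfg)
    net <- familiarize(net, 5L)$net
    ev <- generate_event(net$world, event_length = 3L, event_id = 1L,
                         seed = sd * 31L + 7L)
    enc <- encode_event(net, ev, dwell = 2L)
    net <- enc$net
    m1 <- enc$trace$moments[[1]]
    cue <- with_seed(sd * 13L + 5L,
                     sample(m1, max(1L, ceiling(0.3 * length(m1)))))
    ret <- retrieve(net, cue, max_steps = 12L, cue_dwell = 2L)
    met <- recall_metrics(ret$timeline, enc$trace)
    data.frame(seed = sd, recall_fraction = met$recall_fraction,
               order_correlation = met$order_correlation,
               purity = ret$purity, cue_size = length(cue),
               episode_size = length(unique(unlist(enc$trace$moments))))
  })
  metrics <- do.call(rbind, rows)
  n_completed <- sum(metrics$recall_fraction >= recall_target,
                     na.rm = TRUE)
  pass <- switch(which,
    completion = n_completed >= ceiling(0.8 * length(seeds)),
    order = all(!is.na(metrics$order_correlation)) &&
      all(metrics$order_correlation == 1),
    purity = all(metrics$purity == 0))
  list(name = paste0("recall_", which), pass = pass, metrics = metrics,
       summary = c(mean_recall = mean(metrics$recall_fraction,
                                      na.rm = TRUE),
                   n_completed = n_completed,
                   mean_order = mean(metrics$order_correlation,
                                     na.rm = TRUE),
                   max_purity = max(metrics$purity)))
}

# run a mixed schedule (familiarize, novel block, event, retrieval) and
# check the exclusive-contribution rule over the full activity log
.exp_gating_xor <- function(seeds, cfg) {
  rows <- lapply(seeds, function(sd) {
    net <- .fresh_net(sd, cfg)
    net <- familiarize(net, 5L)$net
    net <- present_block(net, novelty_fraction = 0.5,
                         n_presentations = 5L,
                         mode = "familiarize")$net
    ev <- generate_event(net$world, event_length = 3L, event_id = 1L,
                         seed = sd * 31L + 7L)
    enc <- encode_event(net, ev, dwell = 2L)
    net <- enc$net
    m1 <- enc$trace$moments[[1]]
    if (length(m1)) {
      cue <- with_seed(sd, sample(m1, max(1L, ceiling(0.3 * length(m1)))))
      net <- retrieve(net, cue)$net
    }
    log <- activity_log(net)
    bad_mode <- sum(!log$mode %in% c("basal", "apical"))
    dup <- if (nrow(log)) {
      agg <- stats::aggregate(mode ~ step + unit, data = log,
                              FUN = function(m) length(unique(m)))
      sum(agg$mode > 1)
    } else 0L
    data.frame(seed = sd, fired_rows = nrow(log),
               violations = bad_mode + dup)
  })
  metrics <- do.call(rbind, rows)
  pass <- sum(metrics$fired_rows) > 0 && sum(metrics$violations) == 0
  list(name = "gating_xor", pass = pass, metrics = metrics,
       summary = c(violations = sum(metrics$violations),
                   fired_rows = sum(metrics$fired_rows)))
}

.exp_novelty_p2 <- function(seeds, cfg, n_block = 10L) {
  rows <- lapply(seeds, function(sd) {
    net <- .fresh_net(sd, cfg)
    net <- familiarize(net, 5L)$net
    fam <- present_block(net, novelty_fraction = 0,
                         n_presentations = n_block, mode = "familiarize")
    net <- fam$net
    nov <- present_block(net, novelty_fraction = 0.5,
                         n_presentations = n_block, mode = "familiarize",
                         stream_seed = sd * 71L + 3L)
    n_pcols <- length(net$pcols)
    data.frame(seed = sd,
               p2_rate_familiar = mean(fam$reports$p2_count) / n_pcols,
               p2_rate_novel = mean(nov$reports$p2_count) / n_pcols)
  })
  metrics <- do.call(rbind, rows)
  wins <- sum(metrics$p2_rate_novel > metrics$p2_rate_familiar)
  p <- stats::binom.test(wins, nrow(metrics),
                         alternative = "greater")$p.value
  pass <- wins >= ceiling(0.9 * length(seeds)) && p < 0.05
  list(name = "novelty_p2", pass = pass, metrics = metrics,
       summary = c(wins = wins, n = nrow(metrics), sign_test_p = p,
                   mean_novel = mean(metrics$p2_rate_novel),
                   mean_familiar = mean(metrics$p2_rate_familiar)))
}
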