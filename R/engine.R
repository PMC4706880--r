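#' @title Presentation cycle, familiarization, episodic encoding, retrieval
#'
#' @description
#' The engine orchestrates the fixed evaluation order of one presentation:
#' deliver pending delayed P3 output, step all cortical columns (layer IV,
#' II/III, deep), summarize per-area detection rates to the entorhinal
#' input, run the DG-CA3 competition, release and decode the converged
#' selection into per-perirhinal-column P2 drive, step the perirhinal
#' columns (intermediate, P1, gate, P2, P3), and finally — in plastic modes
#' — apply expansion drive and episodic recording, then the slow change
#' constraints (overdetection threshold raising and synapse pruning).
#' Retrieval is a separate regime: plasticity frozen, no competition (the
#' release gate withheld), cue units clamped, and activity flowing around
#' the deep-to-P3-to-deep loop with delayed P3 output.
#'
#' Evaluation is single-threaded and deterministic: identical configuration
#' and seed give identical logs.
#'
#' @name engine
NULL

.freeze <- function(net) {
  for (k in names(net$plasticity)) net$plasticity[[k]]$expansion_enabled <- FALSE
  net$frozen <- TRUE
  net
}

.thaw <- function(net) {
  for (k in names(net$plasticity)) net$plasticity[[k]]$expansion_enabled <- TRUE
  net$frozen <- FALSE
  net
}

.deliver_emissions <- function(net, s, active) {
  due <- net$pending$emit_step == s
  emitted <- net$pending$unit[due]
  net$pending <- net$pending[!due, , drop = FALSE]
  active[emitted] <- TRUE
  list(net = net, active = active, emitted = emitted)
}

.log_fired_units <- function(net, s) {
  rows <- list()
  for (col in net$columns) {
    for (u in col$deep) {
      if (u$fired) {
        rows[[length(rows) + 1L]] <-
          data.frame(step = s, unit = u$id, kind = "deep",
                     mode = u$fire_mode)
      }
    }
  }
  for (p in net$pcols) {
    for (u in p$P3) {
      if (u$fired) {
        rows[[length(rows) + 1L]] <-
          data.frame(step = s, unit = u$id, kind = "P3",
                     mode = u$fire_mode)
      }
    }
  }
  if (length(rows)) {
    net$logs$activity[[length(net$logs$activity) + 1L]] <-
      do.call(rbind, rows)
  }
  net
}

#' Run one presentation cycle
#'
#' Executes the fixed sense - compete - release - expand - log order for a
#' single stimulus.
#'
#' @param net an `hcm_network`.
#' @param stimulus an `hcm_stimulus`.
#' @param mode `"familiarize"` or `"encode"` (plastic) or `"probe"`
#'   (measurement only, no weight change).
#' @return `list(net = updated network, report = one-row data frame)` with
#'   per-presentation metrics (novelty label, competition iterations and
#'   convergence, total equilibrium CA3 activity, counts of firing P1/P2/P3
#'   and of driven/candidate/expanded columns, mean area detection rate).
#' @export
run_presentation_cycle <- function(net, stimulus,
                                   mode = c("familiarize", "encode",
                                            "probe")) {
  mode <- match.arg(mode)
  net$step <- net$step + 1L
  net$presentation <- net$presentation + 1L
  s <- net$step

  active <- logical(net$n_sources)
  em <- .deliver_emissions(net, s, active)
  net <- em$net
  active <- em$active
  active[stimulus$features] <- TRUE

  # cortical columns
  statuses <- vector("list", length(net$columns))
  for (i in seq_along(net$columns)) {
    r <- step_column(net$columns[[i]], stimulus$features, s, active)
    net$columns[[i]] <- r$col
    statuses[[i]] <- r$status
    active <- r$active
  }
  rates <- area_detection_rate(statuses)

  # entorhinal summary, competition, release, decode
  ec <- summarize_entorhinal(rates, net$cfg$ec_gain)
  state <- run_competition(ec, net$comp_cfg)
  state <- release_and_decode(state, net$group_weights > 0.1,
                              net$cfg$decode_gain)
  drive <- state$selection

  # perirhinal columns
  p1_count <- p2_count <- p3_count <- 0L
  for (p in seq_along(net$pcols)) {
    r <- step_perirhinal(net$pcols[[p]], s, drive[p], active)
    net$pcols[[p]] <- r$pcol
    active <- r$active
    p1_count <- p1_count + sum(r$rec$p1_active)
    p2_count <- p2_count + sum(r$rec$p2_fired)
    p3_count <- p3_count + length(r$rec$p3_fired)
    if (length(r$rec$p3_fired)) {
      net$pending <- rbind(net$pending,
                           data.frame(unit = r$rec$p3_fired,
                                      emit_step = r$rec$p3_emit_step))
    }
  }

  # plasticity phase
  n_driven <- n_driven_candidate <- 0L
  expanded_cols <- integer(0)
  if (mode != "probe" && !net$frozen) {
    for (p in seq_along(net$pcols)) {
      pcol <- net$pcols[[p]]
      if (!pcol$p2$fired) next
      ed <- expansion_drive(pcol, net$columns, s,
                            net$plasticity$deep, net$plasticity$p1, active)
      net$pcols[[p]] <- ed$pcol
      net$columns <- ed$columns
      active <- ed$active
      if (!is.null(ed$report)) {
        ed$report$presentation <- net$presentation
        net$logs$weights[[length(net$logs$weights) + 1L]] <- ed$report
        dcol <- unique(net$col_of_unit[ed$report$unit])
        expanded_cols <- union(expanded_cols, dcol[!is.na(dcol)])
      }
      if (nrow(ed$driven)) {
        ed$driven$presentation <- net$presentation
        ed$driven$novelty <- stimulus$novelty_label
        net$logs$driven[[length(net$logs$driven) + 1L]] <- ed$driven
        n_driven <- n_driven + nrow(ed$driven)
        n_driven_candidate <- n_driven_candidate + sum(ed$driven$candidate)
      }
      re <- record_episode(net$pcols[[p]], net$columns, s,
                           net$plasticity$p3, net$plasticity$apical,
                           active)
      net$pcols[[p]] <- re$pcol
      net$columns <- re$columns
      if (!is.null(re$report)) {
        re$report$presentation <- net$presentation
        net$logs$weights[[length(net$logs$weights) + 1L]] <- re$report
      }
    }
    net <- .apply_change_constraints(net, statuses)
  }

  net <- .log_fired_units(net, s)
  report <- data.frame(
    presentation = net$presentation, step = s, mode = mode,
    novelty = stimulus$novelty_label,
    iterations = state$iteration, converged = state$converged,
    total_ca3 = total_ca3(state),
    mean_rate = mean(rates),
    n_candidates = sum(vapply(statuses, function(x) x$candidate, FALSE)),
    n_output = sum(vapply(statuses, function(x) x$output_active, FALSE)),
    p1_count = p1_count, p2_count = p2_count, p3_count = p3_count,
    n_driven = n_driven, n_driven_candidate = n_driven_candidate,
    n_expanded = length(expanded_cols))
  net$logs$competition[[length(net$logs$competition) + 1L]] <- report
  list(net = net, report = report)
}

# slow change constraints: overdetection threshold raising (per window)
# and synapse elimination (prune_synapses no-ops until its window elapses)
.apply_change_constraints <- function(net, statuses) {
  out <- vapply(statuses, function(x) x$output_active, FALSE)
  net$det_counts <- net$det_counts + as.numeric(out)
  rw <- net$cfg$raise_window
  if (net$presentation %% rw == 0L) {
    rate <- net$det_counts / rw
    for (i in seq_along(net$columns)) {
      col <- net$columns[[i]]
      for (j in seq_along(col$deep)) {
        col$deep[[j]] <- raise_threshold(col$deep[[j]], rate[i],
                                         net$plasticity$deep)
      }
      net$columns[[i]] <- col
    }
    net$det_counts[] <- 0
  }
  if (net$plasticity$deep$manager_decay < 1) {
    for (i in seq_along(net$columns)) {
      col <- net$columns[[i]]
      for (j in seq_along(col$deep)) {
        col$deep[[j]] <- decay_manager_weights(col$deep[[j]],
                                               net$plasticity$deep)
      }
      net$columns[[i]] <- col
    }
  }
  pw <- net$plasticity$deep$prune_window
  if (net$presentation %% pw == 0L) {
    for (i in seq_along(net$columns)) {
      col <- net$columns[[i]]
      for (lay in c("layer4", "layer23", "deep")) {
        for (j in seq_along(col[[lay]])) {
          col[[lay]][[j]] <- prune_synapses(col[[lay]][[j]],
                                            net$presentation,
                                            net$plasticity$deep)$unit
        }
      }
      net$columns[[i]] <- col
    }
  }
  net
}

#' Present a block of stimuli
#'
#' @param net an `hcm_network`.
#' @param context context index.
#' @param novelty_fraction novelty fraction of the block.
#' @param n_presentations number of presentations.
#' @param mode presentation mode (see [run_presentation_cycle()]).
#' @param stream_seed seed for stimulus sampling within the block.
#' @return `list(net, reports)` with one report row per presentation.
#' @export
present_block <- function(net, context = 1L, novelty_fraction = 0,
                          n_presentations = 10L,
                          mode = "familiarize",
                          stream_seed = net$cfg$world$rng_seed + 17L) {
  stream <- generate_stream(net$world,
                            list(list(context = context,
                                      novelty_fraction = novelty_fraction,
                                      n_presentations = n_presentations)),
                            seed = stream_seed)
  reports <- vector("list", length(stream))
  for (i in seq_along(stream)) {
    r <- run_presentation_cycle(net, stream[[i]], mode)
    net <- r$net
    reports[[i]] <- r$report
  }
  list(net = net, reports = do.call(rbind, reports))
}

#' Familiarize the network on a context
#'
#' Repeated zero-novelty presentations with plasticity on, run before
#' experiments so that columns acquire stable receptive fields (deep
#' basal fields and perirhinal P1 fields are trained by the initial
#' novelty-driven expansions, after which detection rates saturate, CA3
#' activity drops to zero and further change stops).
#'
#' @param net an `hcm_network`.
#' @param n_presentations presentations (default 5; training saturates
#'   within 2-3).
#' @param context context index.
#' @return `list(net, reports)`.
#' @export
familiarize <- function(net, n_presentations = 5L, context = 1L) {
  present_block(net, context, 0, n_presentations, "familiarize")
}

#' Encode a multi-moment event
#'
#' Presents each moment for `dwell` steps in encode mode and logs the
#' ground-truth episode trace (the per-moment sets of deep units that
#' fired during encoding). The trace is a diagnostic oracle only; the
#' retrieval circuitry never reads it.
#'
#' @param net an `hcm_network`.
#' @param event list of moment stimuli from [generate_event()].
#' @param dwell steps each moment is held (co-calibrated with the P3
#'   delay spread: short-delay P3 output lands within the moment,
#'   long-delay output in the next moment).
#' @return `list(net, reports, trace)`; the trace is also stored in
#'   `net$episodes`.
#' @export
encode_event <- function(net, event, dwell = 2L) {
  eid <- event[[1]]$event_id
  moments <- vector("list", length(event))
  reports <- list()
  for (k in seq_along(event)) {
    fired <- integer(0)
    for (d in seq_len(dwell)) {
      r <- run_presentation_cycle(net, event[[k]], "encode")
      net <- r$net
      reports[[length(reports) + 1L]] <- r$report
      for (col in net$columns) {
        for (u in col$deep) if (u$fired) fired <- c(fired, u$id)
      }
    }
    moments[[k]] <- sort(unique(fired))
  }
  trace <- structure(list(event_id = eid, moments = moments,
                          moment_order = seq_along(moments)),
                     class = "hcm_episode_trace")
  net$episodes[[as.character(eid)]] <- trace
  list(net = net, reports = do.call(rbind, reports), trace = trace)
}

#' Retrieve an episode from a partial cue
#'
#' Clamps the cue deep units active for `cue_dwell` steps and iterates the
#' deep to P3-basal to (delayed) P3-output to deep-apical loop with
#' plasticity frozen, no sensory input (so deep apical gates are open) and
#' the hippocampal release withheld (P2 silent, so P3 fires through its
#' trained basal field). Returns the reactivation timeline. Total weight
#' change over the call is exactly zero; the purity field reports the
#' measured |change| from the weight checksum.
#'
#' @param net an `hcm_network`.
#' @param cue integer vector of deep unit ids (may be empty, yielding an
#'   empty timeline with a warning).
#' @param max_steps retrieval steps to iterate.
#' @param cue_dwell steps the cue is clamped.
#' @return `list(net, timeline, purity)`; `timeline` is a list mapping
#'   step index to the set of active deep unit ids.
#' @export
retrieve <- function(net, cue, max_steps = 12L, cue_dwell = 2L) {
  cue <- as.integer(cue)
  if (length(cue) == 0) {
    warning("empty retrieval cue: returning empty timeline")
    return(list(net = net, timeline = list(), purity = 0))
  }
  was_frozen <- net$frozen
  net <- .freeze(net)
  # retrieval is a separate session: delayed outputs scheduled during
  # encoding have lapsed and P3 refractoriness has recovered
  net$pending <- net$pending[0, , drop = FALSE]
  for (p in seq_along(net$pcols)) {
    for (i in seq_along(net$pcols[[p]]$P3)) {
      net$pcols[[p]]$P3[[i]]$refractory_until <- -Inf
    }
  }
  w0 <- network_weight_sum(net)
  n_weight_logs0 <- length(net$logs$weights)
  k_ret <- net$cfg$retrieval_k_winners
  old_k <- vapply(net$pcols, function(p) p$k_winners, 0L)
  for (p in seq_along(net$pcols)) net$pcols[[p]]$k_winners <- k_ret

  timeline <- list()
  for (t in seq_len(max_steps)) {
    net$step <- net$step + 1L
    s <- net$step
    active <- logical(net$n_sources)
    em <- .deliver_emissions(net, s, active)
    net <- em$net
    active <- em$active
    # no sensory input: columns evaluated with empty external input, so
    # internal activity is zero and deep apical gates are open
    for (i in seq_along(net$columns)) {
      r <- step_column(net$columns[[i]], integer(0), s, active)
      net$columns[[i]] <- r$col
      active <- r$active
    }
    if (t <= cue_dwell) active[cue] <- TRUE
    all_deep <- unlist(net$deep_ids)
    match_floor <- net$cfg$retrieval_match_slope *
      mean(active[all_deep])
    for (p in seq_along(net$pcols)) {
      r <- step_perirhinal(net$pcols[[p]], s, 0, active, match_floor)
      net$pcols[[p]] <- r$pcol
      active <- r$active
      if (length(r$rec$p3_fired)) {
        net$pending <- rbind(net$pending,
                             data.frame(unit = r$rec$p3_fired,
                                        emit_step = r$rec$p3_emit_step))
      }
    }
    net <- .log_fired_units(net, s)
    deep_active <- sort(unlist(net$deep_ids)[
      active[unlist(net$deep_ids)]])
    timeline[[t]] <- deep_active
    if (length(deep_active) == 0 && nrow(net$pending) == 0) break
  }
  purity <- abs(network_weight_sum(net) - w0)
  stopifnot(length(net$logs$weights) == n_weight_logs0)
  for (p in seq_along(net$pcols)) net$pcols[[p]]$k_winners <- old_k[p]
  if (!was_frozen) net <- .thaw(net)
  list(net = net, timeline = timeline, purity = purity)
}

#' Recall metrics of a retrieval timeline against the episode trace
#'
#' @param timeline list of per-step active deep-unit id sets from
#'   [retrieve()].
#' @param trace an `hcm_episode_trace` (the ground-truth oracle).
#' @return list with `recall_fraction` (of the full episode deep set ever
#'   reactivated), `moment_steps` (recall latency per moment: the mean
#'   first-reactivation step over the moment's recalled deep units,
#'   weighted by distinctiveness — a unit shared by several moments is
#'   down-weighted by the number of moments containing it, so the latency
#'   reflects when the moment's own content returns; `NA` if nothing was
#'   recalled), and `order_correlation` (Spearman rank correlation between
#'   the recall latencies and the encoded moment order).
#' @export
recall_metrics <- function(timeline, trace) {
  all_set <- sort(unique(unlist(trace$moments)))
  recalled <- sort(unique(unlist(timeline)))
  recall_fraction <- if (length(all_set) == 0) NA_real_ else
    mean(all_set %in% recalled)
  K <- length(trace$moments)
  first_step <- new.env()
  for (t in seq_along(timeline)) {
    for (id in timeline[[t]]) {
      key <- as.character(id)
      if (is.null(first_step[[key]])) first_step[[key]] <- t
    }
  }
  membership_count <- table(unlist(lapply(trace$moments, unique)))
  moment_steps <- vapply(trace$moments, function(m) {
    steps <- unlist(lapply(as.character(m), function(key) {
      v <- first_step[[key]]
      if (is.null(v)) NULL else c(v, 1 / membership_count[[key]])
    }))
    if (is.null(steps)) return(NA_real_)
    sm <- matrix(steps, ncol = 2, byrow = TRUE)
    sum(sm[, 1] * sm[, 2]) / sum(sm[, 2])
  }, 0)
  order_correlation <- if (anyNA(moment_steps) || K < 2) NA_real_ else
    suppressWarnings(stats::cor(moment_steps, seq_len(K),
                                method = "spearman"))
  list(recall_fraction = recall_fraction, moment_steps = moment_steps,
       order_correlation = order_correlation)
}

#' Collected weight-change log as one data frame
#' @param net an `hcm_network`.
#' @return data frame (possibly zero rows) with columns `source`, `delta`,
#'   `unit`, `tree`, `branch`, `presentation`.
#' @export
weight_log <- function(net) {
  if (length(net$logs$weights) == 0) {
    return(data.frame(source = integer(0), delta = numeric(0),
                      unit = integer(0), tree = character(0),
                      branch = integer(0), presentation = integer(0)))
  }
  do.call(rbind, net$logs$weights)
}

#' Collected per-presentation competition log as one data frame
#' @param net an `hcm_network`.
#' @return data frame with one row per presentation.
#' @export
competition_log <- function(net) {
  do.call(rbind, net$logs$competition)
}

#' Collected activity log (deep and P3 firing) as one data frame
#' @param net an `hcm_network`.
#' @return data frame (step, unit, kind, mode).
#' @export
activity_log <- function(net) {
  if (length(net$logs$activity) == 0) {
    return(data.frame(step = integer(0), unit = integer(0),
                      kind = character(0), mode = character(0)))
  }
  do.call(rbind, net$logs$activity)
}
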