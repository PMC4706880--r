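#' @title Gated receptive-field expansion and the change-constraint rules
#'
#' @description
#' Receptive-field expansion is implemented as the branch-level, hippocampally
#' gated Hebbian rule: when a branch carrying active hippocampal (manager)
#' drive detects its condition and the neuron fires shortly afterwards, the
#' backpropagating action potential increments the weights of the branch's
#' recently active regular synapses. Afterwards those synapses can carry the
#' branch over threshold on their own, independent of hippocampal drive — a
#' new condition has been recorded. Three constraint mechanisms keep change
#' minimal: expansion touches only the invoked branch; a field detected too
#' often has its tree threshold raised; synapses that never contribute to
#' detections are eliminated (with a grace period for freshly created,
#' provisional synapses).
#'
#' @name plasticity
NULL

#' Plasticity configuration
#'
#' @param delta_w per-event weight increment (clipped at the branch's
#'   `w_max`).
#' @param recent_window number of steps within which a synapse counts as
#'   "recently active" for the backpropagation rule.
#' @param overdetection_rate detections-per-presentation fraction above which
#'   the tree threshold is raised.
#' @param threshold_step amount (integer ceiling applied) by which the tree
#'   threshold is raised.
#' @param prune_window number of presentations with zero contribution before
#'   a synapse is eliminated; also the grace period for new synapses.
#' @param expansion_enabled master switch; `FALSE` freezes all weight change
#'   (retrieval mode).
#' @param manager_decay optional per-presentation exponential decay factor
#'   applied to manager-synapse weights (`1` = no decay, the default). Models
#'   declining hippocampal-drive synapse weights over time.
#' @return an object of class `hcm_plasticity_config`.
#' @export
plasticity_config <- function(delta_w = 0.15, recent_window = 3L,
                              overdetection_rate = 0.9, threshold_step = 1,
                              prune_window = 40L, expansion_enabled = TRUE,
                              manager_decay = 1.0) {
  stopifnot(delta_w > 0, recent_window >= 1, prune_window >= 1,
            threshold_step > 0,
            overdetection_rate >= 0, overdetection_rate <= 1,
            manager_decay > 0, manager_decay <= 1)
  structure(list(delta_w = delta_w, recent_window = as.integer(recent_window),
                 overdetection_rate = overdetection_rate,
                 threshold_step = threshold_step,
                 prune_window = as.integer(prune_window),
                 expansion_enabled = isTRUE(expansion_enabled),
                 manager_decay = manager_decay),
            class = "hcm_plasticity_config")
}

#' Expand one branch's condition under hippocampal gating
#'
#' Increments by `cfg$delta_w` (clipped at `w_max`) exactly those regular
#' (non-manager) synapses whose `last_active` step falls within
#' `cfg$recent_window` of `step` — and only if the manager synapse is active,
#' the branch detected its condition this step, and the neuron fired within
#' the Hebbian window. Any other circumstance returns an empty change report.
#' Calling with plasticity frozen raises a condition of class
#' `hcm_plasticity_frozen`, which is how the engine proves that retrieval
#' drives no receptive-field change.
#'
#' @param branch an `hcm_branch` whose `last_active` bookkeeping is current
#'   (i.e. [detect_condition()] has run for `step`).
#' @param manager_active logical; hippocampal (P2) drive present on this
#'   branch this step.
#' @param neuron_fired_within_window logical; the unit fired at this step or
#'   the step after the branch detection (backpropagation is instantaneous
#'   in model time).
#' @param step current time step.
#' @param cfg an `hcm_plasticity_config`.
#' @return `list(branch = updated branch, report = data.frame(source, delta))`.
#' @export
expand_branch <- function(branch, manager_active, neuron_fired_within_window,
                          step, cfg) {
  if (!cfg$expansion_enabled) {
    stop(structure(class = c("hcm_plasticity_frozen", "error", "condition"),
                   list(message = "plasticity frozen: expansion refused",
                        call = sys.call())))
  }
  empty <- data.frame(source = integer(0), delta = numeric(0))
  if (!isTRUE(manager_active) || !isTRUE(neuron_fired_within_window)) {
    return(list(branch = branch, report = empty))
  }
  reg <- !branch$is_manager
  active_now <- !is.na(branch$last_active) & branch$last_active == step
  detected <- sum(branch$weights[active_now & reg]) +
    sum(branch$weights[branch$is_manager]) >= branch$threshold
  if (!detected) return(list(branch = branch, report = empty))
  recent <- reg & !is.na(branch$last_active) &
    (step - branch$last_active) < cfg$recent_window &
    branch$last_active <= step
  if (!any(recent)) return(list(branch = branch, report = empty))
  old <- branch$weights[recent]
  new <- pmin(old + cfg$delta_w, branch$w_max[recent])
  branch$weights[recent] <- new
  changed <- new > old
  list(branch = branch,
       report = data.frame(source = branch$sources[recent][changed],
                           delta = (new - old)[changed]))
}

#' Raise a tree threshold when the field is detected too often
#'
#' @param unit an `hcm_unit`.
#' @param detection_rate fraction of presentations (over the measurement
#'   window) on which the field was detected.
#' @param cfg an `hcm_plasticity_config`.
#' @param tree which tree's threshold to consider.
#' @return the updated unit; threshold raised by
#'   `ceiling(cfg$threshold_step)` iff
#'   `detection_rate > cfg$overdetection_rate`, capped at the branch count.
#' @export
raise_threshold <- function(unit, detection_rate, cfg, tree = "basal") {
  tr <- unit[[tree]]
  if (is.null(tr)) return(unit)
  if (detection_rate > cfg$overdetection_rate) {
    tr$threshold <- min(tr$threshold + as.integer(ceiling(cfg$threshold_step)),
                        length(tr$branches))
    unit[[tree]] <- tr
  }
  unit
}

#' Eliminate synapses that never contribute to detections
#'
#' Sweeps both trees of a unit. A sweep only takes place once per
#' `prune_window` presentations (per branch); within a sweep, a synapse is
#' removed iff it is not a manager synapse, it is older than one
#' `prune_window` (the grace period for provisional synapses), and its
#' contribution count has not increased since the previous sweep.
#'
#' @param unit an `hcm_unit`.
#' @param current_presentation presentation counter.
#' @param cfg an `hcm_plasticity_config`.
#' @return `list(unit = updated unit, removed = data.frame(tree, branch,
#'   source))`.
#' @export
prune_synapses <- function(unit, current_presentation, cfg) {
  removed <- list()
  for (role in c("basal", "apical")) {
    tr <- unit[[role]]
    if (is.null(tr)) next
    for (i in seq_along(tr$branches)) {
      b <- tr$branches[[i]]
      if (current_presentation - b$mark_presentation < cfg$prune_window) next
      stale <- !b$is_manager &
        (b$contrib - b$contrib_mark) == 0L &
        (current_presentation - b$birth) >= cfg$prune_window
      if (any(stale)) {
        removed[[length(removed) + 1L]] <-
          data.frame(tree = role, branch = i, source = b$sources[stale])
        keep <- !stale
        for (f in c("sources", "weights", "is_manager", "last_active",
                    "contrib", "contrib_mark", "birth")) {
          b[[f]] <- b[[f]][keep]
        }
      }
      b$contrib_mark <- b$contrib
      b$mark_presentation <- as.integer(current_presentation)
      tr$branches[[i]] <- b
    }
    unit[[role]] <- tr
  }
  unit$basal <- unit$basal
  list(unit = unit,
       removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(tree = character(0), branch = integer(0),
                                 source = integer(0)))
}

#' Apply manager-synapse weight decay
#'
#' Optional mechanism (off by default, `manager_decay = 1`): weights of
#' hippocampal-drive synapses decline geometrically with each presentation,
#' so columns that stop being selected gradually lose their expansion drive.
#' @param unit an `hcm_unit`.
#' @param cfg an `hcm_plasticity_config`.
#' @return the updated unit.
#' @export
decay_manager_weights <- function(unit, cfg) {
  if (cfg$manager_decay >= 1) return(unit)
  for (role in c("basal", "apical")) {
    tr <- unit[[role]]
    if (is.null(tr)) next
    for (i in seq_along(tr$branches)) {
      b <- tr$branches[[i]]
      if (any(b$is_manager)) {
        b$weights[b$is_manager] <- b$weights[b$is_manager] * cfg$manager_decay
        tr$branches[[i]] <- b
      }
    }
    unit[[role]] <- tr
  }
  unit
}
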