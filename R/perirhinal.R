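#' @title Perirhinal interface columns: P1/P2/P3 microcircuit
#'
#' @description
#' A perirhinal column is the interface between a group of member cortical
#' columns and the hippocampus proper. Its intermediate units read the
#' member columns' II/III activity (and relay it toward the entorhinal
#' summary). Three deep populations divide the work: P1 (regular-spiking)
#' detects the column's own trained receptive field and inhibits P2 when it
#' fires; P2 (burst-spiking) fires when entorhinal-decoded drive arrives
#' and the P1 gate is open, broadcasting expansion drive through manager
#' synapses onto member-column deep units, P1, and P3; P3 (late-spiking,
#' with heterogeneous output delays) records episodic traces — deep-unit
#' groups on its basal tree, with its delayed output recorded on the deep
#' units' apical trees — so that recall of one moment drives recall of the
#' next. During P2 activity, interneurons gate the P3 basal contribution
#' off (firing is then attributed to the apical, P2-driven compartment);
#' during retrieval P2 is silent and P3 fires through its trained basal
#' field. P3 recruitment is sparse: a per-step k-winners rule (lateral
#' inhibition) over units holding both apical drive and a basal condition
#' detection, followed by a refractory period, allocates distinct P3 units
#' to distinct moments.
#'
#' @name perirhinal
NULL

#' Create a perirhinal column
#'
#' @param id perirhinal column identifier.
#' @param member_columns integer ids of the member cortical columns.
#' @param intermediate list of `hcm_unit`, one per member column, basal
#'   sources = that column's II/III units.
#' @param P1 list of `hcm_unit`; basal sources = the intermediate units.
#' @param p2_ids global unit ids of the P2 population.
#' @param p2_threshold entorhinal drive threshold for P2 firing.
#' @param P3 list of `hcm_unit` with positive `delay`; basal sources =
#'   member-column deep units, apical source = the P2 population.
#' @param k_winners P3 units recruited per step (lateral inhibition cap).
#' @param refractory steps a P3 unit stays unrecruitable after firing.
#' @return an object of class `hcm_perirhinal_column`.
#' @export
new_perirhinal_column <- function(id, member_columns, intermediate, P1,
                                  p2_ids, p2_threshold, P3,
                                  k_winners = 2L, refractory = 6L) {
  structure(list(id = as.integer(id),
                 member_columns = as.integer(member_columns),
                 intermediate = intermediate, P1 = P1,
                 p2 = list(ids = as.integer(p2_ids),
                           threshold = p2_threshold, fired = FALSE),
                 P3 = P3, k_winners = as.integer(k_winners),
                 refractory = as.integer(refractory)),
            class = "hcm_perirhinal_column")
}

# matched fraction of the unit's basal field at `step`: active non-manager
# weight normalized by total non-manager weight (synaptic scaling), so
# recruitment ranks pattern match rather than raw synaptic mass
.basal_strength <- function(unit, step) {
  act_w <- tot_w <- 0
  for (b in unit$basal$branches) {
    reg <- !b$is_manager
    act <- reg & !is.na(b$last_active) & b$last_active == step
    act_w <- act_w + sum(b$weights[act])
    tot_w <- tot_w + sum(b$weights[reg])
  }
  if (tot_w <= 0) 0 else act_w / tot_w
}

#' Step a perirhinal column for one presentation
#'
#' Evaluates intermediate units, then P1, then the P1-to-P2 gate, then P2,
#' then P3, in order. P2 fires iff the entorhinal drive reaches its
#' threshold and no P1 unit fired. P3 units are recruited k-winners-take-
#' all: during P2 activity (an expansion period) a P3 unit is eligible when
#' its apical (P2) input is active and at least one basal branch detected
#' its condition (the basal tree's firing contribution is gated off;
#' firing is attributed to the apical compartment); with P2 silent
#' (retrieval) eligibility is basal field detection and firing is basal.
#' Recruited P3 units emit output `delay` steps later.
#'
#' @param pcol an `hcm_perirhinal_column`.
#' @param step current time step.
#' @param entorhinal_drive decoded hippocampal drive for this column's P2
#'   population.
#' @param active logical global activity vector (member columns already
#'   stepped).
#' @param match_floor minimum matched fraction of a P3 unit's basal field
#'   (active non-manager weight over total non-manager weight) required
#'   for recruitment with P2 silent. The engine scales this with global
#'   deep activity during retrieval (activity-dependent feedback
#'   inhibition): a sparse cue recruits leniently, a fully active moment
#'   recruits only closely matching units, which forces recall through
#'   the recorded sequence links.
#' @return `list(pcol, active, rec)` where `rec` records `p1_active`,
#'   `p2_fired`, `p3_fired` (unit ids), `p3_emit_step`,
#'   `intermediate_active` (count).
#' @export
step_perirhinal <- function(pcol, step, entorhinal_drive, active,
                            match_floor = 0) {
  for (i in seq_along(pcol$intermediate)) {
    u <- pcol$intermediate[[i]]
    r <- detect_field(u$basal, active, step)
    u$basal <- r$tree
    u <- integrate_unit(u, r$detected, FALSE, TRUE, step)
    active[u$id] <- u$fired
    pcol$intermediate[[i]] <- u
  }
  for (i in seq_along(pcol$P1)) {
    u <- pcol$P1[[i]]
    r <- detect_field(u$basal, active, step)
    u$basal <- r$tree
    u <- integrate_unit(u, r$detected, FALSE, TRUE, step)
    active[u$id] <- u$fired
    pcol$P1[[i]] <- u
  }
  p1_active <- any(vapply(pcol$P1, function(u) u$fired, FALSE))
  p2_fired <- !p1_active && entorhinal_drive >= pcol$p2$threshold
  pcol$p2$fired <- p2_fired
  active[pcol$p2$ids] <- p2_fired

  # P3: evaluate both trees, then recruit sparsely
  eligible <- logical(length(pcol$P3))
  strength <- numeric(length(pcol$P3))
  for (i in seq_along(pcol$P3)) {
    u <- pcol$P3[[i]]
    ra <- detect_field(u$apical, active, step)
    u$apical <- ra$tree
    rb <- detect_field(u$basal, active, step,
                       manager_counts_alone = FALSE)
    u$basal <- rb$tree
    u$fired <- FALSE
    u$fire_mode <- "none"
    free <- step > u$refractory_until
    strength[i] <- .basal_strength(u, step)
    if (p2_fired) {
      eligible[i] <- free && ra$detected && any(rb$branch_detected)
    } else {
      eligible[i] <- free && rb$detected && strength[i] >= match_floor
    }
    pcol$P3[[i]] <- u
  }
  fired_ids <- integer(0)
  emit_steps <- integer(0)
  if (any(eligible)) {
    ord <- order(-strength, seq_along(eligible))
    ord <- ord[eligible[ord]]
    winners <- utils::head(ord, pcol$k_winners)
    for (i in winners) {
      u <- pcol$P3[[i]]
      u$fired <- TRUE
      u$fire_mode <- if (p2_fired) "apical" else "basal"
      u$fire_step <- as.integer(step)
      u$pending_fire_step <- as.integer(step + u$delay)
      u$refractory_until <- step + pcol$refractory
      pcol$P3[[i]] <- u
      fired_ids <- c(fired_ids, u$id)
      emit_steps <- c(emit_steps, u$pending_fire_step)
    }
  }
  rec <- list(p1_active = p1_active, p2_fired = p2_fired,
              p3_fired = fired_ids, p3_emit_step = emit_steps,
              intermediate_active =
                sum(vapply(pcol$intermediate, function(u) u$fired, FALSE)))
  list(pcol = pcol, active = active, rec = rec)
}

# Expand one unit's tree on branches whose manager synapse belongs to
# `manager_ids` and is active. Returns updated unit, change report, and
# whether hippocampal drive tipped an otherwise sub-threshold branch over
# its detection threshold ("effective drive").
.expand_unit <- function(unit, role, step, cfg, manager_ids, active,
                         allow_fire = FALSE) {
  tr <- unit[[role]]
  if (is.null(tr)) {
    return(list(unit = unit, report = NULL, tipped = FALSE,
                fired_assist = FALSE))
  }
  reports <- list()
  tipped <- FALSE
  fired_assist <- FALSE
  for (i in seq_along(tr$branches)) {
    b <- tr$branches[[i]]
    mgr <- b$is_manager & b$sources %in% manager_ids
    if (!any(mgr)) next
    mgr_active <- any(active[b$sources[mgr]])
    if (!mgr_active) next
    reg_now <- sum(b$weights[!b$is_manager & !is.na(b$last_active) &
                               b$last_active == step])
    with_mgr <- reg_now + sum(b$weights[mgr])
    if (with_mgr < b$threshold) next
    if (reg_now < b$threshold) tipped <- TRUE
    if (!unit$fired && allow_fire) {
      # manager-assisted branch detection drives the unit to fire
      unit$fired <- TRUE
      unit$fire_mode <- "basal"
      unit$fire_step <- as.integer(step)
      fired_assist <- TRUE
    }
    if (unit$fired) {
      r <- expand_branch(b, manager_active = TRUE,
                         neuron_fired_within_window = TRUE,
                         step = step, cfg = cfg)
      tr$branches[[i]] <- r$branch
      if (nrow(r$report) > 0) {
        r$report$unit <- unit$id
        r$report$tree <- role
        r$report$branch <- i
        reports[[length(reports) + 1L]] <- r$report
      }
    }
  }
  unit[[role]] <- tr
  list(unit = unit,
       report = if (length(reports)) do.call(rbind, reports) else NULL,
       tipped = tipped, fired_assist = fired_assist)
}

#' Apply P2 expansion drive to member-column deep units and P1
#'
#' The generic receptive-field expansion path: for every member-column
#' deep unit (basal tree) and every P1 unit whose branch carries an active
#' manager synapse from this column's P2 population, a branch that detects
#' with the manager's help drives the unit to fire (if it had not) and the
#' recently active regular synapses are strengthened. A column counts as
#' *receiving above-threshold expansion drive* when the manager input tips
#' an otherwise sub-threshold deep branch over its detection threshold.
#'
#' @param pcol an `hcm_perirhinal_column` whose P2 fired this step.
#' @param columns named list of member `hcm_column` objects (by id).
#' @param step current time step.
#' @param cfg_deep plasticity config for deep basal expansion.
#' @param cfg_p1 plasticity config for P1 expansion (defaults to
#'   `cfg_deep`).
#' @param active logical global activity vector.
#' @return `list(pcol, columns, active, report, driven)` where `driven` is
#'   a data frame (column id, candidate status at selection time) of
#'   member columns that received effective drive.
#' @export
expansion_drive <- function(pcol, columns, step, cfg_deep,
                            cfg_p1 = cfg_deep, active) {
  if (!pcol$p2$fired) {
    stop(structure(class = c("hcm_not_expansion_period", "error",
                             "condition"),
                   list(message = "P2 population silent: no expansion drive",
                        call = sys.call())))
  }
  mids <- pcol$p2$ids
  reports <- list()
  driven <- list()
  for (cid in pcol$member_columns) {
    key <- as.character(cid)
    col <- columns[[key]]
    if (is.null(col)) next
    col_tipped <- FALSE
    for (i in seq_along(col$deep)) {
      r <- .expand_unit(col$deep[[i]], "basal", step, cfg_deep, mids,
                        active, allow_fire = TRUE)
      if (r$fired_assist) active[r$unit$id] <- TRUE
      col$deep[[i]] <- r$unit
      if (!is.null(r$report)) reports[[length(reports) + 1L]] <- r$report
      if (r$tipped) col_tipped <- TRUE
    }
    if (col_tipped) {
      driven[[length(driven) + 1L]] <-
        data.frame(column = col$id,
                   candidate = isTRUE(col$status$candidate),
                   internal_activity = col$status$internal_activity,
                   output_active = isTRUE(col$status$output_active))
    }
    columns[[key]] <- col
  }
  for (i in seq_along(pcol$P1)) {
    r <- .expand_unit(pcol$P1[[i]], "basal", step, cfg_p1, mids, active,
                      allow_fire = TRUE)
    if (r$fired_assist) active[r$unit$id] <- TRUE
    pcol$P1[[i]] <- r$unit
    if (!is.null(r$report)) reports[[length(reports) + 1L]] <- r$report
  }
  list(pcol = pcol, columns = columns, active = active,
       report = if (length(reports)) do.call(rbind, reports) else NULL,
       driven = if (length(driven)) do.call(rbind, driven)
                else data.frame(column = integer(0), candidate = logical(0),
                                internal_activity = numeric(0),
                                output_active = logical(0)))
}

#' Record episodic links during an expansion period
#'
#' Strengthens the reciprocal deep/P3 connectivity that supports later
#' indirect activation: recruited P3 units strengthen basal synapses from
#' the deep units recently active at their detection step, and member-
#' column deep units that fired strengthen apical synapses from P3 units
#' whose delayed output arrived this step. Because P3 output is delayed, a
#' P3 unit detected at one moment strengthens onto the deep units active a
#' moment later — the sequence-recall mechanism. Refused (condition class
#' `hcm_not_expansion_period`) when the column's P2 population is silent.
#'
#' @param pcol an `hcm_perirhinal_column` whose P2 fired this step.
#' @param columns named list of member `hcm_column` objects (by id).
#' @param step current time step.
#' @param cfg_p3 plasticity config for P3 basal recording.
#' @param cfg_apical plasticity config for deep apical recording
#'   (defaults to `cfg_p3`).
#' @param active logical global activity vector.
#' @return `list(pcol, columns, report)`.
#' @export
record_episode <- function(pcol, columns, step, cfg_p3,
                           cfg_apical = cfg_p3, active) {
  if (!pcol$p2$fired) {
    stop(structure(class = c("hcm_not_expansion_period", "error",
                             "condition"),
                   list(message =
                          "P2 population silent: not an expansion period",
                        call = sys.call())))
  }
  mids <- pcol$p2$ids
  reports <- list()
  # P3 basal: recruited units strengthen synapses from recently active deep
  for (i in seq_along(pcol$P3)) {
    u <- pcol$P3[[i]]
    if (!u$fired) next
    r <- .expand_unit(u, "basal", step, cfg_p3, mids, active)
    pcol$P3[[i]] <- r$unit
    if (!is.null(r$report)) reports[[length(reports) + 1L]] <- r$report
  }
  # deep apical: units that fired record the P3 output arriving this step
  for (cid in pcol$member_columns) {
    key <- as.character(cid)
    col <- columns[[key]]
    if (is.null(col)) next
    for (i in seq_along(col$deep)) {
      u <- col$deep[[i]]
      if (!u$fired) next
      r <- .expand_unit(u, "apical", step, cfg_apical, mids, active)
      col$deep[[i]] <- r$unit
      if (!is.null(r$report)) reports[[length(reports) + 1L]] <- r$report
    }
    columns[[key]] <- col
  }
  list(pcol = pcol, columns = columns,
       report = if (length(reports)) do.call(rbind, reports) else NULL)
}
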