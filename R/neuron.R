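#' @title Two-compartment pyramidal units: branches, trees, condition detection
#'
#' @description
#' The atomic computational element of the simulator is the dendritic terminal
#' branch: a set of weighted synapses that jointly define one *condition*. A
#' branch detects its condition at a step when the summed weight of its active
#' synapses reaches the branch threshold (the abstraction of a dendritic
#' calcium event injecting potential toward the soma). A dendritic tree
#' (basal or apical) detects its *receptive field* when enough branches detect
#' their conditions. A pyramidal unit carries one basal tree (the direct,
#' sensory-driven field) and optionally one apical tree (the indirect field,
#' driven by past temporally correlated activity); interneuron gating ensures
#' at most one compartment contributes to firing at any step.
#'
#' Activity is binary per step; there are no membrane dynamics. Synapses are
#' stored as parallel vectors inside the branch (source id, weight, manager
#' flag, last-active step, contribution count, birth presentation). A
#' *manager* synapse models the strong hippocampally-gated drive (from the
#' perirhinal P2 population) that can push an otherwise sub-threshold branch
#' over its detection threshold during an expansion episode.
#'
#' @name neuron
NULL

#' Create a dendritic terminal branch
#'
#' @param sources integer vector of presynaptic source identifiers (global id
#'   space shared by stimulus features and units).
#' @param weights non-negative numeric vector, same length as `sources`; each
#'   weight must be `<= w_max`.
#' @param threshold positive branch detection threshold: the branch detects
#'   its condition when the summed weight of active synapses is `>= threshold`
#'   (ties detect; the boundary uses `>=`).
#' @param manager_source optional single source id of a hippocampal-drive
#'   (P2) synapse onto this branch.
#' @param manager_weight weight of the manager synapse.
#' @param w_max weight ceiling, recycled per synapse (the manager synapse
#'   keeps at least its own weight as ceiling).
#' @param birth presentation index at which the synapses were created (used
#'   by the pruning grace period).
#' @return an object of class `hcm_branch`.
#' @export
new_branch <- function(sources, weights, threshold = 1.0,
                       manager_source = NULL, manager_weight = 1.0,
                       w_max = 1.0, birth = 0L) {
  sources <- as.integer(sources)
  weights <- as.numeric(weights)
  w_max <- rep_len(as.numeric(w_max), length(sources))
  stopifnot(length(sources) == length(weights),
            all(weights >= 0), all(weights <= w_max),
            threshold > 0)
  is_manager <- rep(FALSE, length(sources))
  if (!is.null(manager_source)) {
    sources <- c(sources, as.integer(manager_source))
    weights <- c(weights, as.numeric(manager_weight))
    w_max <- c(w_max, max(manager_weight, if (length(w_max)) max(w_max)
                          else manager_weight))
    is_manager <- c(is_manager, TRUE)
  }
  structure(list(
    sources = sources,
    weights = weights,
    is_manager = is_manager,
    threshold = threshold,
    w_max = w_max,
    last_active = rep(NA_real_, length(sources)),
    contrib = rep(0L, length(sources)),
    contrib_mark = rep(0L, length(sources)),
    mark_presentation = 0L,
    birth = rep(as.integer(birth), length(sources))
  ), class = "hcm_branch")
}

#' Create a dendritic tree
#'
#' @param branches list of `hcm_branch` objects.
#' @param threshold positive integer; minimum number of condition-detecting
#'   branches for the tree's receptive field to be detected. Must not exceed
#'   the number of branches.
#' @param role `"basal"` (direct field) or `"apical"` (indirect field).
#' @return an object of class `hcm_tree`.
#' @export
new_tree <- function(branches, threshold = 3L, role = c("basal", "apical")) {
  role <- match.arg(role)
  threshold <- as.integer(threshold)
  stopifnot(length(branches) >= 1, threshold >= 1,
            threshold <= length(branches))
  structure(list(branches = branches, threshold = threshold, role = role),
            class = "hcm_tree")
}

#' Create a pyramidal unit
#'
#' @param id global unit identifier (integer, in the same id space as
#'   stimulus features).
#' @param basal an `hcm_tree` with role `"basal"`.
#' @param apical optional `hcm_tree` with role `"apical"`.
#' @param kind free-form population label (e.g. `"layer4"`, `"deep"`, `"P3"`).
#' @param column owning column identifier (or `NA`).
#' @param area owning cortical area identifier (or `NA`).
#' @param delay output delay in steps (0 for ordinary units; positive for
#'   late-firing P3 units, whose detection at step `t` emits output at
#'   `t + delay`).
#' @return an object of class `hcm_unit`.
#' @export
new_unit <- function(id, basal, apical = NULL, kind = "generic",
                     column = NA_integer_, area = NA_integer_, delay = 0L) {
  stopifnot(inherits(basal, "hcm_tree"), basal$role == "basal")
  if (!is.null(apical)) stopifnot(inherits(apical, "hcm_tree"),
                                  apical$role == "apical")
  structure(list(
    id = as.integer(id), kind = kind,
    column = as.integer(column), area = as.integer(area),
    basal = basal, apical = apical,
    delay = as.integer(delay),
    fired = FALSE, fire_mode = "none", fire_step = NA_integer_,
    pending_fire_step = NA_integer_,
    refractory_until = -Inf
  ), class = "hcm_unit")
}

.active_synapses <- function(branch, active_sources) {
  if (is.logical(active_sources)) {
    idx <- branch$sources
    ok <- idx >= 1L & idx <= length(active_sources)
    act <- logical(length(idx))
    act[ok] <- active_sources[idx[ok]]
    act
  } else {
    branch$sources %in% active_sources
  }
}

#' Evaluate condition detection on one branch
#'
#' Sums the weights of the branch's active synapses (manager synapse
#' included when its source is active) and compares against the branch
#' threshold with `>=`. Bookkeeping side effects: `last_active` is recorded
#' for every active synapse regardless of the outcome; on detection, the
#' contribution count of every active synapse is incremented (the evidence
#' used by the synapse-elimination rule).
#'
#' @param branch an `hcm_branch`.
#' @param active_sources either a logical activity vector indexed by global
#'   source id, or an integer set of active source ids (may be empty).
#' @param step current time step.
#' @param manager_counts_alone if `FALSE`, a branch whose only active synapse
#'   is the manager synapse does not detect even if the manager weight alone
#'   reaches threshold (hippocampal drive then requires co-active regular
#'   synapses). Default `TRUE`: the manager synapse is treated like any
#'   other weight.
#' @return `list(detected = logical, active_weight = numeric,
#'   branch = updated branch)`.
#' @export
detect_condition <- function(branch, active_sources, step,
                             manager_counts_alone = TRUE) {
  act <- .active_synapses(branch, active_sources)
  total <- sum(branch$weights[act])
  detected <- length(act) > 0 && any(act) && total >= branch$threshold
  if (detected && !manager_counts_alone && !any(act & !branch$is_manager)) {
    detected <- FALSE
  }
  branch$last_active[act] <- step
  if (detected) branch$contrib[act] <- branch$contrib[act] + 1L
  list(detected = detected, active_weight = total, branch = branch)
}

#' Evaluate receptive-field detection on one dendritic tree
#'
#' Runs [detect_condition()] over every branch and compares the count of
#' detecting branches against the tree threshold.
#'
#' @inheritParams detect_condition
#' @param tree an `hcm_tree`.
#' @return `list(detected, detecting_branch_count, branch_detected = logical
#'   vector, tree = updated tree)`.
#' @export
detect_field <- function(tree, active_sources, step,
                         manager_counts_alone = TRUE) {
  n <- length(tree$branches)
  det <- logical(n)
  for (i in seq_len(n)) {
    r <- detect_condition(tree$branches[[i]], active_sources, step,
                          manager_counts_alone)
    det[i] <- r$detected
    tree$branches[[i]] <- r$branch
  }
  cnt <- sum(det)
  list(detected = cnt >= tree$threshold, detecting_branch_count = cnt,
       branch_detected = det, tree = tree)
}

#' Somatic integration under the interneuron gating contract
#'
#' At most one compartment contributes to firing at any step. When the
#' unit's column has sensory-derived intermediate-layer activity
#' (`sensory_context_active`), interneurons targeting the apical entry point
#' block the apical contribution, so the unit can fire only through its
#' basal (direct) field. When no sensory context is present (indirect
#' activation under way), only the apical field can drive firing. Apical
#' branch condition detections are still recorded while gated — the gate
#' blocks the firing contribution, not the dendritic bookkeeping.
#'
#' @param unit an `hcm_unit`.
#' @param basal_detected logical, basal field detected this step.
#' @param apical_detected logical, apical field detected this step.
#' @param sensory_context_active logical; `TRUE` when the unit's column has
#'   intermediate-layer activity driven by current sensory input.
#' @param step current time step.
#' @return the updated unit; `unit$fire_mode` is one of
#'   `"none"`, `"basal"`, `"apical"`.
#' @export
integrate_unit <- function(unit, basal_detected, apical_detected,
                           sensory_context_active, step) {
  mode <- "none"
  if (sensory_context_active) {
    if (isTRUE(basal_detected)) mode <- "basal"
  } else {
    if (isTRUE(apical_detected)) mode <- "apical"
  }
  unit$fired <- mode != "none"
  unit$fire_mode <- mode
  unit$fire_step <- if (unit$fired) as.integer(step) else NA_integer_
  unit
}

#' Total branch weight of non-manager synapses
#' @param branch an `hcm_branch`.
#' @return numeric scalar.
#' @export
regular_weight <- function(branch) sum(branch$weights[!branch$is_manager])

#' Sum of weights over all synapses of a unit (both trees)
#'
#' Used by the retrieval-purity assertions: total absolute weight change
#' across a retrieval run must be exactly zero.
#' @param unit an `hcm_unit`.
#' @return numeric scalar.
#' @export
unit_weight_sum <- function(unit) {
  s <- sum(vapply(unit$basal$branches, function(b) sum(b$weights), 0))
  if (!is.null(unit$apical)) {
    s <- s + sum(vapply(unit$apical$branches, function(b) sum(b$weights), 0))
  }
  s
}
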