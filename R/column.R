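#' @title Cortical columns: layered feedforward structure and candidacy
#'
#' @description
#' A regular cortical column is three layers of pyramidal units evaluated
#' feedforward within a step: external features drive layer IV, layer IV
#' drives layers II/III (the column's *internal* activity), and layers
#' II/III drive the deep layers V/VI, whose firing is the column's output.
#' Receptive fields grow more specific along this chain, so deep fields are
#' detected least often. A column with strong internal activity but no
#' output is *fairly close* to detecting its field and is flagged as an
#' expansion candidate. Deep units also carry an apical (indirect) tree
#' wired from perirhinal P3 units; while sensory-driven intermediate
#' activity is present, interneurons gate the apical contribution off.
#'
#' @name cortical_column
NULL

#' Create a cortical column
#'
#' @param id column identifier.
#' @param area area identifier.
#' @param layer4,layer23,deep lists of `hcm_unit` (deep units may carry
#'   apical trees; wiring invariants: layer IV basal sources are external
#'   features, layer II/III basal sources are layer IV units of the same
#'   column, deep basal sources are layer II/III units of the same column).
#' @param candidacy_floor minimum fraction of firing layer II/III units for
#'   expansion candidacy.
#' @param output_rule `"any"` (default: column output active iff any deep
#'   unit fired) or `"fraction"` with `output_floor`.
#' @param output_floor deep firing fraction used by the `"fraction"` rule.
#' @return an object of class `hcm_column`.
#' @export
new_column <- function(id, area, layer4, layer23, deep,
                       candidacy_floor = 0.5, output_rule = "any",
                       output_floor = 0.5) {
  structure(list(id = as.integer(id), area = as.integer(area),
                 layer4 = layer4, layer23 = layer23, deep = deep,
                 candidacy_floor = candidacy_floor,
                 output_rule = output_rule, output_floor = output_floor,
                 status = NULL),
            class = "hcm_column")
}

#' Step a cortical column for one presentation
#'
#' Evaluates layer IV, then layers II/III, then the deep layers, in order,
#' against the global activity vector; sets `sensory_context_active` for
#' deep units iff the internal (II/III) activity is positive, which drives
#' their apical gate. The returned status carries output activity, internal
#' activity and candidacy (`candidate` implies no output and internal
#' activity at or above the candidacy floor).
#'
#' @param col an `hcm_column`.
#' @param external_input integer vector of active feature ids (may be
#'   empty).
#' @param step current time step.
#' @param active logical global activity vector (features + units); if
#'   `NULL` a fresh vector sized to `n_sources` is created.
#' @param n_sources total source-id space size (required when
#'   `active = NULL`).
#' @return `list(col = updated column, status = hcm_column_status,
#'   active = updated activity vector)`.
#' @export
step_column <- function(col, external_input, step, active = NULL,
                        n_sources = NULL) {
  if (is.null(active)) {
    stopifnot(!is.null(n_sources))
    active <- logical(n_sources)
    active[as.integer(external_input)] <- TRUE
  }
  # layer IV <- external features
  for (i in seq_along(col$layer4)) {
    u <- col$layer4[[i]]
    r <- detect_field(u$basal, active, step)
    u$basal <- r$tree
    u <- integrate_unit(u, r$detected, FALSE, TRUE, step)
    active[u$id] <- u$fired
    col$layer4[[i]] <- u
  }
  # layers II/III <- layer IV
  for (i in seq_along(col$layer23)) {
    u <- col$layer23[[i]]
    r <- detect_field(u$basal, active, step)
    u$basal <- r$tree
    u <- integrate_unit(u, r$detected, FALSE, TRUE, step)
    active[u$id] <- u$fired
    col$layer23[[i]] <- u
  }
  internal <- mean(vapply(col$layer23, function(u) u$fired, FALSE))
  sensory_ctx <- internal > 0
  # deep layers V/VI <- layers II/III (basal), P3 (apical, gated by
  # sensory context)
  for (i in seq_along(col$deep)) {
    u <- col$deep[[i]]
    rb <- detect_field(u$basal, active, step)
    u$basal <- rb$tree
    ap_det <- FALSE
    if (!is.null(u$apical)) {
      ra <- detect_field(u$apical, active, step)
      u$apical <- ra$tree
      ap_det <- ra$detected
    }
    u <- integrate_unit(u, rb$detected, ap_det, sensory_ctx, step)
    active[u$id] <- u$fired
    col$deep[[i]] <- u
  }
  out <- vapply(col$deep, function(u) u$fired, FALSE)
  output_active <- if (col$output_rule == "any") any(out)
                   else mean(out) >= col$output_floor
  status <- structure(list(column = col$id, area = col$area,
                           output_active = output_active,
                           internal_activity = internal,
                           candidate = !output_active &&
                             internal >= col$candidacy_floor),
                      class = "hcm_column_status")
  col$status <- status
  list(col = col, status = status, active = active)
}

#' Per-area column detection rates
#'
#' The fraction of columns producing output in each area — the quantity
#' summarized to the entorhinal layer. Statuses may span several steps
#' (a window); rates are averaged over all supplied rows.
#'
#' @param statuses list of `hcm_column_status` (or a single step's worth).
#' @return named numeric vector of per-area detection rates.
#' @export
area_detection_rate <- function(statuses) {
  if (length(statuses) == 0) stop("no column statuses: empty area window")
  area <- vapply(statuses, function(s) s$area, 0L)
  out <- vapply(statuses, function(s) s$output_active, FALSE)
  rates <- tapply(out, area, mean)
  r <- as.numeric(rates)
  names(r) <- names(rates)
  r
}
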