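#' @title Snapshots, run CSVs, and YAML configuration
#' @name io
NULL

.branch_to_list <- function(b) {
  list(sources = b$sources, weights = b$weights,
       is_manager = b$is_manager, threshold = b$threshold)
}

.unit_to_list <- function(u) {
  out <- list(id = u$id, kind = u$kind, delay = u$delay,
              basal = list(threshold = u$basal$threshold,
                           branches = lapply(u$basal$branches,
                                             .branch_to_list)))
  if (!is.null(u$apical)) {
    out$apical <- list(threshold = u$apical$threshold,
                       branches = lapply(u$apical$branches,
                                         .branch_to_list))
  }
  out
}

#' Dump the network's unit and weight state to a JSON snapshot
#'
#' Schema: units nested in columns and perirhinal columns, each unit with
#' its trees, branches, synapse sources and weights.
#'
#' @param net an `hcm_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_snapshot <- function(net, path) {
  snap <- list(
    n_sources = net$n_sources,
    step = net$step,
    presentation = net$presentation,
    group_weights = net$group_weights,
    columns = lapply(net$columns, function(col) {
      list(id = col$id, area = col$area,
           layer4 = lapply(col$layer4, .unit_to_list),
           layer23 = lapply(col$layer23, .unit_to_list),
           deep = lapply(col$deep, .unit_to_list))
    }),
    pcols = lapply(net$pcols, function(p) {
      list(id = p$id, member_columns = p$member_columns,
           p2_ids = p$p2$ids,
           intermediate = lapply(p$intermediate, .unit_to_list),
           P1 = lapply(p$P1, .unit_to_list),
           P3 = lapply(p$P3, .unit_to_list))
    }))
  jsonlite::write_json(snap, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.apply_unit_snap <- function(u, snap) {
  stopifnot(u$id == snap$id)
  for (i in seq_along(u$basal$branches)) {
    u$basal$branches[[i]]$weights <-
      as.numeric(snap$basal$branches[[i]]$weights)
    u$basal$branches[[i]]$threshold <-
      as.numeric(snap$basal$branches[[i]]$threshold)
  }
  u$basal$threshold <- as.integer(snap$basal$threshold)
  if (!is.null(u$apical) && !is.null(snap$apical)) {
    for (i in seq_along(u$apical$branches)) {
      u$apical$branches[[i]]$weights <-
        as.numeric(snap$apical$branches[[i]]$weights)
      u$apical$branches[[i]]$threshold <-
        as.numeric(snap$apical$branches[[i]]$threshold)
    }
    u$apical$threshold <- as.integer(snap$apical$threshold)
  }
  u
}

#' Load weights and thresholds from a snapshot into a matching network
#'
#' The target network must have been built with the same configuration
#' and seed as the snapshot source (identical wiring); weights, branch
#' and tree thresholds, and group membership are restored.
#'
#' @param net an `hcm_network` with the same wiring as the snapshot.
#' @param path snapshot file written by [save_snapshot()].
#' @return the updated network.
#' @export
load_snapshot <- function(net, path) {
  snap <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(snap$n_sources == net$n_sources)
  for (i in seq_along(net$columns)) {
    cs <- snap$columns[[i]]
    col <- net$columns[[i]]
    for (lay in c("layer4", "layer23", "deep")) {
      for (j in seq_along(col[[lay]])) {
        col[[lay]][[j]] <- .apply_unit_snap(col[[lay]][[j]],
                                            cs[[lay]][[j]])
      }
    }
    net$columns[[i]] <- col
  }
  for (i in seq_along(net$pcols)) {
    ps <- snap$pcols[[i]]
    p <- net$pcols[[i]]
    for (lay in c("intermediate", "P1", "P3")) {
      for (j in seq_along(p[[lay]])) {
        p[[lay]][[j]] <- .apply_unit_snap(p[[lay]][[j]], ps[[lay]][[j]])
      }
    }
    net$pcols[[i]] <- p
  }
  # jsonlite serializes matrices row-wise
  W <- snap$group_weights
  net$group_weights <- matrix(unlist(W), nrow = nrow(net$group_weights),
                              byrow = TRUE)
  net$step <- as.integer(snap$step)
  net$presentation <- as.integer(snap$presentation)
  net
}

#' Write the run logs to CSV files
#'
#' Writes `activity.csv` (step, unit, kind, mode), `weights.csv` (per
#' weight change: source, delta, unit, tree, branch, presentation) and
#' `competition.csv` (per-presentation competition and expansion metrics)
#' into a directory.
#'
#' @param net an `hcm_network`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_csvs <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(activity_log(net), file.path(dir, "activity.csv"),
                   row.names = FALSE)
  utils::write.csv(weight_log(net), file.path(dir, "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(competition_log(net),
                   file.path(dir, "competition.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a network configuration from a YAML file
#'
#' The file may contain three sections: `world` (fields of
#' [world_config()]), `network` (fields of [network_config()] other than
#' `world` and `competition`) and `competition` (fields of
#' [competition_config()]). Missing fields keep their defaults.
#'
#' @param path YAML file.
#' @return an `hcm_network_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  world <- do.call(world_config, as.list(y$world %||% list()))
  comp <- do.call(competition_config, as.list(y$competition %||% list()))
  args <- as.list(y$network %||% list())
  args$world <- world
  args$competition <- comp
  do.call(network_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the default configuration to a YAML file
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_default_config <- function(path) {
  cfg <- network_config()
  y <- list(
    world = unclass(cfg$world),
    network = cfg[setdiff(names(cfg), c("world", "competition"))],
    competition = unclass(cfg$competition))
  y$competition$area_weights <- NULL
  yaml::write_yaml(y, path)
  invisible(path)
}
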