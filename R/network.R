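#' @title Network construction: columns, perirhinal cover, hippocampal groups
#'
#' @description
#' Builds the full simulated circuit from a configuration and a seed:
#' cortical areas of columns wired over a context's feature pattern (with a
#' spread of tuning widths so that area detection rates degrade gradually
#' with novelty), a random overlapping cover of perirhinal columns over the
#' cortical columns, and the hippocampal competition configuration with its
#' CA3 column-group membership (initialized randomly, thereafter updated by
#' co-expansion).
#'
#' Synaptic weights are chosen as exact binary fractions (1/16, 1/8, 3/16,
#' 1/4, 1/2) so that detection-threshold boundaries are exact in floating
#' point: an untrained deep basal branch (8 II/III synapses at 1/16) sums
#' to exactly 0.5 and needs the 0.5 hippocampal manager synapse plus full
#' II/III activity to reach the 1.0 threshold; after one expansion
#' (increment 1/16) the trained branch sums to 1.0 on its own, and the
#' manager input tips it over threshold exactly when 4..7 of the 8 II/III
#' units fire — the same window as expansion candidacy.
#'
#' @name network
NULL

#' Network configuration
#'
#' Defaults define the standard desk-experiment circuit: 4 areas of 16
#' columns; each column reads a 12-feature support sampled from its home
#' context through layer IV units of one of five tuning widths (a branch
#' detects on 3..7 of its 8 sampled features); 8 II/III units each read 3
#' of the 4 layer IV units; deep units read all 8 II/III units. Perirhinal
#' columns form a 2-cover with about 3 members each, holding 1 P1, 2 P2 and
#' 12 P3 units (half short-delay, half long-delay).
#'
#' @param world an `hcm_world_config`.
#' @param n_areas number of cortical areas.
#' @param columns_per_area columns per area.
#' @param n_l4,n_l23,n_deep units per column layer.
#' @param support_size features sampled per column from its context.
#' @param l4_syn layer IV synapses per branch.
#' @param l4_k_classes cycle of layer IV activation requirements (synapses
#'   needed of `l4_syn`), the tuning-width spread.
#' @param deep_w_init,apical_w_init initial (weak/provisional) synapse
#'   weights on deep basal and deep apical branches.
#' @param deep_w_max,apical_w_max,p1_w_max,p3_w_max per-pathway weight
#'   ceilings, the minimal-change constraint: expansion raises a weight
#'   only to the level at which the trained pattern detects, never
#'   beyond, so the detection and candidacy windows do not drift with
#'   repeated expansion episodes.
#' @param apical_threshold deep apical branch detection threshold.
#' @param manager_weight weight of hippocampal-drive (P2) synapses; below
#'   branch threshold, so drive requires co-active regular synapses.
#' @param members_per_pcol,covers perirhinal cover geometry: each cortical
#'   column belongs to `covers` perirhinal columns of about
#'   `members_per_pcol` members.
#' @param intermediate_weight weight of member-II/III synapses on
#'   perirhinal intermediate units (default: an intermediate unit fires
#'   only on full member II/III activity, aligning the P1 gate with
#'   member-column detection).
#' @param n_p1,n_p2,n_p3 perirhinal deep population sizes per column.
#' @param p1_w_init initial P1 basal weight.
#' @param p2_threshold entorhinal drive threshold for P2 firing.
#' @param p3_basal_branches,p3_basal_syn,p3_w_init P3 basal geometry.
#' @param p3_threshold P3 basal branch detection threshold; with the
#'   manager synapse this admits a moderately active member deep group
#'   during encoding, while staying above the total untrained weight so
#'   an untrained P3 never fires outside expansion periods.
#' @param p3_delays cycle of P3 output delays in steps (late firing spans
#'   a range; short delays carry within-moment completion links, long
#'   delays next-moment sequence links).
#' @param apical_branches_per_pcol deep apical branches wired per
#'   containing perirhinal column.
#' @param apical_syn P3 sources sampled per deep apical branch.
#' @param k_winners,retrieval_k_winners P3 recruitment caps per step during
#'   expansion periods and during retrieval.
#' @param retrieval_match_slope activity-dependent inhibition gain at
#'   retrieval: P3 recruitment requires a basal matched fraction of at
#'   least `retrieval_match_slope` times the fraction of deep units
#'   currently active.
#' @param refractory P3 refractory period in steps after firing.
#' @param candidacy_floor minimum II/III firing fraction for candidacy.
#' @param delta_deep,delta_p1,delta_p3,delta_apical per-pathway expansion
#'   increments.
#' @param ec_gain,decode_gain entorhinal summary and CA1 decode gains.
#' @param group_decay decay applied to a CA3 group's membership weights
#'   when the group is updated by a new co-expansion episode.
#' @param raise_window presentations per overdetection measurement window.
#' @param competition an `hcm_competition_config`.
#' @return an object of class `hcm_network_config`.
#' @export
network_config <- function(world = world_config(),
                           n_areas = 4L, columns_per_area = 16L,
                           n_l4 = 4L, n_l23 = 8L, n_deep = 3L,
                           support_size = 12L,
                           l4_syn = 8L,
                           l4_k_classes = c(3L, 4L, 5L, 6L, 7L),
                           deep_w_init = 0.0625, apical_w_init = 0.0625,
                           deep_w_max = 0.125, apical_w_max = 0.5,
                           apical_threshold = 0.5,
                           manager_weight = 0.5,
                           members_per_pcol = 3L, covers = 3L,
                           intermediate_weight = 0.125,
                           n_p1 = 1L, n_p2 = 2L, n_p3 = 18L,
                           p1_w_init = 0.1875, p1_w_max = 0.375,
                           p2_threshold = 0.1,
                           p3_basal_branches = 2L, p3_basal_syn = 12L,
                           p3_threshold = 0.625,
                           p3_w_init = 0.0625, p3_w_max = 0.5,
                           p3_delays = c(1L, 2L),
                           apical_branches_per_pcol = 1L, apical_syn = 6L,
                           k_winners = 3L, retrieval_k_winners = 3L,
                           retrieval_match_slope = 0,
                           refractory = 6L,
                           candidacy_floor = 0.5,
                           delta_deep = 0.0625, delta_p1 = 0.1875,
                           delta_p3 = 0.4375, delta_apical = 0.4375,
                           ec_gain = 1.0, decode_gain = 1.0,
                           group_decay = 0.98, raise_window = 20L,
                           competition = competition_config()) {
  structure(as.list(environment()), class = "hcm_network_config")
}

#' Build a network from a configuration and seed
#'
#' @param cfg an `hcm_network_config`.
#' @param seed integer seed for all wiring randomness (the stimulus world
#'   is built from `cfg$world`, whose own seed is set to `seed` unless the
#'   caller changed it from the default).
#' @return an object of class `hcm_network`.
#' @export
build_network <- function(cfg = network_config(), seed = 1L) {
  stopifnot(inherits(cfg, "hcm_network_config"))
  world <- make_world(cfg$world)
  n_cols <- cfg$n_areas * cfg$columns_per_area
  col_area <- rep(seq_len(cfg$n_areas), each = cfg$columns_per_area)
  col_context <- rep(seq_len(cfg$world$n_contexts), length.out = n_cols)

  with_seed(seed, {
    # ---- id layout -------------------------------------------------------
    nf <- cfg$world$n_features
    nxt <- nf
    take <- function(n) {
      ids <- (nxt + 1L):(nxt + n)
      nxt <<- nxt + n
      ids
    }
    l4_ids <- l23_ids <- deep_ids <- vector("list", n_cols)
    for (c in seq_len(n_cols)) {
      l4_ids[[c]] <- take(cfg$n_l4)
      l23_ids[[c]] <- take(cfg$n_l23)
      deep_ids[[c]] <- take(cfg$n_deep)
    }
    # perirhinal cover: `covers` independent partitions into member groups
    memberships <- list()
    for (cv in seq_len(cfg$covers)) {
      perm <- sample(n_cols)
      n_g <- max(1L, floor(n_cols / cfg$members_per_pcol))
      grp <- sort(rep_len(seq_len(n_g), n_cols))
      memberships <- c(memberships, unname(split(perm, grp)))
    }
    n_pcols <- length(memberships)
    int_ids <- p1_ids <- p2_ids <- p3_ids <- vector("list", n_pcols)
    for (p in seq_len(n_pcols)) {
      int_ids[[p]] <- take(length(memberships[[p]]))
      p1_ids[[p]] <- take(cfg$n_p1)
      p2_ids[[p]] <- take(cfg$n_p2)
      p3_ids[[p]] <- take(cfg$n_p3)
    }
    n_sources <- nxt
    pcols_of_col <- lapply(seq_len(n_cols), function(c)
      which(vapply(memberships, function(m) c %in% m, FALSE)))
    col_of_unit <- rep(NA_integer_, n_sources)

    # ---- cortical columns ------------------------------------------------
    columns <- vector("list", n_cols)
    names(columns) <- as.character(seq_len(n_cols))
    for (c in seq_len(n_cols)) {
      ctx <- world$contexts[[col_context[c]]]
      support <- sample(ctx, min(cfg$support_size, length(ctx)))
      k <- cfg$l4_k_classes[((c - 1L) %% length(cfg$l4_k_classes)) + 1L]
      w4 <- (1 + 1e-6) / k
      layer4 <- lapply(seq_len(cfg$n_l4), function(i) {
        brs <- list(new_branch(sample(support, min(cfg$l4_syn,
                                                   length(support))),
                               rep(w4, min(cfg$l4_syn, length(support))),
                               threshold = 1.0))
        new_unit(l4_ids[[c]][i], new_tree(brs, 1L, "basal"),
                 kind = "layer4", column = c, area = col_area[c])
      })
      layer23 <- lapply(seq_len(cfg$n_l23), function(i) {
        src <- sample(l4_ids[[c]], 3L)
        brs <- list(new_branch(src, rep(0.5, 3L), threshold = 1.0))
        new_unit(l23_ids[[c]][i], new_tree(brs, 1L, "basal"),
                 kind = "layer23", column = c, area = col_area[c])
      })
      own_pcols <- pcols_of_col[[c]]
      deep <- lapply(seq_len(cfg$n_deep), function(i) {
        mgr_pcol <- own_pcols[((i - 1L) %% length(own_pcols)) + 1L]
        basal <- list(new_branch(l23_ids[[c]],
                                 rep(cfg$deep_w_init, cfg$n_l23),
                                 threshold = 1.0,
                                 manager_source = p2_ids[[mgr_pcol]][1],
                                 manager_weight = cfg$manager_weight,
                                 w_max = cfg$deep_w_max))
        ap <- list()
        for (pp in own_pcols) {
          for (b in seq_len(cfg$apical_branches_per_pcol)) {
            ns <- min(cfg$apical_syn, length(p3_ids[[pp]]))
            ap[[length(ap) + 1L]] <-
              new_branch(sample(p3_ids[[pp]], ns),
                         rep(cfg$apical_w_init, ns),
                         threshold = cfg$apical_threshold,
                         manager_source = p2_ids[[pp]][1],
                         manager_weight = cfg$manager_weight,
                         w_max = cfg$apical_w_max)
          }
        }
        new_unit(deep_ids[[c]][i], new_tree(basal, 1L, "basal"),
                 apical = new_tree(ap, 1L, role = "apical"),
                 kind = "deep", column = c, area = col_area[c])
      })
      for (u in c(layer4, layer23, deep)) col_of_unit[u$id] <- c
      columns[[c]] <- new_column(c, col_area[c], layer4, layer23, deep,
                                 candidacy_floor = cfg$candidacy_floor)
    }

    # ---- perirhinal columns ----------------------------------------------
    pcols <- vector("list", n_pcols)
    for (p in seq_len(n_pcols)) {
      members <- memberships[[p]]
      inter <- lapply(seq_along(members), function(i) {
        src <- l23_ids[[members[i]]]
        brs <- list(new_branch(src, rep(cfg$intermediate_weight,
                                        length(src)),
                               threshold = 1.0))
        new_unit(int_ids[[p]][i], new_tree(brs, 1L, "basal"),
                 kind = "intermediate")
      })
      P1 <- lapply(seq_len(cfg$n_p1), function(i) {
        brs <- list(new_branch(int_ids[[p]],
                               rep(cfg$p1_w_init, length(int_ids[[p]])),
                               threshold = 1.0,
                               manager_source = p2_ids[[p]][1],
                               manager_weight = cfg$manager_weight,
                               w_max = cfg$p1_w_max))
        new_unit(p1_ids[[p]][i], new_tree(brs, 1L, "basal"), kind = "P1")
      })
      deep_pool <- unlist(deep_ids[members])
      P3 <- lapply(seq_len(cfg$n_p3), function(i) {
        ns <- min(cfg$p3_basal_syn, length(deep_pool))
        brs <- lapply(seq_len(cfg$p3_basal_branches), function(b)
          new_branch(sample(deep_pool, ns), rep(cfg$p3_w_init, ns),
                     threshold = cfg$p3_threshold,
                     manager_source = p2_ids[[p]][1],
                     manager_weight = cfg$manager_weight,
                     w_max = cfg$p3_w_max))
        apical <- new_tree(list(new_branch(p2_ids[[p]],
                                           rep(1.0, length(p2_ids[[p]])),
                                           threshold = 1.0)),
                           1L, role = "apical")
        delay <- cfg$p3_delays[((i - 1L) %% length(cfg$p3_delays)) + 1L]
        new_unit(p3_ids[[p]][i], new_tree(brs, 1L, "basal"),
                 apical = apical, kind = "P3", delay = delay)
      })
      pcols[[p]] <- new_perirhinal_column(p, members, inter, P1,
                                          p2_ids[[p]], cfg$p2_threshold,
                                          P3, cfg$k_winners,
                                          cfg$refractory)
    }

    # ---- hippocampal groups ----------------------------------------------
    n_ca3 <- cfg$competition$n_ca3
    W <- matrix(0, n_ca3, n_pcols)
    for (p in seq_len(n_pcols)) {
      W[sample(n_ca3, min(2L, n_ca3)), p] <- 1
    }

    # recent_window = 1: the backpropagation rule binds strictly
    # same-step coincidences, which is what keeps episodic links
    # moment-specific (delayed P3 output then selects the following
    # moment, not a smear over the window)
    plasticity <- list(
      deep = plasticity_config(delta_w = cfg$delta_deep,
                               recent_window = 1L),
      p1 = plasticity_config(delta_w = cfg$delta_p1, recent_window = 1L),
      p3 = plasticity_config(delta_w = cfg$delta_p3, recent_window = 1L),
      apical = plasticity_config(delta_w = cfg$delta_apical,
                                 recent_window = 1L))

    structure(list(cfg = cfg, world = world, columns = columns,
                   pcols = pcols, comp_cfg = cfg$competition,
                   group_weights = W,
                   plasticity = plasticity, frozen = FALSE,
                   n_sources = n_sources,
                   deep_ids = deep_ids, l23_ids = l23_ids,
                   l4_ids = l4_ids, p3_ids = p3_ids, p2_ids = p2_ids,
                   col_area = col_area, col_of_unit = col_of_unit,
                   step = 0L, presentation = 0L,
                   det_counts = numeric(n_cols),
                   pending = data.frame(unit = integer(0),
                                        emit_step = integer(0)),
                   logs = list(activity = list(), weights = list(),
                               competition = list(), driven = list()),
                   episodes = list()),
              class = "hcm_network")
  })
}

#' Sum of all synaptic weights in the network
#'
#' The checksum used by the retrieval-purity assertions.
#' @param net an `hcm_network`.
#' @return numeric scalar.
#' @export
network_weight_sum <- function(net) {
  s <- 0
  for (col in net$columns) {
    for (lay in c("layer4", "layer23", "deep")) {
      for (u in col[[lay]]) s <- s + unit_weight_sum(u)
    }
  }
  for (p in net$pcols) {
    for (lay in c("intermediate", "P1", "P3")) {
      for (u in p[[lay]]) s <- s + unit_weight_sum(u)
    }
  }
  s
}
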