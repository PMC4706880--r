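#' @title Dentate gyrus / CA3 competition: novelty into expansion-target selection
#'
#' @description
#' The hippocampus proper is modelled as a small rate network with
#' clipped-linear units. Entorhinal input summarizes per-area cortical
#' detection rates. Granule cells relay that input to CA3 through two paths:
#' a direct excitatory one and an interneuron-mediated inhibitory one that
#' switches on above a granule-activity crossover, so that high granule
#' activity (a familiar situation, high detection rates everywhere)
#' suppresses CA3 entirely, while depressed granule activity (novelty)
#' lets CA3 activity build through its recurrent excitation. Growing CA3
#' activity feeds back through mossy cells onto the granule population,
#' recruiting its own inhibition: the rise is self-limiting, and the
#' equilibrium CA3 activity is proportional to the degree of novelty.
#' Once the competition has converged the equilibrium is released (the
#' abstraction of the septal theta-band release) and decoded into drive on
#' the perirhinal P2 populations of the column groups represented by the
#' active CA3 units.
#'
#' @name hippocampus
NULL

#' Competition configuration
#'
#' All units are rate-valued with activity in `[0, activity_cap]` and
#' clipped-linear transfer. Gains must satisfy the dominance requirement:
#' at saturated granule activity the inhibitory path must outweigh the sum
#' of granule excitation and the CA3 baseline, so that a fully familiar
#' input yields exactly zero CA3 activity.
#'
#' @param n_ca3 number of CA3 units (each representing one column group).
#' @param w_rec CA3 recurrent excitatory gain.
#' @param w_gc_exc granule-to-CA3 excitatory gain.
#' @param w_gc_inh granule-to-CA3 interneuron-mediated inhibitory gain.
#' @param gc_inh_theta granule activity at which the inhibitory
#'   interneuron path switches on (the excitation/inhibition crossover).
#' @param w_mossy CA3-to-mossy feedback gain.
#' @param ca3_baseline tonic CA3 excitability allowing activity to seed
#'   when granule drive is absent (complete novelty).
#' @param tol convergence tolerance on the max per-unit change.
#' @param max_iter iteration cap.
#' @param activity_cap saturation level of every unit.
#' @param relax relaxation factor of the synchronous update (in `(0, 1]`).
#' @param area_weights optional `n_ca3 x n_areas` non-negative matrix
#'   mapping entorhinal per-area input onto CA3 units (rows are normalized);
#'   default: every unit reads the mean over all areas.
#' @return an object of class `hcm_competition_config`.
#' @export
competition_config <- function(n_ca3 = 8L, w_rec = 0.5, w_gc_exc = 1.0,
                               w_gc_inh = 4.0, gc_inh_theta = 0.55,
                               w_mossy = 1.0, ca3_baseline = 0.2,
                               tol = 1e-6, max_iter = 500L,
                               activity_cap = 1.0, relax = 0.4,
                               area_weights = NULL) {
  stopifnot(w_rec >= 0, w_gc_exc >= 0, w_gc_inh >= 0, w_mossy >= 0,
            ca3_baseline >= 0, tol > 0, max_iter >= 1, activity_cap > 0,
            relax > 0, relax <= 1, gc_inh_theta >= 0)
  # dominance: saturated granule input must yield net CA3 suppression
  if (w_gc_exc * activity_cap + ca3_baseline -
      w_gc_inh * max(0, activity_cap - gc_inh_theta) >= 0) {
    stop("inhibitory path does not dominate at saturated granule activity; ",
         "increase w_gc_inh or lower gc_inh_theta")
  }
  structure(list(n_ca3 = as.integer(n_ca3), w_rec = w_rec,
                 w_gc_exc = w_gc_exc, w_gc_inh = w_gc_inh,
                 gc_inh_theta = gc_inh_theta, w_mossy = w_mossy,
                 ca3_baseline = ca3_baseline, tol = tol,
                 max_iter = as.integer(max_iter),
                 activity_cap = activity_cap, relax = relax,
                 area_weights = area_weights),
            class = "hcm_competition_config")
}

#' Summarize per-area detection rates into entorhinal input
#'
#' A monotone increasing, pointwise map from the fraction of columns
#' producing output in each area to the entorhinal drive derived from that
#' area. Default is the identity (gain 1, clipped to `[0, 1]`).
#'
#' @param area_rates named numeric vector of per-area detection rates in
#'   `[0, 1]`.
#' @param gain multiplicative gain applied before clipping.
#' @return numeric vector of entorhinal inputs, same names and order.
#' @export
summarize_entorhinal <- function(area_rates, gain = 1.0) {
  stopifnot(all(area_rates >= 0), all(area_rates <= 1), gain > 0)
  pmin(area_rates * gain, 1.0)
}

.clip <- function(x, cap) pmin(pmax(x, 0), cap)

#' Run the DG-CA3 competition to equilibrium
#'
#' Iterates the synchronous relaxation update
#' granule = f(ec + mossy feedback);
#' ca3 = f(recurrent + baseline + granule excitation - granule-gated
#' inhibition); mossy = f(w_mossy * mean(ca3)); until the max per-unit
#' change drops below `tol` or `max_iter` is reached. Non-convergence
#' returns a state with `converged = FALSE` and a warning, never an error.
#'
#' @param ec_input numeric vector of per-area entorhinal inputs in
#'   `[0, activity_cap]`.
#' @param cfg an `hcm_competition_config`.
#' @return an object of class `hcm_hippocampus_state` with fields
#'   `ec_input`, `granule`, `mossy`, `ca3`, `iteration`, `converged`,
#'   `max_ca3_iter` (largest per-unit CA3 activity seen at any
#'   iteration, for boundedness checks), and `selection` (filled by
#'   [release_and_decode()]).
#' @export
run_competition <- function(ec_input, cfg) {
  n_area <- length(ec_input)
  A <- cfg$area_weights
  if (is.null(A)) A <- matrix(1 / n_area, nrow = cfg$n_ca3, ncol = n_area)
  stopifnot(nrow(A) == cfg$n_ca3, ncol(A) == n_area, all(A >= 0))
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A <- A / rs

  cap <- cfg$activity_cap
  granule <- .clip(ec_input, cap)
  mossy <- numeric(n_area)
  ca3 <- numeric(cfg$n_ca3)
  converged <- FALSE
  iter <- 0L
  max_ca3_iter <- 0
  for (iter in seq_len(cfg$max_iter)) {
    g_new <- .clip(ec_input + mossy, cap)
    net_g <- cfg$w_gc_exc * g_new -
      cfg$w_gc_inh * pmax(0, g_new - cfg$gc_inh_theta)
    drive <- cfg$w_rec * ca3 + cfg$ca3_baseline + as.vector(A %*% net_g)
    ca3_new <- .clip(drive, cap)
    mossy_new <- rep(.clip(cfg$w_mossy * mean(ca3_new), cap), n_area)
    delta <- max(abs(ca3_new - ca3), abs(g_new - granule),
                 abs(mossy_new - mossy))
    r <- cfg$relax
    ca3 <- (1 - r) * ca3 + r * ca3_new
    granule <- (1 - r) * granule + r * g_new
    mossy <- (1 - r) * mossy + r * mossy_new
    max_ca3_iter <- max(max_ca3_iter, ca3, ca3_new)
    if (delta < cfg$tol) {
      converged <- TRUE
      # land exactly on the fixed point (relaxation leaves a residual)
      ca3 <- ca3_new; granule <- g_new; mossy <- mossy_new
      break
    }
  }
  if (!converged) warning("DG-CA3 competition did not converge within ",
                          cfg$max_iter, " iterations")
  structure(list(ec_input = ec_input, granule = granule, mossy = mossy,
                 ca3 = ca3, iteration = iter, converged = converged,
                 max_ca3_iter = max(max_ca3_iter, ca3),
                 selection = NULL),
            class = "hcm_hippocampus_state")
}

#' Release the converged CA3 pattern and decode it into P2 drive
#'
#' The release gate abstracts the septal theta release: only a converged
#' competition is decoded; an unconverged state yields zero drive
#' everywhere. Drive to each perirhinal column is the sum of equilibrium
#' activity of the CA3 units whose column groups include it.
#'
#' @param state an `hcm_hippocampus_state`.
#' @param membership `n_ca3 x n_pcols` non-negative (usually binary) matrix;
#'   `membership[j, p] > 0` means perirhinal column `p` belongs to the
#'   column group represented by CA3 unit `j`.
#' @param decode_gain multiplicative gain on the decoded drive.
#' @return the state with `selection` set to the per-perirhinal-column
#'   numeric drive vector.
#' @export
release_and_decode <- function(state, membership, decode_gain = 1.0) {
  stopifnot(inherits(state, "hcm_hippocampus_state"),
            nrow(membership) == length(state$ca3))
  if (!state$converged) {
    state$selection <- numeric(ncol(membership))
  } else {
    state$selection <- decode_gain *
      as.vector(t(membership > 0) %*% state$ca3)
  }
  state
}

#' Total equilibrium CA3 activity of a competition state
#' @param state an `hcm_hippocampus_state`.
#' @return numeric scalar, `sum(state$ca3)`.
#' @export
total_ca3 <- function(state) sum(state$ca3)
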