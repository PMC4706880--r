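#' @title Synthetic sensory world: contexts, novelty, and episodic events
#'
#' @description
#' Stimuli are sets of abstract feature identifiers. A *context* is a fixed
#' random pattern of features drawn from a designated context pool; a
#' fraction of the feature space is reserved as a novelty reservoir whose
#' features are never used by any context, so replacing context features
#' with reservoir features guarantees genuine novelty (the replaced
#' fraction is the stimulus's novelty label). Events are ordered sequences
#' of overlapping moments, each carrying nonzero novelty so that encoding
#' triggers receptive-field expansion. All sampling is integer-only and
#' deterministic given the seed.
#'
#' @name stimuli
NULL

#' World configuration
#'
#' @param n_features total number of abstract features.
#' @param n_contexts number of familiar context patterns.
#' @param pattern_density fraction of `n_features` active in a pattern.
#' @param reservoir_fraction fraction of the feature space reserved for
#'   novel features (never used by contexts).
#' @param event_length default number of moments per event.
#' @param event_overlap fraction of features shared by consecutive event
#'   moments.
#' @param event_novelty novelty fraction carried by each event moment.
#' @param rng_seed integer seed governing all world sampling.
#' @return an object of class `hcm_world_config`.
#' @export
world_config <- function(n_features = 128L, n_contexts = 1L,
                         pattern_density = 0.25, reservoir_fraction = 0.35,
                         event_length = 3L, event_overlap = 0.5,
                         event_novelty = 0.5, rng_seed = 1L) {
  stopifnot(n_features >= 8, n_contexts >= 1,
            pattern_density > 0, pattern_density < 1,
            reservoir_fraction > 0, reservoir_fraction < 1,
            event_length >= 1, event_overlap >= 0, event_overlap < 1,
            event_novelty >= 0, event_novelty <= 1)
  structure(list(n_features = as.integer(n_features),
                 n_contexts = as.integer(n_contexts),
                 pattern_density = pattern_density,
                 reservoir_fraction = reservoir_fraction,
                 event_length = as.integer(event_length),
                 event_overlap = event_overlap,
                 event_novelty = event_novelty,
                 rng_seed = as.integer(rng_seed)),
            class = "hcm_world_config")
}

# evaluate `expr` under a local RNG stream seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Materialize a world: context patterns and the novelty reservoir
#'
#' @param cfg an `hcm_world_config`.
#' @return an object of class `hcm_world` with fields `cfg`, `pool`
#'   (context-eligible feature ids), `reservoir` (novel feature ids),
#'   `contexts` (list of feature-id vectors), `pattern_size`.
#' @export
make_world <- function(cfg) {
  stopifnot(inherits(cfg, "hcm_world_config"))
  n_pool <- cfg$n_features - as.integer(round(cfg$reservoir_fraction *
                                                cfg$n_features))
  pool <- seq_len(n_pool)
  reservoir <- setdiff(seq_len(cfg$n_features), pool)
  pattern_size <- max(2L, as.integer(round(cfg$pattern_density *
                                             cfg$n_features)))
  stopifnot(pattern_size <= n_pool)
  contexts <- with_seed(cfg$rng_seed, {
    lapply(seq_len(cfg$n_contexts),
           function(i) sort(sample(pool, pattern_size)))
  })
  structure(list(cfg = cfg, pool = pool, reservoir = reservoir,
                 contexts = contexts, pattern_size = pattern_size),
            class = "hcm_world")
}

.new_stimulus <- function(features, novelty, context = NA_integer_,
                          event_id = NA_integer_, moment = NA_integer_) {
  structure(list(features = sort(as.integer(features)),
                 novelty_label = novelty, context = context,
                 event_id = event_id, moment_index = moment),
            class = "hcm_stimulus")
}

#' Generate a blocked stimulus stream
#'
#' Within each block, every stimulus starts from the block's context
#' pattern and replaces `novelty_fraction` of its features with features
#' drawn from the novelty reservoir (resampled per presentation), so the
#' replaced features are guaranteed never to occur in any context.
#'
#' @param world an `hcm_world`.
#' @param schedule list of blocks, each a list with elements `context`
#'   (context index), `novelty_fraction`, and `n_presentations`.
#' @param seed optional integer overriding the world seed for stream
#'   sampling (so repeated blocks can differ across seeds).
#' @return ordered list of `hcm_stimulus` objects.
#' @export
generate_stream <- function(world, schedule, seed = world$cfg$rng_seed) {
  stopifnot(inherits(world, "hcm_world"))
  with_seed(seed, {
    out <- list()
    for (blk in schedule) {
      f <- blk$novelty_fraction
      stopifnot(f >= 0, f <= 1, blk$context >= 1,
                blk$context <= length(world$contexts))
      pat <- world$contexts[[blk$context]]
      k_new <- as.integer(round(f * length(pat)))
      if (k_new > length(world$reservoir)) {
        stop("novelty features exhausted: stimulus needs ", k_new,
             " novel features but the reservoir holds ",
             length(world$reservoir))
      }
      for (i in seq_len(blk$n_presentations)) {
        if (k_new == 0) {
          feats <- pat
        } else {
          drop <- sample(seq_along(pat), k_new)
          feats <- c(pat[-drop], sample(world$reservoir, k_new))
        }
        out[[length(out) + 1L]] <- .new_stimulus(feats, f, blk$context)
      }
    }
    out
  })
}

#' Generate a multi-moment event for episodic encoding
#'
#' Moments are distinct but overlapping patterns, each carrying nonzero
#' novelty (events must be encodable, i.e. able to trigger expansion).
#' Consecutive moments share `event_overlap` of their features; the
#' non-shared part is refreshed from the context pattern and the novelty
#' reservoir.
#'
#' @param world an `hcm_world`.
#' @param event_length number of moments (default from the world config).
#' @param context context index the event is embedded in.
#' @param event_id integer tag carried by every moment.
#' @param seed integer seed for event sampling.
#' @return ordered list of `hcm_stimulus` objects with `moment_index`
#'   `0 .. event_length - 1`.
#' @export
generate_event <- function(world, event_length = world$cfg$event_length,
                           context = 1L, event_id = 1L,
                           seed = world$cfg$rng_seed + 1000L) {
  stopifnot(inherits(world, "hcm_world"), event_length >= 1)
  nf <- world$cfg$event_novelty
  if (nf <= 0) stop("events must carry nonzero novelty to be encodable")
  pat <- world$contexts[[context]]
  m <- length(pat)
  k_new <- max(1L, as.integer(round(nf * m)))
  n_ctx <- m - k_new
  k_keep <- as.integer(round(world$cfg$event_overlap * n_ctx))
  with_seed(seed, {
    # every moment carries the same composition: n_ctx context features
    # (a fraction carried over from the previous moment) plus k_new fresh
    # reservoir features, so familiarity stays constant across moments
    # while each moment is distinct and genuinely novel
    moments <- vector("list", event_length)
    prev_ctx <- prev2_ctx <- integer(0)
    for (k in seq_len(event_length)) {
      base <- if (k == 1) integer(0) else sample(prev_ctx, k_keep)
      # refresh preferentially from features absent in recent moments,
      # falling back to features of the immediately preceding moment, so
      # feature overlap decays with temporal distance
      n_fill <- n_ctx - length(base)
      fresh <- setdiff(pat, c(base, prev_ctx, prev2_ctx))
      fill <- sample(fresh, min(n_fill, length(fresh)))
      if (length(fill) < n_fill) {
        more <- setdiff(pat, c(base, fill, prev2_ctx))
        fill <- c(fill, sample(more, min(n_fill - length(fill),
                                         length(more))))
      }
      if (length(fill) < n_fill) {
        fill <- c(fill, sample(setdiff(pat, c(base, fill)),
                               n_fill - length(fill)))
      }
      ctx_part <- c(base, fill)
      prev2_ctx <- prev_ctx
      if (k_new > length(world$reservoir)) {
        stop("novelty features exhausted while building event moment")
      }
      nov_part <- sample(world$reservoir, k_new)
      moments[[k]] <- .new_stimulus(c(ctx_part, nov_part), nf, context,
                                    event_id, k - 1L)
      prev_ctx <- ctx_part
    }
    moments
  })
}

#' Serialize a stimulus list to line-oriented JSON
#'
#' One stimulus per line, replayable with [read_stream()].
#' @param stimuli list of `hcm_stimulus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(stimuli, path) {
  lines <- vapply(stimuli, function(s) {
    jsonlite::toJSON(list(features = s$features,
                          novelty_label = s$novelty_label,
                          context = s$context, event_id = s$event_id,
                          moment_index = s$moment_index),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a line-oriented JSON stimulus stream
#' @param path file written by [write_stream()].
#' @return list of `hcm_stimulus`.
#' @export
read_stream <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln)
    .new_stimulus(x$features, x$novelty_label,
                  if (is.null(x$context)) NA_integer_ else x$context,
                  if (is.null(x$event_id)) NA_integer_ else x$event_id,
                  if (is.null(x$moment_index)) NA_integer_ else
                    x$moment_index)
  })
}
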