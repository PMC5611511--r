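# Seeded generator of benchmark-like fixed-point-network response
# collections: nonnegative node patterns, saturating-rise envelopes,
# Gaussian-then-clip noise at a configurable SNR, and mixture stimuli as
# superpositions of constituent patterns.

#' Default mixture stimuli for the benchmark-like collection
#'
#' Three behavioral mixtures built from the first three constituents
#' (B1 the equal-weight blend, B2/B3 near-equal perturbations of the same
#' constituents), five non-behavioral mixtures (a blend missing one
#' constituent, one with a replaced constituent, and unrelated blends),
#' and a noise-only control.
#'
#' @param m number of mono-molecular stimuli (>= 8 for the full set).
#' @return list of mixture definitions: `label`, `weights` (length m),
#'   `class`.
#' @export
default_mixtures <- function(m = 8L) {
  wt <- function(...) {
    w <- numeric(m)
    idx <- list(...)
    for (p in idx) w[p[[1]]] <- p[[2]]
    w
  }
  stopifnot(m >= 8L)
  list(
    list(label = "B1", class = "behavioral",
         weights = wt(list(1, 1), list(2, 1), list(3, 1))),
    list(label = "B2", class = "behavioral",
         weights = wt(list(1, 0.9), list(2, 1.1), list(3, 1))),
    list(label = "B3", class = "behavioral",
         weights = wt(list(1, 1.1), list(2, 0.9), list(3, 1))),
    list(label = "E1", class = "non-behavioral",
         weights = wt(list(1, 1), list(2, 1))),
    list(label = "E2", class = "non-behavioral",
         weights = wt(list(1, 1), list(2, 1), list(4, 1))),
    list(label = "E3", class = "non-behavioral",
         weights = wt(list(4, 1), list(5, 1))),
    list(label = "E4", class = "non-behavioral",
         weights = wt(list(5, 1), list(6, 1), list(7, 1))),
    list(label = "E5", class = "non-behavioral",
         weights = wt(list(7, 1), list(8, 1))),
    list(label = "E6", class = "control", weights = numeric(m))
  )
}

#' Configuration of the synthetic fixed-point-network simulator
#'
#' Defaults emulate the structure of the olfactory benchmark: 106 nodes,
#' 8 mono-molecular stimuli, 5 trials, 1 s recordings sampled at 10 ms
#' with the stimulus ON during the first 500 ms, SNR 3, and mixtures that
#' superpose constituent patterns.
#'
#' @param nodes number of recorded nodes N.
#' @param n_stimuli number of mono-molecular stimuli m.
#' @param trials trials per stimulus.
#' @param n_time time samples per trial.
#' @param dt sampling interval (s).
#' @param on_window stimulus-ON interval `[t_on, t_off)` (s).
#' @param snr signal-to-noise ratio: time-averaged signal power over the
#'   ON window divided by the noise variance, per node, averaged over
#'   assigned nodes. Must be `> 0`; `Inf` disables noise.
#' @param support_overlap fraction of nodes in `[0, 1]` whose pattern
#'   support is shared by all stimuli (with distinct weights); the rest
#'   are split disjointly among stimuli.
#' @param mixtures list of mixture definitions as in [default_mixtures()];
#'   weights must be nonnegative with indices `< n_stimuli`.
#' @param amplitude range (spikes/s) from which per-node pattern weights
#'   are drawn uniformly.
#' @param tau_rise ON-envelope time constant (s): `a(t) = 1 - exp(-t/tau)`,
#'   reaching the fixed point's vicinity within 200–400 ms.
#' @param tau_decay OFF decay time constant (s).
#' @param seed integer seed; the whole collection is reproducible from it.
#' @return `fp_config` list.
#' @export
synthetic_config <- function(nodes = 106L, n_stimuli = 8L, trials = 5L,
                             n_time = 100L, dt = 0.01,
                             on_window = c(0, 0.5), snr = 3,
                             support_overlap = 0.15,
                             mixtures = default_mixtures(n_stimuli),
                             amplitude = c(20, 60),
                             tau_rise = 0.1, tau_decay = 0.1, seed = 0L) {
  if (!is.numeric(snr) || snr <= 0) stop("'snr' must be > 0")
  if (support_overlap < 0 || support_overlap > 1)
    stop("'support_overlap' must be in [0, 1]")
  for (mx in mixtures) {
    if (length(mx$weights) != n_stimuli || any(mx$weights < 0))
      stop("mixture weights must be nonnegative with one entry per mono stimulus")
  }
  structure(list(nodes = as.integer(nodes), n_stimuli = as.integer(n_stimuli),
                 trials = as.integer(trials), n_time = as.integer(n_time),
                 dt = dt, on_window = on_window, snr = snr,
                 support_overlap = support_overlap, mixtures = mixtures,
                 amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay, seed = as.integer(seed)),
            class = "fp_config")
}

#' Draw ground-truth node patterns
#'
#' `round(support_overlap * N)` nodes respond to every stimulus (distinct
#' uniform weights); the remaining nodes are split as evenly as possible
#' into disjoint per-stimulus supports. The per-node ETR ground truth is
#' the stimulus with the maximal pattern weight.
#'
#' @param config an [synthetic_config()].
#' @return `fp_truth` with fields `patterns` (N x m nonnegative),
#'   `assignment` (integer per node), `shared_nodes`, `mixtures`,
#'   `noise_sd` (set when responses are generated), `config`.
#' @export
generate_patterns <- function(config) {
  stopifnot(inherits(config, "fp_config"))
  set.seed(config$seed)
  N <- config$nodes; m <- config$n_stimuli
  n_shared <- round(config$support_overlap * N)
  shared <- if (n_shared > 0) seq_len(n_shared) else integer(0)
  own <- setdiff(seq_len(N), shared)
  G <- matrix(0, N, m)
  if (length(shared))
    G[shared, ] <- matrix(stats::runif(length(shared) * m,
                                       config$amplitude[1],
                                       config$amplitude[2]),
                          length(shared), m)
  owner <- rep(seq_len(m), length.out = length(own))
  for (k in seq_along(own))
    G[own[k], owner[k]] <- stats::runif(1, config$amplitude[1],
                                        config$amplitude[2])
  assignment <- max.col(G, ties.method = "first")
  colnames(G) <- paste0("S", seq_len(m))
  # collection-level noise sd: mean ON-window signal power of the mono
  # stimuli over their assigned nodes, divided by snr
  env2 <- mean(envelope(config)[on_indices_cfg(config)]^2)
  pow <- mean(vapply(seq_len(m), function(i) {
    nodes <- which(assignment == i & G[, i] > 0)
    mean(G[nodes, i]^2) * env2
  }, numeric(1)))
  noise_sd <- if (is.finite(config$snr)) sqrt(pow / config$snr) else 0
  structure(list(patterns = G, assignment = assignment,
                 shared_nodes = shared, mixtures = config$mixtures,
                 noise_sd = noise_sd, config = config),
            class = "fp_truth")
}

on_indices_cfg <- function(config) {
  t <- (seq_len(config$n_time) - 1L) * config$dt
  which(t >= config$on_window[1] & t < config$on_window[2] - 1e-12)
}

# Temporal envelope: saturating rise while the stimulus is ON,
# exponential decay after OFF.
envelope <- function(config) {
  t <- (seq_len(config$n_time) - 1L) * config$dt
  a <- numeric(config$n_time)
  on <- t >= config$on_window[1] & t < config$on_window[2] - 1e-12
  a[on] <- 1 - exp(-(t[on] - config$on_window[1]) / config$tau_rise)
  off <- t >= config$on_window[2] - 1e-12
  if (any(off)) {
    a_off <- 1 - exp(-(config$on_window[2] - config$on_window[1]) / config$tau_rise)
    a[off] <- a_off * exp(-(t[off] - config$on_window[2]) / config$tau_decay)
  }
  a
}

mixture_weights <- function(truth, stimulus) {
  m <- truth$config$n_stimuli
  mono <- paste0("S", seq_len(m))
  if (stimulus %in% mono) {
    w <- numeric(m); w[match(stimulus, mono)] <- 1
    return(w)
  }
  for (mx in truth$mixtures) if (mx$label == stimulus) return(mx$weights)
  stop(sprintf("unknown stimulus label '%s'", stimulus))
}

#' Generate one trial's response
#'
#' The signal is `a(t) * (G %*% weights)` (saturating-rise envelope times
#' the superposed pattern); i.i.d. Gaussian noise with the
#' collection-level standard deviation is added and the result is clipped
#' at zero. The noise stream is seeded deterministically from
#' `(seed, stimulus, trial)`, so the same trial is reproducible while the
#' signal component is identical across trials.
#'
#' @param truth an [generate_patterns()] output.
#' @param stimulus mono label (`"S1"`...) or a mixture label from the
#'   config.
#' @param trial trial index (>= 1).
#' @param config the [synthetic_config()]; defaults to the one in `truth`.
#' @return `fp_response`.
#' @export
generate_response <- function(truth, stimulus, trial = 1L,
                              config = truth$config) {
  stopifnot(inherits(truth, "fp_truth"))
  w <- mixture_weights(truth, stimulus)
  signal <- outer(as.numeric(truth$patterns %*% w), envelope(config))
  stim_id <- match(stimulus,
                   c(paste0("S", seq_len(config$n_stimuli)),
                     vapply(truth$mixtures, `[[`, character(1), "label")))
  set.seed((config$seed %% 100000L) * 20011L + stim_id * 211L + as.integer(trial))
  noise <- if (truth$noise_sd > 0)
    matrix(stats::rnorm(length(signal), sd = truth$noise_sd),
           nrow(signal), ncol(signal))
  else 0
  rates <- pmax(signal + noise, 0)
  response_matrix(rates, stimulus = stimulus, trial = as.integer(trial),
                  dt = config$dt, on_window = config$on_window)
}

#' Generate a full benchmark-like collection
#'
#' Produces the complete stimulus set — `n_stimuli` mono-molecular stimuli
#' plus every configured mixture (by default 8 mono + 3 behavioral + 5
#' non-behavioral + 1 noise-only control = 17 stimuli) — with `trials`
#' trials each, together with the latent ground truth.
#'
#' @param config an [synthetic_config()].
#' @return list with elements `collection` (`fp_collection`) and `truth`
#'   (`fp_truth`).
#' @export
generate_benchmark_like <- function(config = synthetic_config()) {
  truth <- generate_patterns(config)
  mono <- paste0("S", seq_len(config$n_stimuli))
  labels <- c(mono, vapply(config$mixtures, `[[`, character(1), "label"))
  classes <- c(stats::setNames(rep("non-behavioral", length(mono)), mono),
               stats::setNames(vapply(config$mixtures, `[[`, character(1), "class"),
                               vapply(config$mixtures, `[[`, character(1), "label")))
  responses <- list()
  for (s in labels)
    for (k in seq_len(config$trials))
      responses[[length(responses) + 1L]] <-
        generate_response(truth, s, k, config)
  list(collection = response_collection(responses, class_labels = classes),
       truth = truth)
}
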