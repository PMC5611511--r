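# Shared fixtures, all generated in code.

# Small hand-assembled collection: `value_fn(stim_index, trial, node, sample)`
# lets tests plant recognizable values.
make_manual_collection <- function(n_stimuli = 2L, trials = 2L, nodes = 4L,
                                   n_time = 100L, dt = 0.01,
                                   on_window = c(0, n_time * dt / 2),
                                   value_fn = function(s, k, n, t) 1) {
  responses <- list()
  for (s in seq_len(n_stimuli)) {
    for (k in seq_len(trials)) {
      rates <- outer(seq_len(nodes), seq_len(n_time),
                     Vectorize(function(n, t) value_fn(s, k, n, t)))
      responses[[length(responses) + 1L]] <-
        response_matrix(rates, stimulus = paste0("S", s), trial = k,
                        dt = dt, on_window = on_window)
    }
  }
  response_collection(responses)
}

# Noiseless collection with disjoint-support patterns; ideal for recovery.
make_disjoint_collection <- function(nodes = 12L, n_stimuli = 3L,
                                     trials = 2L, seed = 1L) {
  cfg <- synthetic_config(nodes = nodes, n_stimuli = n_stimuli,
                          trials = trials, snr = Inf, support_overlap = 0,
                          mixtures = list(), seed = seed)
  generate_benchmark_like(cfg)
}

# A small but complete benchmark-like simulation (8 mono + 9 mixtures).
make_benchmark_sim <- function(nodes = 60L, trials = 3L, snr = 20,
                               seed = 1L) {
  generate_benchmark_like(synthetic_config(nodes = nodes, trials = trials,
                                           snr = snr, seed = seed))
}

rand_library <- function(nodes, m, seed, positive = FALSE) {
  set.seed(seed)
  v <- if (positive) stats::runif(nodes * m, 0.1, 1) else stats::rnorm(nodes * m)
  matrix(v, nodes, m)
}

# Brute-force row-wise argmax/threshold oracle for ETR.
etr_oracle <- function(L, tau) {
  O <- matrix(0, nrow(L), ncol(L))
  for (i in seq_len(nrow(L))) {
    best <- 1L
    for (j in seq_len(ncol(L))[-1]) if (L[i, j] > L[i, best]) best <- j
    if (L[i, best] > tau) O[i, best] <- L[i, best]
  }
  O
}

# Closed-form least-squares oracle for the OETR objective: the entries of
# t(L) %*% diag(w) %*% O are linear in w, so stack them as the single
# vectorized system A w = vec(I) and take the minimum-norm least-squares
# solution of the whole system at once (MASS::ginv), independently of the
# per-stimulus block solver in the package.
oetr_oracle <- function(L, O) {
  m <- ncol(L)
  assigned <- which(rowSums(O != 0) > 0)
  A <- matrix(0, m * m, length(assigned))
  b <- as.numeric(diag(m))
  for (cdx in seq_along(assigned)) {
    n <- assigned[cdx]
    j <- which(O[n, ] != 0)
    for (i in seq_len(m))
      A[(j - 1L) * m + i, cdx] <- L[n, i] * O[n, j]
  }
  wa <- MASS::ginv(A) %*% b
  w <- numeric(nrow(L))
  w[assigned] <- wa
  list(w = w, objective = sqrt(sum((A %*% wa - b)^2)))
}
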