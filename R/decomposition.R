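# SVD decompositions of response collections and library-matrix construction.
#
# Responses are N x T (nodes x time); "patterns" are always N-vectors, i.e.
# the SVD is taken so that node-space singular vectors are the patterns and
# each pattern k carries a time-coefficient vector a_k(t) = sigma_k alpha_k(t).

#' Trial-averaged response matrix for one stimulus
#'
#' @param collection an `fp_collection`.
#' @param stimulus stimulus label present in the collection.
#' @return N x T numeric matrix, the mean over that stimulus's trials.
#' @export
average_trials <- function(collection, stimulus) {
  stopifnot(inherits(collection, "fp_collection"))
  if (!stimulus %in% collection$stimuli)
    stop(sprintf("unknown stimulus label '%s'", stimulus))
  tr <- collection$trials[[stimulus]]
  Reduce(`+`, lapply(tr, `[[`, "rates")) / length(tr)
}

#' Time-wise concatenation of per-stimulus responses
#'
#' Builds the single matrix `[F_S1, F_S2, ...]` whose columns are the time
#' samples of the selected stimuli laid side by side; the node dimension is
#' preserved. Trials are averaged per stimulus (set `trials = "concat"` to
#' concatenate every trial instead).
#'
#' @param collection an `fp_collection`.
#' @param stimuli nonempty character vector of stimulus labels.
#' @param trials `"average"` (default) or `"concat"`.
#' @return N x (length(stimuli) * T) matrix (or more columns under
#'   `"concat"`).
#' @export
concat_collection <- function(collection, stimuli = collection$stimuli,
                              trials = c("average", "concat")) {
  trials <- match.arg(trials)
  if (!length(stimuli)) stop("'stimuli' must be nonempty")
  blocks <- lapply(stimuli, function(s) {
    if (trials == "average") average_trials(collection, s)
    else {
      if (!s %in% collection$stimuli)
        stop(sprintf("unknown stimulus label '%s'", s))
      do.call(cbind, lapply(collection$trials[[s]], `[[`, "rates"))
    }
  })
  do.call(cbind, blocks)
}

#' Singular-value energy spectrum of a matrix
#'
#' The relative energy of pattern `k` is `H_k = sigma_k^2 / sum_i sigma_i^2`,
#' so the energies are nonincreasing and sum to one. A concentrated spectrum
#' (few large `H_k`) indicates that a low-rank truncation represents the
#' matrix well.
#'
#' @param f numeric matrix with finite entries, not all zero.
#' @return `fp_energy` object with fields `singular_values` and `energies`.
#' @export
svd_energy <- function(f) {
  f <- as.matrix(f)
  if (!all(is.finite(f))) stop("'f' must be finite")
  d <- svd(f, nu = 0, nv = 0)$d
  total <- sum(d^2)
  if (total == 0) stop("degenerate input: all-zero matrix has no energy spectrum")
  structure(list(singular_values = d, energies = d^2 / total),
            class = "fp_energy")
}

#' @export
print.fp_energy <- function(x, ...) {
  k <- min(5L, length(x$energies))
  cat(sprintf("<fp_energy> %d modes; H_1..H_%d = %s\n", length(x$energies), k,
              paste(sprintf("%.3f", x$energies[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

fp_decomposition <- function(f) {
  s <- svd(f)
  total <- sum(s$d^2)
  if (total == 0) stop("degenerate input: all-zero matrix cannot be decomposed")
  structure(list(
    patterns = s$u,                      # N x k orthonormal node-space vectors
    coefficients = s$v %*% diag(s$d, length(s$d)),  # T x k, a_k(t) = sigma_k alpha_k(t)
    spectrum = structure(list(singular_values = s$d,
                              energies = s$d^2 / total),
                         class = "fp_energy")),
    class = "fp_decomposition")
}

#' SVD of the concatenated collection (SVDCon)
#'
#' Applies one SVD to the time-wise concatenation of the selected stimuli.
#' The decomposition's node-space patterns are shared across all stimuli,
#' which mixes them whenever stimulus patterns are correlated.
#'
#' @inheritParams concat_collection
#' @return `fp_decomposition` with fields `patterns` (N x k, orthonormal),
#'   `coefficients` (concatenated-time x k) and `spectrum`.
#' @export
svdcon <- function(collection, stimuli = collection$stimuli,
                   trials = c("average", "concat")) {
  fp_decomposition(concat_collection(collection, stimuli, match.arg(trials)))
}

#' Per-stimulus SVDs (SVDSep)
#'
#' Applies an SVD to each stimulus's (trial-averaged) response matrix
#' separately, yielding one decomposition per stimulus whose first pattern
#' is that stimulus's dominant response mode.
#'
#' @inheritParams concat_collection
#' @return list of `fp_decomposition`, in `stimuli` order.
#' @export
svdsep <- function(collection, stimuli = collection$stimuli,
                   trials = c("average", "concat")) {
  trials <- match.arg(trials)
  out <- lapply(stimuli, function(s)
    fp_decomposition(concat_collection(collection, s, trials)))
  names(out) <- stimuli
  out
}

#' Library matrix of dominant per-stimulus patterns
#'
#' Collects the first (most dominant) pattern vector of each decomposition
#' as the columns of an N x m library matrix `L`. Columns are unit norm and
#' sign-oriented so that each column's entry sum is nonnegative (the
#' dominant pattern of a nonnegative response matrix always admits such a
#' representative), which makes the per-row maximum rule of [etr()]
#' meaningful.
#'
#' @param decompositions list of `fp_decomposition` (e.g. from [svdsep()]),
#'   all with the same node count.
#' @param stimulus_order character labels for the columns; defaults to the
#'   list names.
#' @return `fp_library` with fields `L` (N x m) and `stimulus_order`.
#' @export
build_library <- function(decompositions, stimulus_order = names(decompositions)) {
  if (!length(decompositions)) stop("'decompositions' must be nonempty")
  if (is.null(stimulus_order))
    stimulus_order <- paste0("S", seq_along(decompositions))
  ns <- vapply(decompositions, function(d) nrow(d$patterns), integer(1))
  if (length(unique(ns)) != 1L)
    stop("shape error: decompositions disagree on node count")
  L <- vapply(decompositions, function(d) {
    g <- d$patterns[, 1L]
    if (sum(g) < 0) g <- -g
    g / sqrt(sum(g^2))
  }, numeric(ns[1]))
  colnames(L) <- stimulus_order
  structure(list(L = L, stimulus_order = stimulus_order), class = "fp_library")
}

#' @export
print.fp_library <- function(x, ...) {
  cat(sprintf("<fp_library> %d nodes x %d stimuli (%s)\n", nrow(x$L),
              ncol(x$L), paste(x$stimulus_order, collapse = ", ")))
  invisible(x)
}

#' Export / import a library matrix as CSV
#'
#' N rows, m columns; the header row carries the stimulus labels.
#'
#' @param library an `fp_library`.
#' @param path CSV file path.
#' @return `path` / an `fp_library`.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "fp_library"))
  utils::write.table(
    stats::setNames(as.data.frame(library$L), library$stimulus_order),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  L <- as.matrix(tab)
  dimnames(L) <- list(NULL, names(tab))
  structure(list(L = L, stimulus_order = names(tab)), class = "fp_library")
}
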