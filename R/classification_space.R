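# ETR orthogonalization, OETR convex re-weighting, projection and
# fixed-point coordinates.

as_library <- function(L) {
  if (inherits(L, "fp_library")) return(L)
  L <- as.matrix(L)
  if (is.null(colnames(L))) colnames(L) <- paste0("S", seq_len(ncol(L)))
  structure(list(L = L, stimulus_order = colnames(L)), class = "fp_library")
}

#' Exclusive threshold reduction (ETR)
#'
#' Operates on the node (row) dimension of the library matrix `L`: in each
#' row the maximal element is kept if it exceeds the threshold `tau` and all
#' other elements are set to zero; rows whose maximum does not exceed `tau`
#' become all-zero ("unassigned" nodes). ETR therefore associates each node
#' with at most one stimulus and weights the association by the library
#' value, producing a matrix `O` whose columns have disjoint supports and
#' are hence exactly orthogonal. Ties on the row maximum are resolved to
#' the lowest stimulus index.
#'
#' @param L an `fp_library` or numeric N x m matrix with finite entries.
#' @param tau threshold, `>= 0`. With the default `tau = 0` every row with
#'   a positive maximum is assigned.
#' @return `fp_basis` object with fields `O` (N x m), `tau`,
#'   `assignment` (integer per node, `NA` when unassigned) and
#'   `stimulus_order`.
#' @examples
#' etr(matrix(c(0.5, 0.1, 0.2, 0.7), 2))$O
#' @export
etr <- function(L, tau = 0) {
  lib <- as_library(L)
  M <- lib$L
  if (!all(is.finite(M))) stop("'L' must be finite")
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single number >= 0")
  n <- nrow(M)
  O <- matrix(0, n, ncol(M))
  assignment <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    j <- which.max(M[i, ])          # first maximum = lowest stimulus index
    if (M[i, j] > tau) {
      O[i, j] <- M[i, j]
      assignment[i] <- j
    }
  }
  colnames(O) <- lib$stimulus_order
  structure(list(O = O, tau = tau, assignment = assignment,
                 stimulus_order = lib$stimulus_order),
            class = "fp_basis")
}

#' @export
print.fp_basis <- function(x, ...) {
  cat(sprintf("<fp_basis> ETR basis, %d nodes x %d stimuli; %d assigned, %d unassigned (tau = %g)\n",
              nrow(x$O), ncol(x$O), sum(!is.na(x$assignment)),
              sum(is.na(x$assignment)), x$tau))
  invisible(x)
}

# Minimum-norm least-squares solution of M v = b via SVD pseudoinverse.
pinv_solve <- function(M, b) {
  s <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(numeric(ncol(M)))
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], b)) / s$d[keep])
}

#' Optimal exclusive threshold reduction (OETR) weights
#'
#' Finds the diagonal re-weighting `D^w` of the ETR basis that makes the
#' projected fixed points as close to orthonormal as possible, i.e. solves
#' the convex problem `min_w || L' D^w O - I ||_Fr`. Every entry of
#' `L' D^w O` is linear in `w`, and because the columns of `O` have
#' disjoint supports the problem separates into one small linear
#' least-squares system per stimulus; each is solved in closed form
#' (minimum-norm SVD solution). Nodes left unassigned by ETR get `w = 0`.
#'
#' @param L an `fp_library` or numeric matrix.
#' @param basis an `fp_basis` from [etr()]; computed with threshold `tau`
#'   when omitted.
#' @param tau threshold forwarded to [etr()] when `basis` is missing.
#' @return `fp_weights` with fields `w` (length N) and `objective`
#'   (`|| L' D^w O - I ||_Fr` at the optimum).
#' @examples
#' oetr(matrix(c(2, 0, 0, 4), 2))$w  # (0.25, 0.0625), objective 0
#' @export
oetr <- function(L, basis = NULL, tau = 0) {
  lib <- as_library(L)
  M <- lib$L
  if (is.null(basis)) basis <- etr(lib, tau)
  stopifnot(inherits(basis, "fp_basis"))
  O <- basis$O
  if (nrow(O) != nrow(M) || ncol(O) != ncol(M))
    stop("'basis' does not match the shape of 'L'")
  m <- ncol(M)
  w <- numeric(nrow(M))
  empty <- setdiff(seq_len(m), basis$assignment[!is.na(basis$assignment)])
  if (length(empty))
    warning(sprintf("no node assigned to stimulus %s; identity unreachable on that axis",
                    paste(basis$stimulus_order[empty], collapse = ", ")))
  for (j in seq_len(m)) {
    nodes <- which(!is.na(basis$assignment) & basis$assignment == j)
    if (!length(nodes)) next
    # A[i, n] = L[n, i] * O[n, j]; minimize || A w_nodes - e_j ||
    A <- t(M[nodes, , drop = FALSE] * O[nodes, j])
    ej <- numeric(m); ej[j] <- 1
    w[nodes] <- pinv_solve(A, ej)
  }
  P <- crossprod(M, w * O)
  structure(list(w = w,
                 objective = norm(P - diag(m), type = "F")),
            class = "fp_weights")
}

#' Fixed-point coordinates in a basis
#'
#' The coordinates of the stimulus fixed points in the classification space
#' spanned by the basis `B` are the rows of `L' B`. For an OETR basis with
#' zero residual this is exactly the identity matrix: each fixed point
#' sits on its own unit axis.
#'
#' @param L an `fp_library` or numeric N x m matrix.
#' @param B numeric N x m basis matrix (`O`, `D^w O`, or an ICA basis).
#' @return m x m coordinate matrix, one fixed point per row.
#' @export
fixed_points <- function(L, B) {
  lib <- as_library(L)
  if (inherits(B, "fp_basis")) B <- B$O
  crossprod(lib$L, as.matrix(B))
}

#' Construct a classification space from a library matrix
#'
#' Bundles a projection basis `B`, the fixed-point coordinates `P = L' B`
#' and bookkeeping into an `fp_space`:
#' * `"etr"` — `B = O`, the exclusive basis of [etr()];
#' * `"oetr"` — `B = D^w O` with [oetr()] weights (default);
#' * `"ica"` — Infomax independent components of `L'` (see [ica_basis()]);
#' * `"svdsep"` — `B = L` itself (projection straight onto the library,
#'   the non-orthogonalized baseline).
#'
#' @param L an `fp_library` or numeric N x m matrix.
#' @param method one of `"oetr"`, `"etr"`, `"ica"`, `"svdsep"`.
#' @param tau ETR threshold.
#' @param seed integer seed (used by the ICA method).
#' @param scale positive scalar dividing projected trajectories; see
#'   [build_space()] which estimates it from training data.
#' @return `fp_space` with fields `basis` (N x m), `fixed_points` (m x m),
#'   `method`, `stimulus_order`, `tau`, `scale`, and for OETR `w` and
#'   `objective`, for ICA `converged`.
#' @export
classification_space <- function(L, method = c("oetr", "etr", "ica", "svdsep"),
                                 tau = 0, seed = 0L, scale = 1) {
  method <- match.arg(method)
  lib <- as_library(L)
  if (method == "ica") {
    sp <- ica_basis(lib, seed = seed)
    sp$scale <- scale
    return(sp)
  }
  extra <- NULL
  if (method == "svdsep") {
    B <- lib$L
  } else {
    basis <- etr(lib, tau)
    if (method == "etr") {
      B <- basis$O
    } else {
      wt <- oetr(lib, basis)
      B <- wt$w * basis$O
      extra <- wt
    }
  }
  colnames(B) <- lib$stimulus_order
  structure(list(basis = B, fixed_points = fixed_points(lib, B),
                 method = method, stimulus_order = lib$stimulus_order,
                 tau = tau, scale = scale,
                 w = extra$w, objective = extra$objective,
                 converged = TRUE),
            class = "fp_space")
}

#' @export
print.fp_space <- function(x, ...) {
  cat(sprintf("<fp_space> method '%s', %d nodes -> %d dimensions (%s); scale = %g%s\n",
              x$method, nrow(x$basis), ncol(x$basis),
              paste(x$stimulus_order, collapse = ", "), x$scale,
              if (!is.null(x$objective))
                sprintf(", objective = %.3g", x$objective) else ""))
  invisible(x)
}

#' Project a response onto a classification space
#'
#' Computes the trajectory `x(t) = B' f(t) / scale` for every time sample's
#' node vector `f(t)`.
#'
#' @param response an `fp_response` (or bare N x T matrix).
#' @param space an `fp_space`.
#' @return m x T trajectory matrix, rows named by stimulus order.
#' @export
project_response <- function(response, space) {
  stopifnot(inherits(space, "fp_space"))
  f <- if (inherits(response, "fp_response")) response$rates else as.matrix(response)
  if (nrow(f) != nrow(space$basis))
    stop("response node count does not match the space basis")
  x <- crossprod(space$basis, f) / space$scale
  rownames(x) <- space$stimulus_order
  x
}

#' Infomax ICA basis from a library matrix
#'
#' Runs Infomax independent component analysis on `L'` (each library
#' column viewed as an observed signal over the node index) and uses the
#' estimated independent node-space components as a projection basis.
#' Components are greedily aligned to the stimuli (maximal absolute
#' correlation with the corresponding library column) and sign-oriented
#' positively so that axes are comparable with ETR/OETR spaces.
#' Delegates to [ica::icaimax()]. Non-convergence is flagged in the
#' result (`converged = FALSE`), not raised as an error.
#'
#' @param L an `fp_library` or numeric N x m matrix, `m >= 2`.
#' @param seed integer seed (fixes the run deterministically).
#' @param maxit maximum Infomax iterations.
#' @return `fp_space` with `method = "ica"`.
#' @export
ica_basis <- function(L, seed = 0L, maxit = 200L) {
  lib <- as_library(L)
  m <- ncol(lib$L)
  if (m < 2L) stop("ICA needs at least 2 stimuli")
  set.seed(seed)
  # no centering: the node-mean of a nonnegative pattern library carries its
  # dominant shared mode, and removing it would change the spanned subspace
  fit <- ica::icaimax(lib$L, nc = m, center = FALSE, maxit = maxit)
  S <- fit$S                                  # N x m independent patterns
  # align components to stimuli by maximal |correlation| with library columns
  perm <- integer(m)
  avail <- seq_len(m)
  for (i in seq_len(m)) {
    cors <- vapply(avail, function(k)
      abs(stats::cor(S[, k], lib$L[, i])), numeric(1))
    cors[!is.finite(cors)] <- 0
    pick <- avail[which.max(cors)]
    perm[i] <- pick
    avail <- setdiff(avail, pick)
  }
  B <- S[, perm, drop = FALSE]
  for (i in seq_len(m)) {
    if (stats::cor(B[, i], lib$L[, i]) < 0) B[, i] <- -B[, i]
    nrm <- sqrt(sum(B[, i]^2))
    if (nrm > 0) B[, i] <- B[, i] / nrm
  }
  colnames(B) <- lib$stimulus_order
  structure(list(basis = B, fixed_points = fixed_points(lib, B),
                 method = "ica", stimulus_order = lib$stimulus_order,
                 tau = NA_real_, scale = 1, w = NULL, objective = NULL,
                 converged = isTRUE(fit$converged) || fit$iter < maxit),
            class = "fp_space")
}

#' Build a classification space from a response collection
#'
#' End-to-end constructor: per-stimulus SVDs ([svdsep()]), library of
#' dominant patterns ([build_library()]), basis construction
#' ([classification_space()]), and estimation of the projection scale.
#' The scale is the mean own-axis coordinate of the trial-averaged
#' training responses over the second (plateau) half of the ON window, so
#' that training fixed-point responses land near unit coordinates — the
#' same units in which the fixed points `L' D^w O = I` live and in which
#' hyperellipse radii are specified.
#'
#' @param collection an `fp_collection`.
#' @param method,tau,seed forwarded to [classification_space()].
#' @param stimuli labels of the (mono-molecular) stimuli whose dominant
#'   patterns form the library; defaults to all stimuli.
#' @return `fp_space`.
#' @export
build_space <- function(collection, method = c("oetr", "etr", "ica", "svdsep"),
                        stimuli = collection$stimuli, tau = 0, seed = 0L) {
  method <- match.arg(method)
  lib <- build_library(svdsep(collection, stimuli), stimuli)
  space <- classification_space(lib, method, tau = tau, seed = seed)
  on2 <- plateau_indices(collection)
  own <- vapply(seq_along(stimuli), function(i) {
    x <- crossprod(space$basis, average_trials(collection, stimuli[i]))
    mean(x[i, on2])
  }, numeric(1))
  sc <- mean(own)
  space$scale <- if (is.finite(sc) && sc > 0) sc else 1
  space
}

# Second half of the ON window: envelope plateau samples.
plateau_indices <- function(collection) {
  idx <- on_indices(collection)
  idx[idx >= idx[1] + length(idx) / 2]
}

#' Export / import a classification space
#'
#' Writes `basis.csv` (B), `fixed_points.csv` (P) and `space.json`
#' (method, tau, stimulus order, scale, weights, objective).
#'
#' @param space an `fp_space`.
#' @param path directory.
#' @return `path` / an `fp_space`.
#' @export
write_space <- function(space, path) {
  stopifnot(inherits(space, "fp_space"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_rate_csv(space$basis, file.path(path, "basis.csv"))
  write_rate_csv(space$fixed_points, file.path(path, "fixed_points.csv"))
  jsonlite::write_json(
    list(method = space$method, stimulus_order = space$stimulus_order,
         tau = space$tau, scale = space$scale, w = space$w,
         objective = space$objective, converged = space$converged),
    file.path(path, "space.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_space
#' @export
read_space <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "space.json"),
                              simplifyVector = TRUE)
  B <- read_rate_csv(file.path(path, "basis.csv"))
  colnames(B) <- meta$stimulus_order
  P <- read_rate_csv(file.path(path, "fixed_points.csv"))
  structure(list(basis = B, fixed_points = P, method = meta$method,
                 stimulus_order = meta$stimulus_order,
                 tau = if (is.null(meta$tau)) NA_real_ else meta$tau,
                 scale = meta$scale, w = meta$w, objective = meta$objective,
                 converged = isTRUE(meta$converged)),
            class = "fp_space")
}
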