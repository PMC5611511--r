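# Direct-classification baselines operating on the raw node space:
# hinge-loss SVM (delegated to e1071/libsvm) and RUSBoost (pseudo-loss
# boosting over random under-sampled decision trees), plus the shared
# featurization both use.

#' Featurize a collection into labeled node-space points
#'
#' Every stimulus-ON time sample of every trial becomes one point in node
#' space (one N-vector), labeled `+1` when its stimulus belongs to
#' `positive_stimuli` and `-1` otherwise. With
#' `granularity = "trial"`, each trial's ON window is flattened into a
#' single long vector instead.
#'
#' @param collection an `fp_collection`.
#' @param positive_stimuli nonempty character vector of stimuli of
#'   interest.
#' @param granularity `"sample"` (default) or `"trial"`.
#' @return `fp_points` with fields `x` (points x features matrix), `y`
#'   (+1/-1), `stimulus`, `trial`.
#' @export
featurize <- function(collection, positive_stimuli,
                      granularity = c("sample", "trial")) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(collection, "fp_collection"))
  if (!length(positive_stimuli)) stop("'positive_stimuli' must be nonempty")
  if (!all(positive_stimuli %in% collection$stimuli))
    stop("unknown stimulus in 'positive_stimuli'")
  window <- on_indices(collection)
  xs <- list(); ys <- integer(0); stim <- character(0); trial <- integer(0)
  for (s in collection$stimuli) {
    lab <- if (s %in% positive_stimuli) 1L else -1L
    for (r in collection$trials[[s]]) {
      block <- r$rates[, window, drop = FALSE]
      if (granularity == "sample") {
        xs[[length(xs) + 1L]] <- t(block)
        k <- ncol(block)
      } else {
        xs[[length(xs) + 1L]] <- matrix(as.numeric(block), nrow = 1L)
        k <- 1L
      }
      ys <- c(ys, rep(lab, k))
      stim <- c(stim, rep(s, k))
      trial <- c(trial, rep(r$trial, k))
    }
  }
  structure(list(x = do.call(rbind, xs), y = ys, stimulus = stim,
                 trial = trial),
            class = "fp_points")
}

#' @export
print.fp_points <- function(x, ...) {
  cat(sprintf("<fp_points> %d points x %d features; %d positive, %d negative\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == -1L)))
  invisible(x)
}

# Stratified train/test split: whole trials never straddle the split.
split_by_trial <- function(points, test_fraction = 0.4, seed = 0L) {
  set.seed(seed)
  key <- paste(points$stimulus, points$trial)
  test_keys <- unlist(lapply(split(unique(key),
                                   sub(" .*$", "", unique(key))),
                             function(ks)
                               sample(ks, max(1L, round(test_fraction * length(ks))))))
  test <- key %in% test_keys
  list(train = which(!test), test = which(test))
}

#' Binary SVM baseline with held-out evaluation
#'
#' Trains a hinge-loss support vector machine (via [e1071::svm()], cost
#' `1 / lambda`) on a stratified trial-level split and reports held-out
#' precision, recall and their product. Both labels must be present in
#' the training split.
#'
#' @param points an [featurize()] output.
#' @param lambda weight-penalty parameter; the SVM cost is `1 / lambda`.
#' @param kernel `"linear"` or `"gaussian"` (radial basis).
#' @param test_fraction fraction of trials held out per stimulus.
#' @param seed split seed.
#' @return list with `model`, `precision`, `recall`, `accuracy`,
#'   `predicted` (held-out +1/-1), `test_index`.
#' @export
svm_binary <- function(points, lambda = 1, kernel = c("linear", "gaussian"),
                       test_fraction = 0.4, seed = 0L) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(points, "fp_points"))
  idx <- split_by_trial(points, test_fraction, seed)
  ytr <- factor(points$y[idx$train], levels = c(-1L, 1L))
  if (length(unique(ytr)) < 2L)
    stop("both labels must be present in the training split")
  model <- e1071::svm(points$x[idx$train, , drop = FALSE], ytr,
                      kernel = if (kernel == "linear") "linear" else "radial",
                      cost = 1 / lambda, scale = FALSE)
  pred <- as.integer(as.character(
    stats::predict(model, points$x[idx$test, , drop = FALSE])))
  pr <- precision_recall(pred == 1L, points$y[idx$test] == 1L)
  list(model = model, precision = unname(pr["precision"]),
       recall = unname(pr["recall"]), accuracy = unname(pr["accuracy"]),
       predicted = pred, test_index = idx$test)
}

fit_stump <- function(x, y, weights, maxdepth) {
  df <- data.frame(y = factor(y, levels = c(-1L, 1L)), x)
  rpart::rpart(y ~ ., data = df, weights = weights / mean(weights),
               method = "class",
               control = rpart::rpart.control(maxdepth = maxdepth,
                                              minsplit = 2L, cp = 0,
                                              xval = 0L))
}

stump_prob <- function(tree, x) {
  df <- data.frame(x)
  p <- stats::predict(tree, df, type = "prob")
  # columns are the class levels (-1, 1); return P(correct label = +1)
  p[, "1"]
}

#' RUSBoost: boosting with random under-sampling
#'
#' Pseudo-loss boosting for imbalanced binary classification. Each round
#' draws a random under-sample of the majority class to balance the two
#' classes, fits a depth-limited decision tree on it (weighted by the
#' current distribution), computes the pseudo-loss
#' `eps_t = sum_i D_t(i) (1 - h_t(x_i, y_i) + h_t(x_i, y))` over the
#' mislabel pairs, sets `alpha_t = eps_t / (1 - eps_t)`, updates and
#' renormalizes the weights, and finally predicts by the weighted vote
#' `H(x) = argmax_y sum_t h_t(x, y) log(1 / alpha_t)`. Rounds whose
#' pseudo-loss reaches 0.5 are discarded and resampled (bounded retries).
#'
#' @param points an [featurize()] output (both classes present).
#' @param rounds number of boosting rounds T.
#' @param maxdepth weak-learner tree depth.
#' @param seed integer seed for the under-sampling.
#' @param max_retries resampling attempts per round before giving up on
#'   that round.
#' @return `fp_rusboost` ensemble with a [predict.fp_rusboost()] method;
#'   fields `trees`, `log_inv_alpha`, `eps`.
#' @export
rusboost <- function(points, rounds = 50L, maxdepth = 3L, seed = 0L,
                     max_retries = 10L) {
  stopifnot(inherits(points, "fp_points"))
  x <- points$x; y <- points$y
  if (rounds < 1L) stop("'rounds' must be >= 1")
  counts <- table(factor(y, levels = c(-1L, 1L)))
  if (any(counts == 0L)) stop("minority class is empty")
  minority <- if (counts[["1"]] <= counts[["-1"]]) 1L else -1L
  set.seed(seed)
  n <- length(y)
  D <- rep(1 / n, n)
  trees <- list(); lia <- numeric(0); eps_hist <- numeric(0)
  for (t in seq_len(rounds)) {
    for (attempt in seq_len(max_retries)) {
      min_idx <- which(y == minority)
      maj_idx <- which(y != minority)
      sub <- c(min_idx, sample(maj_idx, length(min_idx)))
      tree <- fit_stump(x[sub, , drop = FALSE], y[sub], D[sub], maxdepth)
      h_pos <- stump_prob(tree, x)          # h_t(x_i, +1)
      h_true <- ifelse(y == 1L, h_pos, 1 - h_pos)
      eps <- sum(D * (1 - h_true + (1 - h_true)))
      if (eps < 0.5) break
      tree <- NULL
    }
    if (is.null(tree)) next                 # no acceptable learner this round
    eps <- max(eps, 1e-10)
    alpha <- eps / (1 - eps)
    D <- D * alpha^(0.5 * (1 + h_true - (1 - h_true)))
    D <- D / sum(D)
    trees[[length(trees) + 1L]] <- tree
    lia <- c(lia, log(1 / alpha))
    eps_hist <- c(eps_hist, eps)
  }
  if (!length(trees))
    stop("no boosting round achieved pseudo-loss below 0.5")
  structure(list(trees = trees, log_inv_alpha = lia, eps = eps_hist,
                 minority = minority),
            class = "fp_rusboost")
}

#' Predict with a RUSBoost ensemble
#'
#' @param object an [rusboost()] ensemble.
#' @param newdata points x features matrix.
#' @param ... unused.
#' @return integer vector of +1/-1 predictions.
#' @export
predict.fp_rusboost <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  vote_pos <- numeric(nrow(newdata))
  vote_neg <- numeric(nrow(newdata))
  for (t in seq_along(object$trees)) {
    h <- stump_prob(object$trees[[t]], newdata)
    vote_pos <- vote_pos + h * object$log_inv_alpha[t]
    vote_neg <- vote_neg + (1 - h) * object$log_inv_alpha[t]
  }
  unname(ifelse(vote_pos >= vote_neg, 1L, -1L))
}

#' @export
print.fp_rusboost <- function(x, ...) {
  cat(sprintf("<fp_rusboost> %d rounds; pseudo-loss range [%.3g, %.3g]\n",
              length(x$trees), min(x$eps), max(x$eps)))
  invisible(x)
}
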