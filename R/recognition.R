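# Hyperellipse Rec scoring, behavioral classification and evaluation.

#' Hyperellipse recognition region
#'
#' An m-dimensional hyperellipse centered at a fixed point, used as a
#' (robust) simplification of the convex-hull classifier. A point `x` is
#' inside when `q = sum_i ((x_i - c_i) / r_i)^2 - 1 <= 0`.
#'
#' @param center numeric m-vector, the fixed-point coordinates.
#' @param radii numeric m-vector of positive per-axis radii; a single
#'   value is recycled (a hypersphere).
#' @return `fp_ellipse` with fields `center`, `radii`.
#' @export
hyperellipse <- function(center, radii) {
  center <- as.numeric(center)
  if (length(radii) == 1L) radii <- rep(radii, length(center))
  radii <- as.numeric(radii)
  if (length(radii) != length(center))
    stop("'radii' must match the dimension of 'center'")
  if (!all(is.finite(radii)) || any(radii <= 0))
    stop("'radii' must be positive")
  structure(list(center = center, radii = radii), class = "fp_ellipse")
}

#' Pointwise hyperellipse membership
#'
#' Evaluates `q(x)` and the binary indicator `s = 1` iff `q <= 0`
#' (boundary points count as inside).
#'
#' @param x numeric m-vector or m x T trajectory matrix (columns = time).
#' @param ellipse an [hyperellipse()].
#' @return integer vector of 0/1 indicators, one per column of `x`.
#' @export
hyperellipse_indicator <- function(x, ellipse) {
  stopifnot(inherits(ellipse, "fp_ellipse"))
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
  if (nrow(x) != length(ellipse$center))
    stop("dimension of 'x' does not match the hyperellipse")
  q <- colSums(((x - ellipse$center) / ellipse$radii)^2) - 1
  as.integer(q <= 0)
}

#' Rec score of a trajectory
#'
#' Integrates the pointwise membership indicator over the scored window:
#' `S` counts the samples inside the hyperellipse and `Rec = S / |window|`
#' is the fraction of scored time the trajectory spends inside.
#'
#' @param trajectory m x T matrix from [project_response()].
#' @param ellipse an [hyperellipse()].
#' @param window integer vector of time-sample indices to score (typically
#'   the stimulus-ON samples); must be nonempty and within `1..T`.
#' @return `fp_rec` with fields `S` (inside count), `total`, `rec`.
#' @export
rec_score <- function(trajectory, ellipse, window = seq_len(ncol(trajectory))) {
  trajectory <- as.matrix(trajectory)
  window <- as.integer(window)
  if (!length(window) || any(window < 1L | window > ncol(trajectory)))
    stop("'window' must be nonempty and within the trajectory length")
  s <- hyperellipse_indicator(trajectory[, window, drop = FALSE], ellipse)
  structure(list(S = sum(s), total = length(window),
                 rec = sum(s) / length(window)),
            class = "fp_rec")
}

#' @export
print.fp_rec <- function(x, ...) {
  cat(sprintf("<fp_rec> %d / %d samples inside: Rec = %.3f\n",
              x$S, x$total, x$rec))
  invisible(x)
}

#' Hyperellipse center for a stimulus
#'
#' For a stimulus on which the space was built, the center is its
#' fixed-point row of `L' D^w O`. For any other stimulus (e.g. a mixture,
#' whose fixed-point coordinates the basis does not define), the center is
#' the mean projected trajectory of its training trials over the ON
#' window.
#'
#' @param space an `fp_space`.
#' @param collection an `fp_collection` containing the stimulus.
#' @param stimulus stimulus label.
#' @return numeric m-vector.
#' @export
stimulus_center <- function(space, collection, stimulus) {
  stopifnot(inherits(space, "fp_space"))
  i <- match(stimulus, space$stimulus_order)
  if (!is.na(i)) return(as.numeric(space$fixed_points[i, ]))
  x <- project_response(average_trials(collection, stimulus), space)
  rowMeans(x[, on_indices(collection), drop = FALSE])
}

#' Rec scores of every trial in a collection
#'
#' Projects each trial onto the space and scores it against the target
#' hyperellipse over the stimulus-ON window.
#'
#' @param collection an `fp_collection`.
#' @param space an `fp_space`.
#' @param ellipse an [hyperellipse()].
#' @return data.frame with columns `stimulus`, `trial`, `rec`.
#' @export
collection_rec_scores <- function(collection, space, ellipse) {
  window <- on_indices(collection)
  rows <- list()
  for (s in collection$stimuli) {
    for (r in collection$trials[[s]]) {
      sc <- rec_score(project_response(r, space), ellipse, window)
      rows[[length(rows) + 1L]] <-
        data.frame(stimulus = s, trial = r$trial, rec = sc$rec,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Mean Rec score per stimulus
#'
#' @param scores data.frame from [collection_rec_scores()].
#' @return named numeric vector of per-stimulus trial-averaged Rec.
#' @export
mean_rec <- function(scores) {
  out <- c(tapply(scores$rec, scores$stimulus, mean))
  out[unique(scores$stimulus)]
}

#' Precision, recall and their product
#'
#' `P = tp / (tp + fp)`, `R = tp / (tp + fn)`; the reported accuracy is
#' the product `P * R`. Empty denominators are reported as 0.
#'
#' @param predicted logical vector of predicted positives.
#' @param truth logical vector of true positives (same length).
#' @return named numeric vector `c(precision, recall, accuracy)`.
#' @export
precision_recall <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  c(precision = p, recall = r, accuracy = p * r)
}

#' Behavioral / non-behavioral classification from mean Rec scores
#'
#' The distribution of per-stimulus mean Rec scores is normalized by its
#' maximum; the decision line is the midpoint between the mean of the
#' normalized distribution and the maximal value (= 1):
#' `d = (mean + 1) / 2`. Stimuli with normalized score strictly above `d`
#' are classified as behavioral (a score exactly at `d` is
#' non-behavioral).
#'
#' @param mean_scores named numeric vector of per-stimulus mean Rec
#'   scores; at least one must be positive.
#' @param truth optional named logical vector: which stimuli are truly
#'   behavioral. When given, precision/recall/accuracy are computed.
#' @return `fp_classification` with fields `mean_scores`, `normalized`,
#'   `d`, `predicted` (named logical) and, with truth, `precision`,
#'   `recall`, `accuracy`.
#' @export
classify_behavioral <- function(mean_scores, truth = NULL) {
  if (!is.numeric(mean_scores) || !length(mean_scores))
    stop("'mean_scores' must be a numeric vector")
  if (max(mean_scores) <= 0)
    stop("degenerate input: all mean Rec scores are zero")
  normalized <- mean_scores / max(mean_scores)
  d <- (mean(normalized) + 1) / 2
  predicted <- normalized > d
  res <- list(mean_scores = mean_scores, normalized = normalized, d = d,
              predicted = predicted,
              precision = NA_real_, recall = NA_real_, accuracy = NA_real_)
  if (!is.null(truth)) {
    if (!is.null(names(mean_scores)) && !is.null(names(truth)))
      truth <- truth[names(mean_scores)]
    pr <- precision_recall(predicted, truth)
    res[c("precision", "recall", "accuracy")] <- as.list(unname(pr))
  }
  structure(res, class = "fp_classification")
}

#' @export
print.fp_classification <- function(x, ...) {
  cat(sprintf("<fp_classification> d = %.3f; behavioral: %s\n", x$d,
              paste(names(x$predicted)[x$predicted], collapse = ", ")))
  if (!is.na(x$accuracy))
    cat(sprintf("  precision %.3f, recall %.3f, accuracy %.3f\n",
                x$precision, x$recall, x$accuracy))
  invisible(x)
}

#' Single-trial recognition against a target hyperellipse
#'
#' A trial trajectory is recognized as the target stimulus when its Rec
#' score reaches `threshold_frac` (default 70%) of the Rec score of the
#' target's averaged trajectory.
#'
#' @param trajectory m x T projected trial trajectory.
#' @param ellipse the target's [hyperellipse()].
#' @param target_rec Rec score of the target averaged trajectory.
#' @param threshold_frac fraction of `target_rec` to reach, default 0.7.
#' @param window time-sample indices to score.
#' @return `TRUE` iff `Rec(trajectory) >= threshold_frac * target_rec`.
#' @export
recognize_trial <- function(trajectory, ellipse, target_rec,
                            threshold_frac = 0.7,
                            window = seq_len(ncol(trajectory))) {
  rec_score(trajectory, ellipse, window)$rec >= threshold_frac * target_rec
}

#' Per-class confidence intervals of trial Rec scores
#'
#' Groups per-trial Rec scores by stimulus class and computes two-sided
#' `(1 - alpha)` confidence intervals for the class mean: Student-t
#' intervals by default, or seeded bootstrap percentile intervals.
#' Classes whose scores are constant get a zero-width interval at the
#' value. The behavioral and non-behavioral classes are flagged
#' `separable` when their intervals are disjoint.
#'
#' @param scores data.frame from [collection_rec_scores()].
#' @param classes named character vector mapping stimulus to class.
#' @param alpha two-sided error level, default 0.01 (99% intervals).
#' @param method `"t"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param seed bootstrap seed.
#' @return data.frame with columns `class`, `mean`, `lower`, `upper`, `n`,
#'   and attribute `separable`.
#' @export
rec_confidence_intervals <- function(scores, classes, alpha = 0.01,
                                     method = c("t", "bootstrap"),
                                     n_boot = 2000L, seed = 0L) {
  method <- match.arg(method)
  cls <- classes[scores$stimulus]
  groups <- split(scores$rec, cls)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    mu <- mean(x)
    if (length(x) < 2L || stats::sd(x) == 0) {
      lo <- hi <- mu
    } else if (method == "t") {
      half <- stats::qt(1 - alpha / 2, df = length(x) - 1L) *
        stats::sd(x) / sqrt(length(x))
      lo <- mu - half; hi <- mu + half
    } else {
      set.seed(seed)
      bm <- vapply(seq_len(n_boot), function(b)
        mean(sample(x, length(x), replace = TRUE)), numeric(1))
      qs <- stats::quantile(bm, c(alpha / 2, 1 - alpha / 2), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    data.frame(class = g, mean = mu, lower = lo, upper = hi, n = length(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sep <- NA
  if (all(c("behavioral", "non-behavioral") %in% out$class)) {
    b <- out[out$class == "behavioral", ]
    nb <- out[out$class == "non-behavioral", ]
    sep <- b$lower > nb$upper || nb$lower > b$upper
  }
  attr(out, "separable") <- sep
  out
}

#' Classify a collection against a target stimulus hyperellipse
#'
#' Convenience pipeline: build the target's hypersphere (center from
#' [stimulus_center()]), score every trial, average per stimulus and apply
#' the decision line. Truth labels default to the collection's class
#' labels (`"behavioral"` vs the rest).
#'
#' @param collection an `fp_collection` with class labels.
#' @param space an `fp_space`.
#' @param target target stimulus label (default `"B1"`).
#' @param radius hypersphere radius in fixed-point units, default 0.65.
#' @return `fp_classification` (see [classify_behavioral()]); the trial
#'   scores are attached as attribute `"scores"`.
#' @export
classify_collection <- function(collection, space, target = "B1",
                                radius = 0.65) {
  center <- stimulus_center(space, collection, target)
  ell <- hyperellipse(center, radius)
  scores <- collection_rec_scores(collection, space, ell)
  ms <- mean_rec(scores)
  truth <- NULL
  if (!is.null(collection$class_labels))
    truth <- collection$class_labels[names(ms)] == "behavioral"
  res <- classify_behavioral(ms, truth)
  attr(res, "scores") <- scores
  res
}

#' Precision/recall as the classifying radius varies
#'
#' Sweeps the radius of the target hypersphere over a grid (default the
#' range 0.5–0.85) and evaluates the behavioral classification at each
#' radius. Also reports the widest contiguous radius interval achieving
#' precision 1.
#'
#' @param space an `fp_space`.
#' @param collection an `fp_collection` with class labels.
#' @param target target stimulus label.
#' @param radii positive radius grid.
#' @return data.frame with columns `radius`, `precision`, `recall`,
#'   `accuracy`; attribute `"precision_one_interval"` is `c(lo, hi, width)`
#'   of the widest contiguous grid run with precision 1 (all `NA` when
#'   none).
#' @export
radius_sweep <- function(space, collection, target = "B1",
                         radii = seq(0.5, 0.85, by = 0.01)) {
  if (!length(radii) || any(!is.finite(radii)) || any(radii <= 0))
    stop("'radii' must be positive")
  rows <- lapply(radii, function(r) {
    # a radius so small that nothing scores positive recognizes nothing
    res <- tryCatch(classify_collection(collection, space, target, radius = r),
                    error = function(e)
                      list(precision = 0, recall = 0, accuracy = 0))
    data.frame(radius = r, precision = res$precision, recall = res$recall,
               accuracy = res$accuracy)
  })
  out <- do.call(rbind, rows)
  runs <- rle(out$precision == 1)
  iv <- c(lo = NA_real_, hi = NA_real_, width = NA_real_)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    ok <- which(runs$values)
    widths <- out$radius[ends[ok]] - out$radius[starts[ok]]
    best <- ok[which.max(widths)]
    iv <- c(lo = out$radius[starts[best]], hi = out$radius[ends[best]],
            width = max(widths))
  }
  attr(out, "precision_one_interval") <- iv
  out
}

#' Mean classification accuracy across an SNR grid
#'
#' For each signal-to-noise ratio, generates benchmark-like collections
#' over a set of seeds, builds the classification space and evaluates
#' behavioral classification against the target mixture; reports the
#' seed-averaged accuracy. A run in which no stimulus scores above zero
#' (nothing falls inside the target region) counts as accuracy 0.
#'
#' @param snrs numeric vector of signal-to-noise ratios.
#' @param seeds integer vector of generator seeds averaged over.
#' @param method space-construction method.
#' @param target,radius,tau see [classify_collection()].
#' @param config_fn function `(snr, seed) -> fp_config`; defaults to
#'   [synthetic_config()] with everything else at its defaults.
#' @return data.frame with columns `snr`, `mean_accuracy`, `n_seeds`.
#' @export
accuracy_by_snr <- function(snrs, seeds = 1:20, method = "oetr",
                            target = "B1", radius = 0.65, tau = 0,
                            config_fn = function(snr, seed)
                              synthetic_config(snr = snr, seed = seed)) {
  rows <- lapply(snrs, function(snr) {
    accs <- vapply(seeds, function(seed) {
      sim <- generate_benchmark_like(config_fn(snr, seed))
      mono <- paste0("S", seq_len(sim$truth$config$n_stimuli))
      suppressWarnings({
        space <- build_space(sim$collection, method, stimuli = mono,
                             tau = tau, seed = seed)
        tryCatch(
          classify_collection(sim$collection, space, target, radius)$accuracy,
          error = function(e) 0)
      })
    }, numeric(1))
    data.frame(snr = snr, mean_accuracy = mean(accs),
               n_seeds = length(seeds))
  })
  do.call(rbind, rows)
}

#' Classification accuracy across space dimensions and methods
#'
#' Mirrors the benchmark analysis: for each dimension `m`, builds the
#' classification space from the first `m` mono-molecular stimuli and
#' evaluates behavioral classification of the whole collection against
#' the target mixture's hypersphere.
#'
#' @param collection an `fp_collection` with class labels.
#' @param methods character subset of `c("oetr", "etr", "ica", "svdsep")`.
#' @param dims integer vector of dimensions (library sizes) to test.
#' @param mono_stimuli ordered labels of the mono-molecular stimuli from
#'   which libraries are built.
#' @param target target mixture label.
#' @param radius hypersphere radius.
#' @param tau ETR threshold.
#' @param seed seed (ICA).
#' @return data.frame with columns `method`, `m`, `precision`, `recall`,
#'   `accuracy`, `d`.
#' @export
evaluate_dimensions <- function(collection, methods = "oetr",
                                dims = seq_along(mono_stimuli),
                                mono_stimuli, target = "B1", radius = 0.65,
                                tau = 0, seed = 0L) {
  rows <- list()
  for (method in methods) {
    for (m in dims) {
      if (method == "ica" && m < 2L) next
      space <- build_space(collection, method,
                           stimuli = mono_stimuli[seq_len(m)],
                           tau = tau, seed = seed)
      res <- classify_collection(collection, space, target, radius)
      rows[[length(rows) + 1L]] <-
        data.frame(method = method, m = m, precision = res$precision,
                   recall = res$recall, accuracy = res$accuracy, d = res$d,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
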