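# Domain types and I/O for multi-node response collections.

#' One trial's multi-node firing-rate response
#'
#' A `fp_response` wraps a nonnegative nodes x time matrix of instantaneous
#' firing rates (a peri-stimulus time histogram, spikes/s) together with its
#' stimulus label, trial index, sampling interval and stimulus-ON window.
#'
#' @param rates numeric matrix, nodes (rows) x time samples (columns),
#'   all entries finite and `>= 0` (spikes/s).
#' @param stimulus single character stimulus label.
#' @param trial integer trial index, `>= 0`.
#' @param dt sampling interval in seconds, `> 0`.
#' @param on_window numeric length-2 vector, half-open interval
#'   `[t_on, t_off)` in seconds during which the stimulus is ON; must lie
#'   within the recording `[0, T * dt)`.
#'
#' @return An object of class `fp_response` with fields `rates`,
#'   `stimulus`, `trial`, `dt`, `on_window`.
#' @examples
#' r <- response_matrix(matrix(1, 4, 10), "S1", 1, dt = 0.01,
#'                      on_window = c(0, 0.05))
#' on_indices(r)
#' @export
response_matrix <- function(rates, stimulus, trial = 0L, dt = 0.01,
                            on_window = c(0, ncol(rates) * dt)) {
  rates <- as.matrix(rates)
  if (!is.numeric(rates) || nrow(rates) < 1L || ncol(rates) < 1L)
    stop("'rates' must be a numeric matrix with N, T > 0")
  if (!all(is.finite(rates)))
    stop("'rates' must be finite")
  if (any(rates < 0))
    stop("'rates' must be nonnegative (firing rates)")
  if (!is.character(stimulus) || length(stimulus) != 1L)
    stop("'stimulus' must be a single label")
  trial <- as.integer(trial)
  if (is.na(trial) || trial < 0L) stop("'trial' must be an integer >= 0")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a positive sampling interval")
  on_window <- as.numeric(on_window)
  if (length(on_window) != 2L || on_window[1] < 0 ||
      on_window[2] <= on_window[1] || on_window[2] > ncol(rates) * dt + 1e-12)
    stop("'on_window' must be [t_on, t_off) within [0, T * dt)")
  structure(list(rates = unname(rates), stimulus = stimulus, trial = trial,
                 dt = dt, on_window = on_window),
            class = "fp_response")
}

#' @export
print.fp_response <- function(x, ...) {
  cat(sprintf("<fp_response> stimulus '%s' trial %d: %d nodes x %d samples (dt = %g s, ON [%g, %g) s)\n",
              x$stimulus, x$trial, nrow(x$rates), ncol(x$rates), x$dt,
              x$on_window[1], x$on_window[2]))
  invisible(x)
}

#' Time-sample indices inside the stimulus-ON window
#'
#' Sample `k` is taken at time `(k - 1) * dt` and counts as ON when that
#' time lies in `[t_on, t_off)`.
#'
#' @param x an `fp_response` or `fp_collection`.
#' @return integer vector of ON sample indices.
#' @export
on_indices <- function(x) {
  t <- (seq_len(if (inherits(x, "fp_response")) ncol(x$rates) else x$n_time) - 1L) * x$dt
  which(t >= x$on_window[1] & t < x$on_window[2] - 1e-12)
}

#' A labeled collection of responses over stimuli and trials
#'
#' Groups `fp_response` objects by stimulus, checks that all share the same
#' node count, sample count, sampling interval and ON window, and attaches
#' optional class labels (`"behavioral"`, `"non-behavioral"`, `"control"`).
#'
#' @param responses list of [response_matrix()] objects (any order; they are
#'   grouped by stimulus label, preserving first appearance order).
#' @param class_labels optional named character vector mapping every stimulus
#'   label to one of `"behavioral"`, `"non-behavioral"`, `"control"`.
#' @return An object of class `fp_collection` with fields `stimuli`,
#'   `trials` (list of lists of `fp_response`), `class_labels`, `n_nodes`,
#'   `n_time`, `dt`, `on_window`.
#' @export
response_collection <- function(responses, class_labels = NULL) {
  if (!length(responses)) stop("'responses' must be a nonempty list")
  if (!all(vapply(responses, inherits, logical(1), "fp_response")))
    stop("all elements of 'responses' must be fp_response objects")
  r1 <- responses[[1]]
  for (r in responses) {
    if (nrow(r$rates) != nrow(r1$rates) || ncol(r$rates) != ncol(r1$rates))
      stop(sprintf("shape mismatch: response '%s' trial %d is %d x %d, expected %d x %d",
                   r$stimulus, r$trial, nrow(r$rates), ncol(r$rates),
                   nrow(r1$rates), ncol(r1$rates)))
    if (abs(r$dt - r1$dt) > 1e-12 || any(abs(r$on_window - r1$on_window) > 1e-12))
      stop("all responses must share dt and on_window")
  }
  stimuli <- unique(vapply(responses, `[[`, character(1), "stimulus"))
  trials <- lapply(stimuli, function(s)
    responses[vapply(responses, function(r) r$stimulus == s, logical(1))])
  names(trials) <- stimuli
  if (!is.null(class_labels)) {
    class_labels <- class_labels[stimuli]
    if (anyNA(class_labels) ||
        !all(class_labels %in% c("behavioral", "non-behavioral", "control")))
      stop("'class_labels' must name every stimulus with behavioral/non-behavioral/control")
  }
  structure(list(stimuli = stimuli, trials = trials,
                 class_labels = class_labels,
                 n_nodes = nrow(r1$rates), n_time = ncol(r1$rates),
                 dt = r1$dt, on_window = r1$on_window),
            class = "fp_collection")
}

#' @export
print.fp_collection <- function(x, ...) {
  cat(sprintf("<fp_collection> %d stimuli, %d nodes x %d samples, %d total trials\n",
              length(x$stimuli), x$n_nodes, x$n_time,
              sum(lengths(x$trials))))
  if (!is.null(x$class_labels))
    cat("  classes:", paste(sprintf("%s=%s", x$stimuli, x$class_labels),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Per-node spike-time trains
#'
#' @param trains list of numeric vectors, one per node, spike times in
#'   seconds; each must lie in `[0, duration)`. Times are sorted.
#' @param duration recording duration in seconds.
#' @return `fp_spikes` object.
#' @export
spike_trains <- function(trains, duration) {
  if (!is.list(trains) || !length(trains)) stop("'trains' must be a nonempty list")
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be > 0")
  trains <- lapply(trains, function(tt) {
    tt <- as.numeric(tt)
    if (any(tt < 0 | tt >= duration)) stop("spike times must lie in [0, duration)")
    sort(tt)
  })
  structure(list(trains = trains, duration = duration), class = "fp_spikes")
}

#' Convert spike trains to a peri-stimulus time histogram
#'
#' Each spike contributes a unit of mass to the instantaneous firing rate.
#' With `kernel_width = 0` the spikes are binned (counts/`dt`); otherwise a
#' Gaussian kernel of standard deviation `kernel_width` is placed on every
#' spike, truncated at the recording boundaries and renormalized so that
#' the time integral of each node's rate equals its spike count.
#'
#' @param spikes an [spike_trains()] object.
#' @param dt sampling interval of the output PSTH, seconds.
#' @param kernel_width Gaussian smoothing width (standard deviation) in
#'   seconds; `0` means pure binning. Default 50 ms.
#' @param stimulus,trial,on_window metadata for the resulting response;
#'   `on_window` defaults to the first half of the recording.
#' @return An [response_matrix()] with `ceiling(duration / dt)` samples.
#' @export
spikes_to_psth <- function(spikes, dt = 0.01, kernel_width = 0.05,
                           stimulus = "", trial = 0L, on_window = NULL) {
  if (!inherits(spikes, "fp_spikes")) stop("'spikes' must be an fp_spikes object")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  if (!is.numeric(kernel_width) || kernel_width < 0)
    stop("'kernel_width' must be >= 0")
  n_time <- as.integer(ceiling(spikes$duration / dt))
  centers <- (seq_len(n_time) - 0.5) * dt
  rates <- matrix(0, nrow = length(spikes$trains), ncol = n_time)
  for (n in seq_along(spikes$trains)) {
    for (s in spikes$trains[[n]]) {
      if (kernel_width == 0) {
        k <- min(n_time, floor(s / dt) + 1L)
        rates[n, k] <- rates[n, k] + 1 / dt
      } else {
        dens <- stats::dnorm(centers, mean = s, sd = kernel_width)
        mass <- sum(dens) * dt
        if (mass > 0) {
          rates[n, ] <- rates[n, ] + dens / mass
        } else {
          k <- min(n_time, floor(s / dt) + 1L)
          rates[n, k] <- rates[n, k] + 1 / dt
        }
      }
    }
  }
  if (is.null(on_window)) on_window <- c(0, min(0.5, n_time * dt))
  response_matrix(rates, stimulus = stimulus, trial = trial, dt = dt,
                  on_window = on_window)
}

sanitize_label <- function(x) {
  if (grepl("[^A-Za-z0-9_.-]", x))
    stop(sprintf("stimulus label '%s' is not filename-safe", x))
  x
}

write_rate_csv <- function(m, path) {
  writeLines(apply(m, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = ",")), path)
}

read_rate_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' Save a response collection as a plain-text directory
#'
#' Writes `collection.json` (stimulus labels, class labels, dt, ON window,
#' dimensions, trial indices) plus one numeric CSV per (stimulus, trial)
#' under `responses/`. Values are written with 17 significant digits so
#' that [load_collection()] round-trips bit-exactly.
#'
#' @param collection an `fp_collection`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
save_collection <- function(collection, path) {
  stopifnot(inherits(collection, "fp_collection"))
  dir.create(file.path(path, "responses"), recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    stimuli = collection$stimuli,
    class_labels = if (!is.null(collection$class_labels))
      as.list(collection$class_labels),
    dt = collection$dt,
    on_window = collection$on_window,
    n_nodes = collection$n_nodes,
    n_time = collection$n_time,
    trials = lapply(collection$trials, function(tr)
      vapply(tr, `[[`, integer(1), "trial"))
  )
  jsonlite::write_json(meta, file.path(path, "collection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (s in collection$stimuli) {
    sanitize_label(s)
    for (r in collection$trials[[s]])
      write_rate_csv(r$rates,
                     file.path(path, "responses",
                               sprintf("%s_%d.csv", s, r$trial)))
  }
  invisible(path)
}

#' Load a response collection written by [save_collection()]
#'
#' @param path directory containing `collection.json` and `responses/`.
#' @return An `fp_collection`.
#' @export
load_collection <- function(path) {
  meta_path <- file.path(path, "collection.json")
  if (!file.exists(meta_path))
    stop(sprintf("not a collection directory: missing metadata file '%s'", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  responses <- list()
  for (s in meta$stimuli) {
    for (k in meta$trials[[s]]) {
      f <- file.path(path, "responses", sprintf("%s_%d.csv", s, k))
      if (!file.exists(f))
        stop(sprintf("missing response file '%s'", f))
      m <- read_rate_csv(f)
      if (nrow(m) != meta$n_nodes || ncol(m) != meta$n_time)
        stop(sprintf("shape mismatch in '%s': %d x %d, expected %d x %d",
                     f, nrow(m), ncol(m), meta$n_nodes, meta$n_time))
      responses[[length(responses) + 1L]] <-
        response_matrix(m, stimulus = s, trial = k, dt = meta$dt,
                        on_window = meta$on_window)
    }
  }
  cl <- meta$class_labels
  if (!is.null(cl)) cl <- unlist(cl)
  response_collection(responses, class_labels = cl)
}

#' Load a benchmark-style directory of CSV response matrices
#'
#' Best-effort loader for externally recorded collections that have been
#' converted to plain CSV: a directory of files named
#' `<stimulus>_<trial>.csv` (nodes x time numeric matrices, no header),
#' optionally with a `classes.csv` file (columns `stimulus,class`) giving
#' behavioral/non-behavioral/control labels.
#'
#' @param path directory of CSV files.
#' @param dt sampling interval of the converted matrices (s).
#' @param on_window stimulus-ON window (s).
#' @return An `fp_collection`.
#' @export
load_benchmark <- function(path, dt = 0.01, on_window = c(0, 0.5)) {
  files <- list.files(path, pattern = "^.+_[0-9]+\\.csv$")
  if (!length(files))
    stop(sprintf("no '<stimulus>_<trial>.csv' files found under '%s'", path))
  responses <- lapply(files, function(f) {
    stim <- sub("_[0-9]+\\.csv$", "", f)
    k <- as.integer(sub("\\.csv$", "", sub("^.+_", "", f)))
    response_matrix(read_rate_csv(file.path(path, f)), stimulus = stim,
                    trial = k, dt = dt, on_window = on_window)
  })
  cl <- NULL
  cpath <- file.path(path, "classes.csv")
  if (file.exists(cpath)) {
    tab <- utils::read.csv(cpath, stringsAsFactors = FALSE)
    cl <- stats::setNames(tab$class, tab$stimulus)
  }
  response_collection(responses, class_labels = cl)
}
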