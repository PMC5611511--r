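test_that("featurize turns ON samples into labeled node-space points", {
  coll <- make_manual_collection(2L, trials = 5L, nodes = 4L, n_time = 100L,
                                 value_fn = function(s, k, n, t)
                                   s * 1000 + k * 100 + n)
  pts <- featurize(coll, "S1")
  expect_identical(dim(pts$x), c(500L, 4L))   # 2 stimuli x 5 trials x 50 ON
  expect_identical(sum(pts$y == 1L), 250L)

  # enumeration oracle: every (stimulus, trial) contributes 50 identical rows
  for (s in 1:2) for (k in 1:5) {
    rows <- pts$x[pts$stimulus == paste0("S", s) & pts$trial == k, ,
                  drop = FALSE]
    expect_identical(nrow(rows), 50L)
    expect_true(all(rows == rep(s * 1000 + k * 100 + 1:4, each = 50)))
  }

  flat <- featurize(coll, "S1", granularity = "trial")
  expect_identical(dim(flat$x), c(10L, 200L))

  expect_error(featurize(coll, character(0)), "nonempty")
  expect_error(featurize(coll, "S9"), "unknown stimulus")
})

make_cluster_points <- function(n_pos, n_neg, sep = 4, seed = 1,
                                shuffle = FALSE) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_pos * 3, mean = sep), n_pos, 3),
             matrix(rnorm(n_neg * 3, mean = 0), n_neg, 3))
  y <- c(rep(1L, n_pos), rep(-1L, n_neg))
  if (shuffle) y <- sample(y)
  n_trials <- 10L
  structure(list(x = x, y = y,
                 stimulus = ifelse(y == 1L, "P", "N"),
                 trial = rep_len(seq_len(n_trials), n_pos + n_neg)),
            class = "fp_points")
}

test_that("SVM separates well-separated clusters and is deterministic", {
  pts <- make_cluster_points(60, 60, sep = 5, seed = 2)
  fit <- svm_binary(pts, lambda = 1, kernel = "linear", seed = 1)
  expect_equal(fit$precision, 1)
  expect_equal(fit$recall, 1)
  fit_g <- svm_binary(pts, lambda = 1, kernel = "gaussian", seed = 1)
  expect_equal(fit_g$accuracy, 1)
  fit2 <- svm_binary(pts, lambda = 1, kernel = "linear", seed = 1)
  expect_identical(fit$predicted, fit2$predicted)
})

test_that("SVM on shuffled labels performs near chance", {
  pts <- make_cluster_points(80, 80, sep = 5, seed = 3, shuffle = TRUE)
  fit <- svm_binary(pts, lambda = 1, kernel = "linear", seed = 1)
  # among predicted positives the true-positive fraction should be within a
  # wide binomial band of the base rate
  n_pred <- sum(fit$predicted == 1L)
  base <- mean(pts$y[fit$test_index] == 1L)
  if (n_pred > 0) {
    half <- 4 * sqrt(base * (1 - base) / n_pred)
    expect_lt(abs(fit$precision - base), max(half, 0.3))
  }
  expect_lt(fit$accuracy, 0.85)
})

test_that("RUSBoost reports the literal pseudo-loss and weight update", {
  # separable 4-point set, depth-1 stump is pure: eps = 0 (clamped), so
  # alpha = eps/(1-eps) at the clamp and the vote weight is log(1/alpha)
  pts <- structure(list(x = matrix(c(1, 2, 8, 9), 4, 1),
                        y = c(-1L, -1L, 1L, 1L),
                        stimulus = c("a", "a", "b", "b"),
                        trial = 1:4),
                   class = "fp_points")
  rb <- rusboost(pts, rounds = 2, maxdepth = 1, seed = 1)
  eps <- 1e-10
  expect_equal(rb$eps, rep(eps, 2))
  expect_equal(rb$log_inv_alpha, rep(log((1 - eps) / eps), 2))
  expect_identical(predict(rb, pts$x), pts$y)

  # alternating labels are unlearnable by a depth-1 stump: every round's
  # pseudo-loss is >= 0.5 and is discarded
  bad <- structure(list(x = matrix(c(1, 2, 3, 4), 4, 1),
                        y = c(1L, -1L, -1L, 1L),
                        stimulus = c("b", "a", "a", "b"), trial = 1:4),
                   class = "fp_points")
  expect_error(rusboost(bad, rounds = 2, maxdepth = 1, seed = 1),
               "pseudo-loss")
  expect_error(rusboost(structure(list(x = matrix(1:4), y = rep(1L, 4),
                                       stimulus = rep("a", 4), trial = 1:4),
                                  class = "fp_points")),
               "minority")
})

test_that("with one round RUSBoost reduces to its weak learner", {
  pts <- make_cluster_points(30, 30, sep = 5, seed = 4)
  rb <- rusboost(pts, rounds = 1, maxdepth = 2, seed = 2)
  expect_length(rb$trees, 1)
  h <- fpspace:::stump_prob(rb$trees[[1]], pts$x)
  expect_identical(predict(rb, pts$x), unname(ifelse(h >= 1 - h, 1L, -1L)))
})

test_that("RUSBoost lifts minority recall over a single unweighted tree", {
  deltas <- vapply(1:4, function(seed) {
    set.seed(seed * 100)
    n1 <- 15L; n0 <- 135L
    x <- rbind(matrix(rnorm(n1 * 2, mean = 1.6), n1, 2),
               matrix(rnorm(n0 * 2, mean = 0), n0, 2))
    y <- c(rep(1L, n1), rep(-1L, n0))
    pts <- structure(list(x = x, y = y,
                          stimulus = ifelse(y == 1L, "P", "N"),
                          trial = rep_len(1:10, n1 + n0)),
                     class = "fp_points")
    rb <- suppressWarnings(rusboost(pts, rounds = 15, maxdepth = 2,
                                    seed = seed))
    single <- fpspace:::fit_stump(x, y, rep(1, n1 + n0), maxdepth = 2)
    rec <- function(pred) sum(pred == 1L & y == 1L) / n1
    rec(predict(rb, x)) -
      rec(ifelse(fpspace:::stump_prob(single, x) >= 0.5, 1L, -1L))
  }, numeric(1))
  expect_gte(mean(deltas), 0)
})

test_that("duplicating majority points leaves RUSBoost stable in expectation", {
  set.seed(55)
  n1 <- 12L; n0 <- 60L
  x <- rbind(matrix(rnorm(n1 * 2, mean = 2.5), n1, 2),
             matrix(rnorm(n0 * 2, mean = 0), n0, 2))
  y <- c(rep(1L, n1), rep(-1L, n0))
  as_pts <- function(x, y) structure(
    list(x = x, y = y, stimulus = ifelse(y == 1L, "P", "N"),
         trial = rep_len(1:10, length(y))), class = "fp_points")
  dup <- as_pts(rbind(x, x[y == -1L, ]), c(y, y[y == -1L]))
  base <- as_pts(x, y)
  rec <- function(pts, seed) {
    rb <- rusboost(pts, rounds = 10, maxdepth = 2, seed = seed)
    pred <- predict(rb, x)
    sum(pred == 1L & y == 1L) / n1
  }
  r_base <- mean(vapply(1:4, function(s) rec(base, s), numeric(1)))
  r_dup <- mean(vapply(1:4, function(s) rec(dup, s), numeric(1)))
  expect_lt(abs(r_base - r_dup), 0.25)
})
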