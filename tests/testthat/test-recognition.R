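test_that("hyperellipse membership counts the boundary as inside", {
  e <- hyperellipse(c(0, 0, 0), c(1, 2, 3))
  expect_identical(hyperellipse_indicator(c(0, 0, 0), e), 1L)
  expect_identical(hyperellipse_indicator(c(0, 2, 0), e), 1L)  # on the boundary
  expect_identical(hyperellipse_indicator(c(0, 2 + 1e-9, 0), e), 0L)

  sphere <- hyperellipse(c(0, 0, 0), 0.65)
  expect_identical(hyperellipse_indicator(c(1.30, 0, 0), sphere), 0L)
  # q at that point is (1.30/0.65)^2 - 1 = 3
  expect_equal(sum((c(1.30, 0, 0) / 0.65)^2) - 1, 3)
  expect_error(hyperellipse(c(0, 0), c(1, -1)), "positive")
})

test_that("Rec is the inside fraction over the scored window", {
  e <- hyperellipse(0, 1)
  at_center <- matrix(0, 1, 40)
  expect_equal(rec_score(at_center, e)$rec, 1)
  far <- matrix(100, 1, 40)
  expect_equal(rec_score(far, e)$rec, 0)

  traj <- matrix(c(rep(0, 30), rep(10, 20)), 1)
  sc <- rec_score(traj, e, window = 1:50)
  expect_identical(sc$S, 30L)
  expect_equal(sc$rec, 0.6)
  expect_error(rec_score(traj, e, window = integer(0)), "nonempty")
  expect_error(rec_score(traj, e, window = 60), "within")
})

test_that("Rec is permutation-invariant and monotone in the radii", {
  set.seed(31)
  traj <- matrix(rnorm(3 * 50), 3, 50)
  center <- rnorm(3)
  e <- hyperellipse(center, c(0.8, 1.1, 0.9))
  perm <- sample(50)
  expect_identical(rec_score(traj, e)$rec, rec_score(traj[, perm], e)$rec)
  recs <- vapply(seq(0.2, 3, by = 0.2), function(r)
    rec_score(traj, hyperellipse(center, r))$rec, numeric(1))
  expect_true(all(diff(recs) >= 0))
  expect_true(all(recs >= 0 & recs <= 1))
})

test_that("the decision line is the midpoint of the normalized mean and 1", {
  scores <- c(B = 1.0, S1 = 0.1, S2 = 0.1, S3 = 0.4, S4 = 0.4)
  res <- classify_behavioral(scores)  # normalized mean 0.4
  expect_equal(res$d, 0.7)
  res2 <- classify_behavioral(c(A = 1.0, B = 0.2, C = 0.2, D = 0.2))
  expect_equal(res2$d, 0.7)
  expect_identical(unname(res2$predicted), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(classify_behavioral(c(0, 0, 0)), "degenerate")
})

test_that("precision, recall and their product follow the counting rules", {
  # tp = 3, fp = 1, fn = 0
  pr <- precision_recall(c(TRUE, TRUE, TRUE, TRUE, FALSE),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(pr), c(0.75, 1, 0.75))
  expect_equal(unname(precision_recall(c(TRUE, FALSE), c(TRUE, FALSE))),
               c(1, 1, 1))
  # empty denominators report 0
  expect_equal(unname(precision_recall(c(FALSE, FALSE), c(TRUE, FALSE))),
               c(0, 0, 0))
  expect_equal(unname(precision_recall(c(TRUE, TRUE), c(FALSE, FALSE))[2]), 0)

  set.seed(17)
  pred <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  truth <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  tp <- 0; fp <- 0; fn <- 0
  for (i in 1:200) {
    if (pred[i] && truth[i]) tp <- tp + 1
    if (pred[i] && !truth[i]) fp <- fp + 1
    if (!pred[i] && truth[i]) fn <- fn + 1
  }
  expect_equal(unname(precision_recall(pred, truth)),
               c(tp / (tp + fp), tp / (tp + fn),
                 tp / (tp + fp) * tp / (tp + fn)))
})

test_that("single-trial recognition thresholds at 70% of the target Rec", {
  e <- hyperellipse(0, 1)
  target <- matrix(0, 1, 100)
  target_rec <- rec_score(target, e)$rec
  expect_true(recognize_trial(target, e, target_rec))
  expect_false(recognize_trial(matrix(50, 1, 100), e, target_rec))

  near <- matrix(c(rep(0, 69), rep(50, 31)), 1)   # Rec = 0.69
  above <- matrix(c(rep(0, 71), rep(50, 29)), 1)  # Rec = 0.71
  expect_false(recognize_trial(near, e, 1.0))
  expect_true(recognize_trial(above, e, 1.0))
})

test_that("confidence intervals behave for constant, separated and equal classes", {
  classes <- c(B1 = "behavioral", E1 = "non-behavioral")
  const <- data.frame(stimulus = rep(c("B1", "E1"), each = 4),
                      trial = rep(1:4, 2), rec = rep(c(0.8, 0.2), each = 4))
  ci <- rec_confidence_intervals(const, classes)
  expect_equal(ci$lower, ci$upper)
  expect_equal(ci$mean[ci$class == "behavioral"], 0.8)
  expect_true(attr(ci, "separable"))

  set.seed(9)
  sep <- data.frame(stimulus = rep(c("B1", "E1"), each = 30),
                    rec = c(rnorm(30, 0.9, 0.02), rnorm(30, 0.1, 0.02)))
  expect_true(attr(rec_confidence_intervals(sep, classes), "separable"))

  overlap_count <- 0
  for (seed in 1:20) {
    set.seed(seed)
    same <- data.frame(stimulus = rep(c("B1", "E1"), each = 10),
                       rec = rnorm(20, 0.5, 0.1))
    ci <- rec_confidence_intervals(same, classes)
    if (!attr(ci, "separable")) overlap_count <- overlap_count + 1
  }
  expect_gte(overlap_count, 18)

  cb <- rec_confidence_intervals(sep, classes, method = "bootstrap",
                                 n_boot = 200, seed = 1)
  cb2 <- rec_confidence_intervals(sep, classes, method = "bootstrap",
                                  n_boot = 200, seed = 1)
  expect_identical(cb, cb2)
  expect_true(all(cb$lower <= cb$mean & cb$mean <= cb$upper))
})

test_that("radius sweeps cover 0.5-0.85 and find a perfect-precision band", {
  expect_error(radius_sweep(NULL, NULL, radii = c(0.5, 0)), "positive")

  sim <- make_benchmark_sim(nodes = 106L, trials = 3L, snr = 30, seed = 2L)
  sp <- build_space(sim$collection, "oetr", stimuli = paste0("S", 1:8))
  sw <- radius_sweep(sp, sim$collection, "B1", radii = seq(0.5, 0.85, 0.05))
  expect_equal(range(sw$radius), c(0.5, 0.85))
  iv <- attr(sw, "precision_one_interval")
  expect_gt(iv[["width"]], 0)
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
})

test_that("high-SNR planted mixtures classify to their planted classes", {
  sim <- make_benchmark_sim(nodes = 106L, trials = 3L, snr = 30, seed = 3L)
  sp <- build_space(sim$collection, "oetr", stimuli = paste0("S", 1:8))
  res <- classify_collection(sim$collection, sp, "B1", 0.65)
  truth <- sim$collection$class_labels == "behavioral"
  expect_identical(unname(res$predicted[names(truth)]), unname(truth))
  expect_equal(res$accuracy, 1)
})
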