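test_that("ETR keeps only the above-threshold row maximum", {
  O <- etr(matrix(c(0.5, 0.1, 0.2, 0.7), 2), tau = 0)$O
  expect_equal(unname(O), matrix(c(0.5, 0, 0, 0.7), 2))

  b <- etr(matrix(c(0.5, 0.1, 0.05, 0.2, 0.7, 0.03), 3), tau = 0.06)
  expect_equal(unname(b$O[3, ]), c(0, 0))
  expect_true(is.na(b$assignment[3]))
  expect_identical(b$assignment[1:2], c(1L, 2L))
})

test_that("ETR matches a brute-force row oracle and is exactly orthogonal", {
  for (seed in 1:5) {
    L <- rand_library(50, 4, seed)
    tau <- c(0, 0.2, 0.5, 0, 0.1)[seed]
    O <- etr(L, tau)$O
    expect_identical(unname(O), etr_oracle(L, tau))
    G <- t(O) %*% O
    expect_identical(unname(G[upper.tri(G) | lower.tri(G)]),
                     rep(0, ncol(L)^2 - ncol(L)))
  }
})

test_that("ETR ties go to the lowest stimulus index and scaling commutes", {
  b <- etr(matrix(c(0.5, 0.5), 1), tau = 0)
  expect_identical(b$assignment, 1L)
  L <- rand_library(30, 3, 9)
  expect_equal(etr(3 * L, 3 * 0.25)$O, 3 * etr(L, 0.25)$O, tolerance = 1e-12)
})

test_that("OETR reproduces closed-form toy solutions", {
  res <- oetr(matrix(c(2, 0, 0, 4), 2))
  expect_equal(res$w, c(0.25, 0.0625))
  expect_equal(res$objective, 0, tolerance = 1e-12)

  res2 <- oetr(diag(3))
  expect_equal(res2$w, rep(1, 3))
  expect_equal(res2$objective, 0, tolerance = 1e-12)
})

test_that("OETR equals the vectorized least-squares oracle", {
  for (seed in 1:5) {
    L <- rand_library(30, 3, seed, positive = TRUE)
    b <- etr(L, 0)
    res <- oetr(L, b)
    oracle <- oetr_oracle(L, b$O)
    expect_equal(res$w, oracle$w, tolerance = 1e-6)
    expect_equal(res$objective, oracle$objective, tolerance = 1e-6)
    # never worse than the unweighted ETR basis
    unweighted <- norm(crossprod(L, b$O) - diag(3), "F")
    expect_lte(res$objective, unweighted + 1e-12)
  }
})

test_that("OETR warns when a stimulus has no assigned node", {
  L <- cbind(c(1, 2, 3), c(0.1, 0.2, 0.3))  # column 2 never wins a row
  expect_warning(res <- oetr(L), "S2")
  expect_length(res$w, 3)
})

test_that("fixed points are L'B, identity for zero-residual OETR", {
  L <- matrix(c(2, 0, 0, 4), 2)
  expect_equal(unname(fixed_points(L, etr(L))), diag(c(4, 16)))
  sp <- classification_space(L, "oetr")
  expect_equal(unname(sp$fixed_points), diag(2), tolerance = 1e-12)

  set.seed(5)
  Lr <- rand_library(12, 3, 5)
  B <- matrix(rnorm(36), 12, 3)
  P <- fixed_points(Lr, B)
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) for (n in 1:12)
    oracle[i, j] <- oracle[i, j] + Lr[n, i] * B[n, j]
  expect_equal(unname(P), oracle, tolerance = 1e-12)
})

test_that("projection maps library columns to unit axes in an OETR space", {
  L <- rbind(diag(c(2, 3, 1)), diag(c(1, 1, 4)))  # disjoint-ish, all rows assigned
  sp <- classification_space(L, "oetr")
  expect_lt(sp$objective, 1e-10)
  for (i in 1:3) {
    x <- project_response(matrix(L[, i], ncol = 1), sp)
    expect_equal(unname(x[, 1]), as.numeric(diag(3)[i, ]), tolerance = 1e-8)
  }
  expect_true(all(project_response(matrix(0, 6, 4), sp) == 0))

  set.seed(8)
  f <- matrix(abs(rnorm(6 * 5)), 6, 5)
  x <- project_response(f, sp)
  oracle <- matrix(0, 3, 5)
  for (j in 1:3) for (t in 1:5)
    oracle[j, t] <- sum(sp$basis[, j] * f[, t]) / sp$scale
  expect_equal(unname(x), oracle, tolerance = 1e-12)
})

test_that("ICA basis spans the library subspace and is seed-deterministic", {
  set.seed(21)
  Q <- qr.Q(qr(matrix(rnorm(60 * 3), 60, 3)))
  sp <- ica_basis(Q, seed = 1)
  cosines <- svd(crossprod(qr.Q(qr(Q)), qr.Q(qr(sp$basis))))$d
  expect_true(all(1 - cosines < 1e-6))

  L <- rand_library(80, 4, 13, positive = TRUE)
  s1 <- ica_basis(L, seed = 3)
  s2 <- ica_basis(L, seed = 3)
  expect_identical(s1$basis, s2$basis)
  expect_true(is.logical(s1$converged))
  expect_error(ica_basis(cbind(1:5)), "at least 2")
})

test_that("ICA unmixes synthetic independent sources", {
  set.seed(4)
  S <- matrix(rexp(200 * 3), 200, 3)
  A <- matrix(runif(9, 0.2, 1), 3, 3)
  sp <- ica_basis(S %*% t(A), seed = 2)
  for (i in 1:3)
    expect_gt(max(abs(stats::cor(sp$basis, S[, i]))), 0.9)
})

test_that("noiseless disjoint synthetic data is assigned exactly as generated", {
  sim <- make_disjoint_collection(nodes = 24L, n_stimuli = 3L, seed = 6L)
  lib <- build_library(svdsep(sim$collection, c("S1", "S2", "S3")),
                       c("S1", "S2", "S3"))
  b <- etr(lib, 0)
  assigned <- !is.na(b$assignment)
  expect_identical(b$assignment[assigned], sim$truth$assignment[assigned])
  expect_identical(sum(assigned), 24L)
})

test_that("spaces survive a disk round trip", {
  sim <- make_disjoint_collection(nodes = 20L)
  sp <- build_space(sim$collection, "oetr", stimuli = c("S1", "S2", "S3"))
  dir <- withr::local_tempdir()
  write_space(sp, dir)
  back <- read_space(dir)
  expect_identical(back$method, sp$method)
  expect_identical(back$stimulus_order, sp$stimulus_order)
  expect_identical(unname(back$basis), unname(sp$basis))
  expect_equal(back$scale, sp$scale, tolerance = 1e-12)
})
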