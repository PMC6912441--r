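test_that("log transform floors and uses the natural log", {
  m <- matrix(c(exp(1), 1, 0, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  y <- logTransform(m, floor = 0.01)
  expect_equal(y["g1", "s1"], 1)
  expect_equal(y["g2", "s1"], 0)
  expect_equal(y["g1", "s2"], log(0.01))
  expect_error(logTransform(m, floor = 0))
})

test_that("rank-1 input yields a pure balanced state", {
  g <- exp(rnorm(6, 2))
  Y <- matrix(rep(log(g), 3), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  fit <- surprisalFit(Y, nConstraints = 2)
  expect_lt(max(singularValues(fit)[-1]), 1e-10)
  expect_lt(max(abs(lambdaValues(fit)[-1, ])), 1e-8)
  expect_true(all(lambdaValues(fit, 0) > 0))
  # balanced state alone reproduces a rank-1 matrix
  expect_equal(reconstructLog(fit, 0), Y, tolerance = 1e-10)
})

test_that("toy decomposition matches an independent eigensolver", {
  Y <- matrix(c(1, 2, 0, 1, 0, 2), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  fit <- surprisalFit(Y, nConstraints = 1)
  e <- eigen(crossprod(Y), symmetric = TRUE)
  expect_equal(singularValues(fit), sqrt(e$values), tolerance = 1e-10)
  # each component's outer product is sign-invariant
  for (a in 0:1) {
    comp <- constraintWeights(fit, a) %o% lambdaValues(fit, a)
    vo <- e$vectors[, a + 1]
    oracle <- as.vector(Y %*% vo) %o% vo
    expect_equal(unname(comp), unname(oracle), tolerance = 1e-9)
  }
})

test_that("full-rank reconstruction recovers the floored input exactly", {
  x <- rand_abundance(20, 6, seed = 8)
  x[3, 2] <- 0                       # exercises the floor
  y <- logTransform(x, 0.01)
  fit <- surprisalFit(y, nConstraints = 5)
  expect_lt(max(abs(exp(reconstructLog(fit, 5)) - pmax(x, 0.01)) /
                  pmax(x, 0.01)), 1e-8)
})

test_that("truncations are Eckart-Young optimal against the eigen oracle", {
  set.seed(21)
  for (dims in list(c(5, 3), c(8, 6), c(7, 4))) {
    Y <- matrix(rnorm(prod(dims), mean = 3, sd = 1), dims[1], dims[2],
                dimnames = list(sprintf("g%d", seq_len(dims[1])),
                                sprintf("s%d", seq_len(dims[2]))))
    fit <- surprisalFit(Y, nConstraints = dims[2] - 1)
    d <- singularValues(fit)
    for (k in 0:(dims[2] - 1)) {
      rec <- reconstructLog(fit, k)
      expect_equal(unname(rec), unname(eigen_truncation(Y, k)),
                   tolerance = 1e-8)
      frob <- sqrt(sum((Y - rec)^2))
      expect_equal(frob, sqrt(sum(d[-(seq_len(k + 1))]^2)),
                   tolerance = 1e-8)
    }
  }
})

test_that("weight columns stay orthonormal with non-increasing spectrum", {
  for (seed in 1:4) {
    Y <- log(rand_abundance(15, 5, seed))
    fit <- surprisalFit(Y, nConstraints = 4)
    G <- constraintWeights(fit)
    expect_lt(max(abs(crossprod(G) - diag(ncol(G)))), 1e-8)
    expect_false(is.unsorted(rev(singularValues(fit))))
  }
})

test_that("sign conventions are deterministic and honor reference groups", {
  Y <- log(rand_abundance(12, 6, seed = 13))
  f1 <- surprisalFit(Y)
  f2 <- surprisalFit(Y)
  expect_identical(constraintWeights(f1), constraintWeights(f2))
  expect_identical(lambdaValues(f1), lambdaValues(f2))
  # the reference group's smallest sample gets a positive multiplier
  refs <- list(colnames(Y)[4:6], colnames(Y)[1:3])
  f3 <- surprisalFit(Y, referenceSamples = refs)
  expect_gt(lambdaValues(f3, 1)[["s04"]], 0)
  expect_gt(lambdaValues(f3, 2)[["s01"]], 0)
  # balanced-state violation (mixed-sign sample loadings) aborts
  Ybad <- matrix(c(1, 2, -1, -2), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(surprisalFit(Ybad), "balanced-state")
})

test_that("propagated multiplier bounds behave like an error envelope", {
  x <- rand_abundance(30, 4, seed = 14)
  fit <- surprisalFit(log(x), nConstraints = 3)
  zero <- matrix(0, 30, 4)
  expect_true(all(lambdaErrorBounds(fit, zero) == 0))
  # constant dispersion with orthonormal weights gives bound = c everywhere
  cst <- matrix(0.3, 30, 4)
  expect_equal(unname(lambdaErrorBounds(fit, cst)),
               matrix(0.3, 4, 4), tolerance = 1e-10)
  expect_error(lambdaErrorBounds(fit, -cst), "negative")
  # monotone in every dispersion entry
  set.seed(15)
  sig <- matrix(runif(120, 0, 0.5), 30, 4)
  b0 <- lambdaErrorBounds(fit, sig)
  sig2 <- sig
  sig2[7, 2] <- sig2[7, 2] + 1
  expect_true(all(lambdaErrorBounds(fit, sig2) >= b0 - 1e-12))
  # Monte-Carlo: the three-sigma envelope holds in >= 99% of draws
  G <- constraintWeights(fit)
  n_ok <- 0L
  n_tot <- 0L
  set.seed(16)
  for (i in 1:200) {
    eps <- matrix(rnorm(length(sig), 0, sig), nrow(sig))
    dl <- abs(crossprod(G, eps))
    n_ok <- n_ok + sum(dl <= 3 * b0 + 1e-12)
    n_tot <- n_tot + length(dl)
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("bootstrap multiplier uncertainty vanishes without noise", {
  sim <- simulateSurprisalData(nGenes = 120, noiseSd = 0, setSize = 10, seed = 17)
  sd0 <- bootstrapLambda(sim$experiment, nBoot = 10, seed = 1)
  expect_lt(max(sd0), 1e-8)
  simn <- simulateSurprisalData(nGenes = 120, noiseSd = 0.2, setSize = 10, seed = 17)
  sdn <- bootstrapLambda(simn$experiment, nBoot = 10, seed = 1)
  expect_true(all(sdn >= 0) && any(sdn > 0))
})

test_that("sample grouping separation is scored by multiplier sign", {
  m <- mock_model(w1 = c(2, -1, 1), lambda1 = c(3, 2, -1, -4))
  sep <- groupSeparation(m, 1, list(A = c("s1", "s2"), B = c("s3", "s4")))
  expect_true(sep$separated)
  expect_equal(unname(sep$agreement), c(1, 1))
  expect_equal(unname(sep$majority), c(1, -1))

  same <- mock_model(w1 = c(2, -1, 1), lambda1 = c(3, 2, 1, 4))
  sep2 <- groupSeparation(same, 1, list(A = c("s1", "s2"),
                                        B = c("s3", "s4")))
  expect_false(sep2$separated)

  zl <- mock_model(w1 = c(2, -1, 1), lambda1 = c(3, 0, -1, -4))
  sep3 <- groupSeparation(zl, 1, list(A = c("s1", "s2"),
                                      B = c("s3", "s4")))
  expect_identical(sep3$zeroSamples, "s2")
  expect_false(sep3$separated)
  expect_error(groupSeparation(m, 0, list(A = "s1", B = "s2")), "alpha")
})

test_that("balanced-state multipliers are nearly constant on synthetic data", {
  sim <- simulateSurprisalData(nGenes = 400, setSize = 10, seed = 18)
  fit <- fit_conventional(sim)$fit
  l0 <- lambdaValues(fit, 0)
  # relative spread stays below the planted constraint/baseline energy ratio
  expect_lt((max(l0) - min(l0)) / mean(l0), 0.15)
})
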