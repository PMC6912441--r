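# Builders for small in-code fixtures shared across test files.

# Random strictly positive abundance matrix with dimnames.
rand_abundance <- function(n, m, seed = 1) {
  set.seed(seed)
  matrix(exp(rnorm(n * m, mean = 2)), n, m,
         dimnames = list(sprintf("g%02d", seq_len(n)),
                         sprintf("s%02d", seq_len(m))))
}

# SurprisalExperiment over a C x T x R grid with supplied abundance values.
grid_se <- function(values, C, Tn, R) {
  kk <- rep(seq_len(C), each = Tn * R)
  mm <- rep(rep(seq_len(Tn), each = R), C)
  rr <- rep(seq_len(R), C * Tn)
  ids <- sprintf("ac%dt%d_r%d", kk, mm, rr)
  colnames(values) <- ids
  SurprisalExperiment(values, data.frame(
    sample_id = ids, concentration_index = kk, time_index = mm,
    replicate_index = rr))
}

# SurprisalModel with a prescribed constraint-1 weight vector (up to a
# positive rescaling) and multipliers; alpha0 is an orthogonal complement of
# the all-ones direction so validity holds.
mock_model <- function(w1, lambda1, w0 = rep(1, length(w1)),
                       lambda0 = 5) {
  n <- length(w1)
  ids <- sprintf("g%d", seq_len(n))
  v1 <- w1 / sqrt(sum(w1^2))
  u0 <- w0 - sum(w0 * v1) * v1
  u0 <- u0 / sqrt(sum(u0^2))
  G <- cbind(alpha0 = u0, alpha1 = v1)
  rownames(G) <- ids
  lambda <- rbind(alpha0 = rep(lambda0, length(lambda1)), alpha1 = lambda1)
  colnames(lambda) <- sprintf("s%d", seq_along(lambda1))
  new("SurprisalModel", G = G, lambda = lambda,
      singularValues = c(abs(lambda0) * sqrt(length(lambda1)),
                         sqrt(sum(lambda1^2))) |> sort(decreasing = TRUE),
      nConstraints = 1L, logFloor = 0.01)
}

# Rank-(k+1) truncation oracle: projection of Y onto the span of the leading
# eigenvectors of t(Y) %*% Y (no call to svd()).
eigen_truncation <- function(Y, k) {
  e <- eigen(crossprod(Y), symmetric = TRUE)
  v <- e$vectors[, seq_len(k + 1L), drop = FALSE]
  Y %*% v %*% t(v)
}

# Collapse + fit with the conventional orientation (positive lambda1 =
# exponential phase, positive lambda2 = high dose).
fit_conventional <- function(sim, nConstraints = 2, method = "mean_linear") {
  col <- collapseReplicates(sim$experiment, method = method,
                            floor = sim$truth@logFloor)
  fit <- surprisalFit(col, nConstraints = nConstraints,
                      referenceSamples = referenceGroups(sampleDesign(col)),
                      floor = sim$truth@logFloor)
  list(collapsed = col, fit = fit)
}
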