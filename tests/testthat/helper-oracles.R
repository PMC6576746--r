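# Independent oracles used across the suite.

# Laplacian quadratic form by explicit double loop over node pairs.
brute_laplacian <- function(U, S) {
  U <- as.matrix(U); S <- as.matrix(S)
  acc <- 0
  for (i in seq_len(nrow(S))) for (j in seq_len(ncol(S))) {
    if (i != j) acc <- acc + S[i, j] * sum((U[i, ] - U[j, ])^2)
  }
  acc / 2
}

# Plain unweighted nonnegative factorization by projected alternating least
# squares; independent of the package's multiplicative-update path.
als_nmf <- function(M, r, iters = 500, seed = 1) {
  set.seed(seed)
  n <- nrow(M); m <- ncol(M)
  U <- matrix(runif(n * r), n, r)
  V <- matrix(runif(m * r), m, r)
  for (k in seq_len(iters)) {
    U <- pmax(M %*% V %*% solve(crossprod(V) + 1e-10 * diag(r)), 0)
    V <- pmax(t(M) %*% U %*% solve(crossprod(U) + 1e-10 * diag(r)), 0)
  }
  list(U = U, V = V, rss = sum((M - U %*% t(V))^2))
}

# Pairwise-comparison AUC by explicit double loop.
brute_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# Shared solver benchmark: generator defaults, density-matched solver
# operating point (see the methods vignette).
benchmark_fit <- function(seed = 42, max_iter = 500) {
  sim <- simulate_interaction_data(seed = seed)
  fit <- suppressWarnings(
    winoccf(sim$R, Q = sim$Q, chem_sim = sim$C, prot_sim = sim$T,
            rank = sim$config$rank, alpha = 0.1, beta = 0.1, gamma = 0.1,
            weights = weight_scheme(1, 0.5, 0.1),
            max_iter = max_iter, tol = 1e-7, seed = seed))
  list(sim = sim, fit = fit)
}

holdout_auc_of <- function(sim, fit) {
  P <- predict(fit)
  obs <- as.matrix(sim$R) != 0
  hm <- matrix(FALSE, nrow(P), ncol(P))
  hm[cbind(sim$holdout$i, sim$holdout$j)] <- TRUE
  rank_auc(P[cbind(sim$holdout$i, sim$holdout$j)], P[!obs & !hm])
}
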