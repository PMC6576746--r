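test_that("laplacian quadratic form matches its pairwise identity", {
  # null cases
  U <- matrix(1, 4, 3)
  S <- matrix(0.5, 4, 4); diag(S) <- 0
  expect_equal(laplacian_quadratic(U, S), 0)
  expect_equal(laplacian_quadratic(matrix(rnorm(8), 4, 2),
                                   matrix(0, 4, 4)), 0)
  # worked 2-node example: S12 = 1, rows (1,0) and (0,1)
  expect_equal(laplacian_quadratic(rbind(c(1, 0), c(0, 1)),
                                   rbind(c(0, 1), c(1, 0))), 2)
  # random symmetric graphs against the explicit double loop
  set.seed(5)
  for (rep_ in 1:5) {
    n <- sample(3:8, 1)
    S <- matrix(runif(n * n), n, n); S <- (S + t(S)) / 2; diag(S) <- 0
    U <- matrix(rnorm(n * 3), n, 3)
    expect_equal(laplacian_quadratic(U, S), brute_laplacian(U, S),
                 tolerance = 1e-10)
  }
  expect_error(laplacian_quadratic(matrix(0, 2, 1),
                                   rbind(c(0, 1), c(0.5, 0))), "symmetric")
})

test_that("objective value matches hand-computed small cases", {
  R1 <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1))
  w1 <- weight_scheme(1, 1, 1)
  exact <- list(U = matrix(1), V = matrix(1), alpha = 0, beta = 0, gamma = 0)
  expect_equal(objective_value(exact, R1, weights = w1), 0)
  half <- list(U = matrix(0.5), V = matrix(1), alpha = 0, beta = 0, gamma = 0)
  expect_equal(objective_value(half, R1, weights = w1), 0.25)

  # zero factors: objective is the weighted mass of the targets
  R <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(1, 2),
                            dims = c(2, 3),
                            dimnames = list(c("a", "b"), c("x", "y", "z")))
  Q <- data.frame(chemical_key = "a", protein_key = "y",
                  value = 0.5, weight = 0.4)
  class(Q) <- c("imputation_matrix", "data.frame")
  w <- weight_scheme(1, 0.4, 0)
  zero <- list(U = matrix(0, 2, 2), V = matrix(0, 3, 2),
               alpha = 0, beta = 0, gamma = 0)
  expect_equal(objective_value(zero, R, Q = Q, weights = w),
               1 * 1^2 + 1 * 2^2 + 0.4 * 0.5^2)
  # overlap between R and Q is rejected
  Qbad <- data.frame(chemical_key = "a", protein_key = "x",
                     value = 1, weight = 0.4)
  class(Qbad) <- c("imputation_matrix", "data.frame")
  expect_error(objective_value(zero, R, Q = Qbad, weights = w), "overlap")
})

test_that("weight scheme enforces the trust ordering", {
  expect_error(weight_scheme(0.5, 1, 0.01), "w_obs >= w_imp")
  expect_error(weight_scheme(1, 0.5, -0.1), "w_obs >= w_imp")
  expect_silent(weight_scheme(1, 1, 1))
})

test_that("planted low-rank data is recovered to high accuracy", {
  set.seed(7)
  U0 <- matrix(runif(30 * 2), 30, 2)
  V0 <- matrix(runif(20 * 2), 20, 2)
  R <- Matrix::Matrix(U0 %*% t(V0), sparse = TRUE)
  fit <- suppressWarnings(
    winoccf(R, rank = 2, alpha = 0, beta = 0, gamma = 0,
            weights = weight_scheme(1, 1, 1), max_iter = 3000,
            tol = 1e-12, seed = 1))
  P <- predict(fit)
  expect_lt(norm(P - as.matrix(R), "F") / norm(as.matrix(R), "F"), 1e-3)
  expect_true(all(fit$U >= 0) && all(fit$V >= 0))
  expect_true(all(P >= 0))
})

test_that("the objective history is non-increasing and seed-reproducible", {
  bench <- benchmark_fit(max_iter = 60)
  h <- bench$fit$history
  expect_true(all(diff(h) <= 1e-9 * pmax(h[-length(h)], 1e-12)))
  # bitwise determinism under an identical seed
  bench2 <- benchmark_fit(max_iter = 60)
  expect_identical(bench$fit$history, bench2$fit$history)
  expect_identical(bench$fit$U, bench2$fit$U)
  # internal and external objective evaluations agree
  o <- objective_value(bench$fit, bench$sim$R, Q = bench$sim$Q,
                       weights = weight_scheme(1, 0.5, 0.1),
                       chem_sim = bench$sim$C, prot_sim = bench$sim$T)
  expect_equal(o, h[length(h)], tolerance = 1e-10)
})

test_that("with no regularization the solver matches an independent alternating solver", {
  set.seed(21)
  M <- matrix(runif(5 * 2), 5, 2) %*% t(matrix(runif(5 * 2), 5, 2))
  fit <- suppressWarnings(
    winoccf(Matrix::Matrix(M, sparse = TRUE), rank = 2, alpha = 0,
            beta = 0, gamma = 0, weights = weight_scheme(1, 1, 1),
            max_iter = 4000, tol = 1e-13, seed = 2))
  oracle <- als_nmf(M, 2, iters = 500, seed = 2)
  rss_fit <- sum((M - predict(fit))^2)
  # both routes drive the residual of this exactly-rank-2 instance to ~0
  expect_lt(rss_fit, 1e-6)
  expect_lt(oracle$rss, 1e-6)
  expect_equal(rss_fit, oracle$rss, tolerance = 1e-4)
})

test_that("degenerate and invalid solver inputs are handled", {
  # no observations at all: factors collapse to zero, objective to zero
  R0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(4, 3))
  fit0 <- suppressWarnings(winoccf(R0, rank = 2, alpha = 0.1, beta = 0,
                                   gamma = 0, max_iter = 5, seed = 1))
  expect_equal(sum(fit0$U) + sum(fit0$V), 0)
  expect_equal(fit0$history[length(fit0$history)], 0)

  # Q overlapping R is refused
  R <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(2, 2),
                            dimnames = list(c("a", "b"), c("x", "y")))
  Qbad <- data.frame(chemical_key = "a", protein_key = "x")
  class(Qbad) <- c("imputation_matrix", "data.frame")
  expect_error(winoccf(R, Q = Qbad, rank = 1, seed = 1), "overlap")

  # negative R is refused
  expect_error(winoccf(Matrix::Matrix(-1, 1, 1), rank = 1), "nonnegative")
})

test_that("target ranking sorts by score with stable index tie-breaks", {
  fit <- structure(list(
    U = matrix(1, 1, 1, dimnames = list("drug", NULL)),
    V = matrix(c(0.9, 0.1, 0.5), 3, 1,
               dimnames = list(c("p1", "p2", "p3"), NULL)),
    R = Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 3),
                             dimnames = list("drug", c("p1", "p2", "p3")))),
    class = "winoccf")
  rk <- rank_targets(fit, "drug")
  expect_equal(rk$protein_key, c("p1", "p3", "p2"))
  # exact ties keep protein index order
  fit$V <- matrix(c(0.5, 0.5, 0.1), 3, 1,
                  dimnames = list(c("p1", "p2", "p3"), NULL))
  expect_equal(rank_targets(fit, "drug")$protein_key, c("p1", "p2", "p3"))
  # masking removes the training positive p1
  expect_equal(rank_targets(fit, "drug", mask_known = TRUE)$protein_key,
               c("p2", "p3"))
  expect_error(rank_targets(fit, "nosuch"), "unknown chemical")
})

test_that("rank-based AUC equals the pairwise comparison oracle", {
  set.seed(9)
  for (rep_ in 1:5) {
    pos <- sample(c(rnorm(15, 1), 0.5, 0.5))
    neg <- c(rnorm(40), 0.5)  # include exact ties
    expect_equal(rank_auc(pos, neg), brute_auc(pos, neg), tolerance = 1e-12)
  }
})
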