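#' Confidence weight scheme for the one-class objective
#'
#' The squared-error sum of the factorization objective runs over *all* cells
#' of the chemicals x proteins matrix, with a class-dependent confidence
#' weight: `w_obs` on observed positive associations (R), `w_imp` on imputed
#' putative associations (Q), and `w_zero` on the remaining unobserved cells,
#' whose target value is the background imputation value (0 by default). The
#' ordering `w_obs >= w_imp >= w_zero >= 0` encodes decreasing trust in the
#' three evidence classes.
#'
#' @param w_obs Weight on observed entries (default 1).
#' @param w_imp Weight on imputed entries (default 0.5); per-entry weights on
#'   an [build_imputation_matrix()] object override this scalar.
#' @param w_zero Weight on unobserved background cells (default 0.01).
#' @return Object of class `weight_scheme`.
#' @export
weight_scheme <- function(w_obs = 1, w_imp = 0.5, w_zero = 0.01) {
  stopifnot(is.numeric(w_obs), is.numeric(w_imp), is.numeric(w_zero))
  if (!(w_obs >= w_imp && w_imp >= w_zero && w_zero >= 0))
    stop("weights must satisfy w_obs >= w_imp >= w_zero >= 0")
  if (w_obs <= 0) stop("'w_obs' must be positive")
  structure(list(w_obs = w_obs, w_imp = w_imp, w_zero = w_zero),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("Weight scheme: w_obs = %g, w_imp = %g, w_zero = %g\n",
              x$w_obs, x$w_imp, x$w_zero))
  invisible(x)
}

# Clean a similarity matrix for Laplacian use: symmetrize, drop self-loops,
# validate the [0,1] range. Returns a dgCMatrix.
prepare_similarity <- function(S, warn_asymmetric = TRUE) {
  S <- methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (!Matrix::isSymmetric(S, tol = 0)) {
    if (warn_asymmetric) warning("asymmetric similarity matrix symmetrized as (S + t(S))/2")
    S <- (S + Matrix::t(S)) / 2
  }
  Matrix::diag(S) <- 0
  S <- Matrix::drop0(S)
  if (length(S@x) && (min(S@x) < 0 || max(S@x) > 1))
    stop("similarity entries must lie in [0, 1]")
  S
}

#' Graph-Laplacian quadratic form of a factor matrix
#'
#' Computes `tr(U' (D - S) U)` for a symmetric similarity matrix S with
#' degree matrix `D = diag(rowSums(S))` — the neighborhood-regularization
#' penalty that draws the latent factors of similar chemicals (or proteins)
#' together. Equal to the pairwise form
#' `0.5 * sum_ij S[i,j] * ||U[i,] - U[j,]||^2`.
#'
#' @param U Numeric factor matrix with one row per graph node.
#' @param S Symmetric similarity matrix (sparse or dense) with entries in
#'   \[0, 1\]; self-loops are ignored.
#' @return Nonnegative scalar.
#' @export
laplacian_quadratic <- function(U, S) {
  U <- as.matrix(U)
  S <- methods::as(methods::as(S, "generalMatrix"), "CsparseMatrix")
  if (nrow(S) != nrow(U)) stop("dimensions of 'U' and 'S' disagree")
  if (!Matrix::isSymmetric(S, tol = 0)) stop("'S' must be symmetric")
  Matrix::diag(S) <- 0
  d <- Matrix::rowSums(S)
  sum(d * rowSums(U^2)) - sum(U * as.matrix(S %*% U))
}

# Normalize the Q argument into aligned sparse value/weight triplets.
# Returns list(i, j, value, weight) in R's index space, plus the background
# imputation value q0.
resolve_imputation <- function(Q, R, w_imp) {
  n <- nrow(R); m <- ncol(R)
  empty <- list(i = integer(0), j = integer(0),
                value = numeric(0), weight = numeric(0), q0 = 0)
  if (is.null(Q)) return(empty)
  if (inherits(Q, "uniform_imputation")) {
    empty$q0 <- Q$value
    return(empty)
  }
  if (inherits(Q, "imputation_matrix") ||
      (is.data.frame(Q) && all(c("chemical_key", "protein_key") %in% names(Q)))) {
    if (is.null(rownames(R)) || is.null(colnames(R)))
      stop("key-based Q requires an R matrix with dimnames")
    i <- match(Q$chemical_key, rownames(R))
    j <- match(Q$protein_key, colnames(R))
    known <- !is.na(i) & !is.na(j)
    if (any(!known))
      warning(sum(!known), " imputed pair(s) outside the index of R dropped")
    val <- if ("value" %in% names(Q)) Q$value else rep(1, nrow(Q))
    wt <- if ("weight" %in% names(Q)) Q$weight else rep(w_imp, nrow(Q))
    return(list(i = i[known], j = j[known],
                value = val[known], weight = wt[known], q0 = 0))
  }
  # sparse/dense matrix aligned with R
  Qm <- methods::as(methods::as(Q, "generalMatrix"), "CsparseMatrix")
  if (!all(dim(Qm) == c(n, m))) stop("matrix Q must have the dimensions of R")
  tq <- Matrix::summary(Qm)
  list(i = tq$i, j = tq$j, value = tq$x, weight = rep(w_imp, nrow(tq)), q0 = 0)
}

# Full objective on explicit cell triplets; the dense background term is
# folded in algebraically (never materialized).
winoccf_objective_core <- function(U, V, ci, cj, mv, wv, w0, q0,
                                   alpha, beta, gamma, C, dC, Tm, dT) {
  n <- nrow(U); m <- nrow(V)
  sumP <- sum(colSums(U) * colSums(V))
  sumP2 <- sum(crossprod(U) * crossprod(V))
  bg <- w0 * (q0^2 * n * m - 2 * q0 * sumP + sumP2)
  corr <- 0
  if (length(ci)) {
    p <- rowSums(U[ci, , drop = FALSE] * V[cj, , drop = FALSE])
    corr <- sum(wv * (mv - p)^2 - w0 * (q0 - p)^2)
  }
  obj <- bg + corr + alpha * (sum(U^2) + sum(V^2))
  if (beta > 0 && !is.null(C))
    obj <- obj + beta * (sum(dC * rowSums(U^2)) - sum(U * as.matrix(C %*% U)))
  if (gamma > 0 && !is.null(Tm))
    obj <- obj + gamma * (sum(dT * rowSums(V^2)) - sum(V * as.matrix(Tm %*% V)))
  obj
}

#' Fit the weighted imputed neighborhood-regularized one-class model
#'
#' Factorizes a sparse positive-only chemical-protein association matrix R,
#' optionally augmented with a structure-screen imputation matrix Q, into
#' nonnegative low-rank factors U (chemicals x rank) and V (proteins x rank)
#' by iteratively minimizing
#' \deqn{\sum_{ij} w_{ij}\,(R_{ij}+Q_{ij}-U_i V_j^T)^2
#'       + \alpha(\|U\|_F^2+\|V\|_F^2)
#'       + \beta\,tr(U^T(D_C-C)U) + \gamma\,tr(V^T(D_T-T)V)}
#' where the sum runs over all cells with class-dependent confidence weights
#' (see [weight_scheme()]), C and T are chemical-chemical and
#' protein-protein similarity matrices with degree matrices D_C and D_T, and
#' the unobserved background (target value 0, or the uniform imputation value)
#' is handled implicitly without densifying. Optimization uses multiplicative
#' updates derived from the objective gradient, which keep the factors
#' nonnegative and the objective non-increasing.
#'
#' @param R Observed interaction matrix: a sparse (or dense) nonnegative
#'   matrix, e.g. from [build_interaction_matrix()]. Dimnames, when present,
#'   become the chemical/protein indices of the model.
#' @param Q Imputed associations: an [build_imputation_matrix()] object (keys
#'   matched against R's dimnames, per-entry confidence weights honoured), a
#'   matrix aligned with R, a [uniform_imputation()] scalar, or `NULL`. Q must
#'   not overlap R.
#' @param chem_sim,prot_sim Optional chemical-chemical / protein-protein
#'   similarity matrices in \[0, 1\] (symmetrized, self-loops dropped).
#' @param rank Latent dimension r (default 100; use far less on small data).
#' @param alpha Frobenius regularization (default 0.1).
#' @param beta,gamma Laplacian regularization strengths for the chemical and
#'   protein graphs (default 0.1 each; ignored without the matching graph).
#' @param weights A [weight_scheme()].
#' @param max_iter Maximum number of update sweeps (default 500).
#' @param tol Relative objective-change convergence tolerance (default 1e-6).
#' @param seed Integer seed for the random nonnegative initialization; fits
#'   with the same seed are bitwise reproducible.
#' @param verbose Print objective every 25 iterations.
#' @return Object of class `winoccf` with components `U`, `V`, `history`
#'   (objective per iteration, starting at the initial point), `iterations`,
#'   `converged`, the hyperparameters, and the training R pattern (for
#'   masking and residuals).
#' @seealso [predict.winoccf()], [rank_targets()], [objective_value()]
#' @examples
#' sim <- simulate_interaction_data(n_chem = 30, n_prot = 20, rank = 3,
#'                                  seed = 1)
#' fit <- winoccf(sim$R, Q = sim$Q, chem_sim = sim$C, prot_sim = sim$T,
#'                rank = 3, max_iter = 50, seed = 1)
#' fit
#' @export
winoccf <- function(R, Q = NULL, chem_sim = NULL, prot_sim = NULL,
                    rank = 100, alpha = 0.1, beta = 0.1, gamma = 0.1,
                    weights = weight_scheme(), max_iter = 500, tol = 1e-6,
                    seed = NULL, verbose = FALSE) {
  cl <- match.call()
  stopifnot(rank >= 1, alpha >= 0, beta >= 0, gamma >= 0,
            max_iter >= 1, tol >= 0)
  if (!inherits(weights, "weight_scheme")) weights <- do.call(weight_scheme, as.list(weights))
  R <- methods::as(methods::as(R, "generalMatrix"), "CsparseMatrix")
  if (length(R@x) && min(R@x) < 0) stop("R must be nonnegative")
  n <- nrow(R); m <- ncol(R)
  r <- as.integer(min(rank, max(n, 1), max(m, 1)))
  if (r < rank)
    message("rank reduced to ", r, " (cannot exceed matrix dimensions)")

  qs <- resolve_imputation(Q, R, weights$w_imp)
  tr_ <- Matrix::summary(R)
  # observed and imputed cells must be disjoint
  if (length(qs$i)) {
    rkey <- paste(tr_$i, tr_$j)
    qkey <- paste(qs$i, qs$j)
    if (any(qkey %in% rkey))
      stop("Q overlaps observed entries of R; imputation is only for unobserved cells")
    if (anyDuplicated(qkey)) stop("duplicate cells in Q")
  }
  w0 <- weights$w_zero
  q0 <- qs$q0
  ci <- c(tr_$i, qs$i)
  cj <- c(tr_$j, qs$j)
  mv <- c(tr_$x, qs$value)
  wv <- c(rep(weights$w_obs, nrow(tr_)), qs$weight)
  if (any(wv * mv - w0 * q0 < 0))
    stop("background imputation exceeds a weighted observed/imputed target; ",
         "lower the uniform imputation value or raise the entry weights")

  C <- if (!is.null(chem_sim)) prepare_similarity(chem_sim) else NULL
  Tm <- if (!is.null(prot_sim)) prepare_similarity(prot_sim) else NULL
  if (!is.null(C) && nrow(C) != n) stop("'chem_sim' does not match nrow(R)")
  if (!is.null(Tm) && nrow(Tm) != m) stop("'prot_sim' does not match ncol(R)")
  dC <- if (!is.null(C)) Matrix::rowSums(C) else NULL
  dT <- if (!is.null(Tm)) Matrix::rowSums(Tm) else NULL
  use_C <- beta > 0 && !is.null(C)
  use_T <- gamma > 0 && !is.null(Tm)

  if (!is.null(seed)) set.seed(seed)
  mbar <- (sum(mv) + q0 * (n * m - length(mv))) / max(n * m, 1)
  scale0 <- sqrt(max(mbar, 0) / r)
  U <- matrix(stats::runif(n * r), n, r) * scale0
  V <- matrix(stats::runif(m * r), m, r) * scale0

  eps <- .Machine$double.eps
  # sparse "delta" matrices: corrections of the background weight/target on
  # the observed + imputed cells
  Wd <- Matrix::sparseMatrix(i = ci, j = cj, x = wv - w0, dims = c(n, m))
  WMd <- Matrix::sparseMatrix(i = ci, j = cj, x = wv * mv - w0 * q0,
                              dims = c(n, m))
  obj <- winoccf_objective_core(U, V, ci, cj, mv, wv, w0, q0,
                                alpha, beta, gamma, C, dC, Tm, dT)
  history <- numeric(max_iter + 1)
  history[1] <- obj
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # --- U update (V fixed) ---
    csV <- colSums(V)
    num <- as.matrix(WMd %*% V)
    if (w0 * q0 > 0) num <- num + w0 * q0 * rep(1, n) %o% csV
    if (use_C) num <- num + beta * as.matrix(C %*% U)
    p <- if (length(ci)) rowSums(U[ci, , drop = FALSE] * V[cj, , drop = FALSE]) else numeric(0)
    SWP <- Matrix::sparseMatrix(i = ci, j = cj, x = (wv - w0) * p, dims = c(n, m))
    den <- w0 * (U %*% crossprod(V)) + as.matrix(SWP %*% V) + alpha * U
    if (use_C) den <- den + beta * (dC * U)
    U <- U * num / (den + eps)
    # --- V update (U fixed) ---
    csU <- colSums(U)
    numv <- as.matrix(Matrix::crossprod(WMd, U))
    if (w0 * q0 > 0) numv <- numv + w0 * q0 * rep(1, m) %o% csU
    if (use_T) numv <- numv + gamma * as.matrix(Tm %*% V)
    p <- if (length(ci)) rowSums(U[ci, , drop = FALSE] * V[cj, , drop = FALSE]) else numeric(0)
    SWP <- Matrix::sparseMatrix(i = ci, j = cj, x = (wv - w0) * p, dims = c(n, m))
    denv <- w0 * (V %*% crossprod(U)) + as.matrix(Matrix::crossprod(SWP, U)) + alpha * V
    if (use_T) denv <- denv + gamma * (dT * V)
    V <- V * numv / (denv + eps)

    obj_new <- winoccf_objective_core(U, V, ci, cj, mv, wv, w0, q0,
                                      alpha, beta, gamma, C, dC, Tm, dT)
    if (is.na(obj_new)) stop("objective became NaN at iteration ", iter)
    history[iter + 1] <- obj_new
    if (verbose && iter %% 25 == 0)
      cat(sprintf("iter %4d  objective %.6g\n", iter, obj_new))
    if (abs(obj - obj_new) <= tol * max(obj, eps)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  if (!converged)
    warning("winoccf did not reach tol = ", tol, " within ", max_iter,
            " iterations")
  dimnames(U) <- list(rownames(R), NULL)
  dimnames(V) <- list(colnames(R), NULL)
  structure(list(U = U, V = V, rank = r, alpha = alpha, beta = beta,
                 gamma = gamma, weights = weights, background_value = q0,
                 history = history[seq_len(iter + 1)], iterations = iter,
                 converged = converged, tol = tol, seed = seed,
                 R = R, n_imputed = length(qs$i), call = cl),
            class = "winoccf")
}

#' Evaluate the one-class factorization objective
#'
#' Recomputes the full weighted objective (squared error over all cells with
#' class weights, Frobenius and graph-Laplacian penalties) for a fitted or
#' hand-constructed model. Mostly useful for testing and for monitoring
#' alternative solvers against the same contract.
#'
#' @param model A `winoccf` fit, or a list with components `U`, `V`, `alpha`,
#'   `beta`, `gamma`.
#' @param R Observed matrix (defaults to the one stored in the fit).
#' @param Q Imputation (as in [winoccf()]); default none.
#' @param weights A [weight_scheme()]; defaults to the fit's.
#' @param chem_sim,prot_sim Optional similarity matrices.
#' @return The objective value (nonnegative scalar).
#' @export
objective_value <- function(model, R = model$R, Q = NULL,
                            weights = model$weights,
                            chem_sim = NULL, prot_sim = NULL) {
  if (is.null(weights)) weights <- weight_scheme()
  if (!inherits(weights, "weight_scheme")) weights <- do.call(weight_scheme, as.list(weights))
  R <- methods::as(methods::as(R, "generalMatrix"), "CsparseMatrix")
  qs <- resolve_imputation(Q, R, weights$w_imp)
  tr_ <- Matrix::summary(R)
  if (length(qs$i) && any(paste(qs$i, qs$j) %in% paste(tr_$i, tr_$j)))
    stop("Q overlaps observed entries of R")
  ci <- c(tr_$i, qs$i); cj <- c(tr_$j, qs$j)
  mv <- c(tr_$x, qs$value)
  wv <- c(rep(weights$w_obs, nrow(tr_)), qs$weight)
  C <- if (!is.null(chem_sim)) prepare_similarity(chem_sim, warn_asymmetric = FALSE) else NULL
  Tm <- if (!is.null(prot_sim)) prepare_similarity(prot_sim, warn_asymmetric = FALSE) else NULL
  winoccf_objective_core(as.matrix(model$U), as.matrix(model$V), ci, cj, mv, wv,
                         weights$w_zero, qs$q0,
                         model$alpha, model$beta, model$gamma,
                         C, if (!is.null(C)) Matrix::rowSums(C) else NULL,
                         Tm, if (!is.null(Tm)) Matrix::rowSums(Tm) else NULL)
}

#' Rank proteins for one chemical by predicted interaction score
#'
#' @param object A fitted `winoccf` model.
#' @param chemical Chemical key (rowname of R) or row index.
#' @param top Keep only the first `top` proteins (default: all).
#' @param mask_known Drop proteins that are training positives for this
#'   chemical (default `FALSE`).
#' @return Data.frame with columns `protein_key`, `score`, sorted by
#'   descending score; ties broken by protein index order (stable).
#' @export
rank_targets <- function(object, chemical, top = NULL, mask_known = FALSE) {
  stopifnot(inherits(object, "winoccf"))
  if (is.character(chemical)) {
    i <- match(chemical, rownames(object$U))
    if (is.na(i)) stop("unknown chemical: ", chemical)
  } else {
    i <- as.integer(chemical)
    if (i < 1 || i > nrow(object$U)) stop("chemical index out of range")
  }
  scores <- drop(object$V %*% object$U[i, ])
  keys <- colnames(object$R)
  if (is.null(keys)) keys <- as.character(seq_along(scores))
  ord <- order(-scores, seq_along(scores))  # stable tie-break on index
  out <- data.frame(protein_key = keys[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  if (mask_known) {
    known <- keys[Matrix::which(object$R[i, ] != 0)]
    out <- out[!out$protein_key %in% known, , drop = FALSE]
  }
  if (!is.null(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve from scores of positives and negatives
#'
#' Mann-Whitney rank formulation; used for held-out evaluation of the
#' factorization.
#'
#' @param pos,neg Numeric score vectors for held-out positives and for
#'   background (unobserved) cells.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
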