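#' @export
print.winoccf <- function(x, ...) {
  cat("Weighted imputed neighborhood-regularized one-class factorization\n")
  cat(sprintf("  %d chemicals x %d proteins, rank %d\n",
              nrow(x$U), nrow(x$V), x$rank))
  cat(sprintf("  observed entries: %d, imputed entries: %d",
              length(x$R@x), x$n_imputed))
  if (x$background_value > 0)
    cat(sprintf(", uniform background %g", x$background_value))
  cat("\n")
  cat(sprintf("  alpha = %g, beta = %g, gamma = %g; %s\n",
              x$alpha, x$beta, x$gamma, format(x$weights)))
  cat(sprintf("  %d iteration(s), objective %.6g -> %.6g (%s)\n",
              x$iterations, x$history[1], x$history[length(x$history)],
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
format.weight_scheme <- function(x, ...) {
  sprintf("w = (%g, %g, %g)", x$w_obs, x$w_imp, x$w_zero)
}

#' @export
summary.winoccf <- function(object, ...) {
  P_obs <- if (length(object$R@x)) {
    tr_ <- Matrix::summary(object$R)
    rowSums(object$U[tr_$i, , drop = FALSE] * object$V[tr_$j, , drop = FALSE])
  } else numeric(0)
  res <- structure(list(
    fit = object,
    objective = object$history[length(object$history)],
    rmse_observed = if (length(P_obs))
      sqrt(mean((Matrix::summary(object$R)$x - P_obs)^2)) else NA_real_,
    score_range_observed = if (length(P_obs)) range(P_obs) else c(NA, NA)
  ), class = "summary.winoccf")
  res
}

#' @export
print.summary.winoccf <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$rmse_observed))
    cat(sprintf("  RMSE on observed entries: %.4g; their scores span [%.3g, %.3g]\n",
                x$rmse_observed, x$score_range_observed[1],
                x$score_range_observed[2]))
  invisible(x)
}

#' Extract the latent factors
#' @param object A `winoccf` fit.
#' @param ... Unused.
#' @return List with the nonnegative factor matrices `U` (chemicals) and `V`
#'   (proteins).
#' @export
coef.winoccf <- function(object, ...) list(U = object$U, V = object$V)

#' Predicted interaction scores
#'
#' Scores are inner products of chemical and protein latent factors,
#' `P[i, j] = U[i, ] . V[j, ]`; nonnegative by construction.
#'
#' @param object A `winoccf` fit.
#' @param chemicals,proteins Optional key or index subsets; default all. Note
#'   the full score matrix is dense.
#' @param ... Unused.
#' @return Dense numeric matrix of scores.
#' @export
predict.winoccf <- function(object, chemicals = NULL, proteins = NULL, ...) {
  sel <- function(keys, M) {
    if (is.null(keys)) return(seq_len(nrow(M)))
    if (is.character(keys)) {
      idx <- match(keys, rownames(M))
      if (anyNA(idx)) stop("unknown key(s): ",
                           paste(keys[is.na(idx)], collapse = ", "))
      idx
    } else as.integer(keys)
  }
  i <- sel(chemicals, object$U)
  j <- sel(proteins, object$V)
  P <- object$U[i, , drop = FALSE] %*% t(object$V[j, , drop = FALSE])
  dimnames(P) <- list(rownames(object$U)[i], rownames(object$V)[j])
  P
}

#' @export
fitted.winoccf <- function(object, ...) predict(object)

#' Residuals on the observed entries
#' @param object A `winoccf` fit.
#' @param ... Unused.
#' @return Numeric vector `R[i,j] - P[i,j]` over the observed (positive)
#'   cells, in the sparse storage order of R.
#' @export
residuals.winoccf <- function(object, ...) {
  if (!length(object$R@x)) return(numeric(0))
  tr_ <- Matrix::summary(object$R)
  tr_$x - rowSums(object$U[tr_$i, , drop = FALSE] *
                    object$V[tr_$j, , drop = FALSE])
}

#' Objective trace plot
#' @param x A `winoccf` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.winoccf <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1, x$history, type = "b", pch = 16,
                 cex = 0.6, xlab = "iteration", ylab = "objective",
                 main = "winOCCF objective trace", ...)
  invisible(x)
}
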