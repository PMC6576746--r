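#' Simulate a low-rank one-class interaction benchmark
#'
#' Generates every input the factorization consumes under the model's own
#' assumption — that chemical and protein space are low-rank. Nonnegative
#' block-structured factors `U*` (chemicals) and `V*` (proteins) are drawn
#' with one dominant latent dimension per block; the truth score matrix is
#' `U* V*'` (plus optional Gaussian noise). The top `density` fraction of
#' truth cells are the positives; a `holdout_fraction` of them is withheld
#' from R (the held-out evaluation set), and a `q_fraction` of the held-out
#' positives is revealed to the model as the imputation matrix Q, playing
#' the role of the structure screen. Chemical-chemical and protein-protein
#' similarity matrices are cosine similarities between the true factor rows,
#' clipped to \[0, 1\], mirroring the bounded Tanimoto/sequence-similarity
#' scores the pipeline consumes in practice.
#'
#' @param n_chem,n_prot Numbers of chemicals and proteins (default 200 x
#'   100).
#' @param rank True latent rank (default 5).
#' @param density Fraction of cells that are positive (default 0.05).
#' @param n_blocks Number of chemical/protein communities (default `rank`).
#' @param noise_sd Gaussian noise on the truth scores (default 0).
#' @param holdout_fraction Fraction of positives withheld from R (default
#'   0.2).
#' @param q_fraction Fraction of the *held-out* positives revealed as Q
#'   (default 0.3).
#' @param q_weight Confidence weight on Q entries (default 0.5).
#' @param seed Integer seed (default 42).
#' @return List with `R` (sparse binary), `Q` ([build_imputation_matrix()]
#'   object), `C`, `T` (sparse similarity), `truth` (dense score matrix),
#'   `holdout` (data.frame of withheld positive pairs), and `config`.
#' @export
simulate_interaction_data <- function(n_chem = 200, n_prot = 100, rank = 5,
                                      density = 0.05, n_blocks = rank,
                                      noise_sd = 0, holdout_fraction = 0.2,
                                      q_fraction = 0.3, q_weight = 0.5,
                                      seed = 42) {
  stopifnot(rank <= min(n_chem, n_prot), density > 0, density < 1,
            holdout_fraction >= 0, holdout_fraction < 1,
            q_fraction >= 0, q_fraction <= 1)
  n_pos_target <- round(density * n_chem * n_prot)
  if (n_pos_target < 1) stop("density too low: no positive cells")
  set.seed(seed)
  chem_keys <- sprintf("CHEM%04d", seq_len(n_chem))
  prot_keys <- sprintf("PROT%04d", seq_len(n_prot))
  block_of <- function(n) sort(rep_len(seq_len(n_blocks), n))
  draw_factors <- function(n) {
    b <- block_of(n)
    f <- matrix(stats::runif(n * rank, 0, 0.1), n, rank)
    k <- ((b - 1) %% rank) + 1
    f[cbind(seq_len(n), k)] <- f[cbind(seq_len(n), k)] + stats::runif(n, 0.5, 1)
    f
  }
  Ustar <- draw_factors(n_chem)
  Vstar <- draw_factors(n_prot)
  truth <- Ustar %*% t(Vstar)
  if (noise_sd > 0)
    truth <- truth + matrix(stats::rnorm(n_chem * n_prot, 0, noise_sd),
                            n_chem, n_prot)
  dimnames(truth) <- list(chem_keys, prot_keys)
  thr <- sort(truth, decreasing = TRUE)[n_pos_target]
  pos <- which(truth >= thr, arr.ind = TRUE)
  n_hold <- round(holdout_fraction * nrow(pos))
  hold_idx <- if (n_hold > 0) sample(nrow(pos), n_hold) else integer(0)
  train <- pos[setdiff(seq_len(nrow(pos)), hold_idx), , drop = FALSE]
  held <- pos[hold_idx, , drop = FALSE]
  R <- Matrix::sparseMatrix(i = train[, 1], j = train[, 2],
                            x = rep(1, nrow(train)),
                            dims = c(n_chem, n_prot),
                            dimnames = list(chem_keys, prot_keys))
  n_q <- round(q_fraction * nrow(held))
  q_idx <- if (n_q > 0) sample(nrow(held), n_q) else integer(0)
  q_pairs <- data.frame(chemical_key = chem_keys[held[q_idx, 1]],
                        protein_key = prot_keys[held[q_idx, 2]],
                        stringsAsFactors = FALSE)
  Q <- build_imputation_matrix(q_pairs, imputed_value = 1,
                               confidence_weight = q_weight, R = R)
  cosine_sim <- function(F_) {
    nr <- sqrt(rowSums(F_^2))
    S <- (F_ / nr) %*% t(F_ / nr)
    S <- pmin(pmax(S, 0), 1)
    diag(S) <- 0
    methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
  }
  C <- cosine_sim(Ustar)
  Tm <- cosine_sim(Vstar)
  dimnames(C) <- list(chem_keys, chem_keys)
  dimnames(Tm) <- list(prot_keys, prot_keys)
  holdout <- data.frame(chemical_key = chem_keys[held[, 1]],
                        protein_key = prot_keys[held[, 2]],
                        i = unname(held[, 1]), j = unname(held[, 2]),
                        stringsAsFactors = FALSE)
  list(R = R, Q = Q, C = C, T = Tm, truth = truth, holdout = holdout,
       config = list(n_chem = n_chem, n_prot = n_prot, rank = rank,
                     density = density, n_blocks = n_blocks,
                     noise_sd = noise_sd,
                     holdout_fraction = holdout_fraction,
                     q_fraction = q_fraction, q_weight = q_weight,
                     seed = seed))
}

#' Default half-log dilution series
#'
#' Ten concentrations serially diluted in half-log steps downward from
#' 100 uM — the standard viability-assay dose grid.
#'
#' @param max_dose Top concentration in uM (default 100).
#' @param n Number of concentrations (default 10).
#' @return Increasing numeric vector of doses (uM).
#' @export
half_log_doses <- function(max_dose = 100, n = 10) {
  sort(max_dose * 10^(-0.5 * (seq_len(n) - 1)))
}

#' Simulate a dose-response curve
#'
#' Evaluates the Hill binding model or the four-parameter sigmoid on a dose
#' grid and adds seeded Gaussian noise.
#'
#' @param model `"hill"` (params `background`, `signal`, `kd`) or
#'   `"sigmoid"` (params `A`, `B`, `C`, `D`).
#' @param params Named list of model parameters.
#' @param doses Dose grid in uM (default [half_log_doses()]).
#' @param noise_sd Gaussian response noise (default 0).
#' @param n_replicates Independent noisy replicates (default 1).
#' @param seed Optional integer seed.
#' @return Data.frame with columns `dose`, `response`, `replicate`.
#' @export
simulate_dose_response <- function(model = c("hill", "sigmoid"), params,
                                   doses = half_log_doses(), noise_sd = 0,
                                   n_replicates = 1, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  mu <- switch(model,
               hill = hill_response(doses, params$background, params$signal,
                                    params$kd),
               sigmoid = sigmoid_response(doses, params$A, params$B,
                                          params$C, params$D))
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(rep_) {
    y <- mu
    if (noise_sd > 0) y <- y + stats::rnorm(length(doses), 0, noise_sd)
    data.frame(dose = doses, response = y, replicate = rep_)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a drug-sensitivity expression study
#'
#' Log2 expression levels are drawn `Normal(8, 1)` for `n_genes` genes across
#' sensitive and resistant cell-line groups; the first `n_de_genes` genes are
#' shifted upward by `effect_size` in the sensitive group (the true
#' sensitivity genes). Activity areas consistent with the labels are
#' attached so the whole screen can be exercised end to end.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_sensitive,n_resistant Group sizes (default 20 each).
#' @param n_de_genes Number of truly differential genes (default 50).
#' @param effect_size Mean log2 shift in the sensitive group (default 2).
#' @param seed Optional integer seed.
#' @return List with `expr` (genes x lines matrix), `activity_areas` (named,
#'   sensitive lines ~ 3, resistant ~ 0.5), `labels`
#'   ([classify_cell_lines()] output) and `de_genes` (character).
#' @export
simulate_expression <- function(n_genes = 1000, n_sensitive = 20,
                                n_resistant = 20, n_de_genes = 50,
                                effect_size = 2, seed = NULL) {
  stopifnot(n_de_genes <= n_genes, n_sensitive >= 2, n_resistant >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_lines <- n_sensitive + n_resistant
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  lines <- c(sprintf("SENS%03d", seq_len(n_sensitive)),
             sprintf("RES%03d", seq_len(n_resistant)))
  expr <- matrix(stats::rnorm(n_genes * n_lines, 8, 1), n_genes, n_lines,
                 dimnames = list(genes, lines))
  if (n_de_genes > 0 && effect_size != 0)
    expr[seq_len(n_de_genes), seq_len(n_sensitive)] <-
      expr[seq_len(n_de_genes), seq_len(n_sensitive)] + effect_size
  aa <- stats::setNames(c(stats::runif(n_sensitive, 2.5, 4.0),
                          stats::runif(n_resistant, 0.2, 1.0)), lines)
  list(expr = expr, activity_areas = aa, labels = classify_cell_lines(aa),
       de_genes = if (n_de_genes > 0) genes[seq_len(n_de_genes)] else character(0))
}
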