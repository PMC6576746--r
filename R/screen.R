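#' Filter structure-screen hits into putative off-target pairs
#'
#' Combines a binding-site-similarity table (template structure vs. candidate
#' structures, with a similarity p-value per candidate) with a protein-ligand
#' docking table and keeps the (chemical, protein) pairs passing the
#' dual-threshold rule: site-similarity p-value strictly below `p_cut` AND
#' docking score strictly below `score_cut` (more negative = stronger
#' predicted binding). When several structures map to one protein accession,
#' the minimum p-value and the best (most negative) docking score per
#' (chemical, protein) pair are used before filtering. Docking records whose
#' protein has no site hit are ignored (with a message), since a pair must be
#' supported by both screens.
#'
#' @param hits Data.frame with columns `template_id`, `candidate_structure`,
#'   `protein_key`, `p_value` (p-values in (0, 1]).
#' @param docks Data.frame with columns `protein_key`, `chemical_key`,
#'   `score`.
#' @param p_cut Site-similarity p-value threshold (default `2.0e-3`).
#' @param score_cut Docking-score threshold (default `-7.5`).
#' @return Data.frame with columns `chemical_key`, `protein_key`, `p_value`,
#'   `score`, sorted by chemical then protein key.
#' @examples
#' sites <- data.frame(template_id = "T", candidate_structure = "S1",
#'                     protein_key = "P1", p_value = 1e-4)
#' docks <- data.frame(protein_key = "P1", chemical_key = "drug", score = -8)
#' filter_offtarget_candidates(sites, docks)
#' @export
filter_offtarget_candidates <- function(hits, docks,
                                        p_cut = 2.0e-3, score_cut = -7.5) {
  stopifnot(is.data.frame(hits), is.data.frame(docks))
  need_h <- c("template_id", "candidate_structure", "protein_key", "p_value")
  need_d <- c("protein_key", "chemical_key", "score")
  if (length(setdiff(need_h, names(hits))))
    stop("site-hit table lacks column(s): ",
         paste(setdiff(need_h, names(hits)), collapse = ", "))
  if (length(setdiff(need_d, names(docks))))
    stop("docking table lacks column(s): ",
         paste(setdiff(need_d, names(docks)), collapse = ", "))
  if (any(hits$p_value <= 0)) stop("site-similarity p-values must be > 0")
  if (any(!is.finite(docks$score))) stop("docking scores must be finite")
  # best evidence per protein (site side) and per pair (docking side)
  pmin_by_prot <- tapply(hits$p_value, hits$protein_key, min)
  orphan <- !docks$protein_key %in% names(pmin_by_prot)
  if (any(orphan))
    message(sum(orphan), " docking record(s) without a matching site hit ignored")
  docks <- docks[!orphan, , drop = FALSE]
  if (nrow(docks) == 0L)
    return(data.frame(chemical_key = character(0), protein_key = character(0),
                      p_value = numeric(0), score = numeric(0)))
  pair <- paste(docks$chemical_key, docks$protein_key, sep = "\r")
  best <- tapply(docks$score, pair, min)
  first <- !duplicated(pair)
  out <- data.frame(chemical_key = docks$chemical_key[first],
                    protein_key = docks$protein_key[first],
                    p_value = as.numeric(pmin_by_prot[docks$protein_key[first]]),
                    score = as.numeric(best[pair[first]]),
                    stringsAsFactors = FALSE)
  out <- out[out$p_value < p_cut & out$score < score_cut, , drop = FALSE]
  out <- out[order(out$chemical_key, out$protein_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the structure-screen imputation matrix Q
#'
#' Turns filtered off-target candidate pairs into the imputation matrix Q that
#' fills unobserved cells of the interaction matrix with putative positives.
#' Each pair carries an imputed value (the target the factorization is asked
#' to reproduce there) and a confidence weight quantifying the uncertainty of
#' the structure-based prediction. Pairs already observed in R are dropped: Q
#' only imputes *unobserved* entries.
#'
#' @param pairs Data.frame with columns `chemical_key`, `protein_key`
#'   (additional columns ignored), e.g. from
#'   [filter_offtarget_candidates()].
#' @param imputed_value Imputed association value in (0, 1], default 1.
#' @param confidence_weight Confidence weight in (0, 1], default 0.5.
#' @param R Optional observed interaction matrix (sparse, with dimnames);
#'   pairs present in R are removed from Q.
#' @return Object of class `imputation_matrix`: a data.frame with columns
#'   `chemical_key`, `protein_key`, `value`, `weight`, duplicates collapsed.
#' @export
build_imputation_matrix <- function(pairs, imputed_value = 1.0,
                                    confidence_weight = 0.5, R = NULL) {
  stopifnot(is.data.frame(pairs))
  if (!(imputed_value > 0 && imputed_value <= 1))
    stop("'imputed_value' must lie in (0, 1]")
  if (!(confidence_weight > 0 && confidence_weight <= 1))
    stop("'confidence_weight' must lie in (0, 1]")
  if (nrow(pairs)) {
    key <- paste(pairs$chemical_key, pairs$protein_key, sep = "\r")
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  q <- data.frame(chemical_key = as.character(pairs$chemical_key),
                  protein_key = as.character(pairs$protein_key),
                  value = rep(imputed_value, nrow(pairs)),
                  weight = rep(confidence_weight, nrow(pairs)),
                  stringsAsFactors = FALSE)
  if (!is.null(R) && nrow(q)) {
    i <- match(q$chemical_key, rownames(R))
    j <- match(q$protein_key, colnames(R))
    both <- !is.na(i) & !is.na(j)
    drop <- logical(nrow(q))
    if (any(both))
      drop[both] <- as.numeric(R[cbind(i[both], j[both])]) != 0
    q <- q[!drop, , drop = FALSE]
  }
  rownames(q) <- NULL
  class(q) <- c("imputation_matrix", "data.frame")
  q
}

#' Uniform background imputation
#'
#' The baseline imputation mode of plain weighted one-class collaborative
#' filtering: every unobserved cell carries the same small imputed value
#' (default 0.1) instead of structure-screen-specific entries. Represented
#' implicitly as a scalar — the dense matrix is never materialized; the solver
#' folds the constant into its background term algebraically.
#'
#' @param value Imputed background value in (0, 1], default 0.1.
#' @return Object of class `uniform_imputation` wrapping the scalar.
#' @export
uniform_imputation <- function(value = 0.1) {
  if (!(is.numeric(value) && length(value) == 1L && value > 0 && value <= 1))
    stop("'value' must be a scalar in (0, 1]")
  structure(list(value = value), class = "uniform_imputation")
}

#' @export
print.uniform_imputation <- function(x, ...) {
  cat("Uniform background imputation, value =", x$value, "\n")
  invisible(x)
}

#' @export
print.imputation_matrix <- function(x, ...) {
  cat("Imputation matrix Q:", nrow(x), "putative pair(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Read a binding-site-similarity table
#' @param path TSV with header `template_id`, `candidate_structure`,
#'   `protein_key`, `p_value`.
#' @return data.frame
#' @export
read_site_hits <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  need <- c("template_id", "candidate_structure", "protein_key", "p_value")
  if (length(setdiff(need, names(df))))
    stop("site-hit file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Read a docking-score table
#' @param path TSV with header `protein_key`, `chemical_key`, `score`.
#' @return data.frame
#' @export
read_docking_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  need <- c("protein_key", "chemical_key", "score")
  if (length(setdiff(need, names(df))))
    stop("docking file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Write an imputation matrix as TSV triples with a weight column
#' @param q `imputation_matrix`
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imputation_matrix <- function(q, path) {
  utils::write.table(as.data.frame(q), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
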