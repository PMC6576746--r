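#' Classify cell lines by activity area
#'
#' Thresholds as printed: sensitive at activity area >= 1.95, resistant at
#' <= 1.3, intermediate strictly in between.
#'
#' @param activity_areas Named numeric vector (names = cell lines) or
#'   data.frame with columns `cell_line`, `activity_area`.
#' @param sensitive_cut,resistant_cut Boundaries (defaults 1.95 and 1.3,
#'   both inclusive on their own side).
#' @return Data.frame with columns `cell_line`, `activity_area`, `label`
#'   (factor: sensitive/intermediate/resistant).
#' @examples
#' classify_cell_lines(c(`SU-DHL-8` = 5.0, other = 1.5))
#' @export
classify_cell_lines <- function(activity_areas, sensitive_cut = 1.95,
                                resistant_cut = 1.3) {
  if (is.data.frame(activity_areas)) {
    aa <- activity_areas$activity_area
    names(aa) <- activity_areas$cell_line
    activity_areas <- aa
  }
  stopifnot(is.numeric(activity_areas), all(is.finite(activity_areas)),
            sensitive_cut > resistant_cut)
  lab <- ifelse(activity_areas >= sensitive_cut, "sensitive",
                ifelse(activity_areas <= resistant_cut, "resistant",
                       "intermediate"))
  data.frame(cell_line = if (is.null(names(activity_areas)))
               as.character(seq_along(activity_areas)) else names(activity_areas),
             activity_area = unname(activity_areas),
             label = factor(lab, levels = c("sensitive", "intermediate",
                                            "resistant")),
             stringsAsFactors = FALSE)
}

#' Per-gene Student's t-test between sensitive and resistant lines
#'
#' Classical pooled-variance two-sample two-sided t-test of log2 expression
#' per gene; intermediate cell lines are excluded from the comparison.
#' Degenerate genes (zero pooled variance) get `t = 0, p = 1` when the group
#' means coincide and `|t| = Inf, p = 0` when they differ.
#'
#' @param expr Numeric matrix, genes x cell lines (log2 levels), with
#'   dimnames.
#' @param labels Output of [classify_cell_lines()] or a named character
#'   vector of labels per cell line.
#' @return Data.frame with columns `gene`, `t`, `p`, `mean_sensitive`,
#'   `mean_resistant`.
#' @export
gene_t_test <- function(expr, labels) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.data.frame(labels)) {
    lab <- as.character(labels$label)
    names(lab) <- labels$cell_line
    labels <- lab
  }
  if (is.null(colnames(expr)))
    colnames(expr) <- names(labels)[seq_len(ncol(expr))]
  lab <- labels[colnames(expr)]
  s_cols <- which(lab == "sensitive")
  r_cols <- which(lab == "resistant")
  if (length(s_cols) < 2)
    stop("the sensitive group has fewer than 2 cell lines")
  if (length(r_cols) < 2)
    stop("the resistant group has fewer than 2 cell lines")
  xs <- expr[, s_cols, drop = FALSE]
  xr <- expr[, r_cols, drop = FALSE]
  n1 <- ncol(xs); n2 <- ncol(xr)
  m1 <- rowMeans(xs); m2 <- rowMeans(xr)
  v1 <- rowSums((xs - m1)^2) / (n1 - 1)
  v2 <- rowSums((xr - m2)^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df)
  zero_var <- se == 0
  if (any(zero_var)) {
    same <- zero_var & (m1 == m2)
    tt[same] <- 0; p[same] <- 1
    diff <- zero_var & (m1 != m2)
    tt[diff] <- sign(m1[diff] - m2[diff]) * Inf
    p[diff] <- 0
  }
  genes <- rownames(expr)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(expr)))
  data.frame(gene = genes, t = unname(tt), p = unname(p),
             mean_sensitive = unname(m1), mean_resistant = unname(m2),
             stringsAsFactors = FALSE)
}

#' Fold change between mean log2 expression levels, as a ratio
#'
#' The piecewise ratio-of-means convention:
#' `E_S / E_R` when the sensitive mean exceeds the resistant mean, and
#' `-E_R / E_S` when it is lower (so direction is carried by the sign). Equal
#' means give 1. Note this is a ratio of *mean log2 levels* — deliberately
#' implemented as printed even though it differs from the usual
#' log-difference fold change, which is available via `log_ratio = TRUE`.
#' Genes whose applicable denominator is not positive are returned as `NA`
#' with a warning.
#'
#' @param mean_sensitive,mean_resistant Mean log2 levels per gene
#'   (vectorized).
#' @param log_ratio If `TRUE`, return the conventional `E_S - E_R`
#'   log2-difference instead.
#' @return Numeric vector.
#' @examples
#' fold_change(4, 2)  #  2
#' fold_change(2, 4)  # -2
#' @export
fold_change <- function(mean_sensitive, mean_resistant, log_ratio = FALSE) {
  stopifnot(length(mean_sensitive) == length(mean_resistant))
  if (log_ratio) return(mean_sensitive - mean_resistant)
  fc <- rep(1, length(mean_sensitive))
  up <- mean_sensitive > mean_resistant
  dn <- mean_sensitive < mean_resistant
  fc[up] <- mean_sensitive[up] / mean_resistant[up]
  fc[dn] <- -mean_resistant[dn] / mean_sensitive[dn]
  bad <- (up & mean_resistant <= 0) | (dn & mean_sensitive <= 0)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with non-positive mean in the applicable ",
            "denominator flagged as NA")
    fc[bad] <- NA_real_
  }
  fc
}

#' Rank-scaled multiple-testing adjustment
#'
#' The q-value formula used for the differential-expression screen:
#' \deqn{q_i = (p_i / rank_i) \times N}
#' with `rank_i` the ascending rank of the i-th p-value (ties share the mean
#' rank) and N the number of tests. This is the Benjamini-Hochberg quantity
#' *without* the step-up monotonicity enforcement — implemented exactly as
#' the formula is stated, so `q` need not be monotone in `p` and can be
#' recomputed entry by entry.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as the input.
#' @examples
#' q_values(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
q_values <- function(p_values) {
  stopifnot(is.numeric(p_values), all(p_values > 0 | p_values == 0),
            all(p_values <= 1))
  n <- length(p_values)
  if (n == 0) return(numeric(0))
  p_values / rank(p_values, ties.method = "average") * n
}

#' Select sensitivity and resistance genes
#'
#' Genes with q-value strictly below the cutoff are split by the sign of
#' their fold change: positive fold change (higher expression in sensitive
#' lines) into the sensitivity list, negative into the resistance list.
#'
#' @param stats Data.frame with columns `gene`, `q`, `fold_change`.
#' @param q_cut Selection threshold, strict (default 1e-3).
#' @return List with character vectors `sensitivity` and `resistance`.
#' @export
select_genes <- function(stats, q_cut = 1.0e-3) {
  stopifnot(all(c("gene", "q", "fold_change") %in% names(stats)))
  hit <- !is.na(stats$q) & stats$q < q_cut & !is.na(stats$fold_change)
  list(sensitivity = stats$gene[hit & stats$fold_change > 0],
       resistance = stats$gene[hit & stats$fold_change < 0])
}

#' Differential-expression screen for drug sensitivity
#'
#' Convenience pipeline: classify cell lines by activity area, run the
#' per-gene pooled t-test between sensitive and resistant groups, attach the
#' ratio fold change and the rank-scaled q-value, and select genes.
#'
#' @param expr Genes x cell lines log2 expression matrix.
#' @param activity_areas Named activity areas per cell line.
#' @param q_cut Selection threshold (default 1e-3, strict).
#' @return List with `stats` (per-gene data.frame adding `fold_change`, `q`,
#'   `direction`), `labels`, and `selected` (the [select_genes()] output).
#' @export
sensitivity_screen <- function(expr, activity_areas, q_cut = 1.0e-3) {
  labels <- classify_cell_lines(activity_areas)
  st <- gene_t_test(expr, labels)
  st$fold_change <- fold_change(st$mean_sensitive, st$mean_resistant)
  st$q <- q_values(st$p)
  st$direction <- ifelse(is.na(st$fold_change), NA_character_,
                         ifelse(st$fold_change >= 0, "sensitivity",
                                "resistance"))
  list(stats = st, labels = labels, selected = select_genes(st, q_cut))
}

#' Hypergeometric gene-set over-representation analysis
#'
#' For each annotation term, tests whether the selected gene set overlaps the
#' term more than expected by chance, with the hypergeometric upper tail
#' (equivalently one-sided Fisher): for overlap k, selection size n, term
#' size K and universe size N, `p = P(X >= k)`. Reports fold enrichment
#' `(k/n)/(K/N)`, a Bonferroni bound `min(1, p * m)` over the m tested terms,
#' and the rank-scaled Benjamini adjustment of [q_values()].
#'
#' @param selected Character vector of selected genes; must be a subset of
#'   `universe`.
#' @param annotation Named list of character vectors (term -> gene set),
#'   e.g. from [read_gmt()].
#' @param universe Character vector of all tested genes.
#' @return Data.frame (one row per term, sorted by p) with columns `term`,
#'   `overlap`, `term_size`, `p`, `fold_enrichment`, `bonferroni`,
#'   `benjamini`.
#' @examples
#' uni <- paste0("g", 1:20)
#' overrepresentation(uni[1:8], list(term = uni[1:5]), uni)
#' @export
overrepresentation <- function(selected, annotation, universe) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe))
    stop("'selected' must be a subset of 'universe'")
  stopifnot(is.list(annotation), length(annotation) > 0)
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(annotation), function(term) {
    genes <- intersect(unique(annotation[[term]]), universe)
    K <- length(genes)
    if (K == 0) {
      message("term '", term, "' has no genes in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(selected, genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (n > 0) (k / n) / (K / N) else NA_real_
    data.frame(term = term, overlap = k, term_size = K, p = p,
               fold_enrichment = fe, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    return(data.frame(term = character(0), overlap = integer(0),
                      term_size = integer(0), p = numeric(0),
                      fold_enrichment = numeric(0), bonferroni = numeric(0),
                      benjamini = numeric(0)))
  out$bonferroni <- pmin(1, out$p * nrow(out))
  out$benjamini <- q_values(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}
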