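#' Read a sparse matrix from Matrix Market or key-based TSV triples
#'
#' Dialect is auto-detected: files starting with `%%MatrixMarket` are read
#' with [Matrix::readMM()] (companion `<path>.rows` / `<path>.cols` index
#' files, one key per line, supply dimnames when present); anything else is
#' parsed as TSV triples `row_key <tab> col_key <tab> value` with a header.
#' For `kind = "similarity"` the matrix is validated to \[0, 1\], square on
#' the union of keys, and symmetrized (with a warning when asymmetric).
#'
#' @param path Input path.
#' @param kind `"interaction"` (rectangular, any nonnegative values) or
#'   `"similarity"`.
#' @return A `dgCMatrix`.
#' @export
read_sparse_triples <- function(path, kind = c("interaction", "similarity")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("^%%MatrixMarket", first)) {
    m <- methods::as(methods::as(Matrix::readMM(path), "generalMatrix"),
                     "CsparseMatrix")
    rfile <- paste0(path, ".rows"); cfile <- paste0(path, ".cols")
    if (file.exists(rfile)) rownames(m) <- readLines(rfile, warn = FALSE)
    if (file.exists(cfile)) colnames(m) <- readLines(cfile, warn = FALSE)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    if (ncol(df) < 3) stop("triple file needs 3 columns: row key, column key, value")
    if (!is.numeric(df[[3]]))
      stop("malformed value column in ", path)
    if (kind == "similarity") {
      keys <- sort(unique(c(df[[1]], df[[2]])))
      m <- Matrix::sparseMatrix(i = match(df[[1]], keys),
                                j = match(df[[2]], keys), x = df[[3]],
                                dims = c(length(keys), length(keys)),
                                dimnames = list(keys, keys))
    } else {
      rk <- sort(unique(df[[1]])); ck <- sort(unique(df[[2]]))
      m <- Matrix::sparseMatrix(i = match(df[[1]], rk),
                                j = match(df[[2]], ck), x = df[[3]],
                                dims = c(length(rk), length(ck)),
                                dimnames = list(rk, ck))
    }
  }
  if (kind == "similarity") {
    if (length(m@x) && (min(m@x) < 0 || max(m@x) > 1))
      stop("similarity values outside [0, 1] in ", path)
    if (!Matrix::isSymmetric(m, tol = 0)) {
      warning("asymmetric similarity matrix symmetrized as (S + t(S))/2")
      m <- (m + Matrix::t(m)) / 2
    }
  } else if (length(m@x) && min(m@x) < 0) {
    stop("negative interaction values in ", path)
  }
  m
}

#' Write a sparse matrix as Matrix Market plus index files, or TSV triples
#'
#' @param m Sparse matrix (with dimnames for key-based output).
#' @param path Output path. For `format = "mm"`, `<path>.rows` and
#'   `<path>.cols` receive one key per line (1-based coordinates in the MM
#'   body, per that format's convention).
#' @param format `"mm"` or `"tsv"`.
#' @param col_names Header names for TSV output.
#' @return `path`, invisibly.
#' @export
write_sparse_triples <- function(m, path, format = c("mm", "tsv"),
                                 col_names = c("row_key", "col_key", "value")) {
  format <- match.arg(format)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  if (format == "mm") {
    Matrix::writeMM(m, path)
    if (!is.null(rownames(m))) writeLines(rownames(m), paste0(path, ".rows"))
    if (!is.null(colnames(m))) writeLines(colnames(m), paste0(path, ".cols"))
  } else {
    tr_ <- Matrix::summary(m)
    rk <- rownames(m); ck <- colnames(m)
    df <- data.frame(a = if (is.null(rk)) tr_$i else rk[tr_$i],
                     b = if (is.null(ck)) tr_$j else ck[tr_$j],
                     value = tr_$x)
    names(df) <- col_names
    df <- df[order(df[[1]], df[[2]]), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write an analysis report as TSV or JSON
#'
#' Column order is preserved deterministically; numbers are written at full
#' precision (display rounding is left to the consumer).
#'
#' @param results Data.frame (or coercible).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path Input path.
#' @param format `"tsv"` or `"json"`; inferred from the extension by default.
#' @return Data.frame.
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
  }
}

#' Read a kinome assay panel CSV
#' @param path CSV with columns `kinase`, `pct_control_10uM`,
#'   `pct_control_100uM`.
#' @return Data.frame.
#' @export
read_kinome_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kinase", "pct_control_100uM")
  if (length(setdiff(need, names(df))))
    stop("kinome panel lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' The numeric defaults used across the toolkit
#'
#' All thresholds and hyperparameters with their default values, in one
#' place: activity cutoffs (IC50 <= 10 uM, Ki <= 5 uM, pKi >= 5, confidence
#' >= 9), the structure-screen filter (p < 2e-3, score < -7.5), the
#' evaluation protocol (percent control < 30 at 100 uM, top 2.5%),
#' sensitivity classification (>= 1.95 / <= 1.3), gene selection (q < 1e-3),
#' and the factorization defaults.
#'
#' @return Named list of defaults.
#' @export
toolkit_defaults <- function() {
  list(ic50_active_uM = 10, ki_active_uM = 5, pki_active = 5,
       min_confidence = 9,
       screen_p_cut = 2.0e-3, screen_score_cut = -7.5,
       imputed_value = 1.0, imputed_weight = 0.5, uniform_imputation = 0.1,
       truth_pct_control = 30.0, top_fraction = 0.025,
       aa_sensitive = 1.95, aa_resistant = 1.3, q_cut = 1.0e-3,
       rank = 100, alpha = 0.1, beta = 0.1, gamma = 0.1,
       w_obs = 1, w_imp = 0.5, w_zero = 0.01,
       max_iter = 500, tol = 1e-6)
}
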