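#' Convert a percent-inhibition measurement to an inhibition constant
#'
#' Single-point competition measurements reported as percent inhibition at a
#' fixed compound concentration are converted to an equivalent inhibition
#' constant via
#' \deqn{K_i = \mathrm{concentration} \times (100 - \%inh) / \%inh}
#' so that the standard Ki activity threshold can be applied to them.
#'
#' @param concentration Assay concentration in micromolar; must be positive.
#' @param percent_inhibition Percent inhibition observed, in (0, 100].
#' @return Ki in micromolar (numeric, vectorized).
#' @examples
#' ki_from_percent_inhibition(10, 50)      # 10 uM
#' ki_from_percent_inhibition(10, 66.667)  # ~5 uM
#' @export
ki_from_percent_inhibition <- function(concentration, percent_inhibition) {
  stopifnot(is.numeric(concentration), is.numeric(percent_inhibition))
  if (any(concentration <= 0))
    stop("'concentration' must be positive (uM)")
  if (any(percent_inhibition <= 0 | percent_inhibition > 100)) {
    if (any(percent_inhibition == 0))
      stop("percent inhibition of 0 gives an undefined (infinite) Ki")
    stop("'percent_inhibition' must lie in (0, 100]")
  }
  concentration * (100 - percent_inhibition) / percent_inhibition
}

#' Convert pKi to Ki
#'
#' @param pki Negative decadic logarithm of Ki expressed in molar units.
#' @param units Output units, `"molar"` (default, Ki = 10^-pKi) or `"uM"`.
#' @return Ki in the requested units.
#' @examples
#' ki_from_pki(6)               # 1e-6 M
#' ki_from_pki(5, units = "uM") # 10 uM
#' @export
ki_from_pki <- function(pki, units = c("molar", "uM")) {
  units <- match.arg(units)
  stopifnot(is.numeric(pki), all(is.finite(pki)))
  ki <- 10^(-pki)
  if (units == "uM") ki <- ki * 1e6
  ki
}

# The printed activity thresholds used throughout: IC50 <= 10 uM,
# Ki <= 5 uM (including Ki obtained from percent inhibition), pKi >= 5.
activity_thresholds <- function() {
  list(ic50_uM = 10, ki_uM = 5, pki = 5)
}

#' Validate a table of activity records
#'
#' Checks the schema and the per-record invariants of a standardized activity
#' table: columns `chemical_key`, `protein_key`, `measure`, `value`, and
#' optionally `concentration`, `source`, `confidence`. `measure` must be one
#' of `ic50`, `ki`, `pki`, `percent_inhibition`; values are in micromolar for
#' ic50/ki, unitless for pki, and percent for percent_inhibition, whose
#' records must (and alone may) carry an assay `concentration` in micromolar.
#'
#' @param records A data.frame of activity records.
#' @return The validated data.frame, invisibly usable downstream.
#' @export
validate_activity_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("chemical_key", "protein_key", "measure", "value")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("activity table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0L) return(records)
  ok_measures <- c("ic50", "ki", "pki", "percent_inhibition")
  bad <- setdiff(unique(records$measure), ok_measures)
  if (length(bad))
    stop("unknown measure(s): ", paste(bad, collapse = ", "))
  if (!"concentration" %in% names(records))
    records$concentration <- NA_real_
  is_pct <- records$measure == "percent_inhibition"
  if (any(is_pct & !is.finite(records$concentration)))
    stop("percent_inhibition records require a positive 'concentration' (uM)")
  if (any(!is_pct & is.finite(records$concentration)))
    stop("'concentration' is only meaningful for percent_inhibition records")
  if (any(records$measure != "pki" & records$value < 0))
    stop("negative activity value")
  if (any(is_pct & (records$value < 0 | records$value > 100)))
    stop("percent inhibition outside [0, 100]")
  records
}

#' Call each activity record active or inactive
#'
#' Applies the standardization rules used to build the one-class interaction
#' matrix: IC50 records are active at value <= 10 uM; Ki records (including
#' percent-inhibition records first converted through
#' [ki_from_percent_inhibition()]) at Ki <= 5 uM; pKi records at pKi >= 5.
#' All boundaries are inclusive, matching the printed inequalities.
#'
#' @param records Data.frame of activity records (see
#'   [validate_activity_records()] for the schema).
#' @return Logical vector, one call per record.
#' @examples
#' recs <- data.frame(
#'   chemical_key = "X", protein_key = "Y",
#'   measure = c("ic50", "ki", "pki"), value = c(10, 5.01, 5),
#'   concentration = NA_real_
#' )
#' is_active(recs)  # TRUE FALSE TRUE
#' @export
is_active <- function(records) {
  records <- validate_activity_records(records)
  if (nrow(records) == 0L) return(logical(0))
  th <- activity_thresholds()
  out <- logical(nrow(records))
  m <- records$measure
  out[m == "ic50"] <- records$value[m == "ic50"] <= th$ic50_uM
  out[m == "ki"] <- records$value[m == "ki"] <= th$ki_uM
  out[m == "pki"] <- records$value[m == "pki"] >= th$pki
  pct <- m == "percent_inhibition"
  if (any(pct)) {
    # %inh = 0 means no measurable inhibition: inactive, not an error, when
    # called in bulk (the scalar converter still refuses division by zero).
    v <- records$value[pct]
    ki <- rep(Inf, sum(pct))
    nz <- v > 0
    ki[nz] <- ki_from_percent_inhibition(records$concentration[pct][nz], v[nz])
    out[pct] <- ki <= th$ki_uM
  }
  out
}

#' Drop low-confidence activity records
#'
#' Records carrying a curation confidence score below the cutoff are excluded;
#' records without a confidence score (sources that do not provide one) are
#' retained. The default reproduces the ChEMBL rule of excluding assays with
#' confidence < 9.
#'
#' @param records Data.frame of activity records.
#' @param min_confidence Minimum confidence kept (default 9); exclusion is
#'   strict (`confidence < min_confidence` is removed).
#' @return The filtered data.frame.
#' @export
filter_by_confidence <- function(records, min_confidence = 9) {
  stopifnot(is.data.frame(records))
  if (!"confidence" %in% names(records) || nrow(records) == 0L) return(records)
  keep <- is.na(records$confidence) | records$confidence >= min_confidence
  records[keep, , drop = FALSE]
}

#' Assemble the sparse one-class interaction matrix R
#'
#' Builds the chemicals x proteins positive-association matrix from
#' standardized activity records. A pair enters the matrix iff at least one of
#' its records is called active (logical OR across sources); pairs observed
#' only as inactive are omitted, reflecting the one-class setting in which
#' absence of an entry means "unobserved", not "non-binding". Row and column
#' indices are the lexicographically sorted unique keys.
#'
#' @param records Data.frame of activity records; confidence filtering is
#'   applied first via [filter_by_confidence()].
#' @param valued If `TRUE`, store per-pair values in (0, 1] supplied in a
#'   `weight` column (duplicates take the maximum); default stores 1.
#' @param min_confidence Passed to [filter_by_confidence()].
#' @return A [Matrix::sparseMatrix()] (`dgCMatrix`) with chemical keys as
#'   rownames and protein keys as colnames.
#' @examples
#' recs <- data.frame(
#'   chemical_key = c("A", "A", "B"), protein_key = c("P1", "P1", "P2"),
#'   measure = "ic50", value = c(1, 2, 50), concentration = NA_real_
#' )
#' build_interaction_matrix(recs)  # one entry: A x P1
#' @export
build_interaction_matrix <- function(records, valued = FALSE, min_confidence = 9) {
  records <- filter_by_confidence(records, min_confidence)
  records <- validate_activity_records(records)
  active <- records[is_active(records), , drop = FALSE]
  if (nrow(active) == 0L) {
    warning("no active records; returning an empty interaction matrix")
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, 0L)))
  }
  chems <- sort(unique(active$chemical_key))
  prots <- sort(unique(active$protein_key))
  i <- match(active$chemical_key, chems)
  j <- match(active$protein_key, prots)
  x <- if (valued && "weight" %in% names(active)) active$weight else rep(1, nrow(active))
  if (any(x <= 0)) stop("stored interaction values must be > 0")
  # duplicate pairs: OR rule for binary, max for valued
  key <- paste(i, j)
  agg <- tapply(x, key, max)
  first <- !duplicated(key)
  m <- Matrix::sparseMatrix(i = i[first], j = j[first],
                            x = as.numeric(agg[key[first]]),
                            dims = c(length(chems), length(prots)),
                            dimnames = list(chems, prots))
  if (!valued) m@x[] <- 1
  m
}

#' Read activity records from a delimited text file
#'
#' @param path Path to a TSV/CSV file with header columns `chemical_key`,
#'   `protein_key`, `measure`, `value`, and optionally `concentration`,
#'   `source`, `confidence`.
#' @param sep Field separator; inferred from the extension by default.
#' @return Validated data.frame of activity records.
#' @export
read_activity_records <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  validate_activity_records(df)
}
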