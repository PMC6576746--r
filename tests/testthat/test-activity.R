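test_that("percent-inhibition and pKi conversions follow the standardization formulas", {
  expect_equal(ki_from_percent_inhibition(10, 50), 10)
  expect_equal(ki_from_percent_inhibition(7, 100), 0)
  expect_equal(ki_from_percent_inhibition(10, 66.667), 10 * 33.333 / 66.667,
               tolerance = 1e-12)
  expect_error(ki_from_percent_inhibition(10, 0), "undefined")
  expect_error(ki_from_percent_inhibition(10, 101), "\\(0, 100\\]")
  expect_error(ki_from_percent_inhibition(0, 50), "positive")

  expect_equal(ki_from_pki(5), 1e-5)
  expect_equal(ki_from_pki(5, units = "uM"), 10)
  expect_equal(ki_from_pki(6, units = "uM"), 1)
  expect_equal(ki_from_pki(0), 1)

  # round trip: pKi of a Ki recovers the Ki
  set.seed(1)
  ki <- 10^runif(50, -9, -3)
  expect_equal(ki_from_pki(-log10(ki)), ki, tolerance = 1e-12)
})

test_that("activity calls use the printed thresholds with inclusive boundaries", {
  rec <- function(measure, value, conc = NA_real_)
    data.frame(chemical_key = "X", protein_key = "Y", measure = measure,
               value = value, concentration = conc)
  expect_true(is_active(rec("ic50", 10)))
  expect_false(is_active(rec("ic50", 10.01)))
  expect_true(is_active(rec("ki", 5)))
  expect_false(is_active(rec("ki", 5.01)))
  expect_true(is_active(rec("pki", 5)))
  expect_false(is_active(rec("pki", 4.99)))
  expect_error(is_active(rec("ec50", 1)), "unknown measure")
})

test_that("percent-inhibition activity equals the Ki-converted 5 uM rule", {
  set.seed(42)
  conc <- 10^runif(100, -1, 2)
  pinh <- runif(100, 1, 100)
  recs <- data.frame(chemical_key = "X", protein_key = "Y",
                     measure = "percent_inhibition", value = pinh,
                     concentration = conc)
  ki_recs <- data.frame(chemical_key = "X", protein_key = "Y",
                        measure = "ki",
                        value = ki_from_percent_inhibition(conc, pinh),
                        concentration = NA_real_)
  expect_identical(is_active(recs), is_active(ki_recs))
})

test_that("confidence filter removes scored sub-threshold records only", {
  recs <- data.frame(chemical_key = "X", protein_key = "Y", measure = "ki",
                     value = 1, concentration = NA_real_,
                     confidence = c(9, 8, NA))
  kept <- filter_by_confidence(recs)
  expect_equal(kept$confidence, c(9, NA))
  # a table without the column passes through untouched
  expect_identical(filter_by_confidence(recs[, -6]), recs[, -6])
})

test_that("interaction matrix holds exactly the distinct active pairs", {
  recs <- data.frame(
    chemical_key = c("A", "A", "B", "B"),
    protein_key = c("P1", "P1", "P2", "P3"),
    measure = c("ic50", "ki", "pki", "ic50"),
    value = c(1, 2, 7, 50),  # first three active, last inactive
    concentration = NA_real_
  )
  R <- build_interaction_matrix(recs)
  expect_equal(length(R@x), 2L)
  expect_equal(sort(rownames(R)), c("A", "B"))
  expect_equal(unname(as.matrix(R)["A", "P1"]), 1)
  expect_equal(unname(as.matrix(R)["B", "P2"]), 1)

  # conflicting records: OR rule makes the pair active
  confl <- data.frame(chemical_key = "A", protein_key = "P1",
                      measure = "ic50", value = c(1, 100),
                      concentration = NA_real_)
  expect_equal(length(build_interaction_matrix(confl)@x), 1L)

  # idempotence under record duplication
  expect_identical(as.matrix(build_interaction_matrix(rbind(recs, recs))),
                   as.matrix(R))

  expect_warning(R0 <- build_interaction_matrix(recs[0, ]), "empty")
  expect_equal(dim(R0), c(0L, 0L))
})

test_that("entry count matches a brute-force active-pair enumeration", {
  set.seed(7)
  for (rep_ in 1:5) {
    n <- 60
    recs <- data.frame(
      chemical_key = sample(paste0("C", 1:8), n, replace = TRUE),
      protein_key = sample(paste0("P", 1:6), n, replace = TRUE),
      measure = sample(c("ic50", "ki", "pki"), n, replace = TRUE),
      value = 10^runif(n, -2, 2),
      concentration = NA_real_
    )
    active <- recs[is_active(recs), ]
    oracle <- unique(paste(active$chemical_key, active$protein_key))
    if (length(oracle) == 0) {
      expect_warning(build_interaction_matrix(recs))
    } else {
      expect_equal(length(build_interaction_matrix(recs)@x), length(oracle))
    }
  }
})

test_that("valued mode keeps the maximum weight per duplicated pair", {
  recs <- data.frame(chemical_key = "A", protein_key = "P",
                     measure = "ki", value = c(1, 1),
                     concentration = NA_real_, weight = c(0.3, 0.8))
  R <- build_interaction_matrix(recs, valued = TRUE)
  expect_equal(unname(R@x), 0.8)
})

test_that("activity records survive a file round trip", {
  recs <- data.frame(chemical_key = c("A", "B"), protein_key = c("P1", "P2"),
                     measure = c("ic50", "percent_inhibition"),
                     value = c(3, 40), concentration = c(NA, 10),
                     source = "unit", confidence = c(9L, NA))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write.table(recs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_activity_records(path)
  expect_equal(back$value, recs$value)
  expect_equal(back$measure, recs$measure)
})
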