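test_that("coverage profile matches the brute-force residue scan", {
  p <- tibble::tibble(start = c(1L, 4L), end = c(5L, 8L))
  prof <- coverage_profile(p, protein_length = 10)
  expect_equal(coverage_fraction(prof), 0.8)
  expect_equal(prof$redundancy[4], 2L)
  expect_false(any(prof$covered[9:10]))

  one <- coverage_profile(tibble::tibble(start = 1L, end = 10L), 10)
  expect_equal(coverage_fraction(one), 1.0)
  expect_equal(one$redundancy, rep(1L, 10))

  none <- coverage_profile(tibble::tibble(start = integer(0),
                                          end = integer(0)), 10)
  expect_equal(coverage_fraction(none), 0)
  expect_equal(none$redundancy, rep(0L, 10))
})

test_that("coverage/redundancy equals the oracle on random maps", {
  withr::local_seed(401)
  for (i in 1:200) {
    len <- sample(30:200, 1)
    pep <- unique(random_peptide_map(len, sample(1:40, 1)))
    prof <- coverage_profile(pep, len)
    oracle <- brute_force_profile(pep$start, pep$end, len)
    expect_identical(prof$covered, oracle$covered)
    expect_identical(prof$redundancy, oracle$redundancy)
    # conservation: total redundancy equals total peptide length
    expect_equal(sum(prof$redundancy), sum(pep$end - pep$start + 1L))
  }
})

test_that("coverage profile enforces bounds and single-protein input", {
  p <- tibble::tibble(protein = "P", start = 1L, end = 12L,
                      sequence = "AAAAAAAAAAAA")
  expect_error(coverage_profile(p, protein_length = 10), "1-12")
  expect_warning(prof <- coverage_profile(p), "max\\(end\\)")
  expect_equal(attr(prof, "protein_length"), 12L)
  two <- tibble::tibble(protein = c("P", "Q"), start = 1L, end = 5L)
  expect_error(coverage_profile(two, 10), "single protein")
})

test_that("relative fractional uptake scales by max uptake with guards", {
  expect_equal(rfu(2.0, 8.0), 0.25)
  expect_equal(rfu(0, 5), 0)
  expect_equal(rfu(0.5, 8.0), 0.0625)
  expect_warning(z <- rfu(c(1, 2), c(4, 0)), "max_uptake == 0")
  expect_equal(z, c(0.25, NA))
  expect_warning(rfu(10, 4), "outside")
})

test_that("projection combines overlapping significant peptides as specified", {
  mk <- function(starts, ends, deltas, labels, max_uptake = 8) {
    cls <- tibble::tibble(
      protein = "P", start = starts, end = ends,
      sequence = strrep("A", ends - starts + 1),
      modification = NA_character_, max_uptake = max_uptake,
      exposure = 5, delta = deltas, limit = 0.3,
      label = factor(labels,
                     levels = c("deprotected", "protected",
                                "nonsignificant"))
    )
    attr(cls, "mode") <- "per_timepoint"
    cls
  }
  one <- mk(4L, 8L, 0.5, "deprotected")
  prof <- project_differences(one, 10)
  expect_equal(prof$value[4:8], rep(0.5, 5))
  expect_true(all(is.na(prof$value[c(1:3, 9:10)])))

  two <- mk(c(2L, 6L), c(6L, 9L), c(0.4, 0.8), rep("deprotected", 2))
  mean_prof <- project_differences(two, 10)
  expect_equal(mean_prof$value[6], 0.6)
  expect_equal(mean_prof$value[3], 0.4)
  max_prof <- project_differences(two, 10, combine = "max_magnitude")
  expect_equal(max_prof$value[6], 0.8)

  # non-significant coverage renders as zero, not missing
  mix <- mk(c(1L, 6L), c(5L, 9L), c(0.5, 0.1),
            c("deprotected", "nonsignificant"))
  p <- project_differences(mix, 10)
  expect_equal(p$value[6:9], rep(0, 4))

  # delta_RFU payload divides by max uptake
  r <- project_differences(one, 10, payload = "delta_RFU")
  expect_equal(r$value[5], 0.5 / 8)
  expect_equal(attr(r, "value_kind"), "delta_RFU")
})

test_that("no uncovered residue ever carries a projected value", {
  withr::local_seed(402)
  for (i in 1:50) {
    len <- sample(30:100, 1)
    pep <- unique(random_peptide_map(len, sample(2:15, 1)))
    cls <- tibble::tibble(
      protein = "P", start = pep$start, end = pep$end,
      sequence = NA_character_, modification = NA_character_,
      max_uptake = 8, exposure = 5,
      delta = round(runif(nrow(pep), -1, 1), 2), limit = 0.4
    )
    cls$label <- factor(
      ifelse(cls$delta > 0.4, "deprotected",
             ifelse(cls$delta < -0.4, "protected", "nonsignificant")),
      levels = c("deprotected", "protected", "nonsignificant")
    )
    attr(cls, "mode") <- "per_timepoint"
    for (combine in c("mean", "max_magnitude")) {
      prof <- project_differences(cls, len, combine = combine)
      expect_true(all(is.na(prof$value[!prof$covered])))
      expect_false(anyNA(prof$value[prof$covered]))
    }
  }
})

test_that("state uptake projects to per-residue heat-map tracks", {
  st <- toy_states()
  prof <- uptake_profile(st, "WT", 5, protein_length = 12)
  expect_equal(prof$value[1], 1.5 / 4)
  expect_equal(prof$value[8], 3.0 / 6)
  abs_prof <- uptake_profile(st, "WT", 5, 12, metric = "absolute")
  expect_equal(abs_prof$value[1], 1.5)
  expect_error(uptake_profile(st, "APO", 5, 12), "APO")
})

test_that("residue profiles export as CSV", {
  prof <- coverage_profile(tibble::tibble(start = 1L, end = 5L), 8)
  path <- tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(out), 8)
  expect_named(out, c("residue", "covered", "redundancy", "value"))
  expect_equal(sum(out$covered), 5)
})
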