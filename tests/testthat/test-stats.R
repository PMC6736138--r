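test_that("two-tailed t critical values match the standard 98%/99% defaults", {
  expect_equal(round(critical_value(0.98, 2), 3), 6.965)
  expect_equal(round(critical_value(0.99, 2), 3), 9.925)
  # normal limit at large df
  expect_equal(critical_value(0.95, 1e6), 1.95996, tolerance = 1e-4)
  expect_error(critical_value(1.2, 2), "fraction")
  expect_error(critical_value(0.98, 0), "df")
})

test_that("timepoint dispersion is the across-peptide sample SD of deltas", {
  d <- tibble::tibble(
    protein = "P", start = c(1, 6), end = c(5, 12),
    sequence = c("AAAAA", "CCCCCCC"), modification = NA_character_,
    max_uptake = c(4, 6), exposure = 5,
    delta_uptake = c(0.5, -0.5), pooled_sd = c(0.1, 0.3)
  )
  disp <- timepoint_dispersion(d)
  expect_equal(disp$sigma, sqrt(((0.5 - 0)^2 + (-0.5 - 0)^2) / 1))
  expect_equal(disp$sigma, 0.7071068, tolerance = 1e-6)
  expect_equal(disp$sigma_sq, disp$sigma^2)
  expect_equal(disp$n_obs, 2L)

  equal <- d
  equal$delta_uptake <- 0.3
  expect_equal(timepoint_dispersion(equal)$sigma, 0)

  pooled <- timepoint_dispersion(d, method = "pooled")
  expect_equal(pooled$sigma, 0.2)

  expect_error(timepoint_dispersion(d[1, ]), "fewer than 2")
})

test_that("dispersion on a null dataset recovers the generator noise level", {
  spec <- synthetic_spec(
    protein_length = 2000, gap_regions = list(), effect_blocks = list(),
    noise_sd = 0.05, exposures = c(0.5, 5), seed = 11L
  )
  gen <- generate_dataset(spec)
  disp <- timepoint_dispersion(gen$differences)
  # delta of two replicate means: sd = noise_sd * sqrt(2/N)
  expected <- 0.05 * sqrt(2 / 3)
  expect_gt(nrow(gen$peptides), 500)
  expect_true(all(abs(disp$sigma - expected) / expected < 0.10))
})

test_that("confidence limits follow the hand formulas and their reductions", {
  expect_equal(per_timepoint_limit(0.10, 3, 6.965), 6.965 * 0.10 / sqrt(3))
  expect_equal(per_timepoint_limit(0, 3, 6.965), 0)
  expect_equal(per_timepoint_limit(0.20, 3, 6.965),
               2 * per_timepoint_limit(0.10, 3, 6.965))
  expect_equal(summed_limit(c(0.10, 0.10), 3, 6.965),
               6.965 * sqrt(0.02 / 3))
  expect_equal(summed_limit(c(0, 0), 3, 6.965), 0)
  # single-timepoint reduction is exact
  expect_identical(summed_limit(0.10, 3, 6.965),
                   per_timepoint_limit(0.10, 3, 6.965))
  disp <- tibble::tibble(exposure = 5, sigma = 0.1, sigma_sq = 0.01,
                         n_obs = 10L)
  expect_identical(summed_limit(disp, 3, 6.965),
                   per_timepoint_limit(disp, 3, 6.965))
  expect_error(summed_limit(numeric(0), 3, 6.965), "no dispersions")
  expect_error(summed_limit(rbind(disp, disp), 3, 6.965), "distinct")
  expect_error(per_timepoint_limit(0.1, 0, 6.965), "n_replicates")
})

test_that("classification labels follow sign and the conservative boundary", {
  d <- tibble::tibble(
    protein = "P", start = c(1, 6, 14), end = c(5, 12, 20),
    sequence = c("AAAAA", "CCCCCCC", "DDDDDDD"),
    modification = NA_character_, max_uptake = c(4, 6, 6),
    exposure = 5, delta_uptake = c(0.5, -0.5, 0.4),
    pooled_sd = NA_real_
  )
  filt <- confidence_filter(d, n_replicates = 3, alpha_override = 6.965)
  # pin the limit to exactly 0.40 to exercise the boundary rule
  filt$per_timepoint$limit <- 0.40
  cls <- classify(d, filt)
  expect_equal(as.character(cls$label[cls$start == 1]), "deprotected")
  expect_equal(as.character(cls$label[cls$start == 6]), "protected")
  expect_equal(as.character(cls$label[cls$start == 14]), "nonsignificant")
})

test_that("per-timepoint and summed classification partition the inputs", {
  gen <- generate_dataset(small_synth_spec())
  filt <- confidence_filter(gen$differences)
  per_tp <- classify(gen$differences, filt, "per_timepoint")
  n_records <- sum(gen$differences$exposure > 0)
  expect_equal(nrow(per_tp), n_records)
  expect_equal(sum(table(per_tp$label)), n_records)
  expect_false(anyNA(per_tp$label))

  summed <- classify(gen$differences, filt, "summed")
  expect_equal(nrow(summed), nrow(gen$peptides))
  expect_equal(summed$n_exposures, rep(4L, nrow(summed)))
  # summed delta equals the per-exposure sum
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(per_tp), start, end),
    s = sum(delta), .groups = "drop"
  )
  merged <- dplyr::inner_join(tibble::as_tibble(summed), agg,
                              by = c("start", "end"))
  expect_equal(merged$delta, merged$s)
})

test_that("raising the confidence level never adds significant peptides", {
  gen <- generate_dataset(small_synth_spec())
  n_sig <- function(level) {
    filt <- confidence_filter(gen$differences, confidence_level = level)
    sum(classify(gen$differences, filt)$label != "nonsignificant")
  }
  counts <- vapply(c(0.90, 0.95, 0.98, 0.99, 0.999), n_sig, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classification demands a limit for every exposure present", {
  gen <- generate_dataset(small_synth_spec())
  filt <- confidence_filter(gen$differences)
  filt$per_timepoint <- filt$per_timepoint[-1, ]
  expect_error(classify(gen$differences, filt), "no confidence limit")
})
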