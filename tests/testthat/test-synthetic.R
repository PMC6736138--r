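test_that("a null spec with zero noise yields all-zero differences", {
  spec <- synthetic_spec(protein_length = 100, gap_regions = list(),
                         effect_blocks = list(), noise_sd = 0, seed = 5L)
  gen <- generate_dataset(spec)
  expect_true(all(gen$differences$delta_uptake == 0))
  expect_true(all(gen$truth$per_timepoint$true_delta == 0))
  filt <- confidence_filter(gen$differences)
  cls <- classify(gen$differences, filt)
  expect_true(all(cls$label == "nonsignificant"))
})

test_that("noise-free uptake matches the closed-form kinetics oracle", {
  spec <- synthetic_spec(protein_length = 100, gap_regions = list(),
                         effect_blocks = list(
                           list(start = 30, end = 60, factor = 0.2)
                         ),
                         noise_sd = 0, seed = 9L)
  gen <- generate_dataset(spec)
  seq_chars <- strsplit(gen$sequence, "")[[1]]
  # pick a peptide fully inside the perturbed block
  inside <- gen$peptides$start >= 30 & gen$peptides$end <= 60
  expect_true(any(inside))
  p <- gen$peptides[which(inside)[1], ]
  for (t in spec$exposures) {
    for (s in names(gen$rates)) {
      got <- gen$states$uptake_mean[
        gen$states$state == s & gen$states$exposure == t &
          gen$states$start == p$start & gen$states$end == p$end
      ]
      expect_equal(got, oracle_uptake(seq_chars, gen$rates[[s]],
                                      p$start, p$end, t),
                   tolerance = 1e-10)
    }
    # the peptide's difference equals the analytic uptake shift
    d <- gen$differences$delta_uptake[
      gen$differences$exposure == t &
        gen$differences$start == p$start & gen$differences$end == p$end
    ]
    shift <- oracle_uptake(seq_chars, gen$rates[["MUT"]], p$start, p$end, t) -
      oracle_uptake(seq_chars, gen$rates[["WT"]], p$start, p$end, t)
    expect_equal(d, shift, tolerance = 1e-10)
    # protection (factor < 1) slows exchange in the altered state
    expect_lt(d, 0)
  }
})

test_that("uptake is non-decreasing in exposure and bounded by max uptake", {
  gen <- generate_dataset(synthetic_spec(
    protein_length = 150, gap_regions = list(),
    effect_blocks = list(list(start = 30, end = 60, factor = 0.3)),
    noise_sd = 0, seed = 13L
  ))
  by_pep <- split(gen$states, list(gen$states$state, gen$states$start,
                                   gen$states$end), drop = TRUE)
  for (g in by_pep) {
    g <- g[order(g$exposure), ]
    expect_true(all(diff(g$uptake_mean) >= -1e-12))
    expect_true(all(g$uptake_mean <= g$max_uptake + 1e-9))
  }
})

test_that("max uptake equals length minus one minus internal prolines", {
  gen <- generate_dataset(small_synth_spec())
  seq_chars <- strsplit(gen$sequence, "")[[1]]
  for (i in seq_len(nrow(gen$peptides))) {
    p <- gen$peptides[i, ]
    internal <- seq(p$start + 1L, p$end)
    expected <- (p$end - p$start + 1L) - 1L -
      sum(seq_chars[internal] == "P")
    expect_equal(p$max_uptake, expected)
    # and the stored sequence matches the protein sequence
    expect_equal(p$sequence,
                 paste(seq_chars[p$start:p$end], collapse = ""))
  }
})

test_that("generation is deterministic end-to-end for a fixed seed", {
  spec <- small_synth_spec()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(spec), d1)
  write_dataset(generate_dataset(spec), d2)
  for (f in c("state.csv", "difference.csv", "truth.csv", "spec.yaml")) {
    expect_identical(readBin(file.path(d1, f), "raw",
                             file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw",
                             file.size(file.path(d2, f))),
                     label = f)
  }
  # a different seed changes the data
  other <- generate_dataset(small_synth_spec(seed = 8L))
  expect_false(identical(other$sequence,
                         generate_dataset(spec)$sequence))
})

test_that("effect blocks outside the protein are rejected", {
  expect_error(
    synthetic_spec(protein_length = 50,
                   effect_blocks = list(list(start = 40, end = 60,
                                             factor = 2))),
    "outside protein"
  )
})

test_that("truth_report cross-tabulates observed against true labels", {
  gen <- generate_dataset(small_synth_spec(noise_sd = 0))
  filt <- confidence_filter(gen$differences)
  cls <- classify(gen$differences, filt)
  rep <- truth_report(gen, cls)
  expect_equal(rep$n, nrow(cls))
  # zero noise: observed deltas equal true deltas, so no off-diagonals
  expect_equal(rep$accuracy, 1)
  expect_equal(sum(rep$confusion) - sum(diag(rep$confusion)), 0)

  # corrupted labels land off the diagonal
  corrupted <- cls
  corrupted$label <- factor("deprotected",
                            levels = levels(cls$label))
  rep2 <- truth_report(gen, corrupted)
  expect_lt(rep2$accuracy, 1)
  expect_gt(sum(rep2$confusion) - sum(diag(rep2$confusion)), 0)

  # mismatched peptide sets are a hard error
  expect_error(truth_report(gen, cls[-1, ]), "do not match")
})

test_that("summed-mode truth agrees with the per-timepoint truth", {
  gen <- generate_dataset(small_synth_spec())
  agg <- tapply(gen$truth$per_timepoint$true_delta,
                paste(gen$truth$per_timepoint$start,
                      gen$truth$per_timepoint$end),
                sum)
  key <- paste(gen$truth$summed$start, gen$truth$summed$end)
  expect_equal(as.numeric(agg[key]), gen$truth$summed$true_delta)
})
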