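# Independent brute-force oracles used across tests. These stay naive on
# purpose: per-residue loops and hand formulas, no shared code with the
# implementation under test.

# per-residue scan: coverage and redundancy of a peptide map
brute_force_profile <- function(starts, ends, protein_length) {
  redundancy <- integer(protein_length)
  for (i in seq_along(starts)) {
    for (r in starts[i]:ends[i]) redundancy[r] <- redundancy[r] + 1L
  }
  list(covered = redundancy > 0L, redundancy = redundancy)
}

# hand formula for the per-timepoint band half-width
oracle_limit <- function(sigma, n, alpha) alpha * sigma / sqrt(n)

# hand formula for the summed band (variances add, scaled by replicates)
oracle_summed <- function(sigmas, n, alpha) alpha * sqrt(sum(sigmas^2) / n)

# naive uptake kinetics: loop over exchange-competent residues
oracle_uptake <- function(seq_chars, rates, start, end, t) {
  total <- 0
  for (i in seq(start + 1L, end)) {
    if (seq_chars[i] != "P") total <- total + (1 - exp(-rates[i] * t))
  }
  total
}

random_peptide_map <- function(protein_length, n_peptides) {
  starts <- sample.int(protein_length, n_peptides, replace = TRUE)
  lens <- sample.int(25, n_peptides, replace = TRUE)
  ends <- pmin(starts + lens - 1L, protein_length)
  tibble::tibble(start = starts, end = ends)
}

# small in-memory state table for io/stats unit tests
toy_states <- function() {
  tibble::tibble(
    protein = "P1",
    start = c(1L, 1L, 6L, 6L),
    end = c(5L, 5L, 12L, 12L),
    sequence = c("AAAAA", "AAAAA", "CCCCCCC", "CCCCCCC"),
    modification = NA_character_,
    max_uptake = c(4, 4, 6, 6),
    state = c("WT", "MUT", "WT", "MUT"),
    exposure = 5,
    uptake_mean = c(1.5, 2.0, 3.0, 2.4),
    uptake_sd = c(0.1, 0.1, 0.2, 0.1)
  )
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

small_synth_spec <- function(seed = 7L, ...) {
  synthetic_spec(
    protein_length = 120,
    gap_regions = list(c(55, 64)),
    effect_blocks = list(list(start = 20, end = 40, factor = 0.1),
                         list(start = 80, end = 100, factor = 8)),
    exposures = c(0.5, 5, 30, 240),
    seed = seed,
    ...
  )
}
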