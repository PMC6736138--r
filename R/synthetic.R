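#' Specification for a synthetic differential HDX-MS dataset
#'
#' Defines the study conditions emulated by [generate_dataset()]: a
#' protein with per-residue first-order exchange rates, a peptide map
#' tiling it with overlaps and deliberate gaps, saturating uptake
#' kinetics per timepoint, replicate noise of stated SD, and injected
#' protection/deprotection blocks with known ground truth. Defaults echo
#' a realistic membrane-transporter-sized experiment: ~490 residues,
#' coverage around 90% with deliberate gaps, maximum redundancy above 10,
#' four labelling times spanning three orders of magnitude, triplicate
#' measurement with 0.05 Da replicate noise.
#'
#' @param protein_length Residue count (default 490).
#' @param protein Protein label written to the CSVs.
#' @param exposures Labelling times in minutes (default
#'   `c(0.5, 5, 30, 240)`); exposure 0 rows are always included as the
#'   unlabelled control.
#' @param n_replicates Replicates per measurement N (default 3).
#' @param noise_sd Per-replicate measurement noise SD in Da (default
#'   0.05).
#' @param peptide_mean_length,peptide_length_sd,peptide_min_length,peptide_max_length
#'   Peptide length distribution (residues); lengths are drawn normal and
#'   clamped.
#' @param step_range Integer gaps between successive peptide start
#'   positions (sampled uniformly; smaller = denser map).
#' @param peptides_per_start Integers: how many peptides share each start
#'   position (sampled uniformly; larger = more redundancy).
#' @param gap_regions List of `c(start, end)` regions no peptide may
#'   touch, producing uncovered stretches.
#' @param effect_blocks List of `list(start, end, factor)` regions where
#'   the altered state's per-residue exchange rates are multiplied by
#'   `factor`: `factor < 1` protects (slower exchange), `> 1` deprotects.
#'   Because the perturbation acts on rates, the true uptake difference
#'   varies with exposure, exercising per-timepoint vs summed
#'   classification.
#' @param proline_frac Proline density of the generated sequence;
#'   prolines (and every peptide's first residue) carry no exchangeable
#'   amide, so they are excluded from uptake and from `MaxUptake`.
#' @param rate_meanlog,rate_sdlog Log-normal parameters of the
#'   per-residue exchange rates (1/min); defaults give curves that
#'   saturate across the default exposures.
#' @param states Labels `c(reference, altered)`.
#' @param state_order Sign convention of the difference file; default
#'   altered minus reference, so positive = deprotected.
#' @param seed Integer seed; generation is fully reproducible given the
#'   spec.
#'
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(protein_length = 490,
                           protein = "SYNPROT",
                           exposures = c(0.5, 5, 30, 240),
                           n_replicates = 3,
                           noise_sd = 0.05,
                           peptide_mean_length = 12,
                           peptide_length_sd = 3,
                           peptide_min_length = 6,
                           peptide_max_length = 20,
                           step_range = 1:4,
                           peptides_per_start = 1:3,
                           gap_regions = default_gap_regions(protein_length),
                           effect_blocks = default_effect_blocks(protein_length),
                           proline_frac = 0.05,
                           rate_meanlog = log(0.05),
                           rate_sdlog = 1.5,
                           states = c(reference = "WT", altered = "MUT"),
                           state_order = NULL,
                           seed = 42L) {
  if (is.null(state_order)) state_order <- c(states[[2]], states[[1]])
  for (b in effect_blocks) {
    if (b$start < 1 || b$end > protein_length || b$end < b$start) {
      stop("effect block outside protein: ", b$start, "-", b$end,
           call. = FALSE)
    }
    if (b$factor <= 0) stop("effect block factor must be > 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(exposures <= 0)) stop("exposures must be > 0", call. = FALSE)
  structure(
    list(
      protein_length = protein_length, protein = protein,
      exposures = sort(exposures), n_replicates = n_replicates,
      noise_sd = noise_sd,
      peptide_mean_length = peptide_mean_length,
      peptide_length_sd = peptide_length_sd,
      peptide_min_length = peptide_min_length,
      peptide_max_length = peptide_max_length,
      step_range = step_range, peptides_per_start = peptides_per_start,
      gap_regions = gap_regions, effect_blocks = effect_blocks,
      proline_frac = proline_frac,
      rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
      states = states, state_order = validate_state_order(state_order),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @rdname synthetic_spec
#' @details `default_gap_regions()` and `default_effect_blocks()` place
#'   the default uncovered stretches and rate-perturbation blocks at
#'   fixed fractions of the protein length (so any length yields a valid
#'   spec): gaps at the N terminus, mid-protein and three quarters in;
#'   one protection block (rate factor 0.25) in the N-terminal third and
#'   one deprotection block (factor 4) past the middle.
#' @export
default_gap_regions <- function(protein_length) {
  frac <- function(f) max(1L, round(f * protein_length))
  list(c(1, frac(0.02)),
       c(frac(0.465), frac(0.495)),
       c(frac(0.775), frac(0.815)))
}

#' @rdname synthetic_spec
#' @export
default_effect_blocks <- function(protein_length) {
  frac <- function(f) max(1L, round(f * protein_length))
  list(
    list(start = frac(0.12), end = frac(0.18), factor = 0.25),
    list(start = frac(0.61), end = frac(0.69), factor = 4)
  )
}

amino_acids_no_pro <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "Q", "R",
    "S", "T", "V", "W", "Y")
}

overlaps_any <- function(start, end, regions) {
  for (r in regions) if (start <= r[2] && end >= r[1]) return(TRUE)
  FALSE
}

#' Generate a ground-truthed synthetic differential HDX-MS dataset
#'
#' Simulates the full measurement chain. Per-residue exchange follows
#' first-order kinetics: a residue with rate `k` contributes
#' `1 - exp(-k t)` Da after `t` minutes in deuterated buffer. A peptide's
#' true uptake is the sum over its exchange-competent residues (all
#' residues except the first and prolines); `MaxUptake` is the count of
#' those residues. The altered state applies each effect block as a
#' multiplicative rate perturbation. Each reported mean/SD comes from
#' `n_replicates` noisy replicate measurements; the difference table is
#' the between-state difference of the replicate means, with the SDs
#' pooled as a sum of variances.
#'
#' @param spec A [synthetic_spec()].
#'
#' @return List of class `hdx_synth`: `spec`, `sequence`, `rates` (per
#'   state, per residue, 1/min), `peptides`, `states` (state-record
#'   tibble as from [parse_state_csv()]), `differences` (with
#'   `state_order` attribute), and `truth` — `per_timepoint` (true delta
#'   per peptide/exposure, noise-free) and `summed` (true summed delta
#'   per peptide).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_dataset_impl(spec))
}

generate_dataset_impl <- function(spec) {
  L <- spec$protein_length
  sequence <- sample(amino_acids_no_pro(), L, replace = TRUE)
  sequence[stats::runif(L) < spec$proline_frac] <- "P"
  non_pro <- as.numeric(sequence != "P")

  rates_ref <- stats::rlnorm(L, spec$rate_meanlog, spec$rate_sdlog)
  rates_alt <- rates_ref
  for (b in spec$effect_blocks) {
    rates_alt[b$start:b$end] <- rates_alt[b$start:b$end] * b$factor
  }

  peptides <- tile_peptides(spec, sequence)
  if (nrow(peptides) == 0L) stop("spec produced no peptides", call. = FALSE)

  # cumulative sums over exchange-competent residues give O(1) per-peptide
  # true uptake: sum_{i = start+1 .. end} non_pro[i] * (1 - exp(-k_i t))
  cum_np <- cumsum(non_pro)
  peptides$max_uptake <- cum_np[peptides$end] - cum_np[peptides$start]

  true_uptake <- function(rates, t) {
    u <- cumsum(non_pro * (1 - exp(-rates * t)))
    u[peptides$end] - u[peptides$start]
  }
  n_pep <- nrow(peptides)
  n_exp <- length(spec$exposures)
  tru <- list(
    ref = vapply(spec$exposures, function(t) true_uptake(rates_ref, t),
                 numeric(n_pep)),
    alt = vapply(spec$exposures, function(t) true_uptake(rates_alt, t),
                 numeric(n_pep))
  )

  measure <- function(true_mat) {
    n <- spec$n_replicates
    reps <- matrix(
      rep(as.vector(true_mat), each = n) +
        stats::rnorm(length(true_mat) * n, 0, spec$noise_sd),
      nrow = n
    )
    m <- colMeans(reps)
    dev <- sweep(reps, 2, m)
    s <- if (n > 1) sqrt(colSums(dev^2) / (n - 1)) else rep(0, ncol(reps))
    list(mean = matrix(m, n_pep, n_exp), sd = matrix(s, n_pep, n_exp))
  }
  meas <- list(ref = measure(tru$ref), alt = measure(tru$alt))

  state_tbl <- function(label, mm) {
    tp <- tibble::tibble(
      peptides[rep(seq_len(n_pep), n_exp), ],
      state = label,
      exposure = rep(spec$exposures, each = n_pep),
      uptake_mean = as.vector(mm$mean),
      uptake_sd = as.vector(mm$sd)
    )
    t0 <- tibble::tibble(peptides, state = label, exposure = 0,
                         uptake_mean = 0, uptake_sd = 0)
    dplyr::arrange(rbind(t0, tp), .data$start, .data$end, .data$exposure)
  }
  states <- rbind(state_tbl(spec$states[["reference"]], meas$ref),
                  state_tbl(spec$states[["altered"]], meas$alt))

  differences <- compute_differences(states, spec$state_order)

  sign_alt <- if (spec$state_order[1] == spec$states[["altered"]]) 1 else -1
  true_delta <- sign_alt * (tru$alt - tru$ref)
  truth_tp <- tibble::tibble(
    peptides[rep(seq_len(n_pep), n_exp), ],
    exposure = rep(spec$exposures, each = n_pep),
    true_delta = as.vector(true_delta)
  )
  truth_sum <- tibble::tibble(
    peptides,
    true_delta = rowSums(true_delta),
    n_exposures = n_exp
  )
  structure(
    list(
      spec = spec,
      sequence = paste(sequence, collapse = ""),
      rates = stats::setNames(
        list(rates_ref, rates_alt),
        c(spec$states[["reference"]], spec$states[["altered"]])
      ),
      peptides = peptides,
      states = states,
      differences = differences,
      truth = list(per_timepoint = truth_tp, summed = truth_sum)
    ),
    class = "hdx_synth"
  )
}

tile_peptides <- function(spec, sequence) {
  L <- spec$protein_length
  starts <- integer(0); ends <- integer(0)
  pos <- 1L
  while (pos <= L - spec$peptide_min_length + 1L) {
    n_here <- sample_one(spec$peptides_per_start)
    for (j in seq_len(n_here)) {
      len <- round(stats::rnorm(1, spec$peptide_mean_length,
                                spec$peptide_length_sd))
      len <- max(spec$peptide_min_length, min(spec$peptide_max_length, len))
      end <- min(pos + len - 1L, L)
      if (end - pos + 1L < spec$peptide_min_length) next
      if (overlaps_any(pos, end, spec$gap_regions)) next
      starts <- c(starts, pos); ends <- c(ends, as.integer(end))
    }
    pos <- pos + sample_one(spec$step_range)
  }
  pep <- unique(tibble::tibble(start = starts, end = ends))
  pep <- pep[order(pep$start, pep$end), , drop = FALSE]
  tibble::tibble(
    protein = spec$protein,
    start = pep$start,
    end = pep$end,
    sequence = substring(sequence_string(sequence), pep$start, pep$end),
    modification = NA_character_
  )
}

sequence_string <- function(x) if (length(x) > 1L) paste(x, collapse = "") else x

# sample() treats a length-1 integer vector as 1:n; avoid that trap
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' @export
print.hdx_synth <- function(x, ...) {
  cat("<hdx_synth>", nrow(x$peptides), "peptides on",
      x$spec$protein_length, "residues,",
      length(x$spec$exposures), "timepoints, noise_sd =",
      x$spec$noise_sd, "Da\n")
  invisible(x)
}

#' Write a synthetic dataset as a fixture directory
#'
#' Writes `state.csv` and `difference.csv` in the DynamX dialect (so they
#' round-trip through [parse_state_csv()] / [parse_difference_csv()]),
#' `truth.csv` with the noise-free per-peptide per-timepoint deltas, and
#' `spec.yaml` recording the generating parameters. Output is
#' byte-deterministic for a given spec.
#'
#' @param gen A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_dataset <- function(gen, dir) {
  stopifnot(inherits(gen, "hdx_synth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sd_dialect <- dynamx_state_dialect()
  st <- gen$states
  names(st) <- sd_dialect[names(st)]
  state_path <- file.path(dir, "state.csv")
  readr::write_csv(st, state_path, progress = FALSE, na = "")

  dd <- gen$differences
  dd_dialect <- dynamx_difference_dialect()
  df_out <- tibble::as_tibble(dd)
  names(df_out) <- dd_dialect[names(df_out)]
  diff_path <- file.path(dir, "difference.csv")
  readr::write_csv(df_out, diff_path, progress = FALSE, na = "")

  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(gen$truth$per_timepoint, truth_path, progress = FALSE,
                   na = "")

  spec_path <- file.path(dir, "spec.yaml")
  spec_list <- gen$spec
  class(spec_list) <- NULL
  spec_list$states <- as.list(spec_list$states)
  yaml::write_yaml(spec_list, spec_path)
  invisible(c(state = state_path, difference = diff_path,
              truth = truth_path, spec = spec_path))
}

#' Confusion counts of a classification against the generator truth
#'
#' Labels the noise-free true deltas with the same rule and limits the
#' observed classification used, then cross-tabulates truth against
#' observation. The peptide sets must match exactly.
#'
#' @param gen A [generate_dataset()] result.
#' @param classified A [classify()] result computed from `gen`'s
#'   differences (either mode).
#'
#' @return List: `confusion` (3x3 truth-by-observed table), `n`,
#'   `accuracy`, and `false_positive_rate` (truly null items labelled
#'   significant).
#' @export
truth_report <- function(gen, classified) {
  stopifnot(inherits(gen, "hdx_synth"))
  mode <- attr(classified, "mode")
  truth <- if (identical(mode, "summed")) {
    gen$truth$summed
  } else {
    gen$truth$per_timepoint
  }
  keys <- intersect(c(peptide_key_cols(), "exposure"), names(truth))
  obs <- tibble::as_tibble(classified)
  if (identical(mode, "summed")) obs$exposure <- NULL
  merged <- dplyr::inner_join(truth, obs, by = keys)
  if (nrow(merged) != nrow(truth) || nrow(merged) != nrow(obs)) {
    stop("peptide sets of truth and classification do not match (",
         nrow(truth), " truth vs ", nrow(obs), " observed, ",
         nrow(merged), " shared)", call. = FALSE)
  }
  lv <- c("deprotected", "protected", "nonsignificant")
  truth_label <- factor(
    ifelse(merged$true_delta > merged$limit, "deprotected",
           ifelse(merged$true_delta < -merged$limit, "protected",
                  "nonsignificant")),
    levels = lv
  )
  confusion <- table(truth = truth_label, observed = merged$label)
  null_items <- truth_label == "nonsignificant"
  list(
    confusion = confusion,
    n = nrow(merged),
    accuracy = sum(diag(confusion)) / nrow(merged),
    false_positive_rate = if (any(null_items)) {
      mean(merged$label[null_items] != "nonsignificant")
    } else {
      NA_real_
    }
  )
}
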