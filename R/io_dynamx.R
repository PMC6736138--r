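#' Default DynamX column dialects
#'
#' Column-name mappings from the internal field names used throughout
#' hdxdiff to the header names of a DynamX-style CSV export. Any entry can
#' be overridden to accommodate other instrument vendors, since the file
#' format is plain CSV and only the header names differ.
#'
#' @param ... Named character overrides, e.g. `uptake_mean = "Mean Uptake"`.
#'
#' @return Named character vector mapping internal names to CSV headers.
#' @examples
#' dynamx_state_dialect()
#' dynamx_state_dialect(uptake_sd = "SD")
#' @export
dynamx_state_dialect <- function(...) {
  dialect <- c(
    protein      = "Protein",
    start        = "Start",
    end          = "End",
    sequence     = "Sequence",
    modification = "Modification",
    max_uptake   = "MaxUptake",
    state        = "State",
    exposure     = "Exposure",
    uptake_mean  = "Uptake",
    uptake_sd    = "Uptake SD"
  )
  apply_dialect_overrides(dialect, list(...))
}

#' @rdname dynamx_state_dialect
#' @export
dynamx_difference_dialect <- function(...) {
  dialect <- c(
    protein      = "Protein",
    start        = "Start",
    end          = "End",
    sequence     = "Sequence",
    modification = "Modification",
    max_uptake   = "MaxUptake",
    exposure     = "Exposure",
    delta_uptake = "Uptake Difference",
    pooled_sd    = "Uptake SD"
  )
  apply_dialect_overrides(dialect, list(...))
}

apply_dialect_overrides <- function(dialect, overrides) {
  if (length(overrides) == 0L) return(dialect)
  if (is.null(names(overrides)) || any(names(overrides) == "")) {
    stop("dialect overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), names(dialect))
  if (length(unknown) > 0L) {
    stop("unknown dialect field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dialect[names(overrides)] <- unlist(overrides)
  dialect
}

# Columns that must resolve in the file; the rest are optional.
.state_required <- c("protein", "start", "end", "sequence", "max_uptake",
                     "state", "exposure", "uptake_mean", "uptake_sd")
.diff_required  <- c("protein", "start", "end", "sequence", "exposure",
                     "delta_uptake")

peptide_key_cols <- function() {
  c("protein", "start", "end", "sequence", "modification")
}

read_dialect_csv <- function(path, dialect, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE,
                         name_repair = "minimal")
  if (nrow(raw) == 0L) stop("empty file: ", path, call. = FALSE)
  missing <- setdiff(required, names(dialect))
  if (length(missing) > 0L) {
    stop("dialect does not define required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  absent <- required[!(dialect[required] %in% names(raw))]
  if (length(absent) > 0L) {
    stop("missing required column(s): ",
         paste(sprintf("%s (header '%s')", absent, dialect[absent]),
               collapse = ", "),
         " in ", path, call. = FALSE)
  }
  present <- names(dialect)[dialect %in% names(raw)]
  out <- tibble::as_tibble(stats::setNames(
    lapply(present, function(f) raw[[dialect[[f]]]]), present
  ))
  if (!("modification" %in% names(out))) out$modification <- NA_character_
  out
}

parse_numeric_fields <- function(x, fields) {
  for (f in fields) x[[f]] <- suppressWarnings(as.numeric(x[[f]]))
  x
}

drop_unparseable <- function(x, fields) {
  bad <- rep(FALSE, nrow(x))
  for (f in fields) bad <- bad | is.na(x[[f]])
  list(kept = x[!bad, , drop = FALSE], skipped = sum(bad))
}

check_peptide_invariants <- function(x) {
  if (any(x$start < 1)) warning("peptide start < 1 present", call. = FALSE)
  if (any(x$end < x$start)) {
    stop("peptide with end < start: ",
         format_peptide(x[which(x$end < x$start)[1L], ]), call. = FALSE)
  }
  has_seq <- !is.na(x$sequence) & nzchar(x$sequence)
  len_ok <- nchar(x$sequence[has_seq]) == (x$end - x$start + 1)[has_seq]
  if (any(!len_ok)) {
    warning(sum(!len_ok), " row(s) with sequence length != end - start + 1",
            call. = FALSE)
  }
  if ("max_uptake" %in% names(x)) {
    bad <- !is.na(x$max_uptake) &
      (x$max_uptake < 0 | x$max_uptake > nchar(x$sequence))
    if (any(bad)) {
      warning(sum(bad), " row(s) with max_uptake outside [0, peptide length]",
              call. = FALSE)
    }
  }
  invisible(x)
}

format_peptide <- function(row) {
  sprintf("%s %s-%s %s", row$protein, row$start, row$end, row$sequence)
}

#' Parse a DynamX-style state CSV
#'
#' The state file holds one row per protein/peptide/state/exposure with the
#' peptide bounds, sequence, maximum possible deuterium uptake, the mean
#' observed uptake across replicates and its standard deviation. Rows whose
#' required numeric fields do not parse are skipped and counted in the
#' parse report; duplicated (peptide, state, exposure) rows are a hard
#' error because silently aggregating them would corrupt the downstream
#' dispersion statistics.
#'
#' @param path CSV file path.
#' @param dialect Column-name mapping, see [dynamx_state_dialect()].
#'
#' @return A tibble of state records (columns `protein`, `start`, `end`,
#'   `sequence`, `modification`, `max_uptake`, `state`, `exposure`,
#'   `uptake_mean`, `uptake_sd`) with a `parse_report` attribute listing
#'   `rows_read`, `skipped` and `states`. Exposures are in minutes, uptake
#'   in Da. Retrieve the report with [parse_report()].
#' @export
parse_state_csv <- function(path, dialect = dynamx_state_dialect()) {
  x <- read_dialect_csv(path, dialect, .state_required)
  rows_read <- nrow(x)
  x <- parse_numeric_fields(
    x, c("start", "end", "max_uptake", "exposure", "uptake_mean", "uptake_sd")
  )
  parsed <- drop_unparseable(
    x, c("start", "end", "max_uptake", "exposure", "uptake_mean", "uptake_sd")
  )
  x <- parsed$kept
  if (nrow(x) == 0L) stop("no parseable data rows in ", path, call. = FALSE)
  check_peptide_invariants(x)
  if (any(x$uptake_mean < 0)) {
    warning(sum(x$uptake_mean < 0),
            " row(s) with negative uptake (tolerated as measurement noise)",
            call. = FALSE)
  }
  if (any(x$uptake_sd < 0)) stop("negative uptake SD present", call. = FALSE)
  key <- x[, c(peptide_key_cols(), "state", "exposure")]
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (peptide, state, exposure) row: ",
         format_peptide(x[which(dup)[1L], ]),
         " state=", x$state[which(dup)[1L]],
         " exposure=", x$exposure[which(dup)[1L]], call. = FALSE)
  }
  x <- x[, c(peptide_key_cols(), "max_uptake", "state", "exposure",
             "uptake_mean", "uptake_sd")]
  attr(x, "parse_report") <- list(
    rows_read = rows_read,
    skipped = parsed$skipped,
    states = sort(unique(x$state))
  )
  x
}

#' Parse a DynamX-style difference CSV
#'
#' The difference file carries one row per peptide/exposure with the signed
#' deuterium-uptake difference between two states. The sign convention
#' (which state is subtracted from which) is not recorded in the file, so
#' it must be supplied via `state_order` and is attached to the result;
#' every downstream output echoes it.
#'
#' Exposure-0 rows (the unlabelled control) are retained on parse but are
#' excluded from timepoint statistics by [hdx_dataset()] and the stats
#' functions.
#'
#' @param path CSV file path.
#' @param dialect Column-name mapping, see [dynamx_difference_dialect()].
#' @param state_order Character pair `c(A, B)` declaring that
#'   `delta_uptake = uptake(A) - uptake(B)`; stored as an attribute.
#'
#' @return Tibble of difference records (`protein`, `start`, `end`,
#'   `sequence`, `modification`, `max_uptake`, `exposure`, `delta_uptake`,
#'   `pooled_sd`) with `parse_report` and `state_order` attributes.
#' @export
parse_difference_csv <- function(path,
                                 dialect = dynamx_difference_dialect(),
                                 state_order = NULL) {
  # A state-style file (single-state uptake column, no difference column)
  # cannot express a two-state comparison: detect and refuse early.
  probe <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           n_max = 1, progress = FALSE,
                           name_repair = "minimal")
  if (!(dialect[["delta_uptake"]] %in% names(probe)) &&
      any(c("Uptake", "State") %in% names(probe))) {
    stop("difference file requires a two-state comparison: found ",
         "single-state columns but no '", dialect[["delta_uptake"]],
         "' column in ", path, call. = FALSE)
  }
  x <- read_dialect_csv(path, dialect, .diff_required)
  rows_read <- nrow(x)
  numf <- intersect(c("start", "end", "max_uptake", "exposure",
                      "delta_uptake", "pooled_sd"), names(x))
  x <- parse_numeric_fields(x, numf)
  parsed <- drop_unparseable(x, c("start", "end", "exposure", "delta_uptake"))
  x <- parsed$kept
  if (nrow(x) == 0L) stop("no parseable data rows in ", path, call. = FALSE)
  check_peptide_invariants(x)
  key <- x[, c(peptide_key_cols(), "exposure")]
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (peptide, exposure) row: ",
         format_peptide(x[which(dup)[1L], ]),
         " exposure=", x$exposure[which(dup)[1L]], call. = FALSE)
  }
  if (!("max_uptake" %in% names(x))) x$max_uptake <- NA_real_
  if (!("pooled_sd" %in% names(x))) x$pooled_sd <- NA_real_
  x <- x[, c(peptide_key_cols(), "max_uptake", "exposure", "delta_uptake",
             "pooled_sd")]
  attr(x, "parse_report") <- list(rows_read = rows_read,
                                  skipped = parsed$skipped)
  attr(x, "state_order") <- validate_state_order(state_order, required = FALSE)
  x
}

validate_state_order <- function(state_order, required = TRUE) {
  if (is.null(state_order)) {
    if (required) stop("state_order must be supplied", call. = FALSE)
    return(NULL)
  }
  if (length(state_order) != 2L || anyNA(state_order) ||
      state_order[1] == state_order[2]) {
    stop("state_order must be two distinct state labels", call. = FALSE)
  }
  as.character(state_order)
}

#' Retrieve the parse report of a parsed CSV
#'
#' @param x Result of [parse_state_csv()] or [parse_difference_csv()].
#' @return List with `rows_read`, `skipped` and (state files) `states`.
#' @export
parse_report <- function(x) attr(x, "parse_report")

#' Compute per-peptide uptake differences between two states
#'
#' Forms `delta_uptake = uptake_mean(A) - uptake_mean(B)` for every
#' (peptide, exposure) present in both states of `state_order = c(A, B)`,
#' with `pooled_sd = sqrt(sd_A^2 + sd_B^2)` (errors propagated as a simple
#' sum of variances). This lets the pipeline run from a state file alone,
#' and cross-checks a vendor-supplied difference file. Peptide/exposure
#' combinations present in only one state are reported in the `unmatched`
#' attribute, never silently dropped.
#'
#' @param states Tibble from [parse_state_csv()].
#' @param state_order Character pair `c(A, B)`; the result's sign is A - B,
#'   so swapping the pair negates every difference.
#'
#' @return Difference tibble as in [parse_difference_csv()], with
#'   `state_order` and `unmatched` attributes.
#' @examples
#' st <- tibble::tibble(
#'   protein = "P", start = 1, end = 5, sequence = "AAAAA",
#'   modification = NA_character_, max_uptake = 4,
#'   state = c("WT", "MUT"), exposure = 5,
#'   uptake_mean = c(1.5, 2.0), uptake_sd = c(0.1, 0.1)
#' )
#' d <- compute_differences(st, c("MUT", "WT"))
#' d$delta_uptake  # 0.5
#' @export
compute_differences <- function(states, state_order) {
  state_order <- validate_state_order(state_order)
  missing_states <- setdiff(state_order, unique(states$state))
  if (length(missing_states) > 0L) {
    stop("state label(s) not present in data: ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  }
  keys <- c(peptide_key_cols(), "max_uptake", "exposure")
  a <- states[states$state == state_order[1],
              c(keys, "uptake_mean", "uptake_sd")]
  b <- states[states$state == state_order[2],
              c(keys, "uptake_mean", "uptake_sd")]
  merged <- dplyr::full_join(a, b, by = keys, suffix = c("_a", "_b"))
  matched <- !is.na(merged$uptake_mean_a) & !is.na(merged$uptake_mean_b)
  out <- merged[matched, , drop = FALSE]
  out$delta_uptake <- out$uptake_mean_a - out$uptake_mean_b
  out$pooled_sd <- sqrt(out$uptake_sd_a^2 + out$uptake_sd_b^2)
  out <- out[, c(peptide_key_cols(), "max_uptake", "exposure",
                 "delta_uptake", "pooled_sd")]
  out <- dplyr::arrange(out, .data$protein, .data$start, .data$end,
                        .data$exposure)
  unmatched <- merged[!matched, keys, drop = FALSE]
  if (nrow(unmatched) > 0L) {
    message(nrow(unmatched),
            " peptide/exposure combination(s) present in only one state; ",
            "see attr(x, 'unmatched')")
  }
  attr(out, "state_order") <- state_order
  attr(out, "unmatched") <- unmatched
  out
}

#' Assemble a differential HDX dataset
#'
#' Bundles state records, difference records and the sign convention into
#' one object. When no difference table is supplied it is computed from the
#' state records. Difference peptides absent from either state of
#' `state_order` are flagged in the `flagged` field.
#'
#' @param states Tibble from [parse_state_csv()] (optional when
#'   `differences` is supplied).
#' @param differences Tibble from [parse_difference_csv()] or
#'   [compute_differences()]; computed from `states` when `NULL`.
#' @param state_order Character pair `c(A, B)`: `delta = A - B`.
#'
#' @return An object of class `hdx_dataset`: a list with `states`,
#'   `differences`, `state_order`, `timepoints` (sorted distinct exposures
#'   excluding 0) and `flagged`.
#' @export
hdx_dataset <- function(states = NULL, differences = NULL, state_order) {
  state_order <- validate_state_order(state_order)
  if (is.null(differences)) {
    if (is.null(states)) {
      stop("need states and/or differences", call. = FALSE)
    }
    differences <- compute_differences(states, state_order)
    differences_source <- "computed"
  } else {
    differences_source <- "file"
    attr(differences, "state_order") <- state_order
  }
  flagged <- tibble::tibble()
  if (!is.null(states)) {
    for (s in state_order) {
      if (!(s %in% states$state)) {
        stop("state label not present in state data: ", s, call. = FALSE)
      }
    }
    have <- unique(states[states$state %in% state_order, peptide_key_cols()])
    flagged <- dplyr::anti_join(
      unique(differences[, peptide_key_cols()]), have,
      by = peptide_key_cols()
    )
    if (nrow(flagged) > 0L) {
      warning(nrow(flagged),
              " difference peptide(s) absent from the state data",
              call. = FALSE)
    }
  }
  structure(
    list(
      states = states,
      differences = differences,
      state_order = state_order,
      timepoints = sort(unique(differences$exposure[differences$exposure > 0])),
      flagged = flagged,
      differences_source = differences_source
    ),
    class = "hdx_dataset"
  )
}

#' @export
print.hdx_dataset <- function(x, ...) {
  cat("<hdx_dataset>\n")
  cat("  comparison:", x$state_order[1], "-", x$state_order[2], "\n")
  cat("  peptides:  ",
      nrow(unique(x$differences[, peptide_key_cols()])), "\n")
  cat("  timepoints:", paste(x$timepoints, collapse = ", "), "min\n")
  invisible(x)
}

#' Write the significant-peptide CSV
#'
#' Exports the per-peptide per-timepoint breakdown of significant
#' differences (deprotected or protected only) in a fixed column order.
#' Floats are serialized with 6 significant digits.
#'
#' @param path Output CSV path.
#' @param classified A [build_woods()] result or a [classify()] tibble.
#'
#' @return Number of data rows written (invisibly 0 when nothing is
#'   significant; a header-only file is still written).
#' @export
write_significant_csv <- function(path, classified) {
  if (inherits(classified, "woods_dataset")) classified <- classified$segments
  sig <- classified[classified$label != "nonsignificant", , drop = FALSE]
  exposure_chr <- if (nrow(sig) > 0 && anyNA(sig$exposure)) {
    ifelse(is.na(sig$exposure), "sum", format(sig$exposure))
  } else {
    format(sig$exposure)
  }
  out <- tibble::tibble(
    protein = sig$protein,
    start = sig$start,
    end = sig$end,
    sequence = sig$sequence,
    exposure = if (nrow(sig)) exposure_chr else character(0),
    delta_uptake = signif(sig$delta, 6),
    classification = as.character(sig$label)
  )
  readr::write_csv(out, path, progress = FALSE)
  nrow(out)
}
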