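#' Per-residue coverage and redundancy profile
#'
#' Flattens a peptide map to per-residue tracks: `covered` (spanned by at
#' least one peptide, inclusive 1-based bounds) and `redundancy` (number
#' of distinct peptides spanning the residue). Peptides are deduplicated
#' on (protein, start, end, sequence, modification) — DynamX state exports
#' already merge charge states.
#'
#' @param peptides Tibble with at least `start` and `end` columns (any
#'   table carrying peptide bounds works: state records, differences,
#'   classifications). Must describe a single protein.
#' @param protein_length Residue count; defaults to `max(end)` with a
#'   warning, since the true construct length is usually known from the
#'   structure.
#'
#' @return Object of class `residue_profile`: tibble with `residue`,
#'   `covered`, `redundancy`, `value` (NA here) and attributes
#'   `protein_length`, `value_kind` (`"none"`).
#' @examples
#' p <- tibble::tibble(start = c(1, 4), end = c(5, 8))
#' prof <- coverage_profile(p, protein_length = 10)
#' coverage_fraction(prof)  # 0.8
#' @export
coverage_profile <- function(peptides, protein_length = NULL) {
  pep <- unique_peptides(peptides)
  if (nrow(pep) == 0L) {
    if (is.null(protein_length)) {
      stop("no peptides and no protein_length supplied", call. = FALSE)
    }
    redundancy <- integer(protein_length)
  } else {
    if (is.null(protein_length)) {
      protein_length <- max(pep$end)
      warning("protein_length not supplied; defaulting to max(end) = ",
              protein_length, call. = FALSE)
    }
    over <- pep$end > protein_length
    if (any(over)) {
      stop("peptide extends past protein_length (", protein_length, "): ",
           format_peptide_bounds(pep[which(over)[1L], ]), call. = FALSE)
    }
    redundancy <- as.integer(IRanges::coverage(
      IRanges::IRanges(start = pep$start, end = pep$end),
      width = protein_length
    ))
  }
  new_residue_profile(
    tibble::tibble(
      residue = seq_len(protein_length),
      covered = redundancy > 0L,
      redundancy = redundancy,
      value = NA_real_
    ),
    protein_length = protein_length,
    value_kind = "none"
  )
}

unique_peptides <- function(peptides) {
  cols <- intersect(peptide_key_cols(), names(peptides))
  if (!all(c("start", "end") %in% names(peptides))) {
    stop("peptides must have start and end columns", call. = FALSE)
  }
  if ("protein" %in% names(peptides) &&
      length(unique(peptides$protein)) > 1L) {
    stop("profile is per protein; filter to a single protein first",
         call. = FALSE)
  }
  if (length(cols) == 0L) cols <- c("start", "end")
  unique(peptides[, union(cols, c("start", "end")), drop = FALSE])
}

format_peptide_bounds <- function(row) {
  if ("sequence" %in% names(row) && !is.na(row$sequence)) {
    sprintf("%d-%d %s", row$start, row$end, row$sequence)
  } else {
    sprintf("%d-%d", row$start, row$end)
  }
}

new_residue_profile <- function(df, protein_length, value_kind) {
  structure(df,
            class = c("residue_profile", class(df)),
            protein_length = protein_length,
            value_kind = value_kind)
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> %d residues, %.1f%% covered, kind = %s\n",
              attr(x, "protein_length"), 100 * coverage_fraction(x),
              attr(x, "value_kind")))
  NextMethod()
}

#' @rdname coverage_profile
#' @param profile A `residue_profile`.
#' @export
coverage_fraction <- function(profile) {
  sum(profile$covered) / attr(profile, "protein_length")
}

#' Relative fractional uptake
#'
#' Scales absolute uptake (Da) by the peptide's maximum possible uptake,
#' expressing exchange as a fraction of the theoretical maximum. Applied
#' to a between-state difference this yields the differential RFU. Values
#' are not clamped: back-exchange and noise can push RFU slightly outside
#' \[0, 1\], so only values outside \[0, 1.2\] (or below -1.2 for
#' differences) trigger a warning. Peptides with `max_uptake == 0` cannot
#' be scaled; they yield NA with a warning and the rest proceed.
#'
#' @param uptake_mean Uptake (or uptake difference) in Da; vectorized.
#' @param max_uptake Maximum exchangeable deuterons per peptide.
#'
#' @return Fractional uptake, same length as `uptake_mean`.
#' @examples
#' rfu(2.0, 8.0)  # 0.25
#' @export
rfu <- function(uptake_mean, max_uptake) {
  if (length(max_uptake) == 1L) {
    max_uptake <- rep(max_uptake, length(uptake_mean))
  }
  stopifnot(length(max_uptake) == length(uptake_mean))
  zero <- !is.na(max_uptake) & max_uptake == 0
  if (any(zero)) {
    warning(sum(zero), " peptide(s) with max_uptake == 0 cannot be scaled ",
            "to fractional uptake (set to NA)", call. = FALSE)
    max_uptake[zero] <- NA_real_
  }
  if (any(!is.na(max_uptake) & max_uptake < 0)) {
    stop("max_uptake must be >= 0", call. = FALSE)
  }
  out <- uptake_mean / max_uptake
  oob <- !is.na(out) & (out > 1.2 | out < -1.2)
  if (any(oob)) {
    warning(sum(oob), " fractional uptake value(s) outside [-1.2, 1.2]",
            call. = FALSE)
  }
  out
}

#' Project classified uptake differences onto residues
#'
#' Builds the per-residue track used for structure coloring: each residue
#' covered by at least one significant peptide carries the combined
#' payload of those peptides; residues covered only by non-significant
#' peptides carry 0 (rendered white); uncovered residues stay NA
#' (rendered grey).
#'
#' @param classified A [classify()] tibble restricted to one exposure (or
#'   summed mode); supplying several exposures is an error because a
#'   single structure projection shows a single comparison.
#' @param protein_length Residue count (default: from `peptides`' max end
#'   with a warning, via [coverage_profile()]).
#' @param payload `"absolute_dDa"` (delta in Da) or `"delta_RFU"` (delta
#'   scaled by the peptide's max uptake).
#' @param combine How overlapping significant peptides resolve on a
#'   residue: `"mean"` (default; smooth and robust) or `"max_magnitude"`
#'   (the single payload with the largest absolute value; ties resolve to
#'   the earliest-starting peptide).
#'
#' @return A `residue_profile` with `value_kind` set to the payload.
#' @export
project_differences <- function(classified, protein_length = NULL,
                                payload = c("absolute_dDa", "delta_RFU"),
                                combine = c("mean", "max_magnitude")) {
  payload <- match.arg(payload)
  combine <- match.arg(combine)
  if (length(unique(classified$exposure[!is.na(classified$exposure)])) > 1L) {
    stop("classification spans several exposures; filter to one exposure ",
         "or use summed mode", call. = FALSE)
  }
  profile <- coverage_profile(classified, protein_length)
  protein_length <- attr(profile, "protein_length")
  payload_value <- if (payload == "absolute_dDa") {
    classified$delta
  } else {
    rfu(classified$delta, classified$max_uptake)
  }
  sig <- classified$label != "nonsignificant" & !is.na(payload_value)
  value <- rep(NA_real_, protein_length)
  value[profile$covered] <- 0
  sig_idx <- which(sig)
  if (length(sig_idx) > 0L) {
    # stable order: magnitude desc, then start asc, so max_magnitude ties
    # resolve deterministically to the earliest-starting peptide
    sig_idx <- sig_idx[order(-abs(payload_value[sig_idx]),
                             classified$start[sig_idx])]
    if (combine == "mean") {
      acc <- numeric(protein_length)
      cnt <- integer(protein_length)
      for (i in sig_idx) {
        span <- classified$start[i]:classified$end[i]
        acc[span] <- acc[span] + payload_value[i]
        cnt[span] <- cnt[span] + 1L
      }
      hit <- cnt > 0L
      value[hit] <- acc[hit] / cnt[hit]
    } else {
      assigned <- logical(protein_length)
      for (i in sig_idx) {
        span <- classified$start[i]:classified$end[i]
        take <- span[!assigned[span]]
        value[take] <- payload_value[i]
        assigned[take] <- TRUE
      }
    }
  }
  profile$value <- value
  attr(profile, "value_kind") <- payload
  profile
}

#' Per-residue uptake heat-map track
#'
#' Projects state-level uptake at one exposure onto residues, either as
#' absolute uptake (Da) or as relative fractional uptake, averaging
#' overlapping peptides.
#'
#' @param states State tibble from [parse_state_csv()].
#' @param state State label to project.
#' @param exposure Labelling time (minutes) to project.
#' @param protein_length Residue count (default from peptide bounds).
#' @param metric `"RFU"` (default) or `"absolute"` uptake in Da.
#'
#' @return A `residue_profile` with `value_kind` `"RFU"` or
#'   `"absolute_dDa"`.
#' @export
uptake_profile <- function(states, state, exposure, protein_length = NULL,
                           metric = c("RFU", "absolute")) {
  metric <- match.arg(metric)
  d <- states[states$state == state & states$exposure == exposure, ,
              drop = FALSE]
  if (nrow(d) == 0L) {
    stop("no state records for state '", state, "' at exposure ", exposure,
         call. = FALSE)
  }
  profile <- coverage_profile(d, protein_length)
  protein_length <- attr(profile, "protein_length")
  v <- if (metric == "RFU") rfu(d$uptake_mean, d$max_uptake) else d$uptake_mean
  acc <- numeric(protein_length)
  cnt <- integer(protein_length)
  for (i in seq_len(nrow(d))) {
    if (is.na(v[i])) next
    span <- d$start[i]:d$end[i]
    acc[span] <- acc[span] + v[i]
    cnt[span] <- cnt[span] + 1L
  }
  value <- rep(NA_real_, protein_length)
  value[cnt > 0L] <- acc[cnt > 0L] / cnt[cnt > 0L]
  profile$value <- value
  attr(profile, "value_kind") <- if (metric == "RFU") "RFU" else "absolute_dDa"
  profile
}

#' Export a residue profile as CSV
#'
#' Writes the per-residue tracks (`residue`, `covered`, `redundancy`,
#' `value`) for downstream use.
#'
#' @param profile A `residue_profile`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  out <- tibble::tibble(
    residue = profile$residue,
    covered = profile$covered,
    redundancy = profile$redundancy,
    value = signif(profile$value, 6)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
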