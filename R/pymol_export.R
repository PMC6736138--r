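#' Default color palette for structure projection
#'
#' Pole colors for the linear white-to-pole RGB ramps used by
#' [emit_pymol()]: red for deprotection, blue for protection, magenta for
#' redundancy, a solid blue for coverage and grey for uncovered residues.
#'
#' @param ... Named hex-color overrides (e.g. `deprotected = "#CC0000"`).
#' @return Named character vector of hex colors.
#' @export
pymol_palette <- function(...) {
  pal <- c(
    deprotected = "#FF0000",
    protected   = "#0000FF",
    redundancy  = "#FF00FF",
    coverage    = "#2171B5",
    uncovered   = "#999999",
    zero        = "#FFFFFF"
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), names(pal))
    if (length(unknown) > 0L) {
      stop("unknown palette entries: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    pal[names(overrides)] <- unlist(overrides)
  }
  pal
}

# Linear interpolation in RGB between white and a pole color.
# frac = 0 -> white, frac = 1 -> pole.
ramp_hex <- function(frac, pole) {
  stopifnot(all(frac >= 0 & frac <= 1))
  pole_rgb <- grDevices::col2rgb(pole)[, 1]
  ch <- function(p) as.integer(round(255 + frac * (p - 255)))
  sprintf("#%02X%02X%02X", ch(pole_rgb[1]), ch(pole_rgb[2]), ch(pole_rgb[3]))
}

hex_to_pymol <- function(hex) sub("^#", "0x", toupper(hex))

#' Build a PyMOL coloring script from a residue profile
#'
#' Produces the command list for a `.pml` script that paints a loaded
#' structure residue by residue. The script first base-coats the whole
#' chain in the uncovered color (grey), then overrides covered residues
#' with run-length-merged `color 0xRRGGBB, chain C and resi i-j`
#' commands, so later commands win and every residue ends with exactly
#' one effective color.
#'
#' Color semantics by mode: `coverage` — covered residues in one solid
#' color; `redundancy` — white-to-magenta ramp scaled by
#' redundancy / max redundancy; `absolute_dDa` / `delta_RFU` —
#' deprotected (positive) residues on a white-to-red ramp and protected
#' (negative) on white-to-blue, each scaled by |value| / max |value|,
#' zero-valued covered residues white, uncovered grey.
#'
#' @param profile A `residue_profile`; for difference modes its
#'   `value_kind` must match `mode`.
#' @param mode One of `"coverage"`, `"redundancy"`, `"absolute_dDa"`,
#'   `"delta_RFU"`.
#' @param chain Structure chain identifier (default `"A"`).
#' @param palette Pole colors, see [pymol_palette()].
#' @param resi_offset Integer added to every residue number in the
#'   emitted selections, for constructs whose sequence numbering is
#'   shifted relative to the deposited structure (default 0).
#' @param state_order Optional comparison label echoed in the header.
#' @param filter Optional [confidence_filter()] whose settings are echoed
#'   in the header.
#' @param pdb_id Optional PDB identifier recorded in the header comment
#'   (no structure file is read or written).
#' @param include_date Include a generation date comment; off by default
#'   so identical inputs give byte-identical scripts.
#'
#' @return Object of class `pymol_script`: list with `header` (comment
#'   lines), `base_color`, `commands` (tibble `start`, `end`, `color`),
#'   `mode`, `chain`, `resi_offset`.
#' @export
emit_pymol <- function(profile,
                       mode = c("coverage", "redundancy", "absolute_dDa",
                                "delta_RFU"),
                       chain = "A", palette = pymol_palette(),
                       resi_offset = 0L, state_order = NULL, filter = NULL,
                       pdb_id = NULL, include_date = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "residue_profile"))
  kind <- attr(profile, "value_kind")
  if (mode %in% c("absolute_dDa", "delta_RFU") && !identical(kind, mode)) {
    stop("profile value_kind '", kind, "' does not match mode '", mode, "'",
         call. = FALSE)
  }
  n <- nrow(profile)
  colors <- rep(palette[["uncovered"]], n)
  cov <- profile$covered
  if (mode == "coverage") {
    colors[cov] <- palette[["coverage"]]
  } else if (mode == "redundancy") {
    rmax <- max(profile$redundancy)
    if (rmax > 0L) {
      frac <- profile$redundancy[cov] / rmax
      colors[cov] <- ramp_hex(frac, palette[["redundancy"]])
    }
  } else {
    v <- profile$value
    vmax <- suppressWarnings(max(abs(v), na.rm = TRUE))
    has <- cov & !is.na(v)
    if (!is.finite(vmax) || vmax == 0) {
      colors[has] <- palette[["zero"]]
    } else {
      frac <- abs(v[has]) / vmax
      pole <- ifelse(v[has] >= 0, palette[["deprotected"]],
                     palette[["protected"]])
      colors[has] <- ifelse(
        v[has] == 0, palette[["zero"]],
        ifelse(v[has] > 0,
               ramp_hex(frac, palette[["deprotected"]]),
               ramp_hex(frac, palette[["protected"]]))
      )
    }
  }
  # run-length merge consecutive residues of identical color; runs equal
  # to the base coat are dropped (the base coat already covers them)
  runs <- rle(colors)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values != palette[["uncovered"]]
  commands <- tibble::tibble(
    start = starts[keep] + resi_offset,
    end = ends[keep] + resi_offset,
    color = runs$values[keep]
  )
  header <- c(
    sprintf("# hdxdiff %s projection",
            c(coverage = "coverage", redundancy = "redundancy",
              absolute_dDa = "absolute ΔD (Da)",
              delta_RFU = "ΔRFU")[[mode]]),
    sprintf("# chain %s, %d residues%s", chain, n,
            if (resi_offset != 0L) sprintf(", resi offset %+d", resi_offset)
            else "")
  )
  if (!is.null(state_order)) {
    header <- c(header, paste0("# comparison: ",
                               state_order_label(state_order)))
  }
  if (!is.null(filter)) {
    header <- c(header, sprintf(
      "# filter: %g%% confidence, alpha %.4f, N = %d replicates",
      100 * filter$confidence_level, filter$alpha_crit, filter$n_replicates))
  }
  if (!is.null(pdb_id)) header <- c(header, paste0("# structure: ", pdb_id))
  if (include_date) {
    header <- c(header, paste0("# generated: ", format(Sys.Date())))
  }
  structure(
    list(header = header, base_color = palette[["uncovered"]],
         commands = commands, mode = mode, chain = chain,
         resi_offset = as.integer(resi_offset), n_residues = n),
    class = "pymol_script"
  )
}

#' @export
print.pymol_script <- function(x, ...) {
  cat("<pymol_script>", x$mode, "on chain", x$chain, "-",
      nrow(x$commands), "color command(s) +", "base coat\n")
  invisible(x)
}

#' Script text of a PyMOL script object
#'
#' @param script A [emit_pymol()] object.
#' @return Character vector of lines (comments, base coat, color
#'   commands).
#' @export
pymol_script_lines <- function(script) {
  stopifnot(inherits(script, "pymol_script"))
  resi <- ifelse(script$commands$start == script$commands$end,
                 sprintf("%d", script$commands$start),
                 sprintf("%d-%d", script$commands$start, script$commands$end))
  c(
    script$header,
    sprintf("color %s, chain %s", hex_to_pymol(script$base_color),
            script$chain),
    sprintf("color %s, chain %s and resi %s",
            hex_to_pymol(script$commands$color), script$chain, resi)
  )
}

#' Write a PyMOL script to a .pml file
#'
#' Plain text, LF line endings, ASCII-safe (non-ASCII header characters
#' are escaped); writing the same script twice produces byte-identical
#' files.
#'
#' @param script A [emit_pymol()] object.
#' @param path Output `.pml` path.
#' @return The path, invisibly.
#' @export
write_pml <- function(script, path) {
  lines <- pymol_script_lines(script)
  ascii <- stringi_escape_non_ascii(lines)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(ascii, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

stringi_escape_non_ascii <- function(lines) {
  vapply(lines, function(l) {
    if (all(utf8ToInt(enc2utf8(l)) < 128L)) return(l)
    ints <- utf8ToInt(enc2utf8(l))
    paste(vapply(ints, function(i) {
      if (i < 128L) intToUtf8(i) else sprintf("\\u%04x", i)
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
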