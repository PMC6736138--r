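# Minimal test-only .pml reader: applies color commands in order and
# returns the effective per-residue color map. Independent of the
# emitter's run-length encoding.
read_pml_colors <- function(path, protein_length) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  colors <- rep(NA_character_, protein_length)
  for (line in lines) {
    m <- regmatches(line,
                    regexec("^color (0x[0-9A-F]{6}), chain (\\S+)( and resi (\\d+)(-(\\d+))?)?$",
                            line))[[1]]
    if (length(m) == 0L) stop("unparseable pml line: ", line)
    hex <- sub("^0x", "#", m[2])
    if (m[4] == "") {
      colors[] <- hex
    } else {
      from <- as.integer(m[5])
      to <- if (m[7] == "") from else as.integer(m[7])
      colors[from:to] <- hex
    }
  }
  colors
}

# independent reconstruction of the intended per-residue colors for a
# difference-mode profile (linear white->pole ramp by |v|/max|v|)
expected_diff_colors <- function(profile, pal = pymol_palette()) {
  interp <- function(frac, pole) {
    p <- grDevices::col2rgb(pole)[, 1]
    sprintf("#%02X%02X%02X",
            as.integer(round(255 + frac * (p[1] - 255))),
            as.integer(round(255 + frac * (p[2] - 255))),
            as.integer(round(255 + frac * (p[3] - 255))))
  }
  v <- profile$value
  vmax <- suppressWarnings(max(abs(v), na.rm = TRUE))
  out <- rep(pal[["uncovered"]], nrow(profile))
  for (i in seq_len(nrow(profile))) {
    if (!profile$covered[i] || is.na(v[i])) next
    out[i] <- if (v[i] == 0 || vmax == 0) {
      pal[["zero"]]
    } else if (v[i] > 0) {
      interp(abs(v[i]) / vmax, pal[["deprotected"]])
    } else {
      interp(abs(v[i]) / vmax, pal[["protected"]])
    }
  }
  out
}

random_diff_profile <- function() {
  len <- sample(20:120, 1)
  covered <- runif(len) < 0.8
  value <- ifelse(covered, round(runif(len, -1, 1), 3), NA_real_)
  # some covered residues carry exactly zero (non-significant coverage)
  zero <- covered & runif(len) < 0.2
  value[zero] <- 0
  prof <- tibble::tibble(
    residue = seq_len(len),
    covered = covered,
    redundancy = as.integer(covered),
    value = value
  )
  structure(prof,
            class = c("residue_profile", class(prof)),
            protein_length = len,
            value_kind = "absolute_dDa")
}
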