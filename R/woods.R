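#' Assemble a Woods-plot dataset
#'
#' Collects classified peptide segments per exposure together with both
#' the 98% and 99% per-timepoint confidence bands. Only the filter's own
#' confidence level classifies; the second band is attached as a visual
#' aid so users can see which peptides would change status under a
#' tighter or looser filter.
#'
#' @param classified A [classify()] result.
#' @param differences The difference tibble the classification came from.
#' @param filter The [confidence_filter()] actually applied.
#'
#' @return Object of class `woods_dataset`: list with `segments` (ordered
#'   by exposure then start), `limits` (per exposure: `limit98`,
#'   `limit99`, `limit_active`), `mode`, `state_order` and `filter`.
#' @export
build_woods <- function(classified, differences, filter) {
  stopifnot(inherits(filter, "confidence_filter"))
  if (nrow(differences) == 0L || nrow(classified) == 0L) {
    stop("empty difference set", call. = FALSE)
  }
  mode <- attr(classified, "mode")
  alpha98 <- critical_value(0.98, filter$df)
  alpha99 <- critical_value(0.99, filter$df)
  disp <- filter$dispersion
  limits <- if (identical(mode, "summed")) {
    tibble::tibble(
      exposure = NA_real_,
      limit98 = summed_limit(disp, filter$n_replicates, alpha98),
      limit99 = summed_limit(disp, filter$n_replicates, alpha99),
      limit_active = filter$summed
    )
  } else {
    tibble::tibble(
      exposure = disp$exposure,
      limit98 = per_timepoint_limit(disp, filter$n_replicates, alpha98),
      limit99 = per_timepoint_limit(disp, filter$n_replicates, alpha99),
      limit_active = filter$per_timepoint$limit
    )
  }
  segments <- dplyr::arrange(tibble::as_tibble(classified),
                             .data$exposure, .data$start, .data$end)
  state_order <- attr(classified, "state_order")
  structure(
    list(
      segments = segments,
      limits = limits,
      mode = mode,
      state_order = state_order,
      filter = filter
    ),
    class = "woods_dataset"
  )
}

#' @export
print.woods_dataset <- function(x, ...) {
  cat("<woods_dataset>", nrow(x$segments), "segments,",
      nrow(x$limits), "panel(s), mode =", x$mode, "\n")
  invisible(x)
}

state_order_label <- function(state_order) {
  if (is.null(state_order)) {
    "ΔD = state 1 − state 2 (order unspecified)"
  } else {
    sprintf("ΔD = %s − %s", state_order[1], state_order[2])
  }
}

#' Legend text for the confidence bands of a Woods plot
#'
#' Formats the applied limits as plus/minus Da to two decimal places,
#' e.g. `"98%: ±0.40 Da"`.
#'
#' @param ws A `woods_dataset`.
#' @return One string per panel.
#' @export
woods_limit_label <- function(ws) {
  lab <- ifelse(is.na(ws$limits$exposure), "sum",
                paste0(ws$limits$exposure, " min"))
  sprintf("%s: 98%% ±%.2f Da, 99%% ±%.2f Da",
          lab, ws$limits$limit98, ws$limits$limit99)
}

panel_label <- function(exposure) {
  ifelse(is.na(exposure), "Sum", paste0(exposure, " min"))
}

hdx_class_colors <- function() {
  c(deprotected = "#D62728", protected = "#1F77B4",
    nonsignificant = "#B0B0B0")
}

#' Render Woods plots
#'
#' Draws one panel per exposure: each peptide as a horizontal segment
#' from its start to end residue at height delta-uptake (Da), colored red
#' (deprotected), blue (protected) or grey (non-significant); the 98%
#' band dashed and the 99% band dotted, symmetric about zero. The y axis
#' is shared across panels and symmetric about 0 (max |delta| padded
#' 10%). More than `panels_per_fig` exposures paginate into numbered
#' files with a warning, since panels become too crowded beyond about 8
#' timepoints.
#'
#' @param ws A [build_woods()] dataset.
#' @param out Output image path; extension selects the device (`.svg`
#'   vector via cairo, `.pdf` via cairo_pdf, `.png` raster at 300 dpi).
#' @param metric `"dDa"` (absolute difference, default) or `"dRFU"`.
#' @param panels_per_fig Maximum panels per figure (default 8).
#' @param ncol Facet columns per figure (default 2).
#' @param width,height Figure size in inches.
#'
#' @return Character vector of files written, invisibly.
#' @export
render_woods <- function(ws, out, metric = c("dDa", "dRFU"),
                         panels_per_fig = 8, ncol = 2,
                         width = 9, height = 6) {
  metric <- match.arg(metric)
  stopifnot(inherits(ws, "woods_dataset"))
  seg <- ws$segments
  lim <- ws$limits
  if (metric == "dRFU") {
    scale <- seg$max_uptake
    seg$delta <- rfu(seg$delta, scale)
    # bands are in Da; an RFU axis cannot carry them without a per-peptide
    # scale, so bands are dropped for this metric
    lim$limit98 <- NA_real_
    lim$limit99 <- NA_real_
    lim$limit_active <- NA_real_
  }
  exposures <- lim$exposure
  pages <- split(seq_along(exposures),
                 ceiling(seq_along(exposures) / panels_per_fig))
  if (length(pages) > 1L) {
    warning("more than ", panels_per_fig, " timepoints; paginating into ",
            length(pages), " figures", call. = FALSE)
  }
  ymax <- max(abs(seg$delta), abs(lim$limit99), na.rm = TRUE) * 1.1
  if (!is.finite(ymax) || ymax == 0) ymax <- 1
  seg$panel <- panel_label(seg$exposure)
  lim$panel <- panel_label(lim$exposure)
  panel_levels <- panel_label(exposures)
  seg$panel <- factor(seg$panel, levels = panel_levels)
  lim$panel <- factor(lim$panel, levels = panel_levels)
  ylab <- if (metric == "dDa") {
    expression(Delta * D ~ "(Da)")
  } else {
    expression(Delta * RFU)
  }
  files <- character(0)
  for (p in seq_along(pages)) {
    idx <- pages[[p]]
    lim_p <- lim[idx, , drop = FALSE]
    seg_p <- seg[seg$panel %in% lim_p$panel, , drop = FALSE]
    seg_p$panel <- droplevels(seg_p$panel)
    lim_p$panel <- factor(lim_p$panel, levels = levels(seg_p$panel))
    band <- tidyr::pivot_longer(
      lim_p[, c("panel", "limit98", "limit99")],
      cols = c("limit98", "limit99"),
      names_to = "band", values_to = "limit"
    )
    band <- rbind(band, transform(band, limit = -limit))
    band <- band[!is.na(band$limit), , drop = FALSE]
    g <- ggplot2::ggplot(seg_p) +
      ggplot2::geom_hline(yintercept = 0, color = "grey85", linewidth = 0.3) +
      ggplot2::geom_hline(
        data = band,
        ggplot2::aes(yintercept = .data$limit, linetype = .data$band),
        color = "grey30", linewidth = 0.35
      ) +
      ggplot2::geom_segment(
        ggplot2::aes(x = .data$start, xend = .data$end,
                     y = .data$delta, yend = .data$delta,
                     color = .data$label),
        linewidth = 1.1, lineend = "butt"
      ) +
      ggplot2::facet_wrap(~panel, ncol = ncol) +
      ggplot2::scale_color_manual(values = hdx_class_colors(),
                                  drop = FALSE, name = NULL) +
      ggplot2::scale_linetype_manual(
        values = c(limit98 = "dashed", limit99 = "dotted"),
        labels = c(limit98 = "98% limit", limit99 = "99% limit"),
        name = NULL
      ) +
      ggplot2::coord_cartesian(ylim = c(-ymax, ymax)) +
      ggplot2::labs(
        x = "Residue", y = ylab,
        subtitle = state_order_label(ws$state_order),
        caption = paste(woods_limit_label(ws)[idx], collapse = "\n")
      ) +
      ggplot2::theme_bw(base_size = 10) +
      ggplot2::theme(legend.position = "bottom",
                     panel.grid.minor = ggplot2::element_blank())
    path <- if (length(pages) == 1L) out else paginate_path(out, p)
    save_figure(g, path, width = width, height = height)
    files <- c(files, path)
  }
  invisible(files)
}

paginate_path <- function(out, i) {
  ext <- tools::file_ext(out)
  sub(paste0("\\.", ext, "$"), sprintf("_%d.%s", i, ext), out)
}

save_figure <- function(g, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(
    ext,
    svg = function(f) grDevices::svg(f, width = width, height = height),
    pdf = function(f) grDevices::cairo_pdf(f, width = width, height = height),
    png = function(f) grDevices::png(f, width = width, height = height,
                                     units = "in", res = 300),
    stop("unsupported figure format: .", ext, call. = FALSE)
  )
  dev(path)
  on.exit(grDevices::dev.off())
  print(g)
  invisible(path)
}

#' Render wrapped coverage / redundancy maps
#'
#' Draws the protein as rows of `per_row` residues. Coverage: covered
#' residues as filled blocks, gaps blank. Redundancy: per-residue fill on
#' a linear white-to-magenta ramp anchored at redundancy 1 (white) up to
#' the dataset maximum (pure magenta), with the maximum annotated on the
#' key.
#'
#' @param profile A `residue_profile` from [coverage_profile()].
#' @param kind `"coverage"` or `"redundancy"`.
#' @param out Output image path (`.svg`, `.pdf` or `.png`).
#' @param per_row Residues per row (default 100).
#' @param width,height Figure size in inches.
#'
#' @return The output path, invisibly.
#' @export
render_maps <- function(profile, kind = c("coverage", "redundancy"), out,
                        per_row = 100, width = 9, height = NULL) {
  kind <- match.arg(kind)
  if (!inherits(profile, "residue_profile") || nrow(profile) == 0L) {
    stop("empty residue profile", call. = FALSE)
  }
  df <- tibble::tibble(
    residue = profile$residue,
    row = (profile$residue - 1L) %/% per_row,
    col = (profile$residue - 1L) %% per_row + 1L,
    covered = profile$covered,
    redundancy = profile$redundancy
  )
  n_rows <- max(df$row) + 1L
  if (is.null(height)) height <- 0.5 + 0.35 * n_rows
  base <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_tile(fill = NA, color = "grey88", linewidth = 0.15) +
    ggplot2::scale_y_continuous(
      breaks = -(seq_len(n_rows) - 1L),
      labels = (seq_len(n_rows) - 1L) * per_row + 1L
    ) +
    ggplot2::labs(x = "Residue (within row)", y = "Row start") +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  covered_df <- df[df$covered, , drop = FALSE]
  g <- if (kind == "coverage") {
    base +
      ggplot2::geom_tile(data = covered_df, fill = "#2171B5",
                         color = "grey40", linewidth = 0.1) +
      ggplot2::labs(
        title = sprintf("Coverage: %.1f%% of %d residues",
                        100 * coverage_fraction(profile),
                        attr(profile, "protein_length"))
      )
  } else {
    rmax <- max(profile$redundancy)
    if (rmax < 1L) stop("no covered residues to map", call. = FALSE)
    base +
      ggplot2::geom_tile(
        data = covered_df,
        ggplot2::aes(fill = .data$redundancy),
        color = "grey40", linewidth = 0.1
      ) +
      ggplot2::scale_fill_gradient(
        low = "#FFFFFF", high = "#FF00FF",
        limits = c(1, max(rmax, 2)),
        breaks = unique(c(1, rmax)),
        name = "Redundancy",
        # non-raster colorbar keeps vector output free of embedded images
        # (and byte-deterministic)
        guide = ggplot2::guide_colourbar(display = "rectangles")
      ) +
      ggplot2::labs(
        title = sprintf("Redundancy (max %d at residue %d)",
                        rmax, which.max(profile$redundancy))
      )
  }
  save_figure(g, out, width = width, height = height)
  invisible(out)
}
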