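#' Two-tailed Student-t critical value
#'
#' The critical value used to scale the global confidence limits: the
#' `1 - (1 - confidence_level)/2` quantile of the t-distribution with `df`
#' degrees of freedom. With the default triplicate design (`df = 2`) the
#' 98% and 99% values are 6.965 and 9.925.
#'
#' @param confidence_level Fraction in (0, 1), e.g. `0.98`.
#' @param df Degrees of freedom (replicates minus one), `>= 1`.
#'
#' @return The critical value (positive scalar).
#' @examples
#' critical_value(0.98, 2)  # 6.965
#' critical_value(0.99, 2)  # 9.925
#' @export
critical_value <- function(confidence_level, df) {
  if (!is.numeric(confidence_level) || length(confidence_level) != 1L ||
      is.na(confidence_level) ||
      confidence_level <= 0 || confidence_level >= 1) {
    stop("confidence_level must be a fraction in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(df) || length(df) != 1L || is.na(df) || df < 1) {
    stop("df must be >= 1", call. = FALSE)
  }
  stats::qt(1 - (1 - confidence_level) / 2, df = df)
}

#' Per-timepoint dispersion of uptake differences
#'
#' For each labelling time, the dispersion statistic sigma_t that drives
#' the confidence limits. The default (`method = "spread"`) is the sample
#' standard deviation (denominator n - 1) of the per-peptide uptake
#' differences at that exposure — the only dispersion recoverable from a
#' difference file alone. When per-peptide pooled SDs are available,
#' `method = "pooled"` instead uses their mean.
#'
#' Exposure 0 (the unlabelled control) is always excluded.
#'
#' @param differences Difference tibble ([parse_difference_csv()] /
#'   [compute_differences()]).
#' @param exposure Optional single exposure (minutes); default all nonzero
#'   exposures present.
#' @param method `"spread"` (default) or `"pooled"`.
#'
#' @return Tibble with one row per exposure: `exposure`, `sigma` (Da),
#'   `sigma_sq` (Da^2), `n_obs`.
#' @export
timepoint_dispersion <- function(differences, exposure = NULL,
                                 method = c("spread", "pooled")) {
  method <- match.arg(method)
  d <- differences[differences$exposure > 0, , drop = FALSE]
  if (!is.null(exposure)) {
    d <- d[d$exposure %in% exposure, , drop = FALSE]
    if (nrow(d) == 0L) {
      stop("no difference records at exposure ", exposure, call. = FALSE)
    }
  }
  if (nrow(d) == 0L) stop("no nonzero-exposure difference records",
                          call. = FALSE)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$exposure),
    sigma = if (method == "spread") {
      stats::sd(.data$delta_uptake)
    } else {
      mean(.data$pooled_sd, na.rm = TRUE)
    },
    n_obs = dplyr::n(),
    .groups = "drop"
  )
  if (any(out$n_obs < 2)) {
    stop("dispersion undefined: fewer than 2 difference records at ",
         "exposure(s) ", paste(out$exposure[out$n_obs < 2], collapse = ", "),
         call. = FALSE)
  }
  if (method == "pooled" && anyNA(out$sigma)) {
    stop("method = 'pooled' requires pooled_sd values", call. = FALSE)
  }
  tibble::tibble(
    exposure = out$exposure,
    sigma = out$sigma,
    sigma_sq = out$sigma^2,
    n_obs = out$n_obs
  )
}

#' Per-timepoint confidence limit
#'
#' The half-width of the symmetric acceptance band about zero difference
#' at one exposure: `(sigma_t / sqrt(N)) * alpha`, i.e. the standard error
#' of the timepoint's uptake dispersion scaled by the critical value.
#' Uptake differences outside `[-limit, +limit]` are significant.
#'
#' @param disp A [timepoint_dispersion()] tibble, or a numeric vector of
#'   sigma values (Da).
#' @param n_replicates Replicate count N, `>= 1`.
#' @param alpha_crit Critical value from [critical_value()], `> 0`.
#'
#' @return Numeric limit(s) in Da, one per dispersion row.
#' @examples
#' per_timepoint_limit(0.10, n_replicates = 3, alpha_crit = 6.965)  # 0.4022
#' @export
per_timepoint_limit <- function(disp, n_replicates, alpha_crit) {
  check_limit_args(n_replicates, alpha_crit)
  sigma <- if (is.data.frame(disp)) disp$sigma else disp
  if (any(sigma < 0)) stop("sigma must be >= 0", call. = FALSE)
  sigma / sqrt(n_replicates) * alpha_crit
}

#' Summed-data confidence limit
#'
#' For summed data — per-peptide uptake differences aggregated over all
#' timepoints — the variances of the per-timepoint dispersions add (errors
#' propagate as a simple sum of variances), giving
#' `alpha * sqrt(sum_t sigma_t^2 / N)`. With a single timepoint this
#' reduces exactly to [per_timepoint_limit()].
#'
#' @inheritParams per_timepoint_limit
#' @param disp A [timepoint_dispersion()] tibble (one row per distinct
#'   exposure) or numeric vector of sigma values.
#'
#' @return Single limit in Da.
#' @examples
#' summed_limit(c(0.10, 0.10), n_replicates = 3, alpha_crit = 6.965)  # 0.5688
#' @export
summed_limit <- function(disp, n_replicates, alpha_crit) {
  check_limit_args(n_replicates, alpha_crit)
  if (is.data.frame(disp)) {
    if (anyDuplicated(disp$exposure)) {
      stop("dispersions must come from distinct exposures", call. = FALSE)
    }
    sigma_sq <- disp$sigma_sq
  } else {
    sigma_sq <- disp^2
  }
  if (length(sigma_sq) == 0L) stop("no dispersions supplied", call. = FALSE)
  alpha_crit * sqrt(sum(sigma_sq) / n_replicates)
}

check_limit_args <- function(n_replicates, alpha_crit) {
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      is.na(n_replicates) || n_replicates < 1) {
    stop("n_replicates must be >= 1", call. = FALSE)
  }
  if (!is.numeric(alpha_crit) || length(alpha_crit) != 1L ||
      is.na(alpha_crit) || alpha_crit <= 0) {
    stop("alpha_crit must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a confidence filter for a differential dataset
#'
#' Computes the critical value, the per-timepoint limits and the summed
#' limit for a difference table in one object. The degrees of freedom
#' default to `n_replicates - 1`; an explicit `alpha_override` reproduces
#' published critical values (e.g. 6.965) independently of the quantile
#' routine.
#'
#' @inheritParams timepoint_dispersion
#' @param confidence_level Fraction in (0, 1); default 0.98.
#' @param n_replicates Replicate count N; default 3 (hence df = 2).
#' @param df Degrees of freedom; default `n_replicates - 1`.
#' @param alpha_override Optional explicit critical value replacing the
#'   computed quantile.
#'
#' @return Object of class `confidence_filter`: list with
#'   `confidence_level`, `alpha_crit`, `df`, `n_replicates`, `dispersion`
#'   (the [timepoint_dispersion()] tibble), `per_timepoint` (tibble
#'   `exposure`, `limit`), `summed` (Da) and `n_timepoints`.
#' @export
confidence_filter <- function(differences, confidence_level = 0.98,
                              n_replicates = 3, df = n_replicates - 1,
                              alpha_override = NULL,
                              method = c("spread", "pooled")) {
  method <- match.arg(method)
  alpha <- if (is.null(alpha_override)) {
    critical_value(confidence_level, df)
  } else {
    if (!is.numeric(alpha_override) || alpha_override <= 0) {
      stop("alpha_override must be > 0", call. = FALSE)
    }
    alpha_override
  }
  disp <- timepoint_dispersion(differences, method = method)
  structure(
    list(
      confidence_level = confidence_level,
      alpha_crit = alpha,
      df = df,
      n_replicates = n_replicates,
      method = method,
      dispersion = disp,
      per_timepoint = tibble::tibble(
        exposure = disp$exposure,
        limit = per_timepoint_limit(disp, n_replicates, alpha)
      ),
      summed = summed_limit(disp, n_replicates, alpha),
      n_timepoints = nrow(disp)
    ),
    class = "confidence_filter"
  )
}

#' @export
print.confidence_filter <- function(x, ...) {
  cat("<confidence_filter>\n")
  cat(sprintf("  confidence: %g%%  alpha: %.4f  (df = %d, N = %d)\n",
              100 * x$confidence_level, x$alpha_crit, x$df, x$n_replicates))
  for (i in seq_len(nrow(x$per_timepoint))) {
    cat(sprintf("  t = %6g min: +/-%.4f Da (sigma %.4f, n %d)\n",
                x$per_timepoint$exposure[i], x$per_timepoint$limit[i],
                x$dispersion$sigma[i], x$dispersion$n_obs[i]))
  }
  cat(sprintf("  summed:        +/-%.4f Da\n", x$summed))
  invisible(x)
}

#' Classify peptide uptake differences against confidence limits
#'
#' Labels every peptide-timepoint (`mode = "per_timepoint"`) or every
#' peptide's summed difference (`mode = "summed"`) as `deprotected`
#' (delta strictly above +limit), `protected` (strictly below -limit) or
#' `nonsignificant` (inside or exactly on the band; the boundary is
#' conservative). In summed mode the delta is the sum of a peptide's
#' differences over all nonzero exposures present; peptides missing at
#' some exposures are summed over what they have, with the count in
#' `n_exposures`.
#'
#' @param differences Difference tibble.
#' @param filter A [confidence_filter()].
#' @param mode `"per_timepoint"` or `"summed"`.
#'
#' @return Tibble of class `hdx_classification` with peptide identity
#'   columns, `exposure` (NA in summed mode), `delta` (Da), `limit` (Da)
#'   and `label` (factor deprotected/protected/nonsignificant); attribute
#'   `mode`.
#' @export
classify <- function(differences, filter,
                     mode = c("per_timepoint", "summed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(filter, "confidence_filter"))
  d <- differences[differences$exposure > 0, , drop = FALSE]
  if (nrow(d) == 0L) stop("no nonzero-exposure differences", call. = FALSE)
  if (mode == "per_timepoint") {
    missing_exp <- setdiff(unique(d$exposure), filter$per_timepoint$exposure)
    if (length(missing_exp) > 0L) {
      stop("no confidence limit for exposure(s): ",
           paste(missing_exp, collapse = ", "), call. = FALSE)
    }
    d <- dplyr::left_join(d, filter$per_timepoint, by = "exposure")
    out <- tibble::tibble(
      d[, c(peptide_key_cols(), "max_uptake")],
      exposure = d$exposure,
      delta = d$delta_uptake,
      limit = d$limit
    )
  } else {
    agg <- dplyr::summarise(
      dplyr::group_by(d, dplyr::across(dplyr::all_of(
        c(peptide_key_cols(), "max_uptake")
      ))),
      delta = sum(.data$delta_uptake),
      n_exposures = dplyr::n(),
      .groups = "drop"
    )
    out <- tibble::tibble(
      agg[, c(peptide_key_cols(), "max_uptake")],
      exposure = NA_real_,
      delta = agg$delta,
      limit = filter$summed,
      n_exposures = agg$n_exposures
    )
  }
  out$label <- factor(
    ifelse(out$delta > out$limit, "deprotected",
           ifelse(out$delta < -out$limit, "protected", "nonsignificant")),
    levels = c("deprotected", "protected", "nonsignificant")
  )
  out <- dplyr::arrange(out, .data$exposure, .data$start, .data$end)
  attr(out, "mode") <- mode
  attr(out, "state_order") <- attr(differences, "state_order")
  class(out) <- c("hdx_classification", class(out))
  out
}
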