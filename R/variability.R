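#' Per-gene, per-timepoint expression statistics
#'
#' For each gene at each timepoint, computes the arithmetic mean over
#' non-missing individuals, the unbiased (n - 1) sample variance and the
#' squared coefficient of variation `cv2 = var / mean^2` across individuals.
#' Genes observed in fewer than `min_individuals` individuals at a
#' timepoint are flagged by `cv2 = NA` (never dropped silently), as are
#' genes with zero mean.
#'
#' @param panel Long tibble with columns `gene`, `individual`, `timepoint`,
#'   `value` (see [read_expression_panel()]).
#' @param min_individuals Minimum non-missing individuals for a defined CV^2.
#' @return Tibble with columns `gene`, `timepoint`, `mean`, `var`, `cv2`,
#'   `n_used`.
#' @export
panel_stats <- function(panel, min_individuals = 2) {
  check_columns(panel, c("gene", "individual", "timepoint", "value"), "expression panel")
  if (min_individuals < 2) abort_validation("min_individuals must be >= 2")
  panel |>
    dplyr::group_by(.data$gene, .data$timepoint) |>
    dplyr::summarize(
      n_used = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      var = var(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean = ifelse(is.nan(.data$mean), NA_real_, .data$mean),
      cv2 = dplyr::if_else(
        .data$n_used >= min_individuals & !is.na(.data$mean) & .data$mean > 0,
        .data$var / .data$mean^2, NA_real_
      )
    )
}

#' Fit the mean-CV^2 trend
#'
#' Fits a locally weighted regression of `log2(cv2)` on `log2(mean)` -- the
#' expected CV^2 for genes of similar mean expression, against which
#' normalized expression variability is measured. Points with
#' `mean < min_mean` or `cv2 <= 0` are excluded before fitting (log space
#' requires positive values). One robustness iteration downweights
#' outlying genes. Evaluation outside the fitted mean range clamps to the
#' boundary fitted value.
#'
#' @param stats Tibble from [panel_stats()] (typically one timepoint).
#' @param span Loess span (fraction of points in each local fit).
#' @param min_mean Minimum mean expression for a point to enter the fit.
#' @param min_points Minimum usable points; fewer is an error suggesting
#'   lower filters or pooled timepoints.
#' @param iterations Robustness iterations of the Tukey-biweight
#'   reweighting (the first is the least-squares fit); the default 4 keeps
#'   the trend on the bulk of genes even when a minority is strongly
#'   inflated.
#' @return A `cv2_trend` object.
#' @export
fit_cv2_trend <- function(stats, span = 0.3, min_mean = 1, min_points = 50,
                          iterations = 4) {
  check_columns(stats, c("mean", "cv2"), "gene statistics")
  pts <- stats |>
    dplyr::filter(!is.na(.data$cv2), .data$cv2 > 0, .data$mean >= min_mean)
  if (nrow(pts) < min_points) {
    abort_fit(sprintf(
      paste0("only %d usable (gene, timepoint) points for the mean-CV2 trend ",
        "(need >= %d); lower min_mean/min_individuals or pool timepoints"),
      nrow(pts), min_points
    ))
  }
  df <- data.frame(x = log2(pts$mean), y = log2(pts$cv2))
  model <- loess(y ~ x, data = df, span = span, degree = 2,
    family = "symmetric", control = loess.control(iterations = iterations))
  structure(
    list(model = model, range = range(df$x), span = span, n = nrow(df),
      method = "loess"),
    class = "cv2_trend"
  )
}

#' Evaluate a fitted trend
#'
#' @param trend A `cv2_trend`.
#' @param log2_mean Numeric vector of log2 mean expression.
#' @return Expected `log2(cv2)` at each input (boundary-clamped
#'   extrapolation).
#' @export
predict_trend <- function(trend, log2_mean) {
  stopifnot(inherits(trend, "cv2_trend"))
  x <- pmin(pmax(log2_mean, trend$range[1]), trend$range[2])
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  if (any(ok)) out[ok] <- predict(trend$model, newdata = data.frame(x = x[ok]))
  out
}

#' @export
print.cv2_trend <- function(x, ...) {
  cat(sprintf(
    "<cv2_trend> %s fit, span %.2f, %d points, log2-mean range [%.2f, %.2f]\n",
    x$method, x$span, x$n, x$range[1], x$range[2]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mean-CV^2 trend into an evaluation grid
#'
#' @param x A `cv2_trend`.
#' @param n Grid size.
#' @param ... Unused.
#' @return Tibble with `log2_mean`, `log2_cv2_fit`, `cv2_fit`.
#' @export
tidy.cv2_trend <- function(x, n = 100, ...) {
  grid <- seq(x$range[1], x$range[2], length.out = n)
  fit <- predict_trend(x, grid)
  tibble::tibble(log2_mean = grid, log2_cv2_fit = fit, cv2_fit = 2^fit)
}

#' @rdname tidy.cv2_trend
#' @export
glance.cv2_trend <- function(x, ...) {
  tibble::tibble(
    method = x$method, span = x$span, n = x$n,
    residual_sd = sd(x$model$residuals)
  )
}

# NEV for a single set of stats against a fitted trend.
nev_score <- function(cv2, mean, trend) {
  out <- rep(NA_real_, length(cv2))
  ok <- !is.na(cv2) & cv2 > 0 & !is.na(mean) & mean > 0
  out[ok] <- log2(cv2[ok]) - predict_trend(trend, log2(mean[ok]))
  out
}

#' Normalized expression variability (NEV)
#'
#' For each gene at each timepoint, NEV is `log2(cv2 / cv2_hat(mu))`: the
#' log2 ratio of the gene's CV^2 across individuals to the trend-expected
#' CV^2 at its mean expression. NEV < 0 means the gene varies less among
#' individuals than genes of similar mean expression; NEV > 0 means more.
#' The trend is fitted per timepoint by default (`pool_timepoints = TRUE`
#' fits one trend on all timepoints). A gene's summarized NEV is the median
#' over timepoints with defined NEV, reported only when at least
#' `min_timepoints` are defined. Genes with `cv2 = 0` at a timepoint get a
#' missing NEV there, never -Inf.
#'
#' @inheritParams panel_stats
#' @inheritParams fit_cv2_trend
#' @param min_timepoints Minimum defined timepoints for the median summary;
#'   default `ceiling(T / 2)` for `T` observed timepoints.
#' @param pool_timepoints Fit one trend on all timepoints instead of one per
#'   timepoint.
#' @return Tibble with columns `gene`, `nev` (median NEV),
#'   `n_timepoints_used`. Attributes: `by_timepoint` (per-timepoint tibble
#'   with `gene`, `timepoint`, `mean`, `cv2`, `nev`) and `trends` (named
#'   list of `cv2_trend` fits).
#' @export
compute_nev <- function(panel, span = 0.3, min_individuals = 2, min_mean = 1,
                        min_points = 50, min_timepoints = NULL,
                        pool_timepoints = FALSE) {
  stats <- panel_stats(panel, min_individuals = min_individuals)
  timepoints <- unique(stats$timepoint)
  if (is.null(min_timepoints)) min_timepoints <- ceiling(length(timepoints) / 2)

  if (pool_timepoints) {
    trend <- fit_cv2_trend(stats, span = span, min_mean = min_mean,
      min_points = min_points)
    trends <- list(pooled = trend)
    stats$nev <- nev_score(stats$cv2, stats$mean, trend)
  } else {
    trends <- list()
    stats$nev <- NA_real_
    for (tp in timepoints) {
      sel <- stats$timepoint == tp
      trend <- fit_cv2_trend(stats[sel, ], span = span, min_mean = min_mean,
        min_points = min_points)
      trends[[tp]] <- trend
      stats$nev[sel] <- nev_score(stats$cv2[sel], stats$mean[sel], trend)
    }
  }

  summary <- stats |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarize(
      n_timepoints_used = sum(!is.na(.data$nev)),
      nev = if (sum(!is.na(.data$nev)) >= min_timepoints) {
        median(.data$nev, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::select("gene", "nev", "n_timepoints_used")
  summary <- summary[match(unique(panel$gene), summary$gene), ]
  attr(summary, "by_timepoint") <-
    dplyr::select(stats, "gene", "timepoint", "mean", "cv2", "n_used", "nev")
  attr(summary, "trends") <- trends
  summary
}
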