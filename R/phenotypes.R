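#' Environmental responsiveness from a condition atlas
#'
#' For every treatment sample with a resolvable baseline, the per-gene
#' contrast is `log2((expr + c) / (expr_baseline + c))` with pseudocount
#' `c`. Responsiveness is the sum over contrasts of the absolute log2
#' ratios (the magnitude convention; `signed = TRUE` gives the literal
#' signed sum, in which opposite responses cancel). Contrasts where both
#' values sit below the detection floor are skipped and counted.
#'
#' @param atlas A `condition_atlas` (see [read_atlas()]).
#' @param ecotype,tissue Optional filters on the treatment samples used
#'   (e.g. `ecotype = "Col-0"`, `tissue = "seedling"`).
#' @param pseudocount Added to numerator and denominator before the ratio.
#' @param detection_floor Contrasts with both expression values below this
#'   floor are skipped.
#' @param signed Use the signed sum instead of the sum of magnitudes.
#' @return Tibble with columns `gene`, `responsiveness`, `n_contrasts`,
#'   `n_skipped`.
#' @export
responsiveness <- function(atlas, ecotype = NULL, tissue = NULL,
                           pseudocount = 1, detection_floor = 1,
                           signed = FALSE) {
  stopifnot(inherits(atlas, "condition_atlas"))
  treat <- dplyr::filter(atlas$samples, !is.na(.data$baseline))
  if (!is.null(ecotype)) treat <- treat[treat$ecotype %in% ecotype, ]
  if (!is.null(tissue)) treat <- treat[treat$tissue %in% tissue, ]
  if (nrow(treat) == 0) abort_validation("no treatment samples match the filters")
  unresolved <- setdiff(treat$baseline, atlas$samples$sample)
  if (length(unresolved) > 0) {
    abort_validation(sprintf(
      "treatment sample(s) with unresolvable baseline: %s",
      paste(treat$sample[treat$baseline %in% unresolved], collapse = ", ")
    ))
  }
  expr <- atlas$expr
  contrasts <- treat |>
    dplyr::select(treat_sample = "sample", base_sample = "baseline") |>
    dplyr::left_join(
      dplyr::rename(expr, treat_sample = "sample", expr_treat = "value"),
      by = "treat_sample"
    ) |>
    dplyr::left_join(
      dplyr::rename(expr, base_sample = "sample", expr_base = "value"),
      by = c("base_sample", "gene")
    ) |>
    dplyr::mutate(
      skipped = !is.na(.data$expr_treat) & !is.na(.data$expr_base) &
        .data$expr_treat < detection_floor & .data$expr_base < detection_floor,
      ratio = log2((.data$expr_treat + pseudocount) / (.data$expr_base + pseudocount))
    )
  contrasts |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarize(
      responsiveness = if (signed) {
        sum(.data$ratio[!.data$skipped], na.rm = TRUE)
      } else {
        sum(abs(.data$ratio[!.data$skipped]), na.rm = TRUE)
      },
      n_contrasts = sum(!.data$skipped & !is.na(.data$ratio)),
      n_skipped = sum(.data$skipped),
      .groups = "drop"
    )
}

#' Tissue-specificity index tau for one expression profile
#'
#' `tau = sum_j (1 - log2(S_j) / log2(S_max)) / (n - 1)` over `n` tissues,
#' where `S_max` is the highest expression of the gene across tissues.
#' Values below the floor are raised to it before taking logs, which keeps
#' every term in `[0, 1]`, hence `tau` in `[0, 1]`: 0 for perfectly uniform
#' expression, exactly 1 for a gene expressed in a single tissue (all other
#' tissues at the floor). If all tissues are at or below the floor, tau is
#' undefined (`NA`).
#'
#' @param x Nonnegative expression across tissues (length >= 2).
#' @param floor Expression floor applied before `log2` (default 1 unit).
#' @return tau in `[0, 1]`, or `NA`.
#' @export
tau_index <- function(x, floor = 1) {
  if (length(x) < 2) abort_validation("tau needs expression in at least 2 tissues")
  if (any(is.na(x))) return(NA_real_)
  if (any(x < 0)) abort_validation("tau needs nonnegative expression")
  l <- log2(pmax(x, floor))
  lmax <- max(l)
  if (lmax <= 0) return(NA_real_)
  sum(1 - l / lmax) / (length(x) - 1)
}

#' Tissue specificity for a table of genes
#'
#' @param expr Long tibble with columns `gene`, `tissue`, `value`.
#' @param floor Expression floor (see [tau_index()]).
#' @return Tibble with columns `gene`, `tau`, `n_tissues`.
#' @export
tissue_tau <- function(expr, floor = 1) {
  check_columns(expr, c("gene", "tissue", "value"), "tissue expression")
  expr |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarize(
      tau = tau_index(.data$value, floor = floor),
      n_tissues = dplyr::n(),
      .groups = "drop"
    )
}

#' @describeIn tissue_tau tau from the tissue-survey samples of a
#'   `condition_atlas` (samples without a treatment label), averaging
#'   replicate samples per tissue first.
#' @param atlas A `condition_atlas`.
#' @export
atlas_tau <- function(atlas, floor = 1) {
  stopifnot(inherits(atlas, "condition_atlas"))
  survey <- dplyr::filter(atlas$samples, is.na(.data$treatment))
  if (nrow(survey) == 0) abort_validation("atlas has no tissue-survey samples")
  atlas$expr |>
    dplyr::inner_join(dplyr::select(survey, "sample", "tissue"), by = "sample") |>
    dplyr::group_by(.data$gene, .data$tissue) |>
    dplyr::summarize(value = mean(.data$value, na.rm = TRUE), .groups = "drop") |>
    tissue_tau(floor = floor)
}

#' Correlate two per-gene scores
#'
#' Product-moment or rank correlation on the genes where both scores are
#' defined.
#'
#' @param data Tibble with one row per gene.
#' @param x,y Columns to correlate (tidy-eval).
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `method`, `estimate`, `p_value`, `n`.
#' @export
correlate <- function(data, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < 3) abort_validation("correlation needs at least 3 paired values")
  ct <- suppressWarnings(cor.test(xv[ok], yv[ok], method = method, exact = FALSE))
  tibble::tibble(
    method = method,
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    n = sum(ok)
  )
}
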