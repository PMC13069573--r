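#' Cliff's delta with a consistent-variance confidence interval
#'
#' `delta = (#\{x > y\} - #\{x < y\}) / (n * m)`: the probability that a
#' value from `x` exceeds one from `y`, minus the reverse. The confidence
#' interval uses Cliff's consistent variance estimator with the asymmetric
#' z-transform-style bounds, so the interval respects the `[-1, 1]` range.
#' Complete separation (`delta = +/-1`, zero estimated variance) gives a
#' degenerate point interval.
#'
#' @param x,y Numeric samples (NAs dropped).
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `conf_level`,
#'   `n_x`, `n_y`.
#' @export
cliffs_delta <- function(x, y, conf_level = 0.95) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n <- length(x)
  m <- length(y)
  if (n < 1 || m < 1) abort_validation("cliffs_delta needs non-empty samples")
  dmat <- sign(outer(x, y, "-"))
  d <- mean(dmat)
  if (n < 2 || m < 2) {
    return(tibble::tibble(estimate = d, ci_low = NA_real_, ci_high = NA_real_,
      conf_level = conf_level, n_x = n, n_y = m))
  }
  di <- rowMeans(dmat)
  dj <- colMeans(dmat)
  s2 <- (m^2 * sum((di - d)^2) + n^2 * sum((dj - d)^2) - sum((dmat - d)^2)) /
    (n * m * (n - 1) * (m - 1))
  s2 <- max(s2, 0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (s2 == 0) {
    lo <- hi <- d
  } else {
    den <- 1 - d^2 + z^2 * s2
    half <- z * sqrt(s2) * sqrt(pmax(1 - 2 * d^2 + d^4 + z^2 * s2, 0))
    lo <- (d - d^3 - half) / den
    hi <- (d - d^3 + half) / den
  }
  lo <- max(min(lo, d), -1)
  hi <- min(max(hi, d), 1)
  tibble::tibble(estimate = d, ci_low = lo, ci_high = hi,
    conf_level = conf_level, n_x = n, n_y = m)
}

#' Rank-sum group contrasts with effect sizes
#'
#' For each requested pair of group labels, a two-sided Wilcoxon/
#' Mann-Whitney rank-sum test plus Cliff's delta with its 95% CI, with
#' Benjamini-Hochberg (or other [p.adjust()]) correction across the tested
#' contrasts. The score may be NEV or any per-gene score (e.g. expression
#' level for control analyses).
#'
#' @param data Tibble with one row per gene.
#' @param score,group Score and group-label columns (tidy-eval).
#' @param contrasts List of length-2 character vectors of group labels;
#'   default: all pairs in order of appearance.
#' @param p_adjust_method Passed to [p.adjust()] (default `"BH"`).
#' @param conf_level Confidence level for the delta CI.
#' @return Tibble, one row per contrast: `group1`, `group2`, `n1`, `n2`,
#'   `p_value`, `p_adjusted`, `delta`, `delta_low`, `delta_high`.
#' @export
compare_groups <- function(data, score, group, contrasts = NULL,
                           p_adjust_method = "BH", conf_level = 0.95) {
  scores <- dplyr::pull(data, {{ score }})
  labels <- dplyr::pull(data, {{ group }})
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- labels[keep]
  levels <- unique(labels)
  if (is.null(contrasts)) {
    if (length(levels) < 2) abort_validation("need at least two groups")
    contrasts <- combn(levels, 2, simplify = FALSE)
  }
  rows <- purrr::map_dfr(contrasts, function(ct) {
    stopifnot(length(ct) == 2)
    xs <- scores[labels == ct[1]]
    ys <- scores[labels == ct[2]]
    for (k in 1:2) {
      if (sum(labels == ct[k]) < 2) {
        abort_validation(sprintf("group '%s' has fewer than 2 genes", ct[k]))
      }
    }
    w <- suppressWarnings(wilcox.test(xs, ys, alternative = "two.sided", exact = FALSE))
    cd <- cliffs_delta(xs, ys, conf_level = conf_level)
    tibble::tibble(
      group1 = ct[1], group2 = ct[2], n1 = length(xs), n2 = length(ys),
      p_value = w$p.value, delta = cd$estimate,
      delta_low = cd$ci_low, delta_high = cd$ci_high
    )
  })
  rows$p_adjusted <- p.adjust(rows$p_value, method = p_adjust_method)
  dplyr::relocate(rows, "p_adjusted", .after = "p_value")
}

#' Pair-level score table
#'
#' Joins a per-gene score onto a paralog table, yielding per-pair scores
#' and divergences, optionally with clade metadata for age analyses.
#' Pairs in which either member lacks a score are excluded and counted
#' (attribute `n_excluded`).
#'
#' @param pairs Paralog tibble (see [read_paralog_table()]).
#' @param scores Tibble with columns `gene` and the score column.
#' @param score_col Name of the score column in `scores` (default "nev").
#' @param meta Optional gene metadata tibble with `gene`, `clade`.
#' @return Tibble: `pair_id`, `gene_a`, `gene_b`, `mode`, `orientation`,
#'   `score_a`, `score_b`, `dscore` (= a - b), `abs_dscore`, and with
#'   `meta` also `clade_a`, `clade_b`, `dclade`.
#' @export
pair_divergence <- function(pairs, scores, score_col = "nev", meta = NULL) {
  check_columns(pairs, c("gene_a", "gene_b", "mode"), "paralog table")
  check_columns(scores, c("gene", score_col), "score table")
  lookup <- setNames(scores[[score_col]], scores$gene)
  out <- tibble::tibble(
    pair_id = if ("pair_id" %in% names(pairs)) pairs$pair_id else
      paste(pairs$gene_a, pairs$gene_b, sep = "|"),
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    mode = pairs$mode,
    orientation = if ("orientation" %in% names(pairs)) pairs$orientation else "unknown",
    score_a = unname(lookup[pairs$gene_a]),
    score_b = unname(lookup[pairs$gene_b])
  )
  if (!is.null(meta)) {
    check_columns(meta, c("gene", "clade"), "gene metadata")
    clade <- setNames(meta$clade, meta$gene)
    out$clade_a <- unname(clade[out$gene_a])
    out$clade_b <- unname(clade[out$gene_b])
    out$dclade <- out$clade_a - out$clade_b
  }
  n_before <- nrow(out)
  out <- dplyr::filter(out, !is.na(.data$score_a), !is.na(.data$score_b))
  out$dscore <- out$score_a - out$score_b
  out$abs_dscore <- abs(out$dscore)
  attr(out, "n_excluded") <- n_before - nrow(out)
  out
}

#' Within-pair min/max decomposition
#'
#' Splits each paralog pair into its lower-score and higher-score member,
#' giving the pooled "min" and "max" groups contrasted against singletons.
#'
#' @param divergence Tibble from [pair_divergence()].
#' @param singleton_scores Optional tibble (`gene`, score column named as in
#'   `score_col`) of singleton scores to pool in as a third group.
#' @param score_col Score column name used for singletons (default "nev").
#' @return Long tibble with columns `group` (`min`, `max`, `singleton`),
#'   `gene`, `score`; attribute `pairwise` holds the per-pair tibble with
#'   `score_min`, `score_max`.
#' @export
pair_min_max <- function(divergence, singleton_scores = NULL, score_col = "nev") {
  per_pair <- divergence |>
    dplyr::mutate(
      score_min = pmin(.data$score_a, .data$score_b),
      score_max = pmax(.data$score_a, .data$score_b),
      gene_min = ifelse(.data$score_a <= .data$score_b, .data$gene_a, .data$gene_b),
      gene_max = ifelse(.data$score_a <= .data$score_b, .data$gene_b, .data$gene_a)
    )
  pooled <- dplyr::bind_rows(
    tibble::tibble(group = "min", gene = per_pair$gene_min, score = per_pair$score_min),
    tibble::tibble(group = "max", gene = per_pair$gene_max, score = per_pair$score_max)
  )
  if (!is.null(singleton_scores)) {
    check_columns(singleton_scores, c("gene", score_col), "singleton scores")
    sing <- tibble::tibble(
      group = "singleton",
      gene = singleton_scores$gene,
      score = singleton_scores[[score_col]]
    )
    sing <- dplyr::filter(sing, !is.na(.data$score))
    pooled <- dplyr::bind_rows(pooled, sing)
  }
  attr(pooled, "pairwise") <- per_pair
  pooled
}

#' Select the top fraction of score-divergent pairs, deduplicated
#'
#' Within each value of `by` (typically duplication type), keeps the
#' `floor(fraction * n)` pairs with largest absolute divergence (ties broken
#' by pair id for determinism), then greedily deduplicates in descending
#' divergence order so no gene appears in two retained pairs.
#'
#' @param divergence Tibble from [pair_divergence()].
#' @param fraction Fraction of pairs to keep, in (0, 1].
#' @param by Column to select within (default `"mode"`; use a precomputed
#'   SSD/WGD column for pooled small-scale selection).
#' @return The selected rows of `divergence`; attribute `n_before_dedup`
#'   counts the selection prior to deduplication.
#' @export
select_top_divergent <- function(divergence, fraction = 0.05, by = "mode") {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort_validation("fraction must be in (0, 1]")
  }
  check_columns(divergence, c("abs_dscore", "pair_id", "gene_a", "gene_b", by),
    "pair divergence table")
  groups <- split(divergence, divergence[[by]])
  selected <- purrr::map_dfr(groups, function(g) {
    k <- floor(fraction * nrow(g))
    g <- dplyr::arrange(g, dplyr::desc(.data$abs_dscore), .data$pair_id)
    head(g, k)
  })
  n_before <- nrow(selected)
  selected <- dplyr::arrange(selected, dplyr::desc(.data$abs_dscore), .data$pair_id)
  seen <- character(0)
  keep <- logical(nrow(selected))
  for (i in seq_len(nrow(selected))) {
    gs <- c(selected$gene_a[i], selected$gene_b[i])
    if (!any(gs %in% seen)) {
      keep[i] <- TRUE
      seen <- c(seen, gs)
    }
  }
  out <- selected[keep, ]
  attr(out, "n_before_dedup") <- n_before
  out
}

#' Transcription-factor x duplication-mode contingency analysis
#'
#' Classifies each pair as TF (both members TFs) or non-TF (neither);
#' mixed pairs are excluded and counted. Pearson chi-squared without
#' continuity correction on the TF-status x mode table. Modes with no
#' pairs are dropped with a note; expected cells below 1 set a flag but
#' the statistic is still returned.
#'
#' @param pairs Paralog tibble.
#' @param meta Gene metadata with `gene`, `is_tf`.
#' @return One-row tibble: `statistic`, `df`, `p_value`,
#'   `n_mixed_excluded`, `min_expected`, `low_expected`; attribute
#'   `table` holds the contingency table.
#' @export
tf_contingency <- function(pairs, meta) {
  check_columns(meta, c("gene", "is_tf"), "gene metadata")
  tf <- setNames(meta$is_tf, meta$gene)
  a <- unname(tf[pairs$gene_a])
  b <- unname(tf[pairs$gene_b])
  status <- dplyr::case_when(a & b ~ "TF", !a & !b ~ "non-TF", TRUE ~ NA_character_)
  mixed <- sum(is.na(status) & !is.na(a) & !is.na(b))
  keep <- !is.na(status)
  tbl <- table(factor(status[keep], levels = c("TF", "non-TF")), pairs$mode[keep])
  empty <- colnames(tbl)[colSums(tbl) == 0]
  if (length(empty) > 0) {
    inform(sprintf("dropping mode(s) with no pairs: %s", paste(empty, collapse = ", ")))
    tbl <- tbl[, colSums(tbl) > 0, drop = FALSE]
  }
  test <- suppressWarnings(chisq.test(tbl, correct = FALSE))
  out <- tibble::tibble(
    statistic = unname(test$statistic),
    df = unname(test$parameter),
    p_value = test$p.value,
    n_mixed_excluded = mixed,
    min_expected = min(test$expected),
    low_expected = min(test$expected) < 1
  )
  attr(out, "table") <- tbl
  out
}

#' Derived/ancestral age asymmetry of pair divergence
#'
#' Within each duplication class, orients every pair so the derived copy
#' (strictly higher phylostratigraphic clade number, i.e. younger) comes
#' first; pairs with equal or missing clades are excluded. Reports (i) a
#' two-sided paired Wilcoxon signed-rank test of derived vs ancestral
#' scores with the median paired difference, and (ii) the Spearman
#' correlation between Delta-clade and Delta-score computed over both
#' orientations of every pair, which makes it sign-symmetric and invariant
#' to the arbitrary A/B labelling (its p-value is descriptive: the doubling
#' inflates nominal sample size).
#'
#' @param divergence Tibble from [pair_divergence()] with clade columns.
#' @param by Column defining the duplication classes (default `"mode"`).
#' @param min_pairs Below this many usable pairs the result is flagged
#'   `low_power` (still returned).
#' @return Tibble, one row per class: `group`, `n_pairs`,
#'   `n_excluded_ties`, `median_paired_diff`, `p_paired`, `rho`, `p_rho`,
#'   `low_power`.
#' @export
age_asymmetry <- function(divergence, by = "mode", min_pairs = 10) {
  check_columns(divergence, c("score_a", "score_b", "dclade", "dscore", by),
    "pair divergence table")
  divergence |>
    dplyr::group_by(group = .data[[by]]) |>
    dplyr::group_modify(function(g, key) {
      usable <- !is.na(g$dclade) & g$dclade != 0 &
        !is.na(g$score_a) & !is.na(g$score_b)
      n_excl <- sum(!is.na(g$dclade) & g$dclade == 0)
      g <- g[usable, ]
      n <- nrow(g)
      if (n == 0) {
        return(tibble::tibble(n_pairs = 0L, n_excluded_ties = n_excl,
          median_paired_diff = NA_real_, p_paired = NA_real_,
          rho = NA_real_, p_rho = NA_real_, low_power = TRUE))
      }
      derived <- ifelse(g$dclade > 0, g$score_a, g$score_b)
      ancestral <- ifelse(g$dclade > 0, g$score_b, g$score_a)
      p_paired <- if (n >= 2 && any(derived != ancestral)) {
        suppressWarnings(wilcox.test(derived, ancestral, paired = TRUE,
          alternative = "two.sided", exact = FALSE))$p.value
      } else {
        NA_real_
      }
      dd <- c(g$dclade, -g$dclade)
      dn <- c(g$dscore, -g$dscore)
      ct <- suppressWarnings(cor.test(dd, dn, method = "spearman", exact = FALSE))
      tibble::tibble(
        n_pairs = n, n_excluded_ties = n_excl,
        median_paired_diff = median(derived - ancestral),
        p_paired = p_paired,
        rho = unname(ct$estimate), p_rho = ct$p.value,
        low_power = n < min_pairs
      )
    }) |>
    dplyr::ungroup()
}

#' Validate clade-based derived/ancestral inference against synteny labels
#'
#' For transposed pairs whose parental/daughter copies are known from
#' synteny, tests whether daughter loci have higher clade numbers than
#' parental loci: paired Wilcoxon signed-rank, one-sided by default
#' (daughter > parent), ties (equal clades) dropped per the signed-rank
#' convention.
#'
#' @param pairs Paralog tibble with `orientation` labels.
#' @param meta Gene metadata with `gene`, `clade`.
#' @param alternative Test direction (default `"greater"`).
#' @return One-row tibble: `n_pairs`, `n_used` (non-tied), `p_value`,
#'   `median_diff` (daughter - parent clade), `alternative`.
#' @export
validate_synteny_orientation <- function(pairs, meta, alternative = "greater") {
  check_columns(pairs, c("gene_a", "gene_b", "mode", "orientation"), "paralog table")
  check_columns(meta, c("gene", "clade"), "gene metadata")
  lab <- dplyr::filter(pairs, .data$mode == "transposed",
    .data$orientation %in% c("A_is_parent", "B_is_parent"))
  if (nrow(lab) == 0) abort_validation("no transposed pairs with orientation labels")
  clade <- setNames(meta$clade, meta$gene)
  parent <- ifelse(lab$orientation == "A_is_parent",
    clade[lab$gene_a], clade[lab$gene_b])
  daughter <- ifelse(lab$orientation == "A_is_parent",
    clade[lab$gene_b], clade[lab$gene_a])
  ok <- !is.na(parent) & !is.na(daughter)
  parent <- parent[ok]
  daughter <- daughter[ok]
  if (length(parent) == 0) abort_validation("no labeled pairs with both clades present")
  test <- suppressWarnings(wilcox.test(daughter, parent, paired = TRUE,
    alternative = alternative, exact = FALSE))
  tibble::tibble(
    n_pairs = length(parent),
    n_used = sum(daughter != parent),
    p_value = test$p.value,
    median_diff = median(daughter - parent),
    alternative = alternative
  )
}
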