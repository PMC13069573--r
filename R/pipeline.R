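#' Run the full analysis on a synthetic design
#'
#' Generates every input from a seeded design, then executes the pipeline:
#' NEV (per-timepoint CV^2, loess trend, median NEV); environmental
#' responsiveness and tissue specificity from the atlas with their NEV
#' correlations; singleton/SSD/WGD group contrasts (rank-sum, BH-adjusted,
#' Cliff's delta); the within-pair min/max decomposition; top-divergent
#' pair selection with deduplication; semantic similarity of the selected
#' SSD vs WGD pairs; term enrichment of the high-NEV members of the
#' selected SSD pairs; the TF x mode contingency test; derived/ancestral
#' age asymmetry per duplication class; and the synteny orientation
#' validation.
#'
#' @param design A [simulation_design()].
#' @param top_fraction Fraction of most-divergent pairs selected per
#'   duplication class.
#' @param span Loess span for the mean-CV^2 trend.
#' @return A named list of result tibbles (class `nev_analysis`):
#'   `nev`, `phenotypes`, `nev_responsiveness`, `nev_tau`,
#'   `group_comparison`, `min_max_comparison`, `top_pairs`,
#'   `similarity_comparison`, `enrichment`, `tf_contingency`,
#'   `age_asymmetry`, `synteny_validation`, plus `truth` and the `design`.
#' @export
run_analysis <- function(design = simulation_design(), top_fraction = 0.05,
                         span = 0.3) {
  sim <- simulate_panel(design)
  atlas <- simulate_atlas(design, sim$truth)
  meta_out <- simulate_meta(design, sim$truth)
  meta <- meta_out$meta
  pairs <- meta_out$pairs
  ont <- ontology_ic(meta_out$ontology$edges, meta_out$ontology$annotations)

  nev <- compute_nev(sim$panel, span = span)
  resp <- responsiveness(atlas, ecotype = "Col-0", tissue = "seedling")
  taus <- atlas_tau(atlas)
  phen <- nev |>
    dplyr::left_join(resp, by = "gene") |>
    dplyr::left_join(taus, by = "gene")
  nev_resp <- correlate(phen, nev, responsiveness, method = "spearman")
  nev_tau <- correlate(phen, nev, tau, method = "spearman")

  scores <- dplyr::left_join(nev, dplyr::select(meta, "gene", "status"), by = "gene")
  comparison <- compare_groups(scores, nev, status,
    contrasts = list(c("ssd", "singleton"), c("wgd", "singleton"), c("ssd", "wgd")))

  div <- pair_divergence(pairs, nev, meta = meta)
  div$dup_class <- ifelse(div$mode == "wgd", "wgd", "ssd")
  singles <- dplyr::filter(scores, .data$status == "singleton")
  pooled <- pair_min_max(div, singleton_scores = singles)
  minmax <- compare_groups(pooled, score, group,
    contrasts = list(c("max", "singleton"), c("singleton", "min"), c("max", "min")))

  top <- select_top_divergent(div, fraction = top_fraction, by = "dup_class")
  top_sim <- pair_semantic_similarity(top, ont)
  sim_cmp <- compare_divergent_similarity(
    dplyr::filter(top_sim, .data$dup_class == "ssd"),
    dplyr::filter(top_sim, .data$dup_class == "wgd")
  )

  top_ssd <- dplyr::filter(top, .data$dup_class == "ssd")
  high_genes <- ifelse(top_ssd$score_a >= top_ssd$score_b,
    top_ssd$gene_a, top_ssd$gene_b)
  enrichment <- enrich_terms(high_genes, meta$gene, ont)

  tf <- tf_contingency(pairs, meta)
  asym <- age_asymmetry(div, by = "dup_class")
  synteny <- validate_synteny_orientation(pairs, meta)

  structure(
    list(
      nev = nev, phenotypes = phen,
      nev_responsiveness = nev_resp, nev_tau = nev_tau,
      group_comparison = comparison, min_max_comparison = minmax,
      top_pairs = top_sim, similarity_comparison = sim_cmp,
      enrichment = enrichment, tf_contingency = tf,
      age_asymmetry = asym, synteny_validation = synteny,
      truth = sim$truth, design = design
    ),
    class = "nev_analysis"
  )
}

#' @export
print.nev_analysis <- function(x, ...) {
  cat("<nev_analysis>\n")
  cat(sprintf("  genes: %d (NEV defined for %d)\n",
    nrow(x$nev), sum(!is.na(x$nev$nev))))
  cat("  group contrasts (score = NEV):\n")
  cmp <- x$group_comparison
  for (i in seq_len(nrow(cmp))) {
    cat(sprintf("    %s vs %s: delta = %+.3f [%.3f, %.3f], adj. p = %.3g\n",
      cmp$group1[i], cmp$group2[i], cmp$delta[i], cmp$delta_low[i],
      cmp$delta_high[i], cmp$p_adjusted[i]))
  }
  cat(sprintf("  NEV-responsiveness: rho = %.3f (p = %.3g)\n",
    x$nev_responsiveness$estimate, x$nev_responsiveness$p_value))
  asym <- x$age_asymmetry
  for (i in seq_len(nrow(asym))) {
    cat(sprintf("  age asymmetry [%s]: median derived-ancestral = %+.3f (p = %.3g, n = %d)\n",
      asym$group[i], asym$median_paired_diff[i], asym$p_paired[i], asym$n_pairs[i]))
  }
  invisible(x)
}
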