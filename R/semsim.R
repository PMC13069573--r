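#' Build an ontology index with information content
#'
#' Validates the edge set (single root, acyclic), computes the ancestor
#' closure of every term, propagates gene annotations to ancestors (true
#' path rule), and derives each term's information content:
#' `IC(t) = -log p(t)` where `p(t)` is the fraction of annotated genes
#' whose (propagated) annotations include `t`, normalized to `[0, 1]` by
#' the maximum IC over annotated terms. The root has IC 0; terms annotated
#' to no gene have undefined IC and are excluded from similarity.
#'
#' @param edges Tibble with columns `child`, `parent` (is_a edges).
#' @param annotations Tibble with columns `gene`, `term`.
#' @return An `ontology_ic` object.
#' @export
ontology_ic <- function(edges, annotations) {
  check_columns(edges, c("child", "parent"), "ontology edges")
  check_columns(annotations, c("gene", "term"), "ontology annotations")
  validate_ontology_edges(edges)
  terms <- union(edges$child, edges$parent)
  bad <- setdiff(unique(annotations$term), terms)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "annotated term(s) absent from the ontology: %s",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  parents <- split(edges$parent, edges$child)

  ancestors <- vector("list", length(terms))
  names(ancestors) <- terms
  get_anc <- function(t) {
    if (!is.null(ancestors[[t]])) return(ancestors[[t]])
    ps <- parents[[t]]
    anc <- if (is.null(ps)) t else unique(c(t, unlist(lapply(ps, get_anc))))
    ancestors[[t]] <<- anc
    anc
  }
  for (t in terms) get_anc(t)

  gene_terms <- split(annotations$term, annotations$gene)
  gene_terms <- lapply(gene_terms, unique)
  n_genes <- length(gene_terms)
  counts <- setNames(integer(length(terms)), terms)
  for (ts in gene_terms) {
    closed <- unique(unlist(ancestors[ts], use.names = FALSE))
    counts[closed] <- counts[closed] + 1L
  }
  p <- ifelse(counts > 0, counts / n_genes, NA_real_)
  ic_raw <- -log(p)
  max_ic <- suppressWarnings(max(ic_raw, na.rm = TRUE))
  ic <- if (is.finite(max_ic) && max_ic > 0) ic_raw / max_ic else ic_raw * 0

  structure(
    list(
      terms = terms,
      parents = parents,
      ancestors = ancestors,
      gene_terms = gene_terms,
      n_annotated_genes = n_genes,
      ic_table = tibble::tibble(
        term = terms, n_genes = unname(counts),
        p = unname(p), ic_raw = unname(ic_raw), ic = unname(ic)
      ),
      ic = setNames(unname(ic), terms)
    ),
    class = "ontology_ic"
  )
}

#' @export
print.ontology_ic <- function(x, ...) {
  cat(sprintf("<ontology_ic> %d terms, %d annotated genes\n",
    length(x$terms), x$n_annotated_genes))
  invisible(x)
}

#' Information-content table
#'
#' @param ontology An `ontology_ic`, or a tibble of edges (then
#'   `annotations` is required).
#' @param annotations Annotation tibble when `ontology` is an edge table.
#' @return Tibble with `term`, `n_genes`, `p`, `ic_raw`, `ic` (normalized).
#' @export
information_content <- function(ontology, annotations = NULL) {
  if (!inherits(ontology, "ontology_ic")) {
    ontology <- ontology_ic(ontology, annotations)
  }
  ontology$ic_table
}

# Most informative common ancestor: maximum normalized IC over the
# intersection of the two ancestor closures (terms with defined IC only).
mica_ic <- function(ont, t1, t2) {
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  ics <- ont$ic[common]
  ics <- ics[!is.na(ics)]
  if (length(ics) == 0) return(NA_real_)
  max(ics)
}

#' Semantic similarity between two terms
#'
#' The Jiang-Conrath-style distance is
#' `d = IC(t1) + IC(t2) - 2 * IC(MICA)` on normalized IC; the default
#' similarity is `1 - min(1, d)`, bounded in `[0, 1]`. `"jiang_ratio"`
#' gives the alternative `1 / (1 + d)` form; `"resnik"` returns the
#' normalized IC of the MICA.
#'
#' @param ont An [ontology_ic()] index.
#' @param t1,t2 Term ids.
#' @param measure Similarity form.
#' @return Similarity in `[0, 1]` (`NA` if either term lacks IC).
#' @export
term_similarity <- function(ont, t1, t2,
                            measure = c("jiang", "jiang_ratio", "resnik")) {
  measure <- match.arg(measure)
  if (!t1 %in% ont$terms || !t2 %in% ont$terms) {
    abort_validation("both terms must be in the ontology")
  }
  ic1 <- ont$ic[[t1]]
  ic2 <- ont$ic[[t2]]
  if (is.na(ic1) || is.na(ic2)) return(NA_real_)
  mica <- mica_ic(ont, t1, t2)
  if (is.na(mica)) return(NA_real_)
  if (measure == "resnik") return(mica)
  d <- ic1 + ic2 - 2 * mica
  if (measure == "jiang") 1 - min(1, d) else 1 / (1 + d)
}

#' Gene-pair semantic similarity (best-match average)
#'
#' Computes the term-by-term similarity matrix between the two genes'
#' annotation sets and combines it by the best-match average: the mean of
#' each A-term's best similarity against B and each B-term's best against
#' A, averaged. Genes without usable annotations give `NA`.
#'
#' @param ont An [ontology_ic()] index.
#' @param gene_a,gene_b Gene ids (annotations looked up in the index).
#' @param measure Term-similarity form (see [term_similarity()]).
#' @return Similarity in `[0, 1]`, or `NA`.
#' @export
gene_similarity <- function(ont, gene_a, gene_b, measure = "jiang") {
  ta <- ont$gene_terms[[gene_a]]
  tb <- ont$gene_terms[[gene_b]]
  ta <- ta[!is.na(ont$ic[ta])]
  tb <- tb[!is.na(ont$ic[tb])]
  if (length(ta) == 0 || length(tb) == 0) return(NA_real_)
  simmat <- matrix(NA_real_, length(ta), length(tb))
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      simmat[i, j] <- term_similarity(ont, ta[i], tb[j], measure = measure)
    }
  }
  (mean(apply(simmat, 1, max)) + mean(apply(simmat, 2, max))) / 2
}

#' Semantic similarity for a table of paralog pairs
#'
#' @param pairs Tibble with `gene_a`, `gene_b` (extra columns carried
#'   through).
#' @param ont An [ontology_ic()] index.
#' @param measure Term-similarity form.
#' @return `pairs` with a `similarity` column; pairs with an unannotated
#'   member get `NA` and are counted in attribute `n_excluded`.
#' @export
pair_semantic_similarity <- function(pairs, ont, measure = "jiang") {
  check_columns(pairs, c("gene_a", "gene_b"), "pair table")
  sims <- purrr::map2_dbl(pairs$gene_a, pairs$gene_b, function(a, b) {
    if (is.null(ont$gene_terms[[a]]) || is.null(ont$gene_terms[[b]])) {
      return(NA_real_)
    }
    gene_similarity(ont, a, b, measure = measure)
  })
  out <- dplyr::mutate(pairs, similarity = sims)
  attr(out, "n_excluded") <- sum(is.na(sims))
  out
}

#' Hypergeometric term enrichment with FDR control
#'
#' One-sided hypergeometric upper-tail test per term: the probability of
#' seeing at least the observed number of study genes annotated (after
#' ancestor propagation) to the term, given the background frequency. Only
#' terms with at least `min_term_size` annotated background genes are
#' tested; Benjamini-Hochberg FDR is computed across the tested terms; the
#' result keeps terms at or below the FDR threshold, sorted by fold
#' enrichment (`(k/n) / (K/N)`).
#'
#' @param study Character vector of study genes (must be a subset of the
#'   background).
#' @param background Character vector of background genes.
#' @param ont An [ontology_ic()] index carrying the annotations.
#' @param min_term_size Minimum annotated background genes per tested term.
#' @param fdr FDR threshold for the reported terms.
#' @return Tibble with `term`, `k_study`, `n_study`, `k_background`,
#'   `n_background`, `fold_enrichment`, `p_value`, `fdr`; attribute
#'   `all_terms` holds the unfiltered tested table.
#' @export
enrich_terms <- function(study, background, ont, min_term_size = 10, fdr = 0.05) {
  study <- unique(study)
  background <- unique(background)
  offenders <- setdiff(study, background)
  if (length(offenders) > 0) {
    abort_validation(sprintf(
      "study gene(s) not in the background: %s",
      paste(head(offenders, 5), collapse = ", ")
    ))
  }
  closed <- function(genes) {
    ts <- ont$gene_terms[genes]
    ts <- ts[!vapply(ts, is.null, logical(1))]
    if (length(ts) == 0) {
      return(tibble::tibble(gene = character(0), term = character(0)))
    }
    tibble::tibble(
      gene = rep(names(ts), vapply(ts, function(t) {
        length(unique(unlist(ont$ancestors[t], use.names = FALSE)))
      }, integer(1))),
      term = unlist(lapply(ts, function(t) {
        unique(unlist(ont$ancestors[t], use.names = FALSE))
      }), use.names = FALSE)
    )
  }
  bg_anno <- closed(background)
  st_anno <- closed(study)
  N <- length(unique(bg_anno$gene))
  n <- length(unique(st_anno$gene))
  K <- table(bg_anno$term)
  K <- K[K >= min_term_size]
  if (length(K) == 0 || n == 0) {
    out <- tibble::tibble(term = character(0), k_study = integer(0),
      n_study = integer(0), k_background = integer(0), n_background = integer(0),
      fold_enrichment = numeric(0), p_value = numeric(0), fdr = numeric(0))
    attr(out, "all_terms") <- out
    return(out)
  }
  k <- table(factor(st_anno$term, levels = names(K)))
  res <- tibble::tibble(
    term = names(K),
    k_study = as.integer(k),
    n_study = n,
    k_background = as.integer(K),
    n_background = N,
    fold_enrichment = (as.integer(k) / n) / (as.integer(K) / N),
    p_value = phyper(as.integer(k) - 1L, as.integer(K), N - as.integer(K), n,
      lower.tail = FALSE)
  )
  res$fdr <- p.adjust(res$p_value, method = "BH")
  out <- res |>
    dplyr::filter(.data$fdr <= !!fdr) |>
    dplyr::arrange(dplyr::desc(.data$fold_enrichment))
  attr(out, "all_terms") <- res
  out
}

#' Compare semantic similarity between two sets of divergent pairs
#'
#' Rank-sum comparison (plus Cliff's delta) of the pair-similarity samples
#' of two duplication classes -- e.g. the most NEV-divergent SSD pairs vs
#' WGD pairs.
#'
#' @param sim_a,sim_b Numeric similarity vectors, or tibbles with a
#'   `similarity` column.
#' @param labels Length-2 character labels for the two groups.
#' @param conf_level Confidence level for the delta CI.
#' @return One-row tibble in the [compare_groups()] format.
#' @export
compare_divergent_similarity <- function(sim_a, sim_b,
                                         labels = c("ssd", "wgd"),
                                         conf_level = 0.95) {
  pull_sim <- function(s) if (is.data.frame(s)) s$similarity else s
  a <- pull_sim(sim_a)
  b <- pull_sim(sim_b)
  data <- tibble::tibble(
    score = c(a, b),
    group = rep(labels, c(length(a), length(b)))
  )
  compare_groups(data, score, group, contrasts = list(labels),
    conf_level = conf_level)
}
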