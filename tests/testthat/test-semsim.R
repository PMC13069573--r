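# A small hand-built tree used across tests:
#
#   root -- a -- a1
#        |    \- a2
#        \- b -- b1
#
# 10 annotated genes: 5 at a1, 3 at a2, 2 at b1, so after propagation
# p(a) = 8/10, p(b) = 2/10, p(root) = 1.
toy_ontology <- function() {
  edges <- tibble::tibble(
    child = c("a", "b", "a1", "a2", "b1"),
    parent = c("root", "root", "a", "a", "b")
  )
  anno <- tibble::tibble(
    gene = sprintf("g%02d", 1:10),
    term = c(rep("a1", 5), rep("a2", 3), rep("b1", 2))
  )
  ontology_ic(edges, anno)
}

test_that("information content follows the annotation-frequency definition", {
  ont <- toy_ontology()
  ic <- information_content(ont)
  get <- function(t, col) ic[[col]][ic$term == t]
  # root covers every annotated gene
  expect_equal(get("root", "p"), 1)
  expect_equal(get("root", "ic"), 0)
  # propagation: a1-annotated genes count for a and root (true-path rule)
  expect_equal(get("a", "n_genes"), 8)
  expect_equal(get("b", "p"), 0.2)
  # the rarest annotated term(s) carry normalized IC 1
  expect_equal(max(ic$ic, na.rm = TRUE), 1)
  expect_equal(get("b1", "ic"), 1)
})

test_that("Jiang similarity matches hand computation on the toy tree", {
  ont <- toy_ontology()
  ic <- setNames(ont$ic_table$ic, ont$ic_table$term)
  # identity
  expect_equal(term_similarity(ont, "a1", "a1"), 1)
  # hand-computed: MICA(a1, a2) = a
  d12 <- ic[["a1"]] + ic[["a2"]] - 2 * ic[["a"]]
  expect_equal(term_similarity(ont, "a1", "a2"), 1 - min(1, d12))
  # across the root: MICA(a1, b1) = root with IC 0
  d1b <- ic[["a1"]] + ic[["b1"]]
  expect_equal(term_similarity(ont, "a1", "b1"), 1 - min(1, d1b))
  # two maximal-IC leaves whose MICA is the root -> distance >= 1 -> similarity 0
  expect_equal(term_similarity(ont, "b1", "b1"), 1)
  expect_gte(1, term_similarity(ont, "a1", "b1"))
  # the alternative ratio form stays in (0, 1]
  r <- term_similarity(ont, "a1", "a2", measure = "jiang_ratio")
  expect_true(r > 0 && r <= 1)
  # Resnik is the normalized MICA IC
  expect_equal(term_similarity(ont, "a1", "a2", measure = "resnik"), ic[["a"]])
})

test_that("MICA equals brute-force common-ancestor search on random trees", {
  set.seed(41)
  for (rep in 1:10) {
    d <- tiny_design(seed = 41L + rep, n_terms = 50)
    s <- simulate_panel(d)
    m <- simulate_meta(d, s$truth)
    ont <- ontology_ic(m$ontology$edges, m$ontology$annotations)
    ic <- setNames(ont$ic_table$ic, ont$ic_table$term)
    terms <- sample(ont$terms, 12)
    for (i in seq(1, 11, by = 2)) {
      t1 <- terms[i]
      t2 <- terms[i + 1]
      expect_equal(
        nevar:::mica_ic(ont, t1, t2),
        brute_mica_ic(m$ontology$edges, ic, t1, t2)
      )
    }
  }
})

test_that("similarity is symmetric, bounded and 1 on identical annotation sets", {
  ont <- toy_ontology()
  # identical term sets -> BMA 1; singleton identity
  expect_equal(gene_similarity(ont, "g01", "g02"), 1)
  # A = {t1}, B = {t2} reduces to the term similarity
  expect_equal(
    gene_similarity(ont, "g01", "g09"),
    term_similarity(ont, "a1", "b1")
  )
  # symmetry over all annotated pairs
  genes <- names(ont$gene_terms)
  for (i in 1:5) {
    g1 <- sample(genes, 1)
    g2 <- sample(genes, 1)
    s12 <- gene_similarity(ont, g1, g2)
    expect_equal(s12, gene_similarity(ont, g2, g1))
    expect_true(s12 >= 0 && s12 <= 1)
  }
})

test_that("pair similarity excludes unannotated genes and counts them", {
  ont <- toy_ontology()
  pairs <- tibble::tibble(
    gene_a = c("g01", "g01"), gene_b = c("g02", "nope"), mode = "tandem"
  )
  res <- pair_semantic_similarity(pairs, ont)
  expect_equal(res$similarity[1], 1)
  expect_true(is.na(res$similarity[2]))
  expect_equal(attr(res, "n_excluded"), 1)
})

test_that("hypergeometric p equals the exact tail sum on small universes", {
  set.seed(42)
  for (i in 1:50) {
    N <- sample(10:60, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    exact <- sum(stats::dhyper(k:min(K, n), K, N - K, n))
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE), exact,
      tolerance = 1e-12)
  }
})

test_that("enrichment applies the term-size filter, FDR threshold and fold sort", {
  ont <- toy_ontology()
  # study: both b1 genes plus three a1 genes
  study <- c("g09", "g10", "g01", "g02", "g03")
  res <- enrich_terms(study, sprintf("g%02d", 1:10), ont, min_term_size = 2, fdr = 1)
  all_terms <- attr(res, "all_terms")
  # a term covering the entire background cannot be enriched: p = 1
  expect_equal(all_terms$p_value[all_terms$term == "root"], 1)
  # b1: k=2, K=2, n=5, N=10 -> closed-form tail
  expect_equal(
    all_terms$p_value[all_terms$term == "b1"],
    stats::dhyper(2, 2, 8, 5)
  )
  expect_equal(all_terms$fold_enrichment[all_terms$term == "b1"], (2 / 5) / (2 / 10))
  expect_true(all(all_terms$fdr >= all_terms$p_value))
  # terms below the size filter are not tested
  res10 <- enrich_terms(study, sprintf("g%02d", 1:10), ont, min_term_size = 9)
  expect_false("b1" %in% attr(res10, "all_terms")$term)
  # fold-enrichment sort on the reported rows
  expect_true(all(diff(res$fold_enrichment) <= 1e-12))
  # study must be a subset of the background
  expect_error(enrich_terms(c("g01", "zz"), sprintf("g%02d", 1:10), ont),
    class = "nevar_validation_error", regexp = "zz")
})

test_that("planted annotation divergence separates SSD from WGD pair similarity", {
  d <- simulation_design(n_singletons = 50, n_ssd_pairs = 100, n_wgd_pairs = 100,
    n_individuals = 4, n_timepoints = 2, seed = 43L)
  s <- simulate_panel(d)
  m <- simulate_meta(d, s$truth)
  ont <- ontology_ic(m$ontology$edges, m$ontology$annotations)
  sims <- pair_semantic_similarity(m$pairs, ont)
  ssd <- sims$similarity[sims$mode != "wgd"]
  wgd <- sims$similarity[sims$mode == "wgd"]
  cmp <- compare_divergent_similarity(ssd, wgd)
  expect_lt(cmp$p_value, 0.05)
  expect_lt(cmp$delta, 0)
  expect_lt(median(ssd, na.rm = TRUE), median(wgd, na.rm = TRUE))
})

test_that("identical annotation rules for both modes give no similarity difference", {
  # re-annotate every paired gene from the full leaf set, ignoring mode
  d <- simulation_design(n_singletons = 20, n_ssd_pairs = 80, n_wgd_pairs = 80,
    n_individuals = 4, n_timepoints = 2, seed = 44L)
  s <- simulate_panel(d)
  m <- simulate_meta(d, s$truth)
  edges <- m$ontology$edges
  leaves <- setdiff(unique(edges$child), unique(edges$parent))
  set.seed(45)
  genes <- c(m$pairs$gene_a, m$pairs$gene_b)
  anno <- tibble::tibble(
    gene = rep(genes, each = 3),
    term = unlist(lapply(genes, function(g) sample(leaves, 3)))
  )
  ont <- ontology_ic(edges, anno)
  sims <- pair_semantic_similarity(m$pairs, ont)
  cmp <- compare_divergent_similarity(
    sims$similarity[sims$mode != "wgd"],
    sims$similarity[sims$mode == "wgd"]
  )
  expect_gt(cmp$p_value, 0.05)
})
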