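test_that("Cliff's delta matches the brute-force oracle on random instances", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    m <- sample(3:25, 1)
    # integer values force ties into the mix
    x <- sample(0:10, n, replace = TRUE)
    y <- sample(0:10, m, replace = TRUE)
    expect_equal(cliffs_delta(x, y)$estimate, brute_cliffs_delta(x, y))
  }
})

test_that("Cliff's delta hits its anchors and symmetry", {
  # identical samples: delta 0, rank-sum p 1
  x <- c(1, 2, 3, 4)
  cd <- cliffs_delta(x, x)
  expect_equal(cd$estimate, 0)
  expect_equal(suppressWarnings(
    wilcox.test(x, x, exact = FALSE))$p.value, 1)
  # complete separation
  expect_equal(cliffs_delta(c(10, 11, 12), c(1, 2, 3))$estimate, 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(10, 11, 12))$estimate, -1)
  # antisymmetry and bounds on random data
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(15)
    b <- rnorm(20, 0.5)
    da <- cliffs_delta(a, b)
    db <- cliffs_delta(b, a)
    expect_equal(da$estimate, -db$estimate)
    expect_true(abs(da$estimate) <= 1)
    expect_true(da$ci_low <= da$estimate && da$estimate <= da$ci_high)
  }
})

test_that("group comparison adjusts p-values monotonically and names empty groups", {
  set.seed(13)
  data <- tibble::tibble(
    score = c(rnorm(50), rnorm(50, 1), rnorm(50, 2)),
    group = rep(c("a", "b", "c"), each = 50)
  )
  res <- compare_groups(data, score, group)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$delta >= res$delta_low & res$delta <= res$delta_high))

  bad <- tibble::tibble(score = rnorm(5), group = c("a", "a", "a", "a", "b"))
  expect_error(compare_groups(bad, score, group, contrasts = list(c("a", "b"))),
    class = "nevar_validation_error", regexp = "'b'")
})

test_that("BH adjustment never decreases a p-value and keeps order", {
  p <- c(0.001, 0.02, 0.04, 0.9)
  adj <- p.adjust(p, "BH")
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("planted-shift recovery: delta CI covers the true effect", {
  # shift chosen so the true delta of two unit-variance normals is 0.30
  shift <- sqrt(2) * qnorm((0.30 + 1) / 2)
  set.seed(14)
  covered <- replicate(100, {
    x <- rnorm(1000, shift)
    y <- rnorm(1000)
    cd <- cliffs_delta(x, y)
    cd$ci_low <= 0.30 && 0.30 <= cd$ci_high
  })
  expect_gte(mean(covered), 0.90)
})

test_that("pair min/max decomposition preserves counts and ordering", {
  scores <- tibble::tibble(gene = c("a1", "a2", "b1", "b2", "c1", "c2"),
    nev = c(1.0, -0.5, 0.3, 0.3, NA, 2))
  pairs <- tibble::tibble(gene_a = c("a1", "b1", "c1"),
    gene_b = c("a2", "b2", "c2"), mode = "tandem")
  div <- pair_divergence(pairs, scores)
  expect_equal(attr(div, "n_excluded"), 1)
  pooled <- pair_min_max(div)
  per_pair <- attr(pooled, "pairwise")
  expect_equal(per_pair$score_min[1], -0.5)
  expect_equal(per_pair$score_max[1], 1.0)
  expect_equal(per_pair$score_min[2], per_pair$score_max[2])
  # n pairs in -> n values in each pooled group
  expect_equal(sum(pooled$group == "min"), 2)
  expect_equal(sum(pooled$group == "max"), 2)
  expect_true(all(per_pair$score_max >= per_pair$score_min))
})

test_that("top-divergence selection counts, deduplicates and breaks ties deterministically", {
  div <- tibble::tibble(
    pair_id = sprintf("p%03d", 1:100),
    gene_a = sprintf("ga%03d", 1:100),
    gene_b = sprintf("gb%03d", 1:100),
    mode = "tandem",
    abs_dscore = seq(1, 0.01, length.out = 100)
  )
  sel <- select_top_divergent(div, fraction = 0.05)
  expect_equal(nrow(sel), 5)
  expect_equal(sel$pair_id, sprintf("p%03d", 1:5))

  # shared gene: the weaker pair is dropped
  shared <- div[1:10, ]
  shared$gene_a[2] <- shared$gene_a[1]
  sel2 <- select_top_divergent(shared, fraction = 1)
  expect_false("p002" %in% sel2$pair_id)
  expect_equal(attr(sel2, "n_before_dedup"), 10)

  # all equal divergences: deterministic id-ordered prefix
  ties <- dplyr::mutate(div, abs_dscore = 0.5)
  sel3 <- select_top_divergent(ties, fraction = 0.1)
  expect_equal(sel3$pair_id, sprintf("p%03d", 1:10))

  expect_error(select_top_divergent(div, fraction = 0),
    class = "nevar_validation_error")
})

test_that("TF contingency matches the hand-computed chi-squared", {
  # 2x2 table [[10,90],[50,50]]
  pairs <- tibble::tibble(
    gene_a = sprintf("a%03d", 1:200), gene_b = sprintf("b%03d", 1:200),
    mode = rep(c("tandem", "wgd"), each = 100)
  )
  tf_a <- c(rep(TRUE, 10), rep(FALSE, 90), rep(TRUE, 50), rep(FALSE, 50))
  meta <- tibble::tibble(
    gene = c(pairs$gene_a, pairs$gene_b),
    is_tf = c(tf_a, tf_a)
  )
  res <- tf_contingency(pairs, meta)
  O <- matrix(c(10, 90, 50, 50), 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E))
  expect_equal(res$df, 1)

  # mixed pairs excluded and counted
  meta$is_tf[meta$gene == "b001"] <- FALSE
  res2 <- tf_contingency(pairs, meta)
  expect_equal(res2$n_mixed_excluded, 1)

  # a mode with no pairs is dropped with a note
  pairs3 <- dplyr::mutate(pairs, mode = ifelse(mode == "wgd", "tandem", mode))
  expect_message(tf_contingency(pairs3, meta), regexp = NA)
  expect_equal(ncol(attr(tf_contingency(pairs3, meta), "table")), 1)
})

test_that("age asymmetry recovers planted derived inflation and stays orientation invariant", {
  d <- simulation_design(n_singletons = 20, n_ssd_pairs = 300, n_wgd_pairs = 300,
    n_individuals = 10, n_timepoints = 3, seed = 15L)
  s <- simulate_panel(d)
  m <- simulate_meta(d, s$truth)
  nev <- compute_nev(s$panel)
  div <- pair_divergence(m$pairs, nev, meta = m$meta)
  div$dup_class <- ifelse(div$mode == "wgd", "wgd", "ssd")
  res <- age_asymmetry(div, by = "dup_class")
  ssd <- res[res$group == "ssd", ]
  wgd <- res[res$group == "wgd", ]
  expect_gt(ssd$median_paired_diff, 0)
  expect_lt(ssd$p_paired, 0.05)
  expect_lt(abs(wgd$median_paired_diff), 0.25)

  # flipping every A/B label leaves the results identical
  flipped <- div |>
    dplyr::mutate(
      tmp = gene_a, gene_a = gene_b, gene_b = tmp,
      tmp2 = score_a, score_a = score_b, score_b = tmp2,
      tmp3 = clade_a, clade_a = clade_b, clade_b = tmp3,
      dclade = -dclade, dscore = -dscore
    )
  res_flip <- age_asymmetry(flipped, by = "dup_class")
  expect_equal(res_flip$median_paired_diff, res$median_paired_diff)
  expect_equal(res_flip$p_paired, res$p_paired)
  expect_equal(res_flip$rho, res$rho)
})

test_that("shuffled orientation labels give a null synteny validation", {
  d <- simulation_design(n_singletons = 10, n_ssd_pairs = 400, n_wgd_pairs = 5,
    n_individuals = 4, n_timepoints = 2,
    orientation_consistency = 1, tie_fraction = 0, seed = 16L)
  s <- simulate_panel(d)
  m <- simulate_meta(d, s$truth)
  res <- validate_synteny_orientation(m$pairs, m$meta)
  expect_lt(res$p_value, 1e-4)

  set.seed(17)
  lab <- m$pairs$orientation != "unknown"
  ps <- replicate(100, {
    shuffled <- m$pairs
    shuffled$orientation[lab] <- sample(c("A_is_parent", "B_is_parent"),
      sum(lab), replace = TRUE)
    validate_synteny_orientation(shuffled, m$meta)$p_value
  })
  # under shuffled labels the one-sided p is approximately uniform
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  no_labels <- dplyr::mutate(m$pairs, orientation = "unknown")
  expect_error(validate_synteny_orientation(no_labels, m$meta),
    class = "nevar_validation_error")
})
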