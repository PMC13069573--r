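make_panel <- function(values_by_gene, timepoint = "T1") {
  purrr::imap_dfr(values_by_gene, function(v, g) {
    tibble::tibble(
      gene = g,
      individual = sprintf("I%02d", seq_along(v)),
      timepoint = timepoint,
      value = v
    )
  })
}

test_that("per-timepoint statistics match hand arithmetic", {
  panel <- make_panel(list(
    constant = c(5, 5, 5, 5),
    hand = c(1, 2, 3),
    small = c(2, 4),
    scaled = c(20, 40)
  ))
  stats <- panel_stats(panel)
  get <- function(g, col) stats[[col]][stats$gene == g]
  expect_equal(get("constant", "mean"), 5)
  expect_equal(get("constant", "cv2"), 0)
  # unbiased variance of 1,2,3 is 1; cv2 = 1/4
  expect_equal(get("hand", "mean"), 2)
  expect_equal(get("hand", "cv2"), 0.25)
  # CV2 is scale invariant
  expect_equal(get("small", "cv2"), get("scaled", "cv2"))
})

test_that("genes below the individual threshold are flagged missing, not dropped", {
  panel <- make_panel(list(ok = c(1, 2, 3), short = c(4, NA, NA)))
  stats <- panel_stats(panel, min_individuals = 2)
  expect_equal(nrow(stats), 2)
  expect_true(is.na(stats$cv2[stats$gene == "short"]))
  expect_equal(stats$n_used[stats$gene == "short"], 1)
})

test_that("trend fit recovers a closed-form cv2 = 10/mean law within 5%", {
  means <- 2^seq(1, 12, length.out = 400)
  stats <- tibble::tibble(
    gene = sprintf("g%03d", seq_along(means)), timepoint = "T1",
    mean = means, var = NA_real_, cv2 = 10 / means, n_used = 14L
  )
  trend <- fit_cv2_trend(stats)
  interior <- quantile(log2(means), c(0.05, 0.95))
  grid <- seq(interior[1], interior[2], length.out = 50)
  fitted_cv2 <- 2^predict_trend(trend, grid)
  truth <- 10 / 2^grid
  expect_true(all(abs(fitted_cv2 / truth - 1) < 0.05))
})

test_that("a flat cv2 profile yields a flat trend and doubling means shifts the trend", {
  means <- 2^seq(1, 10, length.out = 200)
  flat <- tibble::tibble(gene = as.character(seq_along(means)), timepoint = "T1",
    mean = means, var = NA_real_, cv2 = 0.5, n_used = 14L)
  trend <- fit_cv2_trend(flat)
  fits <- predict_trend(trend, seq(1.5, 9.5, length.out = 20))
  expect_true(all(abs(fits - log2(0.5)) < 1e-6))

  wiggly_cv2 <- 10 / means + 0.05
  s1 <- dplyr::mutate(flat, cv2 = wiggly_cv2)
  s2 <- dplyr::mutate(flat, mean = 2 * means, cv2 = wiggly_cv2)
  t1 <- fit_cv2_trend(s1)
  t2 <- fit_cv2_trend(s2)
  grid <- seq(2, 9, length.out = 25)
  expect_true(all(abs(predict_trend(t2, grid + 1) - predict_trend(t1, grid)) < 1e-6))
})

test_that("too few usable points is a fit error with guidance", {
  stats <- tibble::tibble(gene = c("a", "b"), timepoint = "T1",
    mean = c(10, 20), var = NA_real_, cv2 = c(0.1, 0.2), n_used = 5L)
  expect_error(fit_cv2_trend(stats), class = "nevar_fit_error", regexp = "pool")
})

test_that("NEV follows its definition: trend residual in log2 space, median summary", {
  means <- 2^seq(1, 10, length.out = 300)
  stats <- tibble::tibble(gene = as.character(seq_along(means)), timepoint = "T1",
    mean = means, var = NA_real_, cv2 = 10 / means, n_used = 14L)
  trend <- fit_cv2_trend(stats)
  interior_mean <- 2^5
  on_trend <- 2^predict_trend(trend, log2(interior_mean))
  # cv2 exactly on the trend -> NEV 0; cv2 at 4x the trend -> NEV 2
  expect_equal(log2(on_trend) - predict_trend(trend, log2(interior_mean)), 0)
  expect_equal(log2(4 * on_trend) - predict_trend(trend, log2(interior_mean)), 2)
  # median over per-timepoint NEVs
  expect_equal(median(c(-1, 0, 3)), 0)
})

test_that("cv2 = 0 gives a missing NEV, never -Inf, and the summary respects min_timepoints", {
  d <- tiny_design(seed = 21L)
  s <- simulate_panel(d)
  panel <- s$panel
  # force one gene constant at every timepoint
  g0 <- s$truth$gene[1]
  panel$value[panel$gene == g0] <- 7
  nev <- compute_nev(panel)
  by_tp <- attr(nev, "by_timepoint")
  expect_true(all(is.na(by_tp$nev[by_tp$gene == g0])))
  expect_true(is.na(nev$nev[nev$gene == g0]))
  expect_equal(nev$n_timepoints_used[nev$gene == g0], 0)
  expect_false(any(is.infinite(nev$nev)))
})

test_that("NEV is invariant under a global scaling of the panel", {
  d <- tiny_design(seed = 22L)
  s <- simulate_panel(d)
  nev1 <- compute_nev(s$panel)
  scaled <- dplyr::mutate(s$panel, value = value * 7)
  nev2 <- compute_nev(scaled)
  ok <- !is.na(nev1$nev) & !is.na(nev2$nev)
  expect_gt(mean(ok), 0.9)
  expect_equal(nev1$nev[ok], nev2$nev[ok], tolerance = 1e-6)
})

test_that("null simulations are centred: gene-median NEV near 0, trend removed", {
  d <- simulation_design(n_singletons = 800, n_ssd_pairs = 0, n_wgd_pairs = 0,
    seed = 23L)
  s <- simulate_panel(d)
  nev <- compute_nev(s$panel)
  expect_lt(abs(median(nev$nev, na.rm = TRUE)), 0.1)
  # residual NEV-mean association is reported, not forced to zero
  joined <- dplyr::left_join(nev, s$truth[, c("gene", "mu")], by = "gene")
  r <- correlate(joined, nev, mu, method = "spearman")
  expect_true(is.finite(r$estimate))
})

test_that("pooled-trend fitting is available and behaves like the per-timepoint fit", {
  d <- tiny_design(seed = 24L)
  s <- simulate_panel(d)
  nev_pool <- compute_nev(s$panel, pool_timepoints = TRUE)
  expect_equal(names(attr(nev_pool, "trends")), "pooled")
  nev_tp <- compute_nev(s$panel)
  both <- !is.na(nev_pool$nev) & !is.na(nev_tp$nev)
  expect_gt(cor(nev_pool$nev[both], nev_tp$nev[both]), 0.9)
})
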