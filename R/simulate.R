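#' Define a synthetic study design
#'
#' Bundles every tunable of the synthetic-data generator. The generator
#' emulates the structure of a replicated single-genotype expression study:
#' a gene x individual x timepoint count tensor with mean-dependent
#' overdispersion, duplication groups (singletons, SSD pairs, WGD pairs)
#' with planted variance inflation, a treatment/baseline + tissue atlas
#' whose responsiveness is coupled to the planted variability, clade
#' (gene-age) assignments in which the derived SSD copy is younger, TF
#' flags depleted among SSD pairs, and a random rooted-tree ontology whose
#' annotations give SSD copies disjoint term sets.
#'
#' The expected coefficient of variation squared of a gene with mean `mu`
#' and multiplier `m` is `m * (1/mu + phi0)`, so the expected normalized
#' expression variability (NEV) of an inflated group is `log2(m)` by
#' construction -- the analytic recovery target used throughout the tests.
#'
#' @param n_singletons,n_ssd_pairs,n_wgd_pairs Group sizes (pairs count two
#'   genes each).
#' @param n_individuals Individuals (biological replicates) per timepoint.
#' @param n_timepoints Timepoints of the diurnal series.
#' @param phi0 Asymptotic CV^2 of the dispersion trend `1/mu + phi0`.
#' @param mean_range Range of gene mean expression; means are drawn
#'   log-uniformly inside it.
#' @param timepoint_sd Log2 SD of per-(gene, timepoint) mean shifts.
#' @param singleton_multiplier,ssd_multiplier,wgd_multiplier Planted
#'   variance multipliers (relative to the trend) per group.
#' @param ssd_derived_inflation Extra multiplier on the derived copy of each
#'   SSD pair.
#' @param tf_fraction Named vector of TF fractions per group
#'   (`singleton`, `ssd`, `wgd`).
#' @param tie_fraction Fraction of SSD pairs with equal clades
#'   (Delta-clade = 0 ties).
#' @param orientation_consistency Fraction of transposed pairs whose
#'   synteny orientation label agrees with the clade-inferred derived copy.
#' @param n_tissues,n_treatments Atlas design: tissue-survey columns and
#'   treatment/baseline contrast pairs.
#' @param resp_base,resp_coupling,resp_noise_sd Responsiveness scale of a
#'   gene: `max(0, resp_base + resp_coupling * log2(multiplier) + noise)`.
#' @param baseline_sd Log2 SD of atlas baseline values around the gene mean.
#' @param n_terms,ontology_depth,terms_per_gene Ontology design: number of
#'   terms in the random rooted tree, maximum depth, and leaf terms
#'   annotated per gene.
#' @param seed Integer seed; recorded in every output and the run log.
#' @return A `sim_design` list.
#' @export
simulation_design <- function(n_singletons = 2000,
                              n_ssd_pairs = 1000,
                              n_wgd_pairs = 1000,
                              n_individuals = 14,
                              n_timepoints = 6,
                              phi0 = 0.05,
                              mean_range = c(5, 5000),
                              timepoint_sd = 0.3,
                              singleton_multiplier = 1,
                              ssd_multiplier = 2,
                              wgd_multiplier = 2,
                              ssd_derived_inflation = 2,
                              tf_fraction = c(singleton = 0.10, ssd = 0.05, wgd = 0.25),
                              tie_fraction = 0.1,
                              orientation_consistency = 0.9,
                              n_tissues = 8,
                              n_treatments = 10,
                              resp_base = 0.2,
                              resp_coupling = 0.5,
                              resp_noise_sd = 0.1,
                              baseline_sd = 0.2,
                              n_terms = 60,
                              ontology_depth = 4,
                              terms_per_gene = 3,
                              seed = 42L) {
  design <- as.list(environment())
  counts <- c(n_singletons, n_ssd_pairs, n_wgd_pairs, n_individuals,
    n_timepoints, n_tissues, n_treatments, n_terms, terms_per_gene)
  if (any(counts < 0)) abort_validation("design counts must be nonnegative")
  mult <- c(singleton_multiplier, ssd_multiplier, wgd_multiplier, ssd_derived_inflation)
  if (any(mult <= 0)) abort_validation("multipliers must be positive")
  if (phi0 <= 0) abort_validation("phi0 must be positive")
  if (tie_fraction < 0 || tie_fraction > 1) abort_validation("tie_fraction must be in [0, 1]")
  if (!all(c("singleton", "ssd", "wgd") %in% names(tf_fraction))) {
    abort_validation("tf_fraction must name singleton, ssd and wgd")
  }
  design$seed <- as.integer(seed)
  structure(design, class = "sim_design")
}

# Gene roster shared by the three generators: ids, groups, roles, planted
# multipliers, means, responsiveness scales and tissue preferences.
sim_truth <- function(design) {
  d <- design
  n_pair_genes <- 2L * (d$n_ssd_pairs + d$n_wgd_pairs)
  make_ids <- function(prefix, n, suffix = "") {
    if (n == 0) return(character(0))
    sprintf("%s%04d%s", prefix, seq_len(n), suffix)
  }
  singles <- tibble::tibble(
    gene = make_ids("SIN", d$n_singletons),
    group = "singleton", pair_id = NA_character_, role = NA_character_,
    multiplier = d$singleton_multiplier
  )
  pair_block <- function(prefix, n, base_mult, derived_extra) {
    if (n == 0) {
      return(tibble::tibble(gene = character(0), group = character(0),
        pair_id = character(0), role = character(0), multiplier = numeric(0)))
    }
    pid <- make_ids(prefix, n)
    # the derived copy is A or B at random so orientation carries no signal
    derived_is_a <- runif(n) < 0.5
    tibble::tibble(
      gene = c(paste0(pid, "A"), paste0(pid, "B")),
      group = tolower(prefix),
      pair_id = rep(pid, 2),
      role = c(ifelse(derived_is_a, "derived", "ancestral"),
               ifelse(derived_is_a, "ancestral", "derived")),
      multiplier = base_mult *
        ifelse(c(derived_is_a, !derived_is_a), derived_extra, 1)
    )
  }
  truth <- dplyr::bind_rows(
    singles,
    pair_block("SSD", d$n_ssd_pairs, d$ssd_multiplier, d$ssd_derived_inflation),
    pair_block("WGD", d$n_wgd_pairs, d$wgd_multiplier, 1)
  )
  n <- nrow(truth)
  truth$mu <- exp(runif(n, log(d$mean_range[1]), log(d$mean_range[2])))
  truth$resp_scale <- pmax(0, d$resp_base +
    d$resp_coupling * log2(truth$multiplier) + rnorm(n, 0, d$resp_noise_sd))
  truth$specificity <- runif(n)
  truth$tissue_pref <- sample.int(max(d$n_tissues, 1L), n, replace = TRUE)
  truth$seed <- d$seed
  truth
}

#' Simulate an expression panel with planted variability
#'
#' Draws counts per (gene, individual, timepoint) from a negative binomial
#' whose variance is `multiplier * (mu + phi0 * mu^2)`, i.e. the baseline
#' CV^2 trend `1/mu + phi0` inflated by the gene's planted multiplier.
#' Per-(gene, timepoint) means wobble by `2^N(0, timepoint_sd)` to mimic a
#' diurnal series. Identical seeds give identical output (Mersenne-Twister,
#' seeded at entry).
#'
#' @param design A [simulation_design()].
#' @return List with `panel` (long tibble `gene`, `individual`, `timepoint`,
#'   `value`) and `truth` (one row per gene: group, pair id,
#'   derived/ancestral role, planted multiplier, mean, responsiveness scale,
#'   tissue preference, seed).
#' @export
simulate_panel <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  truth <- sim_truth(design)
  d <- design
  n_genes <- nrow(truth)
  individuals <- sprintf("I%02d", seq_len(d$n_individuals))
  timepoints <- sprintf("T%d", seq_len(d$n_timepoints))

  grid <- tidyr::expand_grid(gene_idx = seq_len(n_genes), timepoint = timepoints)
  grid$mu_gt <- truth$mu[grid$gene_idx] * 2^rnorm(nrow(grid), 0, d$timepoint_sd)
  grid$mult <- truth$multiplier[grid$gene_idx]

  cells <- tidyr::expand_grid(
    gt = seq_len(nrow(grid)),
    individual = individuals
  )
  mu <- grid$mu_gt[cells$gt]
  target_var <- grid$mult[cells$gt] * (mu + d$phi0 * mu^2)
  excess <- target_var - mu
  value <- numeric(length(mu))
  pois <- excess <= 0
  if (any(pois)) value[pois] <- stats::rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    size <- mu[!pois]^2 / excess[!pois]
    value[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = size)
  }
  panel <- tibble::tibble(
    gene = truth$gene[grid$gene_idx[cells$gt]],
    individual = cells$individual,
    timepoint = grid$timepoint[cells$gt],
    value = value
  ) |>
    dplyr::arrange(match(.data$gene, truth$gene), .data$individual, .data$timepoint)
  list(panel = panel, truth = truth)
}

#' Simulate a condition/tissue atlas coupled to planted variability
#'
#' Treatment expression is `baseline * 2^effect` with the effect drawn from
#' `N(0, resp_scale)` per contrast, so a gene's expected responsiveness is
#' proportional to its planted responsiveness scale -- which the design
#' couples monotonically to the planted variability multiplier (the
#' noise-plasticity coupling). Tissue-survey columns mix a uniform profile
#' with a single-tissue spike according to the gene's planted specificity.
#'
#' @param design A [simulation_design()].
#' @param truth Truth table from [simulate_panel()].
#' @return A `condition_atlas`.
#' @export
simulate_atlas <- function(design, truth) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed + 1L)
  d <- design
  n <- nrow(truth)
  tissues <- sprintf("tissue%02d", seq_len(d$n_tissues))

  base_ids <- sprintf("base%02d", seq_len(d$n_treatments))
  treat_ids <- sprintf("treat%02d", seq_len(d$n_treatments))
  samples <- dplyr::bind_rows(
    tibble::tibble(sample = base_ids, tissue = "seedling",
      treatment = "control", baseline = NA_character_, ecotype = "Col-0"),
    tibble::tibble(sample = treat_ids, tissue = "seedling",
      treatment = sprintf("treatment%02d", seq_len(d$n_treatments)),
      baseline = base_ids, ecotype = "Col-0"),
    tibble::tibble(sample = paste0("survey_", tissues), tissue = tissues,
      treatment = NA_character_, baseline = NA_character_, ecotype = "Col-0")
  )

  base_mat <- truth$mu * 2^matrix(rnorm(n * d$n_treatments, 0, d$baseline_sd),
    n, d$n_treatments)
  effect <- matrix(rnorm(n * d$n_treatments, 0, 1), n, d$n_treatments) * truth$resp_scale
  treat_mat <- base_mat * 2^effect

  # tissue profile: (1 - s) * uniform + s * one-hot spike at the preferred tissue
  spike <- matrix(0, n, d$n_tissues)
  spike[cbind(seq_len(n), truth$tissue_pref)] <- d$n_tissues
  tissue_mat <- truth$mu * ((1 - truth$specificity) + truth$specificity * spike)

  mat <- cbind(base_mat, treat_mat, tissue_mat)
  colnames(mat) <- samples$sample
  expr <- tibble::as_tibble(mat) |>
    dplyr::mutate(gene = truth$gene, .before = 1) |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value")
  new_condition_atlas(expr, samples)
}

#' Simulate gene metadata, paralog table and ontology
#'
#' Clades: singletons uniform on 1..15; WGD copies independent uniform on
#' 1..12 (no planted asymmetry); SSD ancestral copies uniform on 1..10 with
#' the derived copy at `ancestral + U{1..5}` capped at 15, except for a
#' configured fraction of Delta-clade = 0 ties. Transposed pairs carry
#' synteny parent/daughter orientation labels agreeing with the
#' clade-inferred derived copy for a configurable majority. TF flags are
#' drawn per pair (both copies share the flag; mixed pairs do not arise) at
#' the group-specific fraction. The ontology is a random rooted tree;
#' singletons and WGD copies sample leaf terms freely (a WGD pair shares one
#' term set) while the two copies of an SSD pair draw from disjoint leaf
#' halves, planting functional divergence.
#'
#' @param design A [simulation_design()].
#' @param truth Truth table from [simulate_panel()].
#' @return List with `meta` (gene metadata tibble), `pairs` (paralog
#'   tibble) and `ontology` (list of `edges` and `annotations` tibbles).
#' @export
simulate_meta <- function(design, truth) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed + 2L)
  d <- design

  truth <- dplyr::mutate(truth, clade = NA_integer_)
  is_single <- truth$group == "singleton"
  truth$clade[is_single] <- sample.int(15L, sum(is_single), replace = TRUE)
  is_wgd <- truth$group == "wgd"
  truth$clade[is_wgd] <- sample.int(12L, sum(is_wgd), replace = TRUE)

  ssd_pairs <- unique(truth$pair_id[truth$group == "ssd"])
  if (length(ssd_pairs) > 0) {
    anc_clade <- sample.int(10L, length(ssd_pairs), replace = TRUE)
    der_clade <- pmin(15L, anc_clade + sample.int(5L, length(ssd_pairs), replace = TRUE))
    tie <- runif(length(ssd_pairs)) < d$tie_fraction
    der_clade[tie] <- anc_clade[tie]
    idx <- match(truth$pair_id, ssd_pairs)
    in_ssd <- !is.na(idx) & truth$group == "ssd"
    truth$clade[in_ssd] <- ifelse(truth$role[in_ssd] == "derived",
      der_clade[idx[in_ssd]], anc_clade[idx[in_ssd]])
  }

  # pair-level TF flags; singletons gene-level
  truth$is_tf <- FALSE
  truth$is_tf[is_single] <- runif(sum(is_single)) < d$tf_fraction[["singleton"]]
  for (grp in c("ssd", "wgd")) {
    pids <- unique(truth$pair_id[truth$group == grp])
    if (length(pids) == 0) next
    flag <- runif(length(pids)) < d$tf_fraction[[grp]]
    sel <- truth$group == grp
    truth$is_tf[sel] <- flag[match(truth$pair_id[sel], pids)]
  }

  ontology <- sim_ontology(d)
  leaves <- ontology$leaves
  half1 <- leaves[seq_along(leaves) %% 2 == 1]
  half2 <- leaves[seq_along(leaves) %% 2 == 0]
  k <- min(d$terms_per_gene, length(half1), length(half2))
  pick <- function(pool, k) paste(sample(pool, k), collapse = ";")
  terms <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    terms[i] <- switch(truth$group[i],
      singleton = pick(leaves, min(d$terms_per_gene, length(leaves))),
      wgd = NA_character_, # filled pair-wise below
      ssd = if (truth$role[i] == "derived") pick(half2, k) else pick(half1, k)
    )
  }
  wgd_pids <- unique(truth$pair_id[is_wgd])
  for (pid in wgd_pids) {
    shared <- pick(leaves, min(d$terms_per_gene, length(leaves)))
    terms[which(truth$pair_id == pid & is_wgd)] <- shared
  }
  truth$go_terms <- terms

  meta <- tibble::tibble(
    gene = truth$gene,
    status = truth$group,
    clade = truth$clade,
    is_tf = truth$is_tf,
    go_terms = truth$go_terms,
    mean_expr = truth$mu
  )

  pair_rows <- truth |>
    dplyr::filter(!is.na(.data$pair_id)) |>
    dplyr::group_by(.data$pair_id) |>
    dplyr::summarize(
      gene_a = .data$gene[1], gene_b = .data$gene[2],
      role_a = .data$role[1],
      group = .data$group[1], .groups = "drop"
    )
  n_pairs <- nrow(pair_rows)
  mode <- ifelse(pair_rows$group == "wgd", "wgd",
    sample(ssd_modes(), n_pairs, replace = TRUE))
  ks <- ifelse(pair_rows$group == "wgd", runif(n_pairs, 2, 4), runif(n_pairs, 0.1, 2))
  orientation <- rep("unknown", n_pairs)
  transposed <- which(mode == "transposed")
  if (length(transposed) > 0) {
    consistent <- runif(length(transposed)) < d$orientation_consistency
    # consistent label: the ancestral copy is the parent
    a_is_parent <- (pair_rows$role_a[transposed] == "ancestral") == consistent
    orientation[transposed] <- ifelse(a_is_parent, "A_is_parent", "B_is_parent")
  }
  pairs <- tibble::tibble(
    gene_a = pair_rows$gene_a, gene_b = pair_rows$gene_b,
    mode = mode, orientation = orientation, ks = ks
  )
  list(
    meta = meta,
    pairs = validate_paralog_table(pairs),
    ontology = list(edges = ontology$edges, annotations = meta_annotations(meta))
  )
}

# Random rooted tree: term i > 1 attaches to a uniformly chosen earlier term
# of depth < ontology_depth; leaves are terms without children.
sim_ontology <- function(design) {
  n <- max(design$n_terms, 2L)
  ids <- sprintf("GO%04d", seq_len(n))
  depth <- integer(n)
  parent <- integer(n)
  for (i in 2:n) {
    eligible <- which(depth[seq_len(i - 1)] < design$ontology_depth)
    parent[i] <- if (length(eligible) == 1) eligible else sample(eligible, 1)
    depth[i] <- depth[parent[i]] + 1L
  }
  edges <- tibble::tibble(child = ids[-1], parent = ids[parent[-1]])
  leaves <- ids[!(ids %in% edges$parent)]
  list(edges = edges, leaves = leaves, ids = ids)
}

#' Write every synthetic input to a directory
#'
#' Emits exactly the TSV formats the readers consume, plus `truth.tsv`
#' (ground truth; test-only, never consumed by the pipeline) and a
#' `run_log.txt` recording the design, seed and RNG.
#'
#' @param design A [simulation_design()].
#' @param out_dir Output directory.
#' @return Named vector of written paths.
#' @export
simulate_to_dir <- function(design, out_dir) {
  sim <- simulate_panel(design)
  atlas <- simulate_atlas(design, sim$truth)
  meta <- simulate_meta(design, sim$truth)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    panel = file.path(out_dir, "panel.tsv"),
    atlas_expr = file.path(out_dir, "atlas_expr.tsv"),
    atlas_samples = file.path(out_dir, "atlas_samples.tsv"),
    meta = file.path(out_dir, "gene_meta.tsv"),
    pairs = file.path(out_dir, "paralog_pairs.tsv"),
    ontology_edges = file.path(out_dir, "ontology_edges.tsv"),
    ontology_annotations = file.path(out_dir, "ontology_annotations.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    run_log = file.path(out_dir, "run_log.txt")
  )
  write_expression_panel(sim$panel, paths[["panel"]])
  write_atlas(atlas, paths[["atlas_expr"]], paths[["atlas_samples"]])
  write_gene_meta(meta$meta, paths[["meta"]])
  write_paralog_table(meta$pairs, paths[["pairs"]])
  write_ontology(meta$ontology, paths[["ontology_edges"]], paths[["ontology_annotations"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  writeLines(c(
    sprintf("seed: %d", design$seed),
    "rng: Mersenne-Twister (R default)",
    sprintf("generated: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    "design:",
    paste0("  ", names(unclass(design)), ": ",
      vapply(unclass(design), function(x) paste(format(x), collapse = ","), character(1)))
  ), paths[["run_log"]])
  paths
}
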