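#' Read a gene x individual x timepoint expression panel
#'
#' Reads a TSV whose first column holds gene identifiers and whose remaining
#' columns are named `<individual>__<timepoint>` (double underscore
#' separator). The panel holds nonnegative expression of genetically
#' identical individuals sampled repeatedly over a time series -- e.g. the
#' 14-seedling Arabidopsis design this package models.
#'
#' Missing cells are kept as `NA`, never coerced to zero: downstream
#' statistics count contributing individuals explicitly.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble in long form with columns `gene`, `individual`,
#'   `timepoint`, `value`, ordered by gene (file order), then individual,
#'   then timepoint, so column order in the source file is immaterial.
#' @export
read_expression_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) {
    abort_format("expression panel needs a gene column plus at least one sample column")
  }
  names(raw)[1] <- "gene"
  sample_cols <- names(raw)[-1]
  bad <- sample_cols[!grepl("__", sample_cols, fixed = TRUE)]
  if (length(bad) > 0) {
    abort_format(sprintf(
      "malformed expression column name(s) (expected <individual>__<timepoint>): %s",
      paste(bad, collapse = ", ")
    ))
  }
  if (anyDuplicated(raw$gene)) {
    dup <- unique(raw$gene[duplicated(raw$gene)])
    abort_validation(sprintf(
      "duplicate gene identifier(s): %s", paste(head(dup, 5), collapse = ", ")
    ))
  }
  long <- tidyr::pivot_longer(raw, -"gene",
    names_to = c("individual", "timepoint"), names_sep = "__",
    values_to = "value"
  )
  long$value <- as.numeric(long$value)
  neg <- which(!is.na(long$value) & long$value < 0)
  if (length(neg) > 0) {
    abort_validation(sprintf(
      "negative expression value for gene '%s', column '%s__%s'",
      long$gene[neg[1]], long$individual[neg[1]], long$timepoint[neg[1]]
    ))
  }
  gene_order <- unique(raw$gene)
  dplyr::arrange(
    long, match(.data$gene, gene_order), .data$individual, .data$timepoint
  )
}

#' Write an expression panel to TSV
#'
#' Inverse of [read_expression_panel()]: columns are
#' `<individual>__<timepoint>`, one row per gene.
#'
#' @param panel Long tibble with columns `gene`, `individual`, `timepoint`,
#'   `value`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_expression_panel <- function(panel, path) {
  check_columns(panel, c("gene", "individual", "timepoint", "value"), "expression panel")
  wide <- panel |>
    tidyr::unite("column", "individual", "timepoint", sep = "__") |>
    tidyr::pivot_wider(names_from = "column", values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a paralog-pair table
#'
#' Expected TSV columns: `gene_a`, `gene_b`, `mode`, and optionally
#' `orientation` (`A_is_parent`, `B_is_parent`, or `unknown`; synteny-derived
#' parent/daughter labels for transposed duplicates) and `ks` (synonymous
#' substitution rate, nonnegative or missing). Small-scale duplication (SSD)
#' is every mode other than `wgd`.
#'
#' @param path Path to TSV.
#' @return Tibble with columns `gene_a`, `gene_b`, `mode`, `orientation`,
#'   `ks`.
#' @export
read_paralog_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(tbl, c("gene_a", "gene_b", "mode"), "paralog table")
  validate_paralog_table(tbl)
}

validate_paralog_table <- function(tbl) {
  bad_mode <- setdiff(unique(tbl$mode), paralog_modes())
  if (length(bad_mode) > 0) {
    abort_validation(sprintf(
      "unknown duplication mode(s) %s; allowed codes: %s",
      paste(bad_mode, collapse = ", "), paste(paralog_modes(), collapse = ", ")
    ))
  }
  if (any(tbl$gene_a == tbl$gene_b)) {
    abort_validation("paralog pair with identical members (gene_a == gene_b)")
  }
  if (!"orientation" %in% names(tbl)) tbl$orientation <- "unknown"
  tbl$orientation[is.na(tbl$orientation)] <- "unknown"
  bad_or <- setdiff(unique(tbl$orientation), c("A_is_parent", "B_is_parent", "unknown"))
  if (length(bad_or) > 0) {
    abort_validation(sprintf(
      "unknown orientation code(s): %s", paste(bad_or, collapse = ", ")
    ))
  }
  if (!"ks" %in% names(tbl)) tbl$ks <- NA_real_
  if (any(!is.na(tbl$ks) & tbl$ks < 0)) {
    abort_validation("negative ks value in paralog table")
  }
  tibble::as_tibble(tbl)
}

#' Write a paralog-pair table
#' @param pairs Tibble as returned by [read_paralog_table()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_paralog_table <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Read per-gene metadata
#'
#' Expected TSV columns: `gene`, `status` (`singleton`, `ssd`, or `wgd`),
#' `clade` (phylostratigraphic stratum, integer 1..15, oldest = 1, or
#' missing), `is_tf` (logical transcription-factor flag), `go_terms`
#' (semicolon-separated term ids or missing), and optionally `mean_expr`.
#'
#' @param path Path to TSV.
#' @return Tibble of per-gene metadata.
#' @export
read_gene_meta <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(go_terms = readr::col_character(), .default = readr::col_guess()))
  check_columns(tbl, c("gene", "status", "clade", "is_tf", "go_terms"), "gene metadata")
  validate_gene_meta(tbl)
}

validate_gene_meta <- function(tbl) {
  bad_status <- setdiff(unique(tbl$status), c("singleton", "ssd", "wgd"))
  if (length(bad_status) > 0) {
    abort_validation(sprintf(
      "unknown duplication status code(s) %s; allowed: singleton, ssd, wgd",
      paste(bad_status, collapse = ", ")
    ))
  }
  clade <- tbl$clade
  if (any(!is.na(clade) & (clade < 1 | clade > 15 | clade != floor(clade)))) {
    bad <- tbl$gene[which(!is.na(clade) & (clade < 1 | clade > 15))[1]]
    abort_validation(sprintf(
      "clade out of range 1..15 for gene '%s'", bad
    ))
  }
  if (!is.logical(tbl$is_tf)) {
    abort_validation("is_tf must be logical (TRUE/FALSE)")
  }
  if (!"mean_expr" %in% names(tbl)) tbl$mean_expr <- NA_real_
  tibble::as_tibble(tbl)
}

#' @rdname read_gene_meta
#' @param meta Gene metadata tibble.
#' @export
write_gene_meta <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Expand per-gene annotation strings into (gene, term) rows
#'
#' @param meta Gene metadata tibble with a `go_terms` column of
#'   semicolon-separated term ids.
#' @return Tibble with columns `gene`, `term` (unannotated genes dropped).
#' @export
meta_annotations <- function(meta) {
  check_columns(meta, c("gene", "go_terms"), "gene metadata")
  meta |>
    dplyr::filter(!is.na(.data$go_terms), .data$go_terms != "") |>
    dplyr::mutate(term = strsplit(.data$go_terms, ";", fixed = TRUE)) |>
    dplyr::select("gene", "term") |>
    tidyr::unnest("term")
}

#' Read a condition/tissue expression atlas
#'
#' The atlas is a two-file pair: an expression TSV (first column `gene`, one
#' column per sample) and a sample-metadata TSV with columns `sample`,
#' `tissue`, `treatment`, `baseline`, `ecotype`. Treatment samples point to
#' their baseline sample via `baseline`; baseline and tissue-survey samples
#' carry a missing link.
#'
#' @param expr_path Path to the expression TSV.
#' @param sample_path Path to the sample-metadata TSV.
#' @return A `condition_atlas`: list with `expr` (long tibble `gene`,
#'   `sample`, `value`) and `samples` (metadata tibble).
#' @export
read_atlas <- function(expr_path, sample_path) {
  expr <- readr::read_tsv(expr_path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene"
  samples <- readr::read_tsv(sample_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      treatment = readr::col_character(),
      baseline = readr::col_character(),
      .default = readr::col_guess()
    ))
  check_columns(samples, c("sample", "tissue", "treatment", "baseline", "ecotype"),
    "atlas sample metadata")
  long <- tidyr::pivot_longer(expr, -"gene", names_to = "sample", values_to = "value")
  new_condition_atlas(long, samples)
}

new_condition_atlas <- function(expr, samples) {
  extra <- setdiff(unique(expr$sample), samples$sample)
  if (length(extra) > 0) {
    abort_validation(sprintf(
      "expression sample(s) without metadata: %s", paste(head(extra, 5), collapse = ", ")
    ))
  }
  links <- samples$baseline[!is.na(samples$baseline)]
  unresolved <- setdiff(links, samples$sample)
  if (length(unresolved) > 0) {
    abort_validation(sprintf(
      "baseline link(s) do not resolve to an atlas sample: %s",
      paste(head(unresolved, 5), collapse = ", ")
    ))
  }
  linked <- samples$baseline[match(unique(links), samples$sample)]
  if (any(!is.na(linked))) {
    abort_validation("a sample used as a baseline must itself have a missing baseline link")
  }
  if (any(!is.na(expr$value) & expr$value < 0)) {
    abort_validation("negative expression value in atlas")
  }
  structure(
    list(expr = tibble::as_tibble(expr), samples = tibble::as_tibble(samples)),
    class = "condition_atlas"
  )
}

#' @rdname read_atlas
#' @param atlas A `condition_atlas` object.
#' @export
write_atlas <- function(atlas, expr_path, sample_path) {
  wide <- tidyr::pivot_wider(atlas$expr, names_from = "sample", values_from = "value")
  readr::write_tsv(wide, expr_path, progress = FALSE)
  readr::write_tsv(atlas$samples, sample_path, progress = FALSE)
  invisible(c(expr_path, sample_path))
}

#' Read an ontology edge/annotation file pair
#'
#' Edges are a TSV with columns `child`, `parent` (one is_a edge per row;
#' exactly one root term required; the graph must be acyclic). Annotations
#' are a TSV with columns `gene`, `term`; every annotated term must exist in
#' the edge set.
#'
#' @param edges_path Path to the edge TSV.
#' @param annotations_path Path to the annotation TSV.
#' @return List with tibbles `edges` and `annotations`.
#' @export
read_ontology <- function(edges_path, annotations_path) {
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE, progress = FALSE)
  check_columns(edges, c("child", "parent"), "ontology edges")
  anno <- readr::read_tsv(annotations_path, show_col_types = FALSE, progress = FALSE)
  check_columns(anno, c("gene", "term"), "ontology annotations")
  validate_ontology_edges(edges)
  terms <- union(edges$child, edges$parent)
  missing <- setdiff(unique(anno$term), terms)
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "annotated term(s) absent from the ontology: %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  list(edges = tibble::as_tibble(edges), annotations = tibble::as_tibble(anno))
}

validate_ontology_edges <- function(edges) {
  terms <- union(edges$child, edges$parent)
  roots <- setdiff(terms, unique(edges$child))
  if (length(roots) != 1) {
    abort_validation(sprintf(
      "ontology must have exactly one root; found %d (%s)",
      length(roots), paste(head(roots, 5), collapse = ", ")
    ))
  }
  # Acyclicity: iteratively strip terms whose parents are all stripped.
  parents <- split(edges$parent, edges$child)
  remaining <- setdiff(terms, roots)
  done <- roots
  repeat {
    ready <- remaining[vapply(parents[remaining], function(p) all(p %in% done), logical(1))]
    if (length(ready) == 0) break
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining) > 0) {
    abort_validation("ontology edges contain a cycle or a term not reaching the root")
  }
  invisible(edges)
}

#' @rdname read_ontology
#' @param ontology List with `edges` and `annotations` tibbles.
#' @export
write_ontology <- function(ontology, edges_path, annotations_path) {
  readr::write_tsv(ontology$edges, edges_path, progress = FALSE)
  readr::write_tsv(ontology$annotations, annotations_path, progress = FALSE)
  invisible(c(edges_path, annotations_path))
}

#' Write a named list of result tables to a directory
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written file paths.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(names(tables) != ""))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], p, progress = FALSE)
    p
  }, character(1))
  paths
}
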