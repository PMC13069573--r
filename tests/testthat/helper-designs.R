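# Small designs shared across tests. Sizes are kept modest so the default
# run stays fast; acceptance tests size up where a criterion requires it.

tiny_design <- function(seed = 1L, ...) {
  simulation_design(
    n_singletons = 60, n_ssd_pairs = 20, n_wgd_pairs = 20,
    n_individuals = 8, n_timepoints = 3, seed = seed, ...
  )
}

# Brute-force Cliff's delta: explicit O(nm) double loop, the independent
# oracle for the vectorized implementation.
brute_cliffs_delta <- function(x, y) {
  gt <- 0L
  lt <- 0L
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) gt <- gt + 1L else if (xi < yj) lt <- lt + 1L
    }
  }
  (gt - lt) / (length(x) * length(y))
}

# Brute-force MICA: walk every ancestor of both terms via repeated parent
# lookups and take the best IC over the raw intersection.
brute_mica_ic <- function(edges, ic, t1, t2) {
  parents <- split(edges$parent, edges$child)
  all_anc <- function(t) {
    out <- t
    frontier <- t
    while (length(frontier) > 0) {
      nxt <- unique(unlist(parents[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, out)
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  common <- intersect(all_anc(t1), all_anc(t2))
  vals <- ic[common]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else max(vals)
}
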