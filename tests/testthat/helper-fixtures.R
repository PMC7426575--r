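# Shared fixture builders; everything is generated in code at test time.

make_expr <- function(values, state = "raw") {
  if (is.null(dimnames(values))) {
    dimnames(values) <- list(
      paste0("G", seq_len(nrow(values))),
      paste0("S", seq_len(ncol(values)))
    )
  }
  expr_matrix(values, state = state)
}

random_expr <- function(n_genes, n_samples, seed = 1, state = "raw") {
  set.seed(seed)
  make_expr(
    matrix(abs(rnorm(n_genes * n_samples, 5, 2)), n_genes, n_samples),
    state = state
  )
}

# Two well-separated 2-D blobs at +/-5 with sd 0.3, n points each.
blob_expr <- function(n = 50, seed = 1) {
  set.seed(seed)
  v <- cbind(
    matrix(rnorm(2 * n, -5, 0.3), 2, n),
    matrix(rnorm(2 * n, +5, 0.3), 2, n)
  )
  dimnames(v) <- list(c("g1", "g2"), paste0("s", seq_len(2 * n)))
  expr_matrix(v, state = "zscore")
}

write_panel_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

# Default-condition cohort clustered through the standard chain.
cluster_cohort <- function(cohort, seed = 1, n_init = 10, panels = builtin_panel_set()) {
  ez <- zscore_genes(log_transform(cohort$expression))
  ep <- subset_expression(ez, panels)
  model <- fit_gmm(ep, k = 3, seed = seed, n_init = n_init)
  assignment <- assign_subgroups(model, ep)
  list(
    model = model, expr_z = ez, expr_panel = ep,
    assignment = label_phenotypes(assignment, ez, panels)
  )
}

# Map each planted subgroup to the majority recovered cluster.
planted_to_cluster <- function(assignment, truth_subgroup) {
  vapply(1:3, function(g) {
    cl <- assignment$cluster[truth_subgroup == g]
    as.integer(names(which.max(table(cl))))
  }, integer(1))
}
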