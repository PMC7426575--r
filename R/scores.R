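#' Average-expression signature score
#'
#' The per-sample score of a gene signature is the arithmetic mean of the
#' expression of its genes present in the matrix, on whatever scale the
#' matrix currently carries (recorded in provenance). Missing signature
#' genes are reported via the `missing_genes` attribute.
#'
#' @param expr An [expr_matrix].
#' @param sig A `gene_signature` (or character vector of symbols).
#' @return Named numeric vector over samples.
#' @export
signature_score <- function(expr, sig) {
  sub <- subset_expression(expr, sig)
  out <- colMeans(sub$values)
  attr(out, "missing_genes") <- attr(sub, "missing_genes")
  attr(out, "state") <- expr$state
  out
}

#' Percentile-based high/mid/low classes
#'
#' Samples strictly above the `hi`-th percentile are "high", strictly below
#' the `lo`-th are "low", the rest "mid". Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7), pinned
#' for reproducibility. A constant vector yields all "mid" with a warning.
#'
#' @param score Numeric vector (names preserved).
#' @param hi,lo Percent thresholds, `0 <= lo < hi <= 100`.
#' @return Character vector in `{"high","mid","low"}`.
#' @export
percentile_classes <- function(score, hi = 70, lo = 30) {
  stopifnot(is.numeric(score))
  if (!(lo >= 0 && lo < hi && hi <= 100)) {
    abort("thresholds must satisfy 0 <= lo < hi <= 100")
  }
  if (length(unique(score)) == 1) {
    warn("constant score vector: all samples classed 'mid'")
    return(setNames(rep("mid", length(score)), names(score)))
  }
  qs <- quantile(score, probs = c(lo, hi) / 100, type = 7, names = FALSE)
  cls <- rep("mid", length(score))
  cls[score > qs[2]] <- "high"
  cls[score < qs[1]] <- "low"
  setNames(cls, names(score))
}

#' Cytolytic activity (CYT)
#'
#' Geometric mean of GZMA and PRF1 expression on the linear scale with a
#' pseudocount of 1: `sqrt((GZMA + 1) * (PRF1 + 1)) - 1`. The pseudocount
#' keeps zero-expression samples at CYT = 0 while handling zeros inside the
#' geometric mean.
#'
#' @param expr An [expr_matrix] with `state = "raw"` (linear scale).
#' @return Named numeric vector over samples.
#' @export
cytolytic_activity <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$state != "raw") abort("cytolytic_activity requires linear-scale (raw) expression")
  genes <- rownames(expr$values)
  need <- c("GZMA", "PRF1")
  if (!all(need %in% genes)) {
    abort(paste0("missing CYT genes: ", paste(setdiff(need, genes), collapse = ", ")))
  }
  sqrt((expr$values["GZMA", ] + 1) * (expr$values["PRF1", ] + 1)) - 1
}

#' Assemble a per-sample score table
#'
#' Computes the standard score panel on a synthetic or real cohort: immune,
#' stromal and cell-cycle average-expression scores (on log scale), CYT (on
#' linear scale), plus any extra named signatures.
#'
#' @param expr_raw A raw (linear) [expr_matrix].
#' @param signatures Named list of `gene_signature`s, as from
#'   [builtin_signatures()].
#' @param log_offset Offset for the internal log transform.
#' @return Tibble: `sample_id` plus one numeric column per score.
#' @export
score_table <- function(expr_raw, signatures = builtin_signatures(), log_offset = 1) {
  stopifnot(expr_raw$state == "raw")
  expr_log <- log_transform(expr_raw, offset = log_offset)
  avail <- function(sig) any(sig$genes %in% rownames(expr_raw$values))
  out <- tibble::tibble(sample_id = expr_samples(expr_raw))
  for (nm in setdiff(names(signatures), c("CYT", "TIC", "IRP"))) {
    if (avail(signatures[[nm]])) {
      out[[nm]] <- unname(signature_score(expr_log, signatures[[nm]]))
    }
  }
  if (all(c("GZMA", "PRF1") %in% rownames(expr_raw$values))) {
    out$CYT <- unname(cytolytic_activity(expr_raw))
  }
  out
}

#' Subgroup-level mean-z summary of scores
#'
#' Every score is z-scored across all samples (population convention) and
#' then averaged within each subgroup — the standard way subgroup score
#' profiles are displayed as bar charts.
#'
#' @param scores Tibble with `sample_id` plus numeric score columns.
#' @param assignment A `subgroup_assignment` covering all score samples.
#' @return Tibble: `cluster`, `score`, `mean_z`, `n`.
#' @export
subgroup_summary <- function(scores, assignment) {
  stopifnot(inherits(assignment, "subgroup_assignment"), "sample_id" %in% names(scores))
  missing <- setdiff(scores$sample_id, assignment$sample_ids)
  if (length(missing) > 0) {
    abort(paste0("samples without assignment: ", paste(missing, collapse = ", ")))
  }
  cl <- assignment$cluster[scores$sample_id]
  if (any(tabulate(cl, assignment$k) == 0)) abort("empty subgroup in score summary")
  scores |>
    dplyr::mutate(cluster = unname(cl)) |>
    tidyr::pivot_longer(-c("sample_id", "cluster"),
      names_to = "score", values_to = "value"
    ) |>
    dplyr::group_by(.data$score) |>
    dplyr::mutate(z = zscore_pop(.data$value)) |>
    dplyr::group_by(.data$cluster, .data$score) |>
    dplyr::summarise(
      mean_z = mean(.data$z), n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$score, .data$cluster)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
# Handles ties through midranks; identical groups give p = 1.
mw_exact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  n <- length(pooled)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  center <- na * length(b) / 2
  idx <- combn(n, na)
  u_all <- colSums(matrix(rk[idx], nrow = na)) - na * (na + 1) / 2
  p <- mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
  list(statistic = u_obs, p_value = p)
}

#' Two-group comparison of a score
#'
#' Welch's unequal-variance t test (the robust reading of a two-sample
#' "Student's t test"; set `pooled = TRUE` for the classical pooled-variance
#' form) or the Mann-Whitney U test, two-sided. Mann-Whitney uses exact
#' enumeration over all group assignments when either group has fewer than 8
#' samples (and the enumeration is tractable), otherwise the normal
#' approximation with tie correction via `stats::wilcox.test`.
#'
#' @param values Named numeric vector of per-sample scores.
#' @param group_a,group_b Disjoint, non-empty sets of sample names.
#' @param method `"welch_t"` or `"mann_whitney_u"`.
#' @param pooled Use pooled variance for the t test.
#' @param score_name Label carried into the result.
#' @return One-row tibble: `score`, `method`, `statistic`, `p_value`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(values, group_a, group_b,
                           method = c("welch_t", "mann_whitney_u"),
                           pooled = FALSE, score_name = "score") {
  method <- match.arg(method)
  stopifnot(!is.null(names(values)))
  if (length(group_a) == 0 || length(group_b) == 0) abort("empty group")
  if (length(intersect(group_a, group_b)) > 0) abort("overlapping groups")
  miss <- setdiff(c(group_a, group_b), names(values))
  if (length(miss) > 0) abort(paste0("samples missing from values: ", paste(miss, collapse = ", ")))
  a <- values[group_a]
  b <- values[group_b]
  if (method == "welch_t") {
    if (length(a) < 2 || length(b) < 2) abort("welch_t needs >= 2 samples per group")
    tt <- stats::t.test(a, b, var.equal = pooled)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    if (min(length(a), length(b)) < 8 &&
      choose(length(a) + length(b), length(a)) <= 2e5) {
      ex <- mw_exact(a, b)
      statistic <- ex$statistic
      p <- ex$p_value
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
      )
      statistic <- unname(wt$statistic)
      p <- wt$p.value
    }
  }
  tibble::tibble(
    score = score_name, method = method, statistic = statistic,
    p_value = p, n_a = length(a), n_b = length(b)
  )
}

#' Compare every score between each subgroup and the rest
#'
#' Runs [compare_groups()] for every numeric column of a score table,
#' contrasting each subgroup against all other samples. P-values are
#' unadjusted by default; `adjust = TRUE` applies Benjamini-Hochberg within
#' the table.
#'
#' @param scores Tibble with `sample_id` plus numeric score columns.
#' @param assignment A `subgroup_assignment`.
#' @param method Passed to [compare_groups()].
#' @param adjust Apply Benjamini-Hochberg correction.
#' @return Tibble with one row per (score, cluster).
#' @export
compare_subgroup_scores <- function(scores, assignment,
                                    method = "mann_whitney_u", adjust = FALSE) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  cl <- assignment$cluster
  num_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  out <- purrr::map_dfr(num_cols, function(nm) {
    v <- setNames(scores[[nm]], scores$sample_id)
    purrr::map_dfr(seq_len(assignment$k), function(j) {
      ga <- names(cl)[cl == j]
      gb <- names(cl)[cl != j]
      ga <- intersect(ga, names(v))
      gb <- intersect(gb, names(v))
      dplyr::mutate(
        compare_groups(v, ga, gb, method = method, score_name = nm),
        cluster = j, .after = "score"
      )
    })
  })
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Read an immune-cell-fraction table
#'
#' Deconvolution-output dialect: TSV with `sample_id` plus one column per
#' cell type, fractions in `[0, 1]`. Rows with any fraction outside `[0, 1]`
#' or a row sum above 1.05 are rejected with a warning listing them
#' (also attached as attribute `"rejected"`).
#'
#' @param path Path to the TSV.
#' @return Tibble of the retained rows.
#' @export
read_cell_fractions <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"sample_id" %in% names(tbl)) abort("fraction table needs a sample_id column")
  frac <- as.matrix(tbl[, -1, drop = FALSE])
  bad <- apply(frac, 1, function(r) any(r < 0 | r > 1)) | rowSums(frac) > 1.05
  if (any(bad)) {
    warn(paste0(
      "rejected fraction rows failing [0,1]/row-sum checks: ",
      paste(tbl$sample_id[bad], collapse = ", ")
    ))
  }
  out <- tbl[!bad, ]
  attr(out, "rejected") <- tbl$sample_id[bad]
  out
}
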