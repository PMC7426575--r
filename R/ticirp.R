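#' Geometric-mean signature score
#'
#' Per-sample geometric mean of the linear-scale expression of the signature
#' genes present in the matrix, computed with a pseudocount:
#' `exp(mean(log(x + pseudocount))) - pseudocount`. The pseudocount (default
#' 1) prevents a single zero-expression gene from annihilating the score.
#'
#' @param expr An [expr_matrix] with non-negative linear values
#'   (`state = "raw"`).
#' @param sig A `gene_signature` or character vector.
#' @param pseudocount Non-negative pseudocount.
#' @return Named numeric vector over samples; missing genes in attribute
#'   `missing_genes`.
#' @export
geometric_mean_score <- function(expr, sig, pseudocount = 1) {
  stopifnot(inherits(expr, "expr_matrix"), pseudocount >= 0)
  if (expr$state != "raw") abort("geometric_mean_score requires linear-scale (raw) expression")
  sub <- subset_expression(expr, sig)
  if (any(sub$values < 0)) abort("negative expression values")
  if (pseudocount == 0 && any(sub$values == 0)) {
    warn("zero values with pseudocount 0: affected samples score 0")
  }
  out <- exp(colMeans(log(sub$values + pseudocount))) - pseudocount
  attr(out, "missing_genes") <- attr(sub, "missing_genes")
  out
}

#' Tumor-intrinsic classifier (TIC) and immune response predictor (IRP)
#' scores
#'
#' TIC summarizes the tumor-cell-intrinsic competence of the immune
#' escape-initiating domains (type I IFN pathway: IFI16, MYD88, JAK2;
#' antigen presentation: TAP1, TAP2, PSMB9, HLA-DQA1); IRP summarizes the
#' tumor/T-cell interaction axis (IFNGR1, CD274, CXCL9, IFNG, PDCD1, CXCR3).
#' Each is the per-patient geometric mean of its genes' linear expression
#' (pseudocount 1), then normalized within the cohort. Geometric means of
#' expression are close to log-normal, so the default normalization is the
#' population z-score of `log2(score + 1)`, which keeps the quadrant
#' boundary near the cohort's typical sample; a raw-scale z-score and a
#' centered min-max scaling are available as alternatives. Samples are
#' placed in quadrants of the (TIC, IRP) plane: 1 = (+,+), 2 = (-,+),
#' 3 = (-,-), 4 = (+,-), TIC on the x-axis; a normalized score of exactly 0
#' counts as positive.
#'
#' @param expr A raw (linear) [expr_matrix].
#' @param response Optional tibble `sample_id`, `response` with values in
#'   `{PR, NR, PD}` (unlisted samples get `NA`).
#' @param signatures Named list providing `TIC` and `IRP` signatures.
#' @param min_genes Minimum present genes required per signature.
#' @param pseudocount Pseudocount for the geometric means.
#' @param normalization `"log_zscore"` (default), `"zscore"`, or `"minmax"`
#'   (scaled to `[0, 1]` then centered at its midpoint). The two z-score
#'   forms give cohort mean 0.
#' @return A `tic_irp_result` with raw and normalized scores, quadrants and
#'   response labels; `as_tibble()`/`tidy()` give the per-sample table.
#' @export
tic_irp_scores <- function(expr, response = NULL,
                           signatures = builtin_signatures(),
                           min_genes = 4, pseudocount = 1,
                           normalization = c("log_zscore", "zscore", "minmax")) {
  stopifnot(inherits(expr, "expr_matrix"))
  normalization <- match.arg(normalization)
  n <- ncol(expr$values)
  if (n < 3) abort("cohort too small to normalize scores (need >= 3 samples)")
  present <- function(sig) sum(sig$genes %in% rownames(expr$values))
  for (nm in c("TIC", "IRP")) {
    got <- present(signatures[[nm]])
    if (got < min_genes) {
      abort(sprintf(
        "%s has %d/%d genes present (need >= %d); missing: %s",
        nm, got, length(signatures[[nm]]$genes), min_genes,
        paste(setdiff(signatures[[nm]]$genes, rownames(expr$values)), collapse = ", ")
      ))
    }
  }
  tic_raw <- geometric_mean_score(expr, signatures$TIC, pseudocount)
  irp_raw <- geometric_mean_score(expr, signatures$IRP, pseudocount)
  normalize <- switch(normalization,
    log_zscore = function(x) zscore_pop(log2(x + 1)),
    zscore = zscore_pop,
    minmax = function(x) {
      rng <- range(x)
      if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng) - 0.5
    }
  )
  tic_norm <- normalize(unname(tic_raw))
  irp_norm <- normalize(unname(irp_raw))
  quadrant <- dplyr::case_when(
    tic_norm >= 0 & irp_norm >= 0 ~ 1L,
    tic_norm < 0 & irp_norm >= 0 ~ 2L,
    tic_norm < 0 & irp_norm < 0 ~ 3L,
    .default = 4L
  )
  resp <- rep(NA_character_, n)
  if (!is.null(response)) {
    stopifnot(all(c("sample_id", "response") %in% names(response)))
    bad <- setdiff(unique(response$response), c("PR", "NR", "PD", NA))
    if (length(bad) > 0) abort(paste0("invalid response labels: ", paste(bad, collapse = ", ")))
    idx <- match(colnames(expr$values), response$sample_id)
    resp <- response$response[idx]
  }
  structure(
    list(
      sample_ids = colnames(expr$values),
      tic_raw = unname(tic_raw), irp_raw = unname(irp_raw),
      tic_norm = tic_norm, irp_norm = irp_norm,
      quadrant = quadrant, response = resp
    ),
    class = "tic_irp_result"
  )
}

#' @export
print.tic_irp_result <- function(x, ...) {
  cat(sprintf(
    "<tic_irp_result> %d samples; quadrant counts: %s\n",
    length(x$sample_ids),
    paste(tabulate(x$quadrant, 4), collapse = ", ")
  ))
  invisible(x)
}

#' @export
as_tibble.tic_irp_result <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_ids,
    tic_raw = x$tic_raw, irp_raw = x$irp_raw,
    tic_norm = x$tic_norm, irp_norm = x$irp_norm,
    quadrant = x$quadrant, response = x$response
  )
}

#' @export
tidy.tic_irp_result <- function(x, ...) as_tibble.tic_irp_result(x)

#' @export
glance.tic_irp_result <- function(x, ...) {
  ct <- suppressWarnings(stats::cor.test(x$tic_norm, x$irp_norm))
  tibble::tibble(
    n = length(x$sample_ids),
    pearson_r = unname(ct$estimate),
    pearson_p = ct$p.value,
    n_quadrant1 = sum(x$quadrant == 1L),
    n_responders = sum(x$response == "PR", na.rm = TRUE)
  )
}

#' Association of TIC/IRP with checkpoint-blockade response
#'
#' Welch t tests of the normalized TIC and IRP between partial responders
#' (PR) and non-responders (NR and PD pooled), the Pearson correlation
#' between normalized TIC and IRP, and the quadrant-1 responder count.
#'
#' @param result A `tic_irp_result` with response labels.
#' @return List with `tests` (tibble of the two Welch comparisons),
#'   `pearson_r`, `pearson_p`, `quadrant_counts` (tibble), and
#'   `responders_in_q1` / `n_responders`.
#' @export
response_association <- function(result) {
  stopifnot(inherits(result, "tic_irp_result"))
  resp <- result$response
  if (all(is.na(resp))) abort("no response labels present")
  pr <- which(!is.na(resp) & resp == "PR")
  non <- which(!is.na(resp) & resp != "PR")
  if (length(pr) < 2 || length(non) < 2) {
    abort("need >= 2 responders and >= 2 non-responders")
  }
  ids <- result$sample_ids
  tests <- dplyr::bind_rows(
    compare_groups(setNames(result$tic_norm, ids), ids[pr], ids[non],
      method = "welch_t", score_name = "tic_norm"
    ),
    compare_groups(setNames(result$irp_norm, ids), ids[pr], ids[non],
      method = "welch_t", score_name = "irp_norm"
    )
  )
  ct <- stats::cor.test(result$tic_norm, result$irp_norm)
  qtab <- tibble::tibble(
    quadrant = 1:4,
    n = tabulate(result$quadrant, 4),
    n_responders = vapply(
      1:4,
      function(q) sum(result$quadrant == q & !is.na(resp) & resp == "PR"),
      integer(1)
    )
  )
  list(
    tests = tests,
    pearson_r = unname(ct$estimate),
    pearson_p = ct$p.value,
    quadrant_counts = qtab,
    responders_in_q1 = qtab$n_responders[1],
    n_responders = length(pr)
  )
}

#' Scatter of normalized TIC against normalized IRP
#'
#' @param object A `tic_irp_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tic_irp_result <- function(object, ...) {
  df <- as_tibble.tic_irp_result(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$tic_norm, y = .data$irp_norm, colour = .data$response
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "normalized TIC", y = "normalized IRP", colour = "ICB response",
      title = "Tumor-intrinsic classifier vs immune response predictor"
    ) +
    ggplot2::theme_minimal()
}
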