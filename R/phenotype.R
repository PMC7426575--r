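#' Three-axis immune-escape phenotype labels
#'
#' Each subgroup is summarized on three axes of the cancer-immunity cycle —
#' ubiquitination (panel A), type I IFN production/signaling (panel B, split
#' by its sub-tags), and antigen presentation (panel C) — as functioning
#' ("+") or defective ("-"), e.g. `"UB+ IFN1p- AP-"` for a subgroup with
#' ubiquitination intact, type I IFN production defective, and antigen
#' presentation defective.
#'
#' Per axis, the cluster-mean z-score over (samples x panel genes) is
#' computed; the top-ranked cluster is "+", the bottom-ranked "-", and
#' middle clusters take the sign of their mean z (zero is the cohort mean
#' after z-scoring, so positive means above-cohort expression). On the IFN1
#' axis a "-" is refined to "p-" or "s-" by the more defective sub-arm: the
#' production and signaling sub-scores are compared and the lower (more
#' negative) one names the defect; a sub-arm with non-negative mean z is
#' never called defective. Ranking ties break toward the lower cluster
#' index.
#'
#' @param assignment A `subgroup_assignment` from [assign_subgroups()].
#' @param expr_z A z-scored [expr_matrix] covering the cohort (not
#'   necessarily subset to panels).
#' @param panels A `panel_set` containing panels A, B (with
#'   production/signaling tags), and C.
#' @return The assignment with a `phenotypes` tibble attached (one row per
#'   cluster: axis scores, axis calls, `display` string, and a stable
#'   `subgroup` number ordered by ascending panel-B+C mean so the
#'   all-functioning subgroup comes last).
#' @export
label_phenotypes <- function(assignment, expr_z, panels) {
  stopifnot(
    inherits(assignment, "subgroup_assignment"),
    inherits(expr_z, "expr_matrix"),
    inherits(panels, "panel_set")
  )
  if (expr_z$state != "zscore") abort("label_phenotypes requires z-scored expression")
  need <- c("A", "B", "C")
  have <- unique(tibble::as_tibble(panels)$panel)
  if (!all(need %in% have)) {
    abort(paste0(
      "panel set must include panels A, B, C; missing: ",
      paste(setdiff(need, have), collapse = ", ")
    ))
  }
  k <- assignment$k
  sizes <- tabulate(assignment$cluster, k)
  if (any(sizes == 0)) abort("cannot label phenotypes: a cluster has zero samples")

  axis_score <- function(genes) {
    sub <- subset_expression(expr_z, genes)
    vapply(seq_len(k), function(j) {
      mean(sub$values[, assignment$cluster == j, drop = FALSE])
    }, numeric(1))
  }
  ub <- axis_score(signature_genes(panels, panel = "A"))
  ifn_prod <- axis_score(signature_genes(panels, panel = "B", tag = "production"))
  ifn_sig <- axis_score(signature_genes(panels, panel = "B", tag = "signaling"))
  ifn <- axis_score(signature_genes(panels, panel = "B"))
  ap <- axis_score(signature_genes(panels, panel = "C"))

  call_axis <- function(score) {
    rk <- rank(-score, ties.method = "first") # 1 = highest mean z
    dplyr::case_when(
      rk == 1 ~ "+",
      rk == max(rk) ~ "-",
      score > 0 ~ "+",
      .default = "-"
    )
  }
  ub_call <- call_axis(ub)
  ap_call <- call_axis(ap)
  ifn_call <- call_axis(ifn)
  for (j in which(ifn_call == "-")) {
    prod_def <- ifn_prod[j] < 0
    sig_def <- ifn_sig[j] < 0
    ifn_call[j] <- if (prod_def && (!sig_def || ifn_prod[j] < ifn_sig[j])) {
      "p-"
    } else if (sig_def) {
      "s-"
    } else {
      "-"
    }
  }

  display <- sprintf("UB%s IFN1%s AP%s", ub_call, ifn_call, ap_call)
  # Stable reporting order: ascending combined IFN/AP competence, so the
  # fully functioning (AP+ IFN1+) cluster is always the last subgroup number.
  subgroup <- rank(ifn + ap, ties.method = "first")
  phen <- tibble::tibble(
    cluster = seq_len(k),
    subgroup = as.integer(subgroup),
    n = sizes,
    ub_z = ub, ifn_production_z = ifn_prod, ifn_signaling_z = ifn_sig,
    ifn_z = ifn, ap_z = ap,
    ub = ub_call, ifn1 = ifn_call, ap = ap_call,
    display = display
  )
  assignment$phenotypes <- phen
  assignment
}
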