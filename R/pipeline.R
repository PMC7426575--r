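#' Run the full subgrouping analysis
#'
#' Orchestrates the pipeline end-to-end: read expression, normalize
#' (log2(x+1), per-gene z-score), subset to the panel registry, fit the
#' k-component Gaussian mixture, assign and phenotype-label subgroups,
#' compute the score table and subgroup summaries, and — when the optional
#' inputs are present — TMB, arm-CNA summaries, immune-cell-fraction
#' comparisons, and the TIC/IRP response analysis. All outputs are TSV plus
#' a single JSON run report (parameters, seed, input digests, headline
#' numbers). Optional stages are skipped with a notice; a failing stage
#' aborts with the stage name.
#'
#' @param expression_path Expression TSV (required).
#' @param out_dir Output directory (created if needed).
#' @param panel_path Registry TSV; `NULL` uses the built-in registry.
#' @param mutation_path,cna_path,fractions_path,response_path Optional
#'   inputs.
#' @param k Number of subgroups.
#' @param seed Seed for the mixture restarts.
#' @param n_init Number of EM restarts.
#' @param capture_mb Exome capture size for TMB.
#' @return Invisibly, a list with the fitted objects and the report.
#' @export
run_pipeline <- function(expression_path, out_dir,
                         panel_path = NULL,
                         mutation_path = NULL, cna_path = NULL,
                         fractions_path = NULL, response_path = NULL,
                         k = 3, seed = 20180907, n_init = 10,
                         capture_mb = 30) {
  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  panels <- stage("gene_panels", {
    if (is.null(panel_path)) builtin_panel_set() else load_panel_set(panel_path)
  })
  signatures <- builtin_signatures()

  expr_raw <- stage("expression_data", read_expression(expression_path))
  expr_z <- stage("expression_data", zscore_genes(log_transform(expr_raw)))
  expr_panel <- stage("expression_data", subset_expression(expr_z, panels))

  model <- stage("subgroup_discovery", fit_gmm(expr_panel, k = k, seed = seed, n_init = n_init))
  assignment <- stage("subgroup_discovery", assign_subgroups(model, expr_panel))
  assignment <- stage("subgroup_discovery", label_phenotypes(assignment, expr_z, panels))

  assign_tbl <- as_tibble.subgroup_assignment(assignment)
  readr::write_tsv(assign_tbl, file.path(out_dir, "assignments.tsv"), progress = FALSE)
  readr::write_tsv(assignment$phenotypes, file.path(out_dir, "phenotypes.tsv"), progress = FALSE)

  scores <- stage("signature_scores", score_table(expr_raw, signatures))
  tic <- irp <- NULL
  tic_res <- NULL
  sig_ok <- sum(signatures$TIC$genes %in% expr_genes(expr_raw)) >= 4 &&
    sum(signatures$IRP$genes %in% expr_genes(expr_raw)) >= 4
  response <- NULL
  if (!is.null(response_path)) {
    response <- readr::read_tsv(response_path, col_types = "cc", progress = FALSE)
  }
  if (sig_ok) {
    tic_res <- stage("tic_irp", tic_irp_scores(expr_raw, response = response, signatures = signatures))
    ti <- as_tibble.tic_irp_result(tic_res)
    scores$TIC <- ti$tic_raw[match(scores$sample_id, ti$sample_id)]
    scores$IRP <- ti$irp_raw[match(scores$sample_id, ti$sample_id)]
    readr::write_tsv(ti, file.path(out_dir, "tic_irp.tsv"), progress = FALSE)
  } else {
    inform("tic_irp stage skipped: too few TIC/IRP genes in the matrix")
  }
  readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)

  summ <- stage("signature_scores", subgroup_summary(scores, assignment))
  readr::write_tsv(summ, file.path(out_dir, "subgroup_summary.tsv"), progress = FALSE)
  comparisons <- stage(
    "signature_scores",
    compare_subgroup_scores(scores, assignment, method = "mann_whitney_u")
  )

  tmb_tbl <- NULL
  if (!is.null(mutation_path)) {
    muts <- stage("genomic_summaries", read_mutation_table(mutation_path))
    tmb_tbl <- stage("genomic_summaries", tmb(muts,
      capture_mb = capture_mb,
      samples = expr_samples(expr_raw)
    ))
    readr::write_tsv(tmb_tbl, file.path(out_dir, "tmb.tsv"), progress = FALSE)
    top_genes <- muts |>
      dplyr::count(.data$gene, sort = TRUE) |>
      utils::head(17) |>
      dplyr::pull("gene")
    landscape <- stage("genomic_summaries", mutation_landscape(muts, top_genes, assignment))
    readr::write_tsv(landscape, file.path(out_dir, "mutation_landscape.tsv"), progress = FALSE)
  } else {
    inform("genomic_summaries (mutations) skipped: no mutation input")
  }

  scna_tbl <- NULL
  if (!is.null(cna_path)) {
    cna <- stage("genomic_summaries", read_arm_cna(cna_path))
    scna_tbl <- stage("genomic_summaries", scna_burden(cna))
    readr::write_tsv(scna_tbl, file.path(out_dir, "scna.tsv"), progress = FALSE)
    profile <- stage("genomic_summaries", subgroup_arm_profile(cna, assignment))
    readr::write_tsv(profile, file.path(out_dir, "arm_profile.tsv"), progress = FALSE)
  } else {
    inform("genomic_summaries (CNA) skipped: no CNA input")
  }

  if (!is.null(fractions_path)) {
    fractions <- stage("signature_scores", read_cell_fractions(fractions_path))
    frac_cmp <- stage(
      "signature_scores",
      compare_subgroup_scores(fractions, assignment, method = "mann_whitney_u")
    )
    comparisons <- dplyr::bind_rows(comparisons, frac_cmp)
  }
  readr::write_tsv(comparisons, file.path(out_dir, "comparisons.tsv"), progress = FALSE)

  assoc <- NULL
  if (!is.null(tic_res) && !all(is.na(tic_res$response))) {
    n_pr <- sum(tic_res$response == "PR", na.rm = TRUE)
    n_non <- sum(!is.na(tic_res$response) & tic_res$response != "PR")
    if (n_pr >= 2 && n_non >= 2) {
      assoc <- stage("tic_irp", response_association(tic_res))
    } else {
      inform("response association skipped: too few responders/non-responders")
    }
  }

  inputs <- c(
    expression = expression_path, panels = panel_path %||% NA,
    mutations = mutation_path %||% NA, cna = cna_path %||% NA,
    fractions = fractions_path %||% NA, response = response_path %||% NA
  )
  inputs <- inputs[!is.na(inputs)]
  report <- list(
    package = "immunocycle",
    version = as.character(utils::packageVersion("immunocycle")),
    parameters = list(
      k = k, seed = seed, n_init = n_init, capture_mb = capture_mb,
      normalization = "log2(x+1) + per-gene population z-score"
    ),
    inputs = as.list(setNames(
      unname(tools::md5sum(inputs)), names(inputs)
    )),
    n_samples = length(expr_samples(expr_raw)),
    cluster_sizes = as.list(setNames(
      tabulate(assignment$cluster, k),
      paste0("cluster_", seq_len(k))
    )),
    phenotypes = assignment$phenotypes$display,
    loglik = model$loglik,
    converged = model$converged,
    tic_irp = if (!is.null(assoc)) {
      list(
        pearson_r = assoc$pearson_r, pearson_p = assoc$pearson_p,
        responders_in_q1 = assoc$responders_in_q1,
        n_responders = assoc$n_responders
      )
    }
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    panels = panels, model = model, assignment = assignment,
    scores = scores, subgroup_summary = summ, comparisons = comparisons,
    tmb = tmb_tbl, scna = scna_tbl, tic_irp = tic_res,
    response_association = assoc, report = report
  ))
}

#' Simulate a cohort straight to files
#'
#' Thin wrapper over [generate_cohort()] + [write_cohort()] used by the
#' command-line front-end.
#'
#' @param dir Output directory.
#' @param n Cohort size.
#' @param seed Seed.
#' @param icb Use the ICB preset (latent competence + response labels).
#' @return Character vector of written files.
#' @export
simulate_cohort_files <- function(dir, n = 99, seed = 20180907, icb = FALSE) {
  cfg <- if (icb) {
    icb_cohort_config(n_samples = n, seed = seed)
  } else {
    cohort_config(n_samples = n, seed = seed)
  }
  write_cohort(generate_cohort(cfg), dir)
  list.files(dir, full.names = TRUE)
}

#' Benchmark harness for deposited cohorts
#'
#' Runs the full pipeline on locally downloaded expression (and optionally
#' mutation) files from a deposited cohort and reports cluster sizes and
#' per-subgroup mean TMB. This is an integration check against real data:
#' the package never downloads anything, so the files must already exist
#' locally; a missing file is an informative error naming what to supply.
#'
#' @param expression_path Downloaded expression TSV (genes x samples).
#' @param panel_path Full registry TSV (supplementary gene lists).
#' @param mutation_path Optional MAF-like TSV.
#' @param out_dir Where to write pipeline outputs.
#' @param ... Passed to [run_pipeline()].
#' @return List: `cluster_sizes`, `phenotypes`, `tmb_by_subgroup` (or `NULL`).
#' @export
geo_benchmark <- function(expression_path, panel_path = NULL,
                          mutation_path = NULL,
                          out_dir = tempfile("geo_benchmark_"), ...) {
  for (p in c(expression_path, panel_path, mutation_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0(
        "benchmark input not found: ", p,
        "\nThis harness runs on locally downloaded cohort files; ",
        "download the deposited expression/mutation tables and the ",
        "supplementary panel registry first, then pass their paths."
      ))
    }
  }
  res <- run_pipeline(expression_path, out_dir,
    panel_path = panel_path,
    mutation_path = mutation_path, ...
  )
  tmb_by_sg <- NULL
  if (!is.null(res$tmb)) {
    cl <- res$assignment$cluster[res$tmb$sample_id]
    tmb_by_sg <- res$tmb |>
      dplyr::mutate(cluster = unname(cl)) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(mean_tmb = mean(.data$tmb), .groups = "drop")
  }
  list(
    cluster_sizes = tabulate(res$assignment$cluster, res$model$k),
    phenotypes = res$assignment$phenotypes$display,
    tmb_by_subgroup = tmb_by_sg
  )
}

#' Bar chart of subgroup mean-z score profiles
#'
#' @param summ Output of [subgroup_summary()].
#' @return A ggplot.
#' @export
plot_subgroup_summary <- function(summ) {
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$score, y = .data$mean_z, fill = factor(.data$cluster)
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean z-score", fill = "subgroup") +
    ggplot2::theme_minimal()
}

#' Posterior-membership plot of a subgroup assignment
#'
#' @param object A `subgroup_assignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subgroup_assignment <- function(object, ...) {
  df <- as_tibble.subgroup_assignment(object) |>
    tidyr::pivot_longer(dplyr::starts_with("posterior_"),
      names_to = "component", values_to = "posterior"
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sample_id, y = .data$posterior, fill = .data$component
  )) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~cluster, scales = "free_x", space = "free_x") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "samples (by cluster)", y = "posterior membership")
}
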