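#' Synthetic-cohort configuration
#'
#' Generative parameters for a bulk-expression cohort with three planted
#' immune subgroups. Defaults emulate a 99-patient never-smoker LUAD-like
#' cohort: subgroup proportions 37/15/47, per-panel expression shifts
#' encoding the qualitative high/low/very-low pattern of the three immune
#' phenotypes (High = +1, Low = -1, Very low = -2, in z units on the log2
#' scale), per-subgroup TMB Poisson means 1.919 / 2.644 / 1.700 mutations
#' per Mb at a 30 Mb capture, and arm-level copy-number noise scaled so
#' subgroup 1 carries the highest burden.
#'
#' @param n_samples Cohort size.
#' @param subgroup_probs Membership probabilities (length 3, sum 1).
#' @param panel_effects Tibble `subgroup`, `panel`, `tag`, `shift` of z-unit
#'   shifts applied to panel genes (tag `NA` = whole panel).
#' @param signature_effects Tibble `subgroup`, `signature`, `shift` for the
#'   immune / stromal / cell-cycle marker sets.
#' @param effect_scale Global multiplier on all planted shifts (0 = null
#'   cohort with no signal).
#' @param gene_baseline_range Range of per-gene baseline log2 means.
#' @param gene_sd Within-gene log2 noise standard deviation (> 0).
#' @param n_background_genes Unshifted decoy genes added to the matrix.
#' @param tmb_means_per_mb Per-subgroup TMB means (mutations/Mb).
#' @param capture_mb Exome capture size (Mb).
#' @param cna_burden_means Per-subgroup expected mean |log2 ratio| per arm.
#' @param mutation_genes Named numeric vector of gene sampling weights
#'   (EGFR-dominant by default).
#' @param responder_model `NULL`, or a list `intercept`, `slope`, `effect`
#'   planting a latent immune-competence axis: each sample's competence
#'   `c ~ N(0,1)` shifts its TIC and IRP genes by `effect * c` z units on
#'   top of the subgroup panel shifts, and the response is drawn from the
#'   sample's *total* true signature shifts:
#'   `P(PR) = plogis(intercept + slope * (tic_shift + irp_shift) / 2)`,
#'   so responders concentrate in the all-functioning subgroup and, within
#'   it, among high-competence samples.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 99,
                          subgroup_probs = c(37, 15, 47) / 99,
                          panel_effects = default_panel_effects(),
                          signature_effects = default_signature_effects(),
                          effect_scale = 1,
                          gene_baseline_range = c(2, 8),
                          gene_sd = 1,
                          n_background_genes = 100,
                          tmb_means_per_mb = c(1.919, 2.644, 1.700),
                          capture_mb = 30,
                          cna_burden_means = c(0.6, 0.3, 0.4),
                          mutation_genes = default_mutation_genes(),
                          responder_model = NULL,
                          seed = 20180907) {
  cfg <- list(
    n_samples = n_samples, subgroup_probs = subgroup_probs,
    panel_effects = panel_effects, signature_effects = signature_effects,
    effect_scale = effect_scale,
    gene_baseline_range = gene_baseline_range, gene_sd = gene_sd,
    n_background_genes = n_background_genes,
    tmb_means_per_mb = tmb_means_per_mb, capture_mb = capture_mb,
    cna_burden_means = cna_burden_means, mutation_genes = mutation_genes,
    responder_model = responder_model, seed = seed
  )
  if (n_samples < 3) abort("n_samples must be >= 3")
  if (abs(sum(subgroup_probs) - 1) > 1e-9 || any(subgroup_probs < 0)) {
    abort("subgroup_probs must be non-negative and sum to 1")
  }
  if (gene_sd <= 0) abort("gene_sd must be positive")
  if (any(tmb_means_per_mb < 0) || capture_mb <= 0) abort("invalid TMB parameters")
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_panel_effects <- function() {
  # Planted phenotype pattern: subgroup 1 = UB+ IFN1p- AP-,
  # subgroup 2 = UB- IFN1s- AP-, subgroup 3 = UB+ IFN1+ AP+.
  tibble::tribble(
    ~panel, ~tag, ~s1, ~s2, ~s3,
    "A", NA, +1, -2, +1,
    "B", "production", -1, -2, +1,
    "B", "signaling", +1, -2, +1,
    "C", NA, -1, -1, +1,
    "D", NA, +1, -2, +1,
    "E", NA, -1, 0, +1,
    "F", NA, -1, +1, +1,
    "G", NA, -1, +1, +1,
    "H", NA, -1, -1, +1
  ) |>
    tidyr::pivot_longer(c("s1", "s2", "s3"),
      names_to = "subgroup", values_to = "shift"
    ) |>
    dplyr::mutate(subgroup = as.integer(sub("s", "", .data$subgroup))) |>
    dplyr::select("subgroup", "panel", "tag", "shift")
}

#' @rdname cohort_config
#' @export
default_signature_effects <- function() {
  tibble::tribble(
    ~signature, ~s1, ~s2, ~s3,
    "immune", -1, +1, +1,
    "stromal", -1, -1, +1,
    "cell_cycle", +1, -1, -1
  ) |>
    tidyr::pivot_longer(c("s1", "s2", "s3"),
      names_to = "subgroup", values_to = "shift"
    ) |>
    dplyr::mutate(subgroup = as.integer(sub("s", "", .data$subgroup))) |>
    dplyr::select("subgroup", "signature", "shift")
}

#' @rdname cohort_config
#' @export
default_mutation_genes <- function() {
  others <- c(
    "KRAS", "STK11", "KEAP1", "BRAF", "MET", "ERBB2", "PIK3CA", "RB1",
    "NF1", "ATM", "ARID1A", "SMARCA4", "SETD2", "CTNNB1", "MGA", "RBM10",
    "U2AF1", "PTEN", "NOTCH1", "FAT1", "KMT2D", "APC", "ROS1", "ALK",
    "RET", "CDK4", "MDM2", "NKX2-1", "TERT", "MYC"
  )
  c(EGFR = 8, TP53 = 5, CDKN2A = 3, setNames(rep(1, length(others)), others))
}

#' Convenience preset for a small checkpoint-blockade cohort
#'
#' A 13-sample cohort (the size of a small independent ICB-treated cohort)
#' with the same planted subgroup structure plus a latent immune-competence
#' axis driving both the TIC/IRP genes and the response labels, so
#' responder-enrichment properties of the TIC/IRP quadrant analysis can be
#' tested.
#'
#' @param n_samples Cohort size (default 13).
#' @param seed Seed.
#' @param ... Passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
icb_cohort_config <- function(n_samples = 13, seed = 20180907, ...) {
  cohort_config(
    n_samples = n_samples,
    responder_model = list(intercept = -1, slope = 2, effect = 1.5),
    seed = seed,
    ...
  )
}

# shift matrix genes x 3 subgroups from panel/signature effect tables
planted_shifts <- function(genes, panels, cfg, signatures) {
  shifts <- matrix(0, nrow = length(genes), ncol = 3, dimnames = list(genes, NULL))
  pe <- cfg$panel_effects
  for (i in seq_len(nrow(pe))) {
    g <- signature_genes(panels,
      panel = pe$panel[i],
      tag = if (is.na(pe$tag[i])) NULL else pe$tag[i]
    )
    g <- intersect(g, genes)
    shifts[g, pe$subgroup[i]] <- pe$shift[i]
  }
  se <- cfg$signature_effects
  for (i in seq_len(nrow(se))) {
    g <- intersect(signatures[[se$signature[i]]]$genes, genes)
    # panel membership wins where a marker gene is also a panel gene
    free <- g[shifts[g, se$subgroup[i]] == 0]
    shifts[free, se$subgroup[i]] <- se$shift[i]
  }
  shifts * cfg$effect_scale
}

#' Generate a synthetic cohort
#'
#' Draws subgroup memberships, a genes x samples expression matrix with the
#' configured panel shifts planted on the log2 scale (linear values are
#' `2^log2 - 1`, floored at 0, so a `log2(x + 1)` transform recovers the
#' latent scale), a mutation table with Poisson per-subgroup burdens and
#' EGFR-dominant gene weights (plus sporadic EGFR amplifications and CDKN2A
#' deep deletions, which do not count toward TMB), an arm-level CNA table
#' with subgroup-scaled noise, optional response labels, and a truth table
#' recording everything planted. Byte-identical for identical configs.
#'
#' @param config A [cohort_config()].
#' @param panels A `panel_set` (default: the built-in registry).
#' @param signatures Named signature list (default: [builtin_signatures()]).
#' @return List: `expression` ([expr_matrix], raw), `mutations`, `cna`,
#'   `response` (tibble or `NULL`), `truth`, `config`.
#' @export
generate_cohort <- function(config, panels = builtin_panel_set(),
                            signatures = builtin_signatures()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "cohort"), {
    n <- config$n_samples
    sample_ids <- sprintf("S%03d", seq_len(n))
    subgroup <- sample.int(3, n, replace = TRUE, prob = config$subgroup_probs)

    sig_genes <- unique(unlist(purrr::map(
      signatures[c("immune", "stromal", "cell_cycle")], "genes"
    )))
    genes <- unique(c(
      signature_genes(panels), sig_genes,
      sprintf("SYNBG%03d", seq_len(config$n_background_genes))
    ))
    shifts <- planted_shifts(genes, panels, config, signatures)

    mu <- runif(length(genes), config$gene_baseline_range[1], config$gene_baseline_range[2])
    log2_mat <- matrix(
      mu + rnorm(length(genes) * n, sd = config$gene_sd),
      nrow = length(genes), ncol = n, dimnames = list(genes, sample_ids)
    )
    log2_mat <- log2_mat + config$gene_sd * shifts[, subgroup]

    competence <- rep(NA_real_, n)
    tic_shift <- rep(NA_real_, n)
    irp_shift <- rep(NA_real_, n)
    response <- NULL
    if (!is.null(config$responder_model)) {
      rm_ <- config$responder_model
      competence <- rnorm(n)
      tic_genes <- intersect(signatures$TIC$genes, genes)
      irp_genes <- intersect(signatures$IRP$genes, genes)
      tic_irp_genes <- union(tic_genes, irp_genes)
      log2_mat[tic_irp_genes, ] <- log2_mat[tic_irp_genes, ] +
        config$gene_sd * rm_$effect * matrix(competence,
          nrow = length(tic_irp_genes), ncol = n, byrow = TRUE
        )
      # total planted shift of each signature, in z units
      tic_shift <- colMeans(shifts[tic_genes, subgroup, drop = FALSE]) +
        rm_$effect * competence
      irp_shift <- colMeans(shifts[irp_genes, subgroup, drop = FALSE]) +
        rm_$effect * competence
      p_pr <- stats::plogis(rm_$intercept + rm_$slope * (tic_shift + irp_shift) / 2)
      is_pr <- rbinom(n, 1, p_pr) == 1
      labels <- ifelse(is_pr, "PR", ifelse(rbinom(n, 1, 0.5) == 1, "NR", "PD"))
      response <- tibble::tibble(sample_id = sample_ids, response = labels)
    }

    raw <- pmax(2^log2_mat - 1, 0)
    expression <- expr_matrix(raw, state = "raw", provenance = "synthetic")

    gene_w <- config$mutation_genes
    n_mut <- rpois(n, config$tmb_means_per_mb[subgroup] * config$capture_mb)
    mut_classes <- c(missense = 0.75, truncating = 0.2, inframe = 0.05)
    mutations <- purrr::map_dfr(seq_len(n), function(i) {
      k <- n_mut[i]
      rows <- if (k > 0) {
        tibble::tibble(
          sample_id = sample_ids[i],
          gene = sample(names(gene_w), k, replace = TRUE, prob = gene_w),
          variant_class = sample(names(mut_classes), k, replace = TRUE, prob = mut_classes)
        )
      } else {
        tibble::tibble(
          sample_id = character(), gene = character(), variant_class = character()
        )
      }
      if (runif(1) < 0.15) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          sample_id = sample_ids[i], gene = "EGFR", variant_class = "amplification"
        ))
      }
      if (runif(1) < 0.10) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          sample_id = sample_ids[i], gene = "CDKN2A", variant_class = "deep_deletion"
        ))
      }
      rows
    })

    arms <- chromosome_arms()
    sigma_cna <- config$cna_burden_means / sqrt(2 / pi)
    cna <- tidyr::expand_grid(sample_id = sample_ids, arm = arms) |>
      dplyr::mutate(
        log2_ratio = rnorm(
          dplyr::n(),
          sd = rep(sigma_cna[subgroup], each = length(arms))
        )
      )

    truth <- tibble::tibble(
      sample_id = sample_ids,
      subgroup = subgroup,
      tmb_mean = config$tmb_means_per_mb[subgroup],
      cna_burden_mean = config$cna_burden_means[subgroup],
      competence = competence,
      true_tic_shift = tic_shift,
      true_irp_shift = irp_shift,
      response = if (is.null(response)) NA_character_ else response$response
    )

    list(
      expression = expression, mutations = mutations, cna = cna,
      response = response, truth = truth, config = config
    )
  })
}

#' Write a synthetic cohort to a directory
#'
#' Emits `expression.tsv`, `mutations.tsv`, `cna.tsv`, `response.tsv` (if
#' present) and `truth.tsv` in the dialects the reading functions consume;
#' [read_cohort()] round-trips them.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$mutations, file.path(dir, "mutations.tsv"), progress = FALSE)
  readr::write_tsv(cohort$cna, file.path(dir, "cna.tsv"), progress = FALSE)
  if (!is.null(cohort$response)) {
    readr::write_tsv(cohort$response, file.path(dir, "response.tsv"), progress = FALSE)
  }
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort TSVs.
#' @return List with the same shape as [generate_cohort()] output (minus
#'   `config`); missing optional files come back `NULL`.
#' @export
read_cohort <- function(dir) {
  resp_path <- file.path(dir, "response.tsv")
  truth_path <- file.path(dir, "truth.tsv")
  list(
    expression = read_expression(file.path(dir, "expression.tsv")),
    mutations = read_mutation_table(file.path(dir, "mutations.tsv")),
    cna = read_arm_cna(file.path(dir, "cna.tsv")),
    response = if (file.exists(resp_path)) {
      readr::read_tsv(resp_path, col_types = "cc", progress = FALSE)
    },
    truth = if (file.exists(truth_path)) {
      readr::read_tsv(truth_path,
        col_types = readr::cols(sample_id = "c", response = "c", .default = "d"),
        progress = FALSE
      )
    }
  )
}
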