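#' Canonical chromosome-arm vocabulary
#'
#' Autosomal arm labels `1p..22q`, excluding the acrocentric short arms
#' (13p, 14p, 15p, 21p, 22p), giving 39 arms.
#'
#' @param exclude_acrocentric_p Drop the acrocentric p-arms (default).
#' @return Character vector of arm labels.
#' @export
chromosome_arms <- function(exclude_acrocentric_p = TRUE) {
  arms <- as.vector(t(outer(1:22, c("p", "q"), paste0)))
  if (exclude_acrocentric_p) {
    arms <- setdiff(arms, paste0(c(13, 14, 15, 21, 22), "p"))
  }
  arms
}

variant_vocabulary <- c(
  "missense", "truncating", "inframe",
  "amplification", "deep_deletion", "silent", "other"
)

# MAF Variant_Classification -> internal closed vocabulary.
maf_class_map <- c(
  "Missense_Mutation" = "missense",
  "Nonsense_Mutation" = "truncating",
  "Frame_Shift_Del" = "truncating",
  "Frame_Shift_Ins" = "truncating",
  "Splice_Site" = "truncating",
  "Nonstop_Mutation" = "truncating",
  "Translation_Start_Site" = "truncating",
  "In_Frame_Del" = "inframe",
  "In_Frame_Ins" = "inframe",
  "Amplification" = "amplification",
  "Deep_Deletion" = "deep_deletion",
  "Homozygous_Deletion" = "deep_deletion",
  "Silent" = "silent"
)

#' Read a MAF-like somatic mutation table
#'
#' Accepts either MAF headers (`Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`, with classes collapsed to the internal
#' vocabulary via a documented mapping) or the internal headers
#' (`sample_id`, `gene`, `variant_class`). Unmapped MAF classes become
#' `"other"`.
#'
#' @param path Path to the TSV.
#' @return Tibble: `sample_id`, `gene`, `variant_class`.
#' @export
read_mutation_table <- function(path) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (all(c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification") %in% names(tbl))) {
    cls <- unname(maf_class_map[tbl$Variant_Classification])
    cls[is.na(cls)] <- "other"
    tbl <- tibble::tibble(
      sample_id = tbl$Tumor_Sample_Barcode,
      gene = canonicalize_symbols(tbl$Hugo_Symbol),
      variant_class = cls
    )
  } else if (all(c("sample_id", "gene", "variant_class") %in% names(tbl))) {
    tbl <- tbl[c("sample_id", "gene", "variant_class")]
    tbl$gene <- canonicalize_symbols(tbl$gene)
  } else {
    abort("unrecognized mutation table columns")
  }
  bad <- setdiff(unique(tbl$variant_class), variant_vocabulary)
  if (length(bad) > 0) {
    abort(paste0("variant classes outside vocabulary: ", paste(bad, collapse = ", ")))
  }
  tbl
}

#' Read an arm-level copy-number table
#'
#' SEG-like TSV with columns `sample`/`sample_id`, `arm`, `log2_ratio`;
#' arm labels must come from [chromosome_arms()] and each (sample, arm)
#' pair may appear once.
#'
#' @param path Path to the TSV.
#' @return Tibble: `sample_id`, `arm`, `log2_ratio`.
#' @export
read_arm_cna <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if ("sample" %in% names(tbl) && !"sample_id" %in% names(tbl)) {
    names(tbl)[names(tbl) == "sample"] <- "sample_id"
  }
  stopifnot(all(c("sample_id", "arm", "log2_ratio") %in% names(tbl)))
  tbl <- tbl[c("sample_id", "arm", "log2_ratio")]
  bad <- setdiff(unique(tbl$arm), chromosome_arms())
  if (length(bad) > 0) {
    abort(paste0("unknown chromosome arms: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tbl[c("sample_id", "arm")])) {
    abort("duplicate (sample, arm) records")
  }
  tbl
}

#' Tumor mutational burden per sample
#'
#' Mutations per megabase: the count of records whose class is in
#' `counted` (small variants only by default — amplifications and deep
#' deletions are excluded by convention) divided by the exome capture size.
#' Samples listed in `samples` but absent from the table get 0.
#'
#' @param muts Mutation tibble (`sample_id`, `gene`, `variant_class`).
#' @param capture_mb Capture size in Mb (> 0; default 30).
#' @param counted Variant classes counted toward TMB.
#' @param samples Optional full cohort sample vector (default: samples seen).
#' @return Tibble: `sample_id`, `n_mutations`, `tmb`.
#' @export
tmb <- function(muts, capture_mb = 30,
                counted = c("missense", "truncating", "inframe"),
                samples = NULL) {
  stopifnot(capture_mb > 0)
  if (length(counted) == 0) abort("counted classes must be non-empty")
  samples <- samples %||% sort(unique(muts$sample_id))
  counts <- muts |>
    dplyr::filter(.data$variant_class %in% counted) |>
    dplyr::count(.data$sample_id, name = "n_mutations")
  tibble::tibble(sample_id = samples) |>
    dplyr::left_join(counts, by = "sample_id") |>
    dplyr::mutate(
      n_mutations = dplyr::coalesce(.data$n_mutations, 0L),
      tmb = .data$n_mutations / capture_mb
    )
}

#' Arm-level somatic copy-number burden
#'
#' Per-sample burden is the mean absolute arm log2 ratio (unsigned: both
#' amplification and deletion add burden); the normalized sCNA score is its
#' population z-score across the cohort (all-zero if the cohort burden is
#' constant).
#'
#' @param cna Arm CNA tibble (`sample_id`, `arm`, `log2_ratio`).
#' @return Tibble: `sample_id`, `burden`, `scna_score`.
#' @export
scna_burden <- function(cna) {
  if (nrow(cna) == 0) abort("empty CNA table")
  out <- cna |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(burden = mean(abs(.data$log2_ratio)), .groups = "drop")
  out$scna_score <- zscore_pop(out$burden)
  out
}

#' Signed per-subgroup arm profile
#'
#' Mean signed log2 ratio per (subgroup, arm) — amplification and deletion
#' directions are preserved, unlike the scalar burden.
#'
#' @param cna Arm CNA tibble.
#' @param assignment A `subgroup_assignment` covering the CNA samples.
#' @return Tibble: `cluster`, `arm`, `mean_log2_ratio`, `n`.
#' @export
subgroup_arm_profile <- function(cna, assignment) {
  stopifnot(inherits(assignment, "subgroup_assignment"))
  miss <- setdiff(unique(cna$sample_id), assignment$sample_ids)
  if (length(miss) > 0) abort(paste0("CNA samples without assignment: ", paste(miss, collapse = ", ")))
  cna |>
    dplyr::mutate(cluster = unname(assignment$cluster[.data$sample_id])) |>
    dplyr::group_by(.data$cluster, .data$arm) |>
    dplyr::summarise(
      mean_log2_ratio = mean(.data$log2_ratio), n = dplyr::n(), .groups = "drop"
    )
}

#' Mutation landscape by subgroup
#'
#' For each requested gene and subgroup, the fraction of subgroup samples
#' carrying at least one record of that gene (a sample with several variant
#' classes in one gene counts once). A per-class breakdown is attached as
#' attribute `"by_class"`.
#'
#' @param muts Mutation tibble.
#' @param genes Ordered character vector of genes to report.
#' @param assignment A `subgroup_assignment`.
#' @return Tibble: `gene`, `cluster`, `n_altered`, `n_samples`, `frequency`.
#' @export
mutation_landscape <- function(muts, genes, assignment) {
  if (length(genes) == 0) abort("genes must be non-empty")
  stopifnot(inherits(assignment, "subgroup_assignment"))
  genes <- canonicalize_symbols(genes)
  cl_tbl <- tibble::tibble(
    sample_id = assignment$sample_ids,
    cluster = unname(assignment$cluster)
  )
  sizes <- dplyr::count(cl_tbl, .data$cluster, name = "n_samples")
  hits <- muts |>
    dplyr::filter(.data$gene %in% genes, .data$sample_id %in% cl_tbl$sample_id) |>
    dplyr::inner_join(cl_tbl, by = "sample_id")
  alt <- hits |>
    dplyr::distinct(.data$gene, .data$sample_id, .data$cluster) |>
    dplyr::count(.data$gene, .data$cluster, name = "n_altered")
  grid <- tidyr::expand_grid(
    gene = genes, cluster = sort(unique(cl_tbl$cluster))
  )
  out <- grid |>
    dplyr::left_join(alt, by = c("gene", "cluster")) |>
    dplyr::left_join(sizes, by = "cluster") |>
    dplyr::mutate(
      n_altered = dplyr::coalesce(.data$n_altered, 0L),
      frequency = .data$n_altered / .data$n_samples
    )
  by_class <- hits |>
    dplyr::distinct(.data$gene, .data$sample_id, .data$cluster, .data$variant_class) |>
    dplyr::count(.data$gene, .data$cluster, .data$variant_class, name = "n_altered") |>
    dplyr::left_join(sizes, by = "cluster") |>
    dplyr::mutate(frequency = .data$n_altered / .data$n_samples)
  attr(out, "by_class") <- by_class
  out
}
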