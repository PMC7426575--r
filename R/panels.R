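#' Cancer-immune gene panel registries
#'
#' The pipeline clusters tumors on an eight-panel registry of immune
#' function-related genes covering the cancer-immunity cycle:
#' ubiquitination/deubiquitination (A), type I interferon
#' production/signaling (B), antigen-processing/presenting machinery (C),
#' TGF-beta signaling (D), NK-cell activation (E), dendritic-cell activation
#' (F), tumor-microenvironment immune status (G), and CD8 T-cell
#' activation/trafficking/killing (H). The full 546-gene registry is
#' distributed as supplementary data by its authors and is read from a
#' user-supplied file; a reduced built-in registry of curated marker genes
#' ships with the package and is sufficient for simulation and testing.
#'
#' A panel set is a tibble with columns `gene`, `panel` and `tag` (tag is
#' `NA` except where a panel distinguishes functional arms, e.g. panel B's
#' "production" vs "signaling"), carrying `version` and `source` attributes.
#'
#' @name panel_set
NULL

new_panel_set <- function(tbl, version, source) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("gene", "panel", "tag") %in% names(tbl)))
  structure(
    tbl[c("gene", "panel", "tag")],
    version = version,
    source = source,
    class = c("panel_set", class(tibble::tibble()))
  )
}

validate_panel_set <- function(ps, full_registry = FALSE) {
  if (nrow(ps) == 0) abort("panel set is empty")
  bad <- setdiff(unique(ps$panel), LETTERS[1:8])
  if (length(bad) > 0) {
    abort(paste0("panel ids outside A-H: ", paste(bad, collapse = ", ")))
  }
  dup <- ps[duplicated(ps[c("gene", "panel")]), ]
  if (nrow(dup) > 0) {
    abort("duplicate (gene, panel) rows remain after collapse")
  }
  sizes <- table(ps$panel)
  if (any(sizes == 0)) abort("empty panel")
  if (full_registry) {
    if (length(sizes) != 8) {
      abort(sprintf("full registry must have 8 panels, found %d", length(sizes)))
    }
    n_union <- length(unique(ps$gene))
    if (n_union != 546) {
      abort(sprintf("full registry must contain 546 distinct genes, found %d", n_union))
    }
  }
  invisible(ps)
}

#' Load a gene-panel registry from a tab-separated file
#'
#' Expects a UTF-8 TSV with header `gene<TAB>panel<TAB>tag` (the `tag`
#' column may be omitted), one row per (gene, panel) membership. Gene
#' symbols are canonicalized via [canonicalize_symbols()]; duplicate
#' (gene, panel) rows are collapsed with a warning; panel letters outside
#' A-H are rejected. A gene may belong to several panels; the union counts
#' it once.
#'
#' @param path Path to the registry TSV.
#' @param full_registry If `TRUE`, additionally require the 8-panel /
#'   546-gene shape of the complete registry.
#' @param version Version string stored on the result.
#' @return A `panel_set` tibble (columns `gene`, `panel`, `tag`).
#' @export
load_panel_set <- function(path, full_registry = FALSE, version = "1") {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("gene", "panel") %in% names(raw))) {
    abort("panel file must have 'gene' and 'panel' columns")
  }
  if (!"tag" %in% names(raw)) raw$tag <- NA_character_
  if (nrow(raw) == 0) abort("panel file has no rows")
  if (any(is.na(raw$gene) | raw$gene == "" | is.na(raw$panel) | raw$panel == "")) {
    abort("malformed row: empty gene or panel field")
  }
  raw$gene <- canonicalize_symbols(raw$gene)
  raw$panel <- toupper(trimws(raw$panel))
  ndup <- sum(duplicated(raw[c("gene", "panel")]))
  if (ndup > 0) {
    warn(sprintf("collapsed %d duplicate (gene, panel) rows", ndup))
    raw <- raw[!duplicated(raw[c("gene", "panel")]), ]
  }
  raw <- dplyr::arrange(raw, .data$panel)
  ps <- new_panel_set(raw, version = version, source = basename(path))
  validate_panel_set(ps, full_registry = full_registry)
  ps
}

#' Write a panel set back to its TSV dialect
#'
#' Canonical ordering (panels A-H, file order within panel) makes
#' load/write/load round-trips bit-identical.
#'
#' @param ps A `panel_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_set <- function(ps, path) {
  readr::write_tsv(tibble::as_tibble(ps), path, progress = FALSE)
  invisible(path)
}

#' The built-in reduced cancer-immune registry
#'
#' Eight panels of curated marker genes (roughly 10-20 per panel) standing in
#' for the full 546-gene registry, sized for simulation and testing. Panel B
#' rows carry "production"/"signaling" tags because those arms are scored
#' separately when labeling phenotypes.
#'
#' @return A `panel_set` tibble.
#' @export
builtin_panel_set <- function() {
  path <- system.file("extdata", "cancer_immune_panels.tsv",
    package = "immunocycle", mustWork = TRUE
  )
  load_panel_set(path, version = "builtin-test")
}

#' Built-in gene signatures
#'
#' Returns the named gene sets the scoring layer uses:
#' * `TIC` — tumor-intrinsic classifier: IFI16, MYD88, JAK2 (type I IFN
#'   pathway) plus TAP1, TAP2, PSMB9, HLA-DQA1 (antigen presentation).
#' * `IRP` — immune response predictor: IFNGR1, CD274 (PD-L1), CXCL9,
#'   IFNG, PDCD1 (PD-1), CXCR3 — the tumor/T-cell interaction axis.
#' * `CYT` — cytolytic activity: GZMA and PRF1.
#' * `immune`, `stromal`, `cell_cycle` — average-expression marker sets used
#'   as replacements for score gene lists that are distributed only as
#'   supplementary data; configurable via the `extra` argument.
#'
#' @param extra Optional named list of character vectors merged over the
#'   defaults (same-name entries replace the default set).
#' @return Named list of `gene_signature` objects.
#' @export
builtin_signatures <- function(extra = NULL) {
  sets <- list(
    TIC = c("IFI16", "MYD88", "JAK2", "TAP1", "TAP2", "PSMB9", "HLA-DQA1"),
    IRP = c("IFNGR1", "CD274", "CXCL9", "IFNG", "PDCD1", "CXCR3"),
    CYT = c("GZMA", "PRF1"),
    immune = c(
      "PTPRC", "CD2", "CD3E", "CD8A", "CD19", "MS4A1", "CD79A",
      "IL7R", "CCL5", "GZMK"
    ),
    stromal = c(
      "COL1A1", "COL1A2", "COL3A1", "FAP", "PDGFRB", "ACTA2",
      "THY1", "DCN", "LUM", "FN1"
    ),
    cell_cycle = c(
      "MKI67", "PLK1", "CCNB1", "CDK1", "BUB1", "AURKA",
      "TOP2A", "BIRC5", "CCNA2", "CDC20"
    )
  )
  if (!is.null(extra)) {
    stopifnot(is.list(extra), !is.null(names(extra)))
    for (nm in names(extra)) sets[[nm]] <- extra[[nm]]
  }
  out <- purrr::imap(sets, new_gene_signature)
  stopifnot(
    length(intersect(out$TIC$genes, out$IRP$genes)) == 0,
    length(out$CYT$genes) == 2
  )
  out
}

#' Construct a gene signature
#'
#' @param genes Character vector of gene symbols (canonicalized, deduplicated,
#'   order preserved).
#' @param name Signature name.
#' @return A `gene_signature` (list with `name`, `genes`).
#' @export
new_gene_signature <- function(genes, name) {
  genes <- canonicalize_symbols(genes)
  genes <- genes[!duplicated(genes)]
  if (length(genes) == 0) abort("signature has no genes")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf(
    "<gene_signature> %s (%d genes): %s\n",
    x$name, length(x$genes), paste(x$genes, collapse = ", ")
  ))
  invisible(x)
}

# Resolve a panel_set / gene_signature / character vector to gene symbols.
signature_genes <- function(x, panel = NULL, tag = NULL) {
  if (inherits(x, "gene_signature")) {
    return(x$genes)
  }
  if (inherits(x, "panel_set")) {
    tbl <- tibble::as_tibble(x)
    if (!is.null(panel)) tbl <- tbl[tbl$panel %in% panel, ]
    if (!is.null(tag)) tbl <- tbl[!is.na(tbl$tag) & tbl$tag %in% tag, ]
    return(unique(tbl$gene))
  }
  if (is.character(x)) {
    return(unique(canonicalize_symbols(x)))
  }
  abort("cannot resolve genes from object of class ", paste(class(x), collapse = "/"))
}

#' Subset an expression matrix to a panel or signature
#'
#' Keeps the rows of `expr` whose genes belong to the panel/signature,
#' preserving the panel's gene order. Missing genes are reported via the
#' result's provenance (`missing_genes`, `fraction_present` attributes).
#'
#' @param expr An [expr_matrix].
#' @param genes A `panel_set`, `gene_signature`, or character vector.
#' @param panel,tag Optional panel letter(s)/tag(s) to restrict a `panel_set`.
#' @return An `expr_matrix` restricted to the overlapping genes.
#' @export
subset_expression <- function(expr, genes, panel = NULL, tag = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  want <- signature_genes(genes, panel = panel, tag = tag)
  have <- intersect(want, rownames(expr$values))
  if (length(have) == 0) abort("no overlap between requested genes and expression matrix")
  missing <- setdiff(want, have)
  out <- expr
  out$values <- expr$values[have, , drop = FALSE]
  out$provenance <- c(expr$provenance, sprintf("subset:%d/%d genes", length(have), length(want)))
  attr(out, "missing_genes") <- missing
  attr(out, "fraction_present") <- length(have) / length(want)
  out
}

#' Fabricate a synthetic full-size registry file
#'
#' Writes an explicitly synthetic 8-panel registry whose union is exactly
#' 546 gene symbols (the built-in marker genes padded with synthetic
#' `SYNGENE###` symbols), used to exercise the full-registry validation path
#' of [load_panel_set()] when the real supplementary registry is not at hand.
#' The content is a stand-in: panel memberships beyond the built-in markers
#' are arbitrary.
#'
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
synthetic_full_registry <- function(path = tempfile("synthetic_registry_", fileext = ".tsv")) {
  base <- tibble::as_tibble(builtin_panel_set())
  n_have <- length(unique(base$gene))
  n_pad <- 546 - n_have
  stopifnot(n_pad > 0)
  pad <- tibble::tibble(
    gene = sprintf("SYNGENE%03d", seq_len(n_pad)),
    panel = LETTERS[1 + (seq_len(n_pad) - 1) %% 8],
    tag = NA_character_
  )
  readr::write_tsv(dplyr::bind_rows(base, pad), path, progress = FALSE)
  invisible(path)
}
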