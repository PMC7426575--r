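#' Expression matrix container
#'
#' A light wrapper around a dense genes x samples numeric matrix that tracks
#' the normalization state of its values: `raw` (linear, non-negative),
#' `log` (log2 of raw + offset), or `zscore` (per-gene population z-score of
#' the log values). Downstream stages check the state so that, e.g., the
#' mixture model always sees z-scored features and the cytolytic-activity
#' geometric mean always sees linear values.
#'
#' @param values Numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param state One of `"raw"`, `"log"`, `"zscore"`.
#' @param provenance Character vector of applied transforms.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values, state = "raw", provenance = character()) {
  stopifnot(
    is.matrix(values), is.numeric(values),
    !is.null(rownames(values)), !is.null(colnames(values))
  )
  if (anyDuplicated(rownames(values))) abort("duplicate gene ids")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids")
  if (anyNA(values)) abort("expression matrix contains missing values")
  state <- match.arg(state, c("raw", "log", "zscore"))
  if (state == "raw" && any(values < 0)) {
    abort("raw expression values must be non-negative")
  }
  structure(
    list(values = values, state = state, provenance = provenance),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples, state=%s\n",
    nrow(x$values), ncol(x$values), x$state
  ))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Genes and samples of an expression matrix
#' @param expr An `expr_matrix`.
#' @return Character vector of ids.
#' @export
expr_genes <- function(expr) rownames(expr$values)

#' @rdname expr_genes
#' @export
expr_samples <- function(expr) colnames(expr$values)

#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene")
}

#' Read an expression matrix from TSV
#'
#' First column gene ids, header row sample ids, numeric body. Duplicate gene
#' rows are collapsed by mean (with a warning); blank cells are imputed to 0
#' (with a warning giving the count); any other non-numeric cell is an error.
#' The result has `state = "raw"`.
#'
#' @param path Path to the TSV.
#' @return An `expr_matrix` with `state = "raw"`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  # check the raw header before readr repairs duplicated column names
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) abort("duplicate sample ids in header")
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(tbl) < 2 || nrow(tbl) == 0) abort("empty expression matrix")
  genes <- canonicalize_symbols(tbl[[1]])
  body <- as.matrix(tbl[, -1, drop = FALSE])
  blank <- is.na(body) | body == ""
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- !blank & is.na(num)
  if (any(bad)) abort(sprintf("%d non-numeric cells in expression body", sum(bad)))
  if (any(blank)) {
    warn(sprintf("imputed %d blank expression cells to 0", sum(blank)))
    num[blank] <- 0
  }
  dimnames(num) <- list(genes, names(tbl)[-1])
  if (anyDuplicated(genes)) {
    warn(sprintf("collapsed %d duplicate gene rows by mean", sum(duplicated(genes))))
    num <- rowsum(num, group = genes, reorder = TRUE) /
      as.vector(table(genes)[sort(unique(genes))])
  }
  expr_matrix(num, state = "raw", provenance = paste0("read:", basename(path)))
}

#' Write an expression matrix in the same TSV dialect
#'
#' @param expr An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  readr::write_tsv(as_tibble.expr_matrix(expr), path, progress = FALSE)
  invisible(path)
}

#' Log-transform raw expression
#'
#' `log2(x + offset)` applied element-wise. Only valid on `state = "raw"`.
#'
#' @param expr An `expr_matrix` with `state = "raw"`.
#' @param offset Positive pseudocount (default 1).
#' @return An `expr_matrix` with `state = "log"`.
#' @export
log_transform <- function(expr, offset = 1) {
  stopifnot(inherits(expr, "expr_matrix"), offset > 0)
  if (expr$state != "raw") {
    abort(paste0("log_transform requires state 'raw', got '", expr$state, "'"))
  }
  out <- expr
  out$values <- log2(expr$values + offset)
  out$state <- "log"
  out$provenance <- c(expr$provenance, sprintf("log2(x+%g)", offset))
  out
}

#' Z-score each gene across samples
#'
#' Per-gene population z-score (divide by the 1/n standard deviation), the
#' convention of z-score heatmaps: every non-constant gene row ends with mean
#' 0 and standard deviation 1 across samples; constant rows become all-zero
#' (listed in a warning). Intended on log-scale values; calling it on raw
#' values works but warns.
#'
#' @param expr An `expr_matrix` with `state = "log"` (or `"raw"`, warned).
#' @return An `expr_matrix` with `state = "zscore"`.
#' @export
zscore_genes <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr$values) < 2) abort("z-scoring needs at least 2 samples")
  if (expr$state == "raw") {
    warn("z-scoring raw (not log-transformed) expression")
  }
  zr <- zscore_rows(expr$values)
  if (length(zr$constant) > 0) {
    warn(paste0(
      "constant gene rows set to zero: ",
      paste(rownames(expr$values)[zr$constant], collapse = ", ")
    ))
  }
  out <- expr
  out$values <- zr$z
  out$state <- "zscore"
  out$provenance <- c(expr$provenance, "zscore:per-gene population")
  out
}
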