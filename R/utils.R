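#' @importFrom rlang %||% abort warn inform
#' @importFrom stats quantile rnorm rpois runif rbinom sd setNames
#' @importFrom utils combn
NULL

# Population z-score of a vector; constant vectors map to all-zero.
# Population (1/n) variance is used throughout the package so that z-scored
# summaries match the heatmap convention (mean 0, sd 1 over the cohort).
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) {
    return(rep(0, length(x)))
  }
  (x - m) / s
}

# Row-wise population z-score of a matrix, returning indices of constant rows.
zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  centered <- mat - mu
  s <- sqrt(rowMeans(centered^2))
  constant <- which(s == 0)
  s[constant] <- 1
  z <- centered / s
  z[constant, ] <- 0
  list(z = z, constant = constant)
}

#' Map the protein-style aliases used in immuno-oncology gene lists to
#' HGNC symbols
#'
#' Expression matrices are keyed by HGNC symbols while clinical gene lists
#' often use protein names (PD-L1, PD-1, IFN-gamma). A small static alias
#' table is applied whenever symbols enter the package; matching is
#' case-insensitive and the canonical form is uppercase.
#'
#' @param symbols Character vector of gene symbols or protein aliases.
#' @return Character vector of canonical HGNC symbols, same length.
#' @examples
#' canonicalize_symbols(c("PD-L1", "pd-1", "IFNg", "GZMA"))
#' @export
canonicalize_symbols <- function(symbols) {
  stopifnot(is.character(symbols))
  up <- toupper(trimws(symbols))
  alias <- c(
    "PD-L1" = "CD274", "PDL1" = "CD274", "B7-H1" = "CD274",
    "PD-1" = "PDCD1", "PD1" = "PDCD1",
    "IFNγ" = "IFNG", "IFN-γ" = "IFNG", "IFNG" = "IFNG",
    "IFN-GAMMA" = "IFNG", "IFNGAMMA" = "IFNG",
    "NKP30" = "NCR3", "NKP44" = "NCR2", "NKP46" = "NCR1",
    "NKG2D" = "KLRK1", "NKG2A" = "KLRC1", "CD94" = "KLRD1"
  )
  hit <- up %in% names(alias)
  up[hit] <- alias[up[hit]]
  unname(up)
}

# Deterministic child seed derivation: one top-level seed fans out to stages.
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed))
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 7919 + offs) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}
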