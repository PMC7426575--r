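test_that("signature scores are per-sample means over present genes", {
  e <- make_expr(matrix(c(2, 4, 3, 5), 2, 2, dimnames = list(c("A1", "A2"), c("s1", "s2"))))
  sc <- signature_score(e, c("A1", "A2"))
  expect_equal(unname(sc), c(3, 4), ignore_attr = TRUE)

  one <- signature_score(e, "A2")
  expect_equal(unname(one), unname(e$values["A2", ]), ignore_attr = TRUE)

  # loop oracle on a random 30-gene signature over a 100x20 matrix
  big <- random_expr(100, 20, seed = 12)
  set.seed(13)
  sig <- sample(rownames(big$values), 30)
  sc2 <- signature_score(big, sig)
  oracle <- numeric(20)
  for (j in 1:20) {
    tot <- 0
    for (g in sig) tot <- tot + big$values[g, j]
    oracle[j] <- tot / length(sig)
  }
  expect_lt(max(abs(unname(sc2) - oracle)), 1e-12)

  # gene-order permutation invariance
  expect_equal(signature_score(big, rev(sig)), sc2, ignore_attr = TRUE)
})

test_that("percentile classes use interpolated percentiles with strict bounds", {
  sc <- setNames(as.numeric(1:10), paste0("s", 1:10))
  cls <- percentile_classes(sc, hi = 70, lo = 30)
  # sorting oracle: type-7 interpolated percentiles of 1..10 are 3.7 and 7.3
  srt <- sort(sc)
  q30 <- srt[3] + 0.7 * (srt[4] - srt[3])
  q70 <- srt[7] + 0.3 * (srt[8] - srt[7])
  expect_equal(unname(cls), unname(ifelse(sc > q70, "high", ifelse(sc < q30, "low", "mid"))))
  expect_equal(sum(cls == "high"), 3)
  expect_equal(sum(cls == "low"), 3)

  expect_warning(all_mid <- percentile_classes(rep(2, 5)), "constant")
  expect_true(all(all_mid == "mid"))
  expect_error(percentile_classes(sc, hi = 50, lo = 50), "lo < hi")
})

test_that("cytolytic activity is the pseudocounted geometric mean of GZMA and PRF1", {
  mk <- function(g, p) {
    make_expr(matrix(c(g, p), 2, length(g),
      byrow = TRUE,
      dimnames = list(c("GZMA", "PRF1"), paste0("s", seq_along(g)))
    ))
  }
  expect_equal(unname(cytolytic_activity(mk(0, 0))), 0)
  expect_equal(unname(cytolytic_activity(mk(3, 3))), 3)
  expect_equal(unname(cytolytic_activity(mk(1, 7))), 3) # sqrt(2 * 8) - 1

  # scale-equivariance in the large-value limit: doubling doubles CYT + 1
  big <- mk(c(1e6, 2e6), c(3e6, 6e6))
  cyt <- cytolytic_activity(big)
  expect_equal((cyt[2] + 1) / (cyt[1] + 1), 2, tolerance = 1e-3, ignore_attr = TRUE)

  expect_error(cytolytic_activity(log_transform(mk(1, 1))), "linear")
  no_prf1 <- make_expr(matrix(1, 1, 2, dimnames = list("GZMA", c("a", "b"))))
  expect_error(cytolytic_activity(no_prf1), "PRF1")
})

test_that("subgroup summaries are within-cohort z-scores averaged by subgroup", {
  mk_assign <- function(cl) {
    structure(
      list(
        sample_ids = names(cl), cluster = cl,
        posteriors = NULL, k = max(cl), phenotypes = NULL
      ),
      class = "subgroup_assignment"
    )
  }
  scores <- tibble::tibble(sample_id = paste0("s", 1:4), sc = c(0, 0, 2, 2))
  a <- mk_assign(setNames(c(1L, 1L, 2L, 2L), scores$sample_id))
  out <- subgroup_summary(scores, a)
  expect_equal(out$mean_z, c(-1, 1))

  # z-score conservation: subgroup means weighted by size sum to 0
  set.seed(21)
  scores2 <- tibble::tibble(
    sample_id = paste0("s", 1:30),
    a = rnorm(30), b = rexp(30), c = runif(30)
  )
  cl2 <- setNames(sample(1:3, 30, replace = TRUE), scores2$sample_id)
  a2 <- mk_assign(cl2)
  out2 <- subgroup_summary(scores2, a2)
  tot <- out2 |>
    dplyr::group_by(score) |>
    dplyr::summarise(w = sum(mean_z * n))
  expect_lt(max(abs(tot$w)), 1e-9)

  # loop oracle
  for (nm in c("a", "b", "c")) {
    v <- scores2[[nm]]
    z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
    for (g in 1:3) {
      expect_lt(
        abs(out2$mean_z[out2$score == nm & out2$cluster == g] - mean(z[cl2 == g])),
        1e-12
      )
    }
  }
})

test_that("two-group comparisons match exact enumeration and reference tests", {
  v <- setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  mw <- compare_groups(v, paste0("s", 1:3), paste0("s", 4:6), method = "mann_whitney_u")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 0.1) # 2 * 1/20 by full enumeration

  # identical groups: exact-enumeration convention gives p = 1
  w <- setNames(c(5, 5, 5, 5), paste0("s", 1:4))
  same <- compare_groups(w, paste0("s", 1:2), paste0("s", 3:4), method = "mann_whitney_u")
  expect_equal(same$p_value, 1)

  # exact branch agrees with wilcox.test's exact p on untied data
  set.seed(31)
  u <- setNames(rnorm(12), paste0("s", 1:12))
  ours <- compare_groups(u, paste0("s", 1:6), paste0("s", 7:12), method = "mann_whitney_u")
  ref <- stats::wilcox.test(u[1:6], u[7:12], exact = TRUE)
  expect_equal(ours$p_value, ref$p.value)

  # label-swap invariance
  swapped <- compare_groups(u, paste0("s", 7:12), paste0("s", 1:6), method = "mann_whitney_u")
  expect_equal(ours$p_value, swapped$p_value)

  tt <- compare_groups(u, paste0("s", 1:6), paste0("s", 7:12), method = "welch_t")
  ref_t <- stats::t.test(u[1:6], u[7:12])
  expect_equal(tt$p_value, ref_t$p.value)
  swapped_t <- compare_groups(u, paste0("s", 7:12), paste0("s", 1:6), method = "welch_t")
  expect_equal(tt$p_value, swapped_t$p_value)

  expect_error(compare_groups(v, "s1", "s1", method = "welch_t"), "overlap")
  expect_error(compare_groups(v, character(), "s1", method = "welch_t"), "empty")
  expect_error(compare_groups(v, "s1", c("s2", "s3"), method = "welch_t"), ">= 2")
})

test_that("subgroup-wise comparisons assemble a tidy table with optional BH", {
  co <- generate_cohort(cohort_config(seed = 5, n_samples = 40))
  fit <- cluster_cohort(co, seed = 1, n_init = 3)
  scores <- score_table(co$expression)
  cmp <- compare_subgroup_scores(scores, fit$assignment, method = "mann_whitney_u")
  expect_equal(nrow(cmp), 3 * (ncol(scores) - 1))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
  adj <- compare_subgroup_scores(scores, fit$assignment, adjust = TRUE)
  expect_equal(adj$p_adjusted, stats::p.adjust(adj$p_value, "BH"))
})

test_that("cell-fraction tables are sanity-checked on read", {
  tbl <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    t_cells = c(0.2, 1.4, 0.3),
    b_cells = c(0.1, 0.2, 0.9)
  )
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, path, progress = FALSE)
  expect_warning(out <- read_cell_fractions(path), "rejected")
  expect_equal(out$sample_id, "a")
  expect_setequal(attr(out, "rejected"), c("b", "c"))
})
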