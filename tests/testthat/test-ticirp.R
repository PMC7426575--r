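test_that("geometric-mean scores match closed forms and are order-invariant", {
  sig <- new_gene_signature(c("A1", "A2", "A3"), "toy")
  v <- matrix(c(2, 2, 2, 1, 7, 7), 3, 2, dimnames = list(c("A1", "A2", "A3"), c("x", "y")))
  e <- make_expr(v)
  expect_equal(unname(geometric_mean_score(e, sig, pseudocount = 0)["x"]), 2)

  two <- make_expr(matrix(c(1, 7), 2, 1, dimnames = list(c("A1", "A2"), "x")))
  expect_equal(
    unname(geometric_mean_score(two, c("A1", "A2"), pseudocount = 1)), 3,
    ignore_attr = TRUE
  )

  # AM-GM: geometric mean never exceeds the arithmetic mean (pseudocount 0)
  r <- random_expr(20, 8, seed = 9)
  gm <- geometric_mean_score(r, rownames(r$values)[1:10], pseudocount = 0)
  am <- signature_score(r, rownames(r$values)[1:10])
  expect_true(all(gm <= am + 1e-9))

  # gene-order permutation invariance
  expect_equal(
    geometric_mean_score(r, rev(rownames(r$values)[1:10])),
    geometric_mean_score(r, rownames(r$values)[1:10])
  )

  # loop oracle
  gm1 <- geometric_mean_score(r, rownames(r$values)[1:5], pseudocount = 1)
  for (j in 1:8) {
    prod_ <- 1
    for (g in rownames(r$values)[1:5]) prod_ <- prod_ * (r$values[g, j] + 1)
    expect_lt(abs(gm1[j] - (prod_^(1 / 5) - 1)), 1e-9)
  }

  expect_error(geometric_mean_score(log_transform(r), "G1"), "raw")
})

test_that("TIC/IRP scoring normalizes within cohort and assigns quadrants", {
  co <- generate_cohort(cohort_config(seed = 11, n_samples = 50))
  res <- tic_irp_scores(co$expression)
  expect_s3_class(res, "tic_irp_result")
  expect_lt(abs(mean(res$tic_norm)), 1e-9)
  expect_lt(abs(mean(res$irp_norm)), 1e-9)
  expect_equal(sum(tabulate(res$quadrant, 4)), 50)
  # quadrant definition oracle
  expect_equal(
    res$quadrant,
    ifelse(res$tic_norm >= 0,
      ifelse(res$irp_norm >= 0, 1L, 4L),
      ifelse(res$irp_norm >= 0, 2L, 3L)
    )
  )
  # raw scores agree with direct geometric means
  expect_equal(
    res$tic_raw,
    unname(geometric_mean_score(co$expression, builtin_signatures()$TIC))
  )

  # sample-order invariance of raw scores and quadrant counts
  set.seed(1)
  perm <- sample(seq_len(50))
  shuf <- expr_matrix(co$expression$values[, perm], state = "raw")
  res2 <- tic_irp_scores(shuf)
  expect_equal(res2$tic_raw, res$tic_raw[perm], ignore_attr = TRUE)
  expect_equal(tabulate(res2$quadrant, 4), tabulate(res$quadrant, 4))

  # alternative normalizations keep quadrant semantics
  mm <- tic_irp_scores(co$expression, normalization = "minmax")
  expect_true(all(mm$tic_norm >= -0.5 & mm$tic_norm <= 0.5))

  tiny <- expr_matrix(co$expression$values[, 1:2], state = "raw")
  expect_error(tic_irp_scores(tiny), ">= 3")
  few <- expr_matrix(
    co$expression$values[setdiff(rownames(co$expression$values), c("TAP1", "TAP2", "PSMB9", "HLA-DQA1")), ],
    state = "raw"
  )
  expect_error(tic_irp_scores(few), "TIC")
})

test_that("tidy/glance/print expose the per-sample table and summary", {
  co <- generate_cohort(cohort_config(seed = 12, n_samples = 20))
  res <- tic_irp_scores(co$expression)
  td <- tidy(res)
  expect_equal(nrow(td), 20)
  expect_true(all(c("sample_id", "tic_norm", "irp_norm", "quadrant") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n, 20)
  expect_equal(gl$pearson_r, stats::cor(res$tic_norm, res$irp_norm))
  expect_output(print(res), "tic_irp_result")
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("response association reproduces hand-computable correlations", {
  mk_result <- function(tic, irp, resp) {
    structure(
      list(
        sample_ids = paste0("s", seq_along(tic)),
        tic_raw = tic, irp_raw = irp, tic_norm = tic, irp_norm = irp,
        quadrant = ifelse(tic >= 0,
          ifelse(irp >= 0, 1L, 4L), ifelse(irp >= 0, 2L, 3L)
        ),
        response = resp
      ),
      class = "tic_irp_result"
    )
  }
  # perfectly collinear scores: Pearson r = 1 / -1
  x <- c(-2, -1, 0.5, 1, 2, 3)
  resp <- c("PD", "NR", "NR", "PR", "PR", "PR")
  out <- response_association(mk_result(x, 2 * x, resp))
  expect_equal(out$pearson_r, 1)
  expect_equal(response_association(mk_result(x, -x, resp))$pearson_r, -1)
  expect_equal(out$n_responders, 3)
  expect_equal(out$responders_in_q1, 3)
  expect_equal(sum(out$quadrant_counts$n), 6)

  # Pearson loop oracle on a 10-point fixture
  set.seed(15)
  a <- rnorm(10)
  b <- 0.4 * a + rnorm(10)
  resp10 <- rep(c("PR", "NR"), 5)
  got <- response_association(mk_result(a, b, resp10))
  mx <- mean(a)
  my <- mean(b)
  num <- 0
  dx <- 0
  dy <- 0
  for (i in 1:10) {
    num <- num + (a[i] - mx) * (b[i] - my)
    dx <- dx + (a[i] - mx)^2
    dy <- dy + (b[i] - my)^2
  }
  expect_lt(abs(got$pearson_r - num / sqrt(dx * dy)), 1e-12)

  # Welch tests agree with stats::t.test
  ref <- stats::t.test(a[resp10 == "PR"], a[resp10 != "PR"])
  expect_equal(got$tests$p_value[got$tests$score == "tic_norm"], ref$p.value)

  # degenerate inputs are rejected
  expect_error(
    response_association(mk_result(x, x, rep(NA_character_, 6))),
    "no response"
  )
  expect_error(
    response_association(mk_result(x, x, c("PR", rep("NR", 5)))),
    ">= 2"
  )
})

test_that("a sample with uniformly dominant TIC/IRP genes lands in quadrant 1", {
  genes <- unique(c(builtin_signatures()$TIC$genes, builtin_signatures()$IRP$genes))
  set.seed(77)
  v <- matrix(2^rnorm(length(genes) * 9, mean = 4), length(genes), 9,
    dimnames = list(genes, paste0("s", 1:9))
  )
  v <- cbind(v, hero = 2^(rnorm(length(genes), mean = 9)))
  res <- tic_irp_scores(expr_matrix(v, state = "raw"))
  expect_equal(res$quadrant[res$sample_ids == "hero"], 1L)
  expect_equal(which.max(res$tic_norm), which(res$sample_ids == "hero"))
})
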