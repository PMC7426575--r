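mk_assign <- function(cl) {
  structure(
    list(
      sample_ids = names(cl), cluster = cl, posteriors = NULL,
      k = max(cl), phenotypes = NULL
    ),
    class = "subgroup_assignment"
  )
}

test_that("TMB divides counted small variants by capture size", {
  muts <- tibble::tibble(
    sample_id = rep("s1", 62),
    gene = "EGFR",
    variant_class = c(rep("missense", 60), "silent", "amplification")
  )
  out <- tmb(muts, capture_mb = 30, samples = c("s1", "s2"))
  expect_equal(out$tmb[out$sample_id == "s1"], 2.0) # 60 counted / 30 Mb
  expect_equal(out$tmb[out$sample_id == "s2"], 0) # absent sample

  # linear in counts, inverse in capture
  expect_equal(tmb(dplyr::bind_rows(muts, muts), capture_mb = 30, samples = "s1")$tmb, 4.0)
  expect_equal(tmb(muts, capture_mb = 60, samples = "s1")$tmb, 1.0)
  expect_error(tmb(muts, counted = character()), "non-empty")
  expect_error(tmb(muts, capture_mb = 0))
})

test_that("MAF dialect maps onto the internal variant vocabulary", {
  maf <- tibble::tibble(
    Tumor_Sample_Barcode = c("s1", "s1", "s2"),
    Hugo_Symbol = c("EGFR", "TP53", "CDKN2A"),
    Variant_Classification = c("Missense_Mutation", "Frame_Shift_Del", "Homozygous_Deletion")
  )
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(maf, path, progress = FALSE)
  out <- read_mutation_table(path)
  expect_equal(out$variant_class, c("missense", "truncating", "deep_deletion"))
})

test_that("sCNA burden is the mean absolute arm ratio, z-scored across the cohort", {
  null_cna <- tidyr::expand_grid(sample_id = c("a", "b"), arm = c("1p", "1q")) |>
    dplyr::mutate(log2_ratio = 0)
  out0 <- scna_burden(null_cna)
  expect_equal(out0$burden, c(0, 0))
  expect_equal(out0$scna_score, c(0, 0)) # constant-vector rule

  one <- tibble::tibble(sample_id = "a", arm = c("1p", "1q"), log2_ratio = c(1, -1))
  expect_equal(scna_burden(one)$burden, 1)

  # loop oracle on a random 20-sample table
  set.seed(41)
  cna <- tidyr::expand_grid(
    sample_id = paste0("s", 1:20), arm = chromosome_arms()
  ) |>
    dplyr::mutate(log2_ratio = rnorm(dplyr::n(), sd = 0.4))
  out <- scna_burden(cna)
  for (s in out$sample_id) {
    vals <- cna$log2_ratio[cna$sample_id == s]
    tot <- 0
    for (v in vals) tot <- tot + abs(v)
    expect_lt(abs(out$burden[out$sample_id == s] - tot / length(vals)), 1e-12)
  }
  expect_lt(abs(mean(out$scna_score)), 1e-9)
  expect_equal(sqrt(mean((out$scna_score - mean(out$scna_score))^2)), 1, tolerance = 1e-9)
})

test_that("arm profiles keep amplification/deletion signs per subgroup", {
  cna <- tibble::tibble(
    sample_id = c("a", "b", "a", "b"),
    arm = c("1q", "1q", "3p", "3p"),
    log2_ratio = c(0.5, 1.5, -0.4, -0.8)
  )
  a <- mk_assign(setNames(c(1L, 1L), c("a", "b")))
  prof <- subgroup_arm_profile(cna, a)
  expect_equal(prof$mean_log2_ratio[prof$arm == "1q"], 1.0)
  expect_lt(prof$mean_log2_ratio[prof$arm == "3p"], 0)

  # loop oracle on a random fixture with 2 subgroups
  set.seed(42)
  cna2 <- tidyr::expand_grid(sample_id = paste0("s", 1:10), arm = c("1p", "2q", "9p")) |>
    dplyr::mutate(log2_ratio = rnorm(dplyr::n()))
  cl <- setNames(rep(1:2, each = 5), paste0("s", 1:10))
  prof2 <- subgroup_arm_profile(cna2, mk_assign(cl))
  for (i in seq_len(nrow(prof2))) {
    keep <- cna2$arm == prof2$arm[i] & cl[cna2$sample_id] == prof2$cluster[i]
    expect_lt(abs(prof2$mean_log2_ratio[i] - mean(cna2$log2_ratio[keep])), 1e-12)
  }
})

test_that("arm CNA reader enforces the arm vocabulary and uniqueness", {
  ok <- tibble::tibble(sample = "a", arm = "17p", log2_ratio = -0.5)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(ok, path, progress = FALSE)
  expect_equal(read_arm_cna(path)$sample_id, "a")

  bad <- tibble::tibble(sample = "a", arm = "13p", log2_ratio = 0) # acrocentric
  readr::write_tsv(bad, path, progress = FALSE)
  expect_error(read_arm_cna(path), "unknown chromosome arms")

  dup <- tibble::tibble(sample = c("a", "a"), arm = c("1p", "1p"), log2_ratio = c(0, 1))
  readr::write_tsv(dup, path, progress = FALSE)
  expect_error(read_arm_cna(path), "duplicate")
})

test_that("mutation landscape counts samples once per gene and matches a tally oracle", {
  cl <- setNames(rep(1L, 20), paste0("s", 1:20))
  muts <- tibble::tibble(
    sample_id = paste0("s", 1:9), gene = "EGFR", variant_class = "missense"
  )
  out <- mutation_landscape(muts, "EGFR", mk_assign(cl))
  expect_equal(out$frequency, 0.45)

  # several variant classes in one gene count once
  multi <- tibble::tibble(
    sample_id = c("s1", "s1"), gene = "EGFR",
    variant_class = c("missense", "amplification")
  )
  out2 <- mutation_landscape(multi, "EGFR", mk_assign(setNames(1L, "s1")))
  expect_equal(out2$n_altered, 1L)

  # exhaustive per-record tally oracle on a 50-record random fixture
  set.seed(43)
  cl3 <- setNames(sample(1:3, 15, replace = TRUE), paste0("s", 1:15))
  fix <- tibble::tibble(
    sample_id = sample(names(cl3), 50, replace = TRUE),
    gene = sample(c("EGFR", "TP53", "CDKN2A", "KRAS"), 50, replace = TRUE),
    variant_class = sample(c("missense", "truncating", "amplification"), 50, replace = TRUE)
  )
  genes <- c("EGFR", "TP53", "CDKN2A", "KRAS", "ABSENT1")
  out3 <- mutation_landscape(fix, genes, mk_assign(cl3))
  for (i in seq_len(nrow(out3))) {
    seen <- character()
    for (r in seq_len(nrow(fix))) {
      if (fix$gene[r] == out3$gene[i] && cl3[fix$sample_id[r]] == out3$cluster[i]) {
        seen <- union(seen, fix$sample_id[r])
      }
    }
    expect_equal(out3$n_altered[i], length(seen))
  }
  expect_true(all(out3$frequency >= 0 & out3$frequency <= 1))
  expect_true(all(out3$frequency[out3$gene == "ABSENT1"] == 0))

  # monotone non-decreasing under adding records
  more <- dplyr::bind_rows(fix, tibble::tibble(
    sample_id = "s1", gene = "KRAS", variant_class = "missense"
  ))
  out4 <- mutation_landscape(more, genes, mk_assign(cl3))
  expect_true(all(out4$frequency >= out3$frequency))

  # per-class breakdown is emitted
  expect_true(all(c("variant_class", "frequency") %in% names(attr(out3, "by_class"))))
  expect_error(mutation_landscape(fix, character(), mk_assign(cl3)), "non-empty")
})
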