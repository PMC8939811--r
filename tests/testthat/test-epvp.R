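# EPVP: circular shifting, extragenic assignment, the permutation runs,
# validation categories and count-comparison tests.

test_that("circular shift follows the index rule and validates offsets", {
  expect_equal(circular_shift(letters[1:4], 0), letters[1:4])
  expect_equal(circular_shift(letters[1:4], 1), c("d", "a", "b", "c"))
  expect_equal(circular_shift(letters[1:4], 3), c("b", "c", "d", "a"))
  expect_error(circular_shift(letters[1:4], 4), "offset")
  expect_error(circular_shift(letters[1:4], -1), "offset")
  # inverse property
  x <- rnorm(11)
  expect_equal(circular_shift(circular_shift(x, 4), 7), x)
})

test_that("extragenic assignment mixes original and shifted pairs per gene", {
  ss <- tibble::tibble(
    rsid = paste0("rs", 1:6), chrom = 1L, pos = (1:6) * 100L,
    pval = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), n = 101:106
  )
  map <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    rsid = c("rs1", "rs3", "rs3", "rs5", "rs2"),
    chrom = 1L, pos = c(100L, 300L, 300L, 500L, 200L),
    origin = c("intragenic", "extragenic", "extragenic", "intragenic",
               "intragenic")
  )
  out <- epvp_assign(ss, map, offsets = c(`1` = 2L))
  # intragenic pairs untouched
  expect_equal(out$pval[out$gene_id == "gA" & out$rsid == "rs1"], 0.1)
  expect_equal(out$n[out$gene_id == "gB" & out$rsid == "rs5"], 105L)
  # extragenic rs3 takes the value shifted by 2 (from rs1), jointly with n
  expect_equal(out$pval[out$gene_id == "gA" & out$rsid == "rs3"], 0.1)
  expect_equal(out$n[out$gene_id == "gA" & out$rsid == "rs3"], 101L)
  # the same extragenic SNV gets the same pair in every gene containing it
  expect_equal(out$pval[out$gene_id == "gB" & out$rsid == "rs3"],
               out$pval[out$gene_id == "gA" & out$rsid == "rs3"])
  # zero offsets are the identity
  id <- epvp_assign(ss, map, offsets = c(`1` = 0L))
  expect_equal(id$pval, c(0.1, 0.3, 0.3, 0.5, 0.2))
  # a gene with no extragenic SNVs is identical to the genuine values
  expect_equal(id$pval[id$gene_id == "gC"], 0.2)
  expect_error(epvp_assign(ss, map, offsets = c(`2` = 1L)), "chromosome")
})

test_that("zero-offset EPVP reproduces the genuine run exactly", {
  fx <- cached_enriched_maps()
  # identical permutations give zero SD in the validation step, which warns
  ep <- suppressWarnings(
    run_epvp(fx$map_aug, sumstats = fx$ss, panel = fx$panel,
             gene_sets = fx$arch$gene_sets, n_perm = 2, seed = 1,
             set_size = c(10, 200), fixed_offsets = 0)
  )
  for (perm in ep$permutations) {
    expect_equal(perm$gene_scores$z_adjusted,
                 ep$genuine$gene_scores$z_adjusted, tolerance = 1e-12)
    expect_equal(perm$set_scores$z_set,
                 tibble::as_tibble(ep$genuine$gsa)$z_set, tolerance = 1e-12)
  }
  fixture_env$epvp_identity <- ep
})

test_that("random-offset EPVP preserves mapping and intragenic values", {
  fx <- cached_enriched_maps()
  ep <- run_epvp(fx$map_aug, sumstats = fx$ss, panel = fx$panel,
                 gene_sets = fx$arch$gene_sets, n_perm = 3, seed = 42,
                 set_size = c(10, 200))
  # per-gene SNV identity lists are untouched (same scored genes, same K)
  for (perm in ep$permutations) {
    expect_equal(perm$gene_scores$gene_id, ep$genuine$gene_scores$gene_id)
    expect_equal(perm$gene_scores$n_snvs, ep$genuine$gene_scores$n_snvs)
  }
  # intragenic (p, n) pairs bitwise equal under the assignment view
  offs <- ep$permutations[[1]]$offsets
  asg <- epvp_assign(fx$ss, fx$map_aug, offs)
  ss_idx <- stats::setNames(seq_len(nrow(fx$ss)), fx$ss$rsid)
  intra <- asg[asg$origin == "intragenic", ]
  expect_identical(intra$pval, fx$ss$pval[ss_idx[intra$rsid]])
  expect_identical(intra$n, fx$ss$n[ss_idx[intra$rsid]])
  # conservation: multiset of SNVs per gene equals the genuine mapping's
  expect_equal(
    dplyr::count(asg, gene_id),
    dplyr::count(dplyr::filter(fx$map_aug, rsid %in% fx$ss$rsid), gene_id),
    ignore_attr = TRUE
  )
  # determinism: same seed, same offsets and scores
  ep2 <- run_epvp(fx$map_aug, sumstats = fx$ss, panel = fx$panel,
                  gene_sets = fx$arch$gene_sets, n_perm = 3, seed = 42,
                  set_size = c(10, 200))
  expect_identical(ep$permutations[[2]]$offsets, ep2$permutations[[2]]$offsets)
  expect_equal(ep$permutations[[3]]$gene_scores$p_raw,
               ep2$permutations[[3]]$gene_scores$p_raw)
})

test_that("degenerate augmentation makes permutations identical to genuine", {
  fx <- cached_enriched_maps()
  # augmented = baseline: no extragenic SNVs anywhere
  ep <- suppressWarnings(
    run_epvp(fx$map_base, sumstats = fx$ss, panel = fx$panel,
             gene_sets = fx$arch$gene_sets, n_perm = 2, seed = 9,
             set_size = c(10, 200))
  )
  for (perm in ep$permutations) {
    expect_equal(perm$gene_scores$p_raw, ep$genuine$gene_scores$p_raw,
                 tolerance = 1e-12)
  }
  expect_error(
    run_epvp(fx$map_base, sumstats = fx$ss, panel = fx$panel,
             gene_sets = fx$arch$gene_sets, n_perm = 1, seed = 1),
    "n_perm"
  )
  # a baseline not contained in the augmentation is rejected
  bad_base <- dplyr::mutate(fx$map_base[1:5, ], rsid = paste0("zz", 1:5))
  expect_error(
    run_epvp(fx$map_base, bad_base, sumstats = fx$ss, panel = fx$panel,
             gene_sets = fx$arch$gene_sets, n_perm = 2, seed = 1),
    "not contained"
  )
})

test_that("validation categories follow the 1 and 2 SD thresholds", {
  expect_equal(classify_validation(2.5, perm_mean = 1.0, perm_sd = 0.6)$category,
               "strongly_validated")  # d = 2.5
  expect_equal(classify_validation(1.5, perm_mean = 1.0, perm_sd = 0.4)$category,
               "mildly_validated")    # d = 1.25
  expect_equal(classify_validation(1.0, perm_mean = 1.0, perm_sd = 0.5)$category,
               "invalidated")         # d = 0
  expect_equal(classify_validation(3.0, perm_scores = c(1, 1.2, 0.8))$category,
               "strongly_validated")
  expect_warning(
    v <- classify_validation(2, perm_mean = 1, perm_sd = 0),
    "zero"
  )
  expect_equal(v$category, "strongly_validated")
  expect_warning(
    v2 <- classify_validation(0.5, perm_mean = 1, perm_sd = 0),
    "zero"
  )
  expect_equal(v2$category, "invalidated")
})

test_that("count-comparison tests match exact references", {
  # one-sided binomial: N = 7, L = 1 -> 9/256
  out <- count_comparison_tests(novel_count = 7, lost_count = 1)
  expect_equal(out$p_binomial, 9 / 256, tolerance = 1e-12)
  expect_gte(count_comparison_tests(novel_count = 4,
                                    lost_count = 4)$p_binomial, 0.5)

  # one-sample one-sided t: genuine greater
  out2 <- count_comparison_tests(genuine_count = 30,
                                 perm_counts = c(10, 12, 9, 11))
  ref <- t.test(c(10, 12, 9, 11), mu = 30, alternative = "less")$p.value
  expect_equal(out2$p_ttest, ref)
  # degenerate zero-variance permutation counts
  expect_warning(
    eq <- count_comparison_tests(genuine_count = 5, perm_counts = c(5, 5, 5)),
    "zero variance"
  )
  expect_equal(eq$p_ttest, 1)
  expect_warning(
    gt <- count_comparison_tests(genuine_count = 9, perm_counts = c(5, 5, 5)),
    "zero variance"
  )
  expect_equal(gt$p_ttest, 0)
})
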