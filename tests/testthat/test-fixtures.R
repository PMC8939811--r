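# Synthetic-data generator: reference panel, architecture, summary statistics.

test_that("a single-variant panel has trivial LD and valid fields", {
  p <- simulate_reference_panel(60, tibble::tibble(n_snvs = 1, rho = 0),
                                chrom_layout = 1e5, seed = 3)
  expect_equal(nrow(p$variants), 1L)
  expect_identical(unname(stats::cor(p$genotypes)), matrix(1.0))
  expect_true(all(p$genotypes %in% 0:2))
})

test_that("zero within-block correlation gives near-independent dosages", {
  p <- simulate_reference_panel(2000, tibble::tibble(n_snvs = 6, rho = 0),
                                chrom_layout = 1e6, seed = 11)
  R <- stats::cor(p$genotypes)
  expect_lte(max(abs(R[upper.tri(R)])), 0.1)
})

test_that("panel simulation is bit-reproducible and validates inputs", {
  spec <- tibble::tibble(n_snvs = c(3, 2), rho = c(0.4, 0.8))
  p1 <- simulate_reference_panel(80, spec, 5e5, seed = 9)
  p2 <- simulate_reference_panel(80, spec, 5e5, seed = 9)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$variants, p2$variants)
  p3 <- simulate_reference_panel(80, spec, 5e5, seed = 10)
  expect_false(identical(p1$genotypes, p3$genotypes))

  expect_error(simulate_reference_panel(10, spec, 5e5), "n_samples")
  expect_error(simulate_reference_panel(80, tibble::tibble(n_snvs = 0, rho = 0), 5e5),
               "block sizes")
  expect_error(simulate_reference_panel(80, spec, 5e5, maf_range = c(0.005, 0.5)),
               "maf_range")
  expect_error(simulate_reference_panel(80, tibble::tibble(n_snvs = 2, rho = 1), 5e5),
               "correlation")
})

test_that("panel invariants hold: ordering, unique ids, MAF floor", {
  p <- tiny_panel(n_snvs = 12, rho = 0.3, seed = 5)
  v <- p$variants
  expect_false(is.unsorted(v$pos))
  expect_false(any(duplicated(v$rsid)))
  expect_true(all(v$maf >= 0.01 & v$maf <= 0.5))
  expect_true(all(v$a1 != v$a2))
})

test_that("null architecture has an all-zero causal plan", {
  p <- tiny_panel(n_snvs = 40, seed = 8)
  arch <- simulate_architecture(p, n_genes = 5, n_sets = 2,
                                set_size_range = c(2, 3),
                                n_enriched_sets = 0,
                                gene_length_range = c(5e3, 8e3),
                                ri_distance_range = c(2e4, 1e5), seed = 1)
  expect_equal(nrow(arch$causal_plan), nrow(p$variants))
  expect_true(all(arch$causal_plan$lambda == 0))
  expect_length(arch$enriched_sets, 0)
})

test_that("degenerate distance interval pins element midpoints", {
  p <- simulate_reference_panel(60, tibble::tibble(n_snvs = 30, rho = 0),
                                chrom_layout = 5e6, seed = 2)
  arch <- simulate_architecture(p, n_genes = 8, n_sets = 2,
                                set_size_range = c(3, 4),
                                n_enriched_sets = 0,
                                ri_distance_range = c(5e4, 5e4),
                                gene_length_range = c(5e3, 8e3),
                                max_elements_per_gene = 1, seed = 3)
  el <- arch$elements[arch$elements$start > 0, ]  # exclude clipped elements
  expect_gt(nrow(el), 0)
  g <- arch$genes[match(el$gene_id, arch$genes$gene_id), ]
  mid <- (el$start + el$end) / 2
  # the anchoring site (TSS or TES) is exactly 50 kb from the midpoint
  anchored <- abs(abs(mid - g$tss) - 5e4) <= 1 | abs(abs(mid - g$tes) - 5e4) <= 1
  expect_true(all(anchored))
})

test_that("default enriched causal SNVs are invisible to the baseline model", {
  fx <- cached_enriched_maps()
  causal <- fx$arch$causal_plan$rsid[fx$arch$causal_plan$lambda > 0]
  expect_gte(length(causal), 5)
  captured <- fx$base_ann$rsid[!is.na(fx$base_ann$rsid)]
  expect_length(intersect(causal, captured), 0)
  # and each causal SNV is mapped extragenically via the augmentation
  org <- fx$map_aug$origin[fx$map_aug$rsid %in% causal]
  expect_gt(length(org), 0)
  expect_true(all(org == "extragenic"))
  # every enriched set carries >= 5 causal genes
  causal_genes <- unique(fx$map_aug$gene_id[fx$map_aug$rsid %in% causal])
  for (es in fx$arch$enriched_sets) {
    members <- fx$arch$gene_sets$gene_id[fx$arch$gene_sets$set_id == es]
    expect_gte(length(intersect(causal_genes, members)), 5)
  }
})

test_that("a too-small genome is rejected with advice", {
  p <- tiny_panel(n_snvs = 5, seed = 1)
  expect_error(
    simulate_architecture(p, n_genes = 500, n_sets = 2,
                          set_size_range = c(2, 3), n_enriched_sets = 0,
                          seed = 1),
    "genome too small"
  )
})

test_that("null summary statistics are marginally uniform (KS at 10,000 SNVs)", {
  p <- simulate_reference_panel(
    60, tibble::tibble(n_snvs = rep(5L, 2000), rho = 0.6),
    chrom_layout = 5e7, seed = 21
  )
  ss <- simulate_sumstats(p, NULL, n_gwas = 1e4, seed = 22)
  expect_equal(nrow(ss), 10000L)
  D <- suppressWarnings(stats::ks.test(ss$pval, "punif"))$statistic
  expect_lt(unname(D), 1.63 / sqrt(10000))  # 1% critical value
  # null calibration: fraction below 0.05 within 3 Monte-Carlo SEs
  frac <- mean(ss$pval < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("expected z equals R %*% lambda under a planted signal", {
  p <- simulate_reference_panel(60, tibble::tibble(n_snvs = 2, rho = 0.5),
                                chrom_layout = 1e5, seed = 31)
  Rfix <- matrix(c(1, 0.8, 0.8, 1), 2)
  plan <- tibble::tibble(rsid = p$variants$rsid, lambda = c(5, 0))
  zbar <- rowMeans(vapply(
    1:400,
    function(i) simulate_sumstats(p, plan, seed = 1000 + i,
                                  ld = list(`1` = Rfix))$z,
    numeric(2)
  ))
  expect_equal(zbar, c(5, 4), tolerance = 0.05)  # 3 SE ~ 0.15 absolute
})

test_that("summary-statistic simulation validates ids and is deterministic", {
  p <- tiny_panel(seed = 77)
  bad <- tibble::tibble(rsid = "rs_nope", lambda = 2)
  expect_error(simulate_sumstats(p, bad), "rs_nope")
  s1 <- simulate_sumstats(p, NULL, seed = 5)
  s2 <- simulate_sumstats(p, NULL, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$pval > 0 & s1$pval <= 1))
  expect_identical(s1$rsid, p$variants$rsid)
})

test_that("study presets wire named seed streams deterministically", {
  expect_identical(stream_seed(7, "panel"), stream_seed(7, "panel"))
  expect_false(stream_seed(7, "panel") == stream_seed(7, "sumstats"))
  expect_lt(stream_seed(2^30, "epvp:19"), 2^31)
})

test_that("text writers and readers round-trip the fixture formats", {
  fx <- cached_enriched_maps()
  td <- withr::local_tempdir()
  v <- fx$panel$variants[1:50, ]
  write_bim(v, file.path(td, "p.bim"))
  expect_equal(read_bim(file.path(td, "p.bim"))$pos, v$pos)

  write_gene_loc(fx$arch$genes[1:10, ], file.path(td, "g.loc"))
  g2 <- read_gene_loc(file.path(td, "g.loc"))
  expect_equal(g2$start, fx$arch$genes$start[1:10])
  expect_equal(g2$end, fx$arch$genes$end[1:10])
  expect_equal(g2$tss, fx$arch$genes$tss[1:10])

  write_ri_bed(fx$arch$elements[1:20, ], file.path(td, "ri.bed"))
  expect_equal(read_ri_bed(file.path(td, "ri.bed"))$start,
               fx$arch$elements$start[1:20])

  write_gmt(fx$arch$gene_sets, file.path(td, "sets.gmt"))
  gs <- read_gmt(file.path(td, "sets.gmt"))
  expect_setequal(
    paste(gs$set_id, gs$gene_id),
    paste(fx$arch$gene_sets$set_id, fx$arch$gene_sets$gene_id)
  )

  ss <- cached_study("enriched")$sumstats[1:30, ]
  write_sumstats(ss, file.path(td, "ss.tsv"))
  ss2 <- read_sumstats(file.path(td, "ss.tsv"))
  expect_equal(ss2$pval, ss$pval)
})
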