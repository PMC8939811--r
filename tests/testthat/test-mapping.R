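# Feature building, regulatory-interaction processing, SNV annotation,
# per-gene aggregation and coverage.

test_that("flank features follow strand and clip at position zero", {
  genes <- toy_genes()
  f0 <- build_flanked_features(genes, 0, 0)
  expect_setequal(unique(f0$feature_type), "body")

  f <- build_flanked_features(genes, 10, 5)
  upA <- f[f$gene_id == "gA" & f$feature_type == "upstream", ]
  expect_equal(c(upA$start, upA$end), c(0L, 10000L))  # clipped at 0
  dnA <- f[f$gene_id == "gA" & f$feature_type == "downstream", ]
  expect_equal(c(dnA$start, dnA$end), c(20000L, 25000L))

  # minus-strand gene: upstream lies 3'-ward of body end in ref coordinates
  upB <- f[f$gene_id == "gB" & f$feature_type == "upstream", ]
  expect_equal(c(upB$start, upB$end), c(70000L, 80000L))
  dnB <- f[f$gene_id == "gB" & f$feature_type == "downstream", ]
  expect_equal(c(dnB$start, dnB$end), c(55000L, 60000L))

  # flanks never overlap the body
  bodies <- f[f$feature_type == "body", ]
  flanks <- f[f$feature_type != "body", ]
  for (i in seq_len(nrow(flanks))) {
    b <- bodies[bodies$gene_id == flanks$gene_id[i], ]
    expect_true(flanks$end[i] <= b$start || flanks$start[i] >= b$end)
  }
})

test_that("contact pairs become regulatory elements via promoter overlap", {
  genes <- toy_genes()  # gA promoter [8000,10000); gB promoter [70000,72000)
  pairs <- tibble::tibble(
    chrom_a = 1L, start_a = 100000L, end_a = 101000L,
    chrom_b = 1L, start_b = 9000L, end_b = 9500L
  )
  ri <- derive_ri_from_contacts(pairs, genes)
  expect_equal(nrow(ri), 1L)
  expect_equal(ri$gene_id, "gA")
  expect_equal(c(ri$start, ri$end), c(100000L, 101000L))

  # pair overlapping no promoter contributes nothing
  none <- derive_ri_from_contacts(
    tibble::tibble(chrom_a = 1L, start_a = 1e5, end_a = 1.01e5,
                   chrom_b = 1L, start_b = 2e5, end_b = 2.01e5),
    genes
  )
  expect_equal(nrow(none), 0L)

  # one locus overlapping two promoters maps the partner to both genes
  g2 <- dplyr::mutate(toy_genes(),
                      start = c(10000L, 12500L), end = c(20000L, 22000L),
                      strand = "+", tss = start, tes = end)
  both <- derive_ri_from_contacts(
    tibble::tibble(chrom_a = 1L, start_a = 3e5, end_a = 3.01e5,
                   chrom_b = 1L, start_b = 9500L, end_b = 11000L),
    g2
  )
  expect_setequal(both$gene_id, c("gA", "gB"))
  expect_true(all(both$start == 3e5))

  # symmetric rule: both loci in promoters -> two records, crosswise
  sym <- derive_ri_from_contacts(
    tibble::tibble(chrom_a = 1L, start_a = 9000L, end_a = 9500L,
                   chrom_b = 1L, start_b = 68000L, end_b = 69000L),
    toy_genes()  # gB promoter is [70000,72000): B does not hit it
  )
  expect_equal(sym$gene_id, "gA")  # only A's promoter was hit, partner = B locus
  expect_equal(c(sym$start, sym$end), c(68000L, 69000L))

  # inter-chromosomal pairs: dropped with a counted warning
  expect_warning(
    dropped <- derive_ri_from_contacts(
      tibble::tibble(chrom_a = 1L, start_a = 9000L, end_a = 9500L,
                     chrom_b = 2L, start_b = 1000L, end_b = 2000L),
      genes
    ),
    "inter-chromosomal"
  )
  expect_equal(attr(dropped, "n_interchrom_dropped"), 1L)
})

test_that("RI processing merges per gene and enforces intra-chromosomal rule", {
  genes <- toy_genes()
  raw <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gA", "gA"),
    chrom = c(1L, 1L, 1L, 2L, 1L),
    start = c(100L, 150L, 100L, 500L, 900L),
    end = c(200L, 300L, 200L, 600L, 850L)  # last row malformed
  )
  expect_message(out <- process_ri_dataset(raw, genes), "malformed")
  gA <- out[out$gene_id == "gA", ]
  expect_equal(nrow(gA), 1L)               # [100,200) + [150,300) merged
  expect_equal(c(gA$start, gA$end), c(100L, 300L))
  gB <- out[out$gene_id == "gB", ]         # identical interval kept per gene
  expect_equal(c(gB$start, gB$end), c(100L, 200L))
  expect_false(any(out$chrom == 2L))       # chrom-2 record for a chrom-1 gene
  expect_false(any(duplicated(out$element_uid)))
})

test_that("SNV annotation respects half-open boundaries and exclusions", {
  feats <- tibble::tibble(
    gene_id = "gA", feature_id = "gA:body", feature_type = "body",
    chrom = 1L, start = 100L, end = 200L
  )
  v <- toy_variants(c(100, 101, 200, 201))
  ann <- annotate_features_with_snvs(feats, v)
  hit <- ann$rsid[!is.na(ann$rsid)]
  expect_setequal(hit, c("rs2", "rs3"))  # (100,200]: 101 and 200 inside

  # empty feature retained with NA rsid
  empty <- annotate_features_with_snvs(feats, toy_variants(5000))
  expect_equal(nrow(empty), 1L)
  expect_true(is.na(empty$rsid))

  # default human exclusion region removes chr6:30,000,000 SNVs and genes
  mhc_feats <- tibble::tibble(
    gene_id = c("gX", "gY"), feature_id = c("gX:body", "gY:body"),
    feature_type = "body", chrom = 6L,
    start = c(29000000L, 50000000L), end = c(31000000L, 50010000L)
  )
  v6 <- tibble::tibble(rsid = c("rsM", "rsOK"), chrom = 6L,
                       pos = c(30000000L, 50005000L))
  ann6 <- annotate_features_with_snvs(mhc_feats, v6, mhc_region())
  expect_false("rsM" %in% ann6$rsid)
  expect_false("gX" %in% ann6$gene_id)     # gene overlapping the MHC excluded
  expect_true("rsOK" %in% ann6$rsid)
})

test_that("aggregation unions per gene with correct origin labels", {
  base_ann <- tibble::tibble(
    gene_id = c("gA", "gB"), feature_id = c("gA:body", "gB:body"),
    feature_type = "body", chrom = 1L, start = c(0L, 500L),
    end = c(100L, 600L), rsid = c("rs1", "rs2"), pos = c(50L, 550L)
  )
  aug_ann <- tibble::tibble(
    gene_id = c("gA", "gA", "gB"),
    feature_id = c("gA:ri:1", "gA:ri:2", "gB:ri:1"),
    feature_type = "regulatory_element", chrom = 1L,
    start = c(0L, 900L, 40L), end = c(100L, 1000L, 60L),
    rsid = c("rs1", "rs3", "rs1"), pos = c(50L, 950L, 50L)
  )
  map <- aggregate_snv_gene_map(base_ann, aug_ann, "toy")
  expect_equal(attr(map, "mapping_label"), "toy")
  expect_false(any(duplicated(paste(map$gene_id, map$rsid))))
  gA <- map[map$gene_id == "gA", ]
  expect_equal(gA$origin[gA$rsid == "rs1"], "intragenic")
  expect_equal(gA$origin[gA$rsid == "rs3"], "extragenic")
  # rs1 sits in gB's element but gA's body: per-gene origins differ
  expect_equal(map$origin[map$gene_id == "gB" & map$rsid == "rs1"],
               "extragenic")
  # augmentation adding only baseline SNVs is a no-op
  idem <- aggregate_snv_gene_map(base_ann, base_ann, "idem")
  expect_true(all(idem$origin == "intragenic"))
  expect_equal(nrow(idem), 2L)
  # order independence
  perm <- aggregate_snv_gene_map(base_ann[sample(nrow(base_ann)), ],
                                 aug_ann[c(3, 1, 2), ], "toy")
  expect_equal(as.data.frame(perm), as.data.frame(map))
})

test_that("coverage is a per-gene union over SNV-containing features", {
  ann <- tibble::tibble(
    gene_id = "gA",
    feature_id = c("gA:body", "gA:ri:1", "gA:ri:2"),
    feature_type = c("body", "regulatory_element", "regulatory_element"),
    chrom = 1L, start = c(0L, 50L, 200L), end = c(100L, 150L, 300L),
    rsid = c("rs1", "rs2", "rs3"), pos = c(10L, 120L, 250L)
  )
  expect_equal(compute_coverage(ann, "rs1")$coverage_bp, 100)
  expect_equal(compute_coverage(ann, c("rs1", "rs2"))$coverage_bp, 150)
  # feature whose SNV is absent from the sumstats contributes nothing
  expect_equal(compute_coverage(ann, c("rs1", "rs4"))$coverage_bp, 100)
  expect_equal(compute_coverage(ann, character())$coverage_bp, 0)
})

test_that("coverage matches a brute-force per-base counter on random toys", {
  for (seed in 1:5) {
    set.seed(seed)
    n_feat <- 8
    genes <- sample(c("g1", "g2"), n_feat, replace = TRUE)
    start <- sample(0:9000, n_feat)
    width <- sample(50:1500, n_feat)
    v <- toy_variants(sort(sample(1:10000, 25)))
    ann <- tibble::tibble(
      gene_id = genes, feature_id = paste0("f", seq_len(n_feat)),
      feature_type = "regulatory_element", chrom = 1L,
      start = start, end = pmin(start + width, 10000L)
    ) |>
      annotate_features_with_snvs(v)
    present <- sample(v$rsid, 12)
    got <- compute_coverage(ann, present)$coverage_bp

    # oracle: mark covered bases gene by gene
    want <- 0
    for (g in unique(genes)) {
      covered <- logical(10000)
      fg <- ann[ann$gene_id == g & !is.na(ann$rsid) & ann$rsid %in% present, ]
      for (fid in unique(fg$feature_id)) {
        fr <- fg[fg$feature_id == fid, ][1, ]
        covered[(fr$start + 1):fr$end] <- TRUE
      }
      want <- want + sum(covered)
    }
    expect_equal(got, want)
  }
})

test_that("coverage is monotone along the flank ladder", {
  fx <- cached_enriched_maps()
  covs <- vapply(
    list(c(0, 0), c(2, 2), c(10, 10), c(50, 50), c(100, 100)),
    function(fl) {
      f <- build_flanked_features(fx$arch$genes, fl[1], fl[2],
                                  fx$panel$chrom_layout)
      a <- annotate_features_with_snvs(f, fx$panel$variants)
      compute_coverage(a, fx$ss$rsid)$coverage_bp
    },
    numeric(1)
  )
  expect_false(is.unsorted(covs))
})

test_that("annot writer emits one row per feature with its SNVs", {
  fx <- cached_enriched_maps()
  td <- withr::local_tempdir()
  ann <- fx$base_ann[fx$base_ann$gene_id %in% fx$arch$genes$gene_id[1:5], ]
  write_annot(ann, file.path(td, "a.annot"))
  lines <- readLines(file.path(td, "a.annot"))
  expect_equal(length(lines), length(unique(ann$feature_id)))
  expect_true(all(grepl("^\\S+\t\\d+:\\d+:\\d+", lines)))
})
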