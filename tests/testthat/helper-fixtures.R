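# Shared fixtures, generated in code and cached for the duration of the test
# session (several files exercise the same synthetic study).

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

cached_study <- function(preset, seed = 7) {
  cached(paste0("study:", preset, ":", seed),
         function() simulate_regsa_study(seed, preset))
}

# Enriched study with processed sumstats and baseline/augmented maps.
cached_enriched_maps <- function() {
  cached("enriched_maps", function() {
    study <- cached_study("enriched")
    panel <- study$panel
    arch <- study$architecture
    ss <- process_sumstats(study$sumstats, build_variant_dictionary(panel$variants))
    feats <- build_flanked_features(arch$genes, 10, 10, panel$chrom_layout)
    base_ann <- annotate_features_with_snvs(feats, panel$variants)
    ri_ann <- annotate_features_with_snvs(ri_features(arch$elements),
                                          panel$variants)
    list(
      panel = panel, arch = arch, ss = ss,
      base_ann = base_ann, ri_ann = ri_ann,
      map_base = aggregate_snv_gene_map(base_ann, NULL, "baseline"),
      map_aug = aggregate_snv_gene_map(base_ann, ri_ann, "base+RI")
    )
  })
}

# A tiny deterministic panel for unit tests.
tiny_panel <- function(n_snvs = 6, rho = 0.5, n_samples = 200, seed = 42) {
  simulate_reference_panel(
    n_samples = n_samples,
    block_spec = tibble::tibble(n_snvs = n_snvs, rho = rho),
    chrom_layout = 1e6, seed = seed
  )
}

# Two-gene toy annotation set (0-based half-open intervals).
toy_genes <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = c(1L, 1L),
    start = c(10000L, 60000L), end = c(20000L, 70000L),
    strand = c("+", "-"),
    tss = c(10000L, 70000L), tes = c(20000L, 60000L),
    symbol = c("gA", "gB")
  )
}

toy_variants <- function(pos, chrom = 1L) {
  tibble::tibble(
    rsid = paste0("rs", seq_along(pos)), chrom = chrom, pos = as.integer(pos),
    a1 = "A", a2 = "G", maf = 0.3
  )
}

# Deterministic gene-score tibbles for GSA / IRED tests: `z` named by gene.
fake_scores <- function(z) {
  tibble::tibble(gene_id = names(z), z_adjusted = unname(z))
}

# IRED driver fixtures: 120 genes in 12 disjoint 10-gene sets; the first set
# carries the planted drivers. Sets are small relative to the universe so a
# single remaining driver still lifts the set mean visibly.
ired_fixture <- function(drivers, boost = 8) {
  set.seed(404)
  genes <- sprintf("g%03d", 1:120)
  z_base <- stats::setNames(rnorm(120), genes)
  z_aug <- z_base
  z_aug[genes[seq_len(drivers)]] <- z_aug[genes[seq_len(drivers)]] + boost
  sets <- tibble::tibble(
    set_id = rep(sprintf("S%02d", 1:12), each = 10),
    gene_id = genes
  )
  list(base = fake_scores(z_base), aug = fake_scores(z_aug),
       sets = sets, target = "S01")
}
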