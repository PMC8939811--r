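# Synthetic-data generator: block-LD reference panel, gene/RI/gene-set
# architecture with planted distal regulatory signal, and marginal GWAS
# summary statistics simulated per LD block as z ~ MVN(R lambda, R).

UNAMBIGUOUS_PAIRS <- list(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T")
)

#' Simulate a block-LD reference panel
#'
#' Genotype dosages are generated from latent Gaussian haplotypes: within
#' each LD block the latent variables are equicorrelated with the requested
#' correlation, and each haplotype is thresholded at the variant's allele
#' frequency, giving Hardy-Weinberg dosages in \{0, 1, 2\}. Variants in
#' different blocks are independent. Blocks are laid out contiguously along
#' the chromosomes in `chrom_layout`.
#'
#' @param n_samples Number of diploid samples (>= 50).
#' @param block_spec Data frame with columns `n_snvs` and `rho` (one row per
#'   LD block), or a list of `c(n_snvs, rho)` pairs.
#' @param chrom_layout Numeric vector of chromosome lengths in bp; chromosome
#'   numbers are `seq_along(chrom_layout)`.
#' @param maf_range Interval for design minor-allele frequencies, inside
#'   (0.01, 0.5].
#' @param seed Integer seed; the panel is bit-reproducible given it.
#' @param maf_floor Minimum empirical minor-allele frequency; blocks are
#'   redrawn (up to 25 attempts) until every variant satisfies it.
#' @return A `ref_panel` object: list with `n_samples`, `variants` (tibble:
#'   rsid, chrom, pos, a1, a2, maf, block_id), `genotypes` (samples x
#'   variants dosage matrix), `blocks`, and the chromosome layout.
#' @export
simulate_reference_panel <- function(n_samples, block_spec, chrom_layout,
                                     maf_range = c(0.05, 0.5), seed = 1L,
                                     maf_floor = 0.01) {
  if (!is.numeric(n_samples) || n_samples < 50) {
    stop("`n_samples` must be >= 50", call. = FALSE)
  }
  if (is.data.frame(block_spec)) {
    blocks <- tibble::as_tibble(block_spec)
  } else {
    blocks <- tibble::tibble(
      n_snvs = vapply(block_spec, `[`, numeric(1), 1),
      rho = vapply(block_spec, `[`, numeric(1), 2)
    )
  }
  if (any(blocks$n_snvs <= 0)) {
    stop("`block_spec`: block sizes must be positive", call. = FALSE)
  }
  if (any(blocks$rho < 0 | blocks$rho >= 1)) {
    stop("`block_spec`: within-block correlation must lie in [0, 1)", call. = FALSE)
  }
  if (maf_range[1] <= 0.01 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an interval inside (0.01, 0.5]", call. = FALSE)
  }
  stopifnot(all(chrom_layout > 0))

  set.seed(as.integer(seed))
  n_blocks <- nrow(blocks)
  blocks$block_id <- seq_len(n_blocks)

  # Allocate blocks to chromosomes proportionally to length.
  w <- chrom_layout / sum(chrom_layout)
  alloc <- diff(c(0L, round(cumsum(w) * n_blocks)))
  blocks$chrom <- rep(seq_along(chrom_layout), times = alloc)

  var_list <- vector("list", n_blocks)
  geno_list <- vector("list", n_blocks)
  snv_counter <- 0L

  for (ch in seq_along(chrom_layout)) {
    ch_blocks <- which(blocks$chrom == ch)
    n_ch_snvs <- sum(blocks$n_snvs[ch_blocks])
    if (n_ch_snvs == 0) next
    pos <- sort(sample.int(chrom_layout[ch] - 1L, n_ch_snvs)) + 1L
    offset <- 0L
    for (b in ch_blocks) {
      k <- blocks$n_snvs[b]
      rho <- blocks$rho[b]
      p_des <- stats::runif(k, maf_range[1], maf_range[2])
      al <- UNAMBIGUOUS_PAIRS[sample.int(8L, k, replace = TRUE)]

      geno <- NULL
      for (attempt in seq_len(25L)) {
        hap <- function() {
          shared <- stats::rnorm(n_samples)
          z <- sqrt(rho) * matrix(shared, n_samples, k) +
            sqrt(1 - rho) * matrix(stats::rnorm(n_samples * k), n_samples, k)
          sweep(stats::pnorm(z), 2, p_des, `<`) * 1L
        }
        g <- hap() + hap()
        f <- colMeans(g) / 2
        if (all(pmin(f, 1 - f) >= maf_floor)) {
          geno <- g
          break
        }
      }
      if (is.null(geno)) {
        stop("could not satisfy `maf_floor` for block ", b,
             "; raise `maf_range` or `n_samples`", call. = FALSE)
      }
      f <- colMeans(geno) / 2
      ids <- paste0("rs", snv_counter + seq_len(k))
      snv_counter <- snv_counter + k
      var_list[[b]] <- tibble::tibble(
        rsid = ids, chrom = ch, pos = pos[offset + seq_len(k)],
        a1 = vapply(al, `[`, character(1), 1),
        a2 = vapply(al, `[`, character(1), 2),
        maf = pmin(f, 1 - f), block_id = blocks$block_id[b]
      )
      colnames(geno) <- ids
      geno_list[[b]] <- geno
      offset <- offset + k
    }
  }

  variants <- dplyr::bind_rows(var_list)
  genotypes <- do.call(cbind, geno_list)
  stopifnot(!anyDuplicated(variants$rsid))

  structure(
    list(
      n_samples = as.integer(n_samples),
      variants = variants,
      genotypes = genotypes,
      blocks = blocks,
      chrom_layout = chrom_layout
    ),
    class = "ref_panel"
  )
}

#' @export
print.ref_panel <- function(x, ...) {
  cat("<ref_panel> ", x$n_samples, " samples, ", nrow(x$variants),
      " SNVs in ", nrow(x$blocks), " LD blocks on ",
      length(x$chrom_layout), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Simulate a gene / regulatory-interaction / gene-set architecture
#'
#' Places non-overlapping gene bodies on the panel's genome, attaches distal
#' regulatory elements, draws gene-set memberships, and plants causal SNVs.
#' In `signal_mode = "regulatory"` (the default study condition), causal SNVs
#' are placed exclusively inside distal regulatory elements of genes from the
#' enriched set(s), and always outside the baseline-model footprint (gene
#' body +/- `baseline_flank_bp`) of *every* gene, so a proximity-only mapping
#' misses the planted signal by construction. In `signal_mode = "dispersed"`
#' causal SNVs are scattered at assorted distances (0 to `dispersed_max_bp`)
#' from randomly chosen genes, so progressively larger flanks capture
#' progressively more signal.
#'
#' @param panel A `ref_panel`.
#' @param n_genes,n_sets Number of genes and gene sets.
#' @param set_size_range Gene-set sizes, drawn uniformly in this interval
#'   (default within the conventional 25-200 gene-set filter).
#' @param n_enriched_sets Number of sets receiving planted causal signal.
#' @param ri_distance_range Distance (bp) of regulatory-element midpoints
#'   from the anchoring transcription start/end site.
#' @param seed Integer seed.
#' @param gene_length_range Gene-body lengths in bp.
#' @param max_elements_per_gene Background elements per gene, drawn 0..max.
#' @param element_width Width of regulatory elements in bp.
#' @param n_causal_genes_per_set Genes per enriched set receiving causal SNVs
#'   (must be >= 5).
#' @param lambda Per-SNV noncentrality of planted causal SNVs.
#' @param baseline_flank_bp Baseline-model flank size used to define the
#'   footprint causal SNVs must avoid.
#' @param signal_mode `"regulatory"` or `"dispersed"` (see above).
#' @param n_dispersed_causal,dispersed_max_bp Dispersed-mode settings.
#' @return A `synthetic_architecture`: list with `genes`, `elements`,
#'   `gene_sets`, `enriched_sets`, `causal_plan` (lambda for every panel SNV,
#'   zero where not causal) and the generation parameters.
#' @export
simulate_architecture <- function(panel, n_genes, n_sets,
                                  set_size_range = c(25, 50),
                                  n_enriched_sets = 1,
                                  ri_distance_range = c(25e3, 1e6),
                                  seed = 1L,
                                  gene_length_range = c(10e3, 30e3),
                                  max_elements_per_gene = 3,
                                  element_width = 2e3,
                                  n_causal_genes_per_set = 10,
                                  lambda = 6,
                                  baseline_flank_bp = 10e3,
                                  signal_mode = c("regulatory", "dispersed"),
                                  n_dispersed_causal = 40,
                                  dispersed_max_bp = 100e3) {
  stopifnot(inherits(panel, "ref_panel"))
  signal_mode <- match.arg(signal_mode)
  if (n_enriched_sets > 0 && signal_mode == "regulatory" &&
      n_causal_genes_per_set < 5) {
    stop("`n_causal_genes_per_set` must be >= 5 for an enriched set", call. = FALSE)
  }
  set.seed(as.integer(seed))
  layout <- panel$chrom_layout

  # --- gene placement: evenly sized slots, body jittered inside its slot ---
  w <- layout / sum(layout)
  alloc <- diff(c(0L, round(cumsum(w) * n_genes)))
  genes <- vector("list", length(layout))
  gid <- 0L
  for (ch in seq_along(layout)) {
    ng <- alloc[ch]
    if (ng == 0) next
    slot <- floor(layout[ch] / ng)
    if (slot < gene_length_range[2] + 2e3) {
      stop("genome too small to place ", n_genes,
           " non-overlapping genes; enlarge `chrom_layout` or reduce `n_genes`",
           call. = FALSE)
    }
    len <- round(stats::runif(ng, gene_length_range[1], gene_length_range[2]))
    room <- slot - len - 2e3
    start <- (seq_len(ng) - 1L) * slot + 1e3 +
      floor(stats::runif(ng) * pmax(room, 1))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    genes[[ch]] <- tibble::tibble(
      gene_id = sprintf("g%04d", gid + seq_len(ng)),
      chrom = ch, start = as.integer(start), end = as.integer(start + len),
      strand = strand
    )
    gid <- gid + ng
  }
  genes <- dplyr::bind_rows(genes) |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end),
      tes = ifelse(.data$strand == "+", .data$end, .data$start),
      symbol = .data$gene_id
    )

  # --- gene sets ---
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  gene_sets <- purrr::map2_dfr(
    sprintf("set%02d", seq_len(n_sets)), sizes,
    function(sid, sz) tibble::tibble(
      set_id = sid,
      gene_id = sample(genes$gene_id, min(sz, nrow(genes)))
    )
  )
  enriched_sets <- if (n_enriched_sets > 0) {
    sprintf("set%02d", seq_len(n_enriched_sets))
  } else {
    character()
  }

  # --- background regulatory elements ---
  n_elem <- sample(0:max_elements_per_gene, nrow(genes), replace = TRUE)
  elem <- purrr::pmap_dfr(
    list(genes$gene_id, genes$chrom, genes$tss, genes$tes, n_elem),
    function(g, ch, tss, tes, k) {
      if (k == 0) return(NULL)
      d <- round(stats::runif(k, ri_distance_range[1], ri_distance_range[2]))
      anchor_tss <- sample(c(TRUE, FALSE), k, replace = TRUE)
      upstream <- sample(c(TRUE, FALSE), k, replace = TRUE)
      mid <- ifelse(anchor_tss, tss, tes) + ifelse(upstream, -d, d)
      tibble::tibble(
        gene_id = g, chrom = ch,
        start = as.integer(pmax(mid - element_width / 2, 0)),
        end = as.integer(pmax(mid + element_width / 2, element_width))
      )
    }
  )
  # drop elements that fell off the chromosome end
  elem <- dplyr::filter(
    elem, .data$end <= layout[.data$chrom], .data$start < .data$end
  )

  # --- baseline footprints (body +/- flank) used to keep causal SNVs distal ---
  foot <- genes |>
    dplyr::transmute(
      chrom = .data$chrom,
      start = pmax(.data$start - baseline_flank_bp, 0),
      end = .data$end + baseline_flank_bp
    )
  snv <- panel$variants
  in_foot <- rep(FALSE, nrow(snv))
  for (ch in unique(foot$chrom)) {
    f <- foot[foot$chrom == ch, ]
    idx <- which(snv$chrom == ch)
    if (length(idx) == 0) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = snv$pos[idx], width = 1L),
      IRanges::IRanges(start = f$start + 1L, end = f$end)
    )
    in_foot[idx[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }

  lambda_vec <- stats::setNames(rep(0, nrow(snv)), snv$rsid)
  causal_elem <- NULL

  if (signal_mode == "regulatory" && length(enriched_sets) > 0) {
    for (es in enriched_sets) {
      members <- gene_sets$gene_id[gene_sets$set_id == es]
      cg <- sample(members, min(n_causal_genes_per_set, length(members)))
      if (length(cg) < 5) {
        stop("enriched set ", es, " has fewer than 5 candidate causal genes",
             call. = FALSE)
      }
      for (g in cg) {
        gr <- genes[genes$gene_id == g, ]
        d_anchor <- pmin(abs(snv$pos - gr$tss), abs(snv$pos - gr$tes))
        cand <- which(
          snv$chrom == gr$chrom & !in_foot &
            d_anchor >= max(ri_distance_range[1], baseline_flank_bp) &
            d_anchor <= ri_distance_range[2]
        )
        if (length(cand) == 0) {
          stop("no footprint-free SNV available for a causal element of gene ",
               g, call. = FALSE)
        }
        pick <- cand[sample.int(length(cand), 1L)]
        lambda_vec[snv$rsid[pick]] <- lambda
        causal_elem <- dplyr::bind_rows(causal_elem, tibble::tibble(
          gene_id = g, chrom = gr$chrom,
          start = as.integer(max(snv$pos[pick] - element_width / 2, 0)),
          end = as.integer(snv$pos[pick] + element_width / 2)
        ))
      }
    }
  } else if (signal_mode == "dispersed") {
    target <- sample(genes$gene_id, n_dispersed_causal, replace = TRUE)
    for (g in target) {
      gr <- genes[genes$gene_id == g, ]
      cand <- which(
        snv$chrom == gr$chrom &
          snv$pos > gr$start - dispersed_max_bp &
          snv$pos <= gr$end + dispersed_max_bp
      )
      cand <- cand[lambda_vec[snv$rsid[cand]] == 0]
      if (length(cand) == 0) next
      pick <- cand[sample.int(length(cand), 1L)]
      lambda_vec[snv$rsid[pick]] <- lambda
    }
  }

  elements <- dplyr::bind_rows(elem, causal_elem) |>
    dplyr::mutate(source = "synthetic")
  elements <- process_ri_dataset(elements, genes)

  causal_plan <- tibble::tibble(
    rsid = snv$rsid, chrom = snv$chrom, pos = snv$pos,
    lambda = unname(lambda_vec)
  )

  structure(
    list(
      genes = genes, elements = elements, gene_sets = gene_sets,
      enriched_sets = enriched_sets, causal_plan = causal_plan,
      params = list(
        signal_mode = signal_mode, lambda = lambda,
        baseline_flank_bp = baseline_flank_bp,
        ri_distance_range = ri_distance_range, seed = seed
      )
    ),
    class = "synthetic_architecture"
  )
}

#' @export
print.synthetic_architecture <- function(x, ...) {
  cat("<synthetic_architecture> ", nrow(x$genes), " genes, ",
      nrow(x$elements), " regulatory elements, ",
      length(unique(x$gene_sets$set_id)), " gene sets (",
      length(x$enriched_sets), " enriched), ",
      sum(x$causal_plan$lambda > 0), " causal SNVs\n", sep = "")
  invisible(x)
}

#' Reassign regulatory elements to random genes
#'
#' Breaks the element-to-gene assignment of an architecture while keeping
#' every element's genomic interval: each element is relinked to a uniformly
#' drawn gene and the result re-processed (intra-chromosomal filter, per-gene
#' merging, fresh element ids). Used by the specificity control, where a
#' pipeline run on reassigned elements should no longer validate the planted
#' set's gain.
#'
#' @param elements Regulatory-element tibble.
#' @param genes Gene-model tibble to draw targets from.
#' @param seed Integer seed.
#' @return Reassigned, re-processed regulatory-element tibble.
#' @export
reassign_elements <- function(elements, genes, seed = 1L) {
  set.seed(as.integer(seed))
  elements$gene_id <- sample(genes$gene_id, nrow(elements), replace = TRUE)
  process_ri_dataset(elements, genes)
}

#' Simulate GWAS summary statistics from a reference panel
#'
#' Marginal association z-scores are drawn per LD block as
#' `z ~ MVN(R lambda, R)` where `R` is the block's SNV correlation matrix
#' (by default the panel's empirical dosage correlation) and `lambda` the
#' planted per-SNV noncentralities. Two-sided p-values are `2 * (1 - Phi(|z|))`.
#'
#' @param panel A `ref_panel`.
#' @param causal_plan Tibble with columns `rsid` and `lambda`, or `NULL` for
#'   a global null. Unknown rsids are an error.
#' @param n_gwas GWAS sample size recorded per SNV.
#' @param seed Integer seed.
#' @param ld Optional named list of per-block correlation matrices overriding
#'   the empirical ones (names are block ids).
#' @param n_jitter_sd If > 0, per-SNV sample sizes are jittered with this SD.
#' @return Tibble of summary-statistic records: rsid, chrom, pos, a1, a2,
#'   beta, se, pval, n (plus the latent z).
#' @export
simulate_sumstats <- function(panel, causal_plan = NULL, n_gwas = 50000,
                              seed = 1L, ld = NULL, n_jitter_sd = 0) {
  stopifnot(inherits(panel, "ref_panel"), n_gwas > 0)
  snv <- panel$variants
  lambda <- stats::setNames(rep(0, nrow(snv)), snv$rsid)
  if (!is.null(causal_plan)) {
    unknown <- setdiff(causal_plan$rsid, snv$rsid)
    if (length(unknown) > 0) {
      stop("causal SNV id(s) not in panel: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    lambda[causal_plan$rsid] <- causal_plan$lambda
  }
  set.seed(as.integer(seed))
  z <- numeric(nrow(snv))
  for (b in panel$blocks$block_id) {
    idx <- which(snv$block_id == b)
    k <- length(idx)
    if (k == 1L) {
      z[idx] <- lambda[idx] + stats::rnorm(1)
      next
    }
    R <- if (!is.null(ld) && !is.null(ld[[as.character(b)]])) {
      ld[[as.character(b)]]
    } else {
      stats::cor(panel$genotypes[, idx, drop = FALSE])
    }
    Rr <- R * (1 - 1e-8)
    diag(Rr) <- 1 + 1e-8
    L <- chol(Rr)
    z[idx] <- drop(R %*% lambda[idx]) + drop(crossprod(L, stats::rnorm(k)))
  }
  n <- rep(as.integer(n_gwas), nrow(snv))
  if (n_jitter_sd > 0) {
    n <- pmax(as.integer(round(n + stats::rnorm(length(n), 0, n_jitter_sd))), 1L)
  }
  se <- 1 / sqrt(2 * n * snv$maf * (1 - snv$maf))
  tibble::tibble(
    rsid = snv$rsid, chrom = snv$chrom, pos = snv$pos,
    a1 = snv$a1, a2 = snv$a2,
    beta = z * se, se = se,
    pval = pmax(2 * stats::pnorm(-abs(z)), .P_FLOOR),
    n = n, z = z
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper wiring [simulate_reference_panel()],
#' [simulate_architecture()] and [simulate_sumstats()] with the package's
#' default study conditions. Three presets are provided: `"enriched"` (one
#' 30 Mb chromosome, 5,000 SNVs in 1,000 five-SNV LD blocks, 300 genes,
#' 20 gene sets, one set with causal SNVs planted in distal regulatory
#' elements only), `"null"` (no causal signal, many small genes for
#' calibration studies) and `"dispersed"` (causal SNVs scattered within
#' 100 kb of genes, for flank-ladder trend studies).
#'
#' @param seed Master seed; child streams `"panel"`, `"architecture"` and
#'   `"sumstats"` are derived from it via [stream_seed()].
#' @param preset One of `"enriched"`, `"null"`, `"dispersed"`.
#' @param ... Overrides passed to [simulate_architecture()].
#' @return List with `panel`, `architecture`, `sumstats`.
#' @export
simulate_regsa_study <- function(seed = 1L,
                                 preset = c("enriched", "null", "dispersed",
                                            "specificity"),
                                 ...) {
  preset <- match.arg(preset)
  if (preset == "specificity") {
    # larger gene pool and smaller sets, so a randomly reassigned regulatory
    # element rarely lands back inside the planted set by chance
    panel <- simulate_reference_panel(
      n_samples = 500,
      block_spec = tibble::tibble(n_snvs = rep(5L, 1200), rho = 0.7),
      chrom_layout = 60e6,
      seed = stream_seed(seed, "panel")
    )
    arch <- simulate_architecture(
      panel, n_genes = 600, n_sets = 30, set_size_range = c(15, 25),
      n_enriched_sets = 1, seed = stream_seed(seed, "architecture"), ...
    )
    ss <- simulate_sumstats(panel, arch$causal_plan,
                            seed = stream_seed(seed, "sumstats"))
    return(list(panel = panel, architecture = arch, sumstats = ss))
  }
  if (preset == "null") {
    panel <- simulate_reference_panel(
      n_samples = 400,
      block_spec = tibble::tibble(n_snvs = rep(3L, 2600), rho = 0.7),
      chrom_layout = 70e6,
      seed = stream_seed(seed, "panel")
    )
    arch <- simulate_architecture(
      panel, n_genes = 2600, n_sets = 20, set_size_range = c(25, 50),
      n_enriched_sets = 0, gene_length_range = c(6e3, 10e3),
      seed = stream_seed(seed, "architecture"), ...
    )
  } else {
    panel <- simulate_reference_panel(
      n_samples = 500,
      block_spec = tibble::tibble(n_snvs = rep(5L, 1000), rho = 0.7),
      chrom_layout = 30e6,
      seed = stream_seed(seed, "panel")
    )
    arch <- simulate_architecture(
      panel, n_genes = 300, n_sets = 20, set_size_range = c(25, 50),
      n_enriched_sets = if (preset == "enriched") 1 else 0,
      signal_mode = if (preset == "dispersed") "dispersed" else "regulatory",
      seed = stream_seed(seed, "architecture"), ...
    )
  }
  ss <- simulate_sumstats(panel, arch$causal_plan,
                          seed = stream_seed(seed, "sumstats"))
  list(panel = panel, architecture = arch, sumstats = ss)
}
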