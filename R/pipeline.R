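# Orchestration: run the controlled analysis across a ladder of SNV-to-gene
# mappings (flank ladder + regulatory-interaction augmentations of the
# baseline), compare significant genes and gene sets between mappings,
# compute trend statistics, and drive EPVP validation and IRED robustness
# for the configured augmentations.

#' Analysis configuration
#'
#' Bundles the inputs and settings of [run_controlled_analysis()]. Inputs
#' are in-memory objects (tibbles / `ref_panel`); use the `read_*` family to
#' ingest files first.
#'
#' @param panel A `ref_panel`.
#' @param genes Gene-model tibble.
#' @param sumstats_raw Raw summary-statistics tibble.
#' @param gene_sets Long membership tibble (set_id, gene_id).
#' @param ri_datasets Named list of processed regulatory-element tibbles
#'   used to augment the baseline model (may be empty).
#' @param flank_ladder Named list of `c(up_kb, down_kb)` flank mappings; must
#'   contain `baseline_label`.
#' @param baseline_label Name of the baseline mapping in `flank_ladder`.
#' @param alpha Significance level in (0, 1).
#' @param set_size Gene-set size bounds.
#' @param n_perm EPVP permutations.
#' @param seed Master seed.
#' @param exclusion_region Optional `(chrom, start, end)` region excluded
#'   from analysis (e.g. [mhc_region()]); `NULL` for synthetic genomes.
#' @param epvp_on Labels of augmentations to control with EPVP (defaults to
#'   all RI augmentations).
#' @param run_ired Run IRED on validated gaining sets.
#' @param overlap_threshold Redundancy-reduction threshold.
#' @param window_bp Gene-gene correlation window.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(panel, genes, sumstats_raw, gene_sets,
                            ri_datasets = list(),
                            flank_ladder = list(
                              U0D0 = c(0, 0), U2D2 = c(2, 2),
                              U10D10 = c(10, 10), U20D20 = c(20, 20),
                              U50D50 = c(50, 50), U100D100 = c(100, 100)
                            ),
                            baseline_label = "U10D10",
                            alpha = 0.05, set_size = c(25, 200),
                            n_perm = 20, seed = 1L,
                            exclusion_region = NULL,
                            epvp_on = names(ri_datasets),
                            run_ired = TRUE,
                            overlap_threshold = 0.7,
                            window_bp = 5e6) {
  stopifnot(inherits(panel, "ref_panel"), alpha > 0, alpha < 1)
  if (!baseline_label %in% names(flank_ladder)) {
    stop("`flank_ladder` must contain the baseline mapping `",
         baseline_label, "`", call. = FALSE)
  }
  structure(
    list(
      panel = panel, genes = genes, sumstats_raw = sumstats_raw,
      gene_sets = gene_sets, ri_datasets = ri_datasets,
      flank_ladder = flank_ladder, baseline_label = baseline_label,
      alpha = alpha, set_size = set_size, n_perm = n_perm, seed = seed,
      exclusion_region = exclusion_region, epvp_on = epvp_on,
      run_ired = run_ired, overlap_threshold = overlap_threshold,
      window_bp = window_bp
    ),
    class = "analysis_config"
  )
}

#' Classify entity changes between two mappings
#'
#' @param sig_baseline,sig_augmented Character vectors of significant entity
#'   ids from the common tested universe.
#' @return List with `novel` (augmented only), `known` (both), `lost`
#'   (baseline only).
#' @export
classify_model_changes <- function(sig_baseline, sig_augmented) {
  list(
    novel = setdiff(sig_augmented, sig_baseline),
    known = intersect(sig_augmented, sig_baseline),
    lost = setdiff(sig_baseline, sig_augmented)
  )
}

#' Trend statistics across mappings
#'
#' Spearman rank correlation with a one-sided p-value between two
#' per-mapping quantities (e.g. significant-gene counts versus coverage,
#' alternative "greater"; significant-set counts versus gene counts,
#' alternative "less"), and/or a one-sided paired Wilcoxon signed-rank test
#' for score attenuation (alternative: augmented scores smaller).
#'
#' @param x,y Per-mapping numeric vectors (>= 4 values for the correlation;
#'   constant input is an error suggesting more mappings).
#' @param alternative Direction for the Spearman test.
#' @param paired_baseline,paired_augmented Optional paired score vectors for
#'   the attenuation test.
#' @return List with `rho`, `p_rho` and (when paired scores are given)
#'   `p_wilcoxon`.
#' @export
trend_statistics <- function(x = NULL, y = NULL, alternative = "greater",
                             paired_baseline = NULL, paired_augmented = NULL) {
  out <- list()
  if (!is.null(x)) {
    stopifnot(length(x) == length(y))
    if (length(x) < 4) stop("need >= 4 mappings for a rank correlation", call. = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop("constant input; rank correlation undefined - add more mappings",
           call. = FALSE)
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", alternative = alternative,
                      exact = FALSE)
    )
    out$rho <- unname(ct$estimate)
    out$p_rho <- ct$p.value
  }
  if (!is.null(paired_baseline)) {
    stopifnot(length(paired_baseline) == length(paired_augmented))
    diffs <- paired_augmented - paired_baseline
    if (all(diffs == 0)) {
      warning("all paired scores tied; attenuation p-value set to 1")
      out$p_wilcoxon <- 1
    } else {
      out$p_wilcoxon <- suppressWarnings(
        stats::wilcox.test(paired_augmented, paired_baseline, paired = TRUE,
                           alternative = "less")$p.value
      )
    }
  }
  out
}

# Union-restore comparison of significant gene sets between two mappings:
# the universe is the union of the two non-redundant significant lists, and
# a set eliminated as redundant in one mapping but significant (pre-
# reduction) in both is counted as known.
compare_set_lists <- function(sig_full_base, sig_full_aug,
                              nonred_base, nonred_aug) {
  universe <- union(nonred_base, nonred_aug)
  classify_model_changes(
    intersect(universe, sig_full_base),
    intersect(universe, sig_full_aug)
  )
}

#' Run the full controlled analysis
#'
#' Executes, in order: summary-statistics processing; construction of the
#' mapping ladder (each flank mapping, plus each regulatory-interaction
#' augmentation of the baseline); LD-aware gene scoring and adjustment per
#' mapping; competitive gene-set analysis; redundancy reduction; coverage;
#' novel/known/lost comparisons against the baseline (with the
#' union-restore rule for gene sets); gains; trend statistics; EPVP on the
#' configured augmentations; and IRED on validated gaining sets.
#' Counts are reported on the common scored universe (genes and sets with a
#' score for every mapping).
#'
#' @param config An [analysis_config()].
#' @return A `comparison_report` list of tibbles (see `tidy()` /
#'   `glance()`): `mappings`, `changes`, `trends`, `epvp`, `validation`,
#'   `ired`, plus per-mapping score tables in `$runs`.
#' @export
run_controlled_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cf <- config
  panel <- cf$panel
  chrom_lengths <- panel$chrom_layout

  dict <- build_variant_dictionary(panel$variants)
  ss <- process_sumstats(cf$sumstats_raw, dict, cf$exclusion_region)

  base_flanks <- cf$flank_ladder[[cf$baseline_label]]
  base_features <- build_flanked_features(cf$genes, base_flanks[1],
                                          base_flanks[2], chrom_lengths)
  base_ann <- annotate_features_with_snvs(base_features, panel$variants,
                                          cf$exclusion_region)

  # --- build the mapping ladder -------------------------------------------
  mappings <- list()
  for (lab in names(cf$flank_ladder)) {
    fl <- cf$flank_ladder[[lab]]
    feats <- build_flanked_features(cf$genes, fl[1], fl[2], chrom_lengths)
    ann <- annotate_features_with_snvs(feats, panel$variants,
                                       cf$exclusion_region)
    if (all(fl >= base_flanks) && lab != cf$baseline_label) {
      map <- aggregate_snv_gene_map(base_ann, ann, mapping_label = lab)
      cov_ann <- dplyr::bind_rows(base_ann, ann)
    } else {
      map <- aggregate_snv_gene_map(ann, NULL, mapping_label = lab)
      cov_ann <- ann
    }
    mappings[[lab]] <- list(map = map, coverage_ann = cov_ann,
                            kind = "flank")
  }
  for (lab in names(cf$ri_datasets)) {
    ri_ann <- annotate_features_with_snvs(
      ri_features(cf$ri_datasets[[lab]]), panel$variants, cf$exclusion_region
    )
    map <- aggregate_snv_gene_map(base_ann, ri_ann, mapping_label = lab)
    mappings[[lab]] <- list(
      map = map, coverage_ann = dplyr::bind_rows(base_ann, ri_ann),
      kind = "ri"
    )
  }

  # --- score every mapping -------------------------------------------------
  runs <- list()
  for (lab in names(mappings)) {
    m <- mappings[[lab]]
    scores <- adjust_gene_scores(score_genes(m$map, ss, panel))
    Sigma <- gene_gene_correlations(m$map, panel, window_bp = cf$window_bp,
                                    sumstat_snv_ids = ss$rsid)
    gsa <- run_gsa(scores, cf$gene_sets, Sigma,
                   set_size = cf$set_size, alpha = cf$alpha)
    cov <- compute_coverage(m$coverage_ann, ss$rsid, mapping_label = lab)
    runs[[lab]] <- list(label = lab, kind = m$kind, map = m$map,
                        scores = scores, Sigma = Sigma, gsa = gsa,
                        coverage = cov)
  }

  labs <- names(runs)
  common_genes <- Reduce(intersect, purrr::map(runs, ~ .x$scores$gene_id))
  common_sets <- Reduce(intersect, purrr::map(runs, ~ .x$gsa$set_id))

  per_mapping <- purrr::map_dfr(runs, function(r) {
    sig_genes <- r$scores$gene_id[r$scores$p_fdr < cf$alpha]
    sig_sets_full <- r$gsa$set_id[r$gsa$significant]
    nonred <- reduce_redundant_sets(
      tibble::as_tibble(r$gsa)[r$gsa$significant, c("set_id", "p_fdr")],
      cf$gene_sets, cf$overlap_threshold
    )$set_id
    tibble::tibble(
      mapping = r$label, kind = r$kind,
      coverage_bp = r$coverage$coverage_bp,
      n_genes_scored = nrow(r$scores),
      n_sig_genes = length(intersect(sig_genes, common_genes)),
      n_sig_sets = length(intersect(nonred, common_sets)),
      sig_genes = list(intersect(sig_genes, common_genes)),
      sig_sets_full = list(sig_sets_full),
      nonred_sets = list(nonred)
    )
  })

  # --- changes vs baseline -------------------------------------------------
  base_row <- per_mapping[per_mapping$mapping == cf$baseline_label, ]
  changes <- purrr::map_dfr(
    setdiff(labs, cf$baseline_label),
    function(lab) {
      row <- per_mapping[per_mapping$mapping == lab, ]
      gch <- classify_model_changes(base_row$sig_genes[[1]],
                                    row$sig_genes[[1]])
      sch <- compare_set_lists(
        intersect(base_row$sig_sets_full[[1]], common_sets),
        intersect(row$sig_sets_full[[1]], common_sets),
        intersect(base_row$nonred_sets[[1]], common_sets),
        intersect(row$nonred_sets[[1]], common_sets)
      )
      set_gains <- compute_gains(runs[[cf$baseline_label]]$gsa,
                                 runs[[lab]]$gsa, level = "set")
      binom <- if (length(gch$novel) + length(gch$lost) >= 1) {
        count_comparison_tests(novel_count = length(gch$novel),
                               lost_count = length(gch$lost))
      } else {
        list()
      }
      tibble::tibble(
        mapping = lab,
        novel_genes = length(gch$novel), known_genes = length(gch$known),
        lost_genes = length(gch$lost),
        p_novel_vs_lost = binom$p_binomial %||% NA_real_,
        novel_sets = length(sch$novel), known_sets = length(sch$known),
        lost_sets = length(sch$lost),
        n_gaining_sets = sum(set_gains$gaining),
        n_nongaining_sets = sum(!set_gains$gaining)
      )
    }
  )
  if (nrow(changes) > 0) {
    ok <- !is.na(changes$p_novel_vs_lost)
    changes$p_novel_vs_lost_fdr <- NA_real_
    if (any(ok)) {
      changes$p_novel_vs_lost_fdr[ok] <- bh_fdr(clip_p(changes$p_novel_vs_lost[ok]))
    }
  }

  # --- trend statistics ----------------------------------------------------
  trends <- list()
  flank_rows <- per_mapping[per_mapping$kind == "flank", ]
  if (nrow(per_mapping) >= 4 &&
      stats::sd(per_mapping$coverage_bp) > 0 &&
      stats::sd(per_mapping$n_sig_genes) > 0) {
    trends$genes_vs_coverage <- trend_statistics(
      per_mapping$n_sig_genes, per_mapping$coverage_bp,
      alternative = "greater"
    )
    if (stats::sd(per_mapping$n_sig_sets) > 0) {
      trends$sets_vs_genes <- trend_statistics(
        per_mapping$n_sig_sets, per_mapping$n_sig_genes,
        alternative = "less"
      )
    }
  }

  # --- EPVP and IRED on configured augmentations ---------------------------
  epvp <- list()
  ired <- list()
  for (lab in intersect(cf$epvp_on, labs)) {
    ep <- run_epvp(
      runs[[lab]]$map, sumstats = ss, panel = panel,
      gene_sets = cf$gene_sets, n_perm = cf$n_perm,
      seed = stream_seed(cf$seed, paste0("epvp-run:", lab)),
      set_size = cf$set_size, alpha = cf$alpha, window_bp = cf$window_bp
    )
    epvp[[lab]] <- ep
    if (cf$run_ired) {
      vt <- ep$validation
      candidates <- vt$set_id[
        !is.na(vt$gaining) & vt$gaining &
          vt$category %in% c("strongly_validated", "mildly_validated") &
          vt$set_id %in% ep$genuine$gsa$set_id[ep$genuine$gsa$significant]
      ]
      ired[[lab]] <- purrr::map(candidates, function(sid) {
        ired_run(sid, ep$baseline$gene_scores, ep$genuine$gene_scores,
                 cf$gene_sets,
                 Sigma_baseline = runs[[cf$baseline_label]]$Sigma,
                 Sigma_augmented = runs[[lab]]$Sigma,
                 set_size = cf$set_size, alpha = cf$alpha)
      })
      names(ired[[lab]]) <- candidates
    }
  }

  structure(
    list(
      mappings = dplyr::select(per_mapping, -"sig_genes", -"sig_sets_full",
                               -"nonred_sets"),
      changes = changes,
      trends = trends,
      epvp = epvp,
      ired = ired,
      runs = runs,
      common_genes = common_genes,
      common_sets = common_sets,
      sumstats = ss,
      config = cf
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", nrow(x$mappings), " mappings, ",
      length(x$common_genes), " common genes, ",
      length(x$common_sets), " common sets\n", sep = "")
  print(x$mappings)
  invisible(x)
}
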