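# Extragenic p-value push (EPVP): a circular per-chromosome permutation of
# SNV-level p-values and sample sizes applied only to extragenic SNVs
# (SNVs mapped to a gene via augmentation but not via the baseline model).
# The mapping itself — per-gene SNV identities, LD matrices and gene-gene
# correlations — is preserved, so the control mimics replacing genuine
# regulatory interactions by matched, random ones.

#' Circularly shift an ordered vector
#'
#' `output[i] = values[(i - offset) mod L]` (1-based): the whole vector is
#' pushed forward by `offset`, with indices surpassing the end wrapped back
#' to the start.
#'
#' @param values Ordered vector (length L).
#' @param offset Integer in `[0, L - 1]`.
#' @return Shifted vector of the same length.
#' @export
circular_shift <- function(values, offset) {
  L <- length(values)
  if (offset < 0 || offset >= L) {
    stop("`offset` must lie in [0, ", L - 1, "]", call. = FALSE)
  }
  if (offset == 0) return(values)
  values[((seq_len(L) - 1 - offset) %% L) + 1]
}

#' Assign permuted extragenic (p, n) values per gene
#'
#' Orders the summary statistics by position within each chromosome, shifts
#' p-values and sample sizes jointly (as pairs) by the per-chromosome
#' offsets, and assembles each gene's vector: original values at intragenic
#' positions, shifted values at extragenic positions. The same extragenic
#' SNV receives the same shifted pair in every gene containing it, because
#' the shift is computed once per permutation, not per gene.
#'
#' @param sumstats Processed summary statistics.
#' @param map SNV-gene map with origin labels ([aggregate_snv_gene_map()]).
#' @param offsets Named vector of offsets, one per chromosome present.
#' @return Tibble: gene_id, rsid, origin, pval, n.
#' @export
epvp_assign <- function(sumstats, map, offsets) {
  ss <- dplyr::arrange(sumstats, .data$chrom, .data$pos)
  map <- dplyr::filter(map, .data$rsid %in% ss$rsid)
  sh <- shift_sumstat_values(ss, offsets)
  idx <- match(map$rsid, ss$rsid)
  intra <- map$origin == "intragenic"
  tibble::tibble(
    gene_id = map$gene_id, rsid = map$rsid, origin = map$origin,
    pval = ifelse(intra, ss$pval[idx], sh$pval[idx]),
    n = ifelse(intra, ss$n[idx], sh$n[idx])
  )
}

# Shift the (p, n) columns of position-ordered sumstats per chromosome.
shift_sumstat_values <- function(ss, offsets) {
  pval <- ss$pval
  n <- ss$n
  for (ch in unique(ss$chrom)) {
    rows <- which(ss$chrom == ch)
    off <- unname(offsets[as.character(ch)])
    if (length(off) != 1 || is.na(off)) {
      stop("no offset supplied for chromosome ", ch, call. = FALSE)
    }
    pval[rows] <- circular_shift(ss$pval[rows], off)
    n[rows] <- circular_shift(ss$n[rows], off)
  }
  list(pval = pval, n = n)
}

#' Run the EPVP permutation control
#'
#' Scores the augmented mapping with the genuine summary statistics, then
#' performs `n_perm` permutations: per-chromosome offsets are drawn
#' uniformly, extragenic SNVs of every gene receive the shifted (p, n)
#' pairs, every gene is rescored (reusing the genuine run's LD eigenvalues
#' and gene-gene correlations), the per-gene mean sample size is recomputed
#' from the mixed vector, scores are re-adjusted, and the full competitive
#' gene-set analysis is re-run. A baseline run (intragenic SNVs only) is
#' scored alongside so set-level gains can be validated against the
#' permutation distribution.
#'
#' @param map_augmented Augmented SNV-gene map with origin labels.
#' @param map_baseline Baseline map; defaults to the intragenic subset of
#'   `map_augmented` (which must contain it).
#' @param sumstats Processed summary statistics.
#' @param panel A `ref_panel`.
#' @param gene_sets Long membership tibble (set_id, gene_id).
#' @param n_perm Number of permutations (>= 2; the study protocol uses 20).
#' @param seed Master seed; permutation k draws from stream `"epvp:k"`.
#' @param set_size,alpha,window_bp Analysis settings (see [run_gsa()],
#'   [gene_gene_correlations()]).
#' @param fixed_offsets Optional single offset (recycled) or list of
#'   per-permutation named offset vectors; overrides random offsets (used
#'   for identity controls).
#' @return An `epvp_result` list: `genuine` (gene scores, gsa), `baseline`,
#'   `permutations` (per-permutation gene/set scores and offsets),
#'   `validation` tibble, `gains`, and counts of significant genes.
#' @export
run_epvp <- function(map_augmented, map_baseline = NULL, sumstats, panel,
                     gene_sets, n_perm = 20, seed = 1L,
                     set_size = c(25, 200), alpha = 0.05, window_bp = 5e6,
                     fixed_offsets = NULL) {
  if (n_perm < 2) stop("`n_perm` must be >= 2 (SD undefined otherwise)", call. = FALSE)
  if (is.null(map_baseline)) {
    map_baseline <- dplyr::filter(map_augmented, .data$origin == "intragenic")
    attr(map_baseline, "mapping_label") <- "baseline"
  } else {
    extra <- dplyr::anti_join(
      map_baseline[, c("gene_id", "rsid")],
      map_augmented[, c("gene_id", "rsid")],
      by = c("gene_id", "rsid")
    )
    if (nrow(extra) > 0) {
      stop("baseline mapping is not contained in the augmented mapping",
           call. = FALSE)
    }
  }

  ss <- dplyr::arrange(sumstats, .data$chrom, .data$pos)
  ctx <- gene_scoring_context(map_augmented, ss, panel)
  Sigma <- gene_gene_correlations(map_augmented, panel, window_bp = window_bp,
                                  sumstat_snv_ids = ss$rsid)

  genuine_scores <- adjust_gene_scores(score_from_context(ctx))
  genuine_gsa <- run_gsa(genuine_scores, gene_sets, Sigma,
                         set_size = set_size, alpha = alpha)

  base_scores <- adjust_gene_scores(
    score_genes(map_baseline, ss, panel)
  )
  Sigma_base <- gene_gene_correlations(map_baseline, panel,
                                       window_bp = window_bp,
                                       sumstat_snv_ids = ss$rsid)
  base_gsa <- run_gsa(base_scores, gene_sets, Sigma_base,
                      set_size = set_size, alpha = alpha)

  chroms <- unique(ss$chrom)
  chrom_len <- vapply(chroms, function(ch) sum(ss$chrom == ch), integer(1))
  names(chrom_len) <- as.character(chroms)

  perms <- vector("list", n_perm)
  for (k in seq_len(n_perm)) {
    if (is.null(fixed_offsets)) {
      set.seed(stream_seed(seed, paste0("epvp:", k)))
      offs <- vapply(chrom_len, function(L) sample.int(L, 1L) - 1L, integer(1))
    } else if (is.list(fixed_offsets)) {
      offs <- fixed_offsets[[k]]
    } else {
      offs <- stats::setNames(rep(as.integer(fixed_offsets),
                                  length(chrom_len)), names(chrom_len))
    }
    sh <- shift_sumstat_values(ss, offs)
    scores_k <- adjust_gene_scores(
      score_from_context(ctx, pvec_shift = sh$pval, nvec_shift = sh$n)
    )
    gsa_k <- run_gsa(scores_k, gene_sets, Sigma,
                     set_size = set_size, alpha = alpha)
    perms[[k]] <- list(
      perm_index = k, offsets = offs,
      gene_scores = scores_k, set_scores = tibble::as_tibble(gsa_k)
    )
  }

  gains <- compute_gains(base_gsa, genuine_gsa, level = "set")

  perm_sets <- purrr::map_dfr(perms, function(p) {
    dplyr::mutate(p$set_scores[, c("set_id", "z_set")],
                  perm_index = p$perm_index)
  })
  validation <- tibble::as_tibble(genuine_gsa)[, c("set_id", "z_set")] |>
    dplyr::rename(z_genuine = "z_set") |>
    dplyr::left_join(
      perm_sets |>
        dplyr::group_by(.data$set_id) |>
        dplyr::summarise(perm_mean = mean(.data$z_set),
                         perm_sd = stats::sd(.data$z_set), .groups = "drop"),
      by = "set_id"
    ) |>
    dplyr::left_join(gains[, c("entity_id", "gain", "gaining")],
                     by = c(set_id = "entity_id"))
  validation$category <- purrr::pmap_chr(
    list(validation$z_genuine, validation$perm_mean, validation$perm_sd),
    function(zg, m, s) {
      classify_validation(zg, perm_scores = NULL, perm_mean = m, perm_sd = s)$category
    }
  )

  n_sig_genes <- function(sc) sum(sc$p_fdr < alpha)
  structure(
    list(
      genuine = list(gene_scores = genuine_scores, gsa = genuine_gsa),
      baseline = list(gene_scores = base_scores, gsa = base_gsa),
      permutations = perms,
      gains = gains,
      validation = validation,
      n_sig_genes_genuine = n_sig_genes(genuine_scores),
      n_sig_genes_baseline = n_sig_genes(base_scores),
      n_sig_genes_perm = vapply(perms, function(p) n_sig_genes(p$gene_scores),
                                numeric(1)),
      alpha = alpha, n_perm = n_perm, seed = seed
    ),
    class = "epvp_result"
  )
}

#' @export
print.epvp_result <- function(x, ...) {
  cat("<epvp_result> ", x$n_perm, " permutations\n",
      "  significant genes: genuine ", x$n_sig_genes_genuine,
      ", baseline ", x$n_sig_genes_baseline,
      ", permutations ", paste(range(x$n_sig_genes_perm), collapse = "-"),
      "\n  validation: ",
      paste(names(table(x$validation$category[x$validation$gaining])),
            table(x$validation$category[x$validation$gaining]),
            sep = "=", collapse = ", "),
      " (gaining sets)\n", sep = "")
  invisible(x)
}

#' Classify a gene set's validation category
#'
#' Compares the genuine probit-scale set score to the permutation
#' distribution: `d = (z_genuine - mean) / sd`. `d >= 2` is strongly
#' validated, `1 <= d < 2` mildly validated, anything less invalidated.
#' With zero permutation SD the category is decided by the sign of
#' `z_genuine - mean` (strong if positive), with a warning.
#'
#' @param z_genuine Genuine set score.
#' @param perm_scores Permutation scores (>= 2), or `NULL` if `perm_mean`
#'   and `perm_sd` are given directly.
#' @param perm_mean,perm_sd Optional precomputed permutation moments.
#' @return List with `d`, `perm_mean`, `perm_sd`, `category`.
#' @export
classify_validation <- function(z_genuine, perm_scores = NULL,
                                perm_mean = NULL, perm_sd = NULL) {
  if (!is.null(perm_scores)) {
    stopifnot(length(perm_scores) >= 2)
    perm_mean <- mean(perm_scores)
    perm_sd <- stats::sd(perm_scores)
  }
  if (perm_sd == 0) {
    warning("permutation SD is zero; category decided by sign")
    d <- ifelse(z_genuine > perm_mean, Inf, -Inf)
  } else {
    d <- (z_genuine - perm_mean) / perm_sd
  }
  category <- if (d >= 2) {
    "strongly_validated"
  } else if (d >= 1) {
    "mildly_validated"
  } else {
    "invalidated"
  }
  list(d = d, perm_mean = perm_mean, perm_sd = perm_sd, category = category)
}

#' Count-comparison tests for augmentation effects
#'
#' Two tests used to compare significant-entity counts across mappings:
#' a one-sample, one-sided t-test of the permutation counts against the
#' genuine count (alternative: genuine greater), and an exact one-sided
#' binomial test of novel versus lost entities (success probability 0.5,
#' alternative: more novel). Supply whichever pair of arguments applies;
#' p-values from several mappings are meant to be FDR-adjusted together
#' with [bh_fdr()].
#'
#' @param genuine_count Significant-entity count with genuine augmentation.
#' @param perm_counts Vector (>= 2) of counts under permutation.
#' @param novel_count,lost_count Novel (N) and lost (L) entity counts,
#'   N + L >= 1.
#' @return List with `p_ttest` and/or `p_binomial`.
#' @export
count_comparison_tests <- function(genuine_count = NULL, perm_counts = NULL,
                                   novel_count = NULL, lost_count = NULL) {
  out <- list()
  if (!is.null(genuine_count)) {
    stopifnot(!is.null(perm_counts), length(perm_counts) >= 2)
    if (stats::sd(perm_counts) == 0) {
      warning("zero variance in permutation counts; exact comparison used")
      out$p_ttest <- ifelse(genuine_count > perm_counts[1], 0, 1)
    } else {
      out$p_ttest <- stats::t.test(perm_counts, mu = genuine_count,
                                   alternative = "less")$p.value
    }
  }
  if (!is.null(novel_count)) {
    stopifnot(!is.null(lost_count), novel_count + lost_count >= 1)
    out$p_binomial <- stats::binom.test(
      novel_count, novel_count + lost_count, p = 0.5,
      alternative = "greater"
    )$p.value
  }
  out
}
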