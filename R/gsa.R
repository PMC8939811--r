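# Competitive gene-set analysis: generalized least squares of adjusted gene
# scores on set membership with LD-induced gene-gene covariance, probit-scale
# set scores, greedy overlap-based redundancy reduction, and score gains
# between mappings.

#' Competitive gene-set association test
#'
#' Generalized least squares of the adjusted gene Z-scores on an intercept
#' and the set-membership indicator, with covariance `Sigma` (gene-gene
#' correlations; identity when `NULL`). The enrichment coefficient is tested
#' one-sided (upper tail) against a t reference with `n_genes - 2` degrees
#' of freedom. With `Sigma = NULL` or the identity the result coincides with
#' the ordinary one-sided two-sample t-test embedded in OLS.
#'
#' @param z Numeric vector of adjusted gene scores.
#' @param member Logical (or 0/1) membership indicator, same length.
#' @param Sigma Optional covariance/correlation matrix across genes; must be
#'   positive semi-definite (regularized with a warning otherwise).
#' @return List with `beta` (enrichment coefficient), `se`, `p_competitive`
#'   and `df`.
#' @export
competitive_gene_set_test <- function(z, member, Sigma = NULL) {
  member <- as.numeric(member)
  n <- length(z)
  stopifnot(length(member) == n)
  if (sum(member) < 2 || sum(1 - member) < 2) {
    stop("need >= 2 member and >= 2 non-member genes with scores",
         call. = FALSE)
  }
  X <- cbind(intercept = 1, member = member)
  if (is.null(Sigma)) {
    Xw <- X
    zw <- z
  } else {
    L <- tryCatch(chol(Sigma), error = function(e) {
      warning("Sigma is not positive definite; regularizing by eigenvalue clipping")
      es <- eigen(Sigma, symmetric = TRUE)
      S <- es$vectors %*% (pmax(es$values, 1e-8) * t(es$vectors))
      chol(S)
    })
    Xw <- backsolve(L, X, transpose = TRUE)
    zw <- backsolve(L, z, transpose = TRUE)
  }
  fit <- stats::lm.fit(Xw, zw)
  if (fit$rank < 2) stop("singular design: membership is constant", call. = FALSE)
  df <- n - 2
  sigma2 <- sum(fit$residuals^2) / df
  XtX_inv <- chol2inv(chol(crossprod(Xw)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  beta <- unname(fit$coefficients[2])
  list(
    beta = beta, se = se, df = df,
    p_competitive = stats::pt(beta / se, df = df, lower.tail = FALSE)
  )
}

#' Run competitive gene-set analysis over a collection
#'
#' Intersects every set with the scored genes, keeps sets whose effective
#' size lies within `set_size`, applies [competitive_gene_set_test()] per
#' set, FDR-adjusts across tested sets, and attaches probit-scale set scores
#' `z_set = probit(1 - p_fdr)`.
#'
#' @param gene_scores Gene-score tibble with `gene_id` and `z_adjusted`
#'   (from [adjust_gene_scores()]).
#' @param gene_sets Long tibble (set_id, gene_id).
#' @param Sigma Optional gene-gene correlation matrix (dimnames = gene ids);
#'   rows/columns are aligned to the scored genes.
#' @param set_size Effective set-size bounds after intersection, default
#'   c(25, 200).
#' @param alpha Significance level recorded on the result.
#' @return A `gsa_result`: tibble of set scores (set_id, n_genes_tested,
#'   beta, p_competitive, p_fdr, z_set) with metadata attributes; supports
#'   `tidy()`, `glance()` and `autoplot()`.
#' @export
run_gsa <- function(gene_scores, gene_sets, Sigma = NULL,
                    set_size = c(25, 200), alpha = 0.05) {
  stopifnot(all(c("gene_id", "z_adjusted") %in% names(gene_scores)))
  genes <- gene_scores$gene_id
  z <- gene_scores$z_adjusted
  if (!is.null(Sigma)) {
    stopifnot(all(genes %in% rownames(Sigma)))
    Sigma <- Sigma[genes, genes]
  }

  sets <- gene_sets |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::group_by(.data$set_id) |>
    dplyr::filter(dplyr::n() >= set_size[1], dplyr::n() <= set_size[2]) |>
    dplyr::ungroup()

  set_ids <- sort(unique(sets$set_id))
  res <- purrr::map_dfr(set_ids, function(sid) {
    member <- genes %in% sets$gene_id[sets$set_id == sid]
    fit <- competitive_gene_set_test(z, member, Sigma)
    tibble::tibble(
      set_id = sid, n_genes_tested = sum(member),
      beta = fit$beta, p_competitive = fit$p_competitive
    )
  })
  if (nrow(res) > 0) {
    res$p_fdr <- bh_fdr(clip_p(res$p_competitive))
    res$z_set <- probit_setscore(res$p_fdr)
    res$significant <- res$p_fdr < alpha
  } else {
    res <- tibble::tibble(
      set_id = character(), n_genes_tested = integer(), beta = numeric(),
      p_competitive = numeric(), p_fdr = numeric(), z_set = numeric(),
      significant = logical()
    )
  }
  structure(res, class = c("gsa_result", class(res)),
            alpha = alpha, n_genes = length(genes), set_size = set_size)
}

#' Greedy overlap-based redundancy reduction of significant gene sets
#'
#' Orders significant sets by ascending FDR-adjusted p-value (ties broken by
#' set id) and accepts a set iff its Jaccard overlap with every
#' already-accepted set is below `overlap_threshold`. This is an
#' overlap-based substitute for semantic-similarity reduction of GO terms;
#' the default threshold 0.7 is kept for continuity with that convention.
#'
#' @param significant_sets Tibble with `set_id` and `p_fdr` (typically the
#'   significant rows of a [run_gsa()] result).
#' @param gene_sets Long membership tibble (set_id, gene_id).
#' @param overlap_threshold Jaccard threshold in (0, 1].
#' @return The retained (non-redundant) subset of `significant_sets`.
#' @export
reduce_redundant_sets <- function(significant_sets, gene_sets,
                                  overlap_threshold = 0.7) {
  if (nrow(significant_sets) == 0) return(significant_sets)
  ord <- order(significant_sets$p_fdr, significant_sets$set_id)
  members <- split(gene_sets$gene_id, gene_sets$set_id)
  accepted <- character()
  for (sid in significant_sets$set_id[ord]) {
    a <- members[[sid]]
    ok <- TRUE
    for (b_id in accepted) {
      b <- members[[b_id]]
      jac <- length(intersect(a, b)) / length(union(a, b))
      if (jac >= overlap_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, sid)
  }
  dplyr::filter(significant_sets, .data$set_id %in% accepted)
}

#' Score gains between a baseline and an augmented mapping
#'
#' For gene sets the gain is the difference of probit-scale set scores
#' (`z_set`); for genes it is the difference of adjusted scores
#' (`z_adjusted`, before multiple-testing correction). Both runs are
#' restricted to the common scored universe; entities present in only one
#' run are excluded and counted in the `n_excluded` attribute.
#'
#' @param results_baseline,results_augmented Gene-score tibbles (level
#'   "gene") or `gsa_result`s (level "set").
#' @param level `"gene"` or `"set"`.
#' @return Gain tibble: entity_id, score_baseline, score_augmented, gain,
#'   gaining.
#' @export
compute_gains <- function(results_baseline, results_augmented,
                          level = c("set", "gene")) {
  level <- match.arg(level)
  id_col <- if (level == "set") "set_id" else "gene_id"
  score_col <- if (level == "set") "z_set" else "z_adjusted"
  b <- tibble::as_tibble(results_baseline)[, c(id_col, score_col)]
  a <- tibble::as_tibble(results_augmented)[, c(id_col, score_col)]
  names(b) <- c("entity_id", "score_baseline")
  names(a) <- c("entity_id", "score_augmented")
  joined <- dplyr::inner_join(b, a, by = "entity_id")
  if (nrow(joined) == 0) {
    stop("no common scored ", level, "s between the two runs", call. = FALSE)
  }
  out <- joined |>
    dplyr::mutate(
      gain = .data$score_augmented - .data$score_baseline,
      gaining = .data$gain > 0
    )
  attr(out, "n_excluded") <- nrow(b) + nrow(a) - 2 * nrow(joined)
  attr(out, "level") <- level
  out
}
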