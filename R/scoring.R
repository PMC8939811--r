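# LD-aware gene scoring: the SNP-wise mean statistic (mean of per-SNV 1-df
# chi-squares) with its eigenvalue-weighted quadratic-form null, score
# adjustment for residual confounders, and LD-induced gene-gene correlations.

# Upper-tail probability of Q = sum_k lambda_k * chisq_1 at q.
# Numerical quadratic-form tail: Ruben's mixture-of-chi-squares series when
# its geometric convergence is fast, otherwise Imhof's integral; deep tails
# use the Lugannani-Rice saddlepoint, and a moment-matched gamma is the
# last-resort fallback. Exact chi-square shortcut for equal weights.
wchisq_tail <- function(q, lambda, grouped = NULL) {
  if (is.null(grouped)) grouped <- group_eigenvalues(lambda)
  lam <- grouped$lam
  h <- grouped$h
  k <- sum(h)
  if (k == 0L) return(1)
  if (q <= 0) return(1)
  if (length(lam) == 1L) {
    return(stats::pchisq(q / lam, df = k, lower.tail = FALSE))
  }

  gamma_tail <- function() {
    m <- sum(lam * h)
    v <- 2 * sum(lam^2 * h)
    stats::pgamma(q, shape = m^2 / v, scale = v / m, lower.tail = FALSE)
  }

  # Ruben series: convergence rate is max(1 - beta/lambda); only use it when
  # the predicted number of terms is modest
  beta <- 0.90625 * min(lam)
  rate <- 1 - beta / max(lam)
  n_pred <- ceiling(log(1e-10) / log(rate))
  p <- if (is.finite(n_pred) && n_pred <= 2500) {
    ruben_tail(q, lam, h, beta, maxit = n_pred + 50L)
  } else {
    NA_real_
  }

  if (is.na(p)) {
    nl <- length(lam)
    integrand <- function(u) {
      M <- lam %o% u
      theta <- 0.5 * .colSums(atan(M) * h, nl, length(u)) - 0.5 * q * u
      rho <- exp(0.25 * .colSums(log1p(M * M) * h, nl, length(u)))
      sin(theta) / (u * rho)
    }
    p <- tryCatch(
      0.5 + stats::integrate(integrand, 0, Inf, subdivisions = 500L,
                             rel.tol = 1e-7, abs.tol = 1e-9)$value / pi,
      error = function(e) NA_real_
    )
  }
  if (is.na(p) || p < 1e-6 || p > 1 - 1e-6) {
    p_s <- saddlepoint_tail(q, lam, h)
    if (!is.na(p_s) && (is.na(p) || p < 1e-6)) p <- p_s
    if (is.na(p)) p <- gamma_tail()
  }
  min(max(p, .P_FLOOR), 1)
}

# Ruben's expansion of the weighted chi-square upper tail as a mixture of
# central chi-squares with scale beta: P(Q > q) = sum_k a_k P(chisq_{K+2k} >
# q/beta). All mixture weights are non-negative for beta <= min(lambda), so
# the truncation error is bounded by the unassigned mass.
ruben_tail <- function(q, lam, h, beta, maxit, eps = 1e-10) {
  K <- sum(h)
  rl <- 1 - beta / lam
  a_prev <- exp(0.5 * sum(h * log(beta / lam)))
  qb <- q / beta
  a <- numeric(maxit + 1)
  a[1] <- a_prev
  rl_pow <- h
  cm <- numeric(maxit)
  p <- a[1] * stats::pchisq(qb, df = K, lower.tail = FALSE)
  tail_a <- 1 - a[1]
  for (kk in seq_len(maxit)) {
    rl_pow <- rl_pow * rl
    cm[kk] <- sum(rl_pow)
    a[kk + 1] <- sum(a[1:kk] * cm[kk:1]) / (2 * kk)
    p <- p + a[kk + 1] * stats::pchisq(qb, df = K + 2 * kk, lower.tail = FALSE)
    tail_a <- tail_a - a[kk + 1]
    if (tail_a < eps) return(p)
  }
  NA_real_
}

# Lugannani-Rice saddlepoint approximation to P(sum h_j lambda_j chisq_1 > q).
# Cumulant generating function K(z) = -0.5 sum h log(1 - 2 z lambda),
# solved at K'(zhat) = q. Returns NA near the mean (|w| ~ 0), where the
# caller's Imhof integral is reliable anyway.
saddlepoint_tail <- function(q, lam, h) {
  zmax <- 1 / (2 * max(lam)) - 1e-10
  Kp <- function(z) sum(h * lam / (1 - 2 * z * lam))
  zhat <- tryCatch(
    stats::uniroot(function(z) Kp(z) - q, c(-1e4, zmax), tol = 1e-13)$root,
    error = function(e) NA_real_
  )
  if (is.na(zhat) || abs(zhat) < 1e-8) return(NA_real_)
  K0 <- -0.5 * sum(h * log(1 - 2 * zhat * lam))
  K2 <- sum(2 * h * lam^2 / (1 - 2 * zhat * lam)^2)
  w <- sign(zhat) * sqrt(2 * (zhat * q - K0))
  v <- zhat * sqrt(K2)
  if (!is.finite(w) || abs(w) < 1e-8) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Collapse numerically equal quadratic-form weights into (value,
# multiplicity) pairs; the Imhof integrand cost scales with the number of
# distinct weights, and block-LD spectra concentrate on a few values.
group_eigenvalues <- function(lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0L) return(list(lam = numeric(), h = numeric()))
  grp <- table(signif(lambda, 8))
  list(lam = as.numeric(names(grp)), h = as.numeric(grp))
}

#' Empirical SNV correlation (LD) matrix from a reference panel
#'
#' Pearson correlation of genotype dosage columns. Off-diagonals are shrunk
#' toward zero by a factor `1 - shrink` so duplicated columns stay
#' numerically non-singular.
#'
#' @param panel A `ref_panel`.
#' @param snv_ids SNV identifiers (must be in the panel; monomorphic SNVs
#'   are an error naming the offender).
#' @param shrink Off-diagonal shrinkage, default 1e-6.
#' @return Correlation matrix with `snv_ids` as dimnames.
#' @export
snv_correlation_matrix <- function(panel, snv_ids, shrink = 1e-6) {
  missing_ids <- setdiff(snv_ids, colnames(panel$genotypes))
  if (length(missing_ids) > 0) {
    stop("SNV id(s) not in panel: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  g <- panel$genotypes[, snv_ids, drop = FALSE]
  v <- apply(g, 2, stats::var)
  if (any(v == 0)) {
    stop("monomorphic SNV(s): ",
         paste(snv_ids[v == 0], collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(g)
  R <- R * (1 - shrink)
  diag(R) <- 1
  R
}

#' Score one gene with the SNP-wise mean statistic
#'
#' Each SNV p-value is converted to a 1-df chi-square via the upper-tail
#' quantile; the gene statistic is their mean. Under the null the statistic
#' is distributed as `(1/K) * sum_k lambda_k chisq_1`, with `lambda_k` the
#' eigenvalues of the gene's SNV correlation matrix `R`; the upper-tail
#' p-value of that weighted form is computed by numerical (Imhof)
#' integration with a moment-matched gamma fallback. A single-SNV gene score
#' equals the SNV p-value.
#'
#' @param pvals SNV p-values in (0, 1]; zeros are clipped to 1e-300 (the
#'   number of clipped values is reported in the `n_clipped` attribute).
#' @param R SNV correlation matrix, `dim(R) == length(pvals)`.
#' @return List with `t_stat` (mean chi-square) and `p_raw`.
#' @export
score_gene <- function(pvals, R) {
  stopifnot(length(pvals) >= 1, nrow(R) == length(pvals))
  n_clipped <- sum(pvals < .P_FLOOR)
  if (n_clipped > 0) warning(n_clipped, " p-value(s) clipped to 1e-300")
  p <- clip_p(pvals)
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  t_stat <- mean(chi)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  out <- list(t_stat = t_stat,
              p_raw = wchisq_tail(length(p) * t_stat, ev))
  attr(out, "n_clipped") <- n_clipped
  out
}

# Build the reusable per-gene scoring context: SNV row indices into the
# position-ordered sumstats, intragenic flags, LD eigenvalues, and the
# adjustment covariates that do not depend on the (possibly permuted)
# p-values. EPVP reuses this across permutations, mirroring the protocol in
# which LD matrices and gene-gene correlations are computed once from the
# genuine mapping.
gene_scoring_context <- function(map, sumstats, panel, shrink = 1e-6) {
  ss <- dplyr::arrange(sumstats, .data$chrom, .data$pos)
  ss_idx <- stats::setNames(seq_len(nrow(ss)), ss$rsid)
  map <- dplyr::filter(map, .data$rsid %in% ss$rsid)
  maf <- stats::setNames(panel$variants$maf, panel$variants$rsid)

  by_gene <- split(map[, c("rsid", "origin")], map$gene_id)
  genes <- names(by_gene)
  snv_idx <- intragenic <- eig <- eig_grp <- vector("list", length(genes))
  ld_mean_absr <- inv_mac <- n_snvs <- numeric(length(genes))

  for (i in seq_along(genes)) {
    rs <- by_gene[[i]]$rsid
    snv_idx[[i]] <- unname(ss_idx[rs])
    intragenic[[i]] <- by_gene[[i]]$origin == "intragenic"
    R <- snv_correlation_matrix(panel, rs, shrink = shrink)
    eig[[i]] <- pmax(eigen(R, symmetric = TRUE, only.values = TRUE)$values, 0)
    eig_grp[[i]] <- group_eigenvalues(eig[[i]])
    k <- length(rs)
    ld_mean_absr[i] <- if (k == 1) 0 else mean(abs(R[upper.tri(R)]))
    inv_mac[i] <- 1 / mean(2 * panel$n_samples * maf[rs])
    n_snvs[i] <- k
  }

  list(
    genes = genes, sumstats = ss, snv_idx = snv_idx,
    intragenic = intragenic, eig = eig, eig_grp = eig_grp,
    covariates = tibble::tibble(
      gene_id = genes, n_snvs = n_snvs,
      log_n_snvs = log(n_snvs),
      within_gene_ld = ld_mean_absr, inv_mean_mac = inv_mac
    ),
    mapping_label = attr(map, "mapping_label") %||% "mapping"
  )
}

# Score every gene in a context against per-SNV (p, n) vectors aligned with
# the context's ordered sumstats rows. When `pvec_shift`/`nvec_shift` are
# supplied (the EPVP path), each gene mixes the original values at its
# intragenic positions with the shifted values at its extragenic positions —
# this must happen per gene, because one gene's intragenic SNV can be
# another gene's extragenic SNV.
score_from_context <- function(ctx, pvec = NULL, nvec = NULL,
                               pvec_shift = NULL, nvec_shift = NULL) {
  pvec <- pvec %||% ctx$sumstats$pval
  nvec <- nvec %||% ctx$sumstats$n
  k <- length(ctx$genes)
  t_stat <- p_raw <- mean_n <- numeric(k)
  for (i in seq_len(k)) {
    idx <- ctx$snv_idx[[i]]
    p_i <- pvec[idx]
    n_i <- nvec[idx]
    if (!is.null(pvec_shift)) {
      extra <- !ctx$intragenic[[i]]
      p_i[extra] <- pvec_shift[idx][extra]
      n_i[extra] <- nvec_shift[idx][extra]
    }
    chi <- stats::qchisq(clip_p(p_i), df = 1, lower.tail = FALSE)
    t_stat[i] <- mean(chi)
    p_raw[i] <- wchisq_tail(length(idx) * t_stat[i], grouped = ctx$eig_grp[[i]])
    mean_n[i] <- mean(n_i)
  }
  dplyr::left_join(
    tibble::tibble(
      gene_id = ctx$genes, t_stat = t_stat, p_raw = p_raw,
      z_unadjusted = probit_upper(p_raw), mean_n = mean_n
    ),
    ctx$covariates, by = "gene_id"
  ) |>
    dplyr::select("gene_id", "n_snvs", "mean_n", "t_stat", "p_raw",
                  "z_unadjusted", "log_n_snvs", "within_gene_ld",
                  "inv_mean_mac")
}

#' Score all genes of a mapping
#'
#' Applies [score_gene()] to every gene of an SNV-gene map (SNVs absent from
#' the summary statistics are dropped; genes left without SNVs are not
#' scored), then attaches the adjustment covariates. The scoring context
#' (LD eigenvalues, SNV indices) is stored in the `context` attribute for
#' reuse by the permutation control.
#'
#' @param map SNV-gene map from [aggregate_snv_gene_map()].
#' @param sumstats Processed summary-statistics tibble.
#' @param panel A `ref_panel`.
#' @param shrink LD-matrix off-diagonal shrinkage.
#' @return Gene-score tibble: gene_id, n_snvs, mean_n, t_stat, p_raw,
#'   z_unadjusted plus covariates.
#' @export
score_genes <- function(map, sumstats, panel, shrink = 1e-6) {
  ctx <- gene_scoring_context(map, sumstats, panel, shrink = shrink)
  out <- score_from_context(ctx)
  attr(out, "context") <- ctx
  out
}

#' Adjust gene scores for residual confounders
#'
#' Outlying probit-scale gene scores are winsorized at the sample mean
#' +/- `winsor_sd` standard deviations, then ordinary least squares regresses
#' the winsorized score on log SNV count, within-gene LD (mean off-diagonal
#' |r|), inverse mean minor-allele count, and mean per-SNV sample size. The
#' adjusted score is the residual recentred at the winsorized mean,
#' preserving the overall probit scale so scores remain comparable across
#' mappings. With
#' fewer than 10 genes the adjustment is skipped with a warning. Collinear
#' covariates trigger a ridge fallback (penalty 1e-6).
#'
#' @param scores Gene-score tibble from [score_genes()].
#' @param winsor_sd Winsorization threshold in SD units (default 3).
#' @return Input tibble with `z_adjusted`, `p_adjusted` (upper-tail) and
#'   `p_fdr` columns added.
#' @export
adjust_gene_scores <- function(scores, winsor_sd = 3) {
  z <- scores$z_unadjusted
  if (nrow(scores) < 10) {
    warning("fewer than 10 genes; score adjustment skipped")
    out <- dplyr::mutate(scores, z_adjusted = z)
  } else {
    mu <- mean(z)
    s <- stats::sd(z)
    zw <- pmin(pmax(z, mu - winsor_sd * s), mu + winsor_sd * s)
    X <- cbind(
      1, scores$log_n_snvs, scores$within_gene_ld,
      scores$inv_mean_mac, scores$mean_n
    )
    keep <- which(apply(X[, -1, drop = FALSE], 2, stats::sd) > 0) + 1L
    X <- X[, c(1L, keep), drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      message("collinear covariates; using ridge fallback")
      beta <- solve(crossprod(X) + 1e-6 * diag(ncol(X)), crossprod(X, zw))
    } else {
      beta <- qr.coef(qrX, zw)
    }
    fitted <- drop(X %*% beta)
    out <- dplyr::mutate(scores, z_adjusted = zw - fitted + mean(zw))
  }
  out |>
    dplyr::mutate(
      p_adjusted = stats::pnorm(.data$z_adjusted, lower.tail = FALSE),
      p_fdr = bh_fdr(clip_p(.data$p_adjusted))
    )
}

#' LD-induced correlations between gene statistics
#'
#' For genes i and j whose SNV spans lie within `window_bp` of each other
#' (same chromosome), the null covariance of the SNP-wise mean statistics is
#' `cov(T_i, T_j) = (2 / (K_i K_j)) * sum_{a in i, b in j} r_ab^2` with
#' variances computed analogously within gene; the correlation is zero
#' outside the window. The resulting matrix is regularized to positive
#' semi-definiteness by eigenvalue clipping at zero and renormalized to unit
#' diagonal.
#'
#' @param map SNV-gene map (or the `context` attribute of [score_genes()]
#'   output, which guarantees the same SNV universe as the scores).
#' @param panel A `ref_panel`.
#' @param window_bp Window for non-zero correlations (default 5 Mb).
#' @param sumstat_snv_ids Optional restriction of the SNV universe.
#' @return Gene-gene correlation matrix with gene ids as dimnames.
#' @export
gene_gene_correlations <- function(map, panel, window_bp = 5e6,
                                   sumstat_snv_ids = NULL) {
  if (!is.null(sumstat_snv_ids)) {
    map <- dplyr::filter(map, .data$rsid %in% sumstat_snv_ids)
  }
  by_gene <- split(map, map$gene_id)
  genes <- names(by_gene)
  ng <- length(genes)

  # standardized dosages so cross-gene r blocks are one crossprod
  gmat <- panel$genotypes[, unique(map$rsid), drop = FALSE]
  Z <- scale(gmat)
  nlo <- nrow(Z) - 1

  span <- purrr::map_dfr(by_gene, function(g) {
    tibble::tibble(chrom = g$chrom[1], lo = min(g$pos), hi = max(g$pos))
  })

  Sigma <- diag(1, ng)
  vars <- numeric(ng)
  for (i in seq_len(ng)) {
    rs <- by_gene[[i]]$rsid
    Ri <- crossprod(Z[, rs, drop = FALSE]) / nlo
    vars[i] <- 2 * sum(Ri^2) / length(rs)^2
  }
  if (ng > 1) {
    for (i in seq_len(ng - 1)) {
      for (j in seq(i + 1, ng)) {
        if (span$chrom[i] != span$chrom[j]) next
        gap <- max(span$lo[i], span$lo[j]) - min(span$hi[i], span$hi[j])
        if (gap > window_bp) next
        ri <- by_gene[[i]]$rsid
        rj <- by_gene[[j]]$rsid
        Rij <- crossprod(Z[, ri, drop = FALSE], Z[, rj, drop = FALSE]) / nlo
        cv <- 2 * sum(Rij^2) / (length(ri) * length(rj))
        Sigma[i, j] <- Sigma[j, i] <- cv / sqrt(vars[i] * vars[j])
      }
    }
  }
  dimnames(Sigma) <- list(genes, genes)

  es <- eigen(Sigma, symmetric = TRUE)
  if (min(es$values) < 0) {
    Sigma <- es$vectors %*% (pmax(es$values, 0) * t(es$vectors))
    d <- sqrt(diag(Sigma))
    Sigma <- Sigma / outer(d, d)
    dimnames(Sigma) <- list(genes, genes)
  }
  Sigma
}
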