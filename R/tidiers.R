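# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.coverage_report <- function(x, ...) x$per_gene

#' @exportS3Method generics::glance
glance.coverage_report <- function(x, ...) {
  tibble::tibble(mapping = x$mapping_label, coverage_bp = x$coverage_bp,
                 n_genes_covered = nrow(x$per_gene))
}

#' @exportS3Method generics::tidy
tidy.gsa_result <- function(x, ...) tibble::as_tibble(x)

#' @exportS3Method generics::glance
glance.gsa_result <- function(x, ...) {
  tibble::tibble(
    n_sets_tested = nrow(x),
    n_significant = sum(x$significant),
    n_genes = attr(x, "n_genes"),
    alpha = attr(x, "alpha")
  )
}

#' @exportS3Method generics::tidy
tidy.epvp_result <- function(x, ...) x$validation

#' @exportS3Method generics::glance
glance.epvp_result <- function(x, ...) {
  gaining <- x$validation[!is.na(x$validation$gaining) & x$validation$gaining, ]
  tibble::tibble(
    n_perm = x$n_perm,
    n_sig_genes_genuine = x$n_sig_genes_genuine,
    n_sig_genes_baseline = x$n_sig_genes_baseline,
    max_sig_genes_perm = max(x$n_sig_genes_perm),
    n_gaining = nrow(gaining),
    n_strongly_validated = sum(gaining$category == "strongly_validated"),
    n_mildly_validated = sum(gaining$category == "mildly_validated"),
    n_invalidated = sum(gaining$category == "invalidated")
  )
}

#' @exportS3Method generics::tidy
tidy.ired_trace <- function(x, ...) x$iterations

#' @exportS3Method generics::glance
glance.ired_trace <- function(x, ...) {
  tibble::tibble(
    set_id = x$set_id,
    iterations_to_loss = x$iterations_to_loss,
    censored = x$censored,
    stopped_small = x$stopped_small,
    robust = as.logical(x$robust)
  )
}

#' @exportS3Method generics::tidy
tidy.comparison_report <- function(x, ...) x$mappings

#' @exportS3Method generics::glance
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    n_mappings = nrow(x$mappings),
    n_common_genes = length(x$common_genes),
    n_common_sets = length(x$common_sets),
    rho_genes_vs_coverage = x$trends$genes_vs_coverage$rho %||% NA_real_,
    p_genes_vs_coverage = x$trends$genes_vs_coverage$p_rho %||% NA_real_
  )
}
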