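# GWAS summary-statistics quality control and harmonization against a
# reference-panel variant dictionary. Filter order is fixed:
# QC -> harmonize -> duplicates -> MAF -> exclusion region -> sample-size
# outliers; the final wrapper `process_sumstats()` applies it end-to-end and
# reports counts removed per rule.

STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Build a variant dictionary from a reference-panel variant table
#'
#' The dictionary relates rs-identifiers to meta-information (chromosome,
#' position, alleles) one-to-one, and carries the panel minor-allele
#' frequency used by the MAF filter.
#'
#' @param variants Variant tibble (rsid, chrom, pos, a1, a2, maf).
#' @return A dictionary tibble with an unordered allele-pair key column.
#' @export
build_variant_dictionary <- function(variants) {
  stopifnot(!anyDuplicated(variants$rsid))
  dict <- variants |>
    dplyr::mutate(
      allele_key = paste(pmin(.data$a1, .data$a2),
                         pmax(.data$a1, .data$a2), sep = "/")
    )
  stopifnot(!anyDuplicated(paste(dict$chrom, dict$pos, dict$allele_key)))
  dict
}

#' Basic validity and strand-ambiguity filter
#'
#' Removes records with missing or invalid statistics (beta, se <= 0,
#' p outside (0, 1], n <= 0), non-single-nucleotide alleles, identical
#' alleles, and strand-ambiguous allele pairs (A/T, T/A, C/G, G/C).
#'
#' @param raw_records Summary-statistics tibble.
#' @return Filtered tibble; errors if nothing survives.
#' @export
qc_filter_records <- function(raw_records) {
  out <- raw_records |>
    dplyr::filter(
      is.finite(.data$beta), is.finite(.data$se), .data$se > 0,
      is.finite(.data$pval), .data$pval > 0, .data$pval <= 1,
      is.finite(.data$n), .data$n > 0,
      .data$a1 %in% c("A", "C", "G", "T"),
      .data$a2 %in% c("A", "C", "G", "T"),
      .data$a1 != .data$a2,
      !(paste(.data$a1, .data$a2, sep = "/") %in% STRAND_AMBIGUOUS)
    )
  if (nrow(out) == 0) stop("no records survived QC", call. = FALSE)
  out
}

#' Harmonize records against the variant dictionary
#'
#' Primary match on (chromosome, position, unordered allele pair) assigns
#' the dictionary rsid. Records that fail the primary match are rescued via
#' their original rsid when the dictionary holds that rsid with the same
#' allele pair; their chromosome and position are then overwritten from the
#' dictionary. Still-unmatched records are dropped.
#'
#' @param records QC-filtered summary-statistics tibble.
#' @param dictionary Output of [build_variant_dictionary()].
#' @return Harmonized tibble whose rsids are all present in the dictionary.
#' @export
harmonize_variants <- function(records, dictionary) {
  rec <- records |>
    dplyr::mutate(
      allele_key = paste(pmin(.data$a1, .data$a2),
                         pmax(.data$a1, .data$a2), sep = "/")
    )
  dk <- dictionary |>
    dplyr::select("rsid", "chrom", "pos", "allele_key")

  primary <- dplyr::inner_join(
    dplyr::select(rec, -"rsid"), dk,
    by = c("chrom", "pos", "allele_key")
  )
  unmatched <- dplyr::anti_join(rec, dk, by = c("chrom", "pos", "allele_key"))
  rescued <- dplyr::inner_join(
    dplyr::select(unmatched, -"chrom", -"pos"),
    dk, by = c("rsid", "allele_key")
  )
  dplyr::bind_rows(primary, rescued) |>
    dplyr::select(-"allele_key") |>
    dplyr::select("rsid", "chrom", "pos", "a1", "a2",
                  "beta", "se", "pval", "n", dplyr::everything())
}

#' Final duplicate / MAF / region / sample-size filters
#'
#' In order: (1) rsids occurring more than once with *different* statistics
#' are removed entirely (identical duplicate rows are collapsed to one);
#' (2) records with dictionary minor-allele frequency < `maf_min`;
#' (3) records inside `exclusion_region`; (4) records whose sample size lies
#' more than `n_sd` standard deviations (population SD, two-sided) from the
#' mean of the remaining records. With fewer than 3 records the sample-size
#' filter is skipped.
#'
#' @param records Harmonized tibble.
#' @param dictionary Output of [build_variant_dictionary()].
#' @param exclusion_region Optional `(chrom, start, end)` list (0-based
#'   half-open).
#' @param n_sd Sample-size outlier threshold in SD units.
#' @param maf_min Minor-allele-frequency floor.
#' @return Filtered tibble with unique rsids.
#' @export
apply_final_filters <- function(records, dictionary, exclusion_region = NULL,
                                n_sd = 5, maf_min = 0.01) {
  rec <- dplyr::distinct(records,
                         .data$rsid, .data$beta, .data$se, .data$pval, .data$n,
                         .keep_all = TRUE)
  dup <- unique(rec$rsid[duplicated(rec$rsid)])
  rec <- dplyr::filter(rec, !(.data$rsid %in% dup))

  maf <- stats::setNames(dictionary$maf, dictionary$rsid)
  rec <- dplyr::filter(rec, maf[.data$rsid] >= maf_min)

  if (!is.null(exclusion_region)) {
    ex <- as.list(exclusion_region)
    names(ex) <- c("chrom", "start", "end")[seq_along(ex)]
    rec <- dplyr::filter(
      rec, !(.data$chrom == ex$chrom &
               pos_in_interval(.data$pos, ex$start, ex$end))
    )
  }

  if (nrow(rec) >= 3) {
    mu <- mean(rec$n)
    sd_n <- sqrt(mean((rec$n - mu)^2))
    if (sd_n > 0) {
      rec <- dplyr::filter(rec, abs(.data$n - mu) <= n_sd * sd_n)
    }
  }
  rec
}

#' Full summary-statistics processing pipeline
#'
#' Applies [qc_filter_records()], [harmonize_variants()] and
#' [apply_final_filters()] in the fixed order and attaches a QC report
#' (records removed per rule) as the `qc_report` attribute.
#'
#' @inheritParams apply_final_filters
#' @param raw_records Raw summary-statistics tibble.
#' @return Processed tibble, sorted by (chrom, pos), with `qc_report`
#'   attribute.
#' @export
process_sumstats <- function(raw_records, dictionary, exclusion_region = NULL,
                             n_sd = 5, maf_min = 0.01) {
  n0 <- nrow(raw_records)
  s1 <- qc_filter_records(raw_records)
  s2 <- harmonize_variants(s1, dictionary)
  s3 <- apply_final_filters(s2, dictionary, exclusion_region, n_sd, maf_min)
  out <- dplyr::arrange(s3, .data$chrom, .data$pos)
  attr(out, "qc_report") <- tibble::tibble(
    stage = c("input", "qc_valid", "harmonized", "final"),
    n_records = c(n0, nrow(s1), nrow(s2), nrow(out)),
    n_removed = c(0L, n0 - nrow(s1), nrow(s1) - nrow(s2), nrow(s2) - nrow(out))
  )
  out
}
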