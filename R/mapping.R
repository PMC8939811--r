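# SNV-to-gene mapping: flanked gene features, regulatory-interaction
# processing, SNV annotation, per-gene aggregation with origin labels, and
# mapping coverage.
#
# All interval columns in this package are 0-based half-open; a 1-based SNV
# position `pos` lies inside [start, end) iff start < pos <= end. Readers of
# 1-based inclusive formats (gene.loc, .bim) convert on ingestion.

#' Build gene-body and flank features
#'
#' Emits, per gene, a `body` feature plus (when the corresponding flank size
#' is positive) an `upstream` flank anchored at the transcription start site
#' and a `downstream` flank anchored at the transcription end site. Flanks
#' are strand-aware: the upstream flank of a minus-strand gene lies 3'-ward
#' of the body end in reference coordinates. Flanks are clipped at position 0
#' and, when `chrom_lengths` is given, at the chromosome end; they never
#' overlap the body.
#'
#' @param genes Gene-model tibble: gene_id, chrom, start, end, strand,
#'   tss, tes (as produced by [simulate_architecture()] or [read_gene_loc()]).
#' @param up_kb,down_kb Flank sizes in kb (>= 0).
#' @param chrom_lengths Optional numeric vector of chromosome lengths
#'   (indexed by chromosome number) used to clip flanks.
#' @return Feature tibble: gene_id, feature_id, feature_type
#'   (body/upstream/downstream), chrom, start, end.
#' @export
build_flanked_features <- function(genes, up_kb, down_kb, chrom_lengths = NULL) {
  stopifnot(up_kb >= 0, down_kb >= 0, all(genes$start < genes$end))
  up <- round(up_kb * 1000)
  down <- round(down_kb * 1000)

  plus <- genes$strand == "+"
  feature_rows <- function(type, suffix, s, e) {
    tibble::tibble(
      gene_id = genes$gene_id,
      feature_id = paste0(genes$gene_id, ":", suffix),
      feature_type = type,
      chrom = genes$chrom, start = s, end = e
    )
  }
  out <- list(feature_rows("body", "body", genes$start, genes$end))
  if (up > 0) {
    out <- c(out, list(feature_rows(
      "upstream", "up",
      ifelse(plus, genes$start - up, genes$end),
      ifelse(plus, genes$start, genes$end + up)
    )))
  }
  if (down > 0) {
    out <- c(out, list(feature_rows(
      "downstream", "down",
      ifelse(plus, genes$end, genes$start - down),
      ifelse(plus, genes$end + down, genes$start)
    )))
  }

  feats <- dplyr::bind_rows(out) |>
    dplyr::mutate(start = pmax(.data$start, 0))
  if (!is.null(chrom_lengths)) {
    feats <- feats |>
      dplyr::mutate(end = pmin(.data$end, chrom_lengths[.data$chrom]))
  }
  feats |>
    dplyr::filter(.data$start < .data$end) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Derive regulatory interactions from locus-pair (HiC-style) contacts
#'
#' For each contact pair (A, B): if locus B overlaps the promoter window of a
#' gene (the `promoter_kb` region immediately upstream of its transcription
#' start site), locus A becomes a regulatory element of that gene — and
#' symmetrically for A. Inter-chromosomal pairs are dropped and counted in
#' the `n_interchrom_dropped` attribute. Duplicate (gene, interval) records
#' are collapsed.
#'
#' @param locus_pairs Tibble with columns chrom_a, start_a, end_a, chrom_b,
#'   start_b, end_b (0-based half-open).
#' @param genes Gene-model tibble.
#' @param promoter_kb Promoter window size in kb upstream of the TSS.
#' @return Raw regulatory-element tibble (gene_id, chrom, start, end,
#'   source); pass through [process_ri_dataset()] to merge and label.
#' @export
derive_ri_from_contacts <- function(locus_pairs, genes, promoter_kb = 2) {
  stopifnot(all(c("chrom_a", "start_a", "end_a",
                  "chrom_b", "start_b", "end_b") %in% names(locus_pairs)))
  inter <- locus_pairs$chrom_a != locus_pairs$chrom_b
  n_dropped <- sum(inter)
  if (n_dropped > 0) {
    warning(n_dropped, " inter-chromosomal contact pair(s) dropped")
  }
  pairs <- locus_pairs[!inter, , drop = FALSE]

  pw <- round(promoter_kb * 1000)
  promoters <- genes |>
    dplyr::transmute(
      gene_id = .data$gene_id, chrom = .data$chrom,
      start = pmax(ifelse(.data$strand == "+", .data$tss - pw, .data$tss), 0),
      end = ifelse(.data$strand == "+", .data$tss, .data$tss + pw)
    )

  hit_genes <- function(chrom, start, end) {
    # genes whose promoter overlaps [start, end) on `chrom`
    out <- vector("list", length(chrom))
    for (ch in unique(chrom)) {
      p <- promoters[promoters$chrom == ch, ]
      rows <- which(chrom == ch)
      if (nrow(p) == 0) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = start[rows] + 1L, end = end[rows]),
        IRanges::IRanges(start = p$start + 1L, end = p$end)
      )
      for (i in seq_along(rows)) {
        out[[rows[i]]] <-
          p$gene_id[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
      }
    }
    out
  }

  hits_b <- hit_genes(pairs$chrom_b, pairs$start_b, pairs$end_b)
  hits_a <- hit_genes(pairs$chrom_a, pairs$start_a, pairs$end_a)

  rec <- list()
  for (i in seq_len(nrow(pairs))) {
    if (length(hits_b[[i]]) > 0) {
      rec[[length(rec) + 1L]] <- tibble::tibble(
        gene_id = hits_b[[i]], chrom = pairs$chrom_a[i],
        start = pairs$start_a[i], end = pairs$end_a[i]
      )
    }
    if (length(hits_a[[i]]) > 0) {
      rec[[length(rec) + 1L]] <- tibble::tibble(
        gene_id = hits_a[[i]], chrom = pairs$chrom_b[i],
        start = pairs$start_b[i], end = pairs$end_b[i]
      )
    }
  }
  out <- if (length(rec) == 0) {
    tibble::tibble(gene_id = character(), chrom = integer(),
                   start = integer(), end = integer())
  } else {
    dplyr::distinct(dplyr::bind_rows(rec))
  }
  out$source <- "contacts"
  attr(out, "n_interchrom_dropped") <- n_dropped
  out
}

#' Process a raw regulatory-interaction dataset
#'
#' Restricts records to genes present in the background gene list and to
#' intra-chromosomal interactions, drops malformed intervals (start >= end),
#' merges — separately for each gene and source — any overlapping elements
#' into maximal intervals, and assigns sequential element identifiers unique
#' within (gene, source).
#'
#' @param raw_ris Tibble: gene_id, chrom, start, end, optional source.
#' @param genes Background gene-model tibble.
#' @return Regulatory-element tibble: gene_id, chrom, start, end,
#'   element_uid, source.
#' @export
process_ri_dataset <- function(raw_ris, genes) {
  if (!"source" %in% names(raw_ris)) raw_ris$source <- "ri"
  bad <- raw_ris$start >= raw_ris$end
  if (any(bad)) {
    message(sum(bad), " malformed regulatory-element record(s) dropped")
    raw_ris <- raw_ris[!bad, , drop = FALSE]
  }
  gchrom <- stats::setNames(genes$chrom, genes$gene_id)
  keep <- raw_ris$gene_id %in% genes$gene_id &
    raw_ris$chrom == gchrom[raw_ris$gene_id]
  ris <- raw_ris[which(keep), , drop = FALSE]

  ris |>
    dplyr::group_by(.data$gene_id, .data$source, .data$chrom) |>
    dplyr::reframe(merge_intervals(.data$start, .data$end)) |>
    dplyr::group_by(.data$gene_id, .data$source) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(element_uid = paste0(.data$gene_id, ":",
                                       .data$source, ":",
                                       dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "chrom", "start", "end", "element_uid", "source")
}

#' Convert regulatory elements to mapping features
#'
#' @param elements Regulatory-element tibble from [process_ri_dataset()].
#' @return Feature tibble compatible with [annotate_features_with_snvs()].
#' @export
ri_features <- function(elements) {
  elements |>
    dplyr::transmute(
      gene_id = .data$gene_id,
      feature_id = .data$element_uid,
      feature_type = "regulatory_element",
      chrom = .data$chrom, start = .data$start, end = .data$end
    )
}

#' Annotate features with overlapping SNVs
#'
#' Lists, per feature, the SNVs whose position falls inside its interval
#' (half-open containment). Features of excluded genes contribute nothing,
#' and SNVs inside `exclusion_region` (e.g. the MHC) are annotated to no
#' feature. Features with no overlapping SNV are retained with an `NA` rsid
#' row, so they remain visible but cannot count toward coverage.
#'
#' @param features Feature tibble (gene_id, feature_id, feature_type, chrom,
#'   start, end).
#' @param variants Variant tibble (rsid, chrom, pos), sorted by position.
#' @param exclusion_region Optional list/vector `(chrom, start, end)`
#'   (0-based half-open); SNVs inside it and genes overlapping it are
#'   excluded. Use [mhc_region()] for the human default.
#' @return Long annotation tibble: feature columns plus rsid, pos.
#' @export
annotate_features_with_snvs <- function(features, variants,
                                        exclusion_region = NULL) {
  variants <- dplyr::arrange(variants, .data$chrom, .data$pos)
  if (!is.null(exclusion_region)) {
    ex <- as.list(exclusion_region)
    names(ex) <- c("chrom", "start", "end")[seq_along(ex)]
    drop_snv <- variants$chrom == ex$chrom &
      pos_in_interval(variants$pos, ex$start, ex$end)
    variants <- variants[!drop_snv, , drop = FALSE]
    excluded_genes <- features |>
      dplyr::filter(.data$feature_type == "body", .data$chrom == ex$chrom,
                    .data$start < ex$end, .data$end > ex$start) |>
      dplyr::pull("gene_id")
    features <- dplyr::filter(features, !(.data$gene_id %in% excluded_genes))
  }

  out <- vector("list", length(unique(features$chrom)))
  i <- 0L
  for (ch in sort(unique(features$chrom))) {
    f <- features[features$chrom == ch, , drop = FALSE]
    v <- variants[variants$chrom == ch, , drop = FALSE]
    i <- i + 1L
    if (nrow(v) == 0) {
      out[[i]] <- dplyr::mutate(f, rsid = NA_character_, pos = NA_integer_)
      next
    }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(start = f$start + 1L, end = f$end),
      IRanges::IRanges(start = v$pos, width = 1L)
    )
    hit <- tibble::tibble(
      row = S4Vectors::queryHits(ov),
      rsid = v$rsid[S4Vectors::subjectHits(ov)],
      pos = v$pos[S4Vectors::subjectHits(ov)]
    )
    ann <- dplyr::left_join(
      dplyr::mutate(f, row = dplyr::row_number()), hit, by = "row"
    ) |> dplyr::select(-"row")
    out[[i]] <- ann
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$gene_id, .data$chrom, .data$pos)
}

#' The human MHC exclusion region
#'
#' Chromosome 6, positions 28,477,797-33,448,354 (returned under the internal
#' 0-based half-open convention). Synthetic genomes pass `NULL` instead.
#' @return List with chrom, start, end.
#' @export
mhc_region <- function() list(chrom = 6L, start = 28477796L, end = 33448354L)

#' Aggregate feature annotations into a per-gene SNV map
#'
#' Takes the baseline-model annotations (gene body + small flanks) and any
#' number of augmentation annotations (larger flanks, regulatory elements)
#' and aggregates them at the gene level: per gene the union of SNVs, each
#' labelled `intragenic` when it is captured by any baseline feature of that
#' gene and `extragenic` otherwise. A SNV is never mapped twice to the same
#' gene but may map to several genes. SNV order follows genomic order.
#'
#' @param baseline_annotations Annotation tibble from
#'   [annotate_features_with_snvs()] for the baseline model.
#' @param augmentation_annotations Annotation tibble (or `NULL`) for the
#'   augmented features; must use the same variant universe.
#' @param mapping_label Label stored on the result.
#' @return SNV-gene map tibble: gene_id, rsid, chrom, pos, origin; with
#'   attribute `mapping_label`.
#' @export
aggregate_snv_gene_map <- function(baseline_annotations,
                                   augmentation_annotations = NULL,
                                   mapping_label = "mapping") {
  base <- baseline_annotations |>
    dplyr::filter(!is.na(.data$rsid)) |>
    dplyr::distinct(.data$gene_id, .data$rsid, .data$chrom, .data$pos)
  aug <- if (is.null(augmentation_annotations)) {
    base[0, , drop = FALSE]
  } else {
    augmentation_annotations |>
      dplyr::filter(!is.na(.data$rsid)) |>
      dplyr::distinct(.data$gene_id, .data$rsid, .data$chrom, .data$pos)
  }
  map <- dplyr::bind_rows(base, aug) |>
    dplyr::distinct(.data$gene_id, .data$rsid, .keep_all = TRUE) |>
    dplyr::left_join(
      dplyr::mutate(base[, c("gene_id", "rsid")], .base = TRUE),
      by = c("gene_id", "rsid")
    ) |>
    dplyr::mutate(
      origin = ifelse(is.na(.data$.base), "extragenic", "intragenic")
    ) |>
    dplyr::select(-".base") |>
    dplyr::arrange(.data$gene_id, .data$chrom, .data$pos)
  attr(map, "mapping_label") <- mapping_label
  map
}

#' Compute the coverage of a mapping
#'
#' Coverage is the number of non-redundant base pairs covered by all
#' qualifying features of a gene, summed across genes. A feature qualifies
#' iff it contains at least one SNV that is also present in the summary
#' statistics (`sumstat_snv_ids`); base pairs shared between two genes count
#' once per gene.
#'
#' @param annotations Annotation tibble from [annotate_features_with_snvs()]
#'   (features with their SNVs and intervals).
#' @param sumstat_snv_ids Character vector of SNV ids present in the
#'   processed summary statistics.
#' @param mapping_label Label stored on the report.
#' @return A `coverage_report` object; `tidy()` gives the per-gene breakdown,
#'   `glance()` the total.
#' @export
compute_coverage <- function(annotations, sumstat_snv_ids,
                             mapping_label = "mapping") {
  qualifying <- annotations |>
    dplyr::filter(.data$rsid %in% sumstat_snv_ids) |>
    dplyr::distinct(.data$gene_id, .data$feature_id, .data$chrom,
                    .data$start, .data$end)
  per_gene <- qualifying |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      covered_bp = union_length(.data$start, .data$end), .groups = "drop"
    )
  structure(
    list(
      mapping_label = mapping_label,
      coverage_bp = sum(per_gene$covered_bp),
      per_gene = per_gene
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat("<coverage_report> ", x$mapping_label, ": ",
      format(x$coverage_bp, big.mark = ","), " bp across ",
      nrow(x$per_gene), " genes\n", sep = "")
  invisible(x)
}
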