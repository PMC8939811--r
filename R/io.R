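# Readers and writers for the plain-text formats the pipeline exchanges:
# .bim-like variant tables, gene.loc gene models, BED-like regulatory
# interactions, GMT gene-set collections, summary-statistics TSVs, and
# annot-style feature files. On-disk coordinates follow each format's
# convention (1-based inclusive for .bim/gene.loc, 0-based half-open for
# BED); in-memory intervals are always 0-based half-open.

#' Write / read a .bim-like variant table
#'
#' Columns: chrom, rsid, cM (written as 0), pos (1-based), a1, a2.
#' @param variants Variant tibble (rsid, chrom, pos, a1, a2).
#' @param path File path.
#' @return `read_bim()` returns a variant tibble.
#' @export
write_bim <- function(variants, path) {
  readr::write_tsv(
    dplyr::transmute(variants, .data$chrom, .data$rsid, cm = 0,
                     .data$pos, .data$a1, .data$a2),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_bim
#' @export
read_bim <- function(path) {
  readr::read_tsv(path,
                  col_names = c("chrom", "rsid", "cm", "pos", "a1", "a2"),
                  col_types = "icdicc", progress = FALSE) |>
    dplyr::select("rsid", "chrom", "pos", "a1", "a2")
}

#' Write / read a gene.loc-style gene model table
#'
#' Columns: gene_id, chrom, start, stop (1-based inclusive), strand, symbol.
#' `read_gene_loc()` converts to the internal 0-based half-open convention
#' and derives tss/tes boundaries from strand.
#' @param genes Gene-model tibble (internal convention).
#' @param path File path.
#' @export
write_gene_loc <- function(genes, path) {
  readr::write_tsv(
    dplyr::transmute(genes, .data$gene_id, .data$chrom,
                     start = .data$start + 1L, stop = .data$end,
                     .data$strand, symbol = .data$symbol),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_gene_loc
#' @export
read_gene_loc <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("gene_id", "chrom", "start", "stop", "strand", "symbol"),
    col_types = "ciiicc", progress = FALSE
  )
  plus <- raw$strand == "+"
  tibble::tibble(
    gene_id = raw$gene_id, chrom = raw$chrom,
    start = raw$start - 1L, end = raw$stop,
    strand = raw$strand,
    tss = ifelse(plus, raw$start - 1L, raw$stop),
    tes = ifelse(plus, raw$stop, raw$start - 1L),
    symbol = raw$symbol
  )
}

#' Write / read a BED-like regulatory-interaction table
#'
#' Columns: chrom, start, end (0-based half-open, as in BED), gene_id,
#' element_uid, source.
#' @param elements Regulatory-element tibble.
#' @param path File path.
#' @export
write_ri_bed <- function(elements, path) {
  readr::write_tsv(
    dplyr::select(elements, "chrom", "start", "end", "gene_id",
                  "element_uid", "source"),
    path, col_names = FALSE
  )
  invisible(path)
}

#' @rdname write_ri_bed
#' @export
read_ri_bed <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene_id", "element_uid", "source"),
    col_types = "iiiccc", progress = FALSE
  ) |>
    dplyr::select("gene_id", "chrom", "start", "end", "element_uid", "source")
}

#' Write / read a GMT gene-set collection
#'
#' One set per line: set id, description, then member gene ids.
#' @param gene_sets Long tibble (set_id, gene_id).
#' @param path File path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    dplyr::group_by(.data$set_id) |>
    dplyr::summarise(
      line = paste(c(.data$set_id[1], "na", .data$gene_id), collapse = "\t"),
      .groups = "drop"
    )
  writeLines(lines$line, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) return(NULL)
    tibble::tibble(set_id = parts[1], gene_id = parts[-(1:2)])
  })
}

#' Write / read a summary-statistics TSV
#'
#' `read_sumstats()` accepts a column-mapping so arbitrarily named raw files
#' can be ingested: `columns` maps the canonical names (rsid, chrom, pos,
#' a1, a2, beta, se, pval, n) to the names present in the file.
#' @param sumstats Summary-statistics tibble.
#' @param path File path.
#' @param columns Named character vector, canonical -> file column name.
#' @export
write_sumstats <- function(sumstats, path) {
  readr::write_tsv(
    dplyr::select(sumstats, "rsid", "chrom", "pos", "a1", "a2",
                  "beta", "se", "pval", "n"),
    path
  )
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path, columns = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  canonical <- c("rsid", "chrom", "pos", "a1", "a2", "beta", "se", "pval", "n")
  if (!is.null(columns)) {
    missing_map <- setdiff(names(columns), canonical)
    if (length(missing_map) > 0) {
      stop("unknown canonical column(s) in mapping: ",
           paste(missing_map, collapse = ", "), call. = FALSE)
    }
    raw <- dplyr::rename(raw, !!!stats::setNames(unname(columns), names(columns)))
  }
  absent <- setdiff(canonical, names(raw))
  if (length(absent) > 0) {
    stop("summary statistics lack column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dplyr::select(raw, dplyr::all_of(canonical))
}

#' Write an annot-style feature-to-SNV file
#'
#' One row per feature: feature name, `chrom:start:end` (1-based inclusive),
#' then the overlapping SNV ids.
#' @param annotations Annotation tibble from [annotate_features_with_snvs()].
#' @param path File path.
#' @export
write_annot <- function(annotations, path) {
  lines <- annotations |>
    dplyr::group_by(.data$feature_id, .data$chrom, .data$start, .data$end) |>
    dplyr::summarise(
      snvs = paste(stats::na.omit(.data$rsid), collapse = "\t"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      loc = paste(.data$chrom, .data$start + 1L, .data$end, sep = ":"),
      line = ifelse(nchar(.data$snvs) > 0,
                    paste(.data$feature_id, .data$loc, .data$snvs, sep = "\t"),
                    paste(.data$feature_id, .data$loc, sep = "\t"))
    )
  writeLines(lines$line, path)
  invisible(path)
}
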