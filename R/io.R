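#' Read a per-locus allele read-count table
#'
#' Accepts either a wide TSV with one row per biallelic locus and two count
#' columns per condition (`<condition>_ref`, `<condition>_alt` for each of the
#' 13 condition labels of [condition_table()]) or a minimal VCF whose sample
#' columns are named after the conditions and carry `AD` depths. Multi-allelic
#' VCF records are reduced to the two alleles with the largest total read
#' support over all conditions, with a warning.
#'
#' @param path Path to the TSV (`.tsv`/`.txt`) or VCF (`.vcf`) file.
#' @return A long tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `effect`, `condition`, `ref_reads`, `alt_reads`, sorted by
#'   (`chrom`, `pos`). An empty file with a valid header yields a zero-row
#'   table.
#' @export
read_allele_counts <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    return(read_allele_counts_vcf(path))
  }
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- unlist(lapply(condition_levels(), function(cc) paste0(cc, c("_ref", "_alt"))))
  missing <- setdiff(needed, names(wide))
  if (length(missing) > 0) {
    abort(sprintf("counts file is missing condition column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(wide))) {
    abort("counts file must have chrom, pos, ref and alt columns")
  }
  if (!"effect" %in% names(wide)) wide$effect <- "unknown"
  counts_wide_to_long(wide)
}

counts_wide_to_long <- function(wide) {
  long <- wide %>%
    dplyr::rename(.ref_allele = "ref", .alt_allele = "alt") %>%
    tidyr::pivot_longer(
      cols = dplyr::matches("_(ref|alt)$"),
      names_to = c("condition", ".value"),
      names_pattern = "^(.*)_(ref|alt)$"
    ) %>%
    dplyr::rename(ref_reads = "ref", alt_reads = "alt",
                  ref = ".ref_allele", alt = ".alt_allele") %>%
    dplyr::select("chrom", "pos", "ref", "alt", "effect", "condition",
                  "ref_reads", "alt_reads")
  if (nrow(long) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          effect = character(), condition = character(),
                          ref_reads = integer(), alt_reads = integer()))
  }
  validate_allele_counts(long)
  long %>% dplyr::arrange(.data$chrom, .data$pos, .data$condition)
}

validate_allele_counts <- function(counts) {
  bad <- counts$ref_reads < 0 | counts$alt_reads < 0 |
    counts$ref_reads != floor(counts$ref_reads) |
    counts$alt_reads != floor(counts$alt_reads)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("negative, missing or non-integer read count at %s:%d",
                  counts$chrom[i], counts$pos[i]))
  }
  invisible(TRUE)
}

read_allele_counts_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  check_conditions_present(colnames(ad), where = "VCF sample columns")
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- c(fix$REF[i], alts)
    depths <- t(vapply(
      strsplit(ad[i, condition_levels()], ",", fixed = TRUE),
      function(x) {
        out <- suppressWarnings(as.integer(x))
        length(out) <- length(alleles)
        out[is.na(out)] <- 0L
        out
      },
      integer(length(alleles))
    ))
    keep <- utils::head(order(colSums(depths), decreasing = TRUE), 2)
    keep <- sort(keep)
    if (length(alleles) > 2) {
      warn(sprintf("multi-allelic locus %s:%s reduced to alleles %s/%s",
                   fix$CHROM[i], fix$POS[i], alleles[keep[1]], alleles[keep[2]]))
    }
    tibble::tibble(
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = alleles[keep[1]], alt = alleles[keep[2]], effect = "unknown",
      condition = condition_levels(),
      ref_reads = depths[, keep[1]], alt_reads = depths[, keep[2]]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          effect = character(), condition = character(),
                          ref_reads = integer(), alt_reads = integer())
  }
  validate_allele_counts(out)
  out %>% dplyr::arrange(.data$chrom, .data$pos, .data$condition)
}

#' Write an allele count table back to the wide TSV dialect
#'
#' Inverse of [read_allele_counts()] for TSV input: 1-based positions are
#' re-emitted unchanged.
#'
#' @param counts Long count tibble as returned by [read_allele_counts()].
#' @param path Output path.
#' @export
write_allele_counts <- function(counts, path) {
  wide <- counts %>%
    tidyr::pivot_longer(c("ref_reads", "alt_reads"),
                        names_to = "which", values_to = "reads") %>%
    dplyr::mutate(col = paste0(.data$condition,
                               ifelse(.data$which == "ref_reads", "_ref", "_alt"))) %>%
    dplyr::select(-"condition", -"which") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "reads") %>%
    dplyr::arrange(.data$chrom, .data$pos)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read exon coverage and library sizes
#'
#' The coverage TSV has one row per target region and condition
#' (`region_id`, `condition`, `depth`); the library-size TSV has one row per
#' condition (`condition`, `library_size`). All 13 conditions must be present.
#'
#' @param path,lib_path TSV paths.
#' @return `read_coverage()`: tibble (`region_id`, `condition`, `depth`);
#'   `read_library_sizes()`: tibble (`condition`, `library_size`).
#' @export
read_coverage <- function(path) {
  cov <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_conditions_present(cov$condition, where = "coverage table")
  if (any(!is.finite(cov$depth) | cov$depth < 0)) {
    i <- which(!is.finite(cov$depth) | cov$depth < 0)[1]
    abort(sprintf("non-finite or negative depth for region %s, condition %s",
                  cov$region_id[i], cov$condition[i]))
  }
  cov
}

#' @rdname read_coverage
#' @export
read_library_sizes <- function(lib_path) {
  lib <- readr::read_tsv(lib_path, show_col_types = FALSE, progress = FALSE)
  check_conditions_present(lib$condition, where = "library size table")
  if (any(lib$library_size <= 0)) abort("library sizes must be positive")
  lib
}

#' Read target regions from BED
#'
#' BED coordinates (0-based half-open) are kept as-is. Optional columns 4-6
#' are interpreted as `region_id`, `kind` and `gene_id`.
#'
#' @param path BED path.
#' @return Tibble (`region_id`, `chrom`, `start`, `end`, `kind`, `gene_id`,
#'   `length`).
#' @export
read_regions_bed <- function(path) {
  bed <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "region_id", "kind", "gene_id"),
    show_col_types = FALSE, progress = FALSE
  )
  if (any(bed$start >= bed$end)) {
    i <- which(bed$start >= bed$end)[1]
    abort(sprintf("region %s has start >= end", bed$region_id[i]))
  }
  bed %>%
    dplyr::mutate(
      gene_id = dplyr::if_else(.data$gene_id %in% c(".", ""), NA_character_,
                               .data$gene_id),
      length = .data$end - .data$start
    ) %>%
    dplyr::select("region_id", "chrom", "start", "end", "kind", "gene_id",
                  "length")
}

#' Write regions (or any interval table) as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   optionally `region_id`/`name`, `kind`, `gene_id`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name <- if ("region_id" %in% names(x)) x$region_id
          else if ("name" %in% names(x)) x$name else "."
  bed <- tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end, name = name,
    kind = if ("kind" %in% names(x)) x$kind else ".",
    gene_id = if ("gene_id" %in% names(x)) {
      dplyr::if_else(is.na(x$gene_id), ".", x$gene_id)
    } else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read the gene annotation table
#'
#' TSV with columns `gene_id`, `name`, `family` (one of P450, GST, CCE,
#' UDPGT, SULT, ABC, ADH, target, other), `chrom`, `start`, `end`
#' (0-based half-open).
#'
#' @param path TSV path.
#' @export
read_gene_annotation <- function(path) {
  genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  fams <- gene_families()
  bad <- !genes$family %in% fams
  if (any(bad)) {
    abort(sprintf("unknown gene family '%s' for gene %s",
                  genes$family[which(bad)[1]], genes$gene_id[which(bad)[1]]))
  }
  if (any(genes$end <= genes$start)) abort("gene spans must be positive")
  genes
}

#' @rdname read_gene_annotation
#' @export
gene_families <- function() {
  c("P450", "GST", "CCE", "UDPGT", "SULT", "ABC", "ADH", "target", "other")
}

#' Write all pipeline result tables to a directory
#'
#' One TSV per result class, plus a BED file for selection regions. Numeric
#' values survive a write/read round trip to at least six significant digits
#' (tables are written at full double precision).
#'
#' @param tables Named list of tibbles; recognised names are `cnv_genes`,
#'   `trajectory_hits`, `fst_scan`, `selection_regions`, `kdr_report`, `venn`,
#'   `trajectories`, `truth`, plus anything else (written as `<name>.tsv`).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], p, progress = FALSE)
    paths <- c(paths, p)
    if (nm == "selection_regions" && nrow(tables[[nm]]) >= 0 &&
        all(c("chrom", "start", "end") %in% names(tables[[nm]]))) {
      pb <- file.path(out_dir, "selection_regions.bed")
      write_bed(tables[[nm]], pb)
      paths <- c(paths, pb)
    }
  }
  invisible(paths)
}
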