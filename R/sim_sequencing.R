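#' Simulate pooled sequencing read counts at SNP loci
#'
#' For each SNP locus and condition, the sequencing depth is drawn from a
#' negative binomial (capture variability exceeds Poisson noise) and the
#' alt-supporting reads from a binomial at the error-adjusted pool frequency
#' `f' = f (1 - e) + (1 - f) e`.
#'
#' @param design A `cross_design` from [run_cross_design()].
#' @param depth_mean,depth_size Negative-binomial mean and size (dispersion)
#'   of per-locus depth.
#' @param error_rate Per-read allele error rate `e`.
#' @return A long count tibble as from [read_allele_counts()].
#' @export
simulate_counts <- function(design, depth_mean = 100, depth_size = 20,
                            error_rate = 0.001) {
  loci <- design$loci
  snp <- which(loci$locus_class == "snp")
  if (length(snp) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          effect = character(), condition = character(),
                          ref_reads = integer(), alt_reads = integer()))
  }
  rows <- lapply(condition_levels(), function(cond) {
    f <- pop_allele_freq(design$pools[[cond]])[snp]
    depth <- rnbinom(length(snp), mu = depth_mean, size = depth_size)
    fprime <- f * (1 - error_rate) + (1 - f) * error_rate
    alt_n <- rbinom(length(snp), depth, fprime)
    tibble::tibble(
      chrom = loci$chrom[snp], pos = loci$pos[snp],
      ref = loci$ref[snp], alt = loci$alt[snp],
      effect = loci$effect[snp], condition = cond,
      ref_reads = depth - alt_n, alt_reads = alt_n
    )
  })
  dplyr::bind_rows(rows) %>%
    dplyr::arrange(.data$chrom, .data$pos, .data$condition)
}

#' Build a synthetic capture panel of genes and exon regions
#'
#' Lays out `n_genes` genes along a synthetic chromosome, each with a few
#' exon target regions, assigning detoxification families cyclically. Genes
#' named in `cnv_gene_ids` are the ones carrying amplification loci.
#'
#' @param n_genes Number of genes.
#' @param regions_per_gene Exon regions per gene.
#' @param region_length Mean exon region length (bp); individual lengths vary
#'   uniformly between 60% and 180% of it.
#' @param cnv_gene_ids Gene ids (of the form `gene0001`...) that carry
#'   amplifications; only used to label families.
#' @return List with `genes` and `regions` tibbles (0-based half-open
#'   coordinates).
#' @export
simulate_gene_panel <- function(n_genes, regions_per_gene = 4,
                                region_length = 150,
                                cnv_gene_ids = character(0)) {
  fams <- c("P450", "GST", "CCE", "UDPGT", "SULT", "ABC", "ADH")
  gene_id <- sprintf("gene%04d", seq_len(n_genes))
  gene_start <- seq_len(n_genes) * 20000L
  genes <- tibble::tibble(
    gene_id = gene_id,
    name = toupper(gene_id),
    family = fams[(seq_len(n_genes) - 1L) %% length(fams) + 1L],
    chrom = "chrS", start = gene_start, end = gene_start + 5000L
  )
  regions <- tidyr::expand_grid(gene_id = gene_id,
                                exon = seq_len(regions_per_gene)) %>%
    dplyr::left_join(genes %>% dplyr::select("gene_id", "chrom",
                                             gstart = "start"),
                     by = "gene_id") %>%
    dplyr::mutate(
      length = as.integer(round(runif(dplyr::n(), 0.6, 1.8) * region_length)),
      start = .data$gstart + (.data$exon - 1L) * 1000L,
      end = .data$start + .data$length,
      region_id = sprintf("%s_e%d", .data$gene_id, .data$exon),
      kind = "exon"
    ) %>%
    dplyr::select("region_id", "chrom", "start", "end", "kind", "gene_id",
                  "length")
  list(genes = genes, regions = regions)
}

#' Simulate capture coverage over exon regions
#'
#' Region mean depth is negative binomial with expectation
#' `base_depth * library_factor * region_factor * (pool mean copy number / 2)`;
#' genes without an amplification locus sit at the diploid baseline (mean
#' pool copy number 2). Library and capture-efficiency factors are lognormal
#' and shared across conditions (region factor) or loci (library factor), so
#' the downstream normalization can remove them.
#'
#' @param design A `cross_design` whose loci include `cnv_gene` rows with
#'   `gene_id` matching `regions$gene_id`.
#' @param regions Exon region tibble ([simulate_gene_panel()]).
#' @param base_depth Baseline mean depth (reads/bp) at diploid copy number.
#' @param coverage_size Negative-binomial size of depth noise.
#' @param library_sd,region_sd Lognormal sd (log scale) of the library and
#'   region capture factors.
#' @return List with `coverage` (tibble `region_id`, `condition`, `depth`)
#'   and `library_sizes` (tibble `condition`, `library_size`).
#' @export
simulate_coverage <- function(design, regions, base_depth = 100,
                              coverage_size = 100,
                              library_sd = 0.15, region_sd = 0.25) {
  loci <- design$loci
  cnv <- loci[loci$locus_class == "cnv_gene", , drop = FALSE]
  conds <- condition_levels()
  lib_factor <- setNames(rlnorm(length(conds), 0, library_sd), conds)
  region_factor <- setNames(rlnorm(nrow(regions), 0, region_sd),
                            regions$region_id)
  cn_by_gene <- function(cond) {
    cn <- setNames(rep(2, nrow(regions)), regions$gene_id)
    if (nrow(cnv) > 0) {
      pool_cn <- pop_copy_number(design$pools[[cond]], loci)
      idx <- match(regions$gene_id, cnv$gene_id)
      hit <- !is.na(idx)
      cn[hit] <- pool_cn[which(loci$locus_class == "cnv_gene")][idx[hit]]
    }
    unname(cn)
  }
  cov <- lapply(conds, function(cond) {
    mu <- base_depth * lib_factor[cond] * region_factor * cn_by_gene(cond) / 2
    tibble::tibble(
      region_id = regions$region_id, condition = cond,
      depth = rnbinom(nrow(regions), mu = mu, size = coverage_size)
    )
  })
  cov <- dplyr::bind_rows(cov)
  lib <- cov %>%
    dplyr::left_join(regions %>% dplyr::select("region_id", "length"),
                     by = "region_id") %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(library_size = round(sum(.data$depth * .data$length)),
                     .groups = "drop")
  list(coverage = cov, library_sizes = lib)
}
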