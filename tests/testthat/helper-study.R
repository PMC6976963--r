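# Study-condition builders shared by the recovery tests: causal SNPs with a
# 3-fold LD50 shift per allele spread over the three lines among neutral
# intergenic loci, and amplified causal genes among diploid-flat panel genes.

recovery_snp_loci <- function(n_neutral = 5000, beta = log10(3),
                              founder = 0.5) {
  lines10 <- c(rep("Delt", 4), rep("Bend", 3), rep("Feni", 3))
  causal <- locus_spec(
    chrom = "chrC", pos = 1000L * seq_along(lines10),
    founder_freq = founder,
    beta_Delt = ifelse(lines10 == "Delt", beta, 0),
    beta_Bend = ifelse(lines10 == "Bend", beta, 0),
    beta_Feni = ifelse(lines10 == "Feni", beta, 0),
    effect = "nonsynonymous"
  )
  neutral <- locus_spec(
    chrom = rep(c("chr1", "chr2", "chr3"), length.out = n_neutral),
    pos = 50000L * (seq_len(n_neutral) + 2L),
    founder_freq = runif(n_neutral, 0.05, 0.95),
    susceptible_freq = runif(n_neutral),
    effect = "intergenic"
  )
  list(loci = dplyr::bind_rows(causal, neutral) %>%
         dplyr::arrange(chrom, pos),
       causal_line = tibble::tibble(chrom = "chrC",
                                    pos = 1000L * seq_along(lines10),
                                    line = lines10))
}

recovery_cnv_setup <- function(n_neutral_genes = 200, k = 3L,
                               founder = 0.3, beta = 1.0) {
  lines5 <- c("Delt", "Delt", "Bend", "Bend", "Feni")
  panel <- simulate_gene_panel(n_neutral_genes + 5)
  causal_genes <- panel$genes$gene_id[1:5]
  loci <- locus_spec(
    chrom = "chrS",
    pos = panel$genes$start[1:5] + 1L,
    locus_class = "cnv_gene",
    founder_freq = founder, cnv_copies = k,
    beta_Delt = ifelse(lines5 == "Delt", beta, 0),
    beta_Bend = ifelse(lines5 == "Bend", beta, 0),
    beta_Feni = ifelse(lines5 == "Feni", beta, 0),
    ref = "A", alt = "<DUP>", gene_id = causal_genes
  )
  list(loci = loci, panel = panel,
       causal = tibble::tibble(gene_id = causal_genes, line = lines5))
}

# read counts for a two-pool contrast embedded in the 13-condition layout
two_pool_counts <- function(alt_f0, alt_ld80, depth) {
  L <- length(alt_f0)
  dplyr::bind_rows(lapply(condition_levels(), function(cc) {
    altn <- if (cc == "Delt_F0_LD80") alt_ld80 else alt_f0
    tibble::tibble(chrom = "c", pos = seq_len(L) * 10L, ref = "A", alt = "T",
                   effect = "intergenic", condition = cc,
                   ref_reads = depth - altn, alt_reads = altn)
  }))
}
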