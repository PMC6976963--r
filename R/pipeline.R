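#' Simulate a complete synthetic study
#'
#' Builds a locus table emulating the targeted capture panel (neutral
#' intergenic SNPs spread along three chromosomes, per-line causal
#' nonsynonymous SNPs inside candidate genes including three kdr-style
#' target-site loci, and per-line amplified genes), runs the cross /
#' dose-segregation design, and simulates pooled read counts and capture
#' coverage.
#'
#' Neutral intergenic loci draw founder frequencies uniformly on
#' `[0.05, 0.95]` and independent susceptible-strain frequencies uniformly on
#' `[0, 1]`; causal alleles are absent from the susceptible strain.
#'
#' @param n_neutral Neutral SNP loci.
#' @param n_causal_per_line Causal SNPs per insecticide line.
#' @param causal_beta Tolerance shift per causal allele copy (log10 dose;
#'   default `log10(3)`, a 3-fold LD50 shift).
#' @param causal_founder_freq Founder frequency of causal SNPs.
#' @param n_genes Genes on the capture panel.
#' @param n_cnv_per_line Amplified causal genes per line.
#' @param cnv_copies Copies per amplification haplotype.
#' @param cnv_founder_freq Founder frequency of amplification alleles.
#' @param cnv_beta Tolerance shift per amplification allele copy.
#' @param model [tolerance_model()].
#' @param n_founders,census,pool_size Design sizes (see
#'   [run_cross_design()]).
#' @param depth_mean,depth_size,error_rate Read-count model (see
#'   [simulate_counts()]).
#' @param base_depth,coverage_size Coverage model (see
#'   [simulate_coverage()]).
#' @return List with `loci`, `design`, `counts`, `coverage`,
#'   `library_sizes`, `genes`, `regions`, `kdr_loci` and `truth_loci`
#'   (per-locus line assignment and causal flag).
#' @export
simulate_study <- function(n_neutral = 300, n_causal_per_line = 2,
                           causal_beta = log10(3),
                           causal_founder_freq = 0.5,
                           n_genes = 60, n_cnv_per_line = 1,
                           cnv_copies = 3, cnv_founder_freq = 0.3,
                           cnv_beta = 1.0,
                           model = tolerance_model(),
                           n_founders = 2000, census = 2000,
                           pool_size = 100,
                           depth_mean = 100, depth_size = 20,
                           error_rate = 0.001,
                           base_depth = 100, coverage_size = 100) {
  lines <- line_levels()
  panel <- simulate_gene_panel(n_genes)
  genes <- panel$genes
  # dedicate one gene to the sodium-channel target and the first genes of
  # the panel to causal variants
  n_causal <- n_causal_per_line * 3
  n_cnv <- n_cnv_per_line * 3
  stopifnot(n_genes >= n_causal + n_cnv + 1)
  genes$family[1] <- "target"
  genes$name[1] <- "VGSC"

  neutral <- tibble::tibble(
    chrom = rep(c("chr1", "chr2", "chr3"), length.out = n_neutral),
    pos = 50000L * (seq_len(n_neutral) + 2L),
    locus_class = "snp",
    ref = "A", alt = "T",
    founder_freq = runif(n_neutral, 0.05, 0.95),
    susceptible_freq = runif(n_neutral),
    beta_Delt = 0, beta_Bend = 0, beta_Feni = 0,
    cnv_copies = NA_integer_, dominance = 0.5,
    effect = "intergenic", gene_id = NA_character_, recomb = 0.5
  )

  causal_line <- rep(lines, each = n_causal_per_line)
  causal_gene <- genes$gene_id[seq_len(n_causal) + 1L]
  kdr_names <- c("V410L", "V1016I", "F1534C")
  causal <- tibble::tibble(
    chrom = "chrS",
    pos = genes$start[match(causal_gene, genes$gene_id)] + 100L,
    locus_class = "snp",
    ref = "G", alt = "A",
    founder_freq = causal_founder_freq,
    susceptible_freq = 0,
    beta_Delt = ifelse(causal_line == "Delt", causal_beta, 0),
    beta_Bend = ifelse(causal_line == "Bend", causal_beta, 0),
    beta_Feni = ifelse(causal_line == "Feni", causal_beta, 0),
    cnv_copies = NA_integer_, dominance = 0.5,
    effect = "nonsynonymous", gene_id = causal_gene, recomb = 0.5
  )
  # kdr-style target-site loci: high-frequency deltamethrin alleles on VGSC
  kdr <- tibble::tibble(
    chrom = "chrS",
    pos = genes$start[1] + c(410L, 1016L, 1534L),
    locus_class = "snp",
    ref = "C", alt = "T",
    founder_freq = 0.8,
    susceptible_freq = 0,
    beta_Delt = causal_beta, beta_Bend = 0, beta_Feni = 0,
    cnv_copies = NA_integer_, dominance = 0.5,
    effect = "nonsynonymous", gene_id = genes$gene_id[1], recomb = 0.5
  )
  cnv_gene <- genes$gene_id[seq_len(n_cnv) + 1L + n_causal]
  cnv_line <- rep(lines, each = n_cnv_per_line)
  cnv <- tibble::tibble(
    chrom = "chrS",
    pos = genes$start[match(cnv_gene, genes$gene_id)] + 1L,
    locus_class = "cnv_gene",
    ref = "A", alt = "<DUP>",
    founder_freq = cnv_founder_freq,
    susceptible_freq = 0,
    beta_Delt = ifelse(cnv_line == "Delt", cnv_beta, 0),
    beta_Bend = ifelse(cnv_line == "Bend", cnv_beta, 0),
    beta_Feni = ifelse(cnv_line == "Feni", cnv_beta, 0),
    cnv_copies = as.integer(cnv_copies), dominance = 0.5,
    effect = "unknown", gene_id = cnv_gene, recomb = 0.5
  )
  loci <- dplyr::bind_rows(neutral, causal, kdr, cnv) %>%
    dplyr::arrange(.data$chrom, .data$pos)
  validate_locus_spec(loci)

  design <- run_cross_design(loci, model, n_founders = n_founders,
                             census = census, pool_size = pool_size)
  counts <- simulate_counts(design, depth_mean, depth_size, error_rate)
  coverage <- simulate_coverage(design, panel$regions, base_depth,
                                coverage_size)

  causal_line_of <- function(l) {
    dplyr::case_when(l$beta_Delt != 0 ~ "Delt",
                     l$beta_Bend != 0 ~ "Bend",
                     l$beta_Feni != 0 ~ "Feni",
                     TRUE ~ NA_character_)
  }
  truth_loci <- loci %>%
    dplyr::mutate(
      id = paste0(.data$chrom, ":", .data$pos),
      line = causal_line_of(loci),
      causal = !is.na(causal_line_of(loci))
    ) %>%
    dplyr::select("id", "chrom", "pos", "locus_class", "gene_id", "line",
                  "causal")

  list(
    loci = loci, design = design, counts = counts,
    coverage = coverage$coverage, library_sizes = coverage$library_sizes,
    genes = genes, regions = panel$regions,
    kdr_loci = tibble::tibble(name = kdr_names, chrom = kdr$chrom,
                              pos = kdr$pos),
    truth_loci = truth_loci
  )
}

#' Run the full analysis pipeline on one synthetic study
#'
#' Chains the generator and every analysis stage with a single seed:
#' simulate -> CNV scan -> variant QC + trajectory filter -> Bayesian scans
#' (both contrasts of every line) -> integration, then writes every input
#' and result table under `out_dir`. Identical seeds produce byte-identical
#' output files.
#'
#' For synthetic data the CNV rule is applied on the normalized-ratio scale
#' (see [call_cnv_association()] and the methods vignette).
#'
#' @param out_dir Output directory.
#' @param seed Integer seed for all randomness.
#' @param study Named list of overrides passed to [simulate_study()].
#' @param scan A [scan_config()]; the default shortens the published chain
#'   schedule twenty-fold, which is ample for a few hundred loci.
#' @param q_threshold,window_bp Integration settings.
#' @param cnv_scale Profile scale of the CNV pass rule.
#' @return Invisibly, a list with all result tables, the study, the scans
#'   and the evaluation against truth.
#' @export
run_pipeline <- function(out_dir, seed = 1L, study = list(),
                         scan = scan_config("desk", desk_factor = 25),
                         q_threshold = 0.05, window_bp = 5e4,
                         cnv_scale = "ratio") {
  set.seed(seed)
  st <- do.call(simulate_study, study)

  cnv <- cnv_scan(st$coverage, st$regions, st$library_sizes, st$genes,
                  scale = cnv_scale)
  qc <- qc_filter_variants(st$counts)
  traj <- frequency_trajectories(st$counts) %>%
    dplyr::semi_join(qc$retained, by = c("chrom", "pos"))
  hits <- trajectory_filter(traj)

  scans <- list()
  regions <- list()
  for (line in line_levels()) {
    s0 <- bayes_scan(st$counts, fst_contrast(line, "F0"), scan)
    s2 <- bayes_scan(st$counts, fst_contrast(line, "F2"), scan)
    scans[[paste0(line, "_F0")]] <- s0
    scans[[paste0(line, "_F2")]] <- s2
    regions[[line]] <- select_regions(
      hits %>% dplyr::filter(.data$line == !!line),
      s0, s2, st$genes, window_bp, q_threshold
    )
  }
  regions <- dplyr::bind_rows(regions)
  scan_table <- dplyr::bind_rows(lapply(scans, tidy))

  cnv_sets <- lapply(setNames(line_levels(), line_levels()), function(l) {
    cnv$calls$gene_id[cnv$calls$line == l & cnv$calls$pass]
  })
  venn <- venn_counts(cnv_sets)
  nonsyn <- nonsyn_table(hits, st$genes, regions)
  kdr <- kdr_report(st$counts, st$kdr_loci)

  hit_calls <- hits %>%
    dplyr::filter(.data$verdict == "resistance") %>%
    dplyr::mutate(id = paste0(.data$chrom, ":", .data$pos)) %>%
    dplyr::select("id", "line")
  snp_truth <- st$truth_loci %>%
    dplyr::filter(.data$locus_class == "snp")
  cnv_truth <- st$truth_loci %>%
    dplyr::filter(.data$locus_class == "cnv_gene") %>%
    dplyr::mutate(id = .data$gene_id)
  all_gene_truth <- tibble::tibble(id = st$genes$gene_id) %>%
    dplyr::left_join(cnv_truth %>% dplyr::select("id", "line", "causal"),
                     by = "id") %>%
    dplyr::mutate(causal = !is.na(.data$causal) & .data$causal)
  cnv_calls <- cnv$calls %>%
    dplyr::filter(.data$pass) %>%
    dplyr::select(id = "gene_id", "line")
  evaluation <- dplyr::bind_rows(
    truth_eval(hit_calls, snp_truth, "trajectory"),
    truth_eval(cnv_calls, all_gene_truth, "cnv")
  )

  tables <- list(
    trajectories = traj,
    trajectory_hits = hits %>% dplyr::filter(.data$verdict != "none"),
    cnv_profiles = cnv$profiles,
    cnv_genes = cnv$calls %>% dplyr::filter(.data$pass),
    fst_scan = scan_table,
    selection_regions = regions,
    venn = venn,
    nonsyn_hits = nonsyn,
    kdr_report = kdr,
    truth = st$truth_loci,
    evaluation = evaluation
  )
  write_results(tables, out_dir)
  write_allele_counts(st$counts, file.path(out_dir, "counts.tsv"))
  readr::write_tsv(st$coverage, file.path(out_dir, "coverage.tsv"),
                   progress = FALSE)
  readr::write_tsv(st$library_sizes, file.path(out_dir, "library_sizes.tsv"),
                   progress = FALSE)
  readr::write_tsv(st$genes, file.path(out_dir, "genes.tsv"),
                   progress = FALSE)
  write_bed(st$regions, file.path(out_dir, "regions.bed"))

  invisible(structure(
    c(tables, list(study = st, scans = scans)),
    class = "poolcross_run"
  ))
}

#' @export
print.poolcross_run <- function(x, ...) {
  cat("<poolcross run>\n")
  cat(sprintf("  trajectory hits: %d\n", nrow(x$trajectory_hits)))
  cat(sprintf("  CNV genes passing: %d\n", nrow(x$cnv_genes)))
  cat(sprintf("  selection regions: %d\n", nrow(x$selection_regions)))
  print(x$evaluation)
  invisible(x)
}
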