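one_locus <- function(p = 0.5, beta = 0, susceptible = 0, h = 0.5) {
  locus_spec(chrom = "chr1", pos = 100L, founder_freq = p,
             susceptible_freq = susceptible, beta_Delt = beta,
             dominance = h)
}

test_that("founders follow Hardy-Weinberg at the requested frequencies", {
  loci <- one_locus(p = 1)
  pop <- simulate_founders(50, loci)
  expect_true(all(pop_genotypes(pop) == 2L))

  loci <- one_locus(p = 0.5)
  set.seed(1)
  pop <- simulate_founders(10000, loci)
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_lt(abs(pop_allele_freq(pop) - 0.5), 3 * se)

  set.seed(42)
  a <- simulate_founders(500, loci)
  set.seed(42)
  b <- simulate_founders(500, loci)
  expect_identical(a, b)
})

test_that("survival probability is the probit of tolerance minus log-dose", {
  m <- tolerance_model(mu0 = 0, sigma = 1)
  expect_equal(survival_probability(0, 1, m), 0.5)
  expect_lt(survival_probability(0, 1e6, m), 1e-5)
  # a carrier always out-survives a non-carrier at any dose
  for (d in c(0.01, 1, 100)) {
    expect_gt(survival_probability(1, d, m), survival_probability(0, d, m))
  }
  expect_error(survival_probability(0, 0, m), "positive")
  expect_error(survival_probability(0, -1, m), "positive")
})

test_that("find_ld matches the closed form and is monotone in mortality", {
  m <- tolerance_model(mu0 = 0.3, sigma = 0.4)
  # homogeneous population: all homozygous carriers with beta = 0.5
  loci <- one_locus(p = 1, beta = 0.5)
  pop <- simulate_founders(200, loci)
  ld50 <- find_ld(pop, loci, m, "Delt", 0.5)
  expect_equal(ld50, 10^(0.3 + 2 * 0.5), tolerance = 1e-6)
  ld25 <- find_ld(pop, loci, m, "Delt", 0.25)
  ld75 <- find_ld(pop, loci, m, "Delt", 0.75)
  expect_lt(ld25, ld75)
  # two equal subgroups: LD50 between the subgroup LD50s
  loci2 <- one_locus(p = 0.5, beta = 1)
  set.seed(3)
  pop2 <- simulate_founders(5000, loci2)
  ld <- find_ld(pop2, loci2, m, "Delt", 0.5)
  expect_gt(ld, 10^0.3)
  expect_lt(ld, 10^(0.3 + 2))
  expect_error(find_ld(pop, loci, m, "Delt", 1.5), "in \\(0, 1\\)")
})

test_that("selection leaves neutral loci untouched and enriches carriers", {
  m <- tolerance_model(sigma = 0.3)
  loci <- dplyr::bind_rows(
    one_locus(p = 0.5, beta = log10(3)),
    locus_spec(chrom = "chr2", pos = 5L, founder_freq = 0.5)
  )
  set.seed(9)
  pop <- simulate_founders(3000, loci)
  # dose -> 0: everyone survives
  all_alive <- select_survivors(pop, loci, m, "Delt", 1e-9)
  expect_equal(pop_size(all_alive), 3000)

  # analytic oracle for the causal locus: survivor frequency is the
  # survival-weighted genotype frequency at the chosen dose
  dose <- find_ld(pop, loci, m, "Delt", 0.8)
  g <- pop_genotypes(pop)[, 1]
  w <- survival_probability(g * log10(3), dose, m)
  expected <- sum(g / 2 * w) / sum(w)
  reps <- replicate(40, {
    surv <- select_survivors(pop, loci, m, "Delt", dose)
    c(pop_allele_freq(surv)[1], pop_allele_freq(surv)[2])
  })
  se1 <- sd(reps[1, ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps[1, ]) - expected), 4 * se1)
  expect_gt(expected, 0.5) # enrichment over the census frequency
  # neutral locus: survivor frequency within 3 SE of the census frequency
  se2 <- sd(reps[2, ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps[2, ]) - pop_allele_freq(pop)[2]), 3 * se2)
})

test_that("crosses are Mendelian and unlinked loci assort independently", {
  loci <- one_locus()
  hom <- new_pop_for_test(n = 30, g = 2L)
  non <- new_pop_for_test(n = 30, g = 0L)
  off <- cross_populations(hom, non, 100, loci)
  expect_true(all(pop_genotypes(off) == 1L))
  expect_equal(pop_allele_freq(off), 0.5, ignore_attr = TRUE)

  # two unlinked loci: offspring two-locus haplotype frequencies factorize
  loci2 <- dplyr::bind_rows(
    locus_spec("chr1", 1L, founder_freq = 0.5),
    locus_spec("chr1", 2L, founder_freq = 0.5, recomb = 0.5)
  )
  set.seed(11)
  parents <- simulate_founders(2000, loci2)
  off2 <- cross_populations(pop_females(parents), pop_males(parents),
                            10000, loci2)
  h <- off2$hap1
  tab <- table(h[, 1], h[, 2])
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 1e-4)
})

test_that("tight linkage keeps parental haplotypes together", {
  loci2 <- dplyr::bind_rows(
    locus_spec("chr1", 1L, founder_freq = 0.5),
    locus_spec("chr1", 2L, founder_freq = 0.5, recomb = 0.01)
  )
  # parent haplotypes in perfect repulsion: 1-0 and 0-1
  n <- 4000
  mothers <- structure(list(
    hap1 = cbind(rep(1L, n), rep(0L, n)),
    hap2 = cbind(rep(0L, n), rep(1L, n)),
    female = rep(TRUE, n)
  ), class = "poolcross_pop")
  set.seed(13)
  gam <- poolcross:::draw_gametes(mothers, seq_len(n), loci2)
  recombinant <- gam[, 1] == gam[, 2]
  expect_lt(mean(recombinant), 0.03) # ~1% recombinants expected
})

test_that("the full design yields 13 pools and exact truth bookkeeping", {
  loci <- dplyr::bind_rows(
    one_locus(p = 0.6, beta = 0),
    locus_spec("chrS", 7L, locus_class = "cnv_gene", founder_freq = 0.4,
               cnv_copies = 3L, gene_id = "g1")
  )
  set.seed(21)
  des <- run_cross_design(loci, tolerance_model())
  expect_equal(names(des$pools), condition_levels())
  expect_true(all(vapply(des$pools, pop_size, integer(1)) == 100))
  # truth equals the realized pool frequencies exactly
  for (cond in condition_levels()) {
    tr <- des$truth[des$truth$condition == cond, ]
    expect_equal(tr$freq, unname(pop_allele_freq(des$pools[[cond]])))
    expect_equal(tr$copy_number,
                 unname(pop_copy_number(des$pools[[cond]], loci)))
  }
  # neutral loci dilute towards p/2 at F2 (Mendelian, within noise)
  f2 <- des$census[des$census$stage == "F2" & des$census$pos == 100, ]
  expect_true(all(abs(f2$freq - 0.3) < 0.1))
})

test_that("read counts follow the binomial error model", {
  loci <- dplyr::bind_rows(
    one_locus(p = 1, susceptible = 1),       # fixed alt everywhere: f = 1
    locus_spec("chr2", 9L, founder_freq = 0) # absent alt: f = 0
  )
  set.seed(31)
  des <- run_cross_design(loci, tolerance_model())
  counts0 <- simulate_counts(des, depth_mean = 1000, depth_size = 1e6,
                             error_rate = 0)
  l0 <- counts0[counts0$pos == 9, ]
  expect_true(all(l0$alt_reads == 0))
  l1 <- counts0[counts0$pos == 100, ]
  expect_true(all(l1$ref_reads == 0))
  # error rate pushes expected alt count to depth * e at f = 0
  counts_e <- simulate_counts(des, depth_mean = 1000, depth_size = 1e6,
                              error_rate = 0.01)
  le <- counts_e[counts_e$pos == 9, ]
  expect_lt(abs(mean(le$alt_reads) - 10), 3 * sqrt(10 / 13) + 1)
})

test_that("coverage scales with pool mean copy number", {
  loci <- locus_spec("chrS", 7L, locus_class = "cnv_gene",
                     founder_freq = 1, susceptible_freq = 1,
                     cnv_copies = 3L, gene_id = "gene0002")
  set.seed(41)
  des <- run_cross_design(loci, tolerance_model())
  panel <- simulate_gene_panel(10, regions_per_gene = 4)
  cov <- simulate_coverage(des, panel$regions, base_depth = 200,
                           coverage_size = 1e5, library_sd = 0,
                           region_sd = 0)
  cc <- cov$coverage %>%
    dplyr::left_join(panel$regions[, c("region_id", "gene_id")],
                     by = "region_id") %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(depth = mean(.data$depth))
  amp <- cc$depth[cc$gene_id == "gene0002"]
  base <- mean(cc$depth[cc$gene_id != "gene0002"])
  # pool fixed for a 3-copy amplification: genotype copy number 6, ratio 3
  expect_equal(amp / base, 3, tolerance = 0.05)
})
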