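test_that("frequencies come from read ratios with low-coverage flags", {
  counts <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L), ref = "A", alt = "T",
    effect = "x", condition = "F0",
    ref_reads = c(70L, 20L, 0L), alt_reads = c(30L, 5L, 0L)
  )
  f <- estimate_frequencies(counts)
  expect_equal(f$freq[1], 0.30)
  expect_false(f$flagged[1])
  expect_equal(f$freq[2], 0.20) # computed, but flagged at depth 25
  expect_true(f$flagged[2])
  expect_true(is.na(f$freq[3])) # zero depth: undefined + flagged
  expect_true(f$flagged[3])
})

test_that("variant QC drops monomorphic, low-difference and low-depth loci", {
  fb <- function(v) lapply(setNames(condition_levels(), condition_levels()),
                           function(cc) v)
  # identical frequency everywhere -> monomorphic
  same <- make_counts_fixed(fb(0.5), depth = 100L)
  got <- qc_filter_variants(same)
  expect_equal(nrow(got$retained), 0)
  expect_true("dropped_monomorphic" %in% got$report$verdict)

  # max pairwise difference 0.04 -> dropped
  f <- fb(0.50); f[["Delt_F2"]] <- 0.54
  close_ <- make_counts_fixed(f, depth = 100L)
  expect_equal(nrow(qc_filter_variants(close_)$retained), 0)

  # depths all 31, frequency range 0.10-0.60 -> kept
  f2 <- fb(0.1); f2[["F0"]] <- 0.6
  spread <- make_counts_fixed(f2, depth = 31L)
  expect_equal(nrow(qc_filter_variants(spread)$retained), 1)

  # depth exactly 30 in one condition fails the strict depth rule
  low <- make_counts_fixed(f2, depth = 31L)
  low$ref_reads[low$condition == "Feni_F2"] <- 15L
  low$alt_reads[low$condition == "Feni_F2"] <- 15L
  expect_equal(nrow(qc_filter_variants(low)$retained), 0)
})

test_that("trajectory filter reproduces the published worked examples", {
  spec <- trajectory_filter_spec()
  t1 <- trajectory_filter(make_traj(c(0.50, 0.66, 0.30, 0.40, 0.50), "Delt"),
                          spec)
  expect_equal(t1$verdict, "resistance")
  expect_equal(t1$band, "[0.30,0.85)")

  t2 <- trajectory_filter(make_traj(c(0.20, 0.66, 0.30, 0.40, 0.50), "Delt"),
                          spec)
  expect_equal(t2$verdict, "none") # below the Delt 30% floor

  t3 <- trajectory_filter(make_traj(c(0.60, 0.40, 0.70, 0.60, 0.40), "Bend"),
                          spec)
  expect_equal(t3$verdict, "deleterious") # complement passes

  # same initial frequency is a hit for Bend but not for Delt (0.15 floor)
  t4 <- trajectory_filter(make_traj(c(0.20, 0.40, 0.15, 0.25, 0.40), "Bend"),
                          spec)
  expect_equal(t4$verdict, "resistance")

  # flagged stages disqualify the locus
  tr <- make_traj(c(0.50, 0.66, 0.30, 0.40, 0.50), "Delt")
  tr$flagged <- TRUE
  t5 <- trajectory_filter(tr, spec)
  expect_equal(t5$verdict, "none")
  expect_equal(t5$reason, "low_coverage")
})

random_trajectories <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
    effect = "intergenic",
    line = sample(c("Delt", "Bend", "Feni"), n, replace = TRUE),
    f_F0 = runif(n), f_F0_LD80 = runif(n), f_F2 = runif(n),
    f_F2_LD25 = runif(n), f_F2_LD75 = runif(n), flagged = FALSE
  )
}

test_that("trajectory filter is reciprocal under complementation", {
  traj <- random_trajectories(2000, seed = 17)
  comp <- traj
  for (col in c("f_F0", "f_F0_LD80", "f_F2", "f_F2_LD25", "f_F2_LD75")) {
    comp[[col]] <- 1 - comp[[col]]
  }
  v1 <- trajectory_filter(traj)$verdict
  v2 <- trajectory_filter(comp)$verdict
  expect_identical(v1 == "resistance", v2 == "deleterious")
  expect_identical(v1 == "deleterious", v2 == "resistance")
})

test_that("kdr-style report matches the frequency estimates and warns on absent loci", {
  fb <- lapply(setNames(condition_levels(), condition_levels()),
               function(cc) c(0.8, 0.5))
  counts <- make_counts_fixed(fb, depth = 100L)
  named <- tibble::tibble(name = c("V410L", "missing"),
                          chrom = "chr1", pos = c(100L, 999L))
  expect_warning(rep_ <- kdr_report(counts, named), "missing")
  expect_true(all(rep_$name == "V410L"))
  expect_equal(nrow(rep_), 3 * 5) # 1 locus x 3 lines x 5 stages
  f <- estimate_frequencies(counts)
  merged <- merge(rep_, f, by = c("chrom", "pos", "condition"))
  expect_equal(merged$freq.x, merged$freq.y)
})

test_that("coding effects are annotated with the standard genetic code", {
  cds <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100L,
                        end = 112L, strand = "+",
                        seq = "GGAAAATTTCCC") # Gly Lys Phe Pro
  loci <- tibble::tibble(chrom = "chr1",
                         pos = c(103L, 101L, 105L, 120L, 500L),
                         ref = c("A", "G", "A", "A", "A"),
                         alt = c("G", "A", "", "T", "T"))
  loci$alt[3] <- "A" # placeholder, replaced below by a deletion
  loci$ref[3] <- "AA"
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 100L,
                          end = 112L, family = "P450")
  out <- annotate_effect(loci, cds, genes)
  expect_equal(out$effect[1], "synonymous")    # GGA -> GGG (codon pos 3)
  expect_equal(out$effect[2], "nonsynonymous") # GGA -> AGA (Gly -> Arg)
  expect_equal(out$effect[3], "frameshift")    # 1 bp deletion in CDS
  expect_equal(out$effect[4], "intergenic")    # past the gene
  expect_equal(out$effect[5], "intergenic")
  # upstream window
  up <- annotate_effect(tibble::tibble(chrom = "chr1", pos = 99L,
                                       ref = "A", alt = "T"),
                        cds = NULL, genes = genes)
  expect_equal(up$effect, "upstream")
  # malformed CDS warns and is skipped
  bad <- cds; bad$seq <- "GGAA"
  expect_warning(annotate_effect(loci[1, ], bad, genes), "multiple of 3")
})
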