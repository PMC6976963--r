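test_that("the design has exactly 13 conditions with valid line/stage pairs", {
  ct <- condition_table()
  expect_equal(nrow(ct), 13)
  expect_equal(sum(ct$stage == "F0"), 1)
  expect_equal(ct$line[ct$stage == "F0"], "none")
  expect_true(all(ct$line[ct$stage != "F0"] %in% c("Delt", "Bend", "Feni")))
  expect_equal(anyDuplicated(ct$condition), 0)
  expect_equal(length(line_conditions("Bend")), 5)
  expect_equal(line_conditions("Bend")[1], "F0")
})

test_that("wide counts TSV parses, validates and round-trips", {
  loci <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                         effect = "intergenic")
  cbc <- lapply(setNames(condition_levels(), condition_levels()),
                function(cc) cbind(70L, 30L))
  wide <- make_wide_counts(loci, cbc)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, tf)
  counts <- read_allele_counts(tf)
  expect_equal(nrow(counts), 13)
  expect_equal(counts$ref_reads + counts$alt_reads, rep(100L, 13))
  expect_equal(unique(counts$pos), 100L)
  # round trip preserves 1-based positions and counts
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_allele_counts(counts, tf2)
  again <- read_allele_counts(tf2)
  expect_equal(again, counts)
})

test_that("missing condition columns and bad counts are fatal with context", {
  loci <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                         effect = "x")
  cbc <- lapply(setNames(condition_levels(), condition_levels()),
                function(cc) cbind(70L, 30L))
  wide <- make_wide_counts(loci, cbc)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide[, setdiff(names(wide), c("Feni_F2_ref",
                                                 "Feni_F2_alt"))], tf)
  expect_error(read_allele_counts(tf), "Feni_F2")

  wide_bad <- wide
  wide_bad$Delt_F2_ref <- -1L
  readr::write_tsv(wide_bad, tf)
  expect_error(read_allele_counts(tf), "chr1:100")
})

test_that("an empty counts file with a valid header yields an empty table", {
  loci <- tibble::tibble(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         effect = character())
  cbc <- lapply(setNames(condition_levels(), condition_levels()),
                function(cc) cbind(integer(0), integer(0)))
  wide <- make_wide_counts(loci, cbc)
  tf <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, tf)
  counts <- read_allele_counts(tf)
  expect_equal(nrow(counts), 0)
})

test_that("minimal VCF input with AD fields parses and reduces multi-allelics", {
  skip_if_not_installed("vcfR")
  tf <- withr::local_tempfile(fileext = ".vcf")
  samples <- condition_levels()
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  row1 <- paste(c("chr1", "100", ".", "A", "T", ".", "PASS", ".", "GT:AD",
                  rep("0/1:70,30", 13)), collapse = "\t")
  # multi-allelic: third allele barely supported, should be dropped
  row2 <- paste(c("chr1", "200", ".", "G", "A,C", ".", "PASS", ".", "GT:AD",
                  rep("0/1:50,49,1", 13)), collapse = "\t")
  writeLines(c(header, row1, row2), tf)
  expect_warning(counts <- read_allele_counts(tf), "multi-allelic")
  expect_equal(nrow(counts), 26)
  l2 <- counts[counts$pos == 200, ]
  expect_equal(unique(l2$ref), "G")
  expect_equal(unique(l2$alt), "A")
  expect_equal(unique(l2$ref_reads + l2$alt_reads), 99L)
})

test_that("BED regions keep 0-based half-open coordinates on a round trip", {
  reg <- tibble::tibble(region_id = "r1", chrom = "chr2", start = 10L,
                        end = 230L, kind = "intergenic",
                        gene_id = NA_character_, length = 220L)
  tf <- withr::local_tempfile(fileext = ".bed")
  write_bed(reg, tf)
  line <- readLines(tf)
  expect_equal(strsplit(line, "\t")[[1]][1:3], c("chr2", "10", "230"))
  again <- read_regions_bed(tf)
  expect_equal(again$start, 10L)
  expect_equal(again$end, 230L)
  expect_true(is.na(again$gene_id))
})

test_that("result tables survive write/read to six significant digits", {
  tf <- withr::local_tempdir()
  scan <- tibble::tibble(chrom = "chr1", pos = 1:100,
                         fst = runif(100), q = runif(100))
  write_results(list(fst_scan = scan,
                     trajectory_hits = scan[0, ]), tf)
  expect_true(file.exists(file.path(tf, "trajectory_hits.tsv")))
  # header-only file for the empty hit set
  expect_equal(length(readLines(file.path(tf, "trajectory_hits.tsv"))), 1)
  again <- readr::read_tsv(file.path(tf, "fst_scan.tsv"),
                           show_col_types = FALSE)
  expect_equal(again$fst, scan$fst, tolerance = 1e-6)
  expect_equal(again$q, scan$q, tolerance = 1e-6)
})

test_that("config round-trips losslessly through YAML and rejects bad values", {
  cfg <- pipeline_config(cnv = list(t1 = 0.4), seed = 99L)
  tf <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, tf)
  again <- read_config(tf)
  expect_equal(unclass(again), unclass(cfg))
  expect_error(pipeline_config(cnv = list(t1 = -1)), "positive")
  expect_error(pipeline_config(region_qc = list(min_depth = 900)),
               "min_depth < max_depth")
})
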