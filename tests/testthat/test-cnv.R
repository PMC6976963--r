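cov_for <- function(depths_by_region, length_by_region) {
  # depths_by_region: named list region -> vector of 13 depths (or scalar)
  cov <- dplyr::bind_rows(lapply(names(depths_by_region), function(r) {
    tibble::tibble(region_id = r, condition = condition_levels(),
                   depth = rep(depths_by_region[[r]], length.out = 13))
  }))
  regions <- tibble::tibble(region_id = names(depths_by_region),
                            gene_id = names(depths_by_region),
                            length = unlist(length_by_region))
  list(coverage = cov, regions = regions)
}

test_that("region QC applies the printed bounds exactly", {
  d <- cov_for(
    list(r45 = 94.1, r46 = 94.1, rlow = c(29.9, rep(94.1, 12)),
         rhigh = c(rep(94.1, 12), 800.1), redge = c(30, rep(800, 12))),
    list(r45 = 45L, r46 = 46L, rlow = 46L, rhigh = 46L, redge = 46L)
  )
  got <- filter_regions(d$coverage, d$regions)
  expect_setequal(got$retained, c("r46", "redge")) # bounds inclusive
  expect_false("r45" %in% got$retained)            # length strictly > 45
  expect_false("rlow" %in% got$retained)
  expect_false("rhigh" %in% got$retained)
})

test_that("normalization removes library effects and centres regions at 1", {
  # two samples, equal library sizes, depths (100, 300) -> (0.5, 1.5)
  cov <- tibble::tibble(region_id = "r", condition = c("s1", "s2"),
                        depth = c(100, 300))
  lib <- tibble::tibble(condition = c("s1", "s2"), library_size = c(1e6, 1e6))
  out <- normalize_copy_number(cov, lib, "r")
  expect_equal(sort(out$normalized), c(0.5, 1.5))

  # depths proportional to library size -> all normalized values 1
  cov2 <- tibble::tibble(region_id = "r", condition = c("s1", "s2"),
                         depth = c(100, 200))
  lib2 <- tibble::tibble(condition = c("s1", "s2"),
                         library_size = c(1e6, 2e6))
  out2 <- normalize_copy_number(cov2, lib2, "r")
  expect_equal(out2$normalized, c(1, 1))

  # construction property on a random table: per-region means are 1
  set.seed(2)
  cov3 <- tidyr::expand_grid(region_id = sprintf("r%02d", 1:50),
                             condition = condition_levels())
  cov3$depth <- runif(nrow(cov3), 30, 800)
  lib3 <- tibble::tibble(condition = condition_levels(),
                         library_size = runif(13, 5e5, 2e6))
  out3 <- normalize_copy_number(cov3, lib3, unique(cov3$region_id))
  means <- tapply(out3$normalized, out3$region_id, mean)
  expect_true(all(abs(means - 1) < 1e-9))
})

test_that("gene profiles are centre-reduced with population sd, flat genes degenerate", {
  vals <- c(5, rep(1, 12)) # one elevated condition
  norm <- tibble::tibble(region_id = "r1", condition = condition_levels(),
                         normalized = vals)
  regions <- tibble::tibble(region_id = "r1", gene_id = "g1")
  prof <- gene_profiles(norm, regions)
  expect_equal(mean(prof$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(prof$z^2)), 1, tolerance = 1e-12) # denominator n
  expect_equal(prof$condition[which.max(prof$z)], "F0")
  expect_gt(max(prof$z), 0)

  flat <- gene_profiles(
    tibble::tibble(region_id = "r2", condition = condition_levels(),
                   normalized = 1),
    tibble::tibble(region_id = "r2", gene_id = "g2")
  )
  expect_true(all(flat$degenerate))
  expect_true(all(flat$z == 0))
})

test_that("the CNV pass rule evaluates the printed inequalities strictly", {
  prof_from_line_values <- function(v) {
    # v: c(F0, F0_LD80, F2, F2_LD25, F2_LD75) for the Delt line; other
    # conditions held at 0 on the z scale (values passed straight through)
    vals <- setNames(rep(0, 13), condition_levels())
    vals[line_conditions("Delt")] <- v
    tibble::tibble(gene_id = "g", condition = names(vals),
                   normalized = unname(vals), z = unname(vals),
                   degenerate = FALSE)
  }
  pass_of <- function(v) {
    call_cnv_association(prof_from_line_values(v), "Delt")$pass
  }
  expect_true(pass_of(c(0.00, 0.35, 0.10, 0.35, 0.20)))
  expect_false(pass_of(c(0.00, 0.30, 0.10, 0.35, 0.20))) # boundary, strict
  expect_false(pass_of(c(0.00, 0.40, 0.50, 0.80, 0.90))) # F0_LD80 < F2
  # degenerate profiles never pass
  degen <- prof_from_line_values(c(0, 10, 0, 10, 10))
  degen$degenerate <- TRUE
  expect_false(call_cnv_association(degen, "Delt")$pass)
  # missing condition is fatal
  expect_error(
    call_cnv_association(prof_from_line_values(c(0, 1, 0, 1, 1))[-2, ],
                         "Delt"),
    "missing"
  )
})

test_that("the pass rule agrees with its brute-force transcription and is monotone", {
  prof <- random_profiles(2000, seed = 14)
  for (line in c("Delt", "Bend", "Feni")) {
    got <- call_cnv_association(prof, line)
    want <- vapply(seq_len(nrow(got)), function(i) {
      v <- as.numeric(got[i, line_conditions(line)])
      oracle_cnv_pass(v[1], v[2], v[3], v[4], v[5])
    }, logical(1))
    expect_identical(got$pass, want)
  }

  # raising z[F0_LD80] (others fixed) never flips pass -> fail
  prof2 <- random_profiles(500, seed = 15)
  before <- call_cnv_association(prof2, "Feni")
  bump <- prof2
  i80 <- bump$condition == "Feni_F0_LD80"
  set.seed(16)
  bump$z[i80] <- bump$z[i80] + abs(rnorm(sum(i80)))
  bump$normalized <- bump$z
  after <- call_cnv_association(bump, "Feni")
  expect_false(any(before$pass & !after$pass))
})
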