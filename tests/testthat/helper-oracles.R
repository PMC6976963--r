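suppressMessages(library(dplyr))

# population with every individual carrying genotype g at each locus
new_pop_for_test <- function(n, g, L = 1L, female = TRUE) {
  h1 <- matrix(as.integer(g >= 1), n, L)
  h2 <- matrix(as.integer(g >= 2), n, L)
  structure(list(hap1 = h1, hap2 = h2, female = rep(female, n)),
            class = "poolcross_pop")
}

# Independent brute-force transcriptions of the published decision rules.
# These are deliberately written as literal, scalar re-statements of the
# printed conditions, independent of the package implementation.

# CNV pass rule: (F0LD80-F0)>0.3 AND (F0LD80-F2)>0 AND
# [(F2LD25-F2)>0.2 OR (F2LD75-F2)>0.2]
oracle_cnv_pass <- function(f0, f0ld80, f2, f2ld25, f2ld75,
                            t1 = 0.3, t2 = 0.2) {
  a <- (f0ld80 - f0) > t1
  b <- (f0ld80 - f2) > 0
  c <- ((f2ld25 - f2) > t2) || ((f2ld75 - f2) > t2)
  a && b && c
}

# one direction of the trajectory table: initial-frequency bands with their
# minimum F0 -> F0_LD80 rise, decrease after outcrossing, rises with dose,
# and the same minimum on the F2 -> F2_LD75 rise
oracle_traj_one_direction <- function(f, line) {
  f0 <- f[1]; f80 <- f[2]; f2 <- f[3]; f25 <- f[4]; f75 <- f[5]
  floor0 <- if (line == "Delt") 0.30 else 0.15
  if (f0 >= floor0 && f0 < 0.85) {
    need <- 0.15
  } else if (f0 >= 0.85 && f0 < 0.90) {
    need <- 0.10
  } else if (f0 >= 0.90 && f0 < 0.95) {
    need <- 0.05
  } else if (f0 >= 0.95 && f0 <= 1) {
    need <- 0 # any increase
  } else {
    return(FALSE)
  }
  rise_ok <- if (need > 0) (f80 - f0) >= need else (f80 - f0) > 0
  final_ok <- if (need > 0) (f75 - f2) >= need else (f75 - f2) > 0
  rise_ok && (f2 < f80) && (f25 > f2) && (f75 > f25) && final_ok
}

# full verdict, with the reciprocal rule for deleterious alleles
oracle_trajectory <- function(f, line) {
  if (oracle_traj_one_direction(f, line)) return("resistance")
  if (oracle_traj_one_direction(1 - f, line)) return("deleterious")
  "none"
}

# wide counts fixture: one row per locus, two count columns per condition
make_wide_counts <- function(loci, counts_by_condition) {
  wide <- loci
  for (cc in poolcross::condition_levels()) {
    m <- counts_by_condition[[cc]]
    wide[[paste0(cc, "_ref")]] <- m[, 1]
    wide[[paste0(cc, "_alt")]] <- m[, 2]
  }
  wide
}

# counts tibble where every condition has the given per-locus depth and
# alt frequency (deterministic, exact counts)
make_counts_fixed <- function(freqs_by_condition, depth = 100L,
                              chrom = "chr1") {
  L <- length(freqs_by_condition[[1]])
  dplyr::bind_rows(lapply(poolcross::condition_levels(), function(cc) {
    f <- freqs_by_condition[[cc]]
    altn <- as.integer(round(f * depth))
    tibble::tibble(chrom = chrom, pos = seq_len(L) * 100L, ref = "A",
                   alt = "T", effect = "intergenic", condition = cc,
                   ref_reads = depth - altn, alt_reads = altn)
  }))
}

# trajectory tibble from explicit stage frequencies, one line
make_traj <- function(f, line, effect = "intergenic") {
  tibble::tibble(
    chrom = "chr1", pos = 100L, ref = "A", alt = "T", effect = effect,
    line = line, f_F0 = f[1], f_F0_LD80 = f[2], f_F2 = f[3],
    f_F2_LD25 = f[4], f_F2_LD75 = f[5], flagged = FALSE
  )
}

# random gene profiles, one row per gene x condition, on the z scale
random_profiles <- function(n, seed) {
  set.seed(seed)
  tidyr::expand_grid(gene_id = sprintf("g%05d", seq_len(n)),
                     condition = poolcross::condition_levels()) %>%
    dplyr::mutate(z = rnorm(dplyr::n()), normalized = z,
                  degenerate = FALSE)
}

# gene profile tibble from a named vector of 13 values (one per condition)
make_profile <- function(gene_id, values, degenerate = FALSE) {
  stopifnot(length(values) == 13)
  tibble::tibble(
    gene_id = gene_id, condition = poolcross::condition_levels(),
    normalized = values,
    z = if (degenerate) 0 else
      (values - mean(values)) / sqrt(mean((values - mean(values))^2)),
    degenerate = degenerate
  )
}
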